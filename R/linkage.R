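#' Pairwise locus-mismatch distribution
#'
#' For every pair of strains, counts the number of loci at which the two
#' multilocus genotypes differ. A locus "differs" between two strains iff
#' their unordered allele pairs are not identical (a heterozygote A/B matches
#' B/A; no partial credit for sharing one allele).
#'
#' @param gt a `genotype_table` whose strains are all complete at the same
#'   locus set (use [assign_mlgs()]'s exclusion to subset first).
#' @return list with `K` (integer vector of mismatch counts over all
#'   `choose(m, 2)` pairs, pairs ordered `(1,2), (1,3), ..., (m-1,m)`),
#'   `d` (per-locus proportion of pairs differing), `n_pairs`, `n_loci`.
#' @export
pairwise_mismatch <- function(gt) {
  codes <- genotype_codes(gt)
  if (anyNA(codes)) stop("all strains must have complete genotypes", call. = FALSE)
  m <- nrow(codes)
  if (m < 2) stop("need at least 2 strains", call. = FALSE)
  L <- ncol(codes)
  ut <- upper.tri(matrix(0, m, m))
  K <- integer(m * (m - 1) / 2)
  d <- numeric(L)
  for (j in seq_len(L)) {
    diffs <- outer(codes[, j], codes[, j], "!=")[ut]
    K <- K + diffs
    d[j] <- mean(diffs)
  }
  list(K = as.integer(K), d = d, n_pairs = length(K), n_loci = L)
}

# --- fast mismatch-variance engine -----------------------------------------
#
# Vd (population variance of pairwise mismatch counts) is computed from pair
# tallies without materializing the pair matrix. With X_j the indicator that
# a pair differs at locus j:
#   E[K]  = sum_j d_j
#   E[K^2]= sum_j d_j + 2 * sum_{j<k} S_jk / P
# where S_jk = #pairs differing at BOTH j and k, obtained by
# inclusion-exclusion from same-pair counts, which come from tabulating
# genotype classes (and joint classes). Only the joint term changes under
# locus-wise permutation, so the permutation loop is O(m) per locus pair.

vd_engine_prepare <- function(codes) {
  m <- nrow(codes)
  P <- m * (m - 1) / 2
  L <- ncol(codes)
  nlev <- integer(L)
  same <- numeric(L)
  cols <- vector("list", L)
  for (j in seq_len(L)) {
    f <- match(codes[, j], unique(codes[, j]))
    nlev[j] <- max(f)
    nc <- tabulate(f, nlev[j])
    same[j] <- sum(nc * (nc - 1)) / 2
    cols[[j]] <- f
  }
  list(m = m, P = P, L = L, cols = cols, nlev = nlev, same = same,
       d = 1 - same / P)
}

vd_from_cols <- function(eng, cols) {
  P <- eng$P
  sum_d <- sum(eng$d)
  cross <- 0
  for (j in seq_len(eng$L - 1)) {
    for (k in (j + 1):eng$L) {
      joint <- (cols[[j]] - 1L) * eng$nlev[k] + cols[[k]]
      tj <- tabulate(joint, eng$nlev[j] * eng$nlev[k])
      sboth <- sum(tj * (tj - 1)) / 2
      cross <- cross + (P - eng$same[j] - eng$same[k] + sboth)
    }
  }
  ek2 <- sum_d + 2 * cross / P
  ek2 - (sum_d)^2
}

#' Standardized index of association with Monte Carlo permutation test
#'
#' Compares the observed variance `Vd` of pairwise mismatch counts with the
#' variance `Ve = sum_j d_j (1 - d_j)` expected under linkage equilibrium:
#' `I_A^S = (1 / (n - 1)) * (Vd / Ve - 1)` with `n` the number of loci.
#' The null distribution is built by independently shuffling each locus
#' column across strains (which leaves `d_j`, and hence `Ve`, invariant) and
#' recomputing `Vd`. The p-value uses the add-one estimator
#' `p = (1 + #\{Vd_perm >= Vd_obs\}) / (1 + n_iterations)` so it is never 0.
#'
#' All strains are used as sampled (no clone correction). `Vd` is the
#' population variance (denominator = number of pairs); `d_j` is estimated
#' from observed pairs. Both conventions are isolated here so exact variants
#' can be swapped in.
#'
#' @param gt a `genotype_table`; strains with incomplete genotypes are
#'   dropped with a message.
#' @param n_iterations number of permutation replicates (default 1000).
#' @param seed integer seed; mandatory for reproducibility.
#' @return An `ia_result`: list with `vd`, `ve`, `ia_s`, `p_value`,
#'   `n_iterations`, `seed`, `n_strains`, `n_loci`, `undefined` (TRUE when
#'   every locus is monomorphic in the sample, in which case `ia_s` and
#'   `p_value` are `NA`).
#' @export
index_of_association <- function(gt, n_iterations = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  keep <- complete_rows(gt)
  if (!all(keep)) {
    message(sum(!keep), " strain(s) with incomplete genotypes dropped")
    gt <- gt[keep, , drop = FALSE]
  }
  codes <- genotype_codes(gt)
  m <- nrow(codes)
  if (m < 2) stop("need at least 2 complete strains", call. = FALSE)
  L <- ncol(codes)
  if (L < 2) stop("requires >=2 loci", call. = FALSE)

  eng <- vd_engine_prepare(codes)
  ve <- sum(eng$d * (1 - eng$d))
  vd <- vd_from_cols(eng, eng$cols)
  if (ve == 0) {
    return(structure(list(vd = vd, ve = 0, ia_s = NA_real_, p_value = NA_real_,
                          n_iterations = 0L, seed = seed, n_strains = m,
                          n_loci = L, undefined = TRUE), class = "ia_result"))
  }
  ia_s <- (1 / (L - 1)) * (vd / ve - 1)

  set.seed(seed)
  hits <- 0L
  cols <- eng$cols
  for (it in seq_len(n_iterations)) {
    perm <- lapply(cols, function(f) f[sample.int(m)])
    if (vd_from_cols(eng, perm) >= vd - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + n_iterations)
  structure(list(vd = vd, ve = ve, ia_s = ia_s, p_value = p,
                 n_iterations = as.integer(n_iterations), seed = seed,
                 n_strains = m, n_loci = L, undefined = FALSE),
            class = "ia_result")
}

#' @export
print.ia_result <- function(x, ...) {
  if (x$undefined) {
    cat("ia_result: UNDEFINED (all loci monomorphic; Ve = 0)\n")
  } else {
    cat(sprintf(
      "ia_result: I_A^S = %.4f (Vd = %.4f, Ve = %.4f), p = %.4g [%d permutations]\n",
      x$ia_s, x$vd, x$ve, x$p_value, x$n_iterations))
  }
  invisible(x)
}

#' Index of association per sampling date
#'
#' Runs [index_of_association()] on each date's strains; dates with fewer
#' than 3 complete strains or an undefined statistic get `NA`s.
#'
#' @param gt a `genotype_table`.
#' @param n_iterations permutations per date.
#' @param seed master seed; per-date seeds are derived deterministically.
#' @param alpha significance level for the reported flag.
#' @return data frame: date, n, vd, ve, ia_s, p_value, significant.
#' @export
ia_by_date <- function(gt, n_iterations = 1000, seed, alpha = 0.05) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dates <- sort(unique(gt$date))
  rows <- lapply(seq_along(dates), function(i) {
    sub <- gt[gt$date == dates[i], , drop = FALSE]
    attr(sub, "loci") <- loci_of(gt)
    class(sub) <- class(gt)
    n_cmp <- sum(complete_rows(sub))
    base <- data.frame(date = dates[i], n = n_cmp, vd = NA_real_, ve = NA_real_,
                       ia_s = NA_real_, p_value = NA_real_, significant = NA)
    if (n_cmp < 3) return(base)
    r <- suppressMessages(
      index_of_association(sub, n_iterations, seed = derive_seed(seed, i)))
    base$vd <- r$vd; base$ve <- r$ve
    if (!r$undefined) {
      base$ia_s <- r$ia_s; base$p_value <- r$p_value
      base$significant <- r$p_value <= alpha
    }
    base
  })
  do.call(rbind, rows)
}

#' Pearson correlation between two per-date series
#'
#' Drops positions where either value is undefined; requires at least 3
#' complete pairs. Returns `NA` (with a warning) when either series has zero
#' variance.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson product-moment correlation in `[-1, 1]`, or `NA`.
#' @export
correlate_series <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >=3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
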