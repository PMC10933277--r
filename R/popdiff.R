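#' Allele-frequency profile from diploid genotypes
#'
#' Each diploid strain contributes two gene copies per genotyped locus;
#' missing loci contribute nothing. Loci with zero observations are omitted
#' with a warning.
#'
#' @param gt a `genotype_table` (typically one sampling date).
#' @return An `afp` object: list of per-locus named frequency vectors (names
#'   are allele labels, values sum to 1), with per-locus sample sizes (gene
#'   copies) in `attr(x, "n")`.
#' @export
allele_freq_profile <- function(gt) {
  if (nrow(gt) == 0) stop("empty input", call. = FALSE)
  s <- allele_summary(gt)
  empty <- vapply(s, function(l) l$n == 0, logical(1))
  if (any(empty)) {
    warning("locus with zero observations omitted: ",
            paste(names(s)[empty], collapse = ", "))
    s <- s[!empty]
  }
  freqs <- lapply(s, `[[`, "freq")
  structure(freqs, n = vapply(s, function(l) 2L * l$n, integer(1)),
            class = "afp")
}

#' Allele-frequency profile from an MPB frequency table column
#'
#' Rescales normalized amplicon percentages for one sample (or merged date)
#' to sum to 1 per locus.
#'
#' @param freq_tables named list (by locus) of allele x sample percentage
#'   matrices, e.g. the `pct` component of [normalize_and_filter()] output;
#'   a single matrix is treated as one locus.
#' @param sample column name to extract.
#' @return an `afp` object.
#' @export
afp_from_mpb <- function(freq_tables, sample) {
  if (is.matrix(freq_tables)) freq_tables <- list(locus = freq_tables)
  freqs <- lapply(freq_tables, function(mat) {
    if (!sample %in% colnames(mat)) {
      stop("sample not found: ", sample, call. = FALSE)
    }
    v <- mat[, sample]
    v <- v[v > 0]
    if (sum(v) == 0) return(numeric(0))
    v / sum(v)
  })
  keep <- vapply(freqs, length, integer(1)) > 0
  if (!any(keep)) stop("no alleles observed for sample ", sample, call. = FALSE)
  if (any(!keep)) warning("locus with zero observations omitted: ",
                          paste(names(freqs)[!keep], collapse = ", "))
  structure(freqs[keep], n = vapply(freqs[keep], length, integer(1)),
            class = "afp")
}

#' Pairwise F_ST between two allele-frequency profiles
#'
#' Nei-style multilocus G_ST: for each shared locus, `Hs` is the unweighted
#' mean of the two within-sample expected heterozygosities `1 - sum(p^2)` and
#' `Ht` the expected heterozygosity of the unweighted mean frequency vector;
#' the multilocus value is `sum(Ht - Hs) / sum(Ht)`. The unweighted mean is
#' deliberate: sample sizes differ wildly between sampling dates. A small
#' negative (possible with near-identical profiles and rounding) is clipped
#' to 0 with a warning.
#'
#' @param a,b `afp` objects sharing at least one locus name.
#' @return F_ST in `[0, 1]`. When `sum(Ht) == 0` (both samples fixed for the
#'   same allele everywhere) returns 0 with attribute `flag = "ht_zero"`.
#' @export
pairwise_fst <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("no shared locus", call. = FALSE)
  ht_sum <- 0
  num_sum <- 0
  for (l in shared) {
    alleles <- union(names(a[[l]]), names(b[[l]]))
    pa <- stats::setNames(rep(0, length(alleles)), alleles)
    pb <- pa
    pa[names(a[[l]])] <- a[[l]]
    pb[names(b[[l]])] <- b[[l]]
    hs <- ((1 - sum(pa^2)) + (1 - sum(pb^2))) / 2
    pm <- (pa + pb) / 2
    ht <- 1 - sum(pm^2)
    ht_sum <- ht_sum + ht
    num_sum <- num_sum + (ht - hs)
  }
  if (ht_sum == 0) {
    return(structure(0, flag = "ht_zero"))
  }
  fst <- num_sum / ht_sum
  if (fst < 0) {
    if (fst < -1e-9) warning("negative F_ST estimate clipped to 0")
    fst <- 0
  }
  min(fst, 1)
}

#' Pairwise F_ST matrix over labelled profiles
#'
#' @param profiles named list of `afp` objects (labels become row/column
#'   names; duplicates are an error).
#' @return symmetric matrix with zero diagonal, class `fst_matrix`.
#' @export
fst_matrix <- function(profiles) {
  labels <- names(profiles)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("profiles must be uniquely labelled", call. = FALSE)
  }
  n <- length(profiles)
  if (n < 2) stop("need >=2 profiles", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- as.numeric(pairwise_fst(profiles[[i]], profiles[[j]]))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("fst_matrix", class(m)))
}

check_dist_matrix <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square matrix", call. = FALSE)
  if (anyNA(d)) stop("missing entries in distance matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) stop("matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: square the distances, double-centre
#' (`-1/2 * J %*% D^2 %*% J`), eigendecompose; coordinates are eigenvectors
#' scaled by the square root of their eigenvalue. Negative eigenvalues are
#' reported but excluded from the variance denominator; no Lingoes/Cailliez
#' correction is applied.
#'
#' @param d symmetric zero-diagonal distance matrix (e.g. an `fst_matrix`).
#' @return A `pcoa_result`: list with `coordinates` (samples x positive
#'   axes), `eigenvalues` (all, descending), `pct_variance` (per positive
#'   axis, sums to 100).
#' @export
pcoa <- function(d) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need >=2 samples", call. = FALSE)
  # we request all n-1 axes and prune by eigenvalue sign ourselves, so
  # cmdscale's "only k of the first eigenvalues are > 0" warning is expected
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  coords <- fit$points[, pos, drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    pct_variance = 100 * eig[pos] / sum(eig[pos])
  ), class = "pcoa_result")
}

#' Percolation network from a distance matrix
#'
#' The percolation threshold is the largest edge weight in the minimum
#' spanning tree of the distance matrix — equivalently, the minimal
#' threshold t such that the graph restricted to edges with distance <= t is
#' connected. Retained edges are all pairs at or below the threshold; the
#' display weight of an edge is the genetic similarity `1 - F_ST`.
#'
#' @param d symmetric zero-diagonal distance matrix with labelled rows.
#' @return A `percolation_network`: list with `nodes`, `threshold`, and
#'   `edges` (data frame: node_a, node_b, fst, similarity, in_mst).
#' @export
percolation_network <- function(d) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need >=2 nodes", call. = FALSE)
  labels <- rownames(d) %||% as.character(seq_len(n))
  # build the complete graph explicitly: zero distances are real edges too
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  g <- igraph::make_graph(t(pairs), n = n, directed = FALSE)
  mst <- igraph::mst(g, weights = d[pairs])
  mst_pairs <- igraph::as_edgelist(mst, names = FALSE)
  threshold <- max(d[mst_pairs])
  in_mst <- matrix(FALSE, n, n)
  in_mst[mst_pairs] <- TRUE
  in_mst <- in_mst | t(in_mst)

  idx <- which(upper.tri(d) & d <= threshold + 1e-12, arr.ind = TRUE)
  edges <- data.frame(
    node_a = labels[idx[, 1]],
    node_b = labels[idx[, 2]],
    fst = d[idx],
    similarity = 1 - d[idx],
    in_mst = in_mst[idx],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = labels, threshold = threshold, edges = edges),
            class = "percolation_network")
}

#' @export
print.percolation_network <- function(x, ...) {
  cat(sprintf("percolation_network: %d nodes, %d edges, threshold = %.4f\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Evanno delta-K from replicate ln-likelihoods
#'
#' Post-processes the ln-probability output of a Bayesian clustering run
#' (one value per replicate per K). The rate-of-change statistic is
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined only for interior K with positive replicate standard deviation;
#' the most supported K is the argmax of deltaK. Invariant to adding a
#' constant to all ln-probabilities.
#'
#' @param table data frame with columns `K` (integer) and `lnP` (replicate
#'   ln-probabilities, repeated rows per K), or a named list `K -> numeric`.
#' @return An `evanno_table`: data frame with columns `K`, `n_rep`, `mean`,
#'   `sd`, `delta_k`, plus attribute `best_k`.
#' @export
evanno_delta_k <- function(table) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- data.frame(
      K = rep(as.integer(names(table)), lengths(table)),
      lnP = unlist(table, use.names = FALSE))
  }
  stopifnot(all(c("K", "lnP") %in% names(table)))
  ks <- sort(unique(table$K))
  if (length(ks) < 3) stop("need >=3 K values", call. = FALSE)
  if (any(diff(ks) != 1)) stop("K values must be consecutive", call. = FALSE)
  n_rep <- vapply(ks, function(k) sum(table$K == k), integer(1))
  if (any(n_rep < 2)) {
    stop("need >=2 replicates per K for sd (K = ",
         paste(ks[n_rep < 2], collapse = ", "), ")", call. = FALSE)
  }
  mu <- vapply(ks, function(k) mean(table$lnP[table$K == k]), numeric(1))
  sdv <- vapply(ks, function(k) stats::sd(table$lnP[table$K == k]), numeric(1))
  dk <- rep(NA_real_, length(ks))
  interior <- 2:(length(ks) - 1)
  for (i in interior) {
    if (sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
    } else {
      warning("sd = 0 at K = ", ks[i], "; delta-K undefined there")
    }
  }
  out <- data.frame(K = ks, n_rep = n_rep, mean = mu, sd = sdv, delta_k = dk)
  best <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  structure(out, best_k = best, class = c("evanno_table", "data.frame"))
}
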