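# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive: materialize every pair, enumerate every permutation.

# genotype_table from a matrix of per-locus genotype codes: code k at locus j
# becomes the homozygote (100 + 2k, 100 + 2k), so distinct codes are distinct
# unordered allele pairs
gt_from_codes <- function(codes, date = "2020-01-01") {
  m <- nrow(codes)
  L <- ncol(codes)
  alle <- matrix(NA_integer_, m, 2 * L)
  for (j in seq_len(L)) {
    alle[, 2 * j - 1] <- 100L + 2L * codes[, j]
    alle[, 2 * j] <- 100L + 2L * codes[, j]
  }
  genotype_table(sprintf("s%02d", seq_len(m)), rep(date, m), alle,
                 paste0("L", seq_len(L)))
}

# random genotype table with alleles drawn independently per locus
# (linkage equilibrium)
random_le_gt <- function(m, L, n_alleles = 8, date = "2020-01-01") {
  alle <- matrix(sample(100L + 2L * seq_len(n_alleles), m * 2 * L,
                        replace = TRUE), m, 2 * L)
  genotype_table(sprintf("s%03d", seq_len(m)), rep(date, m), alle,
                 paste0("L", seq_len(L)))
}

# all pairs, counted one by one
naive_mismatch <- function(gt) {
  loci <- attr(gt, "loci")
  m <- nrow(gt)
  pairs <- utils::combn(m, 2)
  K <- integer(ncol(pairs))
  per_locus <- matrix(FALSE, ncol(pairs), length(loci))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    for (l in seq_along(loci)) {
      a1 <- gt[[paste0(loci[l], ".a1")]]
      a2 <- gt[[paste0(loci[l], ".a2")]]
      same <- identical(sort(c(a1[i], a2[i])), sort(c(a1[j], a2[j])))
      per_locus[p, l] <- !same
    }
    K[p] <- sum(per_locus[p, ])
  }
  d <- colMeans(per_locus)
  list(K = K, d = d)
}

naive_vd_ve <- function(gt) {
  mm <- naive_mismatch(gt)
  vd <- mean(mm$K^2) - mean(mm$K)^2     # population variance over pairs
  ve <- sum(mm$d * (1 - mm$d))
  list(vd = vd, ve = ve)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# exact permutation distribution of Vd under locus-wise shuffling: enumerate
# the full product space of per-locus permutations (feasible for <=5 strains,
# 2 loci); returns the exact p-value P(Vd_perm >= Vd_obs)
exhaustive_vd_p <- function(gt) {
  loci <- attr(gt, "loci")
  stopifnot(length(loci) == 2)
  m <- nrow(gt)
  obs <- naive_vd_ve(gt)$vd
  perms <- all_perms(m)
  hits <- 0L
  total <- 0L
  a1 <- gt[[paste0(loci[1], ".a1")]]; a2 <- gt[[paste0(loci[1], ".a2")]]
  b1 <- gt[[paste0(loci[2], ".a1")]]; b2 <- gt[[paste0(loci[2], ".a2")]]
  for (p1 in perms) {
    for (p2 in perms) {
      alle <- cbind(a1[p1], a2[p1], b1[p2], b2[p2])
      g <- genotype_table(sprintf("s%02d", 1:m), rep("2020-01-01", m),
                          alle, loci)
      vd <- naive_vd_ve(g)$vd
      total <- total + 1L
      if (vd >= obs - 1e-12) hits <- hits + 1L
    }
  }
  hits / total
}

# minimal threshold t such that the graph with edges {d <= t} is connected,
# found by scanning every candidate threshold with a hand-rolled BFS
brute_percolation_threshold <- function(d) {
  n <- nrow(d)
  cand <- sort(unique(d[upper.tri(d)]))
  connected_at <- function(t) {
    adj <- d <= t + 1e-12
    diag(adj) <- FALSE
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    length(seen) == n
  }
  for (t in cand) if (connected_at(t)) return(t)
  stop("no connecting threshold")
}

# exact two-sided binomial p-value against 0.5 by enumeration
exact_binom_p <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# fabricate long-format reads for the MPB caller
reads_df <- function(sequence, sample, count) {
  data.frame(sequence = sequence, sample = sample, count = count,
             stringsAsFactors = FALSE)
}

# a random symmetric zero-diagonal distance matrix
random_dist <- function(n, max_d = 1) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.01, max_d)
  d <- d + t(d)
  dimnames(d) <- list(paste0("n", 1:n), paste0("n", 1:n))
  d
}
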