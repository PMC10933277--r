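afp <- function(...) {
  # shorthand: afp(L1 = c(A = .5, B = .5), ...)
  structure(list(...), class = "afp")
}

test_that("allele_freq_profile counts gene copies", {
  alle <- rbind(c(100L, 100L), c(100L, 104L))
  gt <- genotype_table(c("a", "b"), rep("2020-01-01", 2), alle, "L1")
  p <- allele_freq_profile(gt)
  expect_equal(unname(p$L1[c("100", "104")]), c(0.75, 0.25))
  expect_error(allele_freq_profile(gt[0, ]), "empty")
})

test_that("afp_from_mpb rescales percentages to frequencies", {
  mat <- matrix(c(60, 40), 2, 1, dimnames = list(c("114.1", "116.1"), "s1"))
  p <- afp_from_mpb(list(PNm1 = mat), "s1")
  expect_equal(unname(p$PNm1), c(0.6, 0.4))
})

test_that("pairwise_fst matches hand-computed Nei G_ST", {
  a <- afp(L1 = c(A = 0.5, B = 0.5))
  b <- afp(L1 = c(A = 1))
  # Hs = (0.5 + 0)/2 = 0.25; mean p = (0.75, 0.25), Ht = 0.375
  expect_equal(pairwise_fst(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(pairwise_fst(a, a), 0)
  fixed_diff <- pairwise_fst(afp(L1 = c(A = 1)), afp(L1 = c(B = 1)))
  expect_equal(fixed_diff, 1)
  same_fixed <- pairwise_fst(afp(L1 = c(A = 1)), afp(L1 = c(A = 1)))
  expect_equal(as.numeric(same_fixed), 0)
  expect_equal(attr(same_fixed, "flag"), "ht_zero")
  expect_error(pairwise_fst(afp(L1 = c(A = 1)), afp(L2 = c(A = 1))),
               "shared")
})

test_that("pairwise_fst is symmetric and bounded on random profiles", {
  set.seed(17)
  rand_afp <- function() {
    f <- function() {
      v <- stats::runif(4)
      stats::setNames(v / sum(v), c("A", "B", "C", "D"))
    }
    afp(L1 = f(), L2 = f())
  }
  for (rep in 1:20) {
    a <- rand_afp(); b <- rand_afp()
    f1 <- as.numeric(pairwise_fst(a, b))
    f2 <- as.numeric(pairwise_fst(b, a))
    expect_equal(f1, f2, tolerance = 1e-12)
    expect_gte(f1, 0)
    expect_lte(f1, 1)
  }
})

test_that("fst_matrix builds labelled symmetric matrices", {
  p <- afp(L1 = c(A = 0.5, B = 0.5))
  m <- fst_matrix(list(x = p, y = p, z = p))
  expect_equal(unclass(m), matrix(0, 3, 3, dimnames = list(c("x", "y", "z"),
                                                           c("x", "y", "z"))),
               ignore_attr = TRUE)
  m2 <- fst_matrix(list(x = afp(L1 = c(A = 0.5, B = 0.5)),
                        y = afp(L1 = c(A = 1))))
  expect_equal(m2["x", "y"], 1 / 3, tolerance = 1e-12)
  expect_error(fst_matrix(list(x = p, x = p)), "label")
})

test_that("F_ST decreases monotonically with migration in a two-deme model", {
  # deterministic island model: demes start fixed for different alleles and
  # exchange a fraction mig of migrants per generation
  fst_at <- function(mig) {
    p1 <- c(A = 1, B = 0)
    p2 <- c(A = 0, B = 1)
    for (g in 1:5) {
      new1 <- (1 - mig) * p1 + mig * p2
      new2 <- (1 - mig) * p2 + mig * p1
      p1 <- new1; p2 <- new2
    }
    as.numeric(pairwise_fst(afp(L1 = p1), afp(L1 = p2)))
  }
  vals <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), fst_at, numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("pcoa recovers simple geometries", {
  # 2 samples at distance d: one axis, coordinates +/- d/2
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- pcoa(d2)
  expect_equal(ncol(r$coordinates), 1)
  expect_equal(sort(r$coordinates[, 1]), c(-0.3, 0.3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r$pct_variance, 100)

  # 3 equidistant samples: two equal positive eigenvalues, 50% each
  d3 <- matrix(0.5, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  suppressWarnings(r3 <- pcoa(d3))
  expect_equal(r3$pct_variance, c(50, 50), tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pcoa reproduces planted 2-D configurations", {
  set.seed(5)
  pts <- matrix(stats::rnorm(8), 4, 2)
  d <- as.matrix(stats::dist(pts))
  r <- pcoa(d)
  rec <- as.matrix(stats::dist(r$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # total positive-eigenvalue variance equals the centered-matrix trace
  dc <- scale(pts, center = TRUE, scale = FALSE)
  expect_equal(sum(r$eigenvalues[r$eigenvalues > 1e-8]), sum(dc^2),
               tolerance = 1e-8)
})

test_that("percolation_network keeps the minimal connecting edge set", {
  # equal distances: threshold d, complete graph retained
  d <- matrix(0.3, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  net <- percolation_network(d)
  expect_equal(net$threshold, 0.3)
  expect_equal(nrow(net$edges), 6)

  # genetically identical nodes (all distances zero) stay fully connected
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  netz <- percolation_network(z)
  expect_equal(netz$threshold, 0)
  expect_equal(nrow(netz$edges), 3)

  # 3 nodes: MST = {AB, BC}, AC pruned
  d3 <- matrix(c(0, .1, .9, .1, 0, .2, .9, .2, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net3 <- percolation_network(d3)
  expect_equal(net3$threshold, 0.2)
  expect_equal(nrow(net3$edges), 2)
  expect_false(any(net3$edges$node_a == "A" & net3$edges$node_b == "C"))
  expect_equal(net3$edges$similarity, 1 - net3$edges$fst)

  # two tight clusters joined by one bridge: bridge sets the threshold
  db <- matrix(0.9, 6, 6)
  db[1:3, 1:3] <- 0.05
  db[4:6, 4:6] <- 0.05
  db[3, 4] <- db[4, 3] <- 0.5
  diag(db) <- 0
  dimnames(db) <- list(paste0("n", 1:6), paste0("n", 1:6))
  expect_equal(percolation_network(db)$threshold, 0.5)

  dmiss <- d3; dmiss[1, 2] <- dmiss[2, 1] <- NA
  expect_error(percolation_network(dmiss), "missing")
})

test_that("MST threshold equals brute-force minimal connecting threshold", {
  set.seed(9)
  for (rep in 1:10) {
    d <- random_dist(8)
    expect_equal(percolation_network(d)$threshold,
                 brute_percolation_threshold(d), tolerance = 1e-12)
  }
})

test_that("evanno_delta_k finds planted structure and rejects degenerates", {
  # piecewise-linear means with a kink at K = 3, sd = 1
  mk <- function(mu) unlist(lapply(mu, function(m) m + c(-1, 0, 1)))
  mus <- c(-200, -150, -100, -95, -90)  # slope change at K = 3
  tab <- data.frame(K = rep(1:5, each = 3), lnP = mk(mus))
  ev <- evanno_delta_k(tab)
  expect_equal(attr(ev, "best_k"), 3)
  expect_equal(ev$delta_k[3], abs(-95 - 2 * (-100) + (-150)), tolerance = 1e-9)

  # linear means: all interior delta-K exactly 0
  lin <- data.frame(K = rep(1:4, each = 2), lnP = mk2 <- rep(c(-1, 1), 4) +
                      rep(seq(-40, -10, by = 10), each = 2))
  evl <- evanno_delta_k(lin)
  expect_equal(evl$delta_k[2:3], c(0, 0))

  # invariance to constant shifts
  shifted <- tab; shifted$lnP <- shifted$lnP + 1234
  expect_equal(evanno_delta_k(shifted)$delta_k, ev$delta_k, tolerance = 1e-9)

  expect_error(evanno_delta_k(data.frame(K = 1:4, lnP = 1:4)), "replicates")
  expect_error(evanno_delta_k(data.frame(K = rep(c(1, 3, 4), 2), lnP = 1:6)),
               "consecutive")
  sd0 <- data.frame(K = rep(1:3, each = 2),
                    lnP = c(-10, -11, -5, -5, -2, -3))
  expect_warning(ev0 <- evanno_delta_k(sd0), "sd = 0")
  expect_true(is.na(ev0$delta_k[2]))
})
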