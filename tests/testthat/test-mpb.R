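LS <- function(...) locus_spec(...)

test_that("build_amplicon_table assembles counts from long format", {
  df <- reads_df(c("ACGT", "ACGT", "AAAA", "CCCC"),
                 c("s1", "s2", "s1", "s2"), c(5, 3, 2, 4))
  tab <- build_amplicon_table(df, LS("X", "AC"))
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(tab$counts[tab$sequence == "ACGT", ], c(s1 = 5, s2 = 3))
  expect_equal(unname(tab$counts[tab$sequence == "AAAA", "s2"]), 0)

  # duplicate listings within a sample are summed
  dup <- reads_df(c("ACGT", "ACGT"), c("s1", "s1"), c(5, 7))
  expect_equal(sum(build_amplicon_table(dup, LS("X", "AC"))$counts), 12)

  expect_error(build_amplicon_table(reads_df(character(0), character(0),
                                             numeric(0)), LS("X", "AC")),
               "no input")
  expect_error(build_amplicon_table(list(), LS("X", "AC")), "no input")
})

test_that("build_amplicon_table reads dereplicated ;size= FASTA", {
  dir <- tempfile(); dir.create(dir)
  f1 <- file.path(dir, "s1.fasta")
  writeLines(c(">a;size=10", "ACACACACAC", ">b;size=2", "GGGGACACAC"), f1)
  f2 <- file.path(dir, "s2.fasta")
  writeLines(c(">a;size=4", "ACACACACAC"), f2)
  tab <- build_amplicon_table(c(s1 = f1, s2 = f2), LS("X", "AC"))
  expect_equal(sum(tab$counts), 16)
  expect_equal(tab$counts[tab$sequence == "ACACACACAC", ], c(s1 = 10, s2 = 4))
})

test_that("filter_singletons removes dataset-wide singletons only", {
  df <- reads_df(c("AAAA", "CCCC", "CCCC", "GGGG"),
                 c("s1", "s1", "s2", "s1"), c(1, 1, 1, 5))
  tab <- filter_singletons(build_amplicon_table(df, LS("X", "AC")))
  # AAAA total 1 -> dropped; CCCC split 1+1 -> kept
  expect_equal(sort(tab$sequence), c("CCCC", "GGGG"))
  rep <- filter_report(tab)
  expect_equal(rep$reads_removed[rep$stage == "singleton"], 1)

  allsing <- build_amplicon_table(reads_df("AAAA", "s1", 1), LS("X", "AC"))
  expect_warning(empty <- filter_singletons(allsing), "singleton")
  expect_equal(length(empty$sequence), 0)
})

test_that("repeat_run finds the longest uninterrupted in-frame run", {
  expect_equal(repeat_run("TTACACACTT", "AC")$units, 3)
  expect_equal(repeat_run("TTACACTT", "AC")$units, 2)
  # interrupted: runs of 2 and 5 -> 5
  s <- paste0("ACAC", "G", "ACACACACAC", "TT")
  r <- repeat_run(s, "AC")
  expect_equal(r$units, 5)
  expect_equal(substr(s, r$start, r$end), "ACACACACAC")
  expect_equal(repeat_run("GGGG", "AC")$units, 0)
})

test_that("repeat_run agrees with brute-force substring scanning", {
  brute <- function(s, motif) {
    k <- nchar(motif); best <- 0
    for (start in 1:nchar(s)) {
      run <- 0
      pos <- start
      while (pos + k - 1 <= nchar(s) && substr(s, pos, pos + k - 1) == motif) {
        run <- run + 1; pos <- pos + k
      }
      best <- max(best, run)
    }
    best
  }
  set.seed(77)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    expect_equal(repeat_run(s, "AC")$units, brute(s, "AC"), label = s)
    expect_equal(repeat_run(s, "ACT")$units, brute(s, "ACT"))
  }
})

test_that("repeat_filter drops sequences under the unit minimum", {
  df <- reads_df(c("TTACACACTT",    # 3 units, kept
                   "TTACACTTTT",    # 2 units, dropped
                   "GGGGGGGGGG"),   # no motif, dropped
                 rep("s1", 3), c(10, 10, 10))
  tab <- repeat_filter(filter_singletons(build_amplicon_table(df, LS("X", "AC"))))
  expect_equal(tab$sequence, "TTACACACTT")
  expect_equal(tab$repeat_units, 3)
  expect_equal(filter_report(tab)$reads_removed[3], 20)
})

test_that("call_alleles names homoplastic alleles deterministically", {
  # two 10-nt sequences (counts 900 / 100) and one 12-nt
  df <- reads_df(c("TTACACACTT", "GGACACACTT", "TTACACACACTT"),
                 rep("s1", 3), c(900, 100, 50))
  calls <- call_alleles(repeat_filter(filter_singletons(
    build_amplicon_table(df, LS("X", "AC")))))
  expect_equal(calls$calls$allele_name, c("10.1", "10.2", "12.1"))
  expect_equal(calls$calls$total_count[1:2], c(900, 100))

  # equal counts: lexicographic tie-break, stable under input shuffling
  df2 <- reads_df(c("GGACACACTT", "TTACACACTT", "AAACACACTT"),
                  rep("s1", 3), c(5, 5, 5))
  c1 <- call_alleles(repeat_filter(build_amplicon_table(df2, LS("X", "AC"))))
  c2 <- call_alleles(repeat_filter(build_amplicon_table(df2[c(3, 1, 2), ],
                                                        LS("X", "AC"))))
  expect_identical(c1$calls$sequence, c2$calls$sequence)
  expect_equal(c1$calls$sequence[1], "AAACACACTT")  # 10.1 by lexicographic order
})

test_that("normalize_and_filter scales to the median and applies thresholds", {
  # two samples with totals 1000 and 3000 -> median 2000, factors 2 and 2/3
  df <- reads_df(rep(c("TTACACACTT", "GGACACACAC"), 2),
                 rep(c("s1", "s2"), each = 2), c(600, 400, 2400, 600))
  calls <- call_alleles(repeat_filter(build_amplicon_table(df, LS("X", "AC"))))
  ft <- normalize_and_filter(calls, min_depth = 100)
  expect_equal(unname(colSums(ft$norm_counts)), c(2000, 2000))
  expect_equal(unname(ft$norm_counts["10.1", ]), c(600 * 2, 2400 * 2 / 3))
  expect_equal(unname(colSums(ft$pct)), c(100, 100), tolerance = 1e-6)
  # normalization preserves within-sample relative frequencies
  expect_equal(unname(ft$pct[, "s1"]), c(60, 40))

  # per-sample abundance zeroing at 0.65%
  df2 <- reads_df(c("TTACACACTT", "GGACACACAC"), c("s1", "s1"), c(9950, 50))
  calls2 <- call_alleles(repeat_filter(build_amplicon_table(df2,
    LS("PNm1", "AC", abundance_threshold_pct = 0.65))))
  ft2 <- normalize_and_filter(calls2, min_depth = 100)
  expect_equal(nrow(ft2$pct), 1)  # 0.5% allele zeroed everywhere -> dropped
  expect_equal(unname(ft2$pct[1, 1]), 99.5)  # no renormalization by default
  ft2r <- normalize_and_filter(calls2, min_depth = 100, renormalize = TRUE)
  expect_equal(unname(ft2r$pct[1, 1]), 100)
})

test_that("min_depth excludes samples, erroring only when none survive", {
  df <- reads_df(c("TTACACACTT", "TTACACACTT"), c("ok", "thin"), c(5000, 200))
  calls <- call_alleles(repeat_filter(build_amplicon_table(df, LS("X", "AC"))))
  expect_warning(ft <- normalize_and_filter(calls, min_depth = 1000),
                 "thin")
  expect_equal(ft$excluded_samples, "thin")
  expect_equal(colnames(ft$pct), "ok")
  expect_error(suppressWarnings(normalize_and_filter(calls, min_depth = 1e6)),
               "below min_depth")
})

test_that("merge_replicates averages frequencies allele by allele", {
  df <- reads_df(rep(c("TTACACACTT", "GGACACACAC"), c(4, 2)),
                 c("r1", "r2", "r3", "r4", "r1", "r2"),
                 c(90, 80, 100, 100, 10, 20))
  calls <- call_alleles(repeat_filter(build_amplicon_table(df, LS("X", "AC"))))
  ft <- normalize_and_filter(calls, min_depth = 10)
  map <- c(r1 = "d1", r2 = "d1", r3 = "d2", r4 = "d2")
  merged <- merge_replicates(ft, map)
  expect_equal(unname(merged$pct["10.1", "d1"]), (90 + 80) / 2)
  # allele present in one replicate only: mean includes the zero
  expect_equal(unname(merged$pct["10.2", "d2"]), 0)
  expect_equal(unname(merged$pct["10.2", "d1"]), 15)
  expect_error(merge_replicates(ft, c(r1 = "d1")), "unmapped")
})

test_that("flank_typing detects recombinant flank combinations", {
  A5 <- "GGGGGGGGGGGG"; B5 <- "CCCCCCCCCCCC"
  A3 <- "TTTTTTTTTTTT"; B3 <- "AAAAAAAAAAAA"
  run <- strrep("AC", 5)
  # (5A,3A) 80%, (5B,3B) 15%, (5A,3B) 5% -> last one is recombinant
  df <- reads_df(c(paste0(A5, run, A3), paste0(B5, strrep("AC", 6), B3),
                   paste0(A5, strrep("AC", 7), B3)),
                 rep("s1", 3), c(800, 150, 50))
  calls <- call_alleles(repeat_filter(build_amplicon_table(df, LS("X", "AC"))))
  ann <- flank_typing(calls)
  expect_equal(ann$flank5_type[ann$total_count == 800], "5A")
  expect_equal(ann$recombinant, ann$total_count == 50)

  # one flank pair only: no recombinants
  df1 <- reads_df(c(paste0(A5, run, A3), paste0(A5, strrep("AC", 6), A3)),
                  rep("s1", 2), c(10, 10))
  ann1 <- flank_typing(call_alleles(repeat_filter(
    build_amplicon_table(df1, LS("X", "AC")))))
  expect_false(any(ann1$recombinant))
  expect_equal(unique(ann1$flank5_type), "5A")

  # short 3' flank: typing undefined on that side, no recombinant calls
  dfs <- reads_df(c(paste0(A5, run, "TT"), paste0(B5, strrep("AC", 6), "TT")),
                  rep("s1", 2), c(10, 10))
  expect_warning(anns <- flank_typing(call_alleles(repeat_filter(
    build_amplicon_table(dfs, LS("X", "AC"))))), "UNDEFINED")
  expect_true(all(is.na(anns$flank3_type)))
  expect_false(any(anns$recombinant))
})

test_that("the filter chain reports stage-by-stage read percentages", {
  df <- reads_df(c("TTACACACTT", "GGACACACAC", "AAAATTTTGG"),
                 rep("s1", 3), c(1990, 9, 1))
  res <- suppressWarnings(  # 10-nt toy reads have short flanks
    mpb_call(df, LS("X", "AC", abundance_threshold_pct = 1),
             min_depth = 100))
  rep <- res$report
  expect_equal(rep$stage, c("input", "singleton", "repeat", "abundance"))
  expect_equal(rep$pct_removed[2], 100 * 1 / 2000, tolerance = 1e-9)
  expect_equal(rep$reads_removed[3], 0)
  expect_equal(rep$reads_removed[4], 9)
})
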