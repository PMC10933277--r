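# Built-in locus definitions for the simulator. Flank sequences are fixed
# arbitrary nucleotide strings (long enough for flank typing); allele sizes
# are expressed in repeat units of the motif.
default_sim_loci <- function(n_loci = 5) {
  base <- list(
    list(locus_name = "SIM1", motif = "AC",
         flank5 = "TGCATTAGGCTTACCGGATCAACGTTGGAT",
         flank3 = "GGTTCAACGATTGCCATAGGCTTGACCTAA"),
    list(locus_name = "SIM2", motif = "AG",
         flank5 = "CCTAGGTTACGGATCCATTGGACCTTAGCA",
         flank3 = "TTGACCGGTATCCATTGCAAGGCTTACGGA"),
    list(locus_name = "SIM3", motif = "ACT",
         flank5 = "GATTACCGGTTAGCCATAGGATTCAACGGT",
         flank3 = "CCATTGGACGGTTAACGGATTCCATAGGCT"),
    list(locus_name = "SIM4", motif = "AT",
         flank5 = "GGCATTACCGGATTCAACGGTTAGCCATAG",
         flank3 = "TTCCGGATTAGCCAATGGCTTAACGGATCC"),
    list(locus_name = "SIM5", motif = "CT",
         flank5 = "AACGGTTACCGATTAGGCATCCATTGGACT",
         flank3 = "GGATTCCAATGGCTTAACGGATCCGTTAGC")
  )
  stopifnot(n_loci >= 1, n_loci <= length(base))
  lapply(base[seq_len(n_loci)], function(l) {
    l$unit_range <- c(5L, 25L)
    l$n_founder_alleles <- 8L
    l
  })
}

#' Simulation configuration
#'
#' The stated world of the synthetic-data generator: a population of diploid
#' strains at `n_loci` microsatellite loci plus one mating-type (MT) locus,
#' sampled at a series of dates. Between consecutive dates each offspring is
#' either a clonal copy of a parent drawn from a skewed offspring
#' distribution (with probability `1 - sex_rate`) or a sexual recombinant of
#' a random MT+ x MT- pair (Mendelian segregation, stepwise +/-1-unit
#' mutation per transmitted allele). MT is determined by presence of the
#' dominant allele A at the MT locus.
#'
#' @param n_loci number of microsatellite loci (default 5).
#' @param pop_size census population size per date (default 10000). Blooms
#'   have enormous census sizes; keeping the census much larger than the
#'   sample prevents sibship structure in the sample from masquerading as
#'   linkage disequilibrium.
#' @param sample_size strains isolated (genotyped) per date (default 100).
#' @param n_dates number of sampling dates (default 6, weekly).
#' @param sex_rate per-offspring probability of sexual origin, in `[0,1]`.
#' @param clonal_skew concentration of the clonal offspring distribution:
#'   parent weights are drawn Gamma(shape = 1/clonal_skew); 0 = uniform
#'   parents. Dominance scales with `pop_size * shape`: one clone takes over
#'   when `clonal_skew` approaches `pop_size` (default 0, no skew).
#' @param mutation_rate stepwise +/-1-repeat-unit probability per transmitted
#'   allele per meiosis (default 1e-3).
#' @param n_founder_alleles distinct founder alleles per locus (default 8;
#'   1 gives a monoclonal founding population).
#' @param mt_allele_sizes fragment sizes segregating at the MT locus.
#' @param mt_allele_a_size the MT+-determining allele A size.
#' @param depth reads per sample per locus for pooled sequencing
#'   (default 1e4).
#' @param n_replicates replicate pooled samples per date (default 1).
#' @param slippage_rate per-read probability of PCR slippage by one repeat
#'   unit (default 0.02).
#' @param substitution_rate per-base per-read substitution probability
#'   (default 2e-4, the effective post-merge error of overlapping
#'   quality-filtered MiSeq read pairs).
#' @param start_date first sampling date.
#' @param loci optional list overriding [default_sim_loci()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 5, pop_size = 10000, sample_size = 100,
                       n_dates = 6,
                       sex_rate = 0.5, clonal_skew = 0,
                       mutation_rate = 1e-3,
                       n_founder_alleles = 8,
                       mt_allele_sizes = c(210L, 218L, 230L, 242L),
                       mt_allele_a_size = 230L,
                       depth = 10000, n_replicates = 1,
                       slippage_rate = 0.02, substitution_rate = 2e-4,
                       start_date = as.Date("2013-07-01"),
                       loci = NULL) {
  stopifnot(sex_rate >= 0, sex_rate <= 1, clonal_skew >= 0,
            mutation_rate >= 0, mutation_rate <= 1,
            slippage_rate >= 0, slippage_rate <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            depth >= 0, pop_size >= 2, n_dates >= 1,
            sample_size >= 1, sample_size <= pop_size,
            mt_allele_a_size %in% mt_allele_sizes)
  loci <- loci %||% default_sim_loci(n_loci)
  loci <- lapply(loci, function(l) {
    l$n_founder_alleles <- as.integer(n_founder_alleles)
    l
  })
  structure(list(loci = loci, n_loci = length(loci), pop_size = pop_size,
                 sample_size = sample_size,
                 n_dates = n_dates, sex_rate = sex_rate,
                 clonal_skew = clonal_skew, mutation_rate = mutation_rate,
                 mt_allele_sizes = as.integer(mt_allele_sizes),
                 mt_allele_a_size = as.integer(mt_allele_a_size),
                 depth = depth, n_replicates = n_replicates,
                 slippage_rate = slippage_rate,
                 substitution_rate = substitution_rate,
                 start_date = as.Date(start_date)),
            class = "sim_config")
}

# fragment length (bp) of an allele with u repeat units
fragment_length_bp <- function(locus, u) {
  nchar(locus$flank5) + nchar(locus$flank3) + u * nchar(locus$motif)
}

sequence_for_units <- function(locus, u) {
  paste0(locus$flank5, strrep(locus$motif, u), locus$flank3)
}

# stepwise +/-1 unit mutation, reflecting at 1 unit
mutate_units <- function(u, rate) {
  hit <- stats::runif(length(u)) < rate
  if (any(hit)) {
    step <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
    u[hit] <- pmax(1L, u[hit] + step)
  }
  u
}

#' Simulate a multiannual series of bloom populations
#'
#' Forward simulation under the regime described in [sim_config()]. Founders
#' draw alleles independently per locus from a randomly weighted founder
#' pool; the MT+-determining allele A starts at frequency
#' `1 - sqrt(0.5)` so that the expected MT ratio is 50:50. If a sexual
#' offspring is requested while one mating type is absent from the parent
#' pool, the offspring falls back to clonal copying and the event is logged
#' (sex cannot occur in a single-MT population).
#'
#' @param config a `sim_config`.
#' @param seed integer seed; identical seed, identical output.
#' @return A `sim_series`: list with `genotypes` (a `genotype_table` of
#'   `sample_size` isolated strains per date, alleles coded as fragment
#'   lengths in bp), `truth` (census-level, per date: `units` per-locus
#'   repeat-unit genotype matrices, `freq_bp` pooled allele frequencies named
#'   by fragment length, `mt` labels, `n_mlg`), `events` (character log), and
#'   the `config`.
#' @export
simulate_population_series <- function(config, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  L <- config$n_loci
  m <- config$pop_size
  loci <- config$loci

  founder_pool <- lapply(loci, function(l) {
    cand <- seq(l$unit_range[1], l$unit_range[2])
    units <- sort(cand[sample.int(length(cand), l$n_founder_alleles)])
    w <- stats::rexp(length(units))
    list(units = units, freq = w / sum(w))
  })
  draw_founder <- function(pool, n) {
    pool$units[sample.int(length(pool$units), n, replace = TRUE,
                          prob = pool$freq)]
  }

  # genotypes: list of L matrices m x 2 (repeat units) + MT matrix (bp sizes)
  units <- lapply(founder_pool, function(p) {
    matrix(draw_founder(p, 2 * m), m, 2)
  })
  p_a <- 1 - sqrt(0.5)
  other <- setdiff(config$mt_allele_sizes, config$mt_allele_a_size)
  draw_mt <- function(n) {
    if (length(other) == 0) {
      # only allele A segregates: the whole population is MT+
      return(rep(config$mt_allele_a_size, n))
    }
    a <- stats::runif(n) < p_a
    out <- integer(n)
    out[a] <- config$mt_allele_a_size
    out[!a] <- other[sample.int(length(other), sum(!a), replace = TRUE)]
    out
  }
  mt_geno <- matrix(draw_mt(2 * m), m, 2)

  events <- character(0)
  dates <- config$start_date + 7 * (seq_len(config$n_dates) - 1)
  truth <- vector("list", config$n_dates)
  all_rows <- vector("list", config$n_dates)

  n_samp <- config$sample_size
  snapshot <- function(d_idx) {
    # truth is the census (what an environmental DNA pool sees); the strain
    # table is a random sample of isolated strains
    mt_label <- ifelse(
      mt_geno[, 1] == config$mt_allele_a_size |
        mt_geno[, 2] == config$mt_allele_a_size, "MT_PLUS", "MT_MINUS")
    freq_bp <- lapply(seq_len(L), function(j) {
      bp <- fragment_length_bp(loci[[j]], as.vector(units[[j]]))
      tab <- table(bp)
      stats::setNames(as.numeric(tab) / (2 * m), names(tab))
    })
    names(freq_bp) <- vapply(loci, `[[`, "", "locus_name")
    key <- do.call(paste, c(lapply(units, function(u)
      paste(pmin(u[, 1], u[, 2]), pmax(u[, 1], u[, 2]))), sep = "|"))
    truth[[d_idx]] <<- list(units = lapply(units, identity),
                            mt_geno = mt_geno,
                            freq_bp = freq_bp, mt = mt_label,
                            n_mlg = length(unique(key)))
    take <- sort(sample.int(m, n_samp))
    alle <- do.call(cbind, lapply(seq_len(L), function(j) {
      matrix(fragment_length_bp(loci[[j]], units[[j]][take, , drop = FALSE]),
             n_samp, 2)
    }))
    all_rows[[d_idx]] <<- list(
      strain_id = sprintf("D%02d_S%04d", d_idx, seq_len(n_samp)),
      date = rep(dates[d_idx], n_samp), alleles = alle,
      mt = mt_label[take])
  }

  snapshot(1)
  if (config$n_dates > 1) {
    for (d in 2:config$n_dates) {
      w <- if (config$clonal_skew > 0) {
        stats::rgamma(m, shape = 1 / config$clonal_skew)
      } else {
        rep(1, m)
      }
      w <- w / sum(w)
      mt_now <- truth[[d - 1]]$mt
      plus <- which(mt_now == "MT_PLUS")
      minus <- which(mt_now == "MT_MINUS")
      sexual <- stats::runif(m) < config$sex_rate
      if (any(sexual) && (length(plus) == 0 || length(minus) == 0)) {
        events <- c(events, sprintf(
          "date %s: %d sexual offspring skipped (single mating type)",
          as.character(dates[d]), sum(sexual)))
        sexual[] <- FALSE
      }
      n_sex <- sum(sexual)
      clone_parent <- sample.int(m, m, replace = TRUE, prob = w)

      new_units <- lapply(units, function(u) u[clone_parent, , drop = FALSE])
      new_mt <- mt_geno[clone_parent, , drop = FALSE]
      if (n_sex > 0) {
        mothers <- plus[sample.int(length(plus), n_sex, replace = TRUE)]
        fathers <- minus[sample.int(length(minus), n_sex, replace = TRUE)]
        pick <- function(g, idx) {
          # one random allele from each parent
          gs <- g[idx, , drop = FALSE]
          gs[cbind(seq_len(nrow(gs)),
                   sample(1:2, nrow(gs), replace = TRUE))]
        }
        for (j in seq_len(L)) {
          a1 <- mutate_units(pick(units[[j]], mothers), config$mutation_rate)
          a2 <- mutate_units(pick(units[[j]], fathers), config$mutation_rate)
          new_units[[j]][sexual, ] <- cbind(a1, a2)
        }
        new_mt[sexual, ] <- cbind(pick(mt_geno, mothers),
                                  pick(mt_geno, fathers))
      }
      units <- new_units
      mt_geno <- new_mt
      snapshot(d)
    }
  }

  gt <- genotype_table(
    strain_id = unlist(lapply(all_rows, `[[`, "strain_id")),
    date = as.Date(unlist(lapply(all_rows, function(r) as.character(r$date)))),
    alleles = do.call(rbind, lapply(all_rows, `[[`, "alleles")),
    loci = vapply(loci, `[[`, "", "locus_name"),
    mating_type = unlist(lapply(all_rows, `[[`, "mt")))
  names(truth) <- as.character(dates)
  structure(list(genotypes = gt, truth = truth, events = events,
                 config = config, dates = dates),
            class = "sim_series")
}

# draw reads for one locus given repeat-unit frequencies; returns a
# dereplicated data.frame(sequence, count)
draw_locus_reads <- function(locus, unit_freq, depth, slippage_rate,
                             substitution_rate) {
  u_vals <- as.integer(names(unit_freq))
  counts <- as.vector(stats::rmultinom(1, depth, unit_freq))
  # PCR slippage: +/- one repeat unit per affected read
  out_units <- integer(0)
  out_n <- integer(0)
  for (i in seq_along(u_vals)) {
    n <- counts[i]
    if (n == 0) next
    ns <- stats::rbinom(1, n, slippage_rate)
    up <- stats::rbinom(1, ns, 0.5)
    down <- ns - up
    keep <- n - ns
    add <- c(keep, up, down)
    vals <- c(u_vals[i], u_vals[i] + 1L, max(1L, u_vals[i] - 1L))
    out_units <- c(out_units, vals[add > 0])
    out_n <- c(out_n, add[add > 0])
  }
  agg <- tapply(out_n, out_units, sum)
  u_out <- as.integer(names(agg))
  n_out <- as.integer(agg)

  seqs <- character(0)
  cnts <- integer(0)
  for (i in seq_along(u_out)) {
    s <- sequence_for_units(locus, u_out[i])
    len <- nchar(s)
    p_any <- 1 - (1 - substitution_rate)^len
    nmut <- stats::rbinom(1, n_out[i], p_any)
    if (n_out[i] - nmut > 0) {
      seqs <- c(seqs, s)
      cnts <- c(cnts, n_out[i] - nmut)
    }
    if (nmut > 0) {
      # one substitution per affected read (adequate for per-base rates
      # << 1/length); position and base uniform
      pos <- sample.int(len, nmut, replace = TRUE)
      for (k in seq_len(nmut)) {
        old <- substr(s, pos[k], pos[k])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        mut <- s
        substr(mut, pos[k], pos[k]) <- new
        seqs <- c(seqs, mut)
        cnts <- c(cnts, 1L)
      }
    }
  }
  agg2 <- tapply(cnts, seqs, sum)
  data.frame(sequence = names(agg2), count = as.integer(agg2),
             stringsAsFactors = FALSE)
}

#' Simulate pooled amplicon reads from simulated truth
#'
#' Draws `depth` reads per sample per locus multinomially from the true
#' pooled allele frequencies, then applies read-level PCR slippage (+/- one
#' repeat unit) and per-base substitution error (substitutions in flanks
#' create homoplastic alleles: same length, different sequence). Emitted as
#' dereplicated long-format tables directly consumable by
#' [build_amplicon_table()].
#'
#' @param series a `sim_series` from [simulate_population_series()].
#' @param seed integer seed.
#' @param dates subset of date labels (default all).
#' @return named list (by locus) of data frames `(sequence, sample, count)`;
#'   sample labels are `<date>_r<k>` for `n_replicates` replicates. The
#'   replicate map is in `attr(x, "replicate_map")`.
#' @export
simulate_pooled_reads <- function(series, seed, dates = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  config <- series$config
  if (config$depth < 1) stop("depth must be >= 1", call. = FALSE)
  set.seed(seed)
  dates <- dates %||% names(series$truth)
  loci <- config$loci
  out <- stats::setNames(vector("list", length(loci)),
                         vapply(loci, `[[`, "", "locus_name"))
  rep_map <- character(0)
  for (j in seq_along(loci)) {
    parts <- list()
    for (d in dates) {
      tr <- series$truth[[d]]
      units <- as.vector(tr$units[[j]])
      tab <- table(units)
      unit_freq <- as.numeric(tab) / length(units)
      names(unit_freq) <- names(tab)
      for (r in seq_len(config$n_replicates)) {
        smp <- paste0(d, "_r", r)
        rep_map[smp] <- d
        reads <- draw_locus_reads(loci[[j]], unit_freq, config$depth,
                                  config$slippage_rate,
                                  config$substitution_rate)
        if (nrow(reads)) reads$sample <- smp
        parts[[length(parts) + 1]] <- reads
      }
    }
    out[[j]] <- do.call(rbind, parts)
  }
  attr(out, "replicate_map") <- rep_map
  out
}

#' Write simulated reads as dereplicated FASTA files
#'
#' One file per sample per locus, headers `seq<N>;size=<count>` in the
#' usearch/vsearch dereplication dialect.
#'
#' @param reads output of [simulate_pooled_reads()].
#' @param dir output directory (created if needed).
#' @return named list (by locus) of named file-path vectors (by sample).
#' @export
write_mpb_fasta <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lapply(stats::setNames(names(reads), names(reads)), function(locus) {
    df <- reads[[locus]]
    samples <- unique(df$sample)
    paths <- vapply(samples, function(s) {
      sub <- df[df$sample == s, , drop = FALSE]
      set <- Biostrings::DNAStringSet(sub$sequence)
      names(set) <- sprintf("seq%d;size=%d", seq_len(nrow(sub)), sub$count)
      path <- file.path(dir, paste0(locus, "_", s, ".fasta"))
      Biostrings::writeXStringSet(set, path, width = 200)
      path
    }, character(1))
    stats::setNames(paths, samples)
  })
}

#' Build a mock strain mixture with known expected allele frequencies
#'
#' Emulates pooling DNA from a handful of strains at chosen proportions to
#' validate quantitative allele recovery. The expected frequency of an
#' allele is the proportion-weighted sum of per-strain dosages (1 for a
#' homozygote, 0.5 per heterozygous allele); reads are then generated with
#' the same error model as [simulate_pooled_reads()].
#'
#' @param strain_units list of strains; each strain is a list (by locus) of
#'   length-2 integer repeat-unit genotypes.
#' @param proportions mixing proportions, summing to 1.
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `expected` (per locus, named by fragment length bp) and
#'   `reads` (long-format tables as in [simulate_pooled_reads()], one sample
#'   `"mixture_r1"`).
#' @export
make_mock_mixture <- function(strain_units, proportions, config, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(strain_units) == 0) stop("need >=1 strain", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  stopifnot(length(proportions) == length(strain_units))
  set.seed(seed)
  loci <- config$loci
  expected <- stats::setNames(vector("list", length(loci)),
                              vapply(loci, `[[`, "", "locus_name"))
  reads <- expected
  for (j in seq_along(loci)) {
    freq_u <- numeric(0)
    for (s in seq_along(strain_units)) {
      g <- strain_units[[s]][[j]]
      for (a in g) {
        key <- as.character(a)
        freq_u[key] <- (if (is.na(freq_u[key])) 0 else freq_u[key]) +
          proportions[s] * 0.5
      }
    }
    expected[[j]] <- stats::setNames(
      as.numeric(freq_u),
      as.character(fragment_length_bp(loci[[j]], as.integer(names(freq_u)))))
    rd <- draw_locus_reads(loci[[j]], freq_u, config$depth,
                           config$slippage_rate, config$substitution_rate)
    if (nrow(rd)) rd$sample <- "mixture_r1"
    reads[[j]] <- rd
  }
  list(expected = expected, reads = reads)
}
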