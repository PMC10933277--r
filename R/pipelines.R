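#' Run the full fingerprinting workflow
#'
#' Chains genotype ingestion, per-date diversity, the index of association,
#' mating-type ratios, pairwise F_ST / PCoA / percolation network across
#' sampling dates, and the MLG recurrence matrix, writing one CSV per report.
#' The bundle is written atomically: outputs land in a staging directory that
#' is renamed into place only when every stage succeeded, so the report
#' bundle is complete or absent.
#'
#' @param config list with elements: `genotypes` (CSV path or a
#'   `genotype_table`), `iterations` (permutations, default 1000), `seed`
#'   (required), `alpha` (default 0.05), `period_map` (optional named vector
#'   `date -> period` for recurrence; default calendar year), `min_date_n`
#'   (minimum complete strains for a date to enter the F_ST/ordination
#'   stage; default 3).
#' @param out_dir output directory.
#' @return (invisibly) named list of output file paths.
#' @export
run_fingerprinting <- function(config, out_dir) {
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required", call. = FALSE)
  gt <- config$genotypes
  if (is.character(gt)) gt <- read_genotype_table(gt)
  iterations <- config$iterations %||% 1000
  alpha <- config$alpha %||% 0.05
  min_n <- config$min_date_n %||% 3
  meta <- list(seed = seed, config_hash = config_hash(config))

  staging <- tempfile("fingerprinting_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  paths <- list()
  emit <- function(df, name, extra_meta = list()) {
    p <- file.path(staging, name)
    write_report_csv(df, p, c(meta, extra_meta))
    paths[[name]] <<- file.path(out_dir, name)
    p
  }

  div <- diversity_by_date(gt)
  emit(div, "diversity_by_date.csv")

  part <- assign_mlgs(gt)
  emit(part$membership, "mlg_membership.csv",
       list(n_mlg = part$n_mlg,
            excluded = length(part$excluded_strains)))

  ia <- ia_by_date(gt, n_iterations = iterations, seed = seed, alpha = alpha)
  emit(ia, "index_of_association.csv")

  if (any(gt$mating_type %in% c("MT_PLUS", "MT_MINUS"))) {
    mtr <- mt_ratio(gt)
    emit(mtr$per_date, "mt_ratio.csv",
         list(mean_ratio = sprintf("%.4f", mtr$mean_ratio),
              sd_ratio = sprintf("%.4f", mtr$sd_ratio)))
  }

  rec <- mlg_recurrence(part, gt, grouping = config$period_map)
  emit(data.frame(period = rownames(rec), rec, check.names = FALSE),
       "mlg_recurrence.csv")

  dates <- sort(unique(gt$date))
  profiles <- list()
  for (d in dates) {
    sub <- gt[gt$date == d, , drop = FALSE]
    attr(sub, "loci") <- loci_of(gt)
    class(sub) <- class(gt)
    if (sum(complete_rows(sub)) >= min_n) {
      profiles[[as.character(as.Date(d, origin = "1970-01-01"))]] <-
        suppressWarnings(allele_freq_profile(sub))
    }
  }
  if (length(profiles) >= 2) {
    fst <- fst_matrix(profiles)
    emit(data.frame(sample = rownames(fst), unclass(fst), check.names = FALSE),
         "fst_matrix.csv")
    ord <- pcoa(fst)
    emit(data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                    check.names = FALSE),
         "pcoa_coordinates.csv",
         list(pct_variance = paste(sprintf("%.2f", ord$pct_variance),
                                   collapse = " ")))
    if (nrow(fst) >= 2 && any(fst > 0)) {
      net <- percolation_network(fst)
      emit(net$edges, "network_edges.csv",
           list(threshold = sprintf("%.6f", net$threshold)))
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(paths)) {
    file.copy(file.path(staging, name), paths[[name]], overwrite = TRUE)
  }
  invisible(paths)
}

#' Run the full MPB workflow
#'
#' Chains the amplicon filter chain per locus, replicate merging, and the
#' downstream F_ST matrix and PCoA over dates; writes one CSV per report
#' (frequency table, allele annotations, filter report per locus; F_ST,
#' PCoA coordinates, recombinant report overall), atomically as in
#' [run_fingerprinting()].
#'
#' @param config list with elements: `loci` (list of `locus_spec`), `reads`
#'   (named list by locus of long-format read tables, or directories/file
#'   lists per locus accepted by [build_amplicon_table()]), `replicate_map`
#'   (named vector `sample -> date`, optional), `min_depth` (default 1000),
#'   `seed` (required, recorded for provenance).
#' @param out_dir output directory.
#' @return (invisibly) named list of output file paths.
#' @export
run_mpb <- function(config, out_dir) {
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required", call. = FALSE)
  min_depth <- config$min_depth %||% 1000
  meta <- list(seed = seed, config_hash = config_hash(config))

  staging <- tempfile("mpb_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  paths <- list()
  emit <- function(df, name, extra_meta = list()) {
    p <- file.path(staging, name)
    write_report_csv(df, p, c(meta, extra_meta))
    paths[[name]] <<- file.path(out_dir, name)
  }

  freq_tables <- list()
  annotations <- list()
  for (spec in config$loci) {
    nm <- spec$locus_name
    res <- mpb_call(config$reads[[nm]], spec, min_depth = min_depth,
                    replicate_map = config$replicate_map)
    freq_tables[[nm]] <- res$freq$pct
    annotations[[nm]] <- res$annotations
    emit(data.frame(allele = rownames(res$freq$pct), res$freq$pct,
                    check.names = FALSE),
         paste0("freq_", nm, ".csv"),
         list(excluded_samples = paste(res$freq$excluded_samples,
                                       collapse = " ")))
    emit(res$annotations, paste0("alleles_", nm, ".csv"))
    emit(res$report, paste0("filter_report_", nm, ".csv"))
  }

  samples <- Reduce(union, lapply(freq_tables, colnames))
  if (length(samples) >= 2) {
    profiles <- lapply(stats::setNames(samples, samples), function(s) {
      tabs <- Filter(function(m) s %in% colnames(m), freq_tables)
      afp_from_mpb(tabs, s)
    })
    fst <- fst_matrix(profiles)
    emit(data.frame(sample = rownames(fst), unclass(fst), check.names = FALSE),
         "fst_matrix.csv")
    ord <- pcoa(fst)
    emit(data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                    check.names = FALSE),
         "pcoa_coordinates.csv",
         list(pct_variance = paste(sprintf("%.2f", ord$pct_variance),
                                   collapse = " ")))
  }
  recomb <- do.call(rbind, lapply(annotations, function(a)
    a[a$recombinant, c("allele_name", "locus", "fragment_length",
                       "flank5_type", "flank3_type"), drop = FALSE]))
  emit(recomb %||% data.frame(), "recombinant_alleles.csv")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(paths)) {
    file.copy(file.path(staging, name), paths[[name]], overwrite = TRUE)
  }
  invisible(paths)
}
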