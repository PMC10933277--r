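#' Define a microsatellite locus for the MPB caller
#'
#' @param locus_name locus label (e.g. "PNm1").
#' @param repeat_motif core repeat motif (e.g. "AC"); exact in-frame tandem
#'   copies of this string define the repeat region.
#' @param min_repeat_units minimum number of uninterrupted repeat units for a
#'   sequence to be kept (default 3; "less than 3 repeat units" excluded).
#' @param abundance_threshold_pct per-sample frequency threshold (percent)
#'   below which an allele is considered erroneous and zeroed (e.g. 0.65 for
#'   PNm1, 1.65 for PNm6420).
#' @param flank_min_len minimum flank length (nt) for flank typing; shorter
#'   flanks are typed UNDEFINED (default 10).
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(locus_name, repeat_motif, min_repeat_units = 3,
                       abundance_threshold_pct = 0,
                       flank_min_len = 10) {
  stopifnot(nchar(repeat_motif) >= 1, abundance_threshold_pct >= 0,
            min_repeat_units >= 1)
  structure(list(locus_name = locus_name,
                 repeat_motif = toupper(repeat_motif),
                 min_repeat_units = as.integer(min_repeat_units),
                 abundance_threshold_pct = abundance_threshold_pct,
                 flank_min_len = as.integer(flank_min_len)),
            class = "locus_spec")
}

# append one stage to the filter log carried on an amplicon table
log_stage <- function(tab, stage, reads_in, reads_out, rows_removed) {
  entry <- data.frame(stage = stage, reads_in = reads_in, reads_out = reads_out,
                      reads_removed = reads_in - reads_out,
                      pct_removed = if (reads_in > 0)
                        100 * (reads_in - reads_out) / reads_in else 0,
                      rows_removed = rows_removed)
  attr(tab, "filter_log") <- rbind(attr(tab, "filter_log"), entry)
  tab
}

#' Filter report of an amplicon or allele table
#'
#' Reads removed at each pipeline stage, as counts and percentages of the
#' stage input.
#'
#' @param tab an `amplicon_table` (or downstream object carrying the log).
#' @return data frame: stage, reads_in, reads_out, reads_removed,
#'   pct_removed, rows_removed.
#' @export
filter_report <- function(tab) {
  attr(tab, "filter_log") %||%
    data.frame(stage = character(0), reads_in = numeric(0),
               reads_out = numeric(0), reads_removed = numeric(0),
               pct_removed = numeric(0), rows_removed = integer(0))
}

new_amplicon_table <- function(seqs, counts, locus, filter_log = NULL) {
  stopifnot(length(seqs) == nrow(counts))
  rownames(counts) <- NULL
  structure(list(locus = locus, sequence = seqs, counts = counts),
            filter_log = filter_log, class = "amplicon_table")
}

#' @export
print.amplicon_table <- function(x, ...) {
  cat(sprintf("amplicon_table [%s]: %d distinct sequences x %d samples, %d reads\n",
              x$locus$locus_name, length(x$sequence), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Build a sequence-by-sample amplicon contingency table
#'
#' Accepts either (a) a named list/vector of per-sample dereplicated FASTA
#' files whose headers carry usearch/vsearch-style `;size=N` annotations
#' (names become sample labels; a missing `;size=` means count 1), or (b) a
#' long-format data frame / TSV path with columns `sequence`, `sample`,
#' `count`. Identical sequences listed more than once in one sample are
#' summed; a sequence absent from a sample gets count 0.
#'
#' @param x input as described above.
#' @param locus a `locus_spec`.
#' @return an `amplicon_table`: distinct sequences x samples count matrix.
#' @export
build_amplicon_table <- function(x, locus) {
  if (is.character(x) && length(x) == 1 && !grepl("\\.fa(sta)?$", x) &&
      file.exists(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("sequence", "sample", "count") %in% names(x)))
    if (nrow(x) == 0) stop("no input sequences", call. = FALSE)
    long <- x
  } else {
    files <- x
    if (length(files) == 0) stop("no input files", call. = FALSE)
    if (is.null(names(files))) {
      names(files) <- sub("\\.[^.]*$", "", basename(unlist(files)))
    }
    parts <- lapply(names(files), function(s) {
      set <- Biostrings::readDNAStringSet(files[[s]])
      if (length(set) == 0) {
        warning("empty sample file: ", files[[s]])
        return(data.frame(sequence = character(0), sample = character(0),
                          count = numeric(0)))
      }
      sz <- sub("^.*;size=([0-9]+).*$", "\\1", names(set))
      count <- suppressWarnings(as.numeric(sz))
      count[is.na(count)] <- 1
      data.frame(sequence = as.character(set), sample = s, count = count,
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, parts)
    if (nrow(long) == 0) stop("no input sequences", call. = FALSE)
  }
  long$sequence <- toupper(long$sequence)
  samples <- unique(long$sample)
  seqs <- unique(long$sequence)
  counts <- matrix(0, length(seqs), length(samples),
                   dimnames = list(NULL, samples))
  i <- match(long$sequence, seqs)
  j <- match(long$sample, samples)
  for (r in seq_len(nrow(long))) {
    counts[i[r], j[r]] <- counts[i[r], j[r]] + long$count[r]
  }
  tab <- new_amplicon_table(seqs, counts, locus)
  log_stage(tab, "input", sum(counts), sum(counts), 0L)
}

#' Remove singleton sequences
#'
#' Drops rows whose dataset-wide total count (summed over all samples)
#' equals 1. A count of 1 in each of two samples (total 2) is retained.
#'
#' @param tab an `amplicon_table`.
#' @return filtered `amplicon_table` (filter log updated).
#' @export
filter_singletons <- function(tab) {
  totals <- rowSums(tab$counts)
  keep <- totals > 1
  if (!any(keep)) warning("all sequences are singletons: empty table")
  out <- new_amplicon_table(tab$sequence[keep],
                            tab$counts[keep, , drop = FALSE],
                            tab$locus, attr(tab, "filter_log"))
  log_stage(out, "singleton", sum(tab$counts), sum(out$counts), sum(!keep))
}

#' Longest uninterrupted tandem repeat run
#'
#' Number of exact, in-frame, adjacent copies of `motif` in the longest
#' uninterrupted run within each sequence (0 if the motif never occurs).
#' Interrupted repeats count only the longest clean run.
#'
#' @param seqs character vector of sequences.
#' @param motif repeat motif.
#' @return list with `units` (integer), `start`, `end` (1-based bounds of the
#'   first longest run; NA when absent).
#' @export
repeat_run <- function(seqs, motif) {
  pat <- paste0("(?:", motif, ")+")
  mlen <- nchar(motif)
  hits <- gregexpr(pat, seqs, perl = TRUE)
  units <- integer(length(seqs))
  start <- rep(NA_integer_, length(seqs))
  for (i in seq_along(seqs)) {
    h <- hits[[i]]
    if (h[1] == -1) next
    lens <- attr(h, "match.length")
    best <- which.max(lens)
    units[i] <- lens[best] %/% mlen
    start[i] <- h[best]
  }
  list(units = units, start = start,
       end = ifelse(is.na(start), NA_integer_, start + units * mlen - 1L))
}

#' Locus-specific repeat filter
#'
#' Computes the repeat-unit count of every sequence via [repeat_run()] and
#' removes sequences with fewer than `min_repeat_units` uninterrupted units
#' (including sequences lacking the motif entirely).
#'
#' @param tab an `amplicon_table`.
#' @return filtered `amplicon_table` with per-row `repeat_units`,
#'   `run_start`, `run_end` components added.
#' @export
repeat_filter <- function(tab) {
  locus <- tab$locus
  run <- repeat_run(tab$sequence, locus$repeat_motif)
  keep <- run$units >= locus$min_repeat_units
  out <- new_amplicon_table(tab$sequence[keep],
                            tab$counts[keep, , drop = FALSE],
                            locus, attr(tab, "filter_log"))
  out$repeat_units <- run$units[keep]
  out$run_start <- run$start[keep]
  out$run_end <- run$end[keep]
  log_stage(out, "repeat", sum(tab$counts), sum(out$counts), sum(!keep))
}

#' Call alleles with homoplasy-aware naming
#'
#' Sequences are grouped by exact fragment length; within a length class
#' every distinct sequence is a separate (homoplastic) allele. The homoplasy
#' index orders alleles of one length by descending dataset-wide count, ties
#' broken lexicographically by sequence, so names like `114.1`, `114.2` are
#' stable under input-order shuffling.
#'
#' @param tab a singleton- and repeat-filtered `amplicon_table` (from
#'   [repeat_filter()]).
#' @return An `allele_calls` object: list with `calls` (data frame:
#'   allele_name, locus, fragment_length, homoplasy_index, repeat_units,
#'   sequence, run_start, run_end, total_count) and `counts` (allele x sample
#'   matrix), filter log carried over.
#' @export
call_alleles <- function(tab) {
  if (is.null(tab$repeat_units)) {
    stop("run repeat_filter() before calling alleles", call. = FALSE)
  }
  len <- nchar(tab$sequence)
  total <- rowSums(tab$counts)
  ord <- order(len, -total, tab$sequence)
  idx <- stats::ave(seq_along(ord), len[ord], FUN = seq_along)
  calls <- data.frame(
    allele_name = paste0(len[ord], ".", idx),
    locus = tab$locus$locus_name,
    fragment_length = len[ord],
    homoplasy_index = idx,
    repeat_units = tab$repeat_units[ord],
    sequence = tab$sequence[ord],
    run_start = tab$run_start[ord],
    run_end = tab$run_end[ord],
    total_count = total[ord],
    stringsAsFactors = FALSE
  )
  counts <- tab$counts[ord, , drop = FALSE]
  rownames(counts) <- calls$allele_name
  structure(list(locus = tab$locus, calls = calls, counts = counts),
            filter_log = attr(tab, "filter_log"), class = "allele_calls")
}

#' Normalize libraries and apply the abundance filter
#'
#' Samples with a raw total below `min_depth` are excluded (flagged, not an
#' error, unless none survive). Counts are scaled so that every retained
#' column totals the median of the retained raw totals; allele frequencies
#' are expressed as percentages of the per-sample total (so pre-filter
#' columns sum to 100). Alleles whose frequency falls below the locus
#' threshold in a sample are zeroed in that sample ("per-sample" mode,
#' the default, removes erroneous alleles while retaining genuinely rare
#' ones elsewhere); `global = TRUE` instead drops alleles whose maximum
#' frequency over samples is below the threshold. Alleles zero everywhere
#' after filtering are dropped. Frequencies are not re-normalized to 100
#' after filtering unless `renormalize = TRUE`.
#'
#' @param calls an `allele_calls` object.
#' @param min_depth minimum raw amplicons per sample (default 1000).
#' @param global use dataset-wide removal instead of per-sample zeroing.
#' @param renormalize rescale columns to 100% after the abundance filter.
#' @return An `allele_freq_table`: list with `pct` (allele x sample
#'   percentages), `norm_counts` (median-normalized counts), `raw_totals`,
#'   `excluded_samples`, `calls`, `locus`.
#' @export
normalize_and_filter <- function(calls, min_depth = 1000, global = FALSE,
                                 renormalize = FALSE) {
  counts <- calls$counts
  raw_totals <- colSums(counts)
  low <- raw_totals < min_depth
  if (all(low)) stop("all samples below min_depth = ", min_depth, call. = FALSE)
  if (any(low)) {
    warning("sample(s) below min_depth excluded: ",
            paste(colnames(counts)[low], collapse = ", "))
  }
  counts <- counts[, !low, drop = FALSE]
  totals <- raw_totals[!low]
  med <- stats::median(totals)
  scale <- med / totals
  norm_counts <- sweep(counts, 2, scale, `*`)
  pct <- sweep(norm_counts, 2, colSums(norm_counts), `/`) * 100

  thr <- calls$locus$abundance_threshold_pct
  reads_in <- sum(norm_counts)
  if (thr > 0) {
    if (global) {
      keep <- apply(pct, 1, max) >= thr
      pct <- pct[keep, , drop = FALSE]
      norm_counts <- norm_counts[keep, , drop = FALSE]
    } else {
      zero <- pct < thr
      pct[zero] <- 0
      norm_counts[zero] <- 0
    }
  }
  nonzero <- rowSums(pct) > 0
  pct <- pct[nonzero, , drop = FALSE]
  norm_counts <- norm_counts[nonzero, , drop = FALSE]
  if (renormalize) {
    pct <- sweep(pct, 2, colSums(pct), `/`) * 100
  }
  out <- structure(list(pct = pct, norm_counts = norm_counts,
                        raw_totals = raw_totals,
                        excluded_samples = names(raw_totals)[low],
                        calls = calls$calls[match(rownames(pct),
                                                  calls$calls$allele_name), ],
                        locus = calls$locus),
                   filter_log = attr(calls, "filter_log"),
                   class = "allele_freq_table")
  log_stage(out, "abundance", reads_in, sum(norm_counts),
            nrow(calls$counts) - nrow(pct))
}

#' Merge replicate samples by date
#'
#' Replicate environmental samples from the same sampling date are merged by
#' the unweighted mean of their allele frequencies, allele by allele (zeros
#' included in the mean).
#'
#' @param ft an `allele_freq_table`.
#' @param replicate_map named character vector `sample -> date`; every
#'   retained sample must be mapped.
#' @return the table with `pct` (and `norm_counts`) keyed by date.
#' @export
merge_replicates <- function(ft, replicate_map) {
  samples <- colnames(ft$pct)
  dates <- unname(replicate_map[samples])
  if (anyNA(dates)) {
    stop("unmapped sample(s): ", paste(samples[is.na(dates)], collapse = ", "),
         call. = FALSE)
  }
  ulev <- unique(dates)
  merge_mat <- function(m) {
    out <- vapply(ulev, function(d) rowMeans(m[, dates == d, drop = FALSE]),
                  numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), ulev))
    out
  }
  ft$pct <- merge_mat(ft$pct)
  ft$norm_counts <- merge_mat(ft$norm_counts)
  ft
}

#' Type flanking sequences and flag recombinant alleles
#'
#' Decomposes every allele as 5'-flank + longest repeat run + 3'-flank and
#' clusters the flanks by exact sequence identity into types (labelled by
#' descending total read abundance: `5A`, `5B`, ...; `3A`, ...). The
#' canonical partner of a 5' type is the 3' type it co-occurs with at
#' highest total abundance (and vice versa). An allele is flagged
#' recombinant when both of its flank types also occur in other alleles but
#' its (5', 3') combination is neither flank's canonical pairing — the
#' signature of intralocus recombination. Flanks shorter than the locus
#' `flank_min_len` make that side's typing UNDEFINED (`NA`), and alleles
#' with an untyped side are never flagged recombinant.
#'
#' @param calls an `allele_calls` object (or the `calls`+`counts` of one).
#' @return the `calls` data frame with `flank5_type`, `flank3_type`,
#'   `recombinant` columns added; attribute `flank_types` holds the type
#'   tables.
#' @export
flank_typing <- function(calls) {
  df <- calls$calls
  locus <- calls$locus
  f5 <- substr(df$sequence, 1, df$run_start - 1)
  f3 <- substr(df$sequence, df$run_end + 1, nchar(df$sequence))
  type_side <- function(fl, prefix) {
    ok <- nchar(fl) >= locus$flank_min_len
    if (!any(ok)) {
      warning("all ", prefix, " flanks shorter than ", locus$flank_min_len,
              " nt: typing UNDEFINED")
      return(rep(NA_character_, length(fl)))
    }
    tot <- tapply(df$total_count[ok], fl[ok], sum)
    lev <- names(sort(tot, decreasing = TRUE))
    codes <- c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                                        function(a, b) paste0(a, b))))
    lab <- stats::setNames(paste0(prefix, codes[seq_along(lev)]), lev)
    out <- rep(NA_character_, length(fl))
    out[ok] <- unname(lab[fl[ok]])
    out
  }
  df$flank5_type <- type_side(f5, "5")
  df$flank3_type <- type_side(f3, "3")

  df$recombinant <- FALSE
  typed <- !is.na(df$flank5_type) & !is.na(df$flank3_type)
  if (any(typed)) {
    pair_tot <- tapply(df$total_count[typed],
                       list(df$flank5_type[typed], df$flank3_type[typed]), sum)
    pair_tot[is.na(pair_tot)] <- 0
    canon5 <- colnames(pair_tot)[apply(pair_tot, 1, which.max)]
    names(canon5) <- rownames(pair_tot)
    canon3 <- rownames(pair_tot)[apply(pair_tot, 2, which.max)]
    names(canon3) <- colnames(pair_tot)
    for (i in which(typed)) {
      t5 <- df$flank5_type[i]; t3 <- df$flank3_type[i]
      shared5 <- any(df$flank5_type[-i] == t5, na.rm = TRUE)
      shared3 <- any(df$flank3_type[-i] == t3, na.rm = TRUE)
      if (shared5 && shared3 &&
          canon5[[t5]] != t3 && canon3[[t3]] != t5) {
        df$recombinant[i] <- TRUE
      }
    }
  }
  attr(df, "flank_types") <- list(
    flank5 = unique(stats::na.omit(df$flank5_type)),
    flank3 = unique(stats::na.omit(df$flank3_type)))
  df
}

#' Run the full MPB filter chain for one locus
#'
#' Convenience wrapper: singleton filter, repeat filter, allele calling,
#' normalization/abundance filter, optional replicate merging and flank
#' typing, in the canonical order.
#'
#' @param x input accepted by [build_amplicon_table()].
#' @param locus a `locus_spec`.
#' @param min_depth minimum raw amplicons per sample.
#' @param replicate_map optional `sample -> date` merge map.
#' @param ... passed to [normalize_and_filter()].
#' @return list with `freq` (`allele_freq_table`), `annotations` (flank-typed
#'   calls), `report` (filter report).
#' @export
mpb_call <- function(x, locus, min_depth = 1000, replicate_map = NULL, ...) {
  tab <- build_amplicon_table(x, locus)
  tab <- filter_singletons(tab)
  tab <- repeat_filter(tab)
  calls <- call_alleles(tab)
  ann <- flank_typing(calls)
  freq <- normalize_and_filter(calls, min_depth = min_depth, ...)
  if (!is.null(replicate_map)) freq <- merge_replicates(freq, replicate_map)
  list(freq = freq, annotations = ann, report = filter_report(freq))
}
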