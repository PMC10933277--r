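#' Read a codominant diploid microsatellite genotype table
#'
#' Parses a CSV with one row per strain: a strain identifier, an ISO-8601
#' sampling date, an optional mating-type column, and then two allele columns
#' per locus (fragment lengths in base pairs, integer-called). Allele columns
#' are recognised as every column not named in the metadata columns; they are
#' paired in header order and the locus name is the column name stripped of a
#' trailing `.a1` / `.a2` (or `_1` / `_2`) suffix.
#'
#' Missing alleles are coded by a sentinel (default `"0"` or empty). A locus
#' is missing as a unit: if only one allele of a pair carries the sentinel the
#' whole locus is set to missing, with a warning. Allele pairs are stored
#' unordered (canonicalised so that `a1 <= a2`).
#'
#' @param path CSV file path.
#' @param id_col,date_col,mt_col metadata column names; `mt_col` is optional
#'   in the file. Mating type values are mapped via `mt_levels`.
#' @param missing_codes character vector of sentinel values marking a missing
#'   allele.
#' @param mt_levels named character vector mapping file values to
#'   `"MT_PLUS"` / `"MT_MINUS"`; anything else becomes `"UNKNOWN"`.
#' @return A `genotype_table`: data frame with columns `strain_id` (character,
#'   unique), `date` (`Date`), `mating_type` (character), and two integer
#'   columns per locus named `<locus>.a1` / `<locus>.a2`. Locus names are in
#'   `attr(x, "loci")`.
#' @export
read_genotype_table <- function(path,
                                id_col = "strain_id", date_col = "date",
                                mt_col = "mating_type",
                                missing_codes = c("0", "", "NA"),
                                mt_levels = c("+" = "MT_PLUS", "-" = "MT_MINUS",
                                              "MT+" = "MT_PLUS", "MT-" = "MT_MINUS",
                                              "MT_PLUS" = "MT_PLUS",
                                              "MT_MINUS" = "MT_MINUS")) {
  if (!file.exists(path)) stop("genotype table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         comment.char = "#")
  for (col in c(id_col, date_col)) {
    if (!col %in% names(raw)) stop("missing required column: ", col, call. = FALSE)
  }
  meta_cols <- c(id_col, date_col, if (mt_col %in% names(raw)) mt_col)
  allele_cols <- setdiff(names(raw), meta_cols)
  if (length(allele_cols) == 0) stop("no allele columns found", call. = FALSE)

  locus_of <- sub("([._](a[12]|[12]))$", "", allele_cols)
  counts <- table(factor(locus_of, levels = unique(locus_of)))
  bad <- names(counts)[counts != 2]
  if (length(bad)) {
    stop("locus ", paste(bad, collapse = ", "),
         " does not have exactly 2 allele columns", call. = FALSE)
  }
  loci <- names(counts)

  ids <- raw[[id_col]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate strain_id: ", paste(unique(dup), collapse = ", "),
                        call. = FALSE)
  dates <- as.Date(raw[[date_col]], format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date in row(s): ",
         paste(which(is.na(dates)), collapse = ", "), call. = FALSE)
  }

  mt <- rep("UNKNOWN", nrow(raw))
  if (mt_col %in% names(raw)) {
    v <- trimws(raw[[mt_col]])
    mapped <- unname(mt_levels[v])
    mt <- ifelse(is.na(mapped), "UNKNOWN", mapped)
  }

  alleles <- matrix(NA_integer_, nrow(raw), length(allele_cols))
  for (j in seq_along(allele_cols)) {
    v <- trimws(raw[[allele_cols[j]]])
    v[v %in% missing_codes] <- NA
    suppressWarnings(num <- as.integer(v))
    bad_rows <- which(!is.na(v) & is.na(num))
    if (length(bad_rows)) {
      stop("non-numeric allele in column ", allele_cols[j], ", row(s): ",
           paste(bad_rows, collapse = ", "), call. = FALSE)
    }
    if (any(num <= 0, na.rm = TRUE)) {
      stop("non-positive fragment length in column ", allele_cols[j], call. = FALSE)
    }
    alleles[, j] <- num
  }

  out <- data.frame(strain_id = ids, date = dates, mating_type = mt,
                    stringsAsFactors = FALSE)
  half_missing <- FALSE
  for (k in seq_along(loci)) {
    a <- alleles[, 2 * k - 1]
    b <- alleles[, 2 * k]
    one_na <- xor(is.na(a), is.na(b))
    if (any(one_na)) {
      half_missing <- TRUE
      a[one_na] <- NA
      b[one_na] <- NA
    }
    swap <- !is.na(a) & !is.na(b) & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[paste0(loci[k], ".a1")]] <- a
    out[[paste0(loci[k], ".a2")]] <- b
  }
  if (half_missing) {
    warning("half-missing allele pair(s) set to missing as a unit")
  }
  structure(out, loci = loci, class = c("genotype_table", "data.frame"))
}

#' Build a genotype table in memory
#'
#' Programmatic constructor used by the simulator and by tests; applies the
#' same canonicalisation as [read_genotype_table()].
#'
#' @param strain_id character vector of unique strain identifiers.
#' @param date sampling dates (`Date` or ISO strings).
#' @param alleles integer matrix with two columns per locus
#'   (`a1, a2, a1, a2, ...`), `NA` for missing.
#' @param loci character vector of locus names.
#' @param mating_type optional character vector (`MT_PLUS` / `MT_MINUS` /
#'   `UNKNOWN`).
#' @return a `genotype_table`.
#' @export
genotype_table <- function(strain_id, date, alleles, loci,
                           mating_type = NULL) {
  stopifnot(ncol(alleles) == 2 * length(loci), !anyDuplicated(strain_id))
  date <- as.Date(date)
  mt <- mating_type %||% rep("UNKNOWN", length(strain_id))
  out <- data.frame(strain_id = as.character(strain_id), date = date,
                    mating_type = mt, stringsAsFactors = FALSE)
  for (k in seq_along(loci)) {
    a <- as.integer(alleles[, 2 * k - 1])
    b <- as.integer(alleles[, 2 * k])
    miss <- is.na(a) | is.na(b)
    a[miss] <- NA; b[miss] <- NA
    swap <- !miss & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[paste0(loci[k], ".a1")]] <- a
    out[[paste0(loci[k], ".a2")]] <- b
  }
  structure(out, loci = loci, class = c("genotype_table", "data.frame"))
}

#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && missing(j)) {
    attr(out, "loci") <- attr(x, "loci")
    class(out) <- class(x)
  }
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d strains, %d loci (%s), %d date(s)\n",
              nrow(x), length(attr(x, "loci")),
              paste(attr(x, "loci"), collapse = ", "),
              length(unique(x$date))))
  NextMethod()
}

loci_of <- function(gt) attr(gt, "loci")

# integer matrix m x L: genotype code per locus (unordered pair identity),
# NA where the locus is missing
genotype_codes <- function(gt) {
  loci <- loci_of(gt)
  m <- nrow(gt)
  codes <- matrix(NA_integer_, m, length(loci),
                  dimnames = list(gt$strain_id, loci))
  for (k in seq_along(loci)) {
    key <- paste(gt[[paste0(loci[k], ".a1")]], gt[[paste0(loci[k], ".a2")]])
    key[is.na(gt[[paste0(loci[k], ".a1")]])] <- NA
    codes[, k] <- match(key, unique(key[!is.na(key)]))
  }
  codes
}

complete_rows <- function(gt) {
  codes <- genotype_codes(gt)
  rowSums(is.na(codes)) == 0
}

#' Assign multilocus genotypes (MLGs)
#'
#' Two strains share an MLG if and only if their complete genotypes are
#' identical at every locus (unordered allele pairs). Strains with any missing
#' locus are excluded from the partition rather than matched leniently, to
#' avoid false clonal matches.
#'
#' @param gt a `genotype_table`.
#' @return An `mlg_partition`: list with `mlg_id` (named character vector over
#'   included strains; labels `MLG0001, ...` by order of first occurrence),
#'   `n_mlg`, `excluded_strains`, and `membership` (data frame strain_id,
#'   mlg_id).
#' @export
assign_mlgs <- function(gt) {
  if (nrow(gt) == 0) stop("empty strain collection", call. = FALSE)
  complete <- complete_rows(gt)
  loci <- loci_of(gt)
  key_cols <- unlist(lapply(loci, function(l) gt[paste0(l, c(".a1", ".a2"))]),
                     recursive = FALSE)
  key <- do.call(paste, c(key_cols, sep = "|"))[complete]
  first <- unique(key)
  idx <- match(key, first)
  labels <- sprintf("MLG%04d", seq_along(first))
  mlg_id <- stats::setNames(labels[idx], gt$strain_id[complete])
  structure(list(
    mlg_id = mlg_id,
    n_mlg = length(first),
    excluded_strains = gt$strain_id[!complete],
    membership = data.frame(strain_id = gt$strain_id[complete],
                            mlg_id = unname(mlg_id),
                            stringsAsFactors = FALSE)
  ), class = "mlg_partition")
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat(sprintf("mlg_partition: %d strains in %d MLGs (%d excluded, incomplete)\n",
              length(x$mlg_id), x$n_mlg, length(x$excluded_strains)))
  invisible(x)
}

#' Genotypic richness R_MLG
#'
#' `R_MLG = (MLG - 1) / (N - 1)` where `MLG` is the number of distinct
#' multilocus genotypes and `N` the number of strains in the sample. Undefined
#' (`NA`) for fewer than two strains: a single strain is evidence neither of
#' clonality nor of diversity.
#'
#' @param n_mlg number of distinct MLGs (or an `mlg_partition`).
#' @param n_strains number of strains counted in the partition.
#' @return richness in `[0, 1]`, or `NA_real_` when `n_strains < 2`.
#' @export
genotypic_richness <- function(n_mlg, n_strains) {
  if (inherits(n_mlg, "mlg_partition")) n_mlg <- n_mlg$n_mlg
  if (n_mlg > n_strains) {
    stop("n_mlg exceeds n_strains: invariant violation", call. = FALSE)
  }
  if (n_strains < 2) return(NA_real_)
  (n_mlg - 1) / (n_strains - 1)
}

#' Per-locus allele counts, frequencies and unbiased heterozygosity
#'
#' Allele frequencies are computed over gene copies of genotyped strains
#' (missing loci excluded). The unbiased expected heterozygosity corrects the
#' plug-in gene diversity for sample size:
#' `uHe = (2N / (2N - 1)) * (1 - sum(p_i^2))`, `N` = number of individuals
#' genotyped at the locus.
#'
#' @param gt a `genotype_table`.
#' @return list with one entry per locus: `n` (individuals genotyped),
#'   `n_alleles`, `freq` (named numeric, sums to 1), `uhe` (`NA` when no
#'   strain is genotyped).
#' @export
allele_summary <- function(gt) {
  if (nrow(gt) == 0) stop("empty strain collection", call. = FALSE)
  loci <- loci_of(gt)
  out <- lapply(loci, function(l) {
    a <- gt[[paste0(l, ".a1")]]
    b <- gt[[paste0(l, ".a2")]]
    keep <- !is.na(a)
    n <- sum(keep)
    if (n == 0) {
      return(list(n = 0L, n_alleles = 0L, freq = numeric(0), uhe = NA_real_))
    }
    tab <- table(c(a[keep], b[keep]))
    p <- as.numeric(tab) / (2 * n)
    names(p) <- names(tab)
    uhe <- if (2 * n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
    list(n = n, n_alleles = length(p), freq = p, uhe = uhe)
  })
  stats::setNames(out, loci)
}

#' Per-date diversity summary
#'
#' For each sampling date: number of complete-genotype strains, number of
#' MLGs, genotypic richness, and (optionally) per-locus allele counts and
#' unbiased heterozygosity. MLG-based statistics use complete genotypes only.
#'
#' @param gt a `genotype_table`.
#' @return data frame with columns `date`, `n_strains`, `n_complete`,
#'   `n_mlg`, `r_mlg`.
#' @export
diversity_by_date <- function(gt) {
  dates <- sort(unique(gt$date))
  rows <- lapply(dates, function(d) {
    sub <- gt[gt$date == d, , drop = FALSE]
    attr(sub, "loci") <- loci_of(gt)
    class(sub) <- class(gt)
    cmp <- sum(complete_rows(sub))
    if (cmp == 0) {
      return(data.frame(date = d, n_strains = nrow(sub), n_complete = 0L,
                        n_mlg = 0L, r_mlg = NA_real_))
    }
    part <- assign_mlgs(sub)
    data.frame(date = d, n_strains = nrow(sub), n_complete = cmp,
               n_mlg = part$n_mlg,
               r_mlg = genotypic_richness(part$n_mlg, cmp))
  })
  do.call(rbind, rows)
}

#' MLG recurrence across periods
#'
#' Counts multilocus genotypes shared between sampling periods (default:
#' calendar years). The diagonal holds the number of distinct MLGs observed in
#' each period; off-diagonal entries count MLGs present in both.
#'
#' @param partition an `mlg_partition` from [assign_mlgs()].
#' @param gt the `genotype_table` the partition was built from.
#' @param grouping either a function mapping a `Date` vector to period labels,
#'   or a named vector `date (as character) -> period`. Default: calendar
#'   year.
#' @return symmetric integer matrix, period x period.
#' @export
mlg_recurrence <- function(partition, gt, grouping = NULL) {
  included <- names(partition$mlg_id)
  sub <- gt[match(included, gt$strain_id), , drop = FALSE]
  if (is.null(grouping)) {
    periods <- format(sub$date, "%Y")
  } else if (is.function(grouping)) {
    periods <- as.character(grouping(sub$date))
  } else {
    periods <- unname(grouping[as.character(sub$date)])
    if (anyNA(periods)) {
      stop("unmapped sampling date(s): ",
           paste(unique(as.character(sub$date)[is.na(periods)]), collapse = ", "),
           call. = FALSE)
    }
  }
  plev <- unique(periods[order(sub$date)])
  sets <- lapply(plev, function(p) unique(partition$mlg_id[periods == p]))
  n <- length(plev)
  m <- matrix(0L, n, n, dimnames = list(plev, plev))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}
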