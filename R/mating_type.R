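#' Assign mating type from the MT-marker fragment pattern
#'
#' The mating type of a strain is read off a multiallelic length-polymorphic
#' marker upstream of the sex-determining gene: presence of one specific
#' allele ("allele A") determines MT+; its absence means MT-. The concrete
#' base-pair size of allele A is population-specific and must be supplied by
#' the caller — there is deliberately no default.
#'
#' @param fragment_sizes integer vector of 1-2 distinct fragment lengths
#'   observed for one strain (diploid marker).
#' @param allele_a_size integer length of allele A in base pairs.
#' @return `"MT_PLUS"` or `"MT_MINUS"`.
#' @export
assign_mating_type <- function(fragment_sizes, allele_a_size) {
  fragment_sizes <- unique(as.integer(fragment_sizes))
  if (length(fragment_sizes) == 0) stop("empty fragment set", call. = FALSE)
  if (length(fragment_sizes) > 2) {
    stop(">2 distinct fragments: possible contamination", call. = FALSE)
  }
  if (any(fragment_sizes <= 0)) stop("fragment sizes must be positive", call. = FALSE)
  if (allele_a_size %in% fragment_sizes) "MT_PLUS" else "MT_MINUS"
}

#' Mating-type ratio per sampling date
#'
#' Computes the per-date fraction of MT+ strains, with an exact two-sided
#' binomial test against the 50:50 equilibrium expectation attached as a
#' supporting statistic (an extension over plain ratio reporting; ignore the
#' p-values if undesired). The summary mean/sd over a date range averages the
#' per-date ratios unweighted — not the pooled-strain ratio — matching how
#' bloom-phase averages are usually quoted; set `pooled = TRUE` for the
#' strain-weighted alternative.
#'
#' @param assignments data frame with columns `date` and `mating_type`
#'   (`"MT_PLUS"` / `"MT_MINUS"`; other values dropped with a message), e.g.
#'   a `genotype_table`.
#' @param from,to optional date range filter (inclusive).
#' @param pooled if TRUE the summary ratio pools strains across dates.
#' @return An `mt_ratio_result`: list with `per_date` (data frame: date,
#'   n_plus, n_minus, ratio_plus, binomial_p), `mean_ratio`, `sd_ratio`,
#'   `pooled`.
#' @export
mt_ratio <- function(assignments, from = NULL, to = NULL, pooled = FALSE) {
  df <- as.data.frame(assignments)[, c("date", "mating_type")]
  df$date <- as.Date(df$date)
  if (!is.null(from)) df <- df[df$date >= as.Date(from), , drop = FALSE]
  if (!is.null(to)) df <- df[df$date <= as.Date(to), , drop = FALSE]
  known <- df$mating_type %in% c("MT_PLUS", "MT_MINUS")
  if (any(!known)) {
    message(sum(!known), " strain(s) with unknown mating type dropped")
    df <- df[known, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no strains with assigned mating type", call. = FALSE)
  dates <- sort(unique(df$date))
  rows <- lapply(dates, function(d) {
    sub <- df[df$date == d, , drop = FALSE]
    np <- sum(sub$mating_type == "MT_PLUS")
    nm <- sum(sub$mating_type == "MT_MINUS")
    data.frame(date = d, n_plus = np, n_minus = nm,
               ratio_plus = np / (np + nm),
               binomial_p = stats::binom.test(np, np + nm, p = 0.5)$p.value)
  })
  per_date <- do.call(rbind, rows)
  if (pooled) {
    mean_ratio <- sum(per_date$n_plus) / sum(per_date$n_plus + per_date$n_minus)
    sd_ratio <- NA_real_
  } else {
    mean_ratio <- mean(per_date$ratio_plus)
    sd_ratio <- stats::sd(per_date$ratio_plus)
  }
  structure(list(per_date = per_date, mean_ratio = mean_ratio,
                 sd_ratio = sd_ratio, pooled = pooled),
            class = "mt_ratio_result")
}

#' @export
print.mt_ratio_result <- function(x, ...) {
  cat(sprintf("mt_ratio_result: %d date(s); mean MT+ ratio = %.3f (sd %.3f)%s\n",
              nrow(x$per_date), x$mean_ratio, x$sd_ratio,
              if (x$pooled) " [pooled]" else ""))
  invisible(x)
}
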