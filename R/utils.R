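#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as CSV with a provenance header
#'
#' Every report file carries commented metadata lines (tool version, seed,
#' configuration hash) so that reruns are auditable.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param meta named list of metadata entries written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("bloomclone ", as.character(utils::packageVersion("bloomclone")))),
            meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_report_csv()]
#'
#' Commented metadata lines are skipped.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Stable short hash of an R object (for provenance headers). Uses the
# serialized representation; stable within a session and across reruns with
# identical inputs.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # fold the bytes into a short hex digest without external dependencies
  v <- as.integer(raw)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  sprintf("%08x", h)
}

# Draw a sub-seed deterministically from a master seed (kept < 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * k) %% 2147483647
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
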