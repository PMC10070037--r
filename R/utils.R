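# Internal helpers: classed conditions, logging, numeric formatting.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a phewasKit error
#'
#' All user-facing failures carry a condition class so callers (and the CLI)
#' can distinguish validation errors, I/O errors, stale caches and numerical
#' failures without parsing messages.
#'
#' @param msg message string
#' @param class one of "validation", "format", "io", "stale_cache",
#'   "numerical", "not_found"
#' @noRd
phewasStop <- function(msg, class = "validation", call. = FALSE) {
  cls <- paste0("phewas_", class, "_error")
  stop(structure(
    class = c(cls, "phewas_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' @noRd
phewasLog <- function(..., level = "INFO", verbose = getOption("phewasKit.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Full-precision decimal rendering of doubles; %.17g round-trips IEEE-754
# exactly through as.numeric(), which the cache and result writers rely on.
formatFull <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

# Missing-cell convention: empty string or "NA" (any case) reads as NA.
readCsvStrict <- function(path) {
  if (!file.exists(path)) {
    phewasStop(sprintf("file not found: %s", path), class = "io")
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("", "NA", "na", "NaN"))
}

# z quantile for 95% Wald intervals, fixed so results are reproducible to
# printed precision across platforms.
Z975 <- 1.959964
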