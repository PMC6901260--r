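#' Write curves and traces to CSV
#'
#' Tidy CSV exchange format (comma-separated, `.` decimal, header row).
#' A `recovery_curve` writes columns `time_s, mean, sem, n` (plus
#' `bleached_mean` when present); a `raw_frap_trace` writes
#' `time_s, roi, whole, background, prebleach` with `prebleach` a 0/1 flag
#' on the leading pre-bleach frames.
#'
#' @param x a [recovery_curve()] or [raw_frap_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  if (inherits(x, "recovery_curve")) {
    df <- data.frame(time_s = x$time_s, mean = x$mean, sem = x$sem,
                     n = rep(attr(x, "n"), nrow(x)))
    if (!is.null(x$bleached_mean)) df$bleached_mean <- x$bleached_mean
  } else if (inherits(x, "raw_frap_trace")) {
    df <- data.frame(time_s = x$times, roi = x$roi, whole = x$whole,
                     background = x$background,
                     prebleach = as.integer(seq_along(x$times) <= x$n_prebleach))
  } else {
    stop("write_curve_csv handles recovery_curve and raw_frap_trace objects")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a curve or raw trace from CSV
#'
#' Auto-detects the object type from the columns: `time_s` + `mean` is a
#' [recovery_curve()]; `time_s` + `roi` + `whole` + `background` +
#' `prebleach` is a [raw_frap_trace()].
#'
#' @param path CSV file path.
#' @return A `recovery_curve` or `raw_frap_trace`.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing required column: time_s")
  if (anyNA(df$time_s)) stop("time_s contains missing values")
  if (anyDuplicated(df$time_s)) stop("time_s contains duplicated time points")
  if (is.unsorted(df$time_s, strictly = TRUE)) stop("time_s must be strictly increasing")
  raw_cols <- c("roi", "whole", "background", "prebleach")
  if (all(raw_cols %in% names(df))) {
    npre <- sum(df$prebleach != 0)
    if (any(diff(df$prebleach) > 0)) stop("prebleach frames must be a leading block")
    return(raw_frap_trace(df$time_s, df$roi, df$whole, df$background, npre))
  }
  if ("mean" %in% names(df)) {
    return(recovery_curve(df$time_s, df$mean,
                          sem = if ("sem" %in% names(df)) df$sem else NA_real_,
                          n = if ("n" %in% names(df)) df$n[1] else 1L,
                          bleached_mean = df$bleached_mean))
  }
  stop("unrecognized columns: need either 'mean' (recovery curve) or '",
       paste(raw_cols, collapse = "', '"), "' (raw trace)")
}
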