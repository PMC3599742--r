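#' Successive RR-interval differences (RRID)
#'
#' The substrate of the whole analysis: for an interval series
#' \eqn{x_1, \dots, x_N}, the RRID series is the signed first difference
#' \eqn{d_i = x_{i+1} - x_i}, \eqn{i = 1, \dots, N-1}. Positive values are
#' decelerations (the heart slows), negative values accelerations; sign and
#' magnitude are both preserved, since a +250 ms and a +100 ms lengthening
#' are physiologically distinct. No detrending, windowing or local-mean
#' normalization is applied.
#'
#' @param record An [rr_record()] with at least 2 intervals.
#'
#' @return An object of class `rrid_series`: a list with `record_id`,
#'   `diffs` (signed differences in ms, length `N - 1`), `source_length`
#'   (`N`) and `label` carried over from the record.
#' @export
#' @examples
#' compute_rrid(rr_record("x", c(800, 810, 790)))$diffs  # 10 -20
compute_rrid <- function(record) {
  stopifnot(inherits(record, "rr_record"))
  n <- length(record$intervals)
  if (n < 2L) {
    stop("record '", record$record_id, "' too short for differencing", call. = FALSE)
  }
  structure(
    list(record_id = record$record_id,
         diffs = diff(record$intervals),
         source_length = n,
         label = record$label),
    class = "rrid_series"
  )
}

#' @export
print.rrid_series <- function(x, ...) {
  cat("RRID series '", x$record_id, "': ", length(x$diffs),
      " differences from ", x$source_length, " intervals, sd ",
      sprintf("%.1f", stats::sd(x$diffs)), " ms\n", sep = "")
  invisible(x)
}
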