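#' RR-interval record
#'
#' An `rr_record` holds an ordered series of interbeat (RR) intervals for one
#' subject or recording, always stored in milliseconds, together with a record
#' identifier and an optional class label (e.g. `"AF"`, `"CHF"`, `"HY"`,
#' `"HE"`, `"WNU"`, `"APNEA"`).
#'
#' @param record_id Character scalar identifying the record.
#' @param intervals Numeric vector of interbeat intervals in milliseconds.
#'   Must have length >= 2 (otherwise no interval difference exists) and all
#'   values strictly positive and finite.
#' @param label Optional character scalar class label, or `NULL`.
#' @param filter Optional function applied to the interval vector before
#'   validation (a hook for future ectopic-beat / artifact filters). The
#'   default `NULL` applies no filtering.
#'
#' @return An object of class `rr_record`: a list with elements `record_id`,
#'   `intervals` (milliseconds) and `label`.
#' @seealso [read_rr_record()], [compute_rrid()]
#' @export
#' @examples
#' r <- rr_record("ex1", c(800, 810, 790), label = "HY")
#' length(r$intervals)
rr_record <- function(record_id, intervals, label = NULL, filter = NULL) {
  if (!is.character(record_id) || length(record_id) != 1L || is.na(record_id)) {
    stop("`record_id` must be a single character string", call. = FALSE)
  }
  intervals <- as.numeric(intervals)
  if (!is.null(filter)) {
    if (!is.function(filter)) stop("`filter` must be a function", call. = FALSE)
    intervals <- as.numeric(filter(intervals))
  }
  if (length(intervals) < 2L) {
    stop("record '", record_id, "' is too short: need at least 2 intervals, got ",
         length(intervals), call. = FALSE)
  }
  if (anyNA(intervals) || any(!is.finite(intervals))) {
    stop("record '", record_id, "' contains missing or non-finite intervals",
         call. = FALSE)
  }
  if (any(intervals <= 0)) {
    stop("record '", record_id, "' contains non-positive intervals; ",
         "RR intervals must be strictly positive", call. = FALSE)
  }
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != 1L || is.na(label)) {
      stop("`label` must be a single character string or NULL", call. = FALSE)
    }
  }
  structure(
    list(record_id = record_id, intervals = intervals, label = label),
    class = "rr_record"
  )
}

#' @export
print.rr_record <- function(x, ...) {
  cat("RR record '", x$record_id, "'",
      if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
      ": ", length(x$intervals), " intervals, mean ",
      sprintf("%.1f", mean(x$intervals)), " ms, SDNN ",
      sprintf("%.1f", stats::sd(x$intervals)), " ms\n", sep = "")
  invisible(x)
}

#' Read an RR-interval record from a plain-text file
#'
#' Reads a PhysioBank-style RR list: one interbeat interval per line. Blank
#' lines and lines starting with `#` are skipped. Values given in seconds are
#' converted to milliseconds at read time; internally all records are in
#' milliseconds.
#'
#' @param path Path to the text file.
#' @param unit Unit of the values in the file: `"ms"` (default) or `"s"`.
#' @param record_id Record identifier; defaults to the file name without
#'   extension.
#' @param label Optional class label.
#' @param filter Optional filter hook passed to [rr_record()].
#'
#' @return An [rr_record()] in milliseconds, input order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0.80", "0.81", "0.79"), f)
#' read_rr_record(f, unit = "s")$intervals   # 800 810 790
read_rr_record <- function(path, unit = c("ms", "s"), record_id = NULL,
                           label = NULL, filter = NULL) {
  unit <- match.arg(unit)
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop("non-numeric value in '", path, "' at line ", lineno[bad[1L]],
         ": \"", raw[lineno[bad[1L]]], "\"", call. = FALSE)
  }
  if (length(vals) < 2L) {
    stop("record file '", path, "' is too short: need at least 2 intervals, got ",
         length(vals), call. = FALSE)
  }
  if (unit == "s") vals <- vals * 1000
  rr_record(record_id, vals, label = label, filter = filter)
}

#' Write an RR-interval record to a plain-text file
#'
#' One interval per line, milliseconds, preceded by a `#` comment naming the
#' record and label. The output is readable by [read_rr_record()].
#'
#' @param record An [rr_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rr_record <- function(record, path) {
  stopifnot(inherits(record, "rr_record"))
  header <- paste0("# record_id=", record$record_id,
                   if (!is.null(record$label)) paste0(" label=", record$label))
  writeLines(c(header, sprintf("%.10g", record$intervals)), path)
  invisible(path)
}

#' A labelled collection of RR records
#'
#' @param records A list of [rr_record()] objects.
#' @return An object of class `rr_corpus` (a list of records).
#' @export
rr_corpus <- function(records) {
  ok <- vapply(records, inherits, logical(1), what = "rr_record")
  if (!all(ok)) stop("all elements must be rr_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id in corpus: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  structure(records, class = "rr_corpus")
}

#' @export
print.rr_corpus <- function(x, ...) {
  labs <- corpus_labels(x)
  cat("RR corpus: ", length(x), " records\n", sep = "")
  if (!all(is.na(labs))) print(table(labs, useNA = "no"))
  invisible(x)
}

#' Class labels of a corpus
#'
#' @param corpus An [rr_corpus()].
#' @return Character vector of labels (`NA` where a record has none).
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus, function(r) if (is.null(r$label)) NA_character_ else r$label,
         character(1))
}

#' @export
`[.rr_corpus` <- function(x, i) {
  rr_corpus(unclass(x)[i])
}
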