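#' Fit a 1-D K-Means symbol model to RRI differences
#'
#' Lloyd's algorithm on one-dimensional data, used to partition RR-interval
#' differences into `k` clusters that become the symbol alphabet. The fit is
#' fully deterministic: initial centroids are the data quantiles at positions
#' \eqn{(i + 0.5)/k}, \eqn{i = 0, \dots, k-1}; iterations alternate
#' nearest-centroid assignment (ties broken toward the smaller centroid) and
#' centroid update (arithmetic mean of assigned points) until the maximum
#' centroid movement falls below `tol` or `max_iter` is reached. A cluster
#' left empty is re-seeded at the data point farthest from its currently
#' assigned centroid. Final centroids are sorted ascending and mapped to
#' letters: `a` for the smallest centroid, `b` for the next, and so on.
#'
#' @param values Numeric vector to cluster (typically RRI differences, ms).
#'   Must contain at least `k` distinct values.
#' @param k Number of clusters, an integer in `[2, 26]` (each cluster gets
#'   one lower-case letter).
#' @param seed Integer seed, stored in the model. The fit itself is
#'   deterministic; the seed is threaded through for API stability and for
#'   pooled-fit subsampling upstream.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param tol Convergence tolerance on centroid movement in ms (default 1e-6).
#' @param trace If `TRUE`, record the within-cluster sum of squares after
#'   every update step in the `wcss_trace` element.
#'
#' @return An object of class `symbol_model`: list with `k`, `centroids`
#'   (ascending, ms), `letters` (the first `k` letters, aligned with
#'   `centroids`), `fit_scope` (filled by callers; `"per_record"` here),
#'   `seed`, `iterations`, `converged`, `wcss` and optionally `wcss_trace`.
#' @export
#' @examples
#' m <- kmeans1d_fit(c(-101, -99, -1, 1, 99, 101), k = 3)
#' m$centroids  # -100 0 100
kmeans1d_fit <- function(values, k, seed = 1L, max_iter = 300L, tol = 1e-6,
                         trace = FALSE) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values contain missing or non-finite entries", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  if (k > 26L) {
    stop("`k` = ", k, " exceeds the 26-letter alphabet", call. = FALSE)
  }
  n_distinct <- length(unique(values))
  if (n_distinct < k) {
    stop("infeasible k: only ", n_distinct, " distinct values for k = ", k,
         "; lower k", call. = FALSE)
  }

  # deterministic quantile seeding at positions (i + 0.5)/k
  cent <- as.numeric(stats::quantile(values, probs = (seq_len(k) - 0.5) / k,
                                     names = FALSE, type = 7))
  if (anyDuplicated(cent)) {
    # heavily tied data can collapse quantiles; fall back to evenly spaced
    # distinct observed values (still deterministic)
    uv <- sort(unique(values))
    cent <- uv[floor((seq_len(k) - 0.5) / k * length(uv)) + 1L]
  }

  wcss_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    assign <- nearest_centroid(values, cent)
    sizes <- tabulate(assign, nbins = k)
    if (any(sizes == 0L)) {
      dist_to_own <- abs(values - cent[assign])
      for (j in which(sizes == 0L)) {
        far <- which.max(dist_to_own)
        cent[j] <- values[far]
        assign[far] <- j
        dist_to_own[far] <- 0
      }
      # reseeding may break centroid order; restore it (pure relabelling)
      ord <- order(cent)
      cent <- cent[ord]
      assign <- order(ord)[assign]
    }
    new_cent <- vapply(seq_len(k), function(j) mean(values[assign == j]),
                       numeric(1))
    movement <- max(abs(new_cent - cent))
    if (trace) {
      wcss_trace <- c(wcss_trace, sum((values - new_cent[assign])^2))
    }
    ord <- order(new_cent)
    cent <- new_cent[ord]
    assign <- order(ord)[assign]
    if (movement < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(k = k,
         centroids = cent,
         letters = letters[seq_len(k)],
         fit_scope = "per_record",
         seed = as.integer(seed),
         iterations = iterations,
         converged = converged,
         wcss = sum((values - cent[nearest_centroid(values, cent)])^2),
         wcss_trace = wcss_trace),
    class = "symbol_model"
  )
}

# Nearest-centroid assignment in 1-D for ascending centroids.
# A point exactly midway between two centroids goes to the smaller one.
nearest_centroid <- function(x, cent) {
  if (length(cent) == 1L) return(rep(1L, length(x)))
  mids <- (cent[-length(cent)] + cent[-1L]) / 2
  findInterval(x, mids, left.open = TRUE) + 1L
}

#' @export
print.symbol_model <- function(x, ...) {
  cat("1-D K-Means symbol model: k = ", x$k, ", fit = ", x$fit_scope,
      ", ", x$iterations, " iterations",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  print(stats::setNames(round(x$centroids, 3), x$letters))
  invisible(x)
}

#' Map RRI differences to symbols with a fitted model
#'
#' Each difference is assigned the letter of its nearest centroid; a value
#' exactly midway between two centroids takes the smaller centroid's letter.
#' Output length equals input length.
#'
#' @param diffs An [compute_rrid()] result, or a plain numeric vector.
#' @param model A fitted [kmeans1d_fit()] model.
#' @param record_id,label Used when `diffs` is a bare numeric vector.
#'
#' @return An object of class `symbol_sequence`: list with `record_id`,
#'   `symbols` (single character string over the first `k` letters), `label`
#'   and `k`.
#' @export
#' @examples
#' m <- kmeans1d_fit(c(-101, -99, -1, 1, 99, 101), k = 3)
#' assign_symbols(c(-100, 0, 100, -100), m)$symbols  # "abca"
assign_symbols <- function(diffs, model, record_id = "series", label = NULL) {
  if (!inherits(model, "symbol_model") || is.null(model$centroids)) {
    stop("`model` must be a fitted symbol_model", call. = FALSE)
  }
  if (inherits(diffs, "rrid_series")) {
    record_id <- diffs$record_id
    label <- diffs$label
    diffs <- diffs$diffs
  }
  diffs <- as.numeric(diffs)
  idx <- nearest_centroid(diffs, model$centroids)
  structure(
    list(record_id = record_id,
         symbols = paste(model$letters[idx], collapse = ""),
         label = label,
         k = model$k),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  s <- x$symbols
  cat("Symbol sequence '", x$record_id, "'",
      if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
      ": length ", nchar(s), ", alphabet size ", x$k, "\n", sep = "")
  cat(substr(s, 1L, 60L), if (nchar(s) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Symbolize one RR record
#'
#' Composition step: difference the record, then symbolize the differences.
#' With `fit_scope = "per_record"` (the default, and the reading that makes
#' the method adaptive) the K-Means model is fitted on this record's own
#' differences, so the alphabet adapts to each record's variability scale.
#' With `fit_scope = "pooled"` a pre-fitted model (typically fitted on
#' training-set differences only) must be supplied, giving symbols that are
#' comparable across records.
#'
#' @param record An [rr_record()].
#' @param k Cluster count (alphabet size), used for per-record fits.
#' @param seed Integer seed threaded to the fit.
#' @param fit_scope `"per_record"` or `"pooled"`.
#' @param pooled_model A fitted [kmeans1d_fit()] model; required when
#'   `fit_scope = "pooled"`.
#' @param ... Further arguments (`max_iter`, `tol`) passed to
#'   [kmeans1d_fit()].
#'
#' @return A list with elements `sequence` (a `symbol_sequence`) and `model`
#'   (the `symbol_model` used).
#' @export
symbolize_record <- function(record, k = 10L, seed = 1L,
                             fit_scope = c("per_record", "pooled"),
                             pooled_model = NULL, ...) {
  fit_scope <- match.arg(fit_scope)
  rrid <- compute_rrid(record)
  if (fit_scope == "pooled") {
    if (is.null(pooled_model)) {
      stop("pooled fit scope requires `pooled_model`", call. = FALSE)
    }
    model <- pooled_model
    model$fit_scope <- "pooled"
  } else {
    model <- kmeans1d_fit(rrid$diffs, k = k, seed = seed, ...)
    model$fit_scope <- "per_record"
  }
  list(sequence = assign_symbols(rrid, model), model = model)
}

#' Write symbol sequences as FASTA-like text
#'
#' One `>record_id label=<label>` header line, then the symbol string (wrapped
#' at 70 characters), for inspection and plain-text fixtures.
#'
#' @param sequences A list of `symbol_sequence` objects (or a single one).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_symbol_fasta <- function(sequences, path) {
  if (inherits(sequences, "symbol_sequence")) sequences <- list(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sequences) {
    header <- paste0(">", s$record_id,
                     if (!is.null(s$label)) paste0(" label=", s$label))
    writeLines(header, con)
    n <- nchar(s$symbols)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(s$symbols, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}

#' Read symbol sequences from FASTA-like text
#'
#' @param path Path written by [write_symbol_fasta()].
#' @return A list of `symbol_sequence` objects.
#' @export
read_symbol_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  hdr <- grep("^>", raw)
  if (length(hdr) == 0L) stop("no sequence headers in '", path, "'", call. = FALSE)
  ends <- c(hdr[-1L] - 1L, length(raw))
  lapply(seq_along(hdr), function(i) {
    h <- sub("^>", "", raw[hdr[i]])
    label <- if (grepl(" label=", h)) sub("^.* label=", "", h) else NULL
    id <- sub(" label=.*$", "", h)
    sym <- paste(raw[seq(hdr[i] + 1L, ends[i])], collapse = "")
    structure(
      list(record_id = id, symbols = sym, label = label,
           k = max(match(unique(strsplit(sym, "")[[1L]]), letters))),
      class = "symbol_sequence"
    )
  })
}
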