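#' Enumerate the gram vocabulary
#'
#' All grams of orders 1..`n_max` over the first `k` letters, in canonical
#' order: by gram length first, then lexicographically. The vocabulary size
#' is \eqn{k + k^2 + \dots + k^{n_{max}}}; with the full 26-letter alphabet
#' and `n_max = 3` that is 18,278 grams. The canonical order fixes the
#' column order of every feature matrix, so files are byte-comparable
#' across runs.
#'
#' @param k Alphabet size, `1 <= k <= 26` (`k = 1` is allowed for degenerate
#'   test cases; analysis uses `k >= 2`).
#' @param n_max Maximal gram order, `>= 1`. Default 3.
#'
#' @return An object of class `gram_vocabulary`: list with `k`, `n_max`,
#'   `grams` (character vector in canonical order) and `size`.
#' @export
#' @examples
#' build_vocabulary(3, 2)$grams  # a b c aa ab ... cc (12 grams)
#' build_vocabulary(26, 3)$size  # 18278
build_vocabulary <- function(k, n_max = 3L) {
  k <- as.integer(k)
  n_max <- as.integer(n_max)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1", call. = FALSE)
  if (k > 26L) stop("`k` = ", k, " exceeds the 26-letter alphabet", call. = FALSE)
  if (is.na(n_max) || n_max < 1L) stop("`n_max` must be >= 1", call. = FALSE)
  ab <- letters[seq_len(k)]
  per_order <- vector("list", n_max)
  per_order[[1L]] <- ab
  if (n_max >= 2L) {
    for (n in 2:n_max) {
      # row-major outer keeps lexicographic order
      per_order[[n]] <- as.vector(t(outer(per_order[[n - 1L]], ab, paste0)))
    }
  }
  grams <- unlist(per_order, use.names = FALSE)
  structure(
    list(k = k, n_max = n_max, grams = grams, size = length(grams)),
    class = "gram_vocabulary"
  )
}

#' @export
print.gram_vocabulary <- function(x, ...) {
  cat("Gram vocabulary: k = ", x$k, ", orders 1..", x$n_max, ", ",
      x$size, " grams\n", sep = "")
  invisible(x)
}

#' Count overlapping n-grams in a symbol sequence
#'
#' Counts every gram of order `n` over all overlapping windows of stride 1,
#' order-sensitively ("ab" and "ba" are different grams). For a sequence of
#' length `L >= n` the counts sum to `L - n + 1`.
#'
#' @param symbols A `symbol_sequence` or a single character string.
#' @param n Gram order, `>= 1`.
#'
#' @return Named integer vector of counts for the grams that occur (absent
#'   grams are simply missing, i.e. zero).
#' @export
#' @examples
#' count_ngrams("ababab", 2)  # ab: 3, ba: 2
count_ngrams <- function(symbols, n) {
  if (inherits(symbols, "symbol_sequence")) symbols <- symbols$symbols
  stopifnot(is.character(symbols), length(symbols) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("gram order `n` must be >= 1", call. = FALSE)
  L <- nchar(symbols)
  if (L < n) return(stats::setNames(integer(0), character(0)))
  starts <- seq_len(L - n + 1L)
  windows <- substring(symbols, starts, starts + n - 1L)
  tab <- table(windows)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-record gram probability features
#'
#' For each gram order `n = 1..n_max`, the probability of a gram is its
#' overlapping-occurrence count divided by the number of windows
#' `L - n + 1`, so the probabilities of each order sum to one. Grams never
#' observed have probability zero. The probabilities over the full
#' vocabulary form the record's row of the probability matrix fed to the
#' classifiers.
#'
#' @param symbols A `symbol_sequence` (or character string).
#' @param vocabulary A [build_vocabulary()] result whose alphabet contains
#'   every letter occurring in `symbols`.
#' @param record_id,label Used when `symbols` is a bare string.
#'
#' @return An object of class `gram_features`: list with `record_id`,
#'   `label`, `vocabulary`, and `probabilities` — a named numeric vector
#'   over the observed grams only (sparse; absent means zero).
#' @export
#' @examples
#' v <- build_vocabulary(2, 2)
#' featurize("abab", v)$probabilities  # a,b = 0.5; ab = 2/3; ba = 1/3
featurize <- function(symbols, vocabulary, record_id = "series", label = NULL) {
  stopifnot(inherits(vocabulary, "gram_vocabulary"))
  if (inherits(symbols, "symbol_sequence")) {
    record_id <- symbols$record_id
    label <- symbols$label
    symbols <- symbols$symbols
  }
  used <- unique(strsplit(symbols, "")[[1L]])
  allowed <- letters[seq_len(vocabulary$k)]
  if (!all(used %in% allowed)) {
    stop("sequence letter(s) ", paste(setdiff(used, allowed), collapse = ", "),
         " outside the k = ", vocabulary$k, " vocabulary alphabet",
         call. = FALSE)
  }
  L <- nchar(symbols)
  probs <- numeric(0)
  for (n in seq_len(vocabulary$n_max)) {
    if (L < n) next
    counts <- count_ngrams(symbols, n)
    probs <- c(probs, counts / (L - n + 1L))
  }
  structure(
    list(record_id = record_id, label = label, vocabulary = vocabulary,
         probabilities = probs),
    class = "gram_features"
  )
}

#' @export
print.gram_features <- function(x, ...) {
  cat("Gram features '", x$record_id, "'",
      if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
      ": ", length(x$probabilities), " non-zero of ",
      x$vocabulary$size, " grams (k = ", x$vocabulary$k,
      ", n_max = ", x$vocabulary$n_max, ")\n", sep = "")
  invisible(x)
}

#' Assemble gram features into a dense feature set
#'
#' Stacks per-record sparse probability vectors into a records-by-vocabulary
#' matrix with columns in canonical vocabulary order — the probability
#' matrix used for classification.
#'
#' @param features A list of [featurize()] results sharing one vocabulary
#'   (same `k`, same `n_max`).
#'
#' @return An object of class `gram_feature_set`: list with `x` (numeric
#'   matrix, rows = records, columns = grams), `record_ids`, `labels`
#'   (character, `NA` if absent) and `vocabulary`.
#' @export
feature_set <- function(features) {
  if (inherits(features, "gram_features")) features <- list(features)
  if (length(features) == 0L) stop("empty feature list", call. = FALSE)
  ok <- vapply(features, inherits, logical(1), what = "gram_features")
  if (!all(ok)) stop("all elements must be gram_features", call. = FALSE)
  voc <- features[[1L]]$vocabulary
  same <- vapply(features, function(f) {
    f$vocabulary$k == voc$k && f$vocabulary$n_max == voc$n_max
  }, logical(1))
  if (!all(same)) {
    stop("inconsistent vocabularies across records (k or n_max differ)",
         call. = FALSE)
  }
  x <- matrix(0, nrow = length(features), ncol = voc$size,
              dimnames = list(NULL, voc$grams))
  for (i in seq_along(features)) {
    p <- features[[i]]$probabilities
    x[i, names(p)] <- p
  }
  structure(
    list(x = x,
         record_ids = vapply(features, `[[`, character(1), "record_id"),
         labels = vapply(features, function(f) {
           if (is.null(f$label)) NA_character_ else f$label
         }, character(1)),
         vocabulary = voc),
    class = "gram_feature_set"
  )
}

#' @export
print.gram_feature_set <- function(x, ...) {
  cat("Gram feature set: ", nrow(x$x), " records x ", ncol(x$x),
      " grams (k = ", x$vocabulary$k, ", n_max = ", x$vocabulary$n_max,
      ")\n", sep = "")
  invisible(x)
}

#' Write a gram feature matrix to CSV
#'
#' Columns: `record_id`, `label`, then one column per gram in canonical
#' vocabulary order. Probabilities are written with 17 significant digits so
#' the file round-trips losslessly through [read_feature_matrix()].
#'
#' @param features A list of [featurize()] results (or a `gram_feature_set`).
#'   May be empty, in which case `vocabulary` must be supplied and a
#'   header-only CSV is written.
#' @param path Output CSV path.
#' @param vocabulary Vocabulary for the header when `features` is empty.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path, vocabulary = NULL) {
  if (inherits(features, "gram_feature_set")) {
    fs <- features
  } else if (length(features) == 0L) {
    if (is.null(vocabulary)) {
      stop("empty feature list needs an explicit `vocabulary` for the header",
           call. = FALSE)
    }
    writeLines(paste(c("record_id", "label", vocabulary$grams), collapse = ","),
               path)
    return(invisible(path))
  } else {
    fs <- feature_set(features)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("record_id", "label", fs$vocabulary$grams), collapse = ","),
             con)
  for (i in seq_len(nrow(fs$x))) {
    writeLines(paste(c(fs$record_ids[i],
                       ifelse(is.na(fs$labels[i]), "", fs$labels[i]),
                       sprintf("%.17g", fs$x[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' Read a gram feature matrix written by [write_feature_matrix()]
#'
#' The vocabulary is reconstructed from the header: `k` is the number of
#' 1-letter gram columns and `n_max` the longest gram length.
#'
#' @param path CSV path.
#' @return A `gram_feature_set` (with zero-row `x` for a header-only file).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(record_id = "character",
                                       label = "character"))
  grams <- setdiff(names(df), c("record_id", "label"))
  if (length(grams) == 0L) stop("no gram columns in '", path, "'", call. = FALSE)
  voc <- build_vocabulary(k = sum(nchar(grams) == 1L),
                          n_max = max(nchar(grams)))
  if (!identical(voc$grams, grams)) {
    stop("gram columns of '", path, "' are not a canonical vocabulary",
         call. = FALSE)
  }
  x <- as.matrix(df[, grams, drop = FALSE])
  dimnames(x) <- list(NULL, grams)
  labels <- df$label
  labels[!is.na(labels) & labels == ""] <- NA_character_
  structure(
    list(x = x, record_ids = df$record_id, labels = labels, vocabulary = voc),
    class = "gram_feature_set"
  )
}
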