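# Shared fixtures built in code: no binary data, everything seeded.

# random symbol sequence over the first k letters
random_sequence <- function(len, k, seed) {
  withr::with_seed(seed,
    paste(sample(letters[seq_len(k)], len, replace = TRUE), collapse = ""))
}

# brute-force overlapping n-gram scan, independent of count_ngrams()
scan_ngrams <- function(s, n) {
  L <- nchar(s)
  if (L < n) return(integer(0))
  out <- new.env(parent = emptyenv())
  for (i in seq_len(L - n + 1L)) {
    g <- substr(s, i, i + n - 1L)
    out[[g]] <- (if (is.null(out[[g]])) 0L else out[[g]]) + 1L
  }
  vals <- vapply(ls(out), function(g) out[[g]], integer(1))
  vals[order(names(vals))]
}

# exhaustive nearest-centroid search (ties to the lower-indexed centroid)
scan_nearest <- function(x, centroids) {
  vapply(x, function(v) which.min(abs(v - centroids)), integer(1))
}

# direct Bayes-rule evaluation of the Gaussian naive Bayes posterior
scan_gnb <- function(model, x) {
  apply(x, 1L, function(row) {
    lp <- vapply(seq_along(model$classes), function(i) {
      model$log_prior[i] +
        sum(stats::dnorm(row, model$mean[i, ], sqrt(model$var[i, ]), log = TRUE))
    }, numeric(1))
    model$classes[which.max(lp)]
  })
}

# a tiny labelled two-class feature set with a perfectly separating feature
tiny_separable_set <- function(n_per_class = 6) {
  voc <- build_vocabulary(2, 1)
  feats <- c(
    lapply(seq_len(n_per_class), function(i) {
      featurize(strrep("a", 10), voc, record_id = paste0("A", i), label = "A")
    }),
    lapply(seq_len(n_per_class), function(i) {
      featurize(strrep("b", 10), voc, record_id = paste0("B", i), label = "B")
    })
  )
  feature_set(feats)
}
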