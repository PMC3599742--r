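#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param stratified Stratify folds by class (default `TRUE`). With a small
#'   class (e.g. 9 records) plain random folds can leave a training fold
#'   without that class; stratification preserves class proportions to
#'   within one record per fold.
#' @param seed Integer seed controlling the fold assignment (and any
#'   classifier randomness routed through it).
#' @param classifier_name Informational name recorded in reports.
#'
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, stratified = TRUE, seed = 1L,
                      classifier_name = "gnb") {
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  structure(
    list(folds = folds, stratified = isTRUE(stratified),
         seed = as.integer(seed), classifier_name = classifier_name),
    class = "cv_config"
  )
}

#' Build cross-validation folds
#'
#' Partitions the index set `1..length(labels)` into `config$folds`
#' validation sets that are pairwise disjoint and exhaustive, so each record
#' is validated exactly once. With stratification (the default), each
#' class's members are shuffled and dealt round-robin across folds, keeping
#' every fold's class counts within one of exact proportionality; the
#' dealing offset rotates between classes so overall fold sizes stay
#' balanced. Deterministic given `config$seed`.
#'
#' @param labels Character vector of class labels, one per record.
#' @param config A [cv_config()].
#'
#' @return A list of `config$folds` elements, each a list with integer
#'   vectors `train` and `validation`.
#' @export
make_folds <- function(labels, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  labels <- as.character(labels)
  n <- length(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (config$folds > n) {
    stop("more folds (", config$folds, ") than records (", n, ")", call. = FALSE)
  }
  nf <- config$folds
  fold_id <- integer(n)
  withr::with_seed(config$seed, {
    if (config$stratified) {
      offset <- 0L
      for (cls in sort(unique(labels))) {
        idx <- which(labels == cls)
        idx <- if (length(idx) > 1L) sample(idx) else idx
        fold_id[idx] <- ((seq_along(idx) - 1L + offset) %% nf) + 1L
        offset <- (offset + length(idx)) %% nf
      }
    } else {
      fold_id <- sample(rep(seq_len(nf), length.out = n))
    }
  })
  lapply(seq_len(nf), function(f) {
    list(train = which(fold_id != f), validation = which(fold_id == f))
  })
}

#' Pluggable classifier interface
#'
#' A classifier is a list with a `name`, a `fit(x, y)` function returning a
#' fitted model, and a `predict(model, x)` function returning a character
#' vector of predicted labels, where `x` is a numeric feature matrix and `y`
#' a character vector. [classifier_gnb()] is the fully specified reference
#' classifier; the others adapt established implementations and require
#' their package (declared in Suggests) at call time.
#'
#' @param name Classifier name.
#' @param fit Function `(x, y) -> model`.
#' @param predict Function `(model, x) -> character`.
#' @return An object of class `aiia_classifier`.
#' @export
new_classifier <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "aiia_classifier")
}

#' @export
print.aiia_classifier <- function(x, ...) {
  cat("classifier:", x$name, "\n")
  invisible(x)
}

#' Reference classifier: Gaussian naive Bayes
#'
#' Deterministic and dependency-free. Class priors are the training class
#' frequencies; each feature gets a class-conditional Gaussian whose
#' variance is floored at `1e-9` times the largest pooled feature variance
#' (so constant features in a class remain usable); prediction is the argmax
#' of log-prior plus summed log-densities, ties resolved toward the first
#' class in sorted order.
#'
#' @return An `aiia_classifier`.
#' @seealso [gnb_fit()], [gnb_predict()]
#' @export
classifier_gnb <- function() {
  new_classifier("gnb",
                 fit = function(x, y) gnb_fit(x, y),
                 predict = function(model, x) gnb_predict(model, x))
}

#' Adapters to established classifier implementations
#'
#' Thin wrappers satisfying the classifier interface: multinomial logistic
#' regression (`nnet::multinom`), kernel naive Bayes (`e1071::naiveBayes`),
#' a support vector machine (`e1071::svm`), a single-hidden-layer neural
#' network (`nnet::nnet`) and a CART decision tree (`rpart::rpart`). Each
#' needs its package installed. The neural network's random initial weights
#' are tied to `seed`.
#'
#' @param seed Integer seed for classifiers with internal randomness.
#' @param ... Passed on to the underlying implementation.
#' @return An `aiia_classifier`.
#' @name classifier_adapters
NULL

#' @rdname classifier_adapters
#' @export
classifier_logistic <- function(...) {
  new_classifier(
    "logistic",
    fit = function(x, y) {
      requireNamespace("nnet", quietly = TRUE) ||
        stop("classifier_logistic needs the 'nnet' package", call. = FALSE)
      d <- data.frame(.y = factor(y), x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = d, trace = FALSE, MaxNWts = 1e6, ...)
    },
    predict = function(model, x) {
      as.character(stats::predict(model,
                                  newdata = as.data.frame(x, check.names = FALSE)))
    })
}

#' @rdname classifier_adapters
#' @export
classifier_naive_bayes <- function(...) {
  new_classifier(
    "naive_bayes",
    fit = function(x, y) {
      requireNamespace("e1071", quietly = TRUE) ||
        stop("classifier_naive_bayes needs the 'e1071' package", call. = FALSE)
      e1071::naiveBayes(x, factor(y), ...)
    },
    predict = function(model, x) as.character(stats::predict(model, x)))
}

#' @rdname classifier_adapters
#' @export
classifier_svm <- function(...) {
  new_classifier(
    "svm",
    fit = function(x, y) {
      requireNamespace("e1071", quietly = TRUE) ||
        stop("classifier_svm needs the 'e1071' package", call. = FALSE)
      e1071::svm(x, factor(y), ...)
    },
    predict = function(model, x) as.character(stats::predict(model, x)))
}

#' @rdname classifier_adapters
#' @export
classifier_nnet <- function(seed = 1L, ...) {
  new_classifier(
    "nnet",
    fit = function(x, y) {
      requireNamespace("nnet", quietly = TRUE) ||
        stop("classifier_nnet needs the 'nnet' package", call. = FALSE)
      withr::with_seed(seed,
        nnet::nnet(x, nnet::class.ind(factor(y)), size = 5, trace = FALSE,
                   softmax = TRUE, MaxNWts = 1e6, ...))
    },
    predict = function(model, x) {
      p <- stats::predict(model, x)
      colnames(p)[max.col(p, ties.method = "first")]
    })
}

#' @rdname classifier_adapters
#' @export
classifier_tree <- function(...) {
  new_classifier(
    "tree",
    fit = function(x, y) {
      requireNamespace("rpart", quietly = TRUE) ||
        stop("classifier_tree needs the 'rpart' package", call. = FALSE)
      d <- data.frame(.y = factor(y), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = d, method = "class", ...)
    },
    predict = function(model, x) {
      as.character(stats::predict(model,
                                  newdata = as.data.frame(x, check.names = FALSE),
                                  type = "class"))
    })
}

#' Look up a classifier by name
#'
#' @param name One of `"gnb"`, `"logistic"`, `"naive_bayes"`, `"svm"`,
#'   `"nnet"`, `"tree"`.
#' @param seed Seed for classifiers with internal randomness.
#' @return An `aiia_classifier`.
#' @export
get_classifier <- function(name, seed = 1L) {
  switch(name,
         gnb = classifier_gnb(),
         logistic = classifier_logistic(),
         naive_bayes = classifier_naive_bayes(),
         svm = classifier_svm(),
         nnet = classifier_nnet(seed = seed),
         tree = classifier_tree(),
         stop("unknown classifier '", name, "'", call. = FALSE))
}

# ---- CV report ---------------------------------------------------------

# truth/pred are character; fold_id integer per record; classes fixes
# the confusion matrix dimension and order.
new_cv_report <- function(truth, pred, fold_id, classes,
                          classifier_name = NA_character_, config = NULL) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  confusion <- table(truth = truth, predicted = pred)
  n_total <- length(truth)
  n_correct <- sum(diag(confusion))
  per_fold <- vapply(sort(unique(fold_id)), function(f) {
    sel <- fold_id == f
    mean(truth[sel] == pred[sel])
  }, numeric(1))
  report <- structure(
    list(confusion = unclass(confusion),
         per_fold_accuracy = per_fold,
         overall_accuracy = n_correct / n_total,
         per_class_accuracy = NULL,
         n_total = n_total,
         n_correct = n_correct,
         n_incorrect = n_total - n_correct,
         classifier_name = classifier_name,
         config = config),
    class = "cv_report"
  )
  report$per_class_accuracy <- per_class_accuracy(report)
  report
}

#' Build a CV report from a confusion matrix
#'
#' For summarizing printed confusion tables or externally computed results
#' in the same accounting structure used by [crossvalidate()].
#'
#' @param confusion Square class-by-class count matrix (rows = truth,
#'   columns = predicted) with identical row and column names.
#' @return A `cv_report` (with no per-fold accuracies).
#' @export
report_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion),
            identical(rownames(confusion), colnames(confusion)))
  n_total <- sum(confusion)
  n_correct <- sum(diag(confusion))
  report <- structure(
    list(confusion = confusion,
         per_fold_accuracy = numeric(0),
         overall_accuracy = n_correct / n_total,
         per_class_accuracy = NULL,
         n_total = n_total,
         n_correct = n_correct,
         n_incorrect = n_total - n_correct,
         classifier_name = NA_character_,
         config = NULL),
    class = "cv_report"
  )
  report$per_class_accuracy <- per_class_accuracy(report)
  report
}

#' Per-class accuracy from a CV report
#'
#' The diagonal of the confusion matrix over its row sums: the fraction of
#' each true class that was correctly classified.
#'
#' @param report A `cv_report`.
#' @return Named numeric vector, one value in `[0, 1]` per class.
#' @export
per_class_accuracy <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  rs <- rowSums(report$confusion)
  if (any(rs == 0)) {
    stop("class(es) with no records: ",
         paste(rownames(report$confusion)[rs == 0], collapse = ", "),
         call. = FALSE)
  }
  diag(report$confusion) / rs
}

#' Format an accuracy the way results tables print it
#'
#' Percentage with one decimal place, rounding half away from zero
#' (126/142 prints as 88.7).
#'
#' @param correct,total Counts, or `total = NULL` to treat `correct` as a
#'   proportion in `[0, 1]`.
#' @return Numeric percentage rounded to one decimal place.
#' @export
#' @examples
#' accuracy_from_counts(126, 142)  # 88.7
accuracy_from_counts <- function(correct, total = NULL) {
  p <- if (is.null(total)) correct else correct / total
  pct <- p * 100
  # round half up at one decimal, guarding against representation error
  floor(pct * 10 + 0.5 + 1e-9) / 10
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validated classification report",
      if (!is.na(x$classifier_name)) paste0(" (", x$classifier_name, ")"),
      "\n", sep = "")
  cat("  Total instances:       ", x$n_total, "\n", sep = "")
  cat("  Correctly classified:  ", x$n_correct, "\n", sep = "")
  cat("  Incorrectly classified:", x$n_incorrect, "\n", sep = " ")
  cat("  Accuracy:              ",
      sprintf("%.1f%%", accuracy_from_counts(x$overall_accuracy)), "\n", sep = "")
  cat("\nPer-class accuracy:\n")
  pc <- x$per_class_accuracy
  tab <- rbind(Total = rowSums(x$confusion),
               Correct = diag(x$confusion),
               Incorrect = rowSums(x$confusion) - diag(x$confusion),
               `Accuracy %` = accuracy_from_counts(pc))
  print(tab)
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' @param report A `cv_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_cv_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  confusion <- apply(report$confusion, 1L, function(row) as.list(row),
                     simplify = FALSE)
  obj <- list(classifier = report$classifier_name,
              n_total = report$n_total,
              n_correct = report$n_correct,
              n_incorrect = report$n_incorrect,
              overall_accuracy = report$overall_accuracy,
              per_class_accuracy = as.list(report$per_class_accuracy),
              per_fold_accuracy = report$per_fold_accuracy,
              confusion = confusion)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---- cross-validation --------------------------------------------------

#' Cross-validated classification
#'
#' Runs `config$folds`-fold cross-validation and aggregates the fold
#' predictions into a single pooled confusion matrix (so `n_correct` counts
#' instances, matching how results tables report "correctly classified
#' instances"; the mean of per-fold accuracies is also available in the
#' report).
#'
#' The input can be a ready-made [feature_set()] (features computed once,
#' which is sound for per-record symbolization: each record's symbols depend
#' only on itself) or an [rr_corpus()]. For a corpus with
#' `fit_scope = "pooled"`, the symbol model is refitted inside every fold on
#' the training records' differences only, then applied to train and
#' validation records, so validation data never influence the centroids.
#'
#' @param x A `gram_feature_set` or an `rr_corpus`.
#' @param config A [cv_config()].
#' @param classifier An `aiia_classifier` (default the Gaussian naive Bayes
#'   reference classifier).
#' @param ... Method-specific arguments.
#' @return A `cv_report`.
#' @export
crossvalidate <- function(x, config = cv_config(), classifier = classifier_gnb(),
                          ...) {
  UseMethod("crossvalidate")
}

#' @rdname crossvalidate
#' @export
crossvalidate.gram_feature_set <- function(x, config = cv_config(),
                                           classifier = classifier_gnb(), ...) {
  labels <- x$labels
  if (anyNA(labels)) stop("all records need labels for classification", call. = FALSE)
  folds <- make_folds(labels, config)
  run_folds(x$x, labels, folds, classifier, config)
}

#' @param k Alphabet size for symbolization (corpus method).
#' @param n_max Maximal gram order (corpus method).
#' @param fit_scope `"per_record"` or `"pooled"` (corpus method).
#' @param pool_max_points When pooling, at most this many training
#'   differences are subsampled (seeded) for the K-Means fit.
#' @rdname crossvalidate
#' @export
crossvalidate.rr_corpus <- function(x, config = cv_config(),
                                    classifier = classifier_gnb(),
                                    k = 10L, n_max = 2L,
                                    fit_scope = c("per_record", "pooled"),
                                    pool_max_points = 50000L, ...) {
  fit_scope <- match.arg(fit_scope)
  labels <- corpus_labels(x)
  if (anyNA(labels)) stop("all records need labels for classification", call. = FALSE)
  voc <- build_vocabulary(k, n_max)
  if (fit_scope == "per_record") {
    feats <- lapply(x, function(r) {
      featurize(symbolize_record(r, k = k, seed = config$seed)$sequence, voc)
    })
    return(crossvalidate(feature_set(feats), config, classifier))
  }

  # pooled scope: refit the symbol model per fold on training diffs only
  rrids <- lapply(x, compute_rrid)
  folds <- make_folds(labels, config)
  n <- length(x)
  pred <- character(n)
  fold_id <- integer(n)
  centroid_sources <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$validation
    pool <- unlist(lapply(rrids[tr], `[[`, "diffs"), use.names = FALSE)
    if (length(pool) > pool_max_points) {
      pool <- withr::with_seed(config$seed + f,
                               sample(pool, pool_max_points))
    }
    model <- kmeans1d_fit(pool, k = k, seed = config$seed)
    model$fit_scope <- "pooled"
    feats <- lapply(rrids, function(d) featurize(assign_symbols(d, model), voc))
    fs <- feature_set(feats)
    fitted <- classifier$fit(fs$x[tr, , drop = FALSE], labels[tr])
    pred[va] <- classifier$predict(fitted, fs$x[va, , drop = FALSE])
    fold_id[va] <- f
    centroid_sources[[f]] <- tr
  }
  report <- new_cv_report(labels, pred, fold_id, sort(unique(labels)),
                          classifier$name, config)
  # bookkeeping: which records' diffs were eligible for centroid fitting
  attr(report, "centroid_sources") <- centroid_sources
  attr(report, "folds") <- folds
  report
}

run_folds <- function(x, labels, folds, classifier, config) {
  n <- length(labels)
  pred <- character(n)
  fold_id <- integer(n)
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$validation
    fitted <- tryCatch(
      classifier$fit(x[tr, , drop = FALSE], labels[tr]),
      error = function(e) {
        stop("classifier '", classifier$name, "' failed on fold ", f, ": ",
             conditionMessage(e), call. = FALSE)
      })
    pred[va] <- classifier$predict(fitted, x[va, , drop = FALSE])
    fold_id[va] <- f
  }
  report <- new_cv_report(labels, pred, fold_id, sort(unique(labels)),
                          classifier$name, config)
  attr(report, "folds") <- folds
  report
}
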