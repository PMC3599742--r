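test_that("validation sets partition the index set exactly", {
  labels <- rep(c("A", "B"), each = 5)
  folds <- make_folds(labels, cv_config(folds = 10, seed = 1))
  val <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(val) == 1L))            # leave-one-out limit
  expect_setequal(unlist(val), 1:10)

  for (s in 1:5) {
    labels <- withr::with_seed(s, sample(c("A", "B", "C"), 53, replace = TRUE))
    folds <- make_folds(labels, cv_config(folds = 7, seed = s))
    val <- unlist(lapply(folds, `[[`, "validation"))
    expect_identical(sort(val), 1:53)              # disjoint and exhaustive
    for (f in folds) {
      expect_length(intersect(f$train, f$validation), 0L)
      expect_setequal(c(f$train, f$validation), 1:53)
    }
  }
})

test_that("stratified folds keep class counts within one of proportionality", {
  labels <- rep(c("AF", "CHF", "HE", "HY", "WNU"), c(9, 43, 20, 20, 50))
  for (s in 1:100) {
    folds <- make_folds(labels, cv_config(folds = 10, seed = s))
    for (f in folds) {
      counts <- table(factor(labels[f$validation], unique(labels)))
      expected <- table(factor(labels, unique(labels))) / 10
      expect_true(all(abs(counts - expected) <= 1))
    }
  }
})

test_that("fold assignment is deterministic given the seed", {
  labels <- rep(c("A", "B"), c(12, 20))
  f1 <- make_folds(labels, cv_config(folds = 5, seed = 42))
  f2 <- make_folds(labels, cv_config(folds = 5, seed = 42))
  f3 <- make_folds(labels, cv_config(folds = 5, seed = 43))
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("more folds than records is rejected", {
  expect_error(make_folds(c("A", "B", "A"), cv_config(folds = 4)), "folds")
})

test_that("GNB reproduces a perfectly separating feature and the symmetric boundary", {
  x <- cbind(f1 = c(rep(0, 6), rep(1, 6)),
             f2 = withr::with_seed(1, stats::rnorm(12)))
  y <- rep(c("A", "B"), each = 6)
  m <- gnb_fit(x, y)
  expect_identical(gnb_predict(m, x), y)

  # symmetric two-class toy: means +-1, equal variance, boundary at 0
  x2 <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
  m2 <- gnb_fit(x2, rep(c("neg", "pos"), each = 3))
  expect_identical(gnb_predict(m2, matrix(c(-0.01, 0.01), ncol = 1)),
                   c("neg", "pos"))
})

test_that("GNB predictions equal direct log-posterior evaluation", {
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(stats::rnorm(30 * 4), 30, 4))
    y <- withr::with_seed(s + 50, sample(c("A", "B", "C"), 30, replace = TRUE))
    m <- gnb_fit(x, y)
    expect_identical(gnb_predict(m, x), unname(scan_gnb(m, x)))
  }
})

test_that("GNB agrees with an established naive Bayes on well-behaved data", {
  skip_if_not_installed("e1071")
  x <- withr::with_seed(3, rbind(matrix(stats::rnorm(40, 0), 20, 2),
                                 matrix(stats::rnorm(40, 3), 20, 2)))
  colnames(x) <- c("u", "v")
  y <- rep(c("A", "B"), each = 20)
  ours <- gnb_predict(gnb_fit(x, y), x)
  ref <- as.character(stats::predict(e1071::naiveBayes(x, factor(y)), x))
  expect_identical(ours, ref)
})

test_that("single-class training data produce a degenerate-model error", {
  expect_error(gnb_fit(matrix(1:4, 2), c("A", "A")), "single class")
})

test_that("cross-validation is perfect on constant distinct feature vectors", {
  fs <- tiny_separable_set()
  report <- crossvalidate(fs, cv_config(folds = 4, seed = 1))
  expect_equal(report$overall_accuracy, 1.0)
  expect_equal(unname(report$per_class_accuracy), c(1, 1))
})

test_that("CV report accounting identities hold", {
  fs <- withr::with_seed(10, {
    voc <- build_vocabulary(3, 2)
    feats <- lapply(1:30, function(i) {
      featurize(random_sequence(60, 3, seed = 600 + i), voc,
                record_id = paste0("r", i),
                label = sample(c("A", "B", "C"), 1))
    })
    feature_set(feats)
  })
  report <- crossvalidate(fs, cv_config(folds = 5, seed = 2))
  expect_identical(sum(report$confusion), report$n_total)
  expect_identical(sum(diag(report$confusion)), report$n_correct)
  expect_identical(report$n_correct + report$n_incorrect, report$n_total)
  expect_equal(report$overall_accuracy, report$n_correct / report$n_total)
  expect_equal(report$per_class_accuracy,
               diag(report$confusion) / rowSums(report$confusion))
  expect_identical(report$n_total, 30L)
})

test_that("cross-validation with a fixed seed is byte-identical", {
  fs <- tiny_separable_set(8)
  r1 <- crossvalidate(fs, cv_config(folds = 4, seed = 9))
  r2 <- crossvalidate(fs, cv_config(folds = 4, seed = 9))
  expect_identical(r1, r2)
})

test_that("accuracy under label permutation is at chance level", {
  # permutation-null Monte Carlo: features carry no class signal
  x <- withr::with_seed(123, matrix(stats::rnorm(40 * 6), 40, 6))
  colnames(x) <- paste0("f", 1:6)
  base_labels <- rep(c("A", "B"), each = 20)
  accs <- vapply(1:200, function(rep_i) {
    y <- withr::with_seed(1000 + rep_i, sample(base_labels))
    fs <- structure(list(x = x, record_ids = as.character(1:40), labels = y,
                         vocabulary = build_vocabulary(6, 1)),
                    class = "gram_feature_set")
    crossvalidate(fs, cv_config(folds = 5, seed = rep_i))$overall_accuracy
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("per-class accuracy is diagonal over row sums, errors on empty rows", {
  conf <- matrix(c(7, 2, 0, 50), 2, byrow = TRUE,
                 dimnames = list(c("AF", "WNU"), c("AF", "WNU")))
  report <- report_from_confusion(conf)
  pc <- per_class_accuracy(report)
  expect_equal(accuracy_from_counts(pc[["AF"]]), 77.8)
  expect_equal(pc[["WNU"]], 1.0)

  ident <- diag(3)
  dimnames(ident) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(per_class_accuracy(report_from_confusion(ident))),
               c(1, 1, 1))

  bad <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(report_from_confusion(bad), "no records")
})

test_that("classifier failures abort with the fold index", {
  fs <- tiny_separable_set()
  broken <- new_classifier("broken",
                           fit = function(x, y) stop("boom"),
                           predict = function(m, x) "A")
  expect_error(crossvalidate(fs, cv_config(folds = 3, seed = 1), broken),
               "fold 1")
})

test_that("adapter classifiers run under the common interface", {
  fs <- tiny_separable_set(8)
  cfg <- cv_config(folds = 4, seed = 5)
  for (name in c("logistic", "naive_bayes", "svm", "tree")) {
    pkg <- switch(name, logistic = "nnet", naive_bayes = "e1071",
                  svm = "e1071", tree = "rpart")
    skip_if_not_installed(pkg)
    report <- crossvalidate(fs, cfg, get_classifier(name))
    expect_s3_class(report, "cv_report")
    expect_identical(report$n_total, 16L)
  }
})

test_that("pooled symbolization refits centroids per fold without leakage", {
  corpus <- generate_study("study2", seed = 2, length = 150)[c(1:5, 21:25, 41:45, 61:65)]
  report <- crossvalidate(corpus, cv_config(folds = 5, seed = 3),
                          k = 4, n_max = 1, fit_scope = "pooled")
  sources <- attr(report, "centroid_sources")
  folds <- attr(report, "folds")
  expect_length(sources, 5L)
  for (f in seq_along(folds)) {
    expect_length(intersect(sources[[f]], folds[[f]]$validation), 0L)
    expect_setequal(sources[[f]], folds[[f]]$train)
  }
  expect_identical(report$n_total, 20L)
})

test_that("reports serialize to JSON with full accounting", {
  fs <- tiny_separable_set()
  report <- crossvalidate(fs, cv_config(folds = 3, seed = 1))
  js <- jsonlite::fromJSON(write_cv_report(report))
  expect_equal(js$overall_accuracy, report$overall_accuracy)
  expect_equal(js$n_total, report$n_total)
  expect_equal(js$confusion$A$A + js$confusion$B$B, report$n_correct)
})
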