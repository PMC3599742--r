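#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `path,label,unit` listing one RR text
#' file per row. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return An [rr_corpus()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("path", "label", "unit")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns path,label,unit", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  records <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_rr_record(p, unit = df$unit[i], label = df$label[i])
  })
  rr_corpus(records)
}

#' Write a corpus as RR text files plus a manifest
#'
#' One plain-text RR file per record (milliseconds, one interval per line)
#' and a `manifest.csv` with columns `path,label,unit`.
#'
#' @param corpus An [rr_corpus()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, outdir) {
  stopifnot(inherits(corpus, "rr_corpus"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(corpus, function(r) {
    p <- file.path(outdir, paste0(r$record_id, ".txt"))
    write_rr_record(r, p)
    basename(p)
  }, character(1))
  manifest <- data.frame(path = paths,
                         label = corpus_labels(corpus),
                         unit = "ms")
  mp <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Run the full analysis pipeline
#'
#' read -> difference -> symbolize -> featurize -> cross-validated
#' classification. When `outdir` is given, all artifacts are written there:
#' the symbol sequences (`symbols.fasta`), the feature matrix
#' (`features.csv`), the classification report (`report.json`) and the full
#' run configuration including every seed (`config.json`).
#'
#' @param x An [rr_corpus()] or a manifest CSV path.
#' @param k Alphabet size (cluster count), 2--26.
#' @param n_max Maximal gram order.
#' @param fit_scope `"per_record"` (adaptive, default) or `"pooled"`.
#' @param classifier An `aiia_classifier` or a name for [get_classifier()].
#' @param folds Number of cross-validation folds.
#' @param stratified Stratify folds by class.
#' @param seed Master seed for fold assignment and any classifier
#'   randomness.
#' @param outdir Optional output directory for artifacts.
#' @return A `cv_report`.
#' @export
run_pipeline <- function(x, k = 10L, n_max = 2L,
                         fit_scope = c("per_record", "pooled"),
                         classifier = "gnb", folds = 10L, stratified = TRUE,
                         seed = 1L, outdir = NULL) {
  fit_scope <- match.arg(fit_scope)
  if (is.character(x)) x <- read_manifest(x)
  stopifnot(inherits(x, "rr_corpus"))
  if (is.character(classifier)) classifier <- get_classifier(classifier, seed)
  config <- cv_config(folds = folds, stratified = stratified, seed = seed,
                      classifier_name = classifier$name)
  report <- crossvalidate(x, config, classifier, k = k, n_max = n_max,
                          fit_scope = fit_scope)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    voc <- build_vocabulary(k, n_max)
    seqs <- lapply(x, function(r) {
      symbolize_record(r, k = k, seed = seed, fit_scope = "per_record")$sequence
    })
    write_symbol_fasta(seqs, file.path(outdir, "symbols.fasta"))
    feats <- lapply(seqs, featurize, vocabulary = voc)
    write_feature_matrix(feats, file.path(outdir, "features.csv"))
    write_cv_report(report, file.path(outdir, "report.json"))
    cfg <- list(k = k, n_max = n_max, fit_scope = fit_scope,
                classifier = classifier$name, folds = folds,
                stratified = stratified, seed = seed,
                n_records = length(x))
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE),
               file.path(outdir, "config.json"))
  }
  report
}

#' Sweep alphabet size and gram order
#'
#' Runs the pipeline over every combination of `k_values` and
#' `n_max_values`, producing the accuracy-versus-cluster-count and
#' accuracy-versus-gram-order curves. Symbol sequences are recomputed per
#' `k` and featurized per `n_max`.
#'
#' @param x An [rr_corpus()] or manifest path.
#' @param k_values Integer vector of alphabet sizes (2--26).
#' @param n_max_values Integer vector of maximal gram orders.
#' @param classifier Classifier or name.
#' @param folds,stratified,seed As in [run_pipeline()].
#' @param fit_scope Symbolization scope.
#' @param path Optional CSV output path for the sweep table.
#' @return A data frame with columns `k`, `n_max`, `classifier`,
#'   `accuracy`, `n_total`, and one `acc_<class>` column per class.
#' @export
sweep_pipeline <- function(x, k_values = 2:26, n_max_values = 1:3,
                           classifier = "gnb", folds = 10L, stratified = TRUE,
                           seed = 1L, fit_scope = "per_record", path = NULL) {
  if (is.character(x)) x <- read_manifest(x)
  stopifnot(inherits(x, "rr_corpus"))
  if (is.character(classifier)) classifier <- get_classifier(classifier, seed)
  config <- cv_config(folds = folds, stratified = stratified, seed = seed,
                      classifier_name = classifier$name)
  fit_scope <- match.arg(fit_scope, c("per_record", "pooled"))
  rows <- list()
  for (k in k_values) {
    seqs <- if (fit_scope == "per_record") {
      lapply(x, function(r) symbolize_record(r, k = k, seed = seed)$sequence)
    }
    for (n_max in n_max_values) {
      report <- if (fit_scope == "per_record") {
        voc <- build_vocabulary(k, n_max)
        feats <- lapply(seqs, featurize, vocabulary = voc)
        crossvalidate(feature_set(feats), config, classifier)
      } else {
        crossvalidate(x, config, classifier, k = k, n_max = n_max,
                      fit_scope = "pooled")
      }
      pc <- report$per_class_accuracy
      row <- data.frame(k = k, n_max = n_max, classifier = classifier$name,
                        accuracy = report$overall_accuracy,
                        n_total = report$n_total)
      for (cls in names(pc)) row[[paste0("acc_", cls)]] <- pc[[cls]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
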