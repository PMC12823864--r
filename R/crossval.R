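# Cross-validated training/evaluation harness mirroring the study protocol:
# stratified k-fold splits repeated over seeds, F-score-argmax thresholding
# on the validation fold, gradient-based subnetwork importance per
# (seed, fold) pair aggregated as mean +/- sd.

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the two-backbone classifier
#'
#' @param x_betti subjects x D Betti feature matrix (or list of bundles, in
#'   which case `x_connectome` may be omitted).
#' @param x_connectome subjects x D connectome feature matrix.
#' @param labels 0/1 vector.
#' @param config a [bmh_net_config]; its seed is replaced per repetition.
#' @param folds number of folds, default 5.
#' @param seeds integer vector of repetition seeds, default `1:5`.
#' @param feature_map subnetwork label per Betti input (derived from bundles
#'   when given); enables importance aggregation.
#' @return object of class `bmh_cv`: data frame `metrics` (one row per
#'   seed/fold), matrix `importance` (rows = seed/fold pairs), and summaries
#'   `metrics_summary`, `importance_summary` (mean +/- sd).
#' @export
bmh_cv <- function(x_betti, x_connectome = NULL, labels,
                   config = desk_config(), folds = 5L, seeds = 1:5,
                   feature_map = NULL) {
  if (is.list(x_betti) && !is.matrix(x_betti) &&
      length(x_betti) && inherits(x_betti[[1]], "feature_bundle")) {
    if (is.null(feature_map)) feature_map <- betti_feature_map(x_betti[[1]])
    fm <- feature_matrices(x_betti)
    x_betti <- fm$betti
    x_connectome <- fm$conn
  }
  labels <- as.integer(labels)
  rows <- list()
  imps <- list()
  for (seed in seeds) {
    fold_id <- stratified_folds(labels, folds, seed)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      va <- !tr
      if (length(unique(labels[tr])) < 2L || sum(va) < 2L) next
      cfg <- config
      cfg$seed <- as.integer((seed * 131L + f) %% .Machine$integer.max)
      fit <- bmh_net(x_betti[tr, , drop = FALSE],
                     x_connectome[tr, , drop = FALSE], labels[tr], cfg)
      scores <- predict(fit, list(betti = x_betti[va, , drop = FALSE],
                                  conn = x_connectome[va, , drop = FALSE]))
      ev <- evaluate(scores, labels[va])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, fold = f, f_score = ev$f_score, accuracy = ev$accuracy,
        precision = ev$precision, sensitivity = ev$sensitivity,
        threshold = ev$binarization_threshold)
      if (!is.null(feature_map)) {
        imps[[length(imps) + 1L]] <- subnetwork_importance(
          fit, list(betti = x_betti[va, , drop = FALSE],
                    conn = x_connectome[va, , drop = FALSE]),
          feature_map = feature_map)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  importance <- if (length(imps)) do.call(rbind, imps) else NULL
  msum <- data.frame(
    metric = c("f_score", "accuracy", "precision", "sensitivity"),
    mean = vapply(c("f_score", "accuracy", "precision", "sensitivity"),
                  function(m) mean(metrics[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("f_score", "accuracy", "precision", "sensitivity"),
                function(m) stats::sd(metrics[[m]], na.rm = TRUE), numeric(1)))
  isum <- NULL
  if (!is.null(importance)) {
    isum <- data.frame(subnetwork = colnames(importance),
                       mean = colMeans(importance),
                       sd = apply(importance, 2, stats::sd))
    isum <- isum[order(-isum$mean), ]
  }
  structure(list(metrics = metrics, importance = importance,
                 metrics_summary = msum, importance_summary = isum),
            class = "bmh_cv")
}

#' @export
print.bmh_cv <- function(x, ...) {
  cat("Cross-validated evaluation over", nrow(x$metrics), "seed/fold pairs\n")
  for (i in seq_len(nrow(x$metrics_summary))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$metrics_summary$metric[i],
                x$metrics_summary$mean[i], x$metrics_summary$sd[i]))
  }
  if (!is.null(x$importance_summary)) {
    cat("Subnetwork importance (mean +/- sd):\n")
    for (i in seq_len(nrow(x$importance_summary))) {
      cat(sprintf("  %-6s %.4f +/- %.4f\n", x$importance_summary$subnetwork[i],
                  x$importance_summary$mean[i], x$importance_summary$sd[i]))
    }
  }
  invisible(x)
}
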