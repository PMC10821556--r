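#' One-vs-rest, macro and micro AUC for a probability matrix
#'
#' Each class's AUC is the binary [roc_auc()] of its predicted probability
#' against membership of that class (one-vs-rest). The macro AUC is the
#' unweighted mean of the per-class AUCs; the micro AUC treats every
#' element of the label indicator matrix as one binary decision, i.e. a
#' single AUC on the flattened `n * k` probabilities versus the flattened
#' indicators.
#'
#' @param prob Numeric matrix or data frame of class probabilities, one
#'   column per class (named), rows summing to 1.
#' @param labels Vector of true class labels; every class in `colnames(prob)`
#'   must occur.
#' @return A `glyco_auc_report`: list with `per_class` (named numeric),
#'   `macro_auc`, `micro_auc`.
#' @export
multiclass_auc <- function(prob, labels) {
  prob <- as.matrix(prob)
  stopifnot(!is.null(colnames(prob)))
  if (max(abs(rowSums(prob) - 1)) > 1e-6) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  labels <- as.character(labels)
  classes <- colnames(prob)
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls) > 0) {
    stop("no samples with label(s): ", paste(missing_cls, collapse = ", "),
      call. = FALSE
    )
  }
  per_class <- vapply(
    classes,
    function(k) roc_auc(prob[, k], labels == k),
    numeric(1)
  )
  indicator <- vapply(classes, function(k) labels == k, logical(nrow(prob)))
  structure(
    list(
      per_class = per_class,
      macro_auc = mean(per_class),
      micro_auc = roc_auc(as.vector(prob), as.vector(indicator))
    ),
    class = "glyco_auc_report"
  )
}

#' @export
print.glyco_auc_report <- function(x, ...) {
  cat("<glyco_auc_report>\n")
  for (k in names(x$per_class)) {
    cat(sprintf("  %-10s AUC = %.3f\n", k, x$per_class[[k]]))
  }
  cat(sprintf("  macro AUC = %.3f | micro AUC = %.3f\n", x$macro_auc, x$micro_auc))
  invisible(x)
}

# Stratified fold assignment: within each class, samples are dealt into
# folds in random order so per-class counts differ by at most one.
.stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    if (length(idx) < folds) {
      stop(
        "class '", k, "' has ", length(idx), " samples, fewer than ",
        folds, " folds; reduce the number of folds",
        call. = FALSE
      )
    }
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Cross-validated three-class random forest evaluation
#'
#' Fits a probability random forest (via ranger, `ntree` trees) on each
#' training fold of a stratified k-fold split and collects out-of-fold
#' class probabilities, so no sample is scored by a model that saw it. The
#' pooled out-of-fold probabilities yield the one-vs-rest/macro/micro AUC
#' report; impurity importances are averaged over folds.
#'
#' @param data Tibble or matrix of features (numeric columns only).
#' @param labels Class label vector, one per row of `data`.
#' @param ntree Number of trees (default 500).
#' @param folds Number of cross-validation folds (default 5, stratified).
#' @param seed Integer seed controlling fold assignment and forests.
#' @param importance ranger importance mode (default `"impurity"`;
#'   `"permutation"` available).
#' @return A `glyco_rf_cv` object: out-of-fold probability matrix,
#'   `report` (a `glyco_auc_report`), `importance` tibble, fold assignment
#'   and the configuration used.
#' @export
rf_multiclass_cv <- function(data, labels, ntree = 500, folds = 5,
                             seed = 1, importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  x <- as.data.frame(data)
  labels <- factor(as.character(labels))
  stopifnot(nrow(x) == length(labels), folds >= 2, ntree >= 1)
  set.seed(seed)
  fold_id <- .stratified_folds(as.character(labels), folds)
  classes <- levels(labels)
  oof <- matrix(NA_real_, nrow(x), length(classes),
    dimnames = list(NULL, classes)
  )
  imp <- matrix(0, folds, ncol(x), dimnames = list(NULL, colnames(x)))
  for (f in seq_len(folds)) {
    train <- fold_id != f
    fit <- ranger::ranger(
      x = x[train, , drop = FALSE], y = labels[train],
      num.trees = ntree, probability = TRUE, importance = importance,
      seed = seed + f, num.threads = 1
    )
    pred <- stats::predict(fit, x[!train, , drop = FALSE], num.threads = 1)
    oof[!train, ] <- pred$predictions[, classes]
    imp[f, ] <- fit$variable.importance[colnames(x)]
  }
  structure(
    list(
      oof_prob = oof,
      labels = labels,
      fold_id = fold_id,
      report = multiclass_auc(oof, labels),
      importance = tibble::tibble(
        feature = colnames(x),
        importance = colMeans(imp)
      ) |> dplyr::arrange(dplyr::desc(.data$importance)),
      config = list(
        ntree = ntree, folds = folds, seed = seed,
        importance = importance
      )
    ),
    class = "glyco_rf_cv"
  )
}

#' @export
print.glyco_rf_cv <- function(x, ...) {
  cat(
    "<glyco_rf_cv>", length(x$labels), "samples,",
    x$config$folds, "folds,", x$config$ntree, "trees\n"
  )
  print(x$report)
  invisible(x)
}

#' Repeated cross-validated feature-count selection
#'
#' Ranks features by their mean cross-validated importance over repeated
#' stratified k-fold runs, then evaluates the top-k panels for each k in
#' `grid` by the mean macro AUC over the same number of repeats. The
#' optimal k is the argmax of the curve, ties broken toward the smaller
#' panel.
#'
#' @inheritParams rf_multiclass_cv
#' @param grid Integer vector of panel sizes to evaluate; values above the
#'   feature count are clipped with a warning.
#' @param repeats Number of repeated CV runs (default 20, must be >= 2).
#' @return A `glyco_feature_selection` object: `ranking` tibble,
#'   `curve` tibble (`k`, `macro_auc`), `optimal_k`, and config.
#' @export
select_top_k <- function(data, labels, grid, ntree = 500, folds = 5,
                         repeats = 20, seed = 1) {
  stopifnot(repeats >= 2)
  x <- as.data.frame(data)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid > ncol(x))) {
    warning("grid values above the feature count (", ncol(x), ") clipped",
      call. = FALSE
    )
    grid <- sort(unique(pmin(grid, ncol(x))))
  }
  stopifnot(all(grid >= 1))
  runs <- purrr::map(seq_len(repeats), function(r) {
    rf_multiclass_cv(x, labels,
      ntree = ntree, folds = folds,
      seed = seed + 1000L * r
    )
  })
  imp_mat <- vapply(
    runs,
    function(cv) {
      cv$importance$importance[match(colnames(x), cv$importance$feature)]
    },
    numeric(ncol(x))
  )
  ranking <- tibble::tibble(
    feature = colnames(x),
    mean_importance = rowMeans(imp_mat)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  curve <- purrr::map_dfr(grid, function(k) {
    # keep original column order so panel = all features reproduces the
    # unrestricted CV run exactly
    feats <- intersect(colnames(x), ranking$feature[seq_len(k)])
    aucs <- vapply(seq_len(repeats), function(r) {
      rf_multiclass_cv(x[, feats, drop = FALSE], labels,
        ntree = ntree, folds = folds, seed = seed + 1000L * r
      )$report$macro_auc
    }, numeric(1))
    tibble::tibble(k = k, macro_auc = mean(aucs), sd = stats::sd(aucs))
  })
  best <- curve$k[order(-curve$macro_auc, curve$k)][1]
  structure(
    list(
      ranking = ranking, curve = curve, optimal_k = best,
      config = list(
        ntree = ntree, folds = folds, repeats = repeats,
        seed = seed, grid = grid
      )
    ),
    class = "glyco_feature_selection"
  )
}

#' @export
print.glyco_feature_selection <- function(x, ...) {
  cat(
    "<glyco_feature_selection> optimal k =", x$optimal_k,
    "over grid", paste(x$config$grid, collapse = ","), "\n"
  )
  print(x$curve)
  invisible(x)
}
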