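#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname glyco_tidiers
#' @title Broom-style tidiers for glycotraits result objects
#' @description `tidy()` returns the per-row detail of a result
#'   (contrasts, importances, loadings, weights); `glance()` returns its
#'   one-row summary (global test, AUC family).
#' @param x A result object.
#' @param ... Unused.
#' @method tidy glyco_comparison
#' @export
tidy.glyco_comparison <- function(x, ...) {
  dplyr::mutate(x$contrasts, variable = x$variable, method = x$method, .before = 1)
}

#' @rdname glyco_tidiers
#' @method glance glyco_comparison
#' @export
glance.glyco_comparison <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, method = x$method,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' @rdname glyco_tidiers
#' @method tidy glyco_auc_report
#' @export
tidy.glyco_auc_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(index = names(x$per_class), auc = unname(x$per_class)),
    tibble::tibble(index = c("macro", "micro"), auc = c(x$macro_auc, x$micro_auc))
  )
}

#' @rdname glyco_tidiers
#' @method glance glyco_auc_report
#' @export
glance.glyco_auc_report <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(
    x$per_class, paste0("auc_", names(x$per_class))
  )))
  out$macro_auc <- x$macro_auc
  out$micro_auc <- x$micro_auc
  out
}

#' @rdname glyco_tidiers
#' @method tidy glyco_rf_cv
#' @export
tidy.glyco_rf_cv <- function(x, ...) x$importance

#' @rdname glyco_tidiers
#' @method glance glyco_rf_cv
#' @export
glance.glyco_rf_cv <- function(x, ...) glance(x$report)

#' @rdname glyco_tidiers
#' @method tidy glyco_pca
#' @export
tidy.glyco_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance),
    std_dev = x$sdev,
    explained_variance = x$explained_variance,
    cumulative = cumsum(x$explained_variance)
  )
}

#' @rdname glyco_tidiers
#' @method tidy glyco_lda
#' @export
tidy.glyco_lda <- function(x, ...) x$weights

#' @rdname glyco_tidiers
#' @method tidy glyco_feature_selection
#' @export
tidy.glyco_feature_selection <- function(x, ...) x$ranking

#' @rdname glyco_tidiers
#' @method glance glyco_feature_selection
#' @export
glance.glyco_feature_selection <- function(x, ...) {
  tibble::tibble(
    optimal_k = x$optimal_k,
    best_macro_auc = max(x$curve$macro_auc),
    repeats = x$config$repeats, folds = x$config$folds
  )
}
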