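#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of a PCA result
#'
#' @param object A `glyco_pca` object.
#' @param dims Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_pca
#' @export
autoplot.glyco_pca <- function(object, dims = c(1, 2), ...) {
  sc <- object$scores
  ev <- object$explained_variance
  xcol <- paste0("PC", dims[1])
  ycol <- paste0("PC", dims[2])
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[xcol]], .data[[ycol]]))
  p <- if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xcol, 100 * ev[dims[1]]),
    y = sprintf("%s (%.1f%%)", ycol, 100 * ev[dims[2]])
  ) +
    ggplot2::theme_minimal()
}

#' Score densities of an LDA projection
#'
#' @param object A `glyco_lda` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_lda
#' @export
autoplot.glyco_lda <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data$score, fill = .data$label)
  ) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "LDA score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves from a cross-validated forest
#'
#' @param object A `glyco_rf_cv` object.
#' @param ... Unused.
#' @return A ggplot of the per-class out-of-fold ROC curves.
#' @method autoplot glyco_rf_cv
#' @export
autoplot.glyco_rf_cv <- function(object, ...) {
  classes <- colnames(object$oof_prob)
  curves <- purrr::map_dfr(classes, function(k) {
    dplyr::mutate(
      roc_points(object$oof_prob[, k], object$labels == k),
      class = sprintf("%s (AUC %.2f)", k, object$report$per_class[[k]])
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Panel-size performance curve from feature selection
#'
#' @param object A `glyco_feature_selection` object.
#' @param ... Unused.
#' @return A ggplot of mean macro AUC against panel size k.
#' @method autoplot glyco_feature_selection
#' @export
autoplot.glyco_feature_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$macro_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$optimal_k,
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(x = "panel size k", y = "mean macro AUC") +
    ggplot2::theme_minimal()
}

#' Boxplots of derived traits by group
#'
#' @param traits Trait tibble from [compute_traits()].
#' @param metadata Tibble with `sample_id` and a grouping column.
#' @param group Grouping column (tidy-eval).
#' @param which Traits to show (default all sixteen).
#' @return A faceted ggplot.
#' @export
plot_trait_panel <- function(traits, metadata, group, which = trait_names()) {
  gq <- rlang::enquo(group)
  df <- dplyr::inner_join(
    traits, dplyr::select(metadata, "sample_id", !!gq),
    by = "sample_id"
  ) |>
    tidyr::pivot_longer(dplyr::all_of(which),
      names_to = "trait", values_to = "abundance"
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(!!gq, .data$abundance, fill = !!gq)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
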