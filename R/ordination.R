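#' Principal component analysis of a sample-by-feature table
#'
#' Features are standardized (mean 0, SD 1) before the decomposition;
#' constant features are dropped with a warning. The first three components
#' are what the downstream 3D score plots use, but all components are kept.
#'
#' @param data Tibble of numeric features, optionally with a `sample_id`
#'   column (carried through to the scores).
#' @param groups Optional vector of group labels (carried to the scores
#'   for plotting).
#' @return A `glyco_pca` object: `scores` tibble, `loadings` matrix,
#'   `explained_variance` (proportions, non-increasing).
#' @export
pca_project <- function(data, groups = NULL) {
  ids <- if ("sample_id" %in% names(data)) data[["sample_id"]] else NULL
  x <- as.data.frame(data[, setdiff(names(data), "sample_id"), drop = FALSE])
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning(
      "dropping constant feature(s): ",
      paste(names(x)[sds == 0], collapse = ", "),
      call. = FALSE
    )
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- tibble::as_tibble(fit$x)
  if (!is.null(ids)) scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids), scores)
  if (!is.null(groups)) scores$group <- groups
  structure(
    list(
      scores = scores,
      loadings = fit$rotation,
      sdev = fit$sdev,
      explained_variance = fit$sdev^2 / sum(fit$sdev^2),
      center = fit$center,
      scale = fit$scale
    ),
    class = "glyco_pca"
  )
}

#' @export
print.glyco_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat(
    "<glyco_pca>", nrow(x$scores), "samples,", length(ev), "components;",
    sprintf(
      "PC1-3 explain %.1f%%\n",
      100 * sum(ev[seq_len(min(3, length(ev)))])
    )
  )
  invisible(x)
}

#' Fisher linear discriminant projection for two classes
#'
#' Computes the Fisher direction `w = S^-1 (mu_1 - mu_0)` with `S` the
#' pooled within-class covariance; a ridge `epsilon * I` stabilises the
#' inverse when `S` is (near) singular, e.g. with more features than
#' samples. Scores are oriented so the positive class has the higher mean;
#' swapping the classes negates the projection.
#'
#' @param data Tibble of numeric features (optional `sample_id` column).
#' @param labels Two-level vector; the second factor level (or `TRUE`) is
#'   the positive class.
#' @param ridge Ridge added to the covariance diagonal, as a fraction of
#'   the mean diagonal element (default `1e-8`, raised automatically until
#'   the system solves).
#' @return A `glyco_lda` object: `weights` tibble and `scores` tibble
#'   (`score`, `label`).
#' @export
lda_project <- function(data, labels, ridge = 1e-8) {
  ids <- if ("sample_id" %in% names(data)) data[["sample_id"]] else NULL
  x <- as.matrix(data[, setdiff(names(data), "sample_id"), drop = FALSE])
  f <- factor(labels)
  if (nlevels(f) != 2) stop("lda_project requires exactly two classes", call. = FALSE)
  lv <- levels(f)
  x0 <- x[f == lv[1], , drop = FALSE]
  x1 <- x[f == lv[2], , drop = FALSE]
  s_pooled <- (crossprod(scale(x0, scale = FALSE)) +
    crossprod(scale(x1, scale = FALSE))) / (nrow(x) - 2)
  delta <- colMeans(x1) - colMeans(x0)
  scale0 <- mean(diag(s_pooled))
  if (scale0 == 0) scale0 <- 1
  eps <- ridge
  w <- NULL
  repeat {
    w <- tryCatch(
      solve(s_pooled + diag(eps * scale0, ncol(x)), delta),
      error = function(e) NULL
    )
    if (!is.null(w)) break
    eps <- max(eps * 100, 1e-8)
    if (eps > 1) stop("pooled covariance unresolvable even with ridge", call. = FALSE)
  }
  scores <- tibble::tibble(score = drop(x %*% w), label = f)
  if (!is.null(ids)) scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids), scores)
  structure(
    list(
      weights = tibble::tibble(feature = colnames(x), weight = unname(w)),
      scores = scores,
      classes = lv,
      ridge = eps
    ),
    class = "glyco_lda"
  )
}

#' @export
print.glyco_lda <- function(x, ...) {
  cat(
    "<glyco_lda>", x$classes[1], "vs", x$classes[2], "on",
    nrow(x$weights), "features\n"
  )
  invisible(x)
}
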