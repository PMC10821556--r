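#' Kolmogorov-Smirnov normality check
#'
#' One-sample K-S statistic of `x` against a normal distribution with the
#' sample mean and SD. Used to route each trait to ANOVA (Gaussian) or
#' Kruskal-Wallis (not). With estimated parameters the plain K-S p-value is
#' anticonservative; the Lilliefors correction is available via
#' `lilliefors = TRUE` (requires the nortest package).
#'
#' @param x Numeric vector, `n >= 5`.
#' @param alpha Significance level for the Gaussian decision.
#' @param lilliefors Use the Lilliefors-corrected test.
#' @return A tibble with `statistic`, `p_value` and `gaussian` (logical;
#'   `FALSE` with `p_value = NA` for constant input).
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = FALSE) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("ks_normality requires n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_, gaussian = FALSE))
  }
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("lilliefors = TRUE requires the nortest package", call. = FALSE)
    }
    ks <- nortest::lillie.test(x)
  } else {
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  tibble::tibble(
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    gaussian = ks$p.value > alpha
  )
}

# Shared constructor for group-comparison results.
.new_comparison <- function(variable, method, statistic, p_value,
                            group_summary, contrasts) {
  structure(
    list(
      variable = variable, method = method,
      statistic = statistic, p_value = p_value,
      group_summary = group_summary, contrasts = contrasts
    ),
    class = "glyco_comparison"
  )
}

#' @export
print.glyco_comparison <- function(x, ...) {
  cat(
    "<glyco_comparison>", x$variable, "by", x$method,
    sprintf("(statistic = %.4g, p = %.3g)\n", x$statistic, x$p_value)
  )
  print(x$contrasts)
  invisible(x)
}

#' One-way ANOVA with Bonferroni pairwise contrasts
#'
#' Global one-way ANOVA F test followed by all pairwise two-sample
#' contrasts using the pooled residual variance. Pairwise p-values are
#' Bonferroni adjusted (`min(1, m * p)` with `m = choose(k, 2)` contrasts)
#' and the 95% confidence intervals of the mean differences use the
#' Bonferroni-adjusted level `1 - alpha / m`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   group label.
#' @param alpha Family significance level (default 0.05).
#' @return A `glyco_comparison` object; [tidy()] gives the contrasts,
#'   [glance()] the global test.
#' @export
anova_bonferroni <- function(data, value, group, alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  n_by <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n_by < 2)) {
    stop("every group needs n >= 2 (offender: ",
      names(n_by)[which(n_by < 2)[1]], ")",
      call. = FALSE
    )
  }
  fit <- stats::aov(v ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  lv <- levels(g)
  means <- tapply(v, g, mean)
  sds <- tapply(v, g, stats::sd)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  tcrit <- stats::qt(1 - alpha / (2 * m), df_res)
  contrasts <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / n_by[[a]] + 1 / n_by[[b]]))
    tstat <- diff / se
    p_raw <- 2 * stats::pt(-abs(tstat), df_res)
    tibble::tibble(
      group_a = a, group_b = b, estimate = diff,
      conf_low = diff - tcrit * se, conf_high = diff + tcrit * se,
      p_value = p_raw, p_adj = min(1, m * p_raw)
    )
  })
  summary_tbl <- tibble::tibble(
    group = lv, n = as.integer(n_by[lv]),
    mean = as.numeric(means[lv]), sd = as.numeric(sds[lv])
  )
  .new_comparison(
    variable = rlang::as_name(rlang::enquo(value)),
    method = "anova_bonferroni",
    statistic = an["g", "F value"], p_value = an["g", "Pr(>F)"],
    group_summary = summary_tbl, contrasts = contrasts
  )
}

#' Kruskal-Wallis test with Dunn post hoc contrasts
#'
#' Tie-corrected Kruskal-Wallis H with Dunn z statistics on pooled rank
#' means; pairwise p-values are Bonferroni adjusted. Confidence intervals
#' are normal-theory intervals on the rank-mean difference at the
#' Bonferroni-adjusted level.
#'
#' @inheritParams anova_bonferroni
#' @return A `glyco_comparison` object (the `estimate` column is the rank
#'   mean difference).
#' @export
kruskal_dunn <- function(data, value, group, alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n_total <- length(v)
  r <- rank(v)
  n_by <- table(g)
  rbar <- tapply(r, g, mean)
  ties <- table(v)
  tie_sum <- sum(ties^3 - ties)
  h_raw <- 12 / (n_total * (n_total + 1)) *
    sum(n_by * (rbar - (n_total + 1) / 2)^2)
  tie_factor <- 1 - tie_sum / (n_total^3 - n_total)
  if (tie_factor <= 0) {
    # all observations identical
    h <- 0
    p_global <- 1
  } else {
    h <- h_raw / tie_factor
    p_global <- stats::pchisq(h, nlevels(g) - 1, lower.tail = FALSE)
  }
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  zcrit <- stats::qnorm(1 - alpha / (2 * m))
  var_term <- n_total * (n_total + 1) / 12 - tie_sum / (12 * (n_total - 1))
  contrasts <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    diff <- rbar[[a]] - rbar[[b]]
    se <- sqrt(var_term * (1 / n_by[[a]] + 1 / n_by[[b]]))
    z <- if (se > 0) diff / se else 0
    p_raw <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    tibble::tibble(
      group_a = a, group_b = b, estimate = diff,
      conf_low = diff - zcrit * se, conf_high = diff + zcrit * se,
      p_value = p_raw, p_adj = min(1, m * p_raw)
    )
  })
  summary_tbl <- tibble::tibble(
    group = lv, n = as.integer(n_by[lv]),
    mean = as.numeric(tapply(v, g, mean)[lv]),
    sd = as.numeric(tapply(v, g, stats::sd)[lv])
  )
  .new_comparison(
    variable = rlang::as_name(rlang::enquo(value)),
    method = "kruskal_dunn",
    statistic = h, p_value = p_global,
    group_summary = summary_tbl, contrasts = contrasts
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, non-constant.
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("pearson_cor requires n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_cor undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney AUC: the probability that a random positive scores above a
#' random negative, with ties counting one half. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    labels <- labels == 1
  }
  stopifnot(is.logical(labels), length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc requires both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `fpr`, `tpr`, suitable for plotting.
#' @export
roc_points <- function(scores, labels) {
  if (is.numeric(labels)) labels <- labels == 1
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  keep <- !duplicated(s, fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[keep] / sum(!labels)),
    tpr = c(0, tp[keep] / sum(labels))
  )
}

#' Group comparison report over all traits
#'
#' Reproduces the published workflow per trait: a K-S check on the
#' within-group residuals routes the trait to one-way ANOVA with
#' Bonferroni post hoc (Gaussian residuals) or to Kruskal-Wallis with Dunn
#' post hoc; per-group means/SDs, pairwise 95% CIs and adjusted p-values
#' are collected in one tidy table.
#'
#' @param traits Trait tibble from [compute_traits()] (or any sample-by-
#'   variable tibble with a `sample_id` column).
#' @param metadata Tibble with `sample_id` and the grouping column.
#' @param group Grouping column in `metadata` (tidy-eval).
#' @param alpha Significance level for routing and CIs.
#' @param lilliefors Passed to [ks_normality()].
#' @return A tibble, one row per (variable, contrast): group means/SDs,
#'   test used, global p, contrast estimate, CI and Bonferroni-adjusted p.
#' @export
trait_group_report <- function(traits, metadata, group, alpha = 0.05,
                               lilliefors = FALSE) {
  gq <- rlang::enquo(group)
  df <- dplyr::inner_join(
    traits,
    dplyr::select(metadata, "sample_id", !!gq),
    by = "sample_id"
  )
  vars <- setdiff(names(traits), "sample_id")
  purrr::map_dfr(vars, function(vn) {
    sub <- df[, c(vn, rlang::as_name(gq))]
    names(sub) <- c("value", "group")
    resid <- sub$value - stats::ave(sub$value, sub$group)
    gaussian <- ks_normality(resid, alpha = alpha, lilliefors = lilliefors)$gaussian
    cmp <- if (isTRUE(gaussian)) {
      anova_bonferroni(sub, value, group, alpha = alpha)
    } else {
      kruskal_dunn(sub, value, group, alpha = alpha)
    }
    gs <- cmp$group_summary
    cmp$contrasts |>
      dplyr::mutate(
        variable = vn, method = cmp$method, p_global = cmp$p_value,
        mean_a = gs$mean[match(.data$group_a, gs$group)],
        sd_a = gs$sd[match(.data$group_a, gs$group)],
        mean_b = gs$mean[match(.data$group_b, gs$group)],
        sd_b = gs$sd[match(.data$group_b, gs$group)],
        .before = 1
      )
  })
}
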