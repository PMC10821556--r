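test_that("K-S normality check distinguishes Gaussian from skewed data", {
  set.seed(1)
  norm_check <- ks_normality(rnorm(10000))
  expect_gt(norm_check$p_value, 0.05)
  expect_true(norm_check$gaussian)

  exp_check <- ks_normality(rexp(10000))
  expect_lt(exp_check$p_value, 0.001)
  expect_false(exp_check$gaussian)

  expect_error(ks_normality(rnorm(4)), "n >= 5")
  const <- ks_normality(rep(1.5, 10))
  expect_false(const$gaussian)
  expect_true(is.na(const$p_value))
})

test_that("one-way ANOVA with Bonferroni contrasts behaves algebraically", {
  df_null <- tibble::tibble(
    value = rep(c(1, 2, 3, 4), 3),
    group = rep(c("a", "b", "c"), each = 4)
  )
  res <- anova_bonferroni(df_null, value, group)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_true(all(res$contrasts$p_adj == 1))

  # two groups: F equals t^2 from the pooled-variance t test
  set.seed(2)
  df2 <- tibble::tibble(
    value = c(rnorm(12, 0), rnorm(15, 0.8)),
    group = rep(c("a", "b"), c(12, 15))
  )
  res2 <- anova_bonferroni(df2, value, group)
  tt <- t.test(value ~ group, data = df2, var.equal = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-9)

  # Bonferroni dominance: adjusted >= raw, capped at 1
  set.seed(3)
  df3 <- tibble::tibble(
    value = rnorm(30), group = rep(c("a", "b", "c"), each = 10)
  )
  res3 <- anova_bonferroni(df3, value, group)
  expect_true(all(res3$contrasts$p_adj >= res3$contrasts$p_value))
  expect_true(all(res3$contrasts$p_adj <= 1))
  expect_equal(nrow(res3$contrasts), 3)
  expect_true(all(res3$contrasts$conf_low <= res3$contrasts$conf_high))

  tiny <- tibble::tibble(value = c(1, 2, 3), group = c("a", "a", "b"))
  expect_error(anova_bonferroni(tiny, value, group), "n >= 2")
})

test_that("Kruskal-Wallis H and Dunn contrasts match rank arithmetic", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    group = rep(c("a", "b", "c"), each = 3)
  )
  res <- kruskal_dunn(df, value, group)
  # rank means 2, 5, 8: H = 12/(9*10) * 3*(9 + 0 + 9) = 7.2, no ties
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  kw <- kruskal.test(value ~ group, data = df)
  expect_equal(res$statistic, unname(kw$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, kw$p.value, tolerance = 1e-9)
  # the extreme pair carries the smallest pairwise p
  extreme <- res$contrasts$p_value[res$contrasts$group_a == "a" &
    res$contrasts$group_b == "c"]
  expect_equal(extreme, min(res$contrasts$p_value))

  # tie correction agrees with the base implementation
  set.seed(4)
  tied <- tibble::tibble(
    value = sample(1:4, 40, replace = TRUE),
    group = rep(c("a", "b", "c", "d"), each = 10)
  )
  res_t <- kruskal_dunn(tied, value, group)
  kw_t <- kruskal.test(value ~ group, data = tied)
  expect_equal(res_t$statistic, unname(kw_t$statistic), tolerance = 1e-9)

  # all values identical: H = 0, p = 1
  flat <- tibble::tibble(value = rep(2, 12), group = rep(c("a", "b", "c"), 4))
  res_f <- kruskal_dunn(flat, value, group)
  expect_equal(res_f$statistic, 0)
  expect_equal(res_f$p_value, 1)
})

test_that("Pearson correlation handles exact, simulated and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(2, 5)), "constant")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "n >= 3")

  # bivariate normal with rho = -0.26 at the study's n = 140
  set.seed(6)
  n <- 140
  rho <- -0.26
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  est <- pearson_cor(a, b)
  expect_lt(abs(est$r - rho), 0.15)
  expect_lt(est$r, 0)
})

test_that("rank AUC equals brute-force pair counting and is monotone invariant", {
  scores <- c(0.9, 0.8, 0.7, 0.3)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels), 1)

  set.seed(8)
  for (i in 1:10) {
    s <- sample(round(runif(20), 2)) # rounding forces some ties
    l <- runif(20) > 0.5
    if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * s), l), roc_auc(s, l), tolerance = 1e-12)
  }

  set.seed(9)
  s_null <- rnorm(1000)
  l_null <- runif(1000) > 0.5
  expect_lt(abs(roc_auc(s_null, l_null) - 0.5), 0.05)

  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  s <- rnorm(60)
  l <- rbinom(60, 1, plogis(s))
  if (all(l == 1) || all(l == 0)) l[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, l == 1), ref, tolerance = 1e-9)
})

test_that("trait report routes traits through K-S to the right test family", {
  set.seed(12)
  n <- 30
  traits <- tibble::tibble(
    sample_id = paste0("s", 1:(3 * n)),
    gaussian_trait = rnorm(3 * n) + rep(c(0, 0.5, 1), each = n),
    skewed_trait = rexp(3 * n) * rep(c(1, 1.5, 2), each = n)
  )
  md <- tibble::tibble(
    sample_id = traits$sample_id,
    diagnosis = rep(c("normal", "benign", "cancer"), each = n)
  )
  rep_out <- trait_group_report(traits, md, diagnosis)
  expect_equal(nrow(rep_out), 2 * 3) # 2 traits x 3 contrasts
  expect_equal(
    unique(rep_out$method[rep_out$variable == "gaussian_trait"]),
    "anova_bonferroni"
  )
  expect_equal(
    unique(rep_out$method[rep_out$variable == "skewed_trait"]),
    "kruskal_dunn"
  )
  expect_true(all(rep_out$p_adj >= rep_out$p_value - 1e-12))
})
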