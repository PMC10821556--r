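lib <- glycan_library()

test_that("iterative proportional fitting hits feasible targets and rejects infeasible ones", {
  tg <- default_trait_targets()
  benign <- subset(tg, group == "benign")
  targets <- setNames(benign$mean, benign$trait)
  fit <- calibrate_group_means(targets, lib)
  expect_lt(max(abs(fit$residuals)), 1e-6)
  expect_equal(sum(fit$abundance$abundance), 100, tolerance = 1e-9)
  expect_true(all(fit$abundance$abundance >= 0))

  # the fitted vector reproduces the group trait means through the full
  # trait computation
  prof <- tibble::tibble(
    sample_id = "m", key = fit$abundance$key,
    abundance = fit$abundance$abundance
  )
  tr <- compute_traits(prof, lib)
  expect_equal(tr$man, 2.98, tolerance = 1e-6)
  expect_equal(tr$s_total, 82.11, tolerance = 1e-6)
  expect_equal(tr$g_total, 7.73, tolerance = 1e-6)
  # the published B total row (11.72) rounds off its own parts:
  # 3.36 + 8.35 = 11.71, which additivity makes the attainable value
  expect_equal(tr$b_total, 3.36 + 8.35, tolerance = 1e-6)

  # doubling all targets is infeasible: disjoint groups exceed 100%
  expect_error(calibrate_group_means(targets * 2, lib), "infeasible")
})

test_that("disjoint targets covering the whole glycome fit in one pass", {
  # constrain only the sialylation levels plus the neutral classes so the
  # groups partition cleanly
  targets <- c(
    man = 4, g0 = 4, g1 = 4, g2 = 4, f_neutral = 0, f_sialo = 0,
    b_neutral = 0, b_sialo = 0, s1 = 30, s2 = 40, s3 = 7, s4 = 3
  )
  nofuc <- lib[lib$dhex == 0 & !lib$bisected, ]
  fit <- calibrate_group_means(targets, nofuc)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("subject sampling is deterministic, renormalized and variance-tuned", {
  spec <- cohort_spec(group_sizes = c(benign = 40))
  sim1 <- simulate_cohort(spec, seed = 9, emit_peaks = FALSE)
  sim2 <- simulate_cohort(spec, seed = 9, emit_peaks = FALSE)
  expect_identical(sim1$abundances, sim2$abundances)
  expect_identical(sim1$metadata, sim2$metadata)

  sums <- tapply(sim1$abundances$abundance, sim1$abundances$sample_id, sum)
  expect_equal(as.numeric(sums), rep(100, 40), tolerance = 1e-9)

  # SD of total sialylation tuned to the group target within 20%
  sd_target <- 3.51
  s_tot <- sim1$traits$s_total
  expect_lt(abs(sd(s_tot) - sd_target) / sd_target, 0.2)

  # cohort trait means sit on the calibrated targets
  expect_equal(mean(sim1$traits$man), 2.98, tolerance = 1e-6)
  expect_equal(mean(s_tot), 82.11, tolerance = 1e-6)
})

test_that("ground-truth traits equal compute_traits of the true abundances", {
  spec <- cohort_spec(group_sizes = c(cancer_early = 5, cancer_late = 5))
  sim <- simulate_cohort(spec, seed = 10, emit_peaks = FALSE)
  recomputed <- compute_traits(sim$abundances, sim$library)
  expect_equal(sim$traits, recomputed)
})

test_that("peak emission round-trips and degrades gracefully with jitter", {
  # moderate jitter: cohort-mean per-glycan recovery error < 0.5 points
  spec <- cohort_spec(group_sizes = c(benign = 20))
  sim <- simulate_cohort(spec, seed = 12)
  cfg <- annotation_config()
  pk <- recalibrate_peaks(sim$peaks, lib$mz, cfg)
  noise <- estimate_noise(pk, lib$mz, cfg$tolerance)
  prof <- pk |>
    annotate_peaks(lib, cfg, noise = noise) |>
    normalize_profile() |>
    average_replicates()
  rec_mean <- tapply(prof$abundance, prof$key, mean)
  true_mean <- tapply(sim$abundances$abundance, sim$abundances$key, mean)
  expect_lt(max(abs(rec_mean - true_mean[names(rec_mean)])), 0.5)

  # replicate CV shrinks as spectra get cleaner
  cv_of <- function(mz_jitter, spot_cv, noise_peaks) {
    spec <- cohort_spec(
      group_sizes = c(benign = 6),
      mz_jitter_ppm = mz_jitter, spot_cv = spot_cv,
      noise_peaks = noise_peaks, peak_noise_sd = 0.002
    )
    sim <- simulate_cohort(spec, seed = 13)
    prof <- sim$peaks |>
      annotate_peaks(lib, annotation_config(snr_threshold = 0)) |>
      normalize_profile()
    prof |>
      dplyr::group_by(sample_id, key) |>
      dplyr::summarise(
        cv = sd(abundance) / mean(abundance), .groups = "drop"
      ) |>
      dplyr::pull(cv) |>
      mean(na.rm = TRUE)
  }
  expect_lt(cv_of(0, 0, 0), 1e-9)
})

test_that("covariates reproduce the targeted CA125 correlations", {
  spec <- cohort_spec(group_sizes = c(benign = 70, cancer_early = 35, cancer_late = 35))
  sim <- simulate_cohort(spec, seed = 14, emit_peaks = FALSE)
  md <- sim$metadata
  tr <- sim$traits[match(md$sample_id, sim$traits$sample_id), ]
  expect_equal(cor(tr$s_total, md$ca125), -0.26, tolerance = 1e-6)
  expect_equal(cor(tr$man, md$ca125), 0.29, tolerance = 1e-6)
  expect_equal(cor(tr$g0, md$ca125), 0.23, tolerance = 1e-6)
  expect_equal(cor(tr$g1, md$ca125), 0.28, tolerance = 1e-6)
  # HE4 independent of glycosylation but shifted upward in cancer
  expect_lt(abs(cor(tr$s_total, md$he4)), 0.25)
  expect_gt(
    mean(md$he4[md$diagnosis == "cancer"]),
    mean(md$he4[md$diagnosis == "benign"])
  )
})

test_that("zero correlation targets give independent CA125", {
  spec <- cohort_spec(
    group_sizes = c(benign = 70, cancer_early = 35, cancer_late = 35),
    cor_targets = c(s_total = 0, man = 0, g0 = 0, g1 = 0)
  )
  sim <- simulate_cohort(spec, seed = 15, emit_peaks = FALSE)
  md <- sim$metadata
  tr <- sim$traits[match(md$sample_id, sim$traits$sample_id), ]
  expect_lt(abs(cor(tr$s_total, md$ca125)), 0.1)
  expect_lt(abs(cor(tr$man, md$ca125)), 0.1)
})

test_that("jointly infeasible correlation targets are rejected", {
  spec <- cohort_spec(
    group_sizes = c(benign = 35, cancer_early = 35),
    cor_targets = c(s_total = 0.95, man = 0.95, g0 = 0.95, g1 = -0.95)
  )
  expect_error(simulate_cohort(spec, seed = 16, emit_peaks = FALSE), "infeasible")
})
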