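make_spot <- function(mz, intensity, sample_id = "s1", replicate = 1L) {
  tibble::tibble(
    sample_id = sample_id, replicate = replicate,
    mz = mz, intensity = intensity
  )
}

test_that("recalibration recovers constant and linear mass offsets", {
  cal <- seq(1200, 3600, by = 300)
  clean <- make_spot(cal, rep(10, length(cal)))

  # zero offset: unchanged
  out <- recalibrate_peaks(clean, cal)
  expect_equal(out$mz, cal, tolerance = 1e-9)

  # +0.10 Da constant shift, degree 1 fit: residuals < 1e-6
  shifted <- make_spot(cal + 0.10, rep(10, length(cal)))
  out <- recalibrate_peaks(shifted, cal)
  expect_lt(max(abs(out$mz - cal)), 1e-6)

  # ppm-style linear drift is removed by the linear fit
  drifted <- make_spot(cal * (1 + 30e-6), rep(10, length(cal)))
  out <- recalibrate_peaks(drifted, cal)
  expect_lt(max(abs(out$mz - cal)), 1e-6)
})

test_that("too few matched calibrants leaves the spot unchanged with a warning", {
  peaks <- make_spot(c(1200.0, 1500.0), c(5, 5))
  cal <- c(1200, 1500, 2000, 2500, 3000)
  expect_warning(
    out <- recalibrate_peaks(peaks, cal, annotation_config(min_calibrants = 5)),
    "calibrants matched"
  )
  expect_equal(out$mz, peaks$mz)
})

test_that("annotation matches within tolerance and is injective", {
  lib <- glycan_library()
  h5n2_mz <- lib$mz[lib$key == "H5N2"]

  exact <- make_spot(h5n2_mz, 100)
  ann <- annotate_peaks(exact, lib, annotation_config(snr_threshold = 0))
  expect_equal(ann$intensity[ann$key == "H5N2"], 100)
  expect_equal(sum(ann$intensity), 100)

  # outside tolerance: no assignment
  off <- make_spot(h5n2_mz + 0.2, 100)
  ann <- annotate_peaks(off, lib, annotation_config(snr_threshold = 0))
  expect_equal(sum(ann$intensity), 0)

  # empty peak list: all-zero map
  empty <- make_spot(numeric(0), numeric(0))
  ann <- annotate_peaks(empty, lib, annotation_config(snr_threshold = 0))
  expect_true(all(ann$intensity == 0))
})

test_that("collision cases resolve to the nearest glycan, ties to lower m/z", {
  # two synthetic library entries 0.2 Da apart, one peak between them
  lib2 <- tibble::tibble(key = c("A", "B"), mz = c(2000.00, 2000.20))
  cfg <- annotation_config(tolerance = 0.15, snr_threshold = 0)

  nearer <- make_spot(2000.14, 50) # 0.14 from A, 0.06 from B
  ann <- annotate_peaks(nearer, lib2, cfg)
  expect_equal(ann$intensity[ann$key == "B"], 50)
  expect_equal(ann$intensity[ann$key == "A"], 0)

  equidistant <- make_spot(2000.10, 50) # exactly 0.10 from both
  ann <- annotate_peaks(equidistant, lib2, cfg)
  expect_equal(ann$intensity[ann$key == "A"], 50)
  expect_equal(ann$intensity[ann$key == "B"], 0)

  # randomized collision cases agree with the brute-force matcher and
  # never assign one peak twice
  set.seed(11)
  for (i in 1:20) {
    lib_mz <- sort(2000 + cumsum(runif(6, 0.05, 0.3)))
    libx <- tibble::tibble(key = paste0("g", seq_along(lib_mz)), mz = lib_mz)
    pk_mz <- sort(2000 + runif(8, 0, 2))
    pk_int <- runif(8, 1, 100)
    ann <- annotate_peaks(make_spot(pk_mz, pk_int), libx, cfg)
    expected <- oracle_match(pk_mz, pk_int, lib_mz, cfg$tolerance)
    expect_equal(ann$intensity[match(libx$key, ann$key)], expected)
    assigned <- ann$intensity[ann$intensity > 0]
    expect_true(!anyDuplicated(assigned) || length(unique(pk_int)) < 8)
  }
})

test_that("signal-to-noise filtering suppresses sub-threshold peaks", {
  lib2 <- tibble::tibble(key = c("A", "B"), mz = c(2000, 2500))
  peaks <- make_spot(c(2000, 2500), c(100, 1))
  # noise given explicitly: B at 1 fails 3 x 2, A passes
  ann <- annotate_peaks(peaks, lib2, annotation_config(snr_threshold = 3), noise = 2)
  expect_equal(ann$intensity[ann$key == "A"], 100)
  expect_equal(ann$intensity[ann$key == "B"], 0)
})

test_that("normalization closes to 100 and is scale invariant", {
  ann <- tibble::tibble(
    sample_id = "s1", replicate = 1L,
    key = c("A", "B"), intensity = c(2, 2)
  )
  expect_equal(normalize_profile(ann)$abundance, c(50, 50))

  ann$intensity <- c(1, 3)
  expect_equal(normalize_profile(ann)$abundance, c(25, 75))

  set.seed(3)
  ann10 <- tibble::tibble(
    sample_id = "s1", replicate = 1L,
    key = letters[1:10], intensity = runif(10, 0.1, 50)
  )
  p1 <- normalize_profile(ann10)
  expect_equal(sum(p1$abundance), 100, tolerance = 1e-9)
  expect_equal(order(p1$abundance), order(ann10$intensity))
  ann_scaled <- dplyr::mutate(ann10, intensity = intensity * 1739.2)
  expect_equal(normalize_profile(ann_scaled)$abundance, p1$abundance)

  allzero <- dplyr::mutate(ann10, intensity = 0)
  expect_error(normalize_profile(allzero), "no annotated signal")
})

test_that("replicate averaging means percentages and renormalizes", {
  prof <- tibble::tibble(
    sample_id = "s1", replicate = c(1L, 1L, 2L, 2L),
    key = c("A", "B", "A", "B"), abundance = c(60, 40, 40, 60)
  )
  avg <- average_replicates(prof)
  expect_equal(avg$abundance, c(50, 50))

  # three identical replicates: unchanged
  prof3 <- tidyr::crossing(replicate = 1:3, key = c("A", "B")) |>
    dplyr::mutate(sample_id = "s1", abundance = ifelse(key == "A", 30, 70))
  avg3 <- average_replicates(prof3)
  expect_equal(avg3$abundance[avg3$key == "A"], 30)
})

test_that("noiseless synthetic spectra round-trip exactly through annotation", {
  spec <- cohort_spec(
    group_sizes = c(benign = 3, cancer_early = 2, cancer_late = 2),
    mz_jitter_ppm = 0, peak_noise_sd = 0, noise_peaks = 0, spot_cv = 0
  )
  sim <- simulate_cohort(spec, seed = 5)
  prof <- sim$peaks |>
    annotate_peaks(sim$library, annotation_config(snr_threshold = 0)) |>
    normalize_profile() |>
    average_replicates()
  truth <- sim$abundances
  joined <- dplyr::inner_join(prof, truth,
    by = c("sample_id", "key"),
    suffix = c("_rec", "_true")
  )
  expect_equal(joined$abundance_rec, joined$abundance_true, tolerance = 1e-9)
})

test_that("peak CSV files round-trip through read_peaklists", {
  dir <- file.path(tempdir(), "pk_roundtrip")
  dir.create(dir, showWarnings = FALSE)
  pk <- dplyr::bind_rows(
    make_spot(c(1500.1, 2000.2), c(5, 10), "subj-A", 1L),
    make_spot(c(1500.2, 2000.1), c(6, 11), "subj-A", 2L)
  )
  write_peaklists(pk, dir)
  back <- read_peaklists(dir)
  expect_equal(nrow(back), 4)
  expect_equal(sort(unique(back$replicate)), c(1L, 2L))
  expect_equal(back$mz[back$replicate == 1L], c(1500.1, 2000.2))
  unlink(dir, recursive = TRUE)
})
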