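# The twelve elementary traits used as calibration constraints; the four
# totals follow from them by additivity.
.elementary_traits <- c(
  "man", "g0", "g1", "g2", "f_neutral", "f_sialo",
  "b_neutral", "b_sialo", "s1", "s2", "s3", "s4"
)

# Logical membership matrix: library keys x elementary traits.
.trait_membership <- function(annotations) {
  a <- annotations
  m <- cbind(
    man = a$glycan_class == "oligomannose",
    g0 = a$glycan_class == "complex" & a$neu5ac == 0 & a$galactoses == 0,
    g1 = a$glycan_class == "complex" & a$neu5ac == 0 & a$galactoses == 1,
    g2 = a$glycan_class == "complex" & a$neu5ac == 0 & a$galactoses >= 2,
    f_neutral = a$dhex >= 1 & a$neu5ac == 0,
    f_sialo = a$dhex >= 1 & a$neu5ac >= 1,
    b_neutral = a$bisected & a$neu5ac == 0,
    b_sialo = a$bisected & a$neu5ac >= 1,
    s1 = a$neu5ac == 1,
    s2 = a$neu5ac == 2,
    s3 = a$neu5ac == 3,
    s4 = a$neu5ac == 4
  )
  rownames(m) <- a$key
  m
}

#' Group trait targets used to calibrate the synthetic cohort
#'
#' Published group means and SDs (percent of total glycan signal) of the
#' sixteen derived traits for the benign, early-stage and late-stage
#' groups, with two conventions: the benign neutral-fucosylation mean is
#' corrected to `f_total - f_sialo` = 6.80 (the printed 1.32 contradicts
#' the additivity the other columns obey), and the healthy-control column
#' (not tabulated at trait level in the source) is synthesised from the
#' benign column shifted one SD in the directions reported for healthy
#' subjects: lower mannosylation, agalactosylation and neutral bisection,
#' higher total sialylation (spread proportionally over S1-S4). The normal
#' column is a synthetic convention, not a published measurement.
#'
#' @return A tibble with columns `group` (`normal`, `benign`,
#'   `cancer_early`, `cancer_late`), `trait`, `mean`, `sd`.
#' @export
default_trait_targets <- function() {
  tr <- trait_names()
  benign <- c(
    2.98, 2.94, 4.38, 3.35, 7.73, 6.80, 17.10, 23.90,
    3.36, 8.35, 11.72, 20.71, 57.02, 3.31, 1.07, 82.11
  )
  benign_sd <- c(
    0.64, 0.82, 0.74, 0.69, 1.25, 0.16, 2.03, 3.00,
    0.66, 1.46, 1.88, 2.87, 5.21, 0.69, 0.33, 3.51
  )
  early <- c(
    2.95, 2.96, 4.07, 3.08, 7.16, 6.27, 15.79, 22.06,
    3.28, 7.52, 10.80, 20.50, 57.48, 3.86, 1.15, 82.99
  )
  early_sd <- c(
    0.77, 1.01, 1.02, 0.90, 1.83, 1.70, 3.01, 4.44,
    1.01, 1.59, 2.45, 4.82, 7.69, 0.99, 0.48, 4.35
  )
  late <- c(
    3.08, 3.41, 4.42, 3.25, 7.67, 6.48, 16.79, 23.27,
    3.48, 7.79, 11.27, 19.78, 56.56, 4.17, 1.33, 81.84
  )
  late_sd <- c(
    0.79, 0.99, 1.18, 1.48, 2.32, 1.68, 2.60, 3.68,
    1.00, 1.54, 2.22, 7.16, 10.83, 1.00, 0.45, 4.69
  )
  names(benign) <- names(benign_sd) <- tr
  names(early) <- names(early_sd) <- tr
  names(late) <- names(late_sd) <- tr

  normal <- benign
  normal[["man"]] <- benign[["man"]] - benign_sd[["man"]]
  normal[["g0"]] <- benign[["g0"]] - benign_sd[["g0"]]
  normal[["b_neutral"]] <- benign[["b_neutral"]] - benign_sd[["b_neutral"]]
  s_scale <- (benign[["s_total"]] + benign_sd[["s_total"]]) / benign[["s_total"]]
  for (s in c("s1", "s2", "s3", "s4")) normal[[s]] <- benign[[s]] * s_scale
  normal[["g_total"]] <- normal[["g1"]] + normal[["g2"]]
  normal[["f_total"]] <- normal[["f_neutral"]] + normal[["f_sialo"]]
  normal[["b_total"]] <- normal[["b_neutral"]] + normal[["b_sialo"]]
  normal[["s_total"]] <- sum(normal[c("s1", "s2", "s3", "s4")])

  dplyr::bind_rows(
    tibble::tibble(group = "normal", trait = tr, mean = unname(normal), sd = unname(benign_sd)),
    tibble::tibble(group = "benign", trait = tr, mean = unname(benign), sd = unname(benign_sd)),
    tibble::tibble(group = "cancer_early", trait = tr, mean = unname(early), sd = unname(early_sd)),
    tibble::tibble(group = "cancer_late", trait = tr, mean = unname(late), sd = unname(late_sd))
  )
}

#' Specification of a synthetic serum glycomics cohort
#'
#' Collects the study-design parameters the generator emulates: group
#' sizes (60 healthy controls, 70 benign neoplasms, 70 cancer patients
#' split 35 early / 35 late stage), the per-group trait targets, the
#' CA125-trait correlation targets (total sialylation -0.26,
#' mannosylation +0.29, agalactosylation +0.23, mono-galactosylation
#' +0.28), and the spectral noise model: a per-spot mass-calibration
#' offset (Gaussian, SD `mz_jitter_ppm`), a per-peak centroid noise of
#' `peak_noise_sd` Da, triplicate spots with lognormal intensity noise of
#' CV `spot_cv`, and `noise_peaks` spurious baseline peaks per spot with
#' intensities uniform on `noise_intensity` (relative-abundance units).
#'
#' @param group_sizes Named integer vector over any subset of `normal`,
#'   `benign`, `cancer_early`, `cancer_late`.
#' @param trait_targets Tibble as from [default_trait_targets()].
#' @param cor_targets Named numeric vector of CA125-trait Pearson targets.
#' @param mz_jitter_ppm SD of the per-spot calibration offset (ppm).
#' @param peak_noise_sd SD of per-peak centroid noise (Da).
#' @param noise_peaks Spurious peaks per spot.
#' @param noise_intensity Length-2 range of spurious peak intensities.
#' @param spot_cv Lognormal CV of the per-spot total-signal factor.
#' @param replicates Spots per subject.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(
                          normal = 60, benign = 70,
                          cancer_early = 35, cancer_late = 35
                        ),
                        trait_targets = default_trait_targets(),
                        cor_targets = c(
                          s_total = -0.26, man = 0.29,
                          g0 = 0.23, g1 = 0.28
                        ),
                        mz_jitter_ppm = 30, peak_noise_sd = 0.01,
                        noise_peaks = 5, noise_intensity = c(0.01, 0.1),
                        spot_cv = 0.2, replicates = 3) {
  stopifnot(
    all(group_sizes >= 2), !is.null(names(group_sizes)),
    all(names(group_sizes) %in% unique(trait_targets$group)),
    all(abs(cor_targets) < 1), mz_jitter_ppm >= 0, spot_cv >= 0,
    replicates >= 1
  )
  structure(
    list(
      group_sizes = group_sizes, trait_targets = trait_targets,
      cor_targets = cor_targets, mz_jitter_ppm = mz_jitter_ppm,
      peak_noise_sd = peak_noise_sd, noise_peaks = noise_peaks,
      noise_intensity = noise_intensity, spot_cv = spot_cv,
      replicates = replicates
    ),
    class = "cohort_spec"
  )
}

#' Calibrate per-glycan group mean abundances to trait targets
#'
#' Iterative proportional fitting over the (overlapping) trait-membership
#' constraints: starting from a uniform abundance vector summing to 100,
#' each sweep rescales the members of one trait group to its target and
#' the non-members to the complement, preserving the total, until every
#' targeted trait sum is within `tol` of its target or `max_sweeps`
#' elapse. Only the twelve elementary traits act as constraints; the four
#' totals then hold by additivity.
#'
#' @param targets Named numeric vector of trait targets (percent); must
#'   cover the elementary traits (extra names are ignored).
#' @param library Annotated library tibble ([glycan_library()]).
#' @param tol Convergence tolerance on each trait sum.
#' @param max_sweeps Sweep budget.
#' @return A list: `abundance` tibble (`key`, `abundance`, summing to
#'   100), `residuals` (named, target minus fitted), `sweeps` used.
#' @export
calibrate_group_means <- function(targets, library, tol = 1e-6,
                                  max_sweeps = 500) {
  stopifnot(all(.elementary_traits %in% names(targets)))
  t_vec <- targets[.elementary_traits]
  if (any(t_vec < 0 | t_vec > 100)) {
    stop(
      "infeasible targets: trait percentages must lie in [0, 100] (",
      paste(names(t_vec)[t_vec < 0 | t_vec > 100], collapse = ", "), ")",
      call. = FALSE
    )
  }
  m <- .trait_membership(library)
  # the sialylation levels, oligomannose and the neutral-complex
  # galactosylation classes are mutually disjoint; their targets must
  # leave room within 100%
  disjoint <- c("man", "g0", "g1", "g2", "s1", "s2", "s3", "s4")
  if (sum(t_vec[disjoint]) > 100 + 1e-9) {
    stop(
      "infeasible targets: disjoint trait groups (",
      paste(disjoint, collapse = ", "), ") sum to ",
      round(sum(t_vec[disjoint]), 2), " > 100",
      call. = FALSE
    )
  }
  x <- rep(100 / nrow(m), nrow(m))
  names(x) <- rownames(m)
  resid <- function(x) t_vec - colSums(x * m)
  sweeps <- 0L
  while (max(abs(resid(x))) > tol && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (j in .elementary_traits) {
      mem <- m[, j]
      s <- sum(x[mem])
      t_j <- t_vec[[j]]
      if (s > 0 && s < 100) {
        x[mem] <- x[mem] * t_j / s
        x[!mem] <- x[!mem] * (100 - t_j) / (100 - s)
      }
    }
  }
  res <- resid(x)
  if (max(abs(res)) > tol) {
    warning(
      "calibration not converged after ", max_sweeps,
      " sweeps; worst residual ", signif(max(abs(res)), 3),
      " (", names(res)[which.max(abs(res))], ")",
      call. = FALSE
    )
  }
  list(
    abundance = tibble::tibble(key = names(x), abundance = unname(x)),
    residuals = res,
    sweeps = sweeps
  )
}

# Dispersion search: scale factor tau on centred latent normals such that
# the subject-level SD of total sialylation matches its target.
.sample_group <- function(mean_vec, n, sial_mask, sd_target, tol_rel = 0.01) {
  k <- length(mean_vec)
  z <- matrix(stats::rnorm(n * k), n, k)
  z <- sweep(z, 2, colMeans(z)) # centred: cohort means stay on target
  draw <- function(tau) {
    x <- sweep(exp(tau * z), 2, mean_vec, "*")
    x <- 100 * x / rowSums(x)
    # the row renormalization is nonlinear, so centred latents alone leave
    # an O(tau^2) drift of the cohort mean off the calibrated target;
    # rescale each glycan to put the cohort mean back, iterating because
    # the renormalization couples the columns
    for (i in 1:100) {
      cm <- colMeans(x)
      if (max(abs(cm - mean_vec) / mean_vec) < 1e-12) break
      x <- sweep(x, 2, mean_vec / cm, "*")
      x <- 100 * x / rowSums(x)
    }
    x
  }
  sd_stotal <- function(tau) stats::sd(rowSums(draw(tau)[, sial_mask, drop = FALSE]))
  lo <- 0
  hi <- 0.5
  while (sd_stotal(hi) < sd_target && hi < 8) hi <- hi * 2
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (sd_stotal(mid) < sd_target) lo <- mid else hi <- mid
    if (abs(sd_stotal(mid) - sd_target) / sd_target < tol_rel) break
  }
  tau <- (lo + hi) / 2
  list(abundance = draw(tau), tau = tau, sd_achieved = sd_stotal(tau))
}

#' Draw per-subject abundance vectors around calibrated group means
#'
#' Subjects are logistic-normal perturbations of their group mean vector:
#' `x_i = renormalize(mean * exp(tau * z_i))` with `z_i` standard normal
#' latents. The generator is variance-controlled: latents are centred
#' within each group and the per-glycan cohort means are recalibrated onto
#' the fitted targets after renormalization, so group trait means sit on
#' the calibrated values by construction; the single dispersion `tau` per
#' group is tuned by bisection until the subject-level SD of total
#' sialylation matches the group's target SD (within 1% relative).
#'
#' @param spec A [cohort_spec()].
#' @param group_means Tibble `group`, `key`, `abundance` of calibrated
#'   means (from [calibrate_group_means()] per group).
#' @param library Annotated library tibble.
#' @return A list: `abundances` long tibble (`sample_id`, `group`, `key`,
#'   `abundance`), `dispersions` tibble (`group`, `tau`, `sd_achieved`).
#' @export
sample_subjects <- function(spec, group_means, library) {
  sial_keys <- library$key[library$neu5ac >= 1]
  out <- purrr::map(names(spec$group_sizes), function(g) {
    mv <- group_means[group_means$group == g, ]
    mean_vec <- stats::setNames(mv$abundance, mv$key)
    n <- spec$group_sizes[[g]]
    sd_target <- spec$trait_targets$sd[
      spec$trait_targets$group == g & spec$trait_targets$trait == "s_total"
    ]
    res <- .sample_group(mean_vec, n, names(mean_vec) %in% sial_keys, sd_target)
    ids <- sprintf("%s_%03d", g, seq_len(n))
    ab <- tibble::tibble(
      sample_id = rep(ids, each = length(mean_vec)),
      group = g,
      key = rep(names(mean_vec), times = n),
      abundance = as.vector(t(res$abundance))
    )
    list(
      ab = ab,
      disp = tibble::tibble(group = g, tau = res$tau, sd_achieved = res$sd_achieved)
    )
  })
  list(
    abundances = purrr::map_dfr(out, "ab"),
    dispersions = purrr::map_dfr(out, "disp")
  )
}

#' Emit triplicate synthetic peak lists
#'
#' For each subject and replicate spot, each glycan contributes one peak
#' at its theoretical m/z shifted by the spot's calibration offset
#' (Gaussian, SD `mz_jitter_ppm`, linear in m/z) plus per-peak centroid
#' noise; its intensity is the true abundance times the spot's lognormal
#' total-signal factor (CV `spot_cv`), which total-area normalization
#' cancels downstream. `noise_peaks` spurious
#' baseline peaks per spot are added at uniform random m/z in the
#' acquisition window 1000-4500 with intensities uniform on
#' `noise_intensity`.
#'
#' @param abundances Long abundance tibble (`sample_id`, `key`,
#'   `abundance`).
#' @param spec A [cohort_spec()].
#' @param library Annotated library tibble with `key`, `mz`.
#' @return Long peak tibble (`sample_id`, `replicate`, `mz`, `intensity`)
#'   sorted by m/z within spot.
#' @export
emit_peaklists <- function(abundances, spec, library) {
  lib_mz <- stats::setNames(library$mz, library$key)
  sdlog <- sqrt(log(1 + spec$spot_cv^2))
  samples <- unique(abundances$sample_id)
  ab_split <- split(abundances, abundances$sample_id)
  purrr::map_dfr(samples, function(sid) {
    sub <- ab_split[[sid]]
    sub <- sub[sub$abundance > 0, ]
    purrr::map_dfr(seq_len(spec$replicates), function(rep_i) {
      shift_ppm <- stats::rnorm(1, 0, spec$mz_jitter_ppm)
      spot_factor <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      mz_true <- lib_mz[sub$key]
      mz_obs <- mz_true * (1 + shift_ppm / 1e6) +
        stats::rnorm(length(mz_true), 0, spec$peak_noise_sd)
      intensity <- sub$abundance * spot_factor
      pk <- tibble::tibble(
        sample_id = sid, replicate = rep_i,
        mz = unname(mz_obs), intensity = intensity
      )
      if (spec$noise_peaks > 0) {
        pk <- dplyr::bind_rows(pk, tibble::tibble(
          sample_id = sid, replicate = rep_i,
          mz = stats::runif(spec$noise_peaks, 1000, 4500),
          intensity = spot_factor * stats::runif(
            spec$noise_peaks,
            spec$noise_intensity[1], spec$noise_intensity[2]
          )
        ))
      }
      dplyr::arrange(pk, .data$mz)
    })
  })
}

#' Emit CA125 / HE4 clinical covariates
#'
#' CA125 is constructed on the benign + cancer subjects as a linear
#' combination of the targeted traits plus noise, with coefficients solved
#' against the empirical trait covariance so each marginal Pearson
#' correlation hits its target; the noise is residualised against the
#' traits, making the empirical correlations exact. Jointly infeasible
#' targets (non-positive-definite system) raise an error. Healthy controls
#' receive an independent baseline CA125. HE4 is drawn independently of
#' all traits but shifted upward in cancer.
#'
#' @param traits Trait tibble (`sample_id` + trait columns).
#' @param metadata Tibble with `sample_id`, `group` (values `normal`,
#'   `benign`, `cancer_early`, `cancer_late`).
#' @param cor_targets Named numeric vector of trait-CA125 Pearson targets.
#' @return `metadata` with `ca125` and `he4` columns added.
#' @export
emit_covariates <- function(traits, metadata, cor_targets) {
  stopifnot(all(names(cor_targets) %in% names(traits)))
  md <- dplyr::left_join(metadata, traits, by = "sample_id")
  patient <- md$group != "normal"
  t_mat <- scale(as.matrix(md[patient, names(cor_targets), drop = FALSE]))
  r_mat <- stats::cor(t_mat)
  r_target <- unname(cor_targets)
  b <- tryCatch(solve(r_mat, r_target), error = function(e) {
    stop("correlation targets jointly infeasible: trait correlation matrix singular",
      call. = FALSE
    )
  })
  q <- drop(crossprod(r_target, b))
  if (q >= 1) {
    stop(
      "correlation targets jointly infeasible: required signal variance ",
      round(q, 3), " >= 1",
      call. = FALSE
    )
  }
  e0 <- stats::rnorm(sum(patient))
  e_res <- stats::residuals(stats::lm(e0 ~ t_mat))
  e_res <- e_res / stats::sd(e_res)
  ca_std <- drop(t_mat %*% b) + sqrt(1 - q) * e_res
  ca_std <- ca_std / stats::sd(ca_std)
  ca125 <- numeric(nrow(md))
  ca125[patient] <- 350 + 180 * ca_std
  ca125[!patient] <- 300 + 120 * stats::rnorm(sum(!patient))
  he4 <- 60 + 40 * grepl("^cancer", md$group) + stats::rnorm(nrow(md), 0, 15)
  metadata$ca125 <- ca125
  metadata$he4 <- he4
  metadata
}

#' Generate a complete synthetic serum glycomics cohort
#'
#' Runs the whole generator under one seed: calibrates per-group glycan
#' mean vectors to the trait targets, draws subjects, computes the
#' ground-truth traits, attaches clinical covariates and (optionally)
#' emits triplicate peak lists. Every artifact is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param emit_peaks Also generate peak lists (slower); set `FALSE` when
#'   only abundances/traits/covariates are needed.
#' @param out_dir Optional directory: writes per-spot peak CSVs,
#'   `metadata.tsv`, `glycan_library.tsv` and `ground_truth_traits.tsv`.
#' @return A list: `spec`, `library`, `group_means`, `abundances`
#'   (long tibble), `traits` (ground truth), `metadata`, `dispersions`,
#'   and `peaks` (or `NULL`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1,
                            emit_peaks = TRUE, out_dir = NULL) {
  set.seed(seed)
  library <- glycan_library()
  targets_by_group <- split(spec$trait_targets, spec$trait_targets$group)
  group_means <- purrr::map_dfr(names(spec$group_sizes), function(g) {
    tg <- targets_by_group[[g]]
    fit <- calibrate_group_means(
      stats::setNames(tg$mean, tg$trait), library
    )
    dplyr::mutate(fit$abundance, group = g, .before = 1)
  })
  drawn <- sample_subjects(spec, group_means, library)
  traits <- compute_traits(drawn$abundances, library)
  metadata <- drawn$abundances |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::mutate(
      stage = dplyr::case_when(
        group == "cancer_early" ~ "I-II",
        group == "cancer_late" ~ "III-IV",
        TRUE ~ "none"
      ),
      diagnosis = dplyr::if_else(grepl("^cancer", .data$group), "cancer", .data$group)
    )
  metadata <- emit_covariates(traits, metadata, spec$cor_targets)
  peaks <- if (emit_peaks) emit_peaklists(drawn$abundances, spec, library) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(peaks)) write_peaklists(peaks, out_dir)
    readr::write_tsv(metadata, file.path(out_dir, "metadata.tsv"))
    readr::write_tsv(traits, file.path(out_dir, "ground_truth_traits.tsv"))
    readr::write_tsv(
      library[, c("key", "glycan_class", "antennae", "bisected", "galactoses", "mz")],
      file.path(out_dir, "glycan_library.tsv")
    )
  }
  list(
    spec = spec, library = library, group_means = group_means,
    abundances = drawn$abundances, traits = traits, metadata = metadata,
    dispersions = drawn$dispersions, peaks = peaks
  )
}

#' Write per-spot peak CSVs
#'
#' @param peaks Long peak tibble (`sample_id`, `replicate`, `mz`,
#'   `intensity`).
#' @param dir Output directory; files are named `{sample}_{replicate}.csv`.
#' @return Invisibly, the written file paths.
#' @export
write_peaklists <- function(peaks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spots <- dplyr::distinct(peaks, .data$sample_id, .data$replicate)
  paths <- purrr::map2_chr(spots$sample_id, spots$replicate, function(s, r) {
    path <- file.path(dir, sprintf("%s_%d.csv", s, r))
    readr::write_csv(
      peaks[peaks$sample_id == s & peaks$replicate == r, c("mz", "intensity")],
      path
    )
    path
  })
  invisible(paths)
}
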