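#' Annotation configuration
#'
#' Tolerances and thresholds for targeted annotation of centroided peak
#' lists. `tolerance` is the maximum |observed - theoretical| m/z for a
#' match (Da); `snr_threshold` the minimum signal-to-noise for a peak to be
#' quantified; `degree` the recalibration polynomial degree (0 constant
#' offset, 1 linear, 2 quadratic); `min_calibrants` the minimum number of
#' matched calibrants before any correction is attempted.
#'
#' @param tolerance Match tolerance in Da (> 0).
#' @param snr_threshold Signal-to-noise threshold (>= 0).
#' @param degree Calibration polynomial degree, 0, 1 or 2.
#' @param min_calibrants Minimum matched calibrants.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(tolerance = 0.15, snr_threshold = 3,
                              degree = 1, min_calibrants = 5) {
  stopifnot(tolerance > 0, snr_threshold >= 0, degree %in% 0:2, min_calibrants >= 1)
  structure(
    list(
      tolerance = tolerance, snr_threshold = snr_threshold,
      degree = as.integer(degree), min_calibrants = as.integer(min_calibrants)
    ),
    class = "annotation_config"
  )
}

#' Read per-spot peak tables
#'
#' Reads centroided peak lists stored one CSV per MALDI spot with columns
#' `mz`, `intensity` and file names `{sample}_{replicate}.csv`.
#'
#' @param dir Directory containing the CSVs (all `*.csv` files are read),
#'   or a character vector of file paths.
#' @return A long tibble with columns `sample_id`, `replicate`, `mz`,
#'   `intensity`, sorted by m/z within each spot.
#' @export
read_peaklists <- function(dir) {
  files <- if (length(dir) == 1 && dir.exists(dir)) {
    list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  } else {
    dir
  }
  if (length(files) == 0) stop("no peak CSV files found in ", dir, call. = FALSE)
  purrr::map_dfr(files, function(f) {
    stem <- sub("\\.csv$", "", basename(f))
    m <- stringr::str_match(stem, "^(.*)_(\\d+)$")
    if (is.na(m[1, 1])) {
      stop("peak file name '", basename(f), "' does not match {sample}_{replicate}.csv",
        call. = FALSE
      )
    }
    pk <- readr::read_csv(f, col_types = readr::cols(
      mz = readr::col_double(), intensity = readr::col_double()
    ))
    tibble::tibble(
      sample_id = m[1, 2], replicate = as.integer(m[1, 3]),
      mz = pk$mz, intensity = pk$intensity
    )
  }) |>
    dplyr::arrange(.data$sample_id, .data$replicate, .data$mz)
}

# Fit and apply a polynomial m/z correction for one spot.
.recalibrate_spot <- function(mz, calibrant_mz, cfg) {
  matched_obs <- vapply(calibrant_mz, function(cm) {
    d <- abs(mz - cm)
    i <- which.min(d)
    if (length(i) == 1 && d[i] <= 3 * cfg$tolerance) mz[i] else NA_real_
  }, numeric(1))
  keep <- !is.na(matched_obs)
  n_matched <- sum(keep)
  if (n_matched < cfg$min_calibrants) {
    warning(
      sprintf(
        "only %d of %d calibrants matched (min %d); spot left uncalibrated",
        n_matched, length(calibrant_mz), cfg$min_calibrants
      ),
      call. = FALSE
    )
    return(mz)
  }
  degree <- min(cfg$degree, n_matched - 1L)
  obs <- matched_obs[keep]
  err <- obs - calibrant_mz[keep]
  if (degree == 0) {
    correction <- rep(mean(err), length(mz))
  } else {
    fit <- stats::lm(err ~ stats::poly(obs, degree, raw = TRUE))
    correction <- drop(cbind(1, stats::poly(mz, degree, raw = TRUE)) %*% stats::coef(fit))
  }
  mz - correction
}

#' Internally recalibrate peak lists
#'
#' Matches each calibrant m/z to its nearest peak within three times the
#' annotation tolerance and, when at least `min_calibrants` are matched,
#' removes the least-squares polynomial trend of the mass error. Spots with
#' too few matched calibrants are returned unchanged with a warning. Any
#' set of reliably observed theoretical m/z values (e.g. the glycan
#' library's) can serve as calibrants.
#'
#' @param peaks Long peak tibble (`sample_id`, `replicate`, `mz`,
#'   `intensity`) as from [read_peaklists()]; a bare `mz`/`intensity` table
#'   is treated as a single spot.
#' @param calibrant_mz Numeric vector of calibrant m/z values.
#' @param config An [annotation_config()].
#' @return The input tibble with corrected `mz`.
#' @export
recalibrate_peaks <- function(peaks, calibrant_mz, config = annotation_config()) {
  stopifnot(length(calibrant_mz) >= 1)
  if (!"sample_id" %in% names(peaks)) {
    peaks$sample_id <- "sample"
    peaks$replicate <- 1L
  }
  peaks |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      df$mz <- .recalibrate_spot(df$mz, calibrant_mz, config)
      df
    }) |>
    dplyr::ungroup()
}

# Nearest-match assignment for one spot: greedy over (glycan, peak) pairs
# ordered by |mass error| then by glycan m/z, so ties break toward the
# lower-m/z glycan; each peak serves at most one glycan and vice versa.
.annotate_spot <- function(mz, intensity, lib_key, lib_mz, cfg, noise) {
  out <- stats::setNames(rep(0, length(lib_key)), lib_key)
  if (length(mz) == 0) {
    return(out)
  }
  if (is.null(noise)) noise <- stats::median(intensity)
  ok <- if (noise > 0) intensity >= cfg$snr_threshold * noise else rep(TRUE, length(mz))
  mz <- mz[ok]
  intensity <- intensity[ok]
  if (length(mz) == 0) {
    return(out)
  }
  d <- abs(outer(lib_mz, mz, "-"))
  pairs <- which(d <= cfg$tolerance, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(out)
  }
  ord <- order(d[pairs], lib_mz[pairs[, 1]])
  pairs <- pairs[ord, , drop = FALSE]
  used_glycan <- rep(FALSE, length(lib_key))
  used_peak <- rep(FALSE, length(mz))
  for (r in seq_len(nrow(pairs))) {
    g <- pairs[r, 1]
    p <- pairs[r, 2]
    if (!used_glycan[g] && !used_peak[p]) {
      out[g] <- intensity[p]
      used_glycan[g] <- TRUE
      used_peak[p] <- TRUE
    }
  }
  out
}

#' Annotate peak lists against a glycan library
#'
#' Targeted extraction: each library glycan receives the intensity of the
#' nearest peak within the match tolerance that passes the signal-to-noise
#' threshold; unmatched glycans get 0. The assignment is injective: no peak
#' is used for two glycans and no glycan collects two peaks (nearest match
#' wins; exact distance ties go to the lower-m/z glycan). The noise level
#' defaults to the median peak intensity of the spot; pass `noise` to
#' override (see [estimate_noise()] for a targeted-extraction estimate).
#'
#' @param peaks Long peak tibble (see [recalibrate_peaks()]).
#' @param library Annotated library tibble from [glycan_library()] (needs
#'   `key` and `mz`).
#' @param config An [annotation_config()].
#' @param noise Optional noise level (single value, arbitrary intensity
#'   units) used for all spots; `NULL` for the per-spot median default.
#' @return A tibble with columns `sample_id`, `replicate`, `key`,
#'   `intensity`, one row per spot x library glycan.
#' @export
annotate_peaks <- function(peaks, library, config = annotation_config(),
                           noise = NULL) {
  stopifnot(all(c("key", "mz") %in% names(library)))
  if (!"sample_id" %in% names(peaks)) {
    peaks$sample_id <- "sample"
    peaks$replicate <- 1L
  }
  peaks |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(function(df, grp) {
      raw <- .annotate_spot(
        df$mz, df$intensity, library$key, library$mz,
        config, noise
      )
      tibble::tibble(key = names(raw), intensity = unname(raw))
    }) |>
    dplyr::ungroup()
}

#' Estimate the noise level of a spot from unassigned peaks
#'
#' For targeted extraction the peaks that match no library m/z are, by
#' construction, not analytes; their median intensity is a parameter-free
#' noise estimate that does not depend on the analyte dynamic range.
#'
#' @param peaks Long peak tibble.
#' @param library_mz Numeric vector of library m/z values.
#' @param tolerance Match tolerance in Da.
#' @return A single noise estimate: the median intensity over all
#'   unassigned peaks across the table (0 when every peak is assignable).
#' @export
estimate_noise <- function(peaks, library_mz, tolerance = 0.15) {
  near <- vapply(
    peaks$mz,
    function(m) any(abs(library_mz - m) <= tolerance),
    logical(1)
  )
  if (all(near)) {
    return(0)
  }
  stats::median(peaks$intensity[!near])
}

#' Normalize annotated intensities to relative abundances
#'
#' Total-area normalization: within each spot every annotated intensity is
#' divided by the summed intensity over all annotated glycans and expressed
#' as a percentage, so each spot profile sums to 100. Scale invariant:
#' multiplying all intensities of a spot by any k > 0 changes nothing.
#'
#' @param annotated Tibble from [annotate_peaks()] (`sample_id`,
#'   `replicate`, `key`, `intensity`).
#' @return Same shape with `abundance` (percent) in place of `intensity`.
#' @export
normalize_profile <- function(annotated) {
  out <- annotated |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::mutate(total = sum(.data$intensity)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    bad <- out |>
      dplyr::filter(.data$total <= 0) |>
      dplyr::distinct(.data$sample_id, .data$replicate)
    stop(
      "no annotated signal for spot(s): ",
      paste0(bad$sample_id, "/", bad$replicate, collapse = ", "),
      call. = FALSE
    )
  }
  out |>
    dplyr::mutate(abundance = 100 * .data$intensity / .data$total) |>
    dplyr::select("sample_id", "replicate", "key", "abundance")
}

#' Average replicate spot profiles per sample
#'
#' Per-glycan arithmetic mean of the normalized percentages across a
#' sample's replicate spots, renormalized to sum to 100. Averaging on
#' percentages (not raw intensities) cancels spot-to-spot differences in
#' total signal.
#'
#' @param profiles Tibble from [normalize_profile()].
#' @return A tibble with columns `sample_id`, `key`, `abundance`.
#' @export
average_replicates <- function(profiles) {
  out <- profiles |>
    dplyr::group_by(.data$sample_id, .data$key) |>
    dplyr::summarise(abundance = mean(.data$abundance), .groups = "drop_last") |>
    dplyr::mutate(abundance = 100 * .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup()
  out
}

#' Pivot a long profile table to a sample-by-glycan matrix
#'
#' @param profiles Tibble with `sample_id`, `key`, `abundance`.
#' @return A wide tibble, one row per sample, one column per glycan key.
#' @export
profile_matrix <- function(profiles) {
  tidyr::pivot_wider(
    profiles,
    id_cols = "sample_id", names_from = "key",
    values_from = "abundance", values_fill = 0
  )
}
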