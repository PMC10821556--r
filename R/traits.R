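#' Names of the sixteen derived glycan traits
#'
#' @return Character vector: `man`, `g0`, `g1`, `g2`, `g_total`,
#'   `f_neutral`, `f_sialo`, `f_total`, `b_neutral`, `b_sialo`, `b_total`,
#'   `s1`, `s2`, `s3`, `s4`, `s_total`.
#' @export
trait_names <- function() {
  c(
    "man", "g0", "g1", "g2", "g_total",
    "f_neutral", "f_sialo", "f_total",
    "b_neutral", "b_sialo", "b_total",
    "s1", "s2", "s3", "s4", "s_total"
  )
}

#' Compute derived glycan traits per sample
#'
#' Derived traits summarise the normalized glycome by structural feature;
#' each trait is the sum of relative abundances (%) over its member
#' glycans, so a glycan may contribute to several traits:
#'
#' * `man`: oligomannose glycans;
#' * `g0`/`g1`/`g2`: neutral complex glycans with 0 / 1 / >= 2 galactoses
#'   (sialylated glycans are implicitly galactosylated and hybrid hexoses
#'   are ambiguous, so both are excluded); `g_total = g1 + g2`;
#' * `f_neutral`/`f_sialo`: fucosylated glycans without/with sialic acid,
#'   `f_total` their sum;
#' * `b_neutral`/`b_sialo`: bisected glycans without/with sialic acid,
#'   `b_total` their sum;
#' * `s1`..`s4`: glycans carrying exactly 1..4 sialic acids; `s_total`
#'   their sum.
#'
#' @param profiles Long profile tibble (`sample_id`, `key`, `abundance`),
#'   e.g. from [average_replicates()].
#' @param annotations Annotation tibble covering every profile key, e.g.
#'   [glycan_library()] or [classify_structure()] output.
#' @return A tibble with one row per sample and the 16 trait columns.
#' @examples
#' lib <- glycan_library()
#' prof <- tibble::tibble(sample_id = "s1", key = c("H5N2", "H5N4S2"),
#'                        abundance = c(30, 70))
#' compute_traits(prof, lib)
#' @export
compute_traits <- function(profiles, annotations) {
  missing_keys <- setdiff(unique(profiles$key), annotations$key)
  if (length(missing_keys) > 0) {
    stop("unannotated glycan key(s): ", paste(missing_keys, collapse = ", "),
      call. = FALSE
    )
  }
  ann <- annotations[, c("key", "glycan_class", "neu5ac", "dhex", "bisected", "galactoses")]
  joined <- dplyr::left_join(profiles, ann, by = "key")
  joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      man = sum(abundance[glycan_class == "oligomannose"]),
      g0 = sum(abundance[glycan_class == "complex" & neu5ac == 0 & galactoses == 0]),
      g1 = sum(abundance[glycan_class == "complex" & neu5ac == 0 & galactoses == 1]),
      g2 = sum(abundance[glycan_class == "complex" & neu5ac == 0 & galactoses >= 2]),
      f_neutral = sum(abundance[dhex >= 1 & neu5ac == 0]),
      f_sialo = sum(abundance[dhex >= 1 & neu5ac >= 1]),
      b_neutral = sum(abundance[bisected & neu5ac == 0]),
      b_sialo = sum(abundance[bisected & neu5ac >= 1]),
      s1 = sum(abundance[neu5ac == 1]),
      s2 = sum(abundance[neu5ac == 2]),
      s3 = sum(abundance[neu5ac == 3]),
      s4 = sum(abundance[neu5ac == 4]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      g_total = .data$g1 + .data$g2,
      f_total = .data$f_neutral + .data$f_sialo,
      b_total = .data$b_neutral + .data$b_sialo,
      s_total = .data$s1 + .data$s2 + .data$s3 + .data$s4
    ) |>
    dplyr::select("sample_id", dplyr::all_of(trait_names()))
}
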