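#' Classify glycan structures from composition
#'
#' Assigns each composition a structural class and the counts that drive
#' derived-trait membership. Curated annotations (e.g. from fragmentation
#' evidence) always override inference; for compositions not in the curated
#' table a fallback rule set is applied:
#'
#' * oligomannose: `hexnac == 2`, `hex >= 5`, no sialic acid, no fucose;
#' * hybrid: `hexnac == 3` and `hex >= 5`;
#' * otherwise complex, with bisecting GlcNAc inferred when `hexnac >= 5`
#'   and `hex - 3 < hexnac - 2` (a HexNAc in excess of what the hexoses
#'   could pair with as antenna Gal); antennae `= hexnac - 2 - bisected`;
#'   galactoses `= min(max(hex - 3, 0), antennae)`.
#'
#' Compositions with `hexnac == 2` but fewer than five hexoses
#' (paucimannose) are classed `"other"`. Bisection is not decidable from
#' composition alone, which is why the curated table takes precedence.
#'
#' @param composition Data frame with columns `hex`, `hexnac`, `neu5ac`,
#'   `dhex` (plus optionally `key`), or a character vector of keys.
#' @param curated Optional data frame of curated annotations with columns
#'   `key`, `glycan_class`, `antennae`, `bisected`, `galactoses`.
#' @return A tibble with the composition columns plus `glycan_class`
#'   (`oligomannose`/`hybrid`/`complex`/`other`), `antennae`, `bisected`,
#'   `galactoses` and `source` (`curated` or `inferred`).
#' @examples
#' classify_structure(c("H5N2", "H3N5", "H7N6S4"))
#' @export
classify_structure <- function(composition, curated = NULL) {
  if (is.character(composition)) composition <- parse_composition(composition)
  if (!"key" %in% names(composition)) {
    composition$key <- render_composition(composition)
  }
  if (any(composition$hexnac < 2)) {
    bad <- composition$key[composition$hexnac < 2][1]
    stop("'", bad, "' is not an N-glycan (requires hexnac >= 2)", call. = FALSE)
  }

  inferred <- composition |>
    dplyr::mutate(
      glycan_class = dplyr::case_when(
        hexnac == 2L & hex >= 5L & neu5ac == 0L & dhex == 0L ~ "oligomannose",
        hexnac == 2L ~ "other",
        hexnac == 3L & hex >= 5L ~ "hybrid",
        TRUE ~ "complex"
      ),
      bisected = glycan_class == "complex" & hexnac >= 5L &
        (hex - 3L) < (hexnac - 2L),
      antennae = dplyr::case_when(
        glycan_class %in% c("oligomannose", "other") ~ 0L,
        glycan_class == "hybrid" ~ 1L,
        TRUE ~ hexnac - 2L - as.integer(bisected)
      ),
      galactoses = dplyr::if_else(
        glycan_class == "complex",
        pmin(pmax(hex - 3L, 0L), antennae),
        0L
      ),
      source = "inferred"
    )

  if (is.null(curated) || nrow(curated) == 0) {
    return(inferred)
  }
  stopifnot(all(c("key", "glycan_class", "antennae", "bisected", "galactoses")
  %in% names(curated)))
  hit <- match(inferred$key, curated$key)
  use <- !is.na(hit)
  inferred$glycan_class[use] <- curated$glycan_class[hit[use]]
  inferred$antennae[use] <- as.integer(curated$antennae[hit[use]])
  inferred$bisected[use] <- as.logical(curated$bisected[hit[use]])
  inferred$galactoses[use] <- as.integer(curated$galactoses[hit[use]])
  inferred$source[use] <- "curated"
  inferred
}

#' Load an annotated glycan library
#'
#' Reads a glycan library TSV (columns `key`, `class`, `antennae`,
#' `bisected` as 0/1, `galactoses`, `note`) and returns it with parsed
#' counts and theoretical m/z. With no `path` the library shipped with the
#' package is used: 42 compositions covering the serum N-glycome from the
#' oligomannose series (H5N2..H9N2) to tetra-sialylated tetra-antennary
#' glycans (H7N6S4F1), with curated structural flags.
#'
#' @param path Path to a library TSV; `NULL` for the shipped default.
#' @param config A [mass_config()] used for `neutral_mass` and `mz`.
#' @return A tibble with composition counts, structural annotation columns
#'   (`glycan_class`, `antennae`, `bisected`, `galactoses`, `source`,
#'   `note`) and `neutral_mass` / `mz`.
#' @examples
#' glycan_library()
#' @export
glycan_library <- function(path = NULL, config = mass_config()) {
  if (is.null(path)) {
    path <- system.file("extdata", "glycan_library.tsv",
      package = "glycotraits", mustWork = TRUE
    )
  }
  raw <- readr::read_tsv(path,
    col_types = readr::cols(
      key = readr::col_character(),
      class = readr::col_character(),
      antennae = readr::col_integer(),
      bisected = readr::col_integer(),
      galactoses = readr::col_integer(),
      note = readr::col_character()
    )
  )
  curated <- tibble::tibble(
    key = raw$key,
    glycan_class = raw$class,
    antennae = raw$antennae,
    bisected = raw$bisected == 1L,
    galactoses = raw$galactoses
  )
  lib <- classify_structure(parse_composition(raw$key), curated = curated)
  lib$note <- raw$note
  lib$neutral_mass <- neutral_mass(lib, config)
  lib$mz <- theoretical_mz(lib, config)
  lib
}
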