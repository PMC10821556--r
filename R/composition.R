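# Monoisotopic atomic masses (Da); electron mass kept separate so that
# adduct ion masses are true ion masses, not neutral sums.
.atomic <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  Na = 22.98976928,
  electron = 0.00054857990888
)

# Residue masses are the dehydrated (in-chain) monosaccharide masses:
# Hex C6H10O5, HexNAc C8H13NO5, dHex C6H10O4, Neu5Ac C11H17NO8.
.residue_mass <- c(
  hex = 6 * .atomic[["C"]] + 10 * .atomic[["H"]] + 5 * .atomic[["O"]],
  hexnac = 8 * .atomic[["C"]] + 13 * .atomic[["H"]] + .atomic[["N"]] + 5 * .atomic[["O"]],
  dhex = 6 * .atomic[["C"]] + 10 * .atomic[["H"]] + 4 * .atomic[["O"]],
  neu5ac = 11 * .atomic[["C"]] + 17 * .atomic[["H"]] + .atomic[["N"]] + 8 * .atomic[["O"]]
)

.water_mass <- 2 * .atomic[["H"]] + .atomic[["O"]]

# Methylamidation converts each sialic acid carboxyl -OH to -NHCH3:
# elemental difference +C +N +3H -O.
.methylamidation_shift <- .atomic[["C"]] + .atomic[["N"]] +
  3 * .atomic[["H"]] - .atomic[["O"]]

.adduct_mass <- c(
  proton = .atomic[["H"]] - .atomic[["electron"]],
  sodium = .atomic[["Na"]] - .atomic[["electron"]]
)

#' Parse glycan composition keys
#'
#' Composition keys count monosaccharides with the letters used throughout
#' serum glycomics: `H` hexose, `N` N-acetylhexosamine, `S` N-acetylneuraminic
#' acid (sialic acid), `F` deoxyhexose (fucose). `"H5N4S2F1"` is five
#' hexoses, four HexNAc, two sialic acids and one fucose; omitted letters
#' mean zero. Letters may appear in any order but each at most once; `H` and
#' `N` are required.
#'
#' @param key Character vector of composition keys such as `"H5N4S2F1"`.
#' @return A tibble with one row per key and integer columns `hex`, `hexnac`,
#'   `neu5ac`, `dhex`, plus the canonical `key` (see [render_composition()]).
#' @examples
#' parse_composition(c("H5N4S2F1", "H7N2"))
#' @export
parse_composition <- function(key) {
  stopifnot(is.character(key), length(key) >= 1)
  parse_one <- function(k) {
    if (is.na(k) || !nzchar(k)) {
      stop("malformed composition key: ", deparse(k), call. = FALSE)
    }
    tokens <- stringr::str_match_all(k, "([A-Za-z])(\\d+)")[[1]]
    consumed <- paste0(tokens[, 1], collapse = "")
    if (!identical(consumed, k)) {
      stop("malformed composition key '", k, "': unparsable text near '",
        sub(consumed, "", k, fixed = TRUE), "'",
        call. = FALSE
      )
    }
    letters_seen <- tokens[, 2]
    bad <- setdiff(letters_seen, c("H", "N", "S", "F"))
    if (length(bad) > 0) {
      stop("unknown monosaccharide letter '", bad[1], "' in key '", k, "'",
        call. = FALSE
      )
    }
    if (anyDuplicated(letters_seen)) {
      stop("duplicated letter in composition key '", k, "'", call. = FALSE)
    }
    counts <- stats::setNames(rep(0L, 4), c("H", "N", "S", "F"))
    counts[letters_seen] <- as.integer(tokens[, 3])
    if (counts[["H"]] == 0 || counts[["N"]] == 0) {
      stop("composition key '", k, "' must contain H and N counts", call. = FALSE)
    }
    counts
  }
  mat <- vapply(key, parse_one, numeric(4))
  out <- tibble::tibble(
    hex = as.integer(mat["H", ]),
    hexnac = as.integer(mat["N", ]),
    neu5ac = as.integer(mat["S", ]),
    dhex = as.integer(mat["F", ])
  )
  out$key <- render_composition(out)
  out[, c("key", "hex", "hexnac", "neu5ac", "dhex")]
}

#' Render a composition to its canonical key
#'
#' The canonical order is `H`, `N`, `S`, `F`, omitting zero counts, so
#' `render_composition(parse_composition(k))` reproduces `k` for any key
#' already in that dialect.
#'
#' @param composition A data frame with columns `hex`, `hexnac`, `neu5ac`,
#'   `dhex` (as produced by [parse_composition()]).
#' @return Character vector of canonical keys.
#' @export
render_composition <- function(composition) {
  stopifnot(all(c("hex", "hexnac", "neu5ac", "dhex") %in% names(composition)))
  with(composition, {
    if (any(hex < 0 | hexnac < 0 | neu5ac < 0 | dhex < 0)) {
      stop("negative monosaccharide count", call. = FALSE)
    }
    paste0(
      "H", hex, "N", hexnac,
      ifelse(neu5ac > 0, paste0("S", neu5ac), ""),
      ifelse(dhex > 0, paste0("F", dhex), "")
    )
  })
}

#' Mass configuration for theoretical m/z
#'
#' Collects the constants used to turn a composition into a neutral mass and
#' an adduct ion m/z. The defaults reflect the assay this package models:
#' sialic acids stabilised by methylamidation (each `-COOH` becomes
#' `-CONHCH3`, a shift of +13.0316 Da per sialic acid) and detection as
#' singly charged `[M+Na]+` in positive reflector mode. Adduct masses are
#' ion masses: the electron mass is subtracted, a documented convention
#' worth ~0.00055 Da.
#'
#' @param derivatization `"methylamidation"` (default) or `"none"`.
#' @param adduct `"sodium"` (default) or `"proton"`.
#' @return A list of class `mass_config`.
#' @examples
#' mass_config()
#' mass_config(derivatization = "none", adduct = "proton")
#' @export
mass_config <- function(derivatization = c("methylamidation", "none"),
                        adduct = c("sodium", "proton")) {
  derivatization <- match.arg(derivatization)
  adduct <- match.arg(adduct)
  structure(
    list(
      derivatization = derivatization,
      adduct = adduct,
      residue_masses = .residue_mass,
      water_mass = .water_mass,
      adduct_mass = .adduct_mass[[adduct]],
      methylamidation_shift = .methylamidation_shift
    ),
    class = "mass_config"
  )
}

#' @export
print.mass_config <- function(x, ...) {
  cat(
    "<mass_config> derivatization:", x$derivatization,
    "| adduct:", x$adduct,
    sprintf("(+%.4f Da)", x$adduct_mass), "\n"
  )
  invisible(x)
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' Sum of residue masses plus one reducing-end water; under methylamidation
#' the per-sialic-acid shift is applied exactly `neu5ac` times.
#'
#' @param composition Data frame with columns `hex`, `hexnac`, `neu5ac`,
#'   `dhex`, or a character vector of keys.
#' @param config A [mass_config()].
#' @return Numeric vector of neutral masses in Da.
#' @examples
#' neutral_mass("H5N4S2F1")
#' @export
neutral_mass <- function(composition, config = mass_config()) {
  if (is.character(composition)) composition <- parse_composition(composition)
  rm <- config$residue_masses
  shift <- if (config$derivatization == "methylamidation") {
    config$methylamidation_shift
  } else {
    0
  }
  composition$hex * rm[["hex"]] +
    composition$hexnac * rm[["hexnac"]] +
    composition$dhex * rm[["dhex"]] +
    composition$neu5ac * (rm[["neu5ac"]] + shift) +
    config$water_mass
}

#' Theoretical m/z of a singly charged glycan adduct
#'
#' @inheritParams neutral_mass
#' @return Numeric vector of m/z values ([M+Na]+ by default).
#' @examples
#' theoretical_mz("H5N2")
#' @export
theoretical_mz <- function(composition, config = mass_config()) {
  neutral_mass(composition, config) + config$adduct_mass
}
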