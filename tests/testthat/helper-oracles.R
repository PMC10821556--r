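# Independent oracles, written against first principles and kept free of
# the package's own mass/AUC code paths.

# Elemental-composition mass oracle: counts atoms explicitly and sums
# atomic monoisotopic masses.
oracle_atomic <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, Na = 22.98976928, e = 0.00054857990888
)

oracle_elements <- function(hex, hexnac, neu5ac, dhex, methylamidated) {
  # residues: Hex C6H10O5, HexNAc C8H13NO5, dHex C6H10O4, Neu5Ac C11H17NO8;
  # methylamidated Neu5Ac gains CH3N and loses O relative to Neu5Ac + H2O?
  # no: -OH -> -NHCH3 on the carboxyl, i.e. +C +N +3H -O per sialic acid.
  el <- c(C = 0, H = 2, N = 0, O = 1) # reducing-end water H2O
  el <- el + hex * c(C = 6, H = 10, N = 0, O = 5)
  el <- el + hexnac * c(C = 8, H = 13, N = 1, O = 5)
  el <- el + dhex * c(C = 6, H = 10, N = 0, O = 4)
  el <- el + neu5ac * c(C = 11, H = 17, N = 1, O = 8)
  if (methylamidated) el <- el + neu5ac * c(C = 1, H = 3, N = 1, O = -1)
  el
}

oracle_neutral_mass <- function(hex, hexnac, neu5ac, dhex,
                                methylamidated = TRUE) {
  el <- oracle_elements(hex, hexnac, neu5ac, dhex, methylamidated)
  sum(el * oracle_atomic[c("C", "H", "N", "O")])
}

oracle_mz_sodium <- function(hex, hexnac, neu5ac, dhex,
                             methylamidated = TRUE) {
  oracle_neutral_mass(hex, hexnac, neu5ac, dhex, methylamidated) +
    oracle_atomic[["Na"]] - oracle_atomic[["e"]]
}

# Brute-force AUC over all (positive, negative) pairs; ties count 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force one-vs-rest / macro / micro AUC family.
oracle_multiclass <- function(prob, labels) {
  classes <- colnames(prob)
  per <- vapply(classes, function(k) oracle_auc(prob[, k], labels == k), numeric(1))
  ind <- as.vector(vapply(classes, function(k) labels == k, logical(nrow(prob))))
  list(per_class = per, macro = mean(per), micro = oracle_auc(as.vector(prob), ind))
}

# Brute-force nearest-match annotation: enumerate all (glycan, peak)
# pairs within tolerance and assign greedily by distance (ties toward the
# lower-m/z glycan), independently of the package's implementation.
oracle_match <- function(peak_mz, peak_int, lib_mz, tolerance) {
  out <- rep(0, length(lib_mz))
  pairs <- expand.grid(g = seq_along(lib_mz), p = seq_along(peak_mz))
  pairs$d <- abs(lib_mz[pairs$g] - peak_mz[pairs$p])
  pairs <- pairs[pairs$d <= tolerance, ]
  pairs <- pairs[order(pairs$d, lib_mz[pairs$g]), ]
  used_g <- c()
  used_p <- c()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$g[i]
    p <- pairs$p[i]
    if (!(g %in% used_g) && !(p %in% used_p)) {
      out[g] <- peak_int[p]
      used_g <- c(used_g, g)
      used_p <- c(used_p, p)
    }
  }
  out
}

# Small random glycan profile over the shipped library.
random_profile <- function(n_keys = 10, sample_id = "s1", seed = 1) {
  set.seed(seed)
  lib <- glycan_library()
  keys <- sample(lib$key, n_keys)
  ab <- stats::runif(n_keys)
  tibble::tibble(
    sample_id = sample_id, key = keys,
    abundance = 100 * ab / sum(ab)
  )
}
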