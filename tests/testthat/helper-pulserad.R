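# Shared fixtures and independent oracles.

default_grid <- seq(270, 700, by = 2)

# Brute-force diastereoisomer count, independent of the package's
# canonical-form implementation: enumerate every R/S assignment of the new
# centres, expand each assignment into its full orbit under the product's
# symmetry operations (half swap for identical halves; global mirror when no
# fixed centre survives and enantiomers are merged), and count orbits.
oracle_diastereomers <- function(fixed_a, gains_a, fixed_b, gains_b,
                                 homodimer, merge_enantiomers) {
  new_opts <- function(gains) if (gains) list("R", "S") else list(NULL)
  assignments <- list()
  for (na in new_opts(gains_a)) {
    for (nb in new_opts(gains_b)) {
      half_a <- c(rep("S", fixed_a), na)
      half_b <- c(rep("S", fixed_b), nb)
      assignments[[length(assignments) + 1]] <- list(half_a, half_b)
    }
  }
  mirror <- function(h) vapply(h, function(c) if (c == "R") "S" else "R", "")
  orbit_key <- function(asg) {
    variants <- list(asg)
    if (homodimer) variants <- c(variants, list(asg[c(2, 1)]))
    if (merge_enantiomers && fixed_a == 0 && fixed_b == 0) {
      variants <- c(variants,
                    lapply(variants, function(v) lapply(v, mirror)))
    }
    keys <- vapply(variants, function(v) {
      paste(vapply(v, paste, "", collapse = ""), collapse = "/")
    }, "")
    paste(sort(keys), collapse = " ")
  }
  length(unique(vapply(assignments, orbit_key, "")))
}

# All radical-pair types of a compound (including CH3S as adduct partner).
all_pair_types <- function(compound) {
  reg <- radical_registry(compound, include_ch3s = TRUE)
  n <- nrow(reg)
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      pairs[[length(pairs) + 1]] <- c(reg$name[i], reg$name[j])
    }
  }
  pairs
}

# Frozen monoisotopic masses computed with an independent formula-mass
# library (pyteomics) from the same element compositions.
ORACLE_MASS <- list(
  parent1 = 204.0932488, parent2 = 190.0775987,
  dimer1_mh = 407.1781239, dimer2_mh = 379.1468238,
  adduct1_mh = 251.0882463, adduct2_mh = 237.0725962
)
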