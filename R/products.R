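## Stable-product accounting: radical-coupling dimers and CH3S* adducts,
## their exact protonated monoisotopic masses, and the expected number of
## diastereoisomers given the fixed (S) parent stereocentre and the new
## stereocentres created on coupling.

## IUPAC monoisotopic isotope masses (Da), principal isotopes.
ISOTOPE_MASS <- c(C = 12.0, H = 1.00782503, N = 14.00307401,
                  O = 15.99491462, S = 31.97207069)

#' Mass of the proton, Da
#'
#' Used for MH+ ions (charge carrier is a proton, not an H atom).
#' @export
PROTON_MASS <- 1.00727646

#' Molecular formula
#'
#' @param ... Element counts, e.g. `chem_formula(C = 8, H = 16, N = 2,
#'   O = 2, S = 1)`, or a single named vector.
#' @return Named integer vector of class `"chem_formula"` (elements with
#'   zero count dropped).
#' @export
chem_formula <- function(...) {
  args <- c(...)
  if (length(args) == 0) {
    return(structure(stats::setNames(integer(0), character(0)),
                     class = "chem_formula"))
  }
  unknown <- setdiff(names(args), names(ISOTOPE_MASS))
  if (length(unknown)) {
    stop("chem_formula: unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(args < 0) || any(args != round(args))) {
    stop("chem_formula: counts must be non-negative integers", call. = FALSE)
  }
  v <- as.integer(args[args > 0])
  names(v) <- names(args)[args > 0]
  structure(v, class = "chem_formula")
}

#' Add or subtract formulas
#'
#' Element-wise; subtraction below zero is an error (a fragment cannot remove
#' atoms the molecule does not have).
#'
#' @param a,b `"chem_formula"` objects.
#' @return A `"chem_formula"`.
#' @export
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  v <- stats::setNames(integer(length(els)), els)
  v[names(a)] <- v[names(a)] + a
  v[names(b)] <- v[names(b)] + b
  do.call(chem_formula, as.list(v))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  v <- stats::setNames(integer(length(els)), els)
  v[names(a)] <- v[names(a)] + a
  v[names(b)] <- v[names(b)] - b
  if (any(v < 0)) {
    stop("formula_subtract: result would have negative counts", call. = FALSE)
  }
  do.call(chem_formula, as.list(v))
}

#' Monoisotopic mass of a formula
#'
#' @param formula A `"chem_formula"`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "chem_formula"))
  if (length(formula) == 0) return(0)
  sum(ISOTOPE_MASS[names(formula)] * as.numeric(formula))
}

## Parent formulas: CH3C(O)NH-CHX-C(O)NHCH3 with X = CH2CH2SCH3 (1) or
## CH2SCH3 (2).
PARENT_FORMULA <- list(
  `1` = c(C = 8, H = 16, N = 2, O = 2, S = 1),
  `2` = c(C = 7, H = 14, N = 2, O = 2, S = 1)
)

#' Parent-compound formula
#'
#' @param compound 1 (methionine-type) or 2 (S-methyl-cysteine-type).
#' @return A `"chem_formula"`.
#' @export
parent_formula <- function(compound) {
  key <- as.character(compound)
  if (!key %in% names(PARENT_FORMULA)) {
    stop("parent_formula: compound must be 1 or 2", call. = FALSE)
  }
  do.call(chem_formula, as.list(PARENT_FORMULA[[key]]))
}

#' Radical registry of a compound
#'
#' The carbon-centred radicals that couple into stable products, with their
#' formulas (parent minus one H) and stereocentre bookkeeping:
#' \describe{
#'   \item{aS1}{primary *CH2-S radical: parent stereocentre retained (S),
#'     no new centre on coupling}
#'   \item{aS2}{secondary radical alpha to sulfur: parent centre retained,
#'     the radical carbon becomes one new centre}
#'   \item{aC1}{backbone C-alpha radical: the parent centre is destroyed and
#'     re-formed on coupling (0 fixed, 1 new)}
#'   \item{aC2}{primary *CH2 on the N-methyl amide: parent centre retained,
#'     no new centre}
#' }
#' The thiyl radical CH3S* (from desulfurisation) is available as an adduct
#' partner via `include_ch3s`. Compound 2 lacks aC1.
#'
#' @param compound 1 or 2.
#' @param include_ch3s Append the CH3S* half (default FALSE).
#' @return Data frame with columns `name`, `compound`, `fixed_centers`,
#'   `gains_center`, and a `formula` list-column.
#' @export
radical_registry <- function(compound, include_ch3s = FALSE) {
  h <- chem_formula(H = 1)
  rad <- formula_subtract(parent_formula(compound), h)
  names_c <- if (compound == 1) c("aS1", "aS2", "aC1", "aC2")
             else c("aS1", "aS2", "aC2")
  fixed <- c(aS1 = 1L, aS2 = 1L, aC1 = 0L, aC2 = 1L)[names_c]
  gains <- c(aS1 = FALSE, aS2 = TRUE, aC1 = TRUE, aC2 = FALSE)[names_c]
  out <- data.frame(name = names_c, compound = compound,
                    fixed_centers = unname(fixed),
                    gains_center = unname(gains),
                    stringsAsFactors = FALSE)
  out$formula <- rep(list(rad), nrow(out))
  if (include_ch3s) {
    out <- rbind(out, data.frame(name = "CH3S", compound = compound,
                                 fixed_centers = 0L, gains_center = FALSE,
                                 formula = I(list(chem_formula(C = 1, H = 3,
                                                               S = 1)))))
  }
  out
}

half_row <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown radical '", name, "' for this compound", call. = FALSE)
  }
  registry[i, ]
}

#' Protonated mass of a radical-coupling dimer
#'
#' MH+ = mass(half a) + mass(half b) + proton; symmetric in its arguments.
#' Both halves must come from the same parent compound.
#'
#' @param half_a,half_b Radical names (rows of [radical_registry()]).
#' @param compound 1 or 2.
#' @return m/z of the MH+ ion.
#' @export
dimer_mh <- function(half_a, half_b, compound) {
  reg <- radical_registry(compound)
  a <- half_row(reg, half_a); b <- half_row(reg, half_b)
  monoisotopic_mass(a$formula[[1]]) + monoisotopic_mass(b$formula[[1]]) +
    PROTON_MASS
}

#' Protonated mass of a CH3S* adduct
#'
#' MH+ of the sulfide formed by coupling a carbon-centred radical with the
#' thiyl radical CH3S*.
#'
#' @param half Radical name.
#' @param compound 1 or 2.
#' @return m/z of the MH+ ion.
#' @export
adduct_mh <- function(half, compound) {
  reg <- radical_registry(compound)
  a <- half_row(reg, half)
  monoisotopic_mass(a$formula[[1]]) +
    monoisotopic_mass(chem_formula(C = 1, H = 3, S = 1)) + PROTON_MASS
}

## Stereodescriptor classes of a coupling product. Each half contributes a
## tuple: its fixed centres (locked "S") followed by its new centre ("R"/"S")
## if it gains one. Classes are counted up to: swapping identical halves
## (same radical name), and -- when merge_enantiomers and the product has no
## fixed centre -- global mirror inversion.
descriptor_classes <- function(fixed_a, gains_a, fixed_b, gains_b,
                               homodimer, merge_enantiomers) {
  opts <- function(gains) if (gains) c("R", "S") else ""
  combos <- expand.grid(na = opts(gains_a), nb = opts(gains_b),
                        stringsAsFactors = FALSE)
  tup <- function(fixed, new) paste0(strrep("S", fixed), new)
  mirror1 <- function(s) chartr("RS", "SR", s)
  canon <- function(a, b) {
    forms <- list(c(a, b))
    if (homodimer) forms <- c(forms, list(c(b, a)))
    if (merge_enantiomers && fixed_a == 0 && fixed_b == 0) {
      forms <- c(forms, lapply(forms, mirror1))
    }
    min(vapply(forms, paste, character(1), collapse = "|"))
  }
  keys <- mapply(function(na, nb) canon(tup(fixed_a, na), tup(fixed_b, nb)),
                 combos$na, combos$nb)
  unique(keys)
}

#' Number of diastereoisomers of a coupling product
#'
#' Counts the distinct stereoisomer classes of the dimer (or adduct) formed
#' from two radical halves: parent stereocentres are locked at S, each new
#' centre created on coupling may be R or S, configurations of a homodimer
#' are identified under exchange of its two identical halves, and -- when
#' `merge_enantiomers` is TRUE -- products with no fixed centre are counted
#' up to mirror inversion (an achiral LC column cannot separate enantiomers).
#'
#' @param half_a,half_b Radical names.
#' @param compound 1 or 2.
#' @param merge_enantiomers Identify mirror-image pairs when no fixed centre
#'   remains (default TRUE).
#' @return Integer count (>= 1).
#' @export
count_diastereomers <- function(half_a, half_b, compound,
                                merge_enantiomers = TRUE) {
  reg <- radical_registry(compound, include_ch3s = TRUE)
  a <- half_row(reg, half_a); b <- half_row(reg, half_b)
  length(descriptor_classes(a$fixed_centers, a$gains_center,
                            b$fixed_centers, b$gains_center,
                            homodimer = identical(half_a, half_b),
                            merge_enantiomers = merge_enantiomers))
}

#' Enumerate coupling products of a radical pool
#'
#' All unordered pairs with repetition (n(n+1)/2 dimers) plus, optionally,
#' one CH3S* adduct per radical; each product carries its MH+ mass and
#' diastereoisomer count.
#'
#' @param compound 1 or 2.
#' @param radicals Radical names (default: the compound's full registry).
#' @param include_adducts Also list CH3S* adducts (default TRUE).
#' @param merge_enantiomers Passed to [count_diastereomers()].
#' @return Data frame with columns `pair`, `half_a`, `half_b`, `type`,
#'   `formula`, `mh`, `n_diastereomers`, `homodimer`.
#' @export
enumerate_products <- function(compound,
                               radicals = radical_registry(compound)$name,
                               include_adducts = TRUE,
                               merge_enantiomers = TRUE) {
  if (length(radicals) == 0) {
    stop("enumerate_products: empty radical list", call. = FALSE)
  }
  reg <- radical_registry(compound, include_ch3s = TRUE)
  rows <- list()
  n <- length(radicals)
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- radicals[i]; b <- radicals[j]
      f <- formula_add(half_row(reg, a)$formula[[1]],
                       half_row(reg, b)$formula[[1]])
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(a, b, sep = "-"), half_a = a, half_b = b,
        type = "dimer", formula = format(f),
        mh = dimer_mh(a, b, compound),
        n_diastereomers = count_diastereomers(a, b, compound,
                                              merge_enantiomers),
        homodimer = a == b, stringsAsFactors = FALSE)
    }
  }
  if (include_adducts) {
    for (a in radicals) {
      f <- formula_add(half_row(reg, a)$formula[[1]],
                       chem_formula(C = 1, H = 3, S = 1))
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(a, "CH3S", sep = "-"), half_a = a, half_b = "CH3S",
        type = "adduct", formula = format(f),
        mh = adduct_mh(a, compound),
        n_diastereomers = count_diastereomers(a, "CH3S", compound,
                                              merge_enantiomers),
        homodimer = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
format.chem_formula <- function(x, ...) {
  order <- intersect(c("C", "H", "N", "O", "S"), names(x))
  paste0(vapply(order, function(el) {
    if (x[el] == 1) el else paste0(el, x[el])
  }, character(1)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Normalise an adduct-intensity footprint
#'
#' The CH3S* adduct intensities act as a footprint of the relative
#' concentrations of the carbon-centred radicals: dividing by the smallest
#' intensity gives ratios with minimum 1.0.
#'
#' @param intensities Named numeric vector, all > 0.
#' @return Named numeric vector of ratios, minimum exactly 1.
#' @export
normalize_footprint <- function(intensities) {
  if (length(intensities) == 0 || any(intensities <= 0)) {
    stop("normalize_footprint: intensities must all be positive",
         call. = FALSE)
  }
  intensities / min(intensities)
}

#' Match observed peaks against enumerated products
#'
#' Annotates each peak of an LC-MS peak list with every product whose MH+
#' lies within the ppm tolerance; peaks matching more than one constitutional
#' product are flagged ambiguous (all dimers of one compound are isobaric).
#'
#' @param peaklist Data frame with columns `mz`, `intensity`.
#' @param products Data frame from [enumerate_products()].
#' @param tol_ppm Mass tolerance, parts per million (>= 0).
#' @return `peaklist` with added columns `matches` (semicolon-joined pair
#'   names), `n_matches`, `ambiguous`.
#' @export
match_peaks <- function(peaklist, products, tol_ppm = 5) {
  stopifnot(all(c("mz", "intensity") %in% names(peaklist)))
  if (tol_ppm < 0) stop("match_peaks: tol_ppm must be >= 0", call. = FALSE)
  hit <- lapply(peaklist$mz, function(mz) {
    d <- abs(products$mh - mz)
    products$pair[d <= mz * tol_ppm * 1e-6]
  })
  peaklist$matches <- vapply(hit, paste, character(1), collapse = ";")
  peaklist$n_matches <- lengths(hit)
  peaklist$ambiguous <- peaklist$n_matches > 1
  peaklist
}
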