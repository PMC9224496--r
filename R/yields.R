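## Radiation-chemical yields, the Schuler scavenging formula and dosimetry.
## Units at every API boundary: concentrations in M, doses in Gy, G-values in
## umol J^-1, path lengths in cm, density in kg L^-1.

#' Primary radiolytic yields of water
#'
#' G-values (umol J^-1) of the primary species produced by the radiolysis of
#' neutral water: hydrated electron, hydroxyl radical, hydrogen atom, proton
#' and hydrogen peroxide.
#'
#' @param g_eaq,g_ho,g_h,g_hplus,g_h2o2 Yields in umol J^-1, all >= 0.
#' @return A named list of class `"primary_yields"`.
#' @export
primary_yields <- function(g_eaq = 0.28, g_ho = 0.28, g_h = 0.06,
                           g_hplus = 0.28, g_h2o2 = 0.07) {
  vals <- c(g_eaq = g_eaq, g_ho = g_ho, g_h = g_h, g_hplus = g_hplus,
            g_h2o2 = g_h2o2)
  if (any(vals < 0)) stop("primary_yields: yields must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "primary_yields")
}

#' Schuler-formula parameters
#'
#' @param g0 Zero-scavenger yield, umol J^-1.
#' @param g1 Scavengeable spur yield, umol J^-1.
#' @param a Scavenging coefficient, M^-1.
#' @return A named list of class `"schuler_params"`.
#' @export
schuler_params <- function(g0 = 0.539, g1 = 0.307, a = 19.6) {
  if (g0 <= 0 || g1 <= 0 || a <= 0) {
    stop("schuler_params: all parameters must be positive", call. = FALSE)
  }
  structure(list(g0 = g0, g1 = g1, a = a), class = "schuler_params")
}

#' Scavenging-capacity dependence of the radical yield (Schuler formula)
#'
#' \deqn{G(S^\bullet) = g_0 + g_1 \frac{\sqrt{a[S]}}{1+\sqrt{a[S]}}}
#' with the standard constants g0 = 0.539, g1 = 0.307 umol J^-1 and
#' a = 19.6 M^-1. Strictly increasing in the scavenger concentration and
#' bounded above by g0 + g1.
#'
#' @param conc Scavenger concentration, M (>= 0; vectorised).
#' @param params A [schuler_params()] object.
#' @return G-value(s), umol J^-1.
#' @examples
#' schuler_g(2e-4)  # 0.557
#' @export
schuler_g <- function(conc, params = schuler_params()) {
  stopifnot(inherits(params, "schuler_params"))
  if (any(conc < 0)) stop("schuler_g: concentration must be >= 0",
                          call. = FALSE)
  s <- sqrt(params$a * conc)
  params$g0 + params$g1 * s / (1 + s)
}

#' Hydroxyl-radical yield under N2O saturation
#'
#' N2O converts hydrated electrons quantitatively to additional HO*, so the
#' available HO* yield is g_eaq + g_ho (= 0.56 umol J^-1 with the defaults).
#'
#' @param primary A [primary_yields()] object.
#' @return G(HO*), umol J^-1.
#' @export
n2o_ho_yield <- function(primary = primary_yields()) {
  stopifnot(inherits(primary, "primary_yields"))
  primary$g_eaq + primary$g_ho
}

#' Reactive-species fractions under N2O saturation
#'
#' Fraction of the reactive radicals that are HO* versus H* (90:10 with the
#' default yields).
#'
#' @param primary A [primary_yields()] object.
#' @return Named numeric vector `c(ho = , h = )` summing to 1.
#' @export
n2o_radical_fractions <- function(primary = primary_yields()) {
  g_ho <- n2o_ho_yield(primary)
  tot <- g_ho + primary$g_h
  c(ho = g_ho / tot, h = primary$g_h / tot)
}

#' Convert a G-value and dose to a concentration
#'
#' c = G * 1e-6 * dose * density, the concentration (M) of a species produced
#' with yield G (umol J^-1) by an absorbed dose (Gy) in a medium of the given
#' density (kg L^-1).
#'
#' @param g Yield, umol J^-1.
#' @param dose Absorbed dose, Gy.
#' @param density Solution density, kg L^-1 (1.0 for dilute aqueous).
#' @return Concentration, M.
#' @export
g_to_concentration <- function(g, dose, density = 1.0) {
  if (any(g < 0) || any(dose < 0) || any(density < 0)) {
    stop("g_to_concentration: inputs must be >= 0", call. = FALSE)
  }
  g * 1e-6 * dose * density
}

## Thiocyanate dosimeter: (SCN)2.- at 472 nm.
EPS_SCN2_472 <- 7580     # M^-1 cm^-1
G_SCN2 <- 0.635          # umol J^-1, Schuler formula at 10 mM KSCN (rounded)

#' Fricke dosimeter yield
#'
#' G(Fe3+) of the Fricke chemical dosimeter, umol J^-1.
#' @export
G_FRICKE <- 1.61

#' Thiocyanate dosimetry: absorbance to dose
#'
#' Inverts Beer-Lambert for the (SCN)2*- radical anion produced in
#' N2O-saturated 10 mM KSCN (molar absorption coefficient 7580 M^-1 cm^-1 at
#' 472 nm, yield 0.635 umol J^-1):
#' dose = OD472 * 1e6 / (7580 * 0.635 * path).
#'
#' @param od_472 Absorbance at 472 nm (>= 0).
#' @param path Optical path length, cm.
#' @return Absorbed dose, Gy.
#' @export
scn_dosimetry_dose <- function(od_472, path = 1) {
  if (any(od_472 < 0)) stop("scn_dosimetry_dose: od must be >= 0",
                            call. = FALSE)
  if (path <= 0) stop("scn_dosimetry_dose: path must be positive",
                      call. = FALSE)
  od_472 * 1e6 / (EPS_SCN2_472 * G_SCN2 * path)
}

#' Upper bound on substrate conversion under gamma irradiation
#'
#' Fraction of the substrate that HO* could consume at most:
#' min(1, G_ho * 1e-6 * dose / conc). A stoichiometric bound, not a kinetic
#' model.
#'
#' @param conc Substrate concentration, M (> 0).
#' @param dose Total absorbed dose, Gy.
#' @param g_ho HO* yield, umol J^-1.
#' @return Fraction in `[0, 1]`.
#' @export
gamma_conversion_bound <- function(conc, dose, g_ho = n2o_ho_yield()) {
  if (conc <= 0) stop("gamma_conversion_bound: conc must be positive",
                      call. = FALSE)
  pmin(1, g_ho * 1e-6 * dose / conc)
}

#' Irradiation time for a target dose
#'
#' @param dose Target dose, Gy.
#' @param dose_rate Dose rate, Gy min^-1 (> 0).
#' @return Time, minutes.
#' @export
irradiation_time <- function(dose, dose_rate) {
  if (dose_rate <= 0) stop("irradiation_time: dose_rate must be positive",
                           call. = FALSE)
  dose / dose_rate
}

#' Radiolysis constants as a single config block
#'
#' All constants used by the yields module in one list, suitable for
#' serialisation to JSON/YAML: primary yields, Schuler parameters, the
#' thiocyanate dosimeter epsilon and G, and the Fricke G.
#'
#' @return Nested list of constants.
#' @export
radiolysis_constants <- function() {
  list(primary_yields = unclass(primary_yields()),
       schuler = unclass(schuler_params()),
       scn_dosimeter = list(eps_472 = EPS_SCN2_472, g = G_SCN2),
       fricke_g = G_FRICKE)
}
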