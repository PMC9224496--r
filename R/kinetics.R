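## Mass-action reaction networks for the HO*-induced oxidation schemes and
## their stiff ODE integration. Rate constants span ~1e5 s^-1 to 1e10
## M^-1 s^-1, so a stiff-capable integrator (lsoda) is used throughout.

#' Elementary reaction
#'
#' @param reactants Character vector of 1 or 2 species ids. A fixed-
#'   concentration partner (e.g. the parent substrate) may appear here; the
#'   reaction is then effectively pseudo-first-order.
#' @param products Character vector of >= 0 species ids.
#' @param k Rate constant: s^-1 (unimolecular) or M^-1 s^-1 (bimolecular).
#' @param label Free-text description.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(reactants, products = character(), k, label = "") {
  if (!length(reactants) %in% 1:2) {
    stop("reaction: 1 or 2 reactants required", call. = FALSE)
  }
  if (k < 0) stop("reaction: rate constant must be >= 0", call. = FALSE)
  structure(list(reactants = reactants, products = products,
                 order = length(reactants), k = k, label = label),
            class = "reaction")
}

#' Reaction scheme
#'
#' A set of species, elementary reactions, initial concentrations and species
#' held at fixed concentration (the parent substrate during the radical
#' transient window).
#'
#' @param species Character vector of all species ids.
#' @param reactions List of [reaction()] objects.
#' @param initial Named numeric vector of initial concentrations, M.
#' @param fixed Character vector of species held constant.
#' @param params Named list of the rate-constant/branching defaults the scheme
#'   was built from (bookkeeping; optional).
#' @return An object of class `"reaction_scheme"`.
#' @export
reaction_scheme <- function(species, reactions, initial = numeric(),
                            fixed = character(), params = list()) {
  for (r in reactions) {
    unknown <- setdiff(c(r$reactants, r$products), species)
    if (length(unknown)) {
      stop("reaction_scheme: undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (any(initial < 0)) {
    stop("reaction_scheme: initial concentrations must be >= 0",
         call. = FALSE)
  }
  init <- stats::setNames(numeric(length(species)), species)
  init[names(initial)] <- initial
  structure(list(species = species, reactions = reactions, initial = init,
                 fixed = fixed, params = params),
            class = "reaction_scheme")
}

## Default non-printed rate constants and branch fractions. The HO* + M rate
## and the HOS* decay channels follow the typical literature values for
## thioether oxidation ((5-7)e5 s^-1 unimolecular, 1e10 M^-1 s^-1
## proton-assisted, 1e8 M^-1 s^-1 substrate-assisted); the remaining entries
## are declared defaults documented in the methods vignette.
scheme1_defaults <- function() {
  list(k_ho = 1e10,            # HO* + M, total, M^-1 s^-1
       f_hos = 0.75,           # branch fractions of HO* + M
       f_ac1 = 0.15, f_as = 0.06, f_ac2 = 0.04,
       k_d = 5.6e5,            # HOS* -> S*+ + HO-, s^-1
       k_ss_f = 1e8,           # S*+ + M -> SS*+, M^-1 s^-1
       k_ss_r = 1e4,           # SS*+ -> S*+ + M, s^-1
       k_dep = 2e6,            # S*+ -> aS (alpha-deprotonation), s^-1
       k_sn_f = 5e5, k_sn_r = 2e5,   # S*+ <-> SN*
       k_sn_ac2 = 2e5, k_sn_ac1 = 5e4,  # SN* -> aC2 / aC1
       k_rr = 1e9,             # generic radical-radical sink, M^-1 s^-1
       dose = 11, substrate_conc = 2e-4, g_ho = 0.56)
}

scheme2_defaults <- function() {
  list(k_ho = 1e10,
       f_hos = 0.75, f_as = 0.15, f_ac2 = 0.10,  # no aC1 channel
       k_d = 5.6e5,
       k_hos_so = 1e6,         # HOS* -> SO*+ (carbonyl-assisted), s^-1
       k_so = 6e7,             # S*+ -> SO*+ (five-membered), s^-1
       k_so_ac2 = 1e5,         # SO*+ -> aC2, s^-1
       k_dep = 1e6,            # faster alpha-deprotonation than compound 1
       k_ss_f = 1e8, k_ss_r = 1e4,
       k_rr = 1e9,
       dose = 11, substrate_conc = 2e-4, g_ho = 0.56)
}

## All unordered radical-radical pairs -> Prod sink.
rr_sink <- function(radicals, k_rr) {
  out <- list()
  n <- length(radicals)
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[[length(out) + 1]] <- reaction(c(radicals[i], radicals[j]), "Prod",
                                         k_rr, "radical-radical sink")
    }
  }
  out
}

#' Reaction scheme for the methionine-type derivative (compound 1)
#'
#' Network: HO* attacks the substrate giving the sulfur adduct HOS* (major)
#' and direct-abstraction radicals aC1/aS/aC2 (minor); HOS* eliminates HO-
#' in a first-order step (k_d = 5.6e5 s^-1) to the monomeric sulfur radical
#' cation S*+ ("Scat"), which partitions between alpha-deprotonation (aS),
#' reversible dimerisation with a second substrate molecule (SS*+),
#' and the reversible cyclic sulfur-nitrogen species SN*, itself decaying to
#' the carbon radicals aC2 and aC1. All radicals share a second-order
#' radical-radical sink.
#'
#' @param overrides Named list overriding any default parameter (see
#'   `scheme$params` for names).
#' @return A [reaction_scheme()]; initial HO* set from the dose and the
#'   N2O-saturated HO* yield.
#' @export
scheme_compound1 <- function(overrides = list()) {
  p <- utils::modifyList(scheme1_defaults(), overrides)
  stopifnot(abs(p$f_hos + p$f_ac1 + p$f_as + p$f_ac2 - 1) < 1e-12)
  radicals <- c("HOS", "Scat", "SS", "SN", "aS", "aC1", "aC2")
  species <- c("HO", "M", radicals, "Prod")
  rx <- c(list(
    reaction(c("HO", "M"), "HOS", p$k_ho * p$f_hos, "HO addition at S"),
    reaction(c("HO", "M"), "aC1", p$k_ho * p$f_ac1, "direct abstraction aC1"),
    reaction(c("HO", "M"), "aS",  p$k_ho * p$f_as,  "direct abstraction aS"),
    reaction(c("HO", "M"), "aC2", p$k_ho * p$f_ac2, "direct abstraction aC2"),
    reaction("HOS", "Scat", p$k_d, "HOS decay (HO- elimination)"),
    reaction(c("Scat", "M"), "SS", p$k_ss_f, "SS formation"),
    reaction("SS", "Scat", p$k_ss_r, "SS reverse"),
    reaction("Scat", "aS", p$k_dep, "alpha-deprotonation"),
    reaction("Scat", "SN", p$k_sn_f, "SN formation"),
    reaction("SN", "Scat", p$k_sn_r, "SN reverse"),
    reaction("SN", "aC2", p$k_sn_ac2, "SN -> aC2"),
    reaction("SN", "aC1", p$k_sn_ac1, "SN -> aC1")),
    rr_sink(radicals, p$k_rr))
  sc <- reaction_scheme(species, rx,
                        initial = c(HO = g_to_concentration(p$g_ho, p$dose)),
                        fixed = "M", params = p)
  sc$initial["M"] <- p$substrate_conc
  sc
}

#' Reaction scheme for the S-methyl-cysteine-type derivative (compound 2)
#'
#' As [scheme_compound1()] but with the thioether one CH2 closer to the
#' backbone: an additional carbonyl-assisted decay of HOS* leads directly to
#' the five-membered sulfur-oxygen species SO*+, S*+ converts rapidly to
#' SO*+ (k >= 6e7 s^-1) rather than to SS*+, the SN channels and the aC1
#' radical are absent, and alpha-deprotonation is faster.
#'
#' @inheritParams scheme_compound1
#' @return A [reaction_scheme()].
#' @export
scheme_compound2 <- function(overrides = list()) {
  p <- utils::modifyList(scheme2_defaults(), overrides)
  stopifnot(abs(p$f_hos + p$f_as + p$f_ac2 - 1) < 1e-12)
  radicals <- c("HOS", "Scat", "SS", "SO", "aS", "aC2")
  species <- c("HO", "M", radicals, "Prod")
  rx <- c(list(
    reaction(c("HO", "M"), "HOS", p$k_ho * p$f_hos, "HO addition at S"),
    reaction(c("HO", "M"), "aS",  p$k_ho * p$f_as,  "direct abstraction aS"),
    reaction(c("HO", "M"), "aC2", p$k_ho * p$f_ac2, "direct abstraction aC2"),
    reaction("HOS", "Scat", p$k_d, "HOS decay (HO- elimination)"),
    reaction("HOS", "SO", p$k_hos_so, "carbonyl-assisted HOS -> SO"),
    reaction("Scat", "SO", p$k_so, "S*+ -> SO (five-membered)"),
    reaction("SO", "aC2", p$k_so_ac2, "SO -> aC2"),
    reaction("Scat", "aS", p$k_dep, "alpha-deprotonation"),
    reaction(c("Scat", "M"), "SS", p$k_ss_f, "SS formation"),
    reaction("SS", "Scat", p$k_ss_r, "SS reverse")),
    rr_sink(radicals, p$k_rr))
  sc <- reaction_scheme(species, rx,
                        initial = c(HO = g_to_concentration(p$g_ho, p$dose)),
                        fixed = "M", params = p)
  sc$initial["M"] <- p$substrate_conc
  sc
}

#' Hydrogen-atom reaction fragment
#'
#' H* adds to the thioether sulfur (k = 1.7e9 M^-1 s^-1) giving a sulfuranyl
#' radical that fragments to the desulfurised product and the thiyl radical
#' CH3S*, which in turn couples with each carbon-centred radical of the
#' compound (the adduct "footprint" used in product accounting).
#'
#' @param compound 1 or 2 (compound 2 lacks the aC1 radical).
#' @param overrides Named list overriding `k_h` (1.7e9), `k_frag` (1e6 s^-1),
#'   `k_add` (1e9), `dose` (11 Gy), `g_h` (0.06), `substrate_conc` (2e-4 M).
#' @return A [reaction_scheme()] fragment with its own initial H*
#'   concentration from G(H*) and the dose.
#' @export
scheme_h_atom <- function(compound = 1, overrides = list()) {
  p <- utils::modifyList(list(k_h = 1.7e9, k_frag = 1e6, k_add = 1e9,
                              dose = 11, g_h = 0.06, substrate_conc = 2e-4),
                         overrides)
  cradicals <- if (compound == 1) c("aS", "aC1", "aC2") else c("aS", "aC2")
  adducts <- paste0("Add_", cradicals)
  species <- c("H", "M", "SuH", "CH3S", "Desulf", cradicals, adducts)
  rx <- c(list(
    reaction(c("H", "M"), "SuH", p$k_h, "H addition at S"),
    reaction("SuH", c("Desulf", "CH3S"), p$k_frag, "sulfuranyl fragmentation")),
    Map(function(r, a) reaction(c("CH3S", r), a, p$k_add,
                                paste("CH3S adduct of", r)),
        cradicals, adducts))
  sc <- reaction_scheme(species, rx,
                        initial = c(H = g_to_concentration(p$g_h, p$dose)),
                        fixed = "M", params = p)
  sc$initial["M"] <- p$substrate_conc
  sc
}

#' Merge two reaction schemes
#'
#' Union of species and reactions; initial concentrations add; fixed sets
#' union. Used to attach the H-atom fragment to a compound scheme.
#'
#' @param a,b [reaction_scheme()] objects.
#' @return A [reaction_scheme()].
#' @export
merge_schemes <- function(a, b) {
  species <- union(a$species, b$species)
  init <- stats::setNames(numeric(length(species)), species)
  init[names(a$initial)] <- a$initial
  init[names(b$initial)] <- init[names(b$initial)] + b$initial
  reaction_scheme(species, c(a$reactions, b$reactions), initial = init,
                  fixed = union(a$fixed, b$fixed),
                  params = utils::modifyList(a$params, b$params))
}

#' Integrate a reaction scheme
#'
#' Deterministic mass-action integration with [deSolve::lsoda()] (stiff-
#' capable; the networks mix ~1e5 s^-1 and ~1e10 M^-1 s^-1 steps). Fixed
#' species are held constant exactly.
#'
#' @param scheme A [reaction_scheme()].
#' @param t_grid Ascending output times, s, starting >= 0.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-16).
#' @return An object of class `"sim_trace"`: `times`, `conc` matrix
#'   `[time x species]` in M, and the `scheme`.
#' @export
simulate_scheme <- function(scheme, t_grid, rtol = 1e-8, atol = 1e-16) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  if (any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    stop("simulate_scheme: t_grid must be ascending and start at >= 0",
         call. = FALSE)
  }
  species <- scheme$species
  nr <- length(scheme$reactions)
  ns <- length(species)
  ## stoichiometry matrix [species x reactions] and reactant index pairs
  stoich <- matrix(0, ns, nr, dimnames = list(species, NULL))
  r1 <- integer(nr); r2 <- integer(nr); ks <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- scheme$reactions[[j]]
    ri <- match(r$reactants, species)
    r1[j] <- ri[1]
    r2[j] <- if (length(ri) > 1) ri[2] else 0L
    ks[j] <- r$k
    for (i in ri) stoich[i, j] <- stoich[i, j] - 1
    for (p in r$products) {
      i <- match(p, species)
      stoich[i, j] <- stoich[i, j] + 1
    }
  }
  stoich[scheme$fixed, ] <- 0  # fixed species never change
  rhs <- function(t, y, parms) {
    rates <- ks * y[r1] * ifelse(r2 > 0, y[pmax(r2, 1)], 1)
    list(drop(stoich %*% rates))
  }
  t0 <- t_grid
  prepend <- t_grid[1] > 0
  if (prepend) t0 <- c(0, t_grid)
  sol <- deSolve::lsoda(scheme$initial, t0, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("simulate_scheme: solver did not converge; try loosening rtol/atol",
         call. = FALSE)
  }
  conc <- unname(sol[, -1, drop = FALSE])
  if (prepend) conc <- conc[-1, , drop = FALSE]
  colnames(conc) <- species
  structure(list(times = t_grid, conc = conc, scheme = scheme),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("Mass-action simulation: %d species, %d reactions, %d times (%.3g-%.3g s)\n",
              length(x$scheme$species), length(x$scheme$reactions),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.sim_trace <- function(x, species = setdiff(x$scheme$species,
                                                c(x$scheme$fixed, "Prod")),
                           ...) {
  graphics::matplot(x$times * 1e6, x$conc[, species, drop = FALSE] * 1e6,
                    type = "l", lty = 1, col = seq_along(species),
                    xlab = expression(paste("time (", mu, "s)")),
                    ylab = expression(paste("conc (", mu, "M)")), ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Convert a concentration trace to a yield profile
#'
#' G_j(t) = c_j(t) / (dose * 1e-6 * density), the inverse of
#' [g_to_concentration()] applied per species and time.
#'
#' @param trace A `"sim_trace"`.
#' @param dose Absorbed dose, Gy (> 0).
#' @param density Solution density, kg L^-1.
#' @param species Species to keep (default all non-fixed).
#' @return An object of class `"yield_profile"`: `times`, `species`,
#'   `g` matrix `[time x species]` in umol J^-1.
#' @export
trace_to_yields <- function(trace, dose, density = 1.0,
                            species = setdiff(trace$scheme$species,
                                              trace$scheme$fixed)) {
  stopifnot(inherits(trace, "sim_trace"))
  if (dose <= 0) stop("trace_to_yields: dose must be positive", call. = FALSE)
  conc <- pmax(trace$conc[, species, drop = FALSE], 0)  # clip solver noise
  yield_profile(trace$times, conc / (dose * 1e-6 * density))
}

#' Yield profile container
#'
#' @param times Delays, s.
#' @param g Matrix `[time x species]` of G-values with species column names.
#' @return An object of class `"yield_profile"`.
#' @export
yield_profile <- function(times, g) {
  g <- as.matrix(g)
  stopifnot(nrow(g) == length(times), !is.null(colnames(g)))
  structure(list(times = times, species = colnames(g), g = g),
            class = "yield_profile")
}

#' Time of the maximum of a species profile
#'
#' Argmax over the time grid; ties resolve to the earliest time. A flat
#' all-equal trace triggers a warning.
#'
#' @param profile A `"yield_profile"` (or `"yield_fit"`).
#' @param species Species id.
#' @return Time of the maximum, s.
#' @export
species_tmax <- function(profile, species) {
  g <- if (inherits(profile, "yield_fit")) profile$g else profile$g
  if (!species %in% colnames(g)) {
    stop("species_tmax: species '", species, "' not in profile",
         call. = FALSE)
  }
  v <- g[, species]
  if (diff(range(v)) == 0) {
    warning("species_tmax: flat trace; returning the first time point",
            call. = FALSE)
  }
  profile$times[which.max(v)]
}
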