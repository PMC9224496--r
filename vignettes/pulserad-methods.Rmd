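---
title: "Methods: spectral resolution, kinetics and product accounting in pulserad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral resolution, kinetics and product accounting in pulserad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulserad)
```

## The experiment the package models

A short electron pulse deposits ~11 Gy in an N₂O-saturated aqueous solution
of a thioether model peptide (0.2 mM, natural pH, 1 cm optical path).
Radiolysis of water produces e⁻aq (0.28), HO• (0.28) and H• (0.06 µmol J⁻¹);
N₂O converts the hydrated electrons to additional HO•, so HO• (G = 0.56
µmol J⁻¹) is the dominant oxidant (90% of reactive radicals, H• the other
10%). HO• attacks the thioether sulfur to give an adduct radical (HOS•)
plus minor direct H-abstraction products; HOS• eliminates HO⁻ to the
monomeric sulfur radical cation S•⁺, which partitions between
α-deprotonation (αS•), dimerisation with a second substrate molecule
(SS•⁺), and intramolecular three-electron-bonded ring species — S∴N for the
methionine-type substrate, S∴O for the S-methyl-cysteine-type substrate,
whose sulfur sits one CH₂ closer to the backbone carbonyl. Transient
absorption spectra (270–700 nm, 0.2–170 µs) record the superposition of all
these species; LC–MS of γ-irradiated samples records their stable
radical–radical coupling products.

The package implements every computational stage of that study: dosimetry
and yield bookkeeping, multicomponent spectral resolution, mass-action
simulation of the mechanistic schemes, product/mass/stereochemistry
accounting, and a synthetic-data generator that stands in for the
(unavailable) instrument data.

## Yields and dosimetry

The scavenging-capacity dependence of the total radical yield follows the
Schuler formula, G(S•) = g₀ + g₁√(a[S])/(1+√(a[S])) with g₀ = 0.539,
g₁ = 0.307 µmol J⁻¹, a = 19.6 M⁻¹. It is strictly increasing and bounded by
g₀+g₁; at the 0.2 mM working concentration it gives 0.557 µmol J⁻¹.

```{r}
schuler_g(c(2e-4, 1e-2))
```

One published rounding is worth noting: the thiocyanate dosimeter yield is
conventionally quoted as 0.635 µmol J⁻¹ at 10 mM KSCN, while the formula
with the constants above gives 0.6332 — a 0.3% difference that traces to
rounded constants in the convention, not to the implementation. The
dosimetry functions use the conventional 0.635.

Unit discipline: concentrations in M, doses in Gy, G in µmol J⁻¹, path in
cm, density in kg L⁻¹ (fixed at 1.0 for dilute aqueous work, configurable).
No function converts units implicitly.

## Reference spectra

The resolution basis holds seven transients with the measured band maxima
and peak molar absorption coefficients:

| species | λmax (nm) | ε (M⁻¹cm⁻¹) | default FWHM (nm) |
|---------|-----------|--------------|--------------------|
| HOS•    | 340       | 3400         | 70 |
| αC(1)•  | 270 + 370 | 6200 + 1800  | 70 |
| αC(2)•  | 340       | 2000         | 150 |
| αS•     | 290       | 3000         | 70 |
| SS•⁺    | 480       | 6880         | 70 |
| SN•     | 390       | 4500         | 70 |
| SO•⁺    | 400       | 3000         | 70 |

The measured reference *curves* are not tabulated in the public record, so
band shapes are Gaussian-in-wavelength stand-ins anchored exactly at the
printed (λmax, ε) pairs; tabulated curves, when available, can be supplied
as CSV and override the parametric shapes. The two α-(alkylthio)alkyl
isomers are spectroscopically indistinguishable and share the single pooled
αS entry.

**Why αC(2)• is wider.** HOS• and αC(2)• both peak at 340 nm. With equal
Gaussian widths the two basis vectors would be exactly proportional and the
regression singular — which the real reference spectra are not. The αC(2)•
default width is therefore set to 150 nm, the value that minimises the
worst-case coefficient variance of the compound-1 basis in a conditioning
scan over 90–150 nm (basis condition number 154 for compound 1, 64 for
compound 2). Even so, two single-Gaussian bands sharing a centre remain
strongly correlated, and the αC(2)• channel carries the largest recovery
variance of all species; this is a limitation of the parametric stand-in,
not of the solver, and disappears whenever measured curves are supplied.

## Spectral resolution

Each time slice is converted to Gε units, Gε(λ) = OD(λ)·10⁶/(dose·path·ρ),
and resolved by least squares on the basis, Gε(λᵢ) = Σⱼ εⱼ(λᵢ)Gⱼ. The
coefficients Gⱼ are radiation-chemical yields, hence non-negative: the
package solves the non-negativity-constrained problem (Lawson–Hanson NNLS)
by default, with an unconstrained mode kept as a diagnostic flag. On
noiseless full-rank input with an interior solution the two agree to
machine precision, which the test suite asserts.

Resolution is slice-by-slice on the full wavelength grid with uniform
weights; there is no global kinetic-spectral fit, no baseline model, and no
per-slice wavelength windowing. Species sets follow the chemistry: compound
1 is resolved over {HOS, αC1, αC2, αS, SS, SN}, compound 2 over
{HOS, αC2, αS, SS, SO} (`compound_species()`), both configurable. When the
series grid differs from the library grid the library is interpolated onto
the series grid, never the reverse. A basis condition number above 1e8
triggers a warning, and the fit report carries per-slice residual RMS and
condition numbers.

Bookkeeping helpers reproduce the conventional presentation: integer-rounded
percentage contributions (raw fractions retained) and material-balance
totals against the expected Schuler yield.

## Kinetic schemes and their parameters

The two default networks encode the mechanistic schemes as elementary
mass-action steps; equilibria are explicit forward/reverse pairs, never
equilibrium-constant shortcuts. Printed rate constants are used as given:

| step | constant | source |
|------|----------|--------|
| HOS• → S•⁺ + HO⁻ | k_d = 5.6×10⁵ s⁻¹ | measured |
| S•⁺ + M → SS•⁺ | 1×10⁸ M⁻¹s⁻¹ | typical literature value |
| HO• + M (total) | 1×10¹⁰ M⁻¹s⁻¹ | typical literature value |
| S•⁺ → SO•⁺ (compound 2) | 6×10⁷ s⁻¹ | measured lower limit |
| H• + M → sulfuranyl | 1.7×10⁹ M⁻¹s⁻¹ | measured |
| e⁻aq + N₂O | 9.1×10⁹ M⁻¹s⁻¹ | measured (implicit in G(HO•)) |

Constants the record does not print are explicit, documented defaults,
chosen inside the typical bounds above and exposed through the `overrides`
argument (every value is in `scheme$params`):

| parameter | default | rationale |
|-----------|---------|-----------|
| HO• branch: adduct / abstraction | 0.75 / 0.25 | HOS• dominates the early radical pool (~73% at 1 µs) |
| abstraction split, compound 1 (αC1/αS/αC2) | 0.15 / 0.06 / 0.04 | backbone Cα is the prominent early minor species |
| abstraction split, compound 2 (αS/αC2) | 0.15 / 0.10 | no αC1 channel is observed for compound 2 |
| k_dep (S•⁺ → αS•), compound 1 | 2×10⁶ s⁻¹ | S•⁺ must be sub-µs for the observable radicals to carry the full HO• yield by 4 µs |
| k_dep, compound 2 | 1×10⁶ s⁻¹ (plus the 6×10⁷ s⁻¹ SO route) | deprotonation competes with fast SO•⁺ closure |
| k_SN / k_-SN | 5×10⁵ / 2×10⁵ s⁻¹ | SN• is a reversible minor channel |
| SN• → αC2 / αC1 | 2×10⁵ / 5×10⁴ s⁻¹ | six-membered route favoured over re-forming the backbone radical |
| HOS• → SO•⁺ (compound 2 only) | 1×10⁶ s⁻¹ | carbonyl-assisted decay; makes the HOS• maximum earlier and ~2× lower than compound 1's |
| SS•⁺ reverse | 1×10⁴ s⁻¹ | weakly bound dimer cation at 0.2 mM |
| SO•⁺ → αC2 | 1×10⁵ s⁻¹ | slow follow-up deprotonation |
| radical–radical sink | 1×10⁹ M⁻¹s⁻¹, all pairs | diffusion-limited coupling |
| sulfuranyl fragmentation | 1×10⁶ s⁻¹ | fast β-scission to CH₃S• |

Initial HO• and H• concentrations come from the dose via the primary yields
(0.56 and 0.06 µmol J⁻¹ × 11 Gy by default). The fixed substrate
concentration (0.2 mM) makes the bimolecular HO•+M step pseudo-first-order
at 2×10⁶ s⁻¹, so the HOS• population peaks near ln(k₁/k₂)/(k₁−k₂) ≈ 0.9 µs,
and earlier/lower for compound 2 where HOS• decays by two routes. These
qualitative contrasts — earlier, two-fold-lower HOS• maximum for compound
2; negligible SS•⁺ for compound 2; αS• the most abundant compound-1 radical
from 10 µs on — are asserted by the test suite on the default schemes.

Integration uses `deSolve::lsoda` (the networks mix 10⁵ s⁻¹ and 10¹⁰
M⁻¹s⁻¹ scales) at rtol 1e-8 / atol 1e-16; fixed species are zeroed in the
stoichiometry so they are constant exactly. `trace_to_yields()` clips
negative solver noise (below ~1e-15 M) to zero, since yields are physical
concentrations.

The SN(1)/SN(2) isomers are pooled into one SN species, matching the pooled
reference spectrum; the same holds for αS. The H-atom channel is a separate
scheme fragment (`scheme_h_atom()`, mergeable via `merge_schemes()`)
because its products are invisible to the transient spectroscopy and only
matter for product accounting.

## Product accounting

Each carbon-centred radical is a "half" with a formula (parent C₈H₁₆N₂O₂S
or C₇H₁₄N₂O₂S minus one H) and stereocentre bookkeeping: αS1 (primary,
parent centre kept), αS2 (secondary, parent centre kept + one new centre),
αC1 (parent centre destroyed and re-formed: 0 fixed + 1 new), αC2 (primary,
parent centre kept). This registry is the unique assignment consistent with
all the observed diastereoisomer counts and with the greater stability of
secondary over primary alkyl radicals.

Masses are monoisotopic, from a hard-coded IUPAC table (H 1.00782503,
C 12 exact, N 14.00307401, O 15.99491462, S 31.97207069), with MH⁺ built
from the *proton* mass (1.00727646), not the H-atom mass. All dimers of one
compound share a formula and are isobaric: 407.1781 (compound 1) and
379.1468 (compound 2).

Diastereoisomer counting enumerates R/S assignments of the new centres with
fixed centres locked at S, identifies homodimer configurations under
half-exchange, and — when no fixed centre survives — optionally merges
mirror-image pairs (`merge_enantiomers = TRUE` by default, because an
achiral LC column cannot separate enantiomers; every count anchored to an
observed product contains a fixed S centre and is invariant to the flag).
An independent brute-force orbit enumeration in the test suite checks every
pair type of both compounds.

The CH₃S• adduct intensities act as a footprint of relative radical
concentrations; `normalize_footprint()` scales them so the smallest is 1.0.
Peak matching uses a 5 ppm default tolerance and flags ambiguous
(isobaric) assignments rather than resolving them.

## The synthetic-data generator

`make_dataset()` chains the default scheme, the dosimetry conversion and
the forward Beer–Lambert model: od(λ,t) = Σⱼ εⱼ(λ)Gⱼ(t)·10⁻⁶·dose·path +
N(0, σ). Defaults are the study conditions: compound 1 or 2 at 0.2 mM,
11 Gy, 1 cm, 270–700 nm in 2 nm steps, 60 log-spaced delays from 0.2 to
170 µs, σ = 5×10⁻⁴ absorbance. The noise figure is a detector-limited
choice that keeps the 290–490 nm features clearly above noise, as in the
measured spectra; it corresponds to ~45 Gε units at 11 Gy. Noise requires a
seed, generation is scoped with `withr::with_seed` (the global RNG stream
is untouched), and the ground-truth profile and scheme are always returned
with the series.

What the generator does *not* emulate: shot noise and lamp drift,
wavelength-dependent noise, baseline/scatter artefacts, spectrograph
resolution, and any mismatch between the true reference curves and the
Gaussian stand-ins. Passing recovery tests therefore demonstrate that the
resolution machinery is correct and well-conditioned under the declared
noise model — not that the Gaussian library would resolve real instrument
data; for that, measured reference curves should be loaded in place of the
parametric defaults.

Recovery performance is measured, not assumed: noiseless round-trips are
exact to solver precision, and at the default noise the mean absolute
error of the recovered G over all species and times is ~0.009 (compound 1)
and ~0.016 µmol J⁻¹ (compound 2) over 20 seeds, the bound asserted in the
tests being 0.02. Per-species errors are larger for αC(2)• (up to ~0.035
for compound 2) because of the 340 nm overlap discussed above.

## Numerical and design choices

- NNLS via `pracma::lsqnonneg`; unconstrained diagnostic mode via QR.
- Degenerate inputs fail loudly: empty species sets, fewer than 2×
  wavelengths per species, non-ascending grids, all-zero percentage rows.
  Near-collinear bases warn with the condition number but still return the
  NNLS solution.
- Ties in `species_tmax()` resolve to the earliest time; flat traces warn.
- Percentages are integer-rounded for presentation, raw fractions retained.
- Problem sizes in the tests (60 time slices, 216 wavelengths, 20 seeds per
  compound, 40-point rate-recovery grids) are the package's chosen defaults
  for the study conditions; they keep the full suite under a minute on one
  core while leaving every Monte-Carlo bound comfortably resolved.

## Known limitations

- Gaussian reference bands are a declared stand-in for the measured curves;
  the HOS•/αC(2)• overlap is their main artefact.
- No fitting of rate constants to experimental traces is provided (the raw
  traces are not public); the test suite demonstrates k_d recovery from
  synthetic traces by grid search + refinement only.
- No spur-diffusion or stochastic kinetics; Schuler's formula is used as
  given and the ODE model is deterministic mass action.
- Product enumeration predicts what *can* form, not what is observed —
  observed product sets also depend on radical concentrations and
  chromatographic resolution.
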