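# pulserad

Radiation-chemistry toolkit for the oxidation of thioether-containing model
peptides by hydroxyl radicals. It is aimed at pulse-radiolysis and
radical-chemistry groups who need to turn time-resolved transient absorption
matrices into per-species radiation-chemical yields, check those yields
against a mechanistic reaction scheme, and account for the stable
radical-coupling products seen by LC–MS.

The package covers the full workflow for two model substrates sharing the
peptide backbone CH₃C(O)NH–CHX–C(O)NHCH₃: the methionine-type derivative
(X = CH₂CH₂SCH₃, "compound 1") and the S-methyl-cysteine-type derivative
(X = CH₂SCH₃, "compound 2").

## What it computes

**Yields and dosimetry.** Radiation-chemical yields (G, µmol J⁻¹) follow the
Schuler scavenging formula

G(S•) = g₀ + g₁·√(a[S]) / (1 + √(a[S])),  g₀ = 0.539, g₁ = 0.307 µmol J⁻¹, a = 19.6 M⁻¹,

with N₂O saturation converting hydrated electrons to HO• (G(HO•) = 0.56
µmol J⁻¹), thiocyanate dosimetry (ε₄₇₂ = 7580 M⁻¹cm⁻¹, G = 0.635 µmol J⁻¹)
and the Fricke constant G(Fe³⁺) = 1.61 µmol J⁻¹.

**Spectral resolution.** Each time slice of an OD(λ, t) matrix is converted
to Gε units, Gε(λ) = OD(λ)·10⁶/(dose·path), and resolved by non-negative
least squares on a reference-spectrum library,

Gε(λᵢ) = Σⱼ εⱼ(λᵢ)·Gⱼ,

so the regression coefficients Gⱼ are the per-species yields.
`resolve_series()` returns a `yield_fit` object with the usual `coef()`,
`fitted()`, `residuals()`, `summary()` and `plot()` methods.

**Kinetics.** `scheme_compound1()` / `scheme_compound2()` encode the
mass-action networks of the sulfur radical-cation chemistry (HOS• adduct,
k_d = 5.6×10⁵ s⁻¹ HO⁻ elimination, SS•⁺ / SN• / SO•⁺ three-electron-bonded
species, α-(alkylthio)alkyl and Cα radicals), and `simulate_scheme()`
integrates them with a stiff solver.

**Product accounting.** `enumerate_products()` lists all radical-coupling
dimers and CH₃S• adducts with exact protonated monoisotopic masses and
diastereoisomer counts; `normalize_footprint()` converts adduct intensities
to relative radical concentrations; `match_peaks()` annotates LC–MS peak
lists at ppm tolerance.

**Synthetic data.** `make_dataset()` generates complete, seeded synthetic
pulse-radiolysis datasets (kinetics → spectra → noisy OD) with ground truth
attached, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(pulserad)

schuler_g(2e-4)        # 0.5570887  — yield at 0.2 mM substrate
n2o_ho_yield()         # 0.56       — HO* yield under N2O

ds  <- make_dataset(synthetic_spec(compound = 1, seed = 42))
fit <- resolve_series(ds$series, default_library(),
                      allowed = compound_species(1))
fit
#> Transient-spectrum resolution (non-negative least squares)
#>   60 time slices, 216 wavelengths, species: HOS, aC1, aC2, aS, SS, SN
#>   dose 11 Gy, path 1 cm
#>   median residual RMS: 44.91 Geps units

i <- which.min(abs(fit$times - 1e-5))  # the ~10 us slice
round(coef(fit)[i, compound_species(1)], 3)
#>   HOS   aC1   aC2    aS    SS    SN
#> 0.029 0.090 0.000 0.379 0.003 0.016

species_tmax(fit, "HOS") * 1e6   # 0.9912 us: HOS* maximum
material_balance(coef(fit)[i, ], schuler_g(2e-4))$total  # 0.517

dimer_mh("aS2", "aS2", 1)            # 407.1781 — compound-1 dimer MH+
count_diastereomers("aS2", "aS2", 1) # 3  (SSSS, SRSS, SRRS)
normalize_footprint(c(aS2 = 154, aS1 = 94, aC1 = 14, aC2 = 10))
#>  aS2  aS1  aC1  aC2
#> 15.4  9.4  1.4  1.0
```

The resolved slice is the synthetic dataset's ~10 µs composition: the
α-(alkylthio)alkyl radical pool dominates once the HOS• adduct has decayed,
and the total yield of all resolved radicals sits a few percent below the
0.557 µmol J⁻¹ Schuler value because radical–radical coupling has already
started consuming the pool.

A thin command-line wrapper is installed at `inst/exec/pulserad`
(subcommands `yields`, `simulate`, `resolve`, `synth`, `products`).

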