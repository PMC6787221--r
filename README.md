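# linkerflex

Integrative analysis of flexibly linked multidomain proteins in R, for
structural biologists combining solution NMR and small-angle X-ray
scattering. The motivating system is the STAM2 UIM–SH3 tandem — a
ubiquitin-interacting helix joined to an SH3 domain by a disordered linker —
where linker length tunes both interdomain dynamics and avid binding to
Lys63-linked diubiquitin.

The package implements four connected analyses:

* **Binding** — combined amide chemical-shift perturbations
  Δδ = √[((Δδ_H)² + (Δδ_N/5)²)/2] fitted with fast-exchange isotherms:
  the 1:1 single-site model

  Δδ = Δδ_bound · (L₀ + P₀ + K_d − √((L₀ + P₀ + K_d)² − 4 L₀P₀)) / 2P₀

  and a bivalent 2:1 model in which the ligand contributes two binding
  units (2L₀ replaces L₀, 8L₀P₀ replaces 4L₀P₀). Per-residue
  Levenberg–Marquardt fits aggregate to domain K_d ± SD; a shared-K_d
  global mode is also provided.
* **Dynamics** — R₁/R₂/NOE extraction from intensity ladders, exact
  inversion of the reduced spectral-density map into J(0), J(ω_N),
  J(0.87ω_H), per-domain rotational correlation times from the rigid
  R₂/R₁ ratio, and a mass-vs-R₂ "molecular ruler".
* **Shape** — Guinier fits with automatic window selection and curvature
  correction, dimensionless Kratky plots ((qR_g)²·I/I₀ vs qR_g, globular
  reference peak 3/e ≈ 1.104 at √3 ≈ 1.73), regularised P(r) inversion
  with D_max scanning, and concentration-series merging.
* **Ensembles** — coarse-grained Debye profiles of residue-bead models
  (Rcpp), χ scoring with closed-form optimal scaling, pivot-move conformer
  sampling with clash rejection, and N-state (N = 1–5) weighted ensemble
  selection by non-negative least squares, summarised as weighted R_g
  distributions.

A first-class synthetic-data module generates titration tables, relaxation
decays, bead models and scattering curves with serialised ground truth, so
the whole pipeline is validated end-to-end without any experimental
download.

## Worked example

Simulate a 20-residue titration at K_d = 86 µM and re-estimate it, then
build the globular Kratky reference:

```r
library(linkerflex)
set.seed(42)
truth  <- tibble::tibble(residue = 1:20,
                         domain = rep(c("UIM", "SH3"), each = 10),
                         dd_bound = runif(20, 0.2, 0.8))
shifts <- simulate_titration(truth, kd = 86, model = "1to1", seed = 42)
fit    <- fit_kd(csp_series(shifts), model = "1to1")
fit
#> <binding_fit> 1to1 model, per-residue mode
#> # A tibble: 2 × 5
#>   domain n_residues    kd kd_sd dd_bound_mean
#>   <chr>       <int> <dbl> <dbl>         <dbl>
#> 1 SH3            10  85.5  5.06         0.553
#> 2 UIM            10  86.7  4.99         0.584

q    <- seq(0.001, 0.4, length.out = 2000)
prof <- saxs_profile(q, 100 * exp(-q^2 * 20^2 / 3), rep(0.05, 2000))
g    <- guinier_fit(prof)
g
#> <guinier_result> Rg = 20.00 +/- 0.00 A, I0 = 100 (qRg 0.02-1.30, 321 pts)
k <- dimensionless_kratky(prof, g)
attr(k, "peak_height"); attr(k, "peak_q_rg")
#> [1] 1.1036
#> [1] 1.7320
```

The recovered domain K_d values (85.5 ± 5.1 and 86.7 ± 5.0 µM) bracket the
86 µM ground truth within one SD, and the ideal globular profile peaks at
the theoretical (√3, 3/e) reference — the calibration point against which
experimental Kratky curves of partly disordered constructs are compared.
`tidy()`, `glance()` and `autoplot()`/`plot_*()` methods are available for
every result type.

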