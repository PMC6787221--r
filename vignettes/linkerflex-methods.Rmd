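---
title: "Models and methods behind linkerflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind linkerflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerflex)
options(linkerflex.quiet = TRUE)
```

`linkerflex` analyses two-domain proteins joined by disordered linkers — the
motivating system is the STAM2 UIM–SH3 tandem, a ubiquitin-interacting helix
tethered to an SH3 domain — by combining three experimental windows on the
same molecule: NMR titrations (binding), ¹⁵N spin relaxation (ps–ns
dynamics), and small-angle X-ray scattering (global shape and flexibility).
This vignette describes the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Binding: chemical-shift-perturbation titrations

Amide chemical shifts in fast exchange report the population-weighted
average of free and bound states. The combined CSP is

$$\Delta\delta = \sqrt{\tfrac{1}{2}\left[(\Delta\delta_H)^2 +
(\Delta\delta_N/5)^2\right]},$$

the 1/5 factor compensating the larger ¹⁵N dispersion. Two isotherms are
implemented (`binding_curve()`): the single-site 1:1 quadratic isotherm, and
a bivalent 2:1 isotherm in which one ligand (e.g. Lys63-linked diubiquitin)
carries two binding units, so total ligand enters the mass balance as
$2L_0$. The two curves coincide when the 2:1 model is evaluated at $L_0/2$ —
a consistency check asserted in the test suite.

`fit_kd()` fits $(K_d, \Delta\delta_{bound})$ per residue by damped
Levenberg–Marquardt least squares and aggregates per domain as mean ± SD
across residues; a global mode shares one $K_d$ per domain with
residue-specific bound-state shifts profiled out analytically. Both modes
are provided because published tables of this kind rarely state which
convention produced them; per-residue mean ± SD is the default as it
reproduces the usual "SD as error estimate" convention. The LM polish starts
from $K_d = \mathrm{median}(L_0)$; because $K_d$ and
$\Delta\delta_{bound}$ are strongly correlated when the start is far from
the optimum, a failed or bound-saturating fit is restarted from a profiled
coarse grid over $\log K_d$ — a robustness device, not a change of model.

Tunables: exclusion floor 0.02 ppm on the endpoint CSP (below typical shift
precision; residues under it carry no curvature information), $K_d$ bounds
$(0, 10^5]$ µM, significance threshold 0.4 ppm (`csp_significance()`,
configurable; implemented inclusive at the boundary). Broadened residues —
peaks that disappear during the titration — are excluded from fitting and
counted, since intensity loss is not modelled.

## Dynamics: ¹⁵N relaxation and reduced spectral density mapping

$R_1$, $R_2$ and the steady-state heteronuclear NOE are extracted from
intensity ladders by two-parameter exponential fits (`fit_exponential()`)
and ratio formation (`compute_noe()`). With no conformational-exchange term,
the three observables are a linear combination of the spectral density at
three frequencies, $J(0)$, $J(\omega_N)$ and $J(0.87\,\omega_H)$; the 3×3
system is inverted exactly per residue (`reduced_sdm()`), with a negative
$J(0)$ flagged rather than clipped — it signals exchange broadening or
noise. Constants default to $r_{NH} = 1.02$ Å and $\Delta\sigma_N = -160$
ppm at 600 MHz — standard backbone values, both configurable; $K_d$-style
sensitivity is mild because the mapping is linear in $d^2$ and $c^2$.

Per-domain rotational correlation times (`estimate_tau_c()`) are estimated
isotropically from the rigid-Lorentzian $R_2/R_1$ ratio by bisection,
after removing flexible residues (NOE < 0.65) and trimming the 10% most
extreme ratios. A full anisotropic diffusion-tensor analysis is out of
scope; the isotropic estimate suffices to express the package's target
observables — per-domain correlation times, their ordering, and the
narrowing of the inter-domain $R_2$ gap as the linker shortens. The
mass-vs-$R_2$ "molecular ruler" (`molecular_ruler()`) is a least-squares
line through calibrant proteins; deviations of a domain's observed $R_2$
from the line report coupled (rather than independent) tumbling.

## Shape: SAXS analysis

`guinier_fit()` fits $\ln I$ vs $q^2$ over the largest low-$q$ window with
$q_{max} R_g \le 1.3$, iterated to self-consistency. Windows of 15+ points
include a quartic correction term and report $R_g$ from the quadratic
coefficient: compact particles fall below the Gaussian law towards
$qR_g \approx 1.3$, and the uncorrected slope biases $R_g$ upward by ~2% on
a solid sphere. Leading points are rejected on σ-weighted residuals (>2.5)
so that exact synthetic data never triggers rejection; a runs statistic on
the final residuals reports residual curvature.

The dimensionless Kratky transform $(qR_g,\ (qR_g)^2 I/I_0)$ makes shapes
comparable across sizes: any Guinier-regime (idealised globular) curve peaks
at exactly $(\sqrt3,\ 3/e \approx 1.104)$, a parameter-free reference
recomputed by the acceptance script; a solid sphere peaks slightly lower
(≈1.027 by the closed form, matched by the implementation), and disordered
chains rise monotonically.

`pofr_invert()` recovers $P(r)$ by Tikhonov-regularised non-negative least
squares with endpoints pinned to zero, a trapezoid-integrated
$4\pi\,\mathrm{sinc}(qr)$ kernel on a uniform 101-point grid, and a
second-difference roughness penalty. The regularisation weight is chosen by
a discrepancy criterion — the smoothest solution whose misfit stays within
5% of the best achievable over a log-spaced grid — which proved more stable
than an L-curve corner on curves whose noise floor varies by orders of
magnitude across $q$. `dmax_scan()` fits candidate $D_{max}$ values,
selects the smallest one within 5% of the χ optimum whose unconstrained
solution shows no forced negative lobe, and warns when χ is still improving
at the widest candidate.

## Ensembles: coarse-grained profiles and N-state selection

Bead-model profiles use the Debye sum with a uniform per-residue form
factor ($f = 1$), computed in compiled code; the brute-force double loop is
kept in R as the test oracle. The uniform form factor, omission of the
hydration layer and of residue-specific scattering lengths are deliberate
fidelity limits: the package uses profiles comparatively (χ ranking, $R_g$
modes), which survives the simplification, but absolute χ values are not
comparable with atomic-resolution back-calculation.

Conformers are sampled by random pivot rotations at flexible (linker) beads
with clash rejection (`generate_conformers()`); rigid domains move as solid
bodies. The clash rule (4.0 Å between beads ≥ 3 apart in sequence) applies
only to pairs not inside the same rigid body — compact globular domains
legitimately pack non-adjacent beads at ~3.8 Å, so an undiscriminating rule
would reject every conformation of a folded domain. Bead-model validity
itself uses a 3.0 Å cutoff. A rapidly-exploring tree sampler would cover
the pool more efficiently; any broad self-avoiding sampler serves the
selection mathematics downstream, which is implemented in full.

`multistate_fit()` fits non-negative weights for every candidate subset of
$N$ conformers (exhaustive when the subset count permits, seeded stochastic
search with local swaps otherwise), folds the overall scale into the weight
sum, ranks by

$$\chi = \sqrt{\tfrac{1}{M}\sum_k \left(\tfrac{I_{exp}(q_k) - c\,
I_{mod}(q_k)}{\sigma_k}\right)^2},$$

and breaks ties by smaller $N$, then lexicographic member indices, for
reproducibility. Weighted $R_g$ histograms of the top-scoring models
(`rg_distribution()`, 1 Å bins) summarise the conformational landscape.

## Synthetic data: what it emulates, and what it does not

Every analysis stage is exercised end-to-end on generated data with known
ground truth (`simulate_titration()`, `simulate_relaxation()`,
`simulate_saxs()`, `make_two_domain_model()`), serialised alongside the
dataset so recovery tests are exact. The generators reproduce the
statistical structure the analyses assume — isotherm-shaped shift
trajectories with Gaussian noise, Lipari–Szabo rates rendered as noisy
exponential ladders on the standard delay ranges (0.04–2.4 s for $R_1$,
8–224 ms for $R_2$), and SAXS curves as noisy weighted mixtures of conformer
profiles with $\sigma = a\sqrt{I} + b$. They do **not** emulate spectrometer
artefacts (t₁ noise, peak overlap), inter-particle structure factors, or
buffer-subtraction errors, so green recovery tests demonstrate correctness
of the estimators under the stated noise model, not robustness to every
pathology of real data.

Study conditions are fixed at the generator defaults: protein concentration
100 µM with a 12-point ligand ladder to 5× excess; shift noise 0.005 ppm in
¹H (5× that in ¹⁵N, matching the CSP weighting); 2% intensity noise;
SAXS noise $a = 0.01\sqrt{I(0)}$; two-domain geometry of a 15-residue helix,
20-residue linker and 60-residue globule (the wild-type-like construct),
with deletions emulated by shortening those segments. A combined CSP is
split into components with the fixed convention
$\Delta\delta_N = 2\,\Delta\delta_H$, inverted consistently by
`compute_csp()`. One stated emulation target did not survive contact with
the forward model: an order parameter of 0.2 with a 1 ns internal
correlation time does *not* drive the NOE negative at 600 MHz under
standard constants; the disordered-tail regime used in tests
($S^2 = 0.05$, $\tau_e = 100$ ps) does, and reproduces the strongly
negative NOEs characteristic of free termini.

The compact globule is built as a greedy self-avoiding walk on a jittered
FCC lattice trimmed to a sphere of radius $0.6\,N^{1/3}\cdot3.8$ Å — chain
connected (consecutive beads at ~3.8 Å), near-close-packed, deterministic
under seed, clash-free by construction.

## Numerical choices and degenerate inputs

* Optimiser failures are never silent: non-converged residues are flagged
  and excluded from aggregates; fewer than two usable residues per domain is
  an error.
* Non-decaying relaxation series are reported as `not_determined`, not as
  negative rates.
* A flat scattering profile produces a monotone Kratky transform flagged as
  peak-free rather than a spurious maximum.
* `pracma::lsqnonneg` active-set stalls fall back to the clipped
  unconstrained solution (relevant only inside `dmax_scan()` diagnostics).
* All stochastic stages take an explicit integer seed and are bit
  reproducible under it.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: pools of
40–120 conformers with 41–81-point q-grids, 20-residue titrations, 30-seed
noise ensembles, 2000-bead sphere fixtures. These sizes were chosen so the
full validation cycle completes in about a minute while every statistical
claim (bias < 5%, weight recovery ± 0.05, χ ≈ 1) remains well resolved;
all stages scale to realistic pool sizes (10⁴ conformers, 10³ kept models)
through the same interfaces.

## Known limitations

* Isotropic per-domain tumbling; no model-free ($S^2$, $\tau_e$, $R_{ex}$)
  fitting; no anisotropic diffusion tensors.
* No lineshape or exchange-regime analysis of titrations; no cooperative
  (Hill) or competition models.
* Uniform-sphere form factors; no hydration shell; absolute χ values are
  not comparable across back-calculation schemes.
* No ab initio shape reconstruction, Porod volumes, or molecular-weight
  estimation from SAXS.
* Single-chain bead models only; no multi-chain assemblies or mmCIF.
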