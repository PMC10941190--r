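---
title: "Nitrile probe electric fields: models, estimators and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrile probe electric fields: models, estimators and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrilefields)
```

This vignette is the package's account of its science: the electrostatic
model and its conventions, the hydrogen-bond and exchange analyses, the
fitting machinery, what the synthetic generators do and do not emulate,
and the numerical choices that were genuinely open.

## 1. Electrostatic model

### Fields and potentials

Every atom carries a position (Å) and electrostatic parameters: a partial
charge $q$ (e), optionally a permanent point dipole $\boldsymbol\mu$
(e·Å), a traceless Cartesian quadrupole $\Theta$ (e·Å²), an isotropic
polarizability $\alpha$ (Å³) and a Thole damping factor. With
$\mathbf R$ the vector from a site to the evaluation point,
$r = |\mathbf R|$ and $k = 14.39964$ V·Å/e,

$$\phi(\mathbf R) = k\left[\frac{q}{r}
  + \frac{\boldsymbol\mu\cdot\mathbf R}{r^{3}}
  + \frac{\mathbf R^{\mathsf T}\Theta\,\mathbf R}{2r^{5}}\right],
\qquad
\mathbf E = -\nabla\phi .$$

The quadrupole convention is the "$3x_ix_j - r^2\delta_{ij}$" traceless
form whose interaction energy with a field gradient carries the 1/3
contraction factor; the factor 1/2 in the potential above is the
corresponding normalization, and parameter files must follow it (the
trace is validated to $10^{-8}$ at construction). Sums are direct — no
cutoff, no periodic images — because the intended inputs are desk-scale
clusters and trajectory excerpts, not periodic boxes.

### Projection onto the nitrile axis

`projected_probe_field()` evaluates the environment's field at the probe
and projects it on the unit vector from the nitrile C to N, converting
with 1 V/Å = 100 MV/cm. Two conventions needed fixing:

* **Evaluation point.** The default averages the fields at C and at N,
  the common convention for a bond-centered Stark probe; the bond
  midpoint and N-only are available as diagnostics
  (`eval_mode`). For a homogeneous field all three agree.
* **Sign.** Projection on C→N makes an H-bond donor proton in front of N
  produce a *negative* field (a +1 e charge 1 Å beyond N yields
  −1439.964 MV/cm in N-only mode). This matches the convention in which
  H-bonding environments report tens of negative MV/cm.

Sites sharing an exclusion group never interact, and the probe's group is
always excluded from the field it reports, so the probe measures its
environment, not itself.

### Mutual induction

At the polarizable level each site with $\alpha_i > 0$ acquires an
induced dipole $\boldsymbol\mu_i = \alpha_i \mathbf E_i$ where
$\mathbf E_i$ is the permanent field plus the field of all other induced
dipoles. Because $\alpha$ is quoted in Å³, the self-consistency is closed
in e-based units: fields enter as $\phi$-free $e/\text{Å}^2$ quantities
(V/Å divided by $k$), so $\alpha\mathbf E$ is a dipole in e·Å. This is
not a detail: formulating the coupling in V/Å overstates it by a factor
$k \approx 14.4$ and manufactures a polarization catastrophe at ordinary
H-bonding distances.

Dipole–dipole interactions are damped with the Thole exponential scheme,
$\lambda_3 = 1 - e^{-au^3}$, $\lambda_5 = 1 - (1 + au^3)e^{-au^3}$, with
$u = r/(\alpha_i\alpha_j)^{1/6}$ and $a$ the pairwise *minimum* of the
two sites' damping factors (default 0.39). The fixed-point iteration
starts from direct induction and stops when the largest per-site dipole
change is below $10^{-8}$ e·Å (at most 100 iterations; non-convergence is
an error carrying the residual). The solution is verified in the test
suite against an independent linear solve for a two-site system.

The probe's own sites never acquire induced dipoles. Whether the probe's
*permanent* parameters polarize the environment was an open design
choice; the default says yes (`probe_polarizes = TRUE`), as in a real
polarizable force field, with the fully-excluded alternative exposed for
comparison. The two choices differ by several MV/cm for a polarizable
donor at H-bonding distance.

### ESP maps

`esp_grid()` evaluates the potential on a regular plane grid (origin +
two orthonormal axes); nodes closer than $10^{-3}$ Å to a site are masked
rather than reported as near-singular numbers, and `esp_difference()`
takes node-wise differences of identically specified grids. The typical
use is the contrast between a charges-only and a multipolar description
of the same fragment: the multipolar nitrile concentrates negative
potential along the bond axis in front of N (the lone pair), the
monopolar one spreads it angularly — which is the electrostatic origin of
more head-on H-bonding under multipolar descriptions.

## 2. Hydrogen-bond analysis

A donor with heavy atom X and hydrogens H forms an H-bond to the nitrile
N when $d_{NX} < 4.0$ Å (alternate standard cutoff 3.5 Å) **and**
$\theta_{NXH} < 30^\circ$ (minimum over the donor's hydrogens). The
approach angle $\theta_{CNX}$ is measured and stored with every record
but is deliberately *not* a criterion — it is the descriptive quantity
whose distribution the geometry fits summarize. Tightening the distance
cutoff can only lower the H-bonded fraction (tested as a monotonicity
property).

`population_summary()` reports fractions (percent of frames), population
medians and the fraction-weighted field
$(f_{\mathrm{HB}}\,\tilde F_{\mathrm{HB}} +
f_{\mathrm{non}}\,\tilde F_{\mathrm{non}})/100$, with fractions used
exactly as supplied. Medians rather than means are used because the
populations are near-Gaussian but contaminated by exchange tails.
Uncertainties follow the across-trajectory convention: each statistic is
recomputed per trajectory and the error is the standard error over
trajectories (for two trajectories, half the absolute difference). When
reproducing printed reference rows the printed fractions are taken
verbatim — including one row whose printed fractions sum to 100.2 by
rounding — while internal computations always use complementary
fractions. Frames with donors of both classes are attributed
fractionally by record share in `donor_identity_fractions()`; a
"protein-wins" rule is available since the convention is not fixed by
any source.

## 3. Exchange kinetics

Maximal constant-state runs of a uniformly spaced binary trace become
dwell durations (run length × dt); the first and last runs are flagged
right-censored. Two lifetime estimators are provided and never silently
preferred:

* `mean` — arithmetic mean of uncensored dwells;
* `censored-mle` — the exponential MLE with right censoring, total
  observed time over completed events, which equals the mean method on
  fully uncensored data and is invariant to trace reversal.

The two-state first-order model gives one-way rates $k = 1/\tau$, the
relaxation (exchange) rate $k_{\mathrm{ex}} = 1/\tau_{\mathrm{HB}} +
1/\tau_{\mathrm{non}}$, and the predicted equilibrium fraction
$100\,\tau_{\mathrm{HB}}/(\tau_{\mathrm{HB}} + \tau_{\mathrm{non}})$.
Both the relaxation rate and the one-way rates are reported because the
field's ">0.1 ps⁻¹ rate ↔ <10 ps lifetime" shorthand refers to $1/\tau$
usage. A diagnostic compares $k_{\mathrm{ex}}$ with the inverse
vibrational dephasing time (default 4 ps, a typical nitrile value):
exchange much faster than dephasing collapses two bands into one at the
population-weighted frequency, which is what links the bimodal simulated
field distributions to a single room-temperature IR band. No minimum
dwell filter is applied by default because none is part of the model.

## 4. Geometry histograms and Gaussian surfaces

`hist2d()` bins $(\theta_{CNX}, d_{NX})$ on 2° × 0.05 Å bins over
[90°, 180°] × [2.5, 4.0] Å by default — the window in which nitrile
H-bond geometries concentrate — and normalizes to unit maximum, the
convention of the corresponding contour plots. `fit_surface()` fits

$$z(\theta, d) = b + A\exp\!\left(-\tfrac{1}{2(1-\rho^2)}\left[
  t^2 - 2\rho\,t\,s + s^2\right]\right),
  \quad t = \tfrac{\theta-\theta_0}{\sigma_\theta},\;
  s = \tfrac{d-d_0}{\sigma_d}$$

to the normalized counts by Levenberg–Marquardt least squares
(`minpack.lm`), initialized from the histogram's weighted moments, with
bound constraints keeping widths positive and $|\rho| < 0.95$. The
correlation term is off by default and the flat baseline on. Fitting is
done in histogram space (matching how such surfaces are usually
reported); no $\sin\theta$ Jacobian correction is applied because the
reported centers describe the *plotted* distributions — both choices were
open and are recorded here. Note that for a center near the 180° bound
the *sample mean* of truncated draws is biased low by up to a degree or
two, while the *fitted center* is not: the fit locates the peak, which is
why center-recovery tolerances of 0.5° hold even at 163° ± 12°.

## 5. Band fitting

Spectra are modeled as sums of pseudo-Voigt components (area-normalized
Gaussian/Lorentzian mixture, mixing fixed at pure Gaussian by default,
optionally free) on a linear baseline, fit by Levenberg–Marquardt with
starting centers at the largest local maxima of the lightly smoothed
spectrum. The band count (1 vs 2) is chosen by a nested-model F test at
$\alpha = 0.05$; flat or single-band spectra default to one band. The
TDM-proportional observable of a band is $\sqrt{\text{area}}$, and the
fast-exchange frequency is the population-weighted average of the
component centers — the computed check connecting a 74.0 % H-bonded
fraction and cold-matrix band centers of 2246.9/2230.1 cm⁻¹ to a warm
single-band center within ~1.2 cm⁻¹ of 2241.3 cm⁻¹.

## 6. Experiment-vs-simulation comparison

TDM observables convert to fields through an affine calibration,
$F = (\text{tdm} - c)/m$, and transferring a small-molecule calibration
to a protein-attached probe leaves constant offsets (6.4 MV/cm for the
fixed-charge family, 4.1 for the polarizable family, taken as
configuration). The ideal-correlation reference line is therefore unit
slope with intercept −offset.

The regression of simulated on TDM-derived fields uses the unified York
errors-in-both-variables formulation with uncorrelated per-point errors:
weights $W_i = 1/(\sigma_{y,i}^2 + b^2\sigma_{x,i}^2)$, slope iterated to
$10^{-10}$, parameter variances and covariance from the standard York
expressions on the adjusted abscissae. On the packaged reference tables
this reproduces the published constants and their uncertainties at
printed rounding (FC: 0.56 ± 0.04, −3.5 ± 0.8; POL: 1.17 ± 0.09,
−5.3 ± 2.7), so no alternative weighting was needed; Deming and
weighted-y fits are nevertheless reported side by side
(`regression_variants()`) because the weighting variant is the main
sensitivity.

The 2σ confidence band is pointwise,
$2\sqrt{\operatorname{Var}a + 2x\operatorname{Cov}(a,b) +
x^2\operatorname{Var}b}$. One subtlety deserves record: including the
covariance term (the statistically correct pointwise band) narrows the
band inside the data range enough that the polarizable family's
reference line sits *marginally outside* it over part of the range, while
the construction that treats slope and intercept independently — which is
what bands drawn around quoted slope/intercept pairs amount to — contains
it comfortably (and still rejects the fixed-charge line by a wide
margin). Both are available via `use_covariance`; the default keeps the
covariance, and the qualitative conclusion (fixed-charge fails, the
polarizable description is compatible) is the same under either if
"fails" is read as distance-in-sigmas: the fixed-charge line is ~5 band
half-widths away, the polarizable one ~2.

## 7. What the synthetic generators emulate

* `gen_state_trace()` — alternating exponential dwells sampled in
  continuous time, discretized at dt, initial state from the stationary
  distribution. Dwells shorter than dt can vanish, merging neighboring
  runs: the same bias a 10 ps trajectory stride imposes on real state
  series, and the reason recovered lifetimes run a few percent high at
  coarse dt. The continuous dwells are attached as an attribute so
  exponentiality can be tested without the lattice artifact.
* `gen_field_trace()` — i.i.d. state-conditional Gaussians. Real field
  traces are autocorrelated within a dwell; nothing here models that, so
  passing tests validate estimators' statistical behavior, not MD
  realism.
* `gen_scene()` — a rigid 3-site nitrile fragment (C≡N 1.16 Å) plus a
  rigid 3-site water-like donor placed to realize requested
  $(d_{NX}, \theta_{CNX}, \theta_{NXH})$ to $10^{-6}$, with toy
  parameters (O −0.834 e / H +0.417 e; small O dipole and quadrupole; α
  of 0.837/0.496 Å³ at the polarizable level). These are illustrative
  values, not any published water model, and no claim of force-field
  fidelity attaches to them.
* `gen_geometry_samples()` — truncated correlated bivariate normal by
  rejection, reporting the rejection fraction.
* `gen_spectrum()` — pseudo-Voigt sums plus white absorbance noise; no
  solvent background, no baseline drift.

All generators take one explicit integer seed, scope it with
`withr::with_seed` (no hidden global RNG state), and are bit-reproducible.

## 8. Problem sizes and numerical choices

The test suite and pipeline run at deliberately chosen scales: switching
traces of $10^5$–$10^6$ frames at dt = 0.1 ps for kinetics recovery
(lifetimes within 5 %, fractions within 2 points, across 10 seeds),
$10^5$ geometry samples for surface-center recovery (0.5° / 0.01 Å),
100 random frames of up to 100 sites for the brute-force electrostatics
cross-check at $10^{-10}$ relative, and 20 seeds for band-center
robustness (median error < 0.1 cm⁻¹). Dwell-mean recovery at τ = 50 ps
uses dt = 1 ps — about τ/50 — keeping discretization bias near 1 % while
leaving ~1000 completed events.

Other fixed numerics: induction tolerance $10^{-8}$ e·Å; York slope
tolerance $10^{-10}$; surface fits capped at 200 LM iterations, band fits
at 400; histogram bin defaults of 2 MV/cm (fields) and 2° × 0.05 Å
(geometry); ESP singularity mask $10^{-3}$ Å.

## 9. Known limitations

* No periodic boundaries, Ewald summation, cutoffs, or real force-field
  parameter-file parsing: inputs are desk-scale scenes in the package's
  extended-XYZ dialect or PDB-adjacent tables prepared by the user.
* Published population fractions, medians, trajectory-averaged geometry
  centers and donor-identity percentages derive from 100–200 ns MD
  trajectories and are **not** recomputable here; they ship as a
  provenance-flagged metadata fixture, and two printed fraction-weighted
  values (−67.0 and −26.1 MV/cm) cannot be recovered exactly from the
  printed fractions/medians at all — the arithmetic gives −66.87 and
  −26.19, so those were evidently computed from unrounded per-trajectory
  data.
* The exchange analysis is strictly two-state and first-order; no
  lineshape theory beyond the fast/slow diagnostic.
* The band-count F test assumes approximately white residuals; strongly
  structured baselines will inflate the apparent significance of a second
  band.
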