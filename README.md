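# nitrilefields

Electric fields at nitrile vibrational Stark probes, computed from
force-field electrostatics and compared against experimentally derived
fields.

## The problem

Nitrile (−C≡N) probes report the local electric field in a protein
through the vibrational Stark effect: the field component along the bond
axis, *F*<sub>C≡N</sub> (MV/cm), shifts the probe's frequency and — more
robustly in hydrogen-bonding environments — its transition dipole moment
(TDM, the square root of the integrated band intensity). Simulated fields
depend strongly on how the force field describes electrostatics: a
fixed-charge (FC) description carries only atomic monopoles, while a
polarizable (POL) description adds permanent dipoles, quadrupoles and
inducible dipoles. This package provides the full desk-side analysis chain
for benchmarking those descriptions against TDM-derived fields:

* **Electrostatics** — fields and potentials of per-atom parameter sets at
  three levels (charges; permanent multipoles; Thole-damped mutually
  induced dipoles), projected onto the C→N axis with the convention that
  an H-bond donor in front of N gives a negative field; ESP plane maps and
  difference maps.
* **H-bond analysis** — geometric classification (*d*<sub>NX</sub> < 4.0 Å
  and θ<sub>NXH</sub> < 30° by default), deconvolution of field
  distributions into H-bonding/non-H-bonding populations, medians,
  fractions and the fraction-weighted field
  (f<sub>HB</sub>·median<sub>HB</sub> + f<sub>non</sub>·median<sub>non</sub>)/100.
* **Exchange kinetics** — dwell times from binary state traces, two-state
  first-order exchange model (τ<sub>HB</sub>, τ<sub>non</sub>,
  k<sub>ex</sub> = 1/τ<sub>HB</sub> + 1/τ<sub>non</sub>), predicted
  equilibrium fractions, and a fast/slow-exchange diagnostic against the
  vibrational dephasing time.
* **Geometry fitting** — normalized 2D histograms of (θ<sub>CNX</sub>,
  *d*<sub>NX</sub>) and Gaussian-surface fits extracting average H-bond
  angles, distances and widths.
* **Spectra** — pseudo-Voigt band fitting with an F-test band-count
  selector, TDM observables (√area), and the fast-exchange
  population-weighted frequency.
* **Field comparison** — errors-in-both-variables (York) weighted
  regression of simulated vs TDM-derived fields with 2σ confidence bands,
  calibration-transfer offset lines, and Deming / weighted-y variants for
  sensitivity.
* **Synthetic data** — generators for two-state switching traces with
  state-conditional field distributions, toy probe+donor scenes that
  realize exact H-bond geometries, correlated geometry samples and
  multi-band spectra, all seeded and bit-reproducible, so every stage is
  testable against known ground truth.

## Worked example

```r
library(nitrilefields)

# A toy H-bond scene: water-like donor at d_NX = 2.93 A, theta_CNX = 167,
# theta_NXH = 10, with multipoles and polarizabilities on the donor.
fr <- gen_scene(scene_spec(2.93, 167, 10,
                           parameter_level = "multipoles+polarizabilities"))
projected_probe_field(fr, level = "charges")        # -40.5 MV/cm
projected_probe_field(fr, level = "multipoles")     # -45.8 MV/cm
projected_probe_field(fr, include_induction = TRUE) # -51.8 MV/cm

# Two-state switching trajectory and its deconvolution
p  <- switching_params(tau_hb = 6, tau_non = 4, dt = 0.1, seed = 1)
st <- gen_state_trace(p, 2e5)
fl <- gen_field_trace(st, p)
population_summary(fl, st, trajectory = rep(1:2, each = 1e5))
#>   H-bonded fraction:    59.3 +/- 1.0 %
#>   median field (H-bonded):     -60.0 +/- 0.0 MV/cm
#>   median field (non-H-bonded): -20.0 +/- 0.0 MV/cm
#>   fraction-weighted field:     -43.7 +/- 0.4 MV/cm

fit_lifetimes(extract_dwells(st), "censored-mle")
#>   tau_hb  = 6.12 ps  (k = 0.163 ps^-1, 1938 events)
#>   tau_non = 4.19 ps  (k = 0.238 ps^-1, 1939 events)
#>   k_exchange = 0.402 ps^-1
#>   predicted H-bonded fraction = 59.3 %

# Experiment-vs-simulation comparison from the packaged reference tables
york_regression(fixture_comparison_points("FC"))
#>   slope     = 0.5625 +/- 0.0380
#>   intercept = -3.52 +/- 0.84 MV/cm
york_regression(fixture_comparison_points("POL"))
#>   slope     = 1.1738 +/- 0.0885
#>   intercept = -5.30 +/- 2.68 MV/cm
```

A fixed-charge slope near 0.56 means that description underestimates the
stronger (more negative) fields by almost a factor of two, while the
polarizable slope near 1.17 tracks the experimental scale; the exchange
rate of ~0.4 ps⁻¹ (lifetimes well under 10 ps) is fast against a ~4 ps
dephasing time, which is why a single exchange-averaged IR band is
observed at room temperature.

The full chain — simulate, deconvolve, fit kinetics and geometry, compare,
fit spectra — is available as `run_pipeline(pipeline_config(...))`, which
writes versioned CSV/JSON outputs plus a manifest and is byte-reproducible
under a fixed seed.

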