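---
title: "Methods: synthetic bilayer analyses and parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic bilayer analyses and parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerlab)
```

# Scope and design

`bilayerlab` implements the quantitative analyses used in membrane
biophysics studies of small hydrophobic solutes in phospholipid
bilayers: a saturating partition isotherm, dye-leakage quantification,
trajectory observables, umbrella-sampling/WHAM free-energy profiles,
and lamellar SAXS indexing. Because such studies rarely deposit raw
data, the package's validation strategy is *parameter recovery*: every
analysis has a matching generator that produces synthetic inputs from
known ground truth, and the test suite asserts that each estimator
recovers the generating parameters within stated tolerances. Passing
these tests demonstrates estimator correctness on data with the assumed
structure; it does not certify behaviour on real measurements, whose
noise is rarely Gaussian and whose physics the generators simplify
radically (see "What the generators do not emulate").

# The synthetic bilayer

`bilayer_spec()` describes a two-leaflet membrane patch. The defaults
are the conditions of the reference fluid-PC system: 64 lipids per
leaflet (128 total), 14 solute molecules, 298 K, area per lipid
0.63 nm², P–P thickness 4.04 nm, |S_CD| = 0.14 per carbon, lateral
diffusion 5.45 × 10⁻⁸ cm²/s and 66.6% solute monomers. A DMPC-like
variant would use 312 K, 0.61 nm², 3.81 nm and |S_CD| = 0.20.
`gen_bilayer_trajectory()` realizes a `labeled_trajectory` in which
each target is encoded by construction:

* **Lateral motion.** Each lipid performs an independent 2-D Brownian
  walk with per-coordinate step variance 2·D·dt (so the step's squared
  displacement has mean 4·D·dt). Positions are wrapped into the
  periodic box; the unwrapped path is retained so the MSD estimator can
  be checked against the closed form MSD(Δt) = 4·D·Δt. Unit handling is
  fixed by dimensional analysis — 1 cm²/s = 10¹⁴ nm²/10¹² ps =
  100 nm²/ps — and asserted in the tests.
* **Geometry along z.** Phosphate planes sit at ±thickness/2 with
  Gaussian noise (default SD 0.05 nm); carbonyls 0.55 nm below the
  phosphates; terminal methyls near the center. These offsets are
  nominal fluid-PC geometry, chosen once for realism, not fitted.
* **Order parameters.** Every C–D bond of carbon k points at the polar
  angle solving (3 cos²θ − 1)/2 = −|S_CD|ₖ with uniform azimuth, so the
  estimator must return the target exactly (up to sign convention:
  bonds perpendicular to the normal give −0.5, the all-trans limit).
* **Aggregation.** Each frame independently draws the number of
  monomers m ~ Binomial(n, p); the impossible leftover m = n − 1 is
  moved to n or n − 2 with probability ½ each, preserving E[m] exactly.
  Non-monomers form dimers (plus one trimer when odd). Cluster centers
  are placed by rejection sampling at ≥ 0.9 nm minimum-image
  separation; members are offset ≤ 0.13 nm, so intra-cluster distances
  are < 0.30 nm and inter-cluster distances > 0.60 nm — unambiguous for
  the 0.30 nm single-linkage criterion. Solute z-positions center
  between the carbonyl plane and the bilayer center, reproducing the
  qualitative density-profile overlap (solute band overlapping the
  carbonyls more than the terminal methyls).

## What the generators do not emulate

No forces, thermostats or barostats; no lipid conformational sampling
(bond angles are drawn independently each frame); no solvent; no box
fluctuations (the lateral area is exactly n·APL, so the area-per-lipid
series has zero variance); no correlation between observables. Passing
recovery tests therefore validates the estimators, not any simulation
physics.

# Estimator choices

**Partition fit.** Nonlinear least squares via Levenberg–Marquardt
(`minpack.lm::nlsLM`), started from the double-reciprocal linearization
1/R_mem = (R_50/R_sat)(1/x) + 1/R_sat, which is also the independent
cross-check in the noiseless limit. Replicate-SD weighting (1/sd²) is
available but off by default — published fits of this kind rarely state
whether error bars entered the fit, so the unweighted mode is the
reference behaviour and both are tested. Negative noisy ratios are
truncated at zero by the generator with a logged count.

**Leakage summaries.** The initial rate is the slope of a linear fit
over the first decile of samples (minimum 5 points). A linear fit to an
exponential rise underestimates the true initial slope by roughly
k·T_window/2, so rate recovery is only accurate when sampling is fast
relative to the kinetics — the tests check the rate on a trace with
k·t_max ≈ 1 and the plateau (mean of the last decile) on a trace with
k·t_max ≈ 6. The mono-exponential law itself is a synthetic-only
construct: the simplest monotone model with the observed shape, not a
mechanistic claim. Out-of-range leakage values are flagged, never
clipped, to preserve raw-data fidelity.

**MSD / diffusion.** Time-origin averaging over all origins and
particles; displacements from stored unwrapped coordinates, or
minimum-image accumulation (asserting no step exceeds half a box). The
fit window defaults to lags of 10–50% of the trajectory — short lags
are contaminated by the crossover, long lags by estimator variance —
and is a configurable knob. Per-leaflet lateral center-of-mass motion
is removed by default (switchable); with N independent walkers this
shrinks D by a factor (1 − 1/N), ~1.6% at 64 lipids per leaflet, well
inside the reference tolerance. The estimator is verified against a
brute-force double loop on tiny trajectories.

**WHAM.** Standard self-consistent iteration on window constants f_i
and bin probabilities, gauge-fixed at f₁ = 0, with defaults bin width
0.05 nm, relative tolerance 1e-7 and 10⁵ iteration cap (non-convergence
raises an error carrying the f_i trace). Empty bins inside the sampled
range are masked with a warning. The aqueous reference is the
outermost 15% of the grid on the water side, averaged; the profile is
then symmetrized about the bilayer center,
G_sym(z) = (G(z) + G(−z))/2, mirroring half-profiles to full ones.
Uncertainty is available by block bootstrap within windows (warm-started
from the converged constants) but is opt-in (`n_boot = 0` default) to
keep the common path cheap. The umbrella generator samples the biased
Boltzmann density by inverse transform on a ~10× refined grid with a
trapezoid CDF — the earlier left-Riemann version carried a half-grid-step
bias that accumulated to ~0.4 kcal/mol over 40 stitched windows, which
is why the CDF construction matters. With 0.1 nm window spacing,
k = 1000 kJ/mol/nm² and 5000 samples per window, barrier recovery is
within ±0.3 kcal/mol across seeds.

**SAXS.** Reflections are local maxima of a 9-point running mean whose
prominence exceeds a fraction (default 5%) of the dynamic range;
candidates inside the smoothing margin are discarded. Positions are
refined by a least-squares parabola on the raw intensities over ±12
bins (clipped halfway to the nearest neighbouring candidate) — wide
enough to average 2–5% intensity noise down to sub-bin accuracy, narrow
enough that the parabolic approximation of a Gaussian top holds.
Indexing assigns n = round(sₙ/s₁) and flags the pattern non-lamellar
when the 1:2:3 residual exceeds 2%. All s-axis math uses the
s = 2 sin θ/λ convention, so d = 1/s₁ with no 2π factor.

# Numerical conventions and degenerate inputs

Lengths in nm, times in ps, energies internally in kJ/mol and reported
in kcal/mol (×1/4.184); diffusion reported in cm²/s; scattering in Å
and Å⁻¹ as is conventional for the instrument range (0.0075–0.07 Å⁻¹).
Degenerate inputs fail loudly: all-equal x in the isotherm fit,
calibration with F_d ≤ F_i, a leaflet without phosphates, a missing
deuterium partner (reported with molecule ids), unsatisfiable solute
packing, empty umbrella-window support. Ties in peak indexing and
cluster linkage are resolved deterministically. All generators restore
the caller's RNG state and are bit-reproducible given a seed.

# Problem sizes

The shipped analyses use 300-frame trajectories (1000–1500 frames for
cluster statistics, where the binomial frame noise dominates), 41
umbrella windows of 5000 samples, and 626-point scattering curves —
sizes at which every recovery lands well inside its tolerance while the
whole suite runs in well under a minute per module. The workflow
drivers under `analysis/` and the `run_stages()` orchestrator expose
all of these as config knobs.

# Known limitations

The generators' independence assumptions make recovery easier than on
correlated real data; the leakage kinetic law is synthetic-only; WHAM
uncertainty by within-window block bootstrap ignores window-to-window
correlation a pulling protocol could introduce; the GRO reader supports
orthorhombic boxes and the package's own role conventions only; and
the cluster criterion takes the minimum inter-particle distance between
molecules — with one-bead solutes this equals the center distance, but
multi-particle solutes would make the 0.30 nm cutoff a contact, not a
center, criterion.
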