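# bilayerlab

Quantitative analyses for the membrane biophysics of small hydrophobic
solutes — the kind of terpenoid/phospholipid interaction study that
combines partition assays, dye-leakage kinetics, bilayer simulation
observables, umbrella-sampling free energies and lamellar X-ray
scattering. Every analysis in the package is paired with a
synthetic-data generator with known ground truth, so the whole pipeline
is validated by parameter recovery rather than by external data.

The package is aimed at membrane biophysicists who want tested, reusable
implementations of the standard estimators in this area:

* **Partition** — Beer–Lambert quantitation of membrane-incorporated
  solute and the saturating partition isotherm
  R_mem(x) = R_sat · x / (R_50 + x), fitted by Levenberg–Marquardt
  nonlinear least squares with double-reciprocal starting values.
  R_sat is the saturation membrane molar ratio (solute/lipid); R_50 the
  total-solute ratio at half saturation.
* **Leakage** — carboxyfluorescein release,
  %L = 100 · (F_t − F_i) / (F_d − F_i), with trace summaries (extent,
  initial rate, plateau) and composition-modifier simulations
  (PG-like enhancement, PE-like protection).
* **Observables** — area per lipid, phosphate–phosphate thickness,
  deuterium order parameters S_CD = ⟨(3 cos²θ − 1)/2⟩, lateral
  diffusion from the Einstein relation D = lim MSD/(2·d·Δt) with d = 2,
  mass density profiles along the bilayer normal, and single-linkage
  solute cluster statistics under a 0.30 nm distance cutoff.
* **PMF** — WHAM over harmonic umbrella windows, symmetrization about
  the bilayer center, zero-referencing in the aqueous phase and
  permeation-barrier extraction.
* **SAXS** — detector-axis calibration against silver stearate
  (d = 48.8 Å), reflection detection with sub-bin parabolic
  refinement, and 1:2:3 lamellar indexing (s = 2 sin θ/λ convention,
  d = 1/s₁ — no 2π).

## Worked example

Fit a partition isotherm to synthetic data generated from known truth
(R_sat = 0.30, R_50 = 1.2, three replicates, noise SD 0.01):

```r
library(bilayerlab)
data <- gen_partition_data(r_sat = 0.30, r_50 = 1.2,
                           x_values = c(0.25, 0.5, 1, 1.5, 2, 3, 4),
                           noise_sd = 0.01, n_reps = 3, seed = 1)
fit_isotherm(data)
#> partition isotherm: r_sat = 0.3068 +/- 0.01, r_50 = 1.22 +/- 0.11
#> residual sum of squares: 0.001581
```

Both parameters land within their standard errors of the generating
truth: the membrane saturates at about 1 solute per 3.3 lipids.

Recover a water-permeation barrier from synthetic umbrella windows:

```r
prof <- gaussian_barrier_profile(6.8, width = 0.8, z_min = -0.5, z_max = 4.5)
win  <- gen_umbrella_samples(prof, centers = seq(0, 4, by = 0.1),
                             k_spring = 1000, n_per_window = 5000,
                             temperature = 298, seed = 301)
barrier_height(symmetrize_profile(wham(win, bin_width = 0.05)))$height
#> [1] 6.709477
```

The full study-shaped workflow lives under `analysis/` as numbered
drivers (`01_partition.R` … `05_saxs.R`, each takes an optional seed
argument) writing tidy tables under `results/`; `run_stages()` runs the
same stages from one YAML config with a provenance manifest.

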