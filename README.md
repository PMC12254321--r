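# nucphase

Quantitative analysis of nuclear condensate dynamics and phase behavior in
relation to chromatin spatial heterogeneity.

The nucleus is a heterogeneous composite material: chromatin density varies
over micrometers, and droplet-like biomolecular condensates form, grow and
move within that variable mesh. `nucphase` implements the imaging-analysis
pipeline used to quantify this interplay, for microscopists and biophysicists
working with live-cell fluorescence data:

* **Chromatin heterogeneity** — nucleus segmentation (Otsu, 10 µm² size
  floor) and the coefficient of variation of intensity,
  COV = σ_I / (μ_I − I_bg), in 2D mid-planes or 3D stacks; interior/periphery
  masks by binary erosion; nuclear volume from z-stacks.
* **Single-particle microrheology** — spot detection with sub-pixel
  centroids, trajectory linking, time-averaged / ensemble / pairwise mean
  square displacement, and fits of the anomalous-diffusion model
  MSD = D·t^α. The pairwise (relative-displacement) MSD cancels common-mode
  drift exactly. Amplitude distributions at a fixed lag are classified
  unimodal/bimodal by Gaussian-mixture BIC.
* **Condensate coarsening** — Rényi-entropy segmentation with a threshold
  frozen at a reference time, droplet number/size time series, power-law
  coarsening-exponent fits, and a Brownian-coalescence scaling check
  (coarsening exponent ≈ α/3 for size-dependent-mobility coalescence with
  area conservation).
* **Phase-diagram mapping** — intensity→concentration calibration, per-cell
  PS/nonPS classification, an SVM decision boundary on standardized log10
  (Core concentration, Core-to-IDR ratio) axes, and the saturation
  concentration c_sat at a fixed ratio.
* **FRAP** — normalization (background, reference-ROI drift, min–max) and
  single-exponential recovery fits y = b·(1 − e^(−k(t−t0))) for the mobile
  fraction b.
* **Synthetic data with ground truth** — seeded generators for heterogeneous
  nuclei of controllable COV, exact fractional-Brownian trajectories (single
  or mixed populations, localization noise, drift), rendered spot movies,
  droplet nucleation–coalescence simulations with exact area/volume
  conservation, cell ensembles with a known binodal, and FRAP curves. Every
  analysis stage is validated against these generators.

## Worked example

Simulate a two-population probe experiment (a slow sub-diffusive and a fast
diffusive population, as seen for nanoparticles sampling dense vs sparse
chromatin), then analyze it with the same functions you would apply to real
trajectory tables:

```r
library(nucphase)

cfg <- sim_config(seed = 7, frame_interval = 0.1)     # 0.1 s frames
ts <- gen_trajectories(list(
  population_spec(100, 200, D = 0.02, alpha = 0.5, fraction = 0.5),
  population_spec(100, 200, D = 0.20, alpha = 1.0, fraction = 0.5)), cfg)

fit_anomalous(msd_ensemble(ts))
#> Anomalous diffusion fit: MSD = D * t^alpha
#>   D = 0.1108 um^2/s^alpha, alpha = 0.955  (window 0.1-4.98 s, 49 lags, R^2 = 0.9998)

amplitude_distribution(ts, lag = 0.3)
#> MSD amplitude distribution at lag 0.3 s: 200 tracks, bimodal
#>   (means 0.0109 / 0.0586 um^2, fractions 0.50 / 0.50, dBIC 583.9)
```

The pooled fit lands between the two populations (α ≈ 0.95 here), while the
amplitude distribution resolves the mixture: two components of equal weight
whose amplitudes differ ~5-fold, i.e. a mechanically heterogeneous
environment.

Chromatin heterogeneity and the phase diagram, against known ground truth:

```r
g <- gen_chromatin_field(0.45, geometry = c(6, 4.5), config = cfg)
bg <- estimate_background(g$intensity_field, !g$nucleus_mask)
compute_cov(g$intensity_field, g$nucleus_mask, bg)
#> Chromatin heterogeneity (2d): COV = 0.4500 (mean 1100, sd 450, background 100, 4801 px)

ens <- gen_phase_ensemble(800, label_flip_prob = 0.05, config = cfg)  # true c_sat 0.10 uM
saturation_conc(fit_boundary(ens), at_ratio = 1/16)
#> Saturation concentration: 0.108 uM at Core-to-IDR ratio 0.0625
```

The measured COV reproduces the generator's target (0.45), and the SVM
boundary recovers the ground-truth saturation concentration (0.10 µM) to 8%
from 800 noisily-labeled cells.

A FRAP fit:

```r
fit_frap(gen_frap(b = 0.82, k = 0.12, noise_sigma = 0.02, config = cfg))
#> FRAP fit: y = b (1 - exp(-k (t - t0)))
#>   mobile fraction b = 0.821, k = 0.1197 1/s, t0 = 0 s (RSS 0.02996 over 61 points)
```

A thin command-line wrapper for shell pipelines is installed at
`inst/scripts/nucphase.R` (`simulate`, `msd`, `heterogeneity`,
`condensates`, `phasemap`, `frap` subcommands).

See `vignettes/nucphase-methods.Rmd` for the models, parameter defaults,
numerical choices and limitations.

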