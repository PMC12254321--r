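---
title: "Models and methods behind nucphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucphase)
```

`nucphase` quantifies how the spatial heterogeneity of the chromatin network
relates to the dynamics and phase behavior of nuclear condensates. It covers
five analysis stages — chromatin heterogeneity (COV), single-particle
microrheology (MSD and anomalous-diffusion fits), condensate coarsening,
high-throughput phase-diagram mapping, and FRAP — together with a seeded
synthetic-data generator that produces every input with known ground truth,
so each stage can be validated without any microscope data. This vignette
explains the models, the tunable parameters, the numerical choices, and what
the synthetic validation does and does not establish about real data.

## Chromatin heterogeneity

Heterogeneity of a labeled chromatin channel is summarized by the
coefficient of variation of intensity inside a nucleus mask:

$$\mathrm{COV} = \frac{\sigma_I}{\mu_I - I_\mathrm{bg}},$$

where the background $I_\mathrm{bg}$ is the median intensity of a cell-free
region (`estimate_background()`). Masks come from Otsu thresholding of a
1-pixel-blurred image with a 10 µm² minimum size (`segment_nucleus()`);
crucially, the blur is used *only* to build the mask. The statistic itself
is computed on raw intensities — blurring first would systematically
deflate the COV by suppressing exactly the pixel-scale contrast being
measured. The output records this convention. The COV is invariant under a
multiplicative detector gain (applied to signal and background alike) but
not under additive offsets, which is why the background estimate matters;
both properties are asserted in the test suite.

"Mid-plane" 2D analysis uses the z-slice of maximal mask area; 3D analysis
pools all voxels. On a z-uniform synthetic nucleus the two agree exactly.

The synthetic counterpart, `gen_chromatin_field()`, renders an elliptical
nucleus whose interior texture is a low-pass-filtered Gaussian random field,
exponentiated to give blob-like bright clusters and then affinely rescaled
so that the within-mask COV equals the requested target exactly. This is a
statistical stand-in, not a polymer model: it reproduces the first two
moments and a controllable correlation length, nothing about loci,
compartments or dynamics. Exactness of the target is achieved by keeping
the intra-nuclear field noiseless; only the extranuclear background carries
shot noise. Estimator error against this ground truth is therefore
dominated by the background estimate, and stays below 2% across targets
from 0.05 to 1.

## Trajectories and the anomalous-diffusion model

Particle motion is summarized by the time-averaged mean square displacement
and the anomalous-diffusion model

$$\mathrm{MSD}(\tau) = D\,\tau^{\alpha},$$

fitted by ordinary least squares of $\log \mathrm{MSD}$ on $\log \tau$
(`fit_anomalous()`): $\alpha$ is the slope, $D = e^{\mathrm{intercept}}$.
The default fit window runs from one frame interval to 25% of the track
duration — the usual compromise between localization-noise bias at short
lags and exploding estimator variance at long lags; the window is always
recorded in the fit object. The localization-noise floor ($4\sigma^2$ for
2D) is *not* subtracted by default, matching the convention of fitting raw
MSDs; an `offset` argument provides the noise-aware alternative. Tracks
shorter than 10 frames are excluded from ensemble statistics.

The generator `gen_trajectories()` produces exact fractional Brownian
motion: per-axis increments are stationary Gaussian fractional noise with
Hurst index $H = \alpha/2$, sampled through the Cholesky factor of the
exact autocovariance (supported to 4096 steps). Exactness matters because
the same tracks serve as ground truth for the fitters — generator bias
would be indistinguishable from estimator bias. Localization noise is
additive i.i.d. Gaussian on positions (static error only); motion blur
during exposure is not modeled. The apparent ensemble MSD is then
$D\tau^\alpha + 4\sigma_\mathrm{loc}^2 + |v|^2\tau^2$ with drift $v$.

Per-track power-law fits of Brownian tracks carry a small downward bias
(the log of a noisy mean is below the log of the mean), so a 200-track
mean fitted exponent lands near 0.98 rather than 1.00; ensemble fits are
essentially unbiased. Both estimators are exposed — per-cell ensemble
fitting is the default convention for per-condition comparisons, per-track
fitting feeds amplitude distributions.

### Pairwise MSD

For particles embedded in a moving medium, the MSD of the *relative*
separation of co-imaged particle pairs, halved, equals the single-particle
MSD for independent identical diffusers while canceling any common-mode
motion exactly — uniform drift drops out of the separation vector
identically, not just in expectation. The factor of one half is a
normalization choice that makes pairwise and single-point curves directly
comparable on the same axes. Both this equality (within sampling error)
and the exact drift cancellation are asserted in the tests.

### Amplitude bimodality

A mixed mechanical environment shows up as a multimodal distribution of
per-track MSD amplitudes at a fixed lag (0.1 s by default).
`amplitude_distribution()` fits 1- and 2-component Gaussian mixtures to the
log10 amplitudes and calls the distribution bimodal when the 2-component
BIC is better by more than 6 — a conventional "strong evidence" margin that
makes the visual histogram judgment reproducible. Fewer than 20 qualifying
tracks yields `undetermined` rather than a guess.

### Detection and linking

`detect_spots()` finds local maxima of a blurred frame above an intensity
percentile and refines them with an intensity-weighted centroid (local
minimum subtracted) — sub-0.1 px accurate for an isolated high-SNR spot.
`link()` assigns detections to tracks greedily in order of ascending
squared displacement with a hard `max_disp` gate and optional gap memory.
Greedy assignment coincides with the global least-squares assignment
whenever particles are separated by more than twice their per-frame
displacements; crossing particles closer than `max_disp` can swap
identities, which is reported in QC counts rather than silently absorbed.
Tracking is 2D throughout.

## Condensate coarsening

Activation movies are segmented per frame with a threshold frozen at a
reference time (60 s after activation, when sizes reach quasi-equilibrium)
using the Rényi-entropy method in its three-order formulation: per-order
maximum-entropy split points for orders 1/2, 1 and 2 are combined by an
agreement-weighted rule on a 256-level min-max histogram. Freezing the
threshold makes the per-frame size series comparable over time, and
re-segmenting with the frozen value is bit-identical. Components smaller
than 4 px are discarded (single-pixel noise), centroids are
intensity-weighted, and the equivalent diameter is $d = 2\sqrt{A/\pi}$.

One property of entropy thresholds worth knowing: on high-contrast images
they settle just above the background mode, so a blurred droplet edge
contributes a roughly fixed ~1 px halo. Sizes of droplets tens of pixels
across are recovered to a few percent; very small droplets are
systematically padded. This is inherent to the method, not a defect of the
implementation, and the tests probe the large-droplet regime where the
analytic area is meaningful.

The coarsening exponent $\beta$ in $\bar d(t) \propto t^{\beta}$ is fitted
by log–log least squares over a window that by default discards the first
activation minute (nucleation-dominated).

### Brownian-coalescence scaling

For droplets performing Brownian motion with Stokes-like size-dependent
mobility ($\mathrm{step\ variance} \propto d^{-1}$) and merging on contact
with area conservation, Smoluchowski-type kinetics give
$\bar d \propto t^{1/3}$: the coarsening exponent is one third of the
diffusive exponent. `gen_coalescence()` implements exactly this process in
a periodic 2D box — contact when center distance falls below the radius
sum, transitive merging of contact chains within a step at the
conserved-quantity-weighted centroid — and `coalescence_scaling_check()`
measures the ratio on simulated output.

Choices that matter, fixed from a design study of the local slope
$\mathrm{d}\log\bar d/\mathrm{d}\log t$:

* **Packing**: initial area fraction 10%. Dilute systems spend thousands of
  steps in a collision-poor transient before the scaling regime; 10% is
  typical of a condensate-rich nucleus and reaches the regime within a few
  hundred steps of a 2000-step run.
* **Fit window**: the first 5% of the run (transient) is discarded, and
  frames retaining fewer than 10% of the initial droplets are excluded —
  with ~50 droplets or fewer the mean diameter moves in discrete jumps at
  each merge and the log–log slope becomes noise-dominated.
* **Diffusive exponent**: the mean of per-track fits, not a pooled ensemble
  MSD. Mobility is size-dependent and lifetimes correlate with size (the
  long-lived tracks are the big, slow droplets), so a pooled MSD mixes
  different mobility populations at different lags and reads out a spurious
  exponent; each individual track has stationary mobility by construction.
* In 2D the diffusion-limited collision kernel carries logarithmic
  corrections, so measured exponents sit slightly below the ideal 1/3
  (typically 0.30–0.32 over this window); the ratio lands within a few
  percent of 1/3.

Conservation of $\sum d^2$ (area mode) or $\sum d^3$ (volume mode) across
merges is exact up to floating-point roundoff and asserted to 1e−9
relative. For anomalous mobility ($\alpha \ne 1$) droplets carry fractional
Gaussian increment streams; a merge starts a fresh stream, so increment
correlations are exact only within a droplet's lifetime — the Brownian case
used in the scaling analysis is unaffected.

## Phase-diagram mapping

Cells are characterized by their Core concentration and Core-to-IDR ratio;
each is labeled phase-separated (PS) when droplets are detected after
activation (`classify_ps()`, at least one droplet by default, with a
contrast floor so flat shot noise is not read as a condensate).
Fluorescence is converted to concentration by a linear calibration
(`fit_calibration()`), anchored by an equimolar two-fluorophore construct.

`fit_boundary()` separates PS from nonPS cells with a soft-margin SVM on
*standardized log10 axes*: concentrations span decades, and without the log
transform the margin geometry would be dominated by the highest-expressing
cells. The kernel is radial-basis with cost 1 — empirical binodals
are curved in log space, which a linear kernel on raw axes cannot produce;
a linear-kernel mode is retained as a flag. Class imbalance is handled by
inverse-frequency class weights. The boundary polyline is the zero level
set of the decision function on a 200 × 200 grid spanning the data, read
off per ratio column as the first upward sign crossing along the
concentration axis, linearly interpolated. The decision function's sign is
oriented by comparing its mean over the two training classes (a probe
point far outside the data would be meaningless under a radial kernel).

The saturation concentration $c_\mathrm{sat}$ at a fixed Core-to-IDR ratio
(1/16 by default) is the log-log interpolation of that polyline; no
extrapolation outside the sampled ratio range is permitted. On synthetic
ensembles of 800 cells with 5% label flips, the median relative
$c_\mathrm{sat}$ error over seeds is below 15%.

`gen_phase_ensemble()` samples cells log-uniformly over both axes and
labels them against a ground-truth power-law binodal
$c_\mathrm{sat}(r) = c_\mathrm{ref}(r/r_\mathrm{ref})^{\gamma}$ (defaults:
0.10 µM at ratio 1/16, $\gamma = 0.5$), flipping labels with a small
probability to emulate classification noise near the boundary. The
power-law form is a convenience: it is positive, monotone and spans the
sampled decades; it does not claim the thermodynamics of a real binodal
(no re-entrant or valence-capped regimes).

## FRAP

Recovery curves are background-subtracted, optionally drift-corrected by an
unbleached reference ROI (ratio correction against its pre-bleach mean),
and min–max normalized so the post-bleach minimum maps to 0 and the
pre-bleach plateau to 1 (`normalize_frap()`). The single lowest frame
defines the minimum (configurable). The recovery model

$$y(t) = b\,\bigl(1 - e^{-k (t - t_0)}\bigr)$$

is fitted by nonlinear least squares with $t_0$ *fixed* at the bleach time
— it denotes the start of bleaching, not a free parameter; a free-$t_0$
mode exists behind a flag. Multistart over $k \in \{0.01, 0.1, 1, 10\}$
s⁻¹ guards against local minima, and $b$ is softly capped at 1.05 to
absorb noise. The mobile fraction $b$ is recovered to ±0.02 on 60-second
curves with 2% noise, which is the regime needed to distinguish a fully
chromatin-incorporated probe ($b \approx 0.03$) from a partially bound one.

## Reproducibility and problem sizes

Every generator draws from a child stream derived from the master seed of
its `sim_config` by a fixed per-stage offset, so stages are reproducible
independently of call order, and identical seeds give bit-identical output
(asserted by serialization in the tests). The validation suite uses
problem sizes chosen to exercise the asymptotic claims while remaining
desk-scale: 200 tracks × 300 steps for exponent recovery, 500 droplets ×
2000 steps × 10 seeds for the coalescence scaling ratio, ensembles of 800
cells × 10 seeds for boundary recovery, and 100 noisy curves for FRAP.

## What the synthetic validation does not show

The generators emulate the *statistical structure* of live-cell data, not
its physics or its artifacts. Passing tests establish that the estimators
recover known ground truth under Gaussian PSFs, Poisson counting noise,
fractional Brownian motion, ideal merge rules and a noiseless binodal.
They do not establish robustness to photobleaching, motion blur, uneven
illumination, segmentation errors on textured nucleoplasm, non-Markovian
chromatin rearrangement, or 3D effects collapsed into 2D tracking — all of
which are present in real experiments and must be controlled at
acquisition time.
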