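---
title: "Methods: Bayesian image decoding from RGC spike trains under fixational drift"
author: "retinodecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian image decoding from RGC spike trains under fixational drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, numerical choices and known
limitations of the package. Everything described here is implemented in the
exported functions and exercised by the test suite; no empirical claim is made
beyond what the tests and `scripts/acceptance.R` themselves compute.

## The encoding model

The package's central object is the LNBRC — a Linear-Nonlinear-Bernoulli
encoder with recurrent coupling — for retinal ganglion cell (RGC) spiking on
a 1 ms grid. For cell $i$ with binary spike train $s_i[t]$, the generator
signal is

$$
g_i[t] \;=\; m_i^\top v[t-1] \;+\; (s_i * f_i)[t-1] \;+\;
\sum_{j \in N_i} (s_j * c_{ij})[t-1] \;+\; b_i ,
$$

where $v$ is the stimulus movie, $m_i$ a rank-1 space–time separable
stimulus filter, $f_i$ the spike-history (feedback) filter, $c_{ij}$ coupling
filters from the neighbor set $N_i$, and $b_i$ a bias. Spiking is Bernoulli
with probability $\sigma(g_i[t])$, $\sigma(x) = e^x/(1+e^x)$, giving the
negative log-likelihood

$$
-\log p(s \mid v) = \sum_t \big[ \log(1 + e^{g_i[t]}) - s_i[t]\, g_i[t] \big],
$$

which is jointly convex in all filter parameters. Two reference variants are
provided: the LNBR (identical but without coupling filters) and an LNP
benchmark (Poisson spiking in 8.33 ms frame bins with an exponential
nonlinearity).

**Conventions.** All temporal filters are strictly causal (lags start at
1 ms). The stimulus term filters *contrast* — the frame minus the 0.5 gray
screen level — so a gray screen produces zero drive and the bias alone sets
the baseline rate; this is a reparameterization of the bias, not a change of
model. The neighbor rule follows the class-dependent threshold: cell $j$
couples into $i$ when their receptive-field centers are within 2.0
(parasol receivers) or 2.5 (midget receivers) times the median
nearest-neighbor distance of the receiving cell's own type mosaic. Because
the rule does not specify mixed-type pairs, the receiving cell's class
decides the multiplier; a `homotypicOnly` switch restricts coupling to
same-type pairs.

**Bases.** Temporal, feedback and coupling filters are linear combinations
of log-time raised-cosine bumps; the first bump peaks at lag 1 ms and the
last bump's support ends exactly at the configured span (defaults: 5 bumps
over 50 ms for stimulus and feedback kernels, 4 bumps over 30 ms for
coupling). This placement matters: with interior-only bump centers the basis
cannot represent fast exponential decays (the test suite requires a <5%
residual on a 20 ms exponential). Spatial filters live on a rectangular crop
around the receptive field (±1.5 receptive-field radii by default) in a
tensor-product uniform cubic B-spline basis whose knot spacing scales with
the receptive-field size (about 0.75 radii per knot, floor 2 px); uniform
B-splines on an extended knot grid are a partition of unity on the crop, so
smoothness comes from the basis and not from extra penalties.

## Fitting

Each cell is fitted independently by minimizing the NLL plus an L1 penalty on
the spatial spline coefficients and a group L2,1 penalty on each neighbor's
coupling coefficients. Exploiting rank-1 separability, fitting alternates
between the *spatial stage* (spatial + feedback + coupling + bias, temporal
course fixed) and the *temporal stage* (temporal + feedback + coupling +
bias, spatial map fixed); each stage is solved with FISTA with backtracking
and restart-on-increase, followed by a short momentum-free proximal-gradient
refinement that settles penalized groups onto their exact zeros. Design
columns are standardized to unit RMS inside each stage (penalties are defined
in the standardized space, as in `glmnet`) and the line search is initialized
at the local curvature `lambda_max * p(1-p)` rather than the worst-case
`lambda_max/4`, which matters at realistic (few percent per bin) spike
probabilities. The rank-1 scale ambiguity is fixed by a unit-L2,
positive-peak temporal kernel. Because the alternation is not jointly
monotone once the scale is renormalized, the best iterate across alternations
is kept, and a final converging spatial-stage polish produces the reported
model. Default penalties (`l1 = 3`, `l21 = 150` in standardized units) were
fixed once by the prescribed grid-search procedure (held-out NLL on synthetic
probe cells) during development; `gridSearchHyperparams()` re-runs that
selection for any data set, holding out the contiguous trailing 20% of
trials (k-fold rotation is available through repeated calls with rotated
splits).

## Synthetic retina

The generator is first-class, tested code; it defines the study conditions
used throughout the test suite.

* **Mosaics** are jittered triangular lattices per cell type (ON/OFF parasol,
  ON/OFF midget). Defaults: 120 um parasol and 60 um midget spacing (midget
  receptive-field radius 30 um, parasol 55 um; midget spacing about twice
  the midget radius, midgets about twice as dense as parasols linearly).
  The jitter radius is 0.1 lattice spacings, reproducing the high spatial
  regularity of real RGC mosaics — the median nearest-neighbor distance then
  sits within a few percent of the lattice spacing.
* **Ground-truth models** use Gaussian center receptive fields
  (SD = radius/2), biphasic difference-of-gamma temporal kernels (faster and
  more transient for parasols), a decaying refractory feedback kernel
  (−8 at short lags, 8 ms decay), and brief excitatory coupling between a
  seeded random half of close same-type pairs — all projected onto whatever
  bases are configured, so recovery tests compare within the model class.
  The stimulus gain (8 generator units per unit contrast) and baseline
  (15 Hz) were chosen so simulated drift-stimulus rates span roughly
  20–60 Hz, typical of peripheral RGCs under naturalistic movies.
* **Stimuli.** Flashed protocol: 100 ms image (12 frames at 120 Hz) then
  400 ms gray. Drift protocol: one image per 500 ms (60 frames), shifted at
  every frame transition by a discretized 2-D Brownian step. Frame-to-bin
  bookkeeping uses `round(k * 1000/120)` boundaries, giving the 8–9 ms frame
  pattern; frames tile the 1 ms grid exactly.
* **Drift convention.** Each per-axis step is Gaussian with variance
  $D$ um$^2$ per frame, so the 2-D mean squared displacement grows as
  $2Dt$; steps are converted to pixels and rounded half-away-from-zero. The
  source does not state its convention; the alternative ($4Dt$) would halve
  the recovered value, and realized-displacement summaries differ
  accordingly. `estimateDiffusionConstant()` regresses the time-averaged MSD
  through the origin with $1/\Delta^2$ weights over lags up to 10 frames —
  the weighting matches the lag-squared growth of the MSD sampling variance
  and keeps the Monte-Carlo error of the recovered $D$ well under 1% at
  2,000 trajectories.
* **Images** are 1/f-amplitude Gaussian textures with superimposed
  hard-edged rectangles and discs, clipped to [0,1]: spectrally naturalistic,
  with edges that a spectral prior cannot represent well.
* **Spike simulation** is sequential over 1 ms bins. The default closed-loop
  mode feeds every cell's generated past back through feedback *and*
  coupling filters; a `conditioned` mode drives the coupling terms from a
  supplied reference raster instead (matching how simulated rasters are
  compared against recorded repeats), with feedback always from the
  generated past.

What the generator does **not** emulate: photoreceptor and bipolar
biophysics, adaptation, omitted cell types, shared (latent) noise beyond
coupling, persistence or self-avoidance of drift trajectories, and saccades
beyond abrupt image switches. Tests passing on this retina therefore
demonstrate correctness of the machinery and internal consistency of the
method, not performance on recorded data.

## Image priors and MAP reconstruction

The 1/F spectral Gaussian prior penalizes Fourier amplitudes,
$\lambda \sum_k |a_k(y)|^2 / f_k^2$, with $f_k$ the radial frequency in
cycles/image on the unitary DFT grid. The DC weight is set to zero — the
energy is otherwise singular at $f=0$ — leaving mean luminance to the
likelihood. Its Gaussian-denoising subproblem has the closed form
$X_k = Z_k / (1 + 2\lambda\sigma^2 w_k)$ (`denoiseExact1F`), a linear,
self-adjoint operator that serves as the reference denoiser. Any function
`(image, noiseVariance, validMask) -> image` satisfying the contract checked
by `validateDenoiser()` can be plugged in; learned denoisers are plug-ins by
design and no training code ships with the package.

Reconstruction maximizes likelihood x prior by half-quadratic splitting:
alternately minimizing the encoding NLL plus $\tfrac{\rho}{2}\|x - z\|^2$
(backtracking gradient descent, warm-started, relative-objective tolerance
1e-6, 60-iteration default cap) and applying the denoiser at variance
$\lambda/\rho(k)$, over K = 10 log-spaced $\rho$ values. Defaults
($\lambda = 0.1$, $\rho$ from 0.2 to 200) were selected by the prescribed
grid search on held-out synthetic images with MS-SSIM as the objective.
The machinery is verified against closed forms: with a Gaussian
pseudo-likelihood and the exact 1/F denoiser the 10-iteration output matches
the analytic quadratic MAP to better than 0.1% — provided the
pseudo-likelihood is well-conditioned (rows >= pixels). With a
rank-deficient likelihood, modes the data barely constrains move at rate
$h/\rho$ per iteration and a 10-step annealed splitting cannot converge to
the exact MAP; this is a property of the algorithm, not a defect, and the
oracle test is specified accordingly.

Flashed decoding scores the spikes from flash onset to +150 ms. The
known-trajectory decoder evaluates the same likelihood on the movie induced
by shifting the candidate image along the given integer-pixel trajectory;
with a zero trajectory it reduces exactly to flashed-style decoding of the
trial. The noiseless constrained variant replaces the likelihood by the
equality constraint $M^\top x = s$ (columns of $M$: unit-L2-normalized
spatial filters; L2 chosen because "normalized" is otherwise ambiguous) with
the closed-form projection $x = z - M(M^\top M)^{-1}(M^\top z - s)$.
A ridge linear decoder from windowed spike counts provides the regression
benchmark.

## Joint estimation of image and eye trajectory

With unknown drift the posterior requires marginalizing over trajectories;
the package uses MAP-EM with a sequential importance resampling particle
filter (N = 10 particles by default) over integer-pixel cumulative
displacements. Per frame transition, particles propagate through the
Brownian transition prior (bootstrap proposal), are reweighted by the
likelihood of the new frame's spikes given the extended trajectory and the
current image, normalized, and systematically resampled when the effective
sample size falls below N/2. The image is updated once every 5 frame
transitions (and at the last frame) by one encoding step on the
importance-weighted expected NLL — duplicated post-resampling trajectories
are collapsed first — followed by one denoiser pass. The EM quadratic weight
continues the initialization schedule at its cap $\rho(K)$.

Two design choices matter at desk scale and are deliberate:

* **Initialization window.** The initial image is reconstructed assuming a
  fixed eye position, but from only the first 150 ms of the trial. Over that
  window the accumulated drift is small (about 1.5 px SD at D = 10
  um^2/frame and 8 um pixels), so the initial image is sharp and nearly
  registered. Initializing from the full 500 ms instead produces an image
  pre-blurred along the (wrong) zero trajectory; the filter then prefers
  staying at the origin — a self-consistent EM fixed point — and joint
  estimation never escapes it at synthetic population sizes. With the
  windowed initialization the joint decoder beats the zero-assumption
  decoder on essentially every synthetic trial.
* **Importance weights at the image step.** The expectation over the
  trajectory distribution uses the particles' importance weights, not
  equally-weighted resampled copies.

The filter itself is verified against exact inference: on a bounded 5x5
position grid, with a model whose stimulus kernel spans at most one frame
(so the emission depends on two consecutive positions and filtering has an
exact two-frame HMM forward recursion), the particle posterior matches exact
enumeration to total-variation distance < 0.1 at every frame.

The trajectory point estimate is the importance-weighted mean particle path;
`trajectoryError()` reports per-frame Euclidean error and its time-averaged
RMS in micrometers.

## Analyses

* **PSTH**: 1 ms counts, Gaussian smoothing (SD 2 ms) with reflective
  padding (mass-conserving), averaged over repeats.
* **Fraction of PSTH variance explained**: $1 - \mathrm{MSE}/\mathrm{Var}$
  with the population (n-denominator) variance.
* **Cross-correlograms**: spike-time difference histograms in 1 ms bins,
  averaged over repeats; the shift predictor pairs the second cell's response
  from the next trial (cyclically) and is subtracted to remove the component
  predicted by trial structure alone. By this convention the raw
  autocorrelogram of a binary train at lag 0 equals its per-trial spike
  count.
* **Spike-time perturbation**: each spike is independently jittered by a
  zero-mean Gaussian, reflected at the record boundaries and re-binned;
  collisions are resolved by redrawing that spike's jitter (with a
  nearest-free-bin fallback after 200 draws), so spike counts and the
  one-spike-per-bin invariant are preserved exactly. At sparse rates the
  redraw bias is far below the percent level.
* **Repeat shuffling** permutes the repeat axis independently per cell:
  per-cell PSTHs are exactly invariant, noise correlations are destroyed.
* **Drift magnitude**: the standard deviation (n-denominator) of the
  per-frame 2-D cumulative displacement magnitudes about their mean, on the
  realized integer-pixel trajectory, in micrometers. Whether the source
  quantity uses per-axis or 2-D magnitudes is not stated; the 2-D convention
  is pinned here.
* **Cell-type subsetting** restricts model, graph, coupling filters and
  rasters consistently (used for parasol-only/midget-only decoding).

## Evaluation

The valid region is the convex hull of receptive-field extents (16 support
points per cell at center ± radius), rasterized with an even-odd
point-in-polygon test; hulls smaller than one pixel squared are rejected as
degenerate. MS-SSIM uses the standard five scale weights, an 11-px Gaussian
window (SD 1.5), unit data range, and 2x2-mean downsampling; the scale count
is reduced automatically so the coarsest scale still exceeds the window.
Because MS-SSIM needs rectangular support, both images are cropped to the
mask's bounding box and out-of-mask pixels are replaced by the truth's
in-mask mean — deterministic, and windows straddling the hull boundary see
neutral content. For drift reconstructions, whose absolute position is
arbitrary, the score is maximized over integer shifts within a ±5 px default
radius and the argmax shift is reported.

## Problem sizes and determinism

The test suite runs entirely on the synthetic retina at fixed seeds: a
~30-cell, 24x24 px (8 um/px) four-type retina with 20 drift trials for the
decoding comparisons; a 20-cell retina with 60 s of simulated drift stimulus
for fitting recovery; 2,000 trajectories for the diffusion-constant check;
and a 5-cell short-kernel retina for the exact-filtering oracle. These sizes
were chosen so the full suite runs on one CPU core in tens of minutes while
every comparison retains a comfortable margin. All stochastic steps take
explicit seeds, evaluate under a local RNG, and fan out to per-stage child
seeds through a documented counter scheme (`childSeed`); identical
(configuration, seed) pairs give bit-identical mosaics, trajectories,
movies, spikes and reconstructions.

## Known limitations

* The 1/F prior is weak compared with learned denoisers; absolute
  reconstruction quality on the synthetic retina is far below what a strong
  natural-image prior would give, and the package makes no claims about
  MS-SSIM values on recorded data.
* The particle filter states are integer-pixel displacements; sub-pixel
  drift is invisible to it by construction.
* The EM performs one forward pass; no smoothing (backward) pass over
  trajectories is implemented.
* Refitting encoding models per spike-time-perturbation level (as the
  full-scale procedure prescribes) is supported through the ordinary fitting
  interface, but the bundled perturbation analysis decodes with the
  unperturbed-data model: at desk scale refitting only strengthens the
  degradation trend under study.
* Containers are plain-text directories (full-precision text arrays + JSON
  manifest); there is no binary container format.
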