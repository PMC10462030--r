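# retinodecode

Bayesian decoding of natural images from retinal ganglion cell (RGC) spike
trains, with and without fixational drift eye movements — an R implementation
of the full analysis stack, exercisable end to end on a built-in synthetic
retina.

## The scientific problem

The primate retina encodes a visual scene in the spikes of populations of
RGCs while the eye drifts incessantly during fixation. How much of the scene
can be read back out of those spikes — and does the drift help or hurt?
The package addresses this with three components:

1. **Encoding.** Each cell is modeled as a Linear-Nonlinear-Bernoulli
   encoder with recurrent coupling (LNBRC): in 1 ms bins,

   $$g_i[t] = m_i^\top v[t-1] + (s_i * f_i)[t-1]
     + \textstyle\sum_{j \in N_i}(s_j * c_{ij})[t-1] + b_i,
     \qquad P(s_i[t]{=}1) = \sigma(g_i[t]),$$

   with a rank-1 space–time stimulus filter $m_i$, spike-history filter
   $f_i$, coupling filters $c_{ij}$ from nearby cells, and bias $b_i$. The
   negative log-likelihood is jointly convex; models are fitted per cell by
   alternating FISTA with an L1 penalty on the spatial filter and a group
   L2,1 penalty that prunes unnecessary coupling. Uncoupled (LNBR) and
   Poisson (LNP) reference models are included.

2. **Decoding.** Images are reconstructed as approximate MAP estimates,
   $\hat y = \arg\max_y \log p(s \mid y) + \lambda \log p(y)$, by
   half-quadratic splitting: a convex encoding step alternates with a
   Gaussian-denoiser prior step at noise variance $\lambda/\rho(k)$ over an
   increasing $\rho$ schedule. A 1/F spectral Gaussian prior with an exact
   closed-form denoiser ships with the package; any denoiser satisfying the
   documented contract can be plugged in.

3. **Drift inference.** When the eye trajectory is unknown, image and
   trajectory are estimated jointly by MAP-EM: a sequential importance
   resampling particle filter (10 particles) tracks the posterior over
   integer-pixel drift trajectories while the image estimate is updated
   every five stimulus frames from the importance-weighted expected
   likelihood.

A synthetic retina (four-type RGC mosaics, flashed and drift-jittered
stimulus protocols at 120 Hz, Brownian drift with diffusion constant
10 µm²/frame, closed-loop Bernoulli spike simulation) makes every stage
testable without recorded data. Analysis utilities cover PSTHs,
shift-predictor-corrected cross-correlograms, spike-time perturbation,
repeat shuffling, and valid-region MS-SSIM scoring with shift search.

See the methods vignette (`vignettes/retinal-decoding-methods.Rmd`) for the
models, algorithms, parameter defaults and their rationale.

## Worked example

Simulate a small retina, decode one drift trial three ways (known
trajectory, trajectory ignored, trajectory jointly estimated), and score the
reconstructions over the valid region:

```r
library(retinodecode)

types <- data.frame(cell_type = c("ON_parasol", "OFF_parasol",
                                  "ON_midget", "OFF_midget"),
                    spacing = c(110, 110, 60, 60),
                    rf_radius = c(50, 50, 30, 30))
mosaic <- generateMosaic(c(24L, 24L), pixelSize = 8, types, seed = 5)
model  <- makeSyntheticModel(mosaic, seed = 7)

image      <- syntheticImages(4, c(24L, 24L), seed = 30)[[4]]
trajectory <- generateDriftTrajectory(10, 60, pixelSize = 8, seed = 504)
movie      <- makeDriftMovie(image, trajectory, padAllowance = 11)
spikes     <- simulatePopulationResponse(model, movie, seed = 604)

denoiser <- exact1FDenoiser(spectralPrior(c(24L, 24L), 0.1))
schedule <- hqsSchedule()
mask     <- validRegion(mosaic)

known <- reconstructKnownTrajectory(spikes, model, trajectory,
                                    denoiser, schedule)
zero  <- reconstructKnownTrajectory(spikes, model, zeroTrajectory(60, 8),
                                    denoiser, schedule)
joint <- jointReconstruct(spikes, model, denoiser, 60,
                          transition = list(D = 10, pixelSize = 8),
                          schedule = schedule, seed = 704)

spikes
scoreReconstruction(reconImage(known), image, mask, shiftRadius = 5)
scoreReconstruction(reconImage(zero),  image, mask, shiftRadius = 5)
scoreReconstruction(joint$image,       image, mask, shiftRadius = 5)
trajectoryError(joint$trajectory, trajectory)$rms
trajectoryError(matrix(0, 60, 2), trajectory)$rms
```

Output:

```
BinnedSpikes: 30 cells x 500 ms; 1032 spikes ( 68.8 Hz mean rate )
QualityScore: ms-ssim = 0.7418 at shift ( 0 , 0 )
QualityScore: ms-ssim = 0.3039 at shift ( -2 , 2 )
QualityScore: ms-ssim = 0.4434 at shift ( -2 , 0 )
[1] 23.34
[1] 35.48
```

Reading: decoding with the true trajectory recovers the image best
(MS-SSIM 0.74); ignoring the drift smears it badly (0.30); estimating the
trajectory jointly from the spikes alone recovers a large part of the gap
(0.44), and the estimated eye path lands within ~23 µm RMS of the truth,
versus ~35 µm for assuming no movement. Single trials vary; the acceptance
suite verifies this drift-compensation ordering in the mean over 20 trials.

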