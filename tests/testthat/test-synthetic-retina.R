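# Mosaic generation, drift simulation, stimulus protocols, spike simulation.

test_that("mosaic generation: degenerate lattice, determinism, spacing", {
  # a field that supports exactly one cell of a type places it centrally
  one <- generateMosaic(c(10L, 10L), 8,
                        data.frame(cell_type = "ON_midget", spacing = 100,
                                   rf_radius = 30),
                        seed = 1)
  expect_equal(nCells(one), 1)
  expect_equal(unname(unlist(mosaicCells(one)[, c("x", "y")])), c(40, 40))

  # zero jitter: identical centers for any seed
  a <- generateMosaic(c(24L, 24L), 8, smallTypes(), jitterFraction = 0, seed = 1)
  b <- generateMosaic(c(24L, 24L), 8, smallTypes(), jitterFraction = 0, seed = 99)
  expect_identical(mosaicCells(a), mosaicCells(b))

  # same seed, same mosaic; different seed, different jitter
  c1 <- generateMosaic(c(24L, 24L), 8, smallTypes(), seed = 7)
  c2 <- generateMosaic(c(24L, 24L), 8, smallTypes(), seed = 7)
  expect_identical(mosaicCells(c1), mosaicCells(c2))

  # per-type median NN distance ~ lattice spacing (within 10%) at paper-like
  # relative densities (midget twice as dense as parasol)
  big <- generateMosaic(c(64L, 64L), 8, smallTypes(), seed = 3)
  nn <- medianNNDistance(big)
  types <- smallTypes()
  for (k in seq_len(nrow(types))) {
    expect_lt(abs(nn[[types$cell_type[k]]] - types$spacing[k]) / types$spacing[k],
              0.10)
  }

  expect_error(generateMosaic(c(4L, 4L), 8,
                              data.frame(cell_type = "ON_midget",
                                         spacing = 500, rf_radius = 30),
                              seed = 1),
               "too small")
})

test_that("drift trajectories: D = 0, integer steps, convention recovery", {
  z <- generateDriftTrajectory(0, 60, 8, seed = 1)
  expect_true(all(z@steps == 0L))
  expect_equal(positions(z)[1, ], c(0L, 0L), ignore_attr = TRUE)

  tr <- generateDriftTrajectory(10, 60, 8, seed = 2)
  expect_true(all(tr@steps == round(tr@steps)))
  expect_equal(nrow(tr@steps), 59)
  expect_error(generateDriftTrajectory(10, 60, -1, seed = 1), "pixelSize")

  # small-scale MSD recovery (the full 2,000-trajectory version is in the
  # acceptance suite): 300 trajectories already land within ~2%
  trs <- lapply(1:300, function(i) generateDriftTrajectory(10, 60, 8, seed = i))
  est <- estimateDiffusionConstant(trs)
  expect_lt(abs(est$D - 10) / 10, 0.05)

  # per-axis displacement variance grows linearly: chi-square goodness of
  # fit of the per-axis variance at a late frame against D * n
  n <- 30
  disp <- vapply(trs, function(t) positionsUm(t)[n + 1, 1], 0)
  chi <- sum(disp^2) / (10 * n)
  expect_gt(chi, qchisq(0.005, length(trs)))
  expect_lt(chi, qchisq(0.995, length(trs)))
})

test_that("flashed stimulus protocol: 12 image frames + 48 gray, trial table", {
  imgs <- syntheticImages(3, c(16L, 16L), seed = 2)
  mv <- makeFlashedStimulus(imgs, 8)
  expect_equal(nFrames(mv), 180)
  expect_equal(movieDurationMs(mv), 1500)
  # first 12 frames show image 1, next 48 are uniform 0.5 gray
  for (f in 1:12) expect_equal(mv@frames[, , f], imgs[[1]])
  expect_true(all(mv@frames[, , 13:60] == 0.5))
  # trial table: disjoint contiguous bin ranges
  tri <- mv@trials
  expect_equal(nrow(tri), 3)
  expect_equal(tri$bin_start[-1], tri$bin_end[-3] + 1L)
  expect_error(makeFlashedStimulus(list()), "at least one")
})

test_that("drift movie: shift oracle, gray fill, padding contract", {
  img <- syntheticImages(1, c(16L, 16L), seed = 4)[[1]]
  zt <- zeroTrajectory(10, 8)
  mv <- makeDriftMovie(img, zt)
  for (f in 1:10) expect_equal(mv@frames[, , f], img)

  # constant step (1, 0): frame k equals the image shifted k-1 px down
  steps <- matrix(c(1L, 0L), 9, 2, byrow = TRUE)
  tr <- new("DriftTrajectory", steps = steps, stepsUm = steps * 8,
            nFrames = 10L, diffusionConstant = 0, pixelSize = 8)
  mv2 <- makeDriftMovie(img, tr, padAllowance = 9)
  for (f in 1:10) {
    sh <- mv2@frames[, , f]
    expect_equal(sh[f:16, ], img[1:(17 - f), ]) # interior matches exactly
    if (f > 1) expect_true(all(sh[1:(f - 1), ] == 0.5)) # exposed rows gray
  }
  expect_error(makeDriftMovie(img, tr, padAllowance = 3), "padding allowance")
})

test_that("population simulation: silence, chance rate, refractoriness, determinism", {
  mod <- tinyModel()
  mv <- grayMovie(c(16L, 16L), 24)
  Tn <- movieDurationMs(mv)

  silent <- mod
  for (id in names(silent@cells)) {
    silent@cells[[id]]$bias <- -20
    silent@cells[[id]]$spatial$coef[] <- 0
    silent@cells[[id]]$feedback[] <- 0
    silent@cells[[id]]$coupling <- lapply(silent@cells[[id]]$coupling,
                                          function(x) 0 * x)
  }
  s0 <- simulatePopulationResponse(silent, mv, seed = 1)
  expect_equal(sum(spikeMatrix(s0)), 0) # sigmoid(-20) ~ 2e-9

  # zero generator signal: per-bin spike probability 1/2
  half <- silent
  for (id in names(half@cells)) half@cells[[id]]$bias <- 0
  s5 <- simulatePopulationResponse(half, mv, seed = 2)
  p <- mean(spikeMatrix(s5))
  n <- length(spikeMatrix(s5))
  expect_lt(abs(p - 0.5), 2.6 * sqrt(0.25 / n)) # binomial 99% CI

  # strong 1-tap negative feedback forbids consecutive spikes
  refr <- half
  for (id in names(refr@cells)) {
    refr@cells[[id]]$feedback <- c(-30, 0, 0, 0, 0) * 0
  }
  # build an explicit 1-tap refractory kernel through the basis peak
  for (id in names(refr@cells)) refr@cells[[id]]$feedback <- c(-30, -30, -30, -30, -30)
  s6 <- simulatePopulationResponse(refr, mv, seed = 3)
  for (i in seq_len(nrow(spikeMatrix(s6)))) {
    expect_equal(sum(spikeMatrix(s6)[i, -1] * spikeMatrix(s6)[i, -Tn]), 0)
  }

  expect_error(simulatePopulationResponse(mod, mv), "seed")
  a <- simulatePopulationResponse(mod, tinyDriftData()$movie, seed = 9)
  b <- simulatePopulationResponse(mod, tinyDriftData()$movie, seed = 9)
  expect_identical(spikeMatrix(a), spikeMatrix(b))
})

test_that("frame/bin bookkeeping covers the duration exactly", {
  mv <- tinyDriftData()$movie
  expect_equal(sum(diff(mv@frameEdges)), movieDurationMs(mv))
  expect_true(all(diff(mv@frameEdges) %in% c(8L, 9L)))
  expect_equal(ncol(spikeMatrix(tinyDriftData()$spikes)), movieDurationMs(mv))
})
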