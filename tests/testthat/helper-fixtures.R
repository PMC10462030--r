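# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

smallTypes <- function() {
  data.frame(
    cell_type = c("ON_parasol", "OFF_parasol", "ON_midget", "OFF_midget"),
    spacing = c(120, 120, 75, 75),
    rf_radius = c(50, 50, 30, 30),
    stringsAsFactors = FALSE
  )
}

smallMosaic <- function() {
  fixture("smallMosaic", function() {
    generateMosaic(c(24L, 24L), 8, smallTypes(), seed = 5)
  })
}

smallModel <- function() {
  fixture("smallModel", function() makeSyntheticModel(smallMosaic(), seed = 7))
}

# a 2-cell midget-only setup for hand-computable generator-signal cases
tinyMosaic <- function() {
  fixture("tinyMosaic", function() {
    generateMosaic(c(16L, 16L), 8,
                   data.frame(cell_type = c("ON_midget", "OFF_midget"),
                              spacing = c(70, 70), rf_radius = c(30, 30)),
                   seed = 3)
  })
}

tinyModel <- function() {
  fixture("tinyModel", function() makeSyntheticModel(tinyMosaic(), seed = 4))
}

# short drift recording from the tiny model (2 trials x 500 ms)
tinyDriftData <- function() {
  fixture("tinyDriftData", function() {
    imgs <- syntheticImages(2, c(16L, 16L), seed = 5)
    simulateDriftRecording(tinyModel(), imgs, 10, seed = 6)
  })
}

# moderate drift recording from the small model (8 trials x 500 ms)
smallDriftData <- function() {
  fixture("smallDriftData", function() {
    imgs <- syntheticImages(8, c(24L, 24L), seed = 15)
    simulateDriftRecording(smallModel(), imgs, 10, seed = 16)
  })
}

# gray movie helper (constant 0.5 frames)
grayMovie <- function(shape, nFrames) {
  img <- matrix(0.5, shape[1], shape[2])
  makeDriftMovie(img, zeroTrajectory(nFrames, 8))
}

relL2 <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2) / max(sum(as.numeric(b)^2), 1e-300))
}
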