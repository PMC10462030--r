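## Synthetic receptive-field mosaics.

#' Default per-type mosaic geometry
#'
#' Densities are expressed through the triangular-lattice spacing in
#' micrometers. Midget cells are roughly twice as dense (linearly) as parasol
#' cells in the peripheral primate retina, and midget spacing is about twice
#' the midget receptive-field radius.
#'
#' @return data.frame with columns cell_type, spacing (um), rf_radius (um)
#' @export
mosaicDefaults <- function() {
  data.frame(
    cell_type = CELL_TYPES,
    spacing = c(120, 120, 60, 60),
    rf_radius = c(55, 55, 30, 30),
    stringsAsFactors = FALSE
  )
}

## triangular lattice points covering [0,w] x [0,h] um, spacing a
hexLattice <- function(h, w, a) {
  dy <- a * sqrt(3) / 2
  rows <- seq(dy / 2, h, by = dy)
  pts <- lapply(seq_along(rows), function(i) {
    offset <- if (i %% 2 == 0) a / 2 else 0
    xs <- seq(a / 2 + offset, w, by = a)
    if (!length(xs)) return(NULL)
    cbind(x = xs, y = rows[i])
  })
  do.call(rbind, pts)
}

#' Generate a synthetic multi-type RGC mosaic
#'
#' Cells of each requested type are placed on a jittered triangular lattice,
#' the standard surrogate for the approximately hexagonal packing of RGC
#' receptive fields of a single type. Deterministic given \code{seed}.
#'
#' @param fieldShape integer (height, width) of the stimulus field, pixels
#' @param pixelSize micrometers per pixel
#' @param types data.frame with columns cell_type, spacing (um), rf_radius
#'   (um); defaults to \code{mosaicDefaults()}. Density per unit area is
#'   \code{2/(sqrt(3) spacing^2)}.
#' @param jitterFraction uniform jitter radius as a fraction of the lattice
#'   spacing, in [0, 0.5); the 0.1 default reproduces the high spatial
#'   regularity of real RGC mosaics
#' @param seed integer seed
#' @return a \linkS4class{Mosaic}
#' @examples
#' m <- generateMosaic(c(32L, 32L), 8, seed = 1)
#' nCells(m)
#' @export
generateMosaic <- function(fieldShape, pixelSize, types = mosaicDefaults(),
                           jitterFraction = 0.1, seed = 1) {
  stopifnot(length(fieldShape) == 2, pixelSize > 0)
  if (jitterFraction < 0 || jitterFraction >= 0.5) {
    stop("jitterFraction must lie in [0, 0.5)")
  }
  if (any(types$spacing <= 0)) stop("spacings (densities) must be positive")
  hUm <- fieldShape[1] * pixelSize
  wUm <- fieldShape[2] * pixelSize
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(types)), function(k) {
      ty <- types$cell_type[k]
      a <- types$spacing[k]
      r <- types$rf_radius[k]
      if (a >= max(hUm, wUm)) {
        ## degenerate lattice: field supports a single cell, placed centrally
        if (a > 2 * max(hUm, wUm)) {
          stop("field too small for one cell of type ", ty)
        }
        pts <- cbind(x = wUm / 2, y = hUm / 2)
      } else {
        pts <- hexLattice(hUm, wUm, a)
        if (is.null(pts) || nrow(pts) == 0) {
          stop("field too small for one cell of type ", ty)
        }
        if (jitterFraction > 0) {
          ang <- runif(nrow(pts), 0, 2 * pi)
          rad <- jitterFraction * a * sqrt(runif(nrow(pts)))
          pts[, "x"] <- pts[, "x"] + rad * cos(ang)
          pts[, "y"] <- pts[, "y"] + rad * sin(ang)
        }
        keep <- pts[, "x"] > 0 & pts[, "x"] < wUm & pts[, "y"] > 0 & pts[, "y"] < hUm
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts) == 0) stop("field too small for one cell of type ", ty)
      }
      data.frame(cell_type = ty, x = pts[, "x"], y = pts[, "y"],
                 rf_radius = r, stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, rows)
    cells$cell_id <- seq_len(nrow(cells))
    cells$polarity <- typePolarity(cells$cell_type)
    cells <- cells[, c("cell_id", "cell_type", "x", "y", "rf_radius", "polarity")]
    rownames(cells) <- NULL
    new("Mosaic", cells = cells, pixelSize = pixelSize,
        fieldShape = as.integer(fieldShape))
  })
}

#' Median nearest-neighbor distance per cell type
#'
#' @param mosaic a Mosaic
#' @return named numeric vector (um), one entry per type present
#' @export
medianNNDistance <- function(mosaic) {
  cl <- mosaicCells(mosaic)
  out <- c()
  for (ty in unique(cl$cell_type)) {
    sub <- cl[cl$cell_type == ty, ]
    if (nrow(sub) < 2) {
      out[ty] <- NA_real_
      next
    }
    d <- as.matrix(dist(sub[, c("x", "y")]))
    diag(d) <- Inf
    out[ty] <- median(apply(d, 1, min))
  }
  out
}
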