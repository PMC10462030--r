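## Internal numeric and RNG helpers.

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic operations in the package take an explicit integer seed and
#' evaluate under a local RNG so that global RNG state is never disturbed and
#' identical (config, seed) pairs give bit-identical output.
#'
#' @param seed integer scalar
#' @param expr expression to evaluate
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is required for reproducibility")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a top-level seed
#'
#' Deterministic counter scheme used to fan one experiment seed out to
#' per-stage and per-trial seeds. Result is always in [1, 2^31 - 2].
#'
#' @param seed integer top-level seed
#' @param index nonnegative integer counter
#' @return integer child seed
#' @export
childSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  x <- (s * 48271 + 11 + 104729 * as.double(index)) %% 2147483646
  as.integer(x + 1)
}

## log(1 + exp(x)) without overflow
softplus <- function(x) {
  out <- numeric(length(x))
  hi <- x > 30
  lo <- !hi
  out[hi] <- x[hi]
  out[lo] <- log1p(exp(x[lo]))
  out
}

## round half away from zero (base round() rounds half to even)
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Translate an image by integer (dy, dx); exposed pixels take `fill`.
## Positive dy moves content down (toward larger row index), dx rightwards.
shiftImage <- function(img, dy, dx, fill = 0.5) {
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  if (dy <= -h || dy >= h || dx <= -w || dx >= w) return(out)
  out[rs, cs] <- img[rs - dy, cs - dx, drop = FALSE]
  out
}

## Strictly causal FIR filtering: y[t] = sum_{tau=1..L} k[tau] * x[t - tau].
## The kernel's first tap applies at lag 1, enforcing strict causality.
causalFilter <- function(x, kernel) {
  Tn <- length(x)
  L <- length(kernel)
  n <- stats::nextn(Tn + L, 2)
  xf <- stats::fft(c(x, numeric(n - Tn)))
  kf <- stats::fft(c(0, kernel, numeric(n - L - 1)))
  y <- Re(stats::fft(xf * kf, inverse = TRUE)) / n
  y[seq_len(Tn)]
}

## Batched strictly causal filtering: row i of X is filtered with kernels[[i]].
## Rows sharing an identical kernel are transformed in one mvfft call.
batchCausalFilter <- function(X, kernels) {
  n <- nrow(X)
  Tn <- ncol(X)
  L <- max(vapply(kernels, length, 1L))
  m <- stats::nextn(Tn + L, 2)
  keys <- vapply(kernels, function(k) paste(k, collapse = ","), "")
  out <- matrix(0, n, Tn)
  for (key in unique(keys)) {
    rows <- which(keys == key)
    k <- kernels[[rows[1]]]
    kf <- stats::fft(c(0, k, numeric(m - length(k) - 1)))
    Z <- stats::mvfft(rbind(t(X[rows, , drop = FALSE]),
                            matrix(0, m - Tn, length(rows))))
    Y <- Re(stats::mvfft(Z * kf, inverse = TRUE)) / m
    out[rows, ] <- t(Y[seq_len(Tn), , drop = FALSE])
  }
  out
}

## 1-based frame bin boundaries: frame f covers bins frameBins[f] .. frameBins[f+1]-1
frameBinEdges <- function(nFrames, frameRate = 120, msPerBin = 1) {
  round((0:nFrames) * 1000 / (frameRate * msPerBin)) + 1L
}

## Expand per-frame values (vector or matrix with frames in columns) to the
## 1 ms grid using the frame->bin map.
expandFramesToMs <- function(x, edges) {
  counts <- diff(edges)
  if (is.matrix(x)) {
    x[, rep(seq_len(ncol(x)), counts), drop = FALSE]
  } else {
    rep(x, counts)
  }
}

## cosine similarity between two vectors
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
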