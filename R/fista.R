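## FISTA (accelerated proximal gradient) with backtracking, and the proximal
## operators used by the encoding-model fits.

#' Soft-thresholding (L1 proximal operator)
#' @param v numeric vector
#' @param thr threshold (step size x penalty weight)
#' @return shrunken vector
#' @export
proxL1 <- function(v, thr) {
  sign(v) * pmax(abs(v) - thr, 0)
}

#' Group soft-thresholding (L2,1 proximal operator)
#'
#' Shrinks each group toward zero by its Euclidean norm; groups whose norm is
#' below the threshold are set exactly to zero (the mechanism that eliminates
#' unnecessary cell-to-cell coupling).
#'
#' @param v numeric vector
#' @param groups list of index vectors
#' @param thr threshold (step size x penalty weight)
#' @return shrunken vector
#' @export
proxGroupL21 <- function(v, groups, thr) {
  for (g in groups) {
    nrm <- sqrt(sum(v[g]^2))
    v[g] <- if (nrm <= thr) 0 else v[g] * (1 - thr / nrm)
  }
  v
}

## Generic FISTA with backtracking line search and restart-on-increase.
## f(x): smooth loss; grad(x): its gradient; prox(v, step): proximal map of
## the (possibly zero) nonsmooth penalty; pen(x): penalty value.
## Returns list(x, obj, iterations, converged).
fistaSolve <- function(x0, f, grad, prox, pen, L0 = 1, maxIter = 1000,
                       tol = 1e-6, refine = 25) {
  x <- x0
  y <- x0
  tk <- 1
  L <- L0
  fx <- f(x)
  obj <- fx + pen(x)
  best <- list(x = x, obj = obj)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    fy <- f(y)
    gy <- grad(y)
    repeat {
      xn <- prox(y - gy / L, 1 / L)
      d <- xn - y
      fxn <- f(xn)
      if (fxn <= fy + sum(gy * d) + L / 2 * sum(d^2) + 1e-12 * abs(fy)) break
      L <- L * 2
      if (L > 1e16) break
    }
    objn <- fxn + pen(xn)
    if (objn > obj) {
      ## restart momentum from the current best point
      y <- best$x
      tk <- 1
      x <- best$x
      obj <- best$obj
      next
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- xn + (tk - 1) / tn * (xn - x)
    relChange <- abs(obj - objn) / max(1, abs(obj))
    x <- xn
    obj <- objn
    if (obj < best$obj) best <- list(x = x, obj = obj)
    tk <- tn
    L <- max(L / 2, L0)
    if (relChange < tol) {
      converged <- TRUE
      break
    }
  }
  ## momentum-free proximal-gradient refinement: monotone, and settles
  ## penalized coordinates/groups onto their exact zeros near the optimum
  x <- best$x
  obj <- best$obj
  for (it2 in seq_len(refine)) {
    gx <- grad(x)
    repeat {
      xn <- prox(x - gx / L, 1 / L)
      objn <- f(xn) + pen(xn)
      if (objn <= obj + 1e-12 * abs(obj)) break
      L <- L * 2
      if (L > 1e16) {
        xn <- x
        objn <- obj
        break
      }
    }
    if (max(abs(xn - x)) == 0) break
    x <- xn
    obj <- objn
    L <- max(L / 2, L0)
  }
  if (obj < best$obj) best <- list(x = x, obj = obj)
  list(x = best$x, obj = best$obj, iterations = it, converged = converged)
}
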