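# DIRECT (DIviding RECTangles) global optimizer of Jones, Perttunen &
# Stuckman: deterministic, derivative-free minimization over a box by
# sampling rectangle centres and trisecting potentially optimal
# rectangles. Used for the concentrated-likelihood hyperparameter search.

#' DIRECT global minimization over a box
#'
#' Deterministic derivative-free global optimizer. The search box is
#' normalized to the unit hypercube; rectangles are trisected along their
#' longest sides and a rectangle is divided when it is potentially
#' optimal in the Lipschitz sense (lower convex hull of the
#' size/function-value scatter, with the usual epsilon guard against
#' over-refining the incumbent).
#'
#' @param fn objective \code{function(x) -> scalar}; non-finite values are
#'   treated as a large penalty
#' @param lower,upper numeric bounds, equal length
#' @param maxEvals evaluation budget (>= 1)
#' @param epsilon incumbent-improvement guard (Jones' epsilon)
#' @return list with \code{par}, \code{value}, \code{evals}
#' @examples
#' directOptimize(function(x) sum((x - 0.3)^2), c(-1, -1), c(1, 1), 200)
#' @export
directOptimize <- function(fn, lower, upper, maxEvals = 500,
                           epsilon = 1e-4) {
  if (maxEvals < 1) stop("parameter error: maxEvals must be >= 1")
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  span <- upper - lower
  evals <- 0L
  BIG <- 1e300
  evalAt <- function(u) {            # u in unit cube
    evals <<- evals + 1L
    v <- fn(lower + span * u)
    if (!is.finite(v)) BIG else v
  }
  # columns: centres (d x m); sides (d x m); f values; sizes
  centres <- matrix(0.5, nrow = d, ncol = 1L)
  sides <- matrix(1, nrow = d, ncol = 1L)
  fvals <- evalAt(centres[, 1L])
  sizes <- sqrt(sum((sides[, 1L] / 2)^2))
  bestF <- fvals[1L]; bestX <- centres[, 1L]

  while (evals < maxEvals) {
    # potentially optimal rectangles: lower-right convex hull of
    # (size, f) taking the min f within each size class
    szKey <- signif(sizes, 12)
    uniq <- sort(unique(szKey))
    repMin <- vapply(uniq, function(s) min(fvals[szKey == s]), numeric(1L))
    hull <- integer(0)
    i <- length(uniq)
    # start from the largest size, walk the lower hull towards small sizes
    idx <- seq_along(uniq)
    # build lower convex hull over points (uniq, repMin) from small to large
    h <- integer(0)
    for (j in idx) {
      while (length(h) >= 2L) {
        a <- h[length(h) - 1L]; b <- h[length(h)]
        # drop b if it lies above segment a--j
        if ((repMin[b] - repMin[a]) * (uniq[j] - uniq[a]) >=
            (repMin[j] - repMin[a]) * (uniq[b] - uniq[a]))
          h <- h[-length(h)] else break
      }
      h <- c(h, j)
    }
    # keep the non-increasing-in-f part... the hull from the global min
    # size class with min f onward to the largest size
    fh <- repMin[h]
    keep <- h[seq(which.min(fh), length(h))]
    # epsilon guard: must promise sufficient improvement over incumbent
    sel <- integer(0)
    for (j in keep) {
      # slope to the next hull point bounds the Lipschitz constant
      pos <- match(j, keep)
      Kslope <- if (pos < length(keep)) {
        jn <- keep[pos + 1L]
        (repMin[jn] - repMin[j]) / (uniq[jn] - uniq[j])
      } else Inf
      promise <- repMin[j] - Kslope * uniq[j]
      if (is.infinite(Kslope) ||
          promise <= bestF - epsilon * abs(bestF) ||
          abs(bestF) < .Machine$double.eps)
        sel <- c(sel, j)
    }
    if (!length(sel)) sel <- keep[length(keep)]
    rects <- unlist(lapply(sel, function(j) {
      cand <- which(szKey == uniq[j] & fvals == repMin[j])
      cand[1L]
    }))

    for (r in rects) {
      if (evals >= maxEvals) break
      side <- sides[, r]
      smax <- max(side)
      dims <- which(side >= smax * (1 - 1e-12))
      delta <- smax / 3
      # sample both offsets along each longest dimension
      wInfo <- lapply(dims, function(k) {
        cp <- centres[, r]; cm <- centres[, r]
        cp[k] <- cp[k] + delta; cm[k] <- cm[k] - delta
        fp <- if (evals < maxEvals) evalAt(cp) else BIG
        fm <- if (evals < maxEvals) evalAt(cm) else BIG
        list(k = k, cp = cp, cm = cm, fp = fp, fm = fm,
             w = min(fp, fm))
      })
      ordDims <- order(vapply(wInfo, `[[`, numeric(1L), "w"))
      curSide <- side
      for (oi in ordDims) {
        info <- wInfo[[oi]]
        k <- info$k
        curSide[k] <- curSide[k] / 3
        newSz <- sqrt(sum((curSide / 2)^2))
        centres <- cbind(centres, info$cp, info$cm)
        sides <- cbind(sides, curSide, curSide)
        fvals <- c(fvals, info$fp, info$fm)
        sizes <- c(sizes, newSz, newSz)
      }
      sides[, r] <- curSide
      sizes[r] <- sqrt(sum((curSide / 2)^2))
    }
    ib <- which.min(fvals)
    if (fvals[ib] < bestF) { bestF <- fvals[ib]; bestX <- centres[, ib] }
    if (all(sizes < 1e-13)) break
  }
  list(par = as.numeric(lower + span * bestX), value = bestF,
       evals = evals)
}
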