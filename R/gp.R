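# Ordinary Kriging with constant trend: product power-exponential
# correlation, concentrated maximum likelihood (beta and sigma2 profiled
# out in closed form), hyperparameter search by DIRECT over log10(theta),
# Cholesky-based training and posterior prediction.

#' Product power-exponential correlation
#'
#' \code{R(x, x') = prod_j exp(-theta_j |x_j - x'_j|^p_j)}. With
#' \code{p_j = 2} (the default throughout the package) the modelled
#' function is smooth and infinitely differentiable.
#'
#' @param Xa,Xb numeric matrices with matching column counts (rows are
#'   points)
#' @param theta non-negative correlation rates, one per column
#' @param p correlation exponents, recycled over columns
#' @return matrix of correlations, \code{nrow(Xa)} x \code{nrow(Xb)}
#' @examples
#' gpCorrelation(matrix(0), matrix(1), theta = 1)  # exp(-1)
#' @export
gpCorrelation <- function(Xa, Xb, theta, p = 2) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  q <- ncol(Xa)
  if (ncol(Xb) != q) stop("shape error: feature dimensions disagree")
  if (length(theta) == 1L) theta <- rep(theta, q)
  if (length(theta) != q) stop("parameter error: theta length must match q")
  if (any(theta < 0)) stop("parameter error: theta must be non-negative")
  p <- rep(p, length.out = q)
  acc <- matrix(0, nrow(Xa), nrow(Xb))
  for (j in seq_len(q)) {
    if (theta[j] == 0) next
    acc <- acc + theta[j] * abs(outer(Xa[, j], Xb[, j], "-"))^p[j]
  }
  exp(-acc)
}

# Precompute the per-group distance stacks so the concentrated likelihood
# is cheap to evaluate inside DIRECT: R = exp(-sum_g theta_g G_g) where
# G_g = sum_{j in group g} |x_j - x'_j|^p.
makeNllContext <- function(X, y, p = 2, groups = NULL) {
  X <- as.matrix(X)
  q <- ncol(X); l <- nrow(X)
  if (l < 2L) stop("at least 2 samples required")
  if (is.null(groups)) groups <- seq_len(q)
  stopifnot(length(groups) == q)
  gids <- sort(unique(groups))
  G <- lapply(gids, function(g) {
    acc <- matrix(0, l, l)
    for (j in which(groups == g))
      acc <- acc + abs(outer(X[, j], X[, j], "-"))^p
    acc
  })
  list(G = G, gids = gids, y = y, l = l, q = q, groups = groups, p = p,
       degenerate = isTRUE(all.equal(var(y), 0, tolerance = 1e-300)) ||
         var(y) == 0)
}

cholWithNugget <- function(R, nuggetStart = 1e-10, nuggetMax = 1e-4) {
  nug <- nuggetStart * mean(diag(R))
  repeat {
    U <- tryCatch(chol(R + diag(nug, nrow(R))), error = function(e) NULL)
    if (!is.null(U)) return(list(chol = U, nugget = nug))
    nug <- nug * 10
    if (nug > nuggetMax)
      stop(sprintf(
        "conditioning error: Cholesky failed up to nugget %.3g", nug))
  }
}

# concentrated -log likelihood (up to an additive constant) and the
# profiled estimates at a given expanded-by-group theta
nllCore <- function(thetaGroup, ctx, nuggetStart = 1e-10) {
  A <- matrix(0, ctx$l, ctx$l)
  for (g in seq_along(ctx$G))
    A <- A + thetaGroup[g] * ctx$G[[g]]
  R <- exp(-A)
  cn <- cholWithNugget(R, nuggetStart)
  U <- cn$chol
  y <- ctx$y; l <- ctx$l
  one <- rep(1, l)
  Uy <- backsolve(U, y, transpose = TRUE)
  U1 <- backsolve(U, one, transpose = TRUE)
  beta <- sum(U1 * Uy) / sum(U1 * U1)
  res <- Uy - beta * U1
  sigma2 <- sum(res^2) / l
  logdet <- 2 * sum(log(diag(U)))
  nll <- if (sigma2 <= 0) -.Machine$double.xmax
         else 0.5 * l * log(sigma2) + 0.5 * logdet
  list(nll = nll, beta = beta, sigma2 = sigma2, chol = U,
       nugget = cn$nugget)
}

#' Concentrated negative log-likelihood of the Kriging model
#'
#' Profiles the trend and process variance out in closed form
#' (\code{beta = (1'R^-1 1)^-1 1'R^-1 y},
#' \code{sigma2 = (y - 1 beta)' R^-1 (y - 1 beta) / l}) and returns
#' \code{l/2 log sigma2 + 1/2 log det R}, computed through the Cholesky
#' factor (log-det as twice the sum of log diagonal entries). A constant
#' \code{y} makes \code{sigma2 = 0}; the objective then returns its floor
#' and is flagged degenerate.
#'
#' @param theta correlation rates: one per feature, or one per group when
#'   \code{groups} is given
#' @param X training inputs (l x q)
#' @param y training outputs, length l
#' @param p correlation exponent (default 2)
#' @param groups optional integer group label per feature; \code{theta}
#'   then has one entry per distinct group
#' @return scalar objective with attributes \code{beta}, \code{sigma2},
#'   \code{nugget} and \code{degenerate}
#' @export
concentratedNLL <- function(theta, X, y, p = 2, groups = NULL) {
  X <- as.matrix(X)
  if (is.null(groups)) {
    if (length(theta) == 1L) groups <- rep(1L, ncol(X))
    else groups <- seq_len(ncol(X))
  }
  ctx <- makeNllContext(X, y, p, groups)
  if (ctx$degenerate) {
    out <- -.Machine$double.xmax
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- nllCore(theta, ctx)
  out <- r$nll
  attr(out, "beta") <- r$beta
  attr(out, "sigma2") <- r$sigma2
  attr(out, "nugget") <- r$nugget
  attr(out, "degenerate") <- FALSE
  out
}

featureGroups <- function(q) {
  # feature layout [d_1..d_J, yn_1..yn_J, y_self] -> three tied groups
  if (q %% 2L != 1L || q < 3L)
    stop("grouped mode needs q = 2J+1 features; supply groups explicitly")
  J <- (q - 1L) %/% 2L
  c(rep(1L, J), rep(2L, J), 3L)
}

#' Fit a Gaussian-process surrogate by concentrated maximum likelihood
#'
#' Minimizes the concentrated negative log-likelihood over
#' \code{log10(theta)} with the DIRECT global optimizer, then caches the
#' Cholesky factor of the optimal correlation matrix and the solve vector
#' \code{alpha = R^-1 (y - 1 beta)} so posterior means are vector-vector
#' products.
#'
#' Three parameterizations are available: \code{"grouped"} (default for
#' q = 2J+1 neighbourhood features: one theta for the distance block, one
#' for the neighbour-solution block, one for the own-solution feature),
#' \code{"anisotropic"} (one theta per feature) and \code{"isotropic"}
#' (a single shared theta).
#'
#' @param train a \code{\linkS4class{TrainingSet}}, or a list/matrix pair
#'   via \code{X}/\code{y}
#' @param nuggetStart initial diagonal jitter (escalated tenfold on
#'   Cholesky failure up to 1e-4)
#' @param mode \code{"grouped"}, \code{"anisotropic"} or
#'   \code{"isotropic"}
#' @param bounds 2-row matrix of log10-theta bounds per fitted dimension
#'   (default -6..4 for every dimension)
#' @param budget DIRECT objective-evaluation budget
#' @param groups optional explicit feature-group labels (implies
#'   \code{mode = "grouped"})
#' @param p correlation exponent
#' @return list with elements \code{model}
#'   (\code{\linkS4class{GPSurrogate}}) and \code{mle}
#'   (\code{\linkS4class{MLEResult}})
#' @examples
#' set.seed(1)
#' X <- matrix(runif(40), 20, 2)
#' y <- sin(4 * X[, 1]) + X[, 2]
#' fit <- gpFit(list(X = X, y = y), mode = "anisotropic", budget = 120)
#' gpPredict(fit$model, X)$mean - y  # interpolation residuals ~ 0
#' @export
gpFit <- function(train, mode = c("grouped", "anisotropic", "isotropic"),
                  bounds = NULL, budget = 2000, groups = NULL, p = 2,
                  nuggetStart = 1e-10) {
  mode <- match.arg(mode)
  if (is(train, "TrainingSet")) {
    X <- train@X; y <- train@y
  } else {
    X <- as.matrix(train$X); y <- train$y
  }
  if (budget < 1) stop("parameter error: budget must be >= 1")
  q <- ncol(X); l <- nrow(X)
  if (is.null(groups)) {
    groups <- switch(mode,
      grouped = featureGroups(q),
      anisotropic = seq_len(q),
      isotropic = rep(1L, q))
  }
  nG <- length(unique(groups))
  if (is.null(bounds)) bounds <- rbind(rep(-6, nG), rep(4, nG))
  stopifnot(nrow(bounds) == 2L, ncol(bounds) == nG)
  if (var(y) == 0) {
    model <- new("GPSurrogate", theta = rep(0, q), p = rep(p, q),
                 beta = y[1L], sigma2 = 0, chol = NULL,
                 alpha = numeric(l), XTrain = X, yTrain = y,
                 nugget = 0, degenerate = TRUE)
    mle <- new("MLEResult", thetaHat = rep(0, nG), betaHat = y[1L],
               sigma2Hat = 0, nll = -Inf, evals = 0L, bounds = bounds,
               mode = mode)
    return(list(model = model, mle = mle))
  }
  ctx <- makeNllContext(X, y, p, groups)
  obj <- function(logTheta) nllCore(10^logTheta, ctx, nuggetStart)$nll
  opt <- directOptimize(obj, bounds[1L, ], bounds[2L, ],
                        maxEvals = budget)
  if (!is.finite(opt$value) || opt$value >= 1e300)
    stop("fit error: objective was non-finite over the whole search box")
  thetaG <- 10^opt$par
  final <- nllCore(thetaG, ctx, nuggetStart)
  thetaFull <- thetaG[match(groups, sort(unique(groups)))]
  U <- final$chol
  one <- rep(1, l)
  resid <- y - final$beta
  alpha <- backsolve(U, backsolve(U, resid, transpose = TRUE))
  model <- new("GPSurrogate", theta = thetaFull, p = rep(p, q),
               beta = final$beta, sigma2 = final$sigma2, chol = U,
               alpha = as.numeric(alpha), XTrain = X, yTrain = y,
               nugget = final$nugget, degenerate = FALSE)
  mle <- new("MLEResult", thetaHat = thetaG, betaHat = final$beta,
             sigma2Hat = final$sigma2, nll = final$nll,
             evals = as.integer(opt$evals), bounds = bounds, mode = mode)
  list(model = model, mle = mle)
}

#' Posterior mean and variance of a fitted surrogate
#'
#' Posterior mean \code{beta + r' R^-1 (y - 1 beta)} and variance
#' \code{sigma2 (1 - r' R^-1 r + (1 - 1' R^-1 r)^2 / (1' R^-1 1))}
#' (the last term is the trend-estimation uncertainty), vectorized over
#' the rows of \code{Xnew}. Tiny negative variances from round-off are
#' clipped at zero (tolerance 1e-12 sigma2).
#'
#' @param model a \code{\linkS4class{GPSurrogate}}
#' @param Xnew numeric matrix of prediction points (rows)
#' @return list with numeric vectors \code{mean} and \code{variance}
#' @export
gpPredict <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  q <- ncol(model@XTrain)
  if (ncol(Xnew) != q)
    stop("shape error: prediction features must match training features")
  nNew <- nrow(Xnew)
  if (model@degenerate)
    return(list(mean = rep(model@beta, nNew),
                variance = rep(0, nNew)))
  r <- gpCorrelation(Xnew, model@XTrain, model@theta, model@p)  # nNew x l
  mean <- model@beta + as.numeric(r %*% model@alpha)
  U <- model@chol
  l <- length(model@yTrain)
  one <- rep(1, l)
  Ur <- backsolve(U, Matrix::t(r), transpose = TRUE)  # l x nNew
  U1 <- backsolve(U, one, transpose = TRUE)
  rRinvr <- colSums(Ur^2)
  oneRinvr <- as.numeric(crossprod(U1, Ur))
  oneRinv1 <- sum(U1^2)
  varr <- model@sigma2 * (1 - rRinvr + (1 - oneRinvr)^2 / oneRinv1)
  varr[varr < 0 & varr > -1e-12 * max(model@sigma2, 1)] <- 0
  list(mean = mean, variance = varr)
}

#' @describeIn gpPredict S4 method so \code{predict(model, Xnew)} works
#' @param object a \code{GPSurrogate}
#' @export
setMethod("predict", "GPSurrogate", function(object, Xnew, ...) {
  gpPredict(object, Xnew)
})

setMethod("show", "GPSurrogate", function(object) {
  cat(sprintf(
    "GPSurrogate: l = %d training points, q = %d features%s\n",
    nrow(object@XTrain), ncol(object@XTrain),
    if (object@degenerate) " (degenerate constant model)" else ""))
  cat(sprintf("  beta = %.6g, sigma2 = %.6g, nugget = %.3g\n",
              object@beta, object@sigma2, object@nugget))
  th <- sort(unique(signif(object@theta, 6)))
  cat("  theta (distinct): ", paste(format(th, digits = 4),
                                    collapse = ", "), "\n")
})

setMethod("show", "MLEResult", function(object) {
  cat(sprintf("MLEResult (%s): nll = %.6g after %d evaluations\n",
              object@mode, object@nll, object@evals))
  cat("  thetaHat:", paste(format(object@thetaHat, digits = 4),
                           collapse = ", "), "\n")
  cat(sprintf("  betaHat = %.6g, sigma2Hat = %.6g\n",
              object@betaHat, object@sigma2Hat))
})
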