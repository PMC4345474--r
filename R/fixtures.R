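# Synthetic inputs with known structure: draws from a known Gaussian
# process, analytic diffusion/binding profiles, and miniature mesh
# hierarchies, so every module is testable without external data.

#' Specify a synthetic Gaussian-process draw
#'
#' @param q feature dimension
#' @param l sample count
#' @param thetaTrue true correlation rates (length q)
#' @param betaTrue true constant trend
#' @param sigma2True true process variance
#' @param noiseVar i.i.d. observation-noise variance
#' @param seed RNG seed
#' @return a \code{\linkS4class{SyntheticGPSpec}}
#' @export
syntheticGPSpec <- function(q = 2L, l = 80L, thetaTrue = c(5, 0.5),
                            betaTrue = 1, sigma2True = 2, noiseVar = 0,
                            seed = 1L) {
  new("SyntheticGPSpec", q = as.integer(q), l = as.integer(l),
      thetaTrue = thetaTrue, betaTrue = betaTrue,
      sigma2True = sigma2True, noiseVar = noiseVar,
      seed = as.integer(seed))
}

#' Draw (X, y) from a known Gaussian process
#'
#' Inputs are i.i.d. uniform in the unit box; outputs are a draw from the
#' surrogate's own model family (constant trend, product
#' power-exponential correlation with p = 2) at the specified true
#' hyperparameters, plus i.i.d. Gaussian noise. Fully reproducible from
#' the seed.
#'
#' @param spec a \code{\linkS4class{SyntheticGPSpec}}
#' @return list with matrix \code{X} (l x q) and vector \code{y}
#' @examples
#' d <- sampleGP(syntheticGPSpec(l = 10, seed = 7))
#' dim(d$X)
#' @export
sampleGP <- function(spec) {
  stopifnot(is(spec, "SyntheticGPSpec"))
  set.seed(spec@seed)
  X <- matrix(runif(spec@l * spec@q), spec@l, spec@q)
  if (spec@sigma2True == 0) {
    y <- rep(spec@betaTrue, spec@l)
  } else {
    R <- gpCorrelation(X, X, spec@thetaTrue, p = 2)
    Sigma <- spec@sigma2True * R
    U <- tryCatch(chol(Sigma + diag(1e-10 * spec@sigma2True, spec@l)),
                  error = function(e)
                    stop("generation error: implied covariance not PSD"))
    y <- spec@betaTrue + as.numeric(crossprod(U, rnorm(spec@l)))
  }
  if (spec@noiseVar > 0)
    y <- y + rnorm(spec@l, sd = sqrt(spec@noiseVar))
  list(X = X, y = y)
}

#' Closed-form verification profiles
#'
#' Constructs an analytic profile usable as a solver oracle or as a
#' noise-free learning target:
#' \describe{
#'   \item{\code{"annulusLog"}}{steady annular diffusion with constant
#'     mural influx \code{q} and a perivascular sink:
#'     \code{C(r) = q R / Dw * log((R+W)/r)}; parameters \code{R},
#'     \code{W}, \code{Dw}, \code{q}.}
#'   \item{\code{"bindingODE"}}{well-mixed reversible saturable binding
#'     at fixed free concentration \code{C}:
#'     \code{B(t) = Beq (1 - exp(-(ka C + kd) t))} with
#'     \code{Beq = BM C / (Kd + C)}; parameters \code{BM}, \code{Kd},
#'     \code{ka}, \code{C} (evaluator takes \code{t}).}
#'   \item{\code{"halfSpace"}}{1D half-space diffusion from a unit
#'     surface concentration: \code{C(x, t) = erfc(x / (2 sqrt(Dw t)))};
#'     parameters \code{Dw}, \code{t} (evaluator takes depth \code{x}).}
#' }
#'
#' @param kind profile kind
#' @param parameters named list of profile parameters
#' @return list with the \code{kind}, the \code{parameters} and the
#'   closed-form \code{evaluate} function
#' @export
analyticProfile <- function(kind = c("annulusLog", "bindingODE",
                                     "halfSpace"),
                            parameters = list()) {
  kind <- match.arg(kind)
  pr <- parameters
  evaluate <- switch(kind,
    annulusLog = function(xy) {
      r <- if (is.matrix(xy)) sqrt(rowSums(xy^2)) else xy
      if (any(r <= 0)) stop("domain error: profile undefined at r = 0")
      pr$q * pr$R / pr$Dw * log((pr$R + pr$W) / r)
    },
    bindingODE = function(t) {
      kd <- if (is.null(pr$kd)) pr$ka * pr$Kd else pr$kd
      Beq <- pr$BM * pr$C / (pr$Kd + pr$C)
      rate <- pr$ka * pr$C + kd
      Beq * (1 - exp(-rate * t))
    },
    halfSpace = function(x) {
      if (any(x < 0)) stop("domain error: depth must be >= 0")
      erfc <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
      erfc(x / (2 * sqrt(pr$Dw * pr$t)))
    })
  list(kind = kind, parameters = pr, evaluate = evaluate)
}

#' Evaluate an analytic profile on a mesh
#'
#' Evaluates the profile's closed form at the mesh node coordinates and
#' wraps the result as a \code{\linkS4class{ConcentrationField}} (the
#' value is stored in both C and B so either output kind can be used as a
#' noise-free learning target).
#'
#' @param profile result of \code{\link{analyticProfile}}
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @param time nominal field time (s)
#' @return a \code{\linkS4class{ConcentrationField}}
#' @export
analyticField <- function(profile, mesh, time = 0) {
  vals <- switch(profile$kind,
    annulusLog = profile$evaluate(mesh@nodes),
    halfSpace = profile$evaluate(
      sqrt(rowSums(mesh@nodes^2)) - mesh@geometry@R),
    bindingODE = stop("bindingODE is a time profile; evaluate it directly"))
  newConcentrationField(mesh = mesh, C = vals, B = vals, time = time)
}

#' @importFrom stats pnorm
NULL
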