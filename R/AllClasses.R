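#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod
#' @importFrom stats runif rnorm sd var cov dist quantile setNames predict
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Annulus domain geometry
#'
#' Cross-section of an artery modelled as an annulus: lumen radius \code{R}
#' and wall thickness \code{W}, both in metres. The tissue occupies
#' \code{R <= r <= R + W}.
#'
#' @slot R lumen radius (m), strictly positive
#' @slot W wall thickness (m), strictly positive
#' @export
setClass("DomainGeometry",
  representation(R = "numeric", W = "numeric"))

setValidity("DomainGeometry", function(object) {
  if (length(object@R) != 1L || !is.finite(object@R) || object@R <= 0)
    return("lumen radius R must be a single positive number")
  if (length(object@W) != 1L || !is.finite(object@W) || object@W <= 0)
    return("wall thickness W must be a single positive number")
  TRUE
})

#' Triangular mesh with refinement lineage
#'
#' A conforming triangular mesh of the annular wall cross-section. Meshes
#' produced by \code{\link{refineLongestEdge}} keep every parent node (same
#' index, same coordinates) and record their refinement level, so node sets
#' are nested across a refinement hierarchy.
#'
#' @slot nodes numeric matrix, one row per node, columns x and y (metres)
#' @slot elements integer matrix, one row per triangle, counter-clockwise
#'   node indices (1-based)
#' @slot boundaryTag character vector per node: \code{"mural"} (lumen-facing
#'   inner circle), \code{"perivascular"} (outer circle) or
#'   \code{"interior"}
#' @slot level integer refinement level, 0 for a freshly generated mesh
#' @slot parentNodeMap integer vector mapping parent-mesh node index i to
#'   this mesh's node index \code{parentNodeMap[i]}; length 0 at level 0
#' @slot geometry the \code{DomainGeometry} the mesh discretizes
#' @export
setClass("TriMesh",
  representation(nodes = "matrix", elements = "matrix",
                 boundaryTag = "character", level = "integer",
                 parentNodeMap = "integer", geometry = "DomainGeometry"))

setValidity("TriMesh", function(object) {
  n <- nrow(object@nodes)
  if (ncol(object@nodes) != 2L) return("nodes must have two columns (x, y)")
  el <- object@elements
  if (ncol(el) != 3L) return("elements must have three columns")
  if (any(el < 1L) || any(el > n)) return("element node index out of range")
  if (length(object@boundaryTag) != n)
    return("boundaryTag must have one entry per node")
  if (!all(object@boundaryTag %in% c("mural", "perivascular", "interior")))
    return("boundaryTag entries must be mural/perivascular/interior")
  a <- signedAreas(object@nodes, el)
  if (any(a <= 0))
    return(sprintf("element %d is degenerate or clockwise (area %.3e)",
                   which(a <= 0)[1L], min(a)))
  if (object@level > 0L && length(object@parentNodeMap) == 0L)
    return("refined mesh must carry a parentNodeMap")
  if (length(object@parentNodeMap) &&
      anyDuplicated(object@parentNodeMap))
    return("parentNodeMap must be injective")
  TRUE
})

#' Physical parameters of the balloon drug-transport model
#'
#' Diffusion, saturable reversible binding and balloon release-kinetics
#' constants for the free/bound drug model. All values SI; concentrations
#' in mol m^-3 (numerically equal to mmol l^-1). The association and
#' dissociation rates are derived on construction as
#' \code{ka = Dw * Da / (BM * W^2)} and \code{kd = ka * Kd}.
#'
#' @slot Dw free-drug diffusivity in the wall (m^2 s^-1)
#' @slot BM net tissue binding capacity (mol m^-3)
#' @slot Da Damkohler number (dimensionless)
#' @slot Kd equilibrium dissociation constant (mol m^-3)
#' @slot ka association rate (m^3 mol^-1 s^-1), derived
#' @slot kd dissociation rate (s^-1), derived
#' @slot A1 flux-kinetics amplitude (kg m^-3)
#' @slot k1 flux-kinetics rate (s^-1)
#' @slot ZMW drug molecular weight (g mol^-1)
#' @slot t0 balloon inflation time (s)
#' @slot W wall thickness used in the ka derivation (m)
#' @slot coatingThickness balloon coating volume per unit surface area (m),
#'   the geometric factor of the release-flux law
#' @export
setClass("TransportParameters",
  representation(Dw = "numeric", BM = "numeric", Da = "numeric",
                 Kd = "numeric", ka = "numeric", kd = "numeric",
                 A1 = "numeric", k1 = "numeric", ZMW = "numeric",
                 t0 = "numeric", W = "numeric",
                 coatingThickness = "numeric"))

setValidity("TransportParameters", function(object) {
  vals <- c(Dw = object@Dw, BM = object@BM, Da = object@Da, Kd = object@Kd,
            A1 = object@A1, k1 = object@k1, ZMW = object@ZMW,
            t0 = object@t0, W = object@W,
            coatingThickness = object@coatingThickness)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all physical parameters must be finite and strictly positive")
  kaRef <- object@Dw * object@Da / (object@BM * object@W^2)
  if (abs(object@ka - kaRef) > 1e-12 * kaRef)
    return("ka inconsistent with Dw*Da/(BM*W^2)")
  if (abs(object@kd - object@ka * object@Kd) > 1e-12 * object@kd)
    return("kd inconsistent with ka*Kd")
  TRUE
})

#' Time-integration settings for the transport solver
#'
#' @slot rtol relative tolerance of the BDF integrator
#' @slot atol absolute tolerance
#' @slot maxOrder maximum BDF order (1--5)
#' @slot tEnd end time of the simulation (s)
#' @slot nSave number of equally spaced save times used for mass-balance
#'   accounting (the end-time field is always exact)
#' @export
setClass("SolverSettings",
  representation(rtol = "numeric", atol = "numeric", maxOrder = "integer",
                 tEnd = "numeric", nSave = "integer"))

setValidity("SolverSettings", function(object) {
  if (object@rtol <= 0 || object@atol <= 0) return("tolerances must be > 0")
  if (object@tEnd <= 0) return("end time must be > 0")
  if (object@maxOrder < 1L || object@maxOrder > 5L)
    return("maxOrder must be between 1 and 5")
  TRUE
})

#' Free/bound drug concentration field on a mesh
#'
#' Nodal free (\code{C}) and bound (\code{B}) drug concentrations
#' (mol m^-3) at a stated time on a stated mesh, together with the
#' cumulative mural influx and perivascular outflow (mol per unit axial
#' length) accumulated up to that time for mass accounting.
#'
#' @slot mesh the \code{TriMesh} the field lives on
#' @slot C free-drug concentration per node (mol m^-3)
#' @slot B bound-drug concentration per node (mol m^-3)
#' @slot time seconds since the onset of balloon inflation
#' @slot influx cumulative drug influx through the mural boundary (mol m^-1)
#' @slot outflux cumulative outflow through the perivascular sink (mol m^-1)
#' @export
setClass("ConcentrationField",
  representation(mesh = "TriMesh", C = "numeric", B = "numeric",
                 time = "numeric", influx = "numeric", outflux = "numeric"))

setValidity("ConcentrationField", function(object) {
  n <- nrow(object@mesh@nodes)
  if (length(object@C) != n || length(object@B) != n)
    return("C and B must have one value per mesh node")
  TRUE
})

#' Nearest-neighbour feature table
#'
#' Per-node supervised-learning inputs of length q = 2J + 1: the J
#' nearest-neighbour distances sorted ascending, the coarse-level solution
#' at those neighbours (same order), and the coarse-level solution at the
#' node itself.
#'
#' @slot X numeric matrix, one row per node, 2J+1 columns
#' @slot J neighbour count
#' @slot metric distance metric used: cityblock, euclidean or mahalanobis
#' @slot nodeIds node indices (into the source mesh) of the rows
#' @slot sourceLevel refinement level of the mesh the features came from
#' @slot outputKind which field supplied the solution features: free or bound
#' @slot coords node coordinates of the rows (kept for canonical ordering)
#' @export
setClass("NeighborhoodFeatureTable",
  representation(X = "matrix", J = "integer", metric = "character",
                 nodeIds = "integer", sourceLevel = "integer",
                 outputKind = "character", coords = "matrix"))

setValidity("NeighborhoodFeatureTable", function(object) {
  J <- object@J
  if (ncol(object@X) != 2L * J + 1L)
    return("feature matrix must have q = 2J+1 columns")
  if (nrow(object@X) != length(object@nodeIds))
    return("one nodeId per feature row required")
  d <- object@X[, seq_len(J), drop = FALSE]
  if (any(d < 0)) return("neighbour distances must be non-negative")
  if (J > 1L && any(d[, -1L, drop = FALSE] - d[, -J, drop = FALSE] < -1e-15))
    return("neighbour distances must be sorted ascending within each row")
  TRUE
})

#' Supervised-learning training set
#'
#' Feature rows from a level-n mesh paired with the scalar solution at the
#' same (nested) nodes on the level-(n+1) mesh.
#'
#' @slot X feature matrix (l rows, q columns)
#' @slot y fine-level outputs, length l
#' @slot nodeIds coarse-mesh node indices of the rows
#' @slot outputKind free or bound
#' @slot coords coarse-node coordinates (canonical ordering for CV)
#' @export
setClass("TrainingSet",
  representation(X = "matrix", y = "numeric", nodeIds = "integer",
                 outputKind = "character", coords = "matrix"))

setValidity("TrainingSet", function(object) {
  if (nrow(object@X) != length(object@y))
    return("X and y must be aligned")
  TRUE
})

#' Fitted Gaussian-process surrogate
#'
#' Ordinary-Kriging model with constant trend beta, process variance
#' sigma2 and product power-exponential correlation
#' \code{R(x, x') = prod_j exp(-theta_j |x_j - x'_j|^p_j)} with p_j = 2.
#' The upper-triangular Cholesky factor A satisfies
#' \code{A'A = R + nugget I}; \code{alpha = R^-1 (y - 1 beta)} is cached so
#' posterior means are vector--vector products.
#'
#' @slot theta per-feature correlation rates (length q, expanded from the
#'   fitted groups)
#' @slot p correlation exponents (fixed at 2)
#' @slot beta constant trend
#' @slot sigma2 process variance
#' @slot chol upper-triangular Cholesky factor of the nugget-regularized
#'   correlation matrix
#' @slot alpha cached solve of the centred outputs against R
#' @slot XTrain,yTrain retained training data
#' @slot nugget diagonal jitter finally used
#' @slot degenerate TRUE when the training outputs were constant and the
#'   model short-circuits to a constant predictor
#' @export
setClass("GPSurrogate",
  representation(theta = "numeric", p = "numeric", beta = "numeric",
                 sigma2 = "numeric", chol = "matrixOrNULL",
                 alpha = "numeric", XTrain = "matrix", yTrain = "numeric",
                 nugget = "numeric", degenerate = "logical"))

setValidity("GPSurrogate", function(object) {
  if (any(object@theta < 0)) return("theta must be non-negative")
  if (object@sigma2 < 0) return("sigma2 must be non-negative")
  TRUE
})

#' Maximum-likelihood fit summary
#'
#' @slot thetaHat fitted correlation rates (one per fitted group)
#' @slot betaHat generalized-least-squares trend at thetaHat
#' @slot sigma2Hat concentrated process-variance estimate at thetaHat
#' @slot nll final concentrated negative log-likelihood (up to a constant)
#' @slot evals objective evaluations used by DIRECT
#' @slot bounds log10-theta search box
#' @slot mode grouped, anisotropic or isotropic
#' @export
setClass("MLEResult",
  representation(thetaHat = "numeric", betaHat = "numeric",
                 sigma2Hat = "numeric", nll = "numeric", evals = "integer",
                 bounds = "matrix", mode = "character"))

#' Cross-validation configuration
#'
#' k-fold cross-validation repeated over s random shuffles; shuffle i uses
#' seed \code{seed + i}.
#'
#' @slot k fold count (>= 2)
#' @slot s shuffle count (>= 1)
#' @slot seed base random seed
#' @export
setClass("CVConfig",
  representation(k = "integer", s = "integer", seed = "integer"))

setValidity("CVConfig", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (object@s < 1L) return("s must be >= 1")
  TRUE
})

#' Fidelity-experiment report
#'
#' Reference discretization errors (RMSE between refinement levels 0/3 and
#' 1/3) and the cross-validated and deployed surrogate errors per
#' (output kind, metric, J) cell.
#'
#' @slot rmse03 named numeric: RMSE between level-0 and level-3 solutions
#'   over the level-0 node set, one entry per output kind
#' @slot rmse13 named numeric: RMSE between level-1 and level-3 solutions
#'   over the level-1 node set
#' @slot cells data.frame with columns outputKind, metric, J, rmseCvMean,
#'   rmsePredVsTruth
#' @slot raw list of per-shuffle, per-fold raw RMSE values per cell
#' @slot config the resolved experiment configuration
#' @export
setClass("FidelityReport",
  representation(rmse03 = "numeric", rmse13 = "numeric",
                 cells = "data.frame", raw = "list", config = "list"))

setValidity("FidelityReport", function(object) {
  if (any(object@rmse03 < 0) || any(object@rmse13 < 0))
    return("reference RMSEs must be non-negative")
  TRUE
})

#' Synthetic Gaussian-process sampling specification
#'
#' Ground-truth hyperparameters for drawing verification data from the
#' surrogate's own model family.
#'
#' @slot q feature dimension
#' @slot l sample count
#' @slot thetaTrue true correlation rates (length q)
#' @slot betaTrue true trend
#' @slot sigma2True true process variance
#' @slot noiseVar i.i.d. observation-noise variance
#' @slot seed RNG seed
#' @export
setClass("SyntheticGPSpec",
  representation(q = "integer", l = "integer", thetaTrue = "numeric",
                 betaTrue = "numeric", sigma2True = "numeric",
                 noiseVar = "numeric", seed = "integer"))

setValidity("SyntheticGPSpec", function(object) {
  if (object@sigma2True < 0 || object@noiseVar < 0)
    return("variances must be non-negative")
  if (length(object@thetaTrue) != object@q)
    return("thetaTrue must have length q")
  TRUE
})

# internal constructor: the slot name "C" would partially match new()'s
# "Class" formal, so Class must be bound by exact name
newConcentrationField <- function(mesh, C, B, time, influx = 0,
                                  outflux = 0) {
  do.call(methods::new, list(Class = "ConcentrationField", mesh = mesh,
                             C = C, B = B, time = time, influx = influx,
                             outflux = outflux))
}
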