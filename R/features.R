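# Nearest-neighbour feature construction: J neighbour distances plus
# coarse-level solution values at the neighbours and at the node itself,
# q = 2J + 1 features per node.

supportedMetrics <- c("cityblock", "euclidean", "mahalanobis")

pairwiseDistances <- function(coords, metric) {
  metric <- match.arg(metric, supportedMetrics)
  if (metric == "cityblock")
    return(as.matrix(dist(coords, method = "manhattan")))
  if (metric == "euclidean")
    return(as.matrix(dist(coords, method = "euclidean")))
  # mahalanobis: whiten by the sample covariance of the node coordinates
  S <- cov(coords)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("metric error: coordinate covariance is singular")
  white <- coords %*% solve(ch)
  as.matrix(dist(white, method = "euclidean"))
}

#' Nearest neighbours of every mesh node
#'
#' For each node, the J distinct other nodes with the smallest metric
#' distance, sorted ascending (ties broken by node index). The
#' \code{mahalanobis} metric whitens coordinates by the sample covariance
#' of the mesh's node coordinates; \code{cityblock} is the L1 norm in the
#' Cartesian frame of mesh generation.
#'
#' @param mesh a \code{\linkS4class{TriMesh}} (or a numeric coordinate
#'   matrix)
#' @param J neighbour count, < node count
#' @param metric \code{"cityblock"}, \code{"euclidean"} or
#'   \code{"mahalanobis"}
#' @return list with integer matrix \code{index} (n x J) and numeric
#'   matrix \code{distance} (n x J)
#' @examples
#' m <- buildAnnulusMesh(domainGeometry(), 64, seed = 1)
#' nn <- nearestNeighbors(m, J = 3, metric = "euclidean")
#' dim(nn$index)
#' @export
nearestNeighbors <- function(mesh, J, metric = "cityblock") {
  coords <- if (is(mesh, "TriMesh")) mesh@nodes else as.matrix(mesh)
  n <- nrow(coords)
  if (J >= n) stop("parameter error: J must be smaller than the node count")
  if (J < 1) stop("parameter error: J must be >= 1")
  D <- pairwiseDistances(coords, metric)
  diag(D) <- Inf                                 # self-exclusion
  idx <- matrix(0L, n, J); dd <- matrix(0, n, J)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))[seq_len(J)] # ties -> lowest index
    idx[i, ] <- ord
    dd[i, ] <- D[i, ord]
  }
  list(index = idx, distance = dd)
}

#' Build the supervised-learning feature table
#'
#' Row i is \code{[d_i1..d_iJ, y0(neigh 1)..y0(neigh J), y0(node i)]}
#' where \code{y0} is the chosen solution field (free or bound drug) on
#' the source mesh and the neighbour order is ascending distance.
#'
#' @param field a \code{\linkS4class{ConcentrationField}}
#' @param neighbours result of \code{\link{nearestNeighbors}} on the same
#'   mesh (computed when omitted)
#' @param J neighbour count
#' @param metric distance metric (used when \code{neighbours} is omitted,
#'   recorded either way)
#' @param outputKind \code{"free"} (field C) or \code{"bound"} (field B)
#' @param standardize z-score the distance block with the table's own
#'   mean and standard deviation (off by default; distances are then in
#'   raw metres and solution features in mol m^-3)
#' @return a \code{\linkS4class{NeighborhoodFeatureTable}}
#' @export
buildFeatureTable <- function(field, neighbours = NULL, J,
                              metric = "cityblock",
                              outputKind = c("free", "bound"),
                              standardize = FALSE) {
  outputKind <- match.arg(outputKind)
  mesh <- field@mesh
  n <- nrow(mesh@nodes)
  if (length(field@C) != n)
    stop("alignment error: field is not defined on the given mesh")
  if (is.null(neighbours))
    neighbours <- nearestNeighbors(mesh, J, metric)
  if (nrow(neighbours$index) != n || ncol(neighbours$index) != J)
    stop("alignment error: neighbour table does not match mesh and J")
  y0 <- if (outputKind == "free") field@C else field@B
  dblock <- neighbours$distance
  if (standardize) {
    mu <- mean(dblock); sdv <- sd(as.vector(dblock))
    if (sdv > 0) dblock <- (dblock - mu) / sdv + abs(min((dblock - mu) / sdv))
  }
  X <- cbind(dblock,
             matrix(y0[neighbours$index], n, J),
             y0)
  colnames(X) <- c(paste0("d_", seq_len(J)),
                   paste0("yn_", seq_len(J)), "y_self")
  new("NeighborhoodFeatureTable", X = X, J = as.integer(J),
      metric = metric, nodeIds = seq_len(n),
      sourceLevel = mesh@level, outputKind = outputKind,
      coords = mesh@nodes)
}

#' Pair coarse-level features with fine-level outputs
#'
#' Builds the training set: the feature rows of the coarse mesh paired
#' with the solution value at the image of each coarse node on the fine
#' mesh (exact node correspondence through the nesting map; no
#' interpolation).
#'
#' @param coarseFeatures a \code{\linkS4class{NeighborhoodFeatureTable}}
#' @param fineField a \code{\linkS4class{ConcentrationField}} on a
#'   refinement descendant of the feature mesh
#' @param correspondence optional \code{\link{commonNodes}} pairing;
#'   recomputed when omitted (requires the feature table's coords to be a
#'   prefix of the fine mesh's nodes)
#' @return a \code{\linkS4class{TrainingSet}}
#' @export
buildTrainingSet <- function(coarseFeatures, fineField,
                             correspondence = NULL) {
  nC <- nrow(coarseFeatures@X)
  fineN <- nrow(fineField@mesh@nodes)
  if (is.null(correspondence)) {
    if (nC > fineN)
      stop("correspondence error: fine mesh smaller than coarse features")
    d2 <- rowSums((coarseFeatures@coords -
                   fineField@mesh@nodes[seq_len(nC), , drop = FALSE])^2)
    if (any(d2 != 0))
      stop("correspondence error: meshes are not nested")
    correspondence <- cbind(coarse = seq_len(nC), fine = seq_len(nC))
  }
  if (!all(coarseFeatures@nodeIds %in% correspondence[, "coarse"]))
    stop("correspondence error: unmapped coarse node")
  fineIdx <- correspondence[match(coarseFeatures@nodeIds,
                                  correspondence[, "coarse"]), "fine"]
  yFine <- if (coarseFeatures@outputKind == "free") fineField@C
           else fineField@B
  new("TrainingSet", X = coarseFeatures@X, y = yFine[fineIdx],
      nodeIds = coarseFeatures@nodeIds,
      outputKind = coarseFeatures@outputKind,
      coords = coarseFeatures@coords)
}

setMethod("show", "NeighborhoodFeatureTable", function(object) {
  cat(sprintf(
    "NeighborhoodFeatureTable: %d nodes, J = %d (%s metric), q = %d\n",
    nrow(object@X), object@J, object@metric, ncol(object@X)))
  cat(sprintf("  source level %d, output kind %s\n",
              object@sourceLevel, object@outputKind))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: l = %d samples, q = %d features (%s drug)\n",
              nrow(object@X), ncol(object@X), object@outputKind))
})
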