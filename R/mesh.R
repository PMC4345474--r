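# Structured annulus meshing and longest-edge bisection refinement.
# All coordinates in metres; node indices 1-based; elements counter-clockwise.

signedAreas <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  p2 <- nodes[elements[, 2L], , drop = FALSE]
  p3 <- nodes[elements[, 3L], , drop = FALSE]
  0.5 * ((p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
         (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L]))
}

#' Construct an annulus geometry
#'
#' @param R lumen radius in metres (default 3 mm)
#' @param W wall thickness in metres (default 0.5 mm)
#' @return a \code{\linkS4class{DomainGeometry}}
#' @examples
#' geom <- domainGeometry()
#' lumenRadius(geom)
#' @export
domainGeometry <- function(R = 3e-3, W = 5e-4) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0 ||
      !is.numeric(W) || length(W) != 1L || !is.finite(W) || W <= 0)
    stop("invalid geometry: R and W must be single positive numbers")
  new("DomainGeometry", R = R, W = W)
}

#' @rdname domainGeometry
#' @param geometry a \code{DomainGeometry}
#' @export
lumenRadius <- function(geometry) geometry@R

#' @rdname domainGeometry
#' @export
wallThickness <- function(geometry) geometry@W

#' Accessors for TriMesh objects
#'
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @return \code{nodeCoords}: numeric matrix of node coordinates;
#'   \code{meshElements}: integer element-connectivity matrix;
#'   \code{boundaryTags}: per-node tag vector; \code{meshLevel}: integer
#'   refinement level; \code{parentNodeMap}: injection of parent node
#'   indices into this mesh.
#' @name TriMesh-accessors
NULL

#' @rdname TriMesh-accessors
#' @export
nodeCoords <- function(mesh) mesh@nodes

#' @rdname TriMesh-accessors
#' @export
meshElements <- function(mesh) mesh@elements

#' @rdname TriMesh-accessors
#' @export
boundaryTags <- function(mesh) mesh@boundaryTag

#' @rdname TriMesh-accessors
#' @export
meshLevel <- function(mesh) mesh@level

#' @rdname TriMesh-accessors
#' @export
parentNodeMap <- function(mesh) mesh@parentNodeMap

setMethod("show", "TriMesh", function(object) {
  cat(sprintf(
    "TriMesh: %d nodes, %d elements, level %d\n",
    nrow(object@nodes), nrow(object@elements), object@level))
  cat(sprintf("  annulus R = %.4g m, W = %.4g m\n",
              object@geometry@R, object@geometry@W))
  cat(sprintf("  boundary nodes: %d mural, %d perivascular\n",
              sum(object@boundaryTag == "mural"),
              sum(object@boundaryTag == "perivascular")))
})

#' Generate a triangular mesh of the annular wall cross-section
#'
#' Builds an unstructured-looking triangulation of the annulus
#' \code{R <= r <= R+W}: rings of nodes whose radial layer thicknesses
#' are randomized (and optionally geometrically graded), with a
#' seed-deterministic jitter of every node position, criss-cross
#' triangulated. The element count lands within 20\% of
#' \code{targetElements}. The random layer widths and the jitter give
#' the mesh variably sized elements, as a generic Delaunay mesher
#' produces, with the size variation spatially uncorrelated with
#' position; the downstream surrogate's distance features are
#' informative only under such variability, so it is on by default.
#' Inner-circle nodes are tagged \code{mural}, outer-circle nodes
#' \code{perivascular}; boundary nodes are jittered only tangentially
#' and stay exactly on their circles. Equal seeds give identical meshes.
#'
#' @param geometry a \code{\linkS4class{DomainGeometry}}
#' @param targetElements requested element count (>= 16)
#' @param seed integer seed controlling phase, layer widths and jitter
#' @param grade geometric growth factor of the expected radial layer
#'   thickness from the mural to the perivascular side (1 = uniform)
#' @param jitter node-position perturbation as a fraction of the local
#'   spacing (0 = regular rings); reduced automatically if it would
#'   invert an element
#' @param ringJitter relative spread of the random radial layer
#'   thicknesses (0 = equal layers)
#' @return a level-0 \code{\linkS4class{TriMesh}}
#' @examples
#' mesh <- buildAnnulusMesh(domainGeometry(), 200, seed = 1)
#' mesh
#' @export
buildAnnulusMesh <- function(geometry, targetElements, seed = 1L,
                             grade = 1, jitter = 0.35,
                             ringJitter = 0.45) {
  stopifnot(is(geometry, "DomainGeometry"))
  if (targetElements < 16) stop("targetElements must be >= 16")
  R <- geometry@R; W <- geometry@W
  rMid <- R + W / 2
  # 2 * nr * nt elements; isotropy wants 2*pi*rMid/nt ~ W/nr on average
  nr <- max(1L, as.integer(round(sqrt(targetElements * W /
                                      (4 * pi * rMid)))))
  nt <- max(8L, as.integer(round(targetElements / (2 * nr))))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  idx <- function(i, j) i * nt + (j %% nt) + 1L
  build <- function(jf) {
    set.seed(as.integer(seed))
    # radial layer thicknesses: graded trend times a random factor
    w <- grade^(seq_len(nr) - 1L) *
      runif(nr, 1 - ringJitter, 1 + ringJitter)
    radii <- R + W * c(0, cumsum(w)) / sum(w)
    layer <- diff(radii)
    phase <- runif(1L, 0, 2 * pi / nt)
    nodes <- matrix(0, nrow = (nr + 1L) * nt, ncol = 2L)
    slot <- 2 * pi / nt
    for (i in seq(0L, nr)) {
      ang <- phase + slot * (seq_len(nt) - 1L) +
        runif(nt, -jf, jf) * slot            # tangential jitter
      r <- rep(radii[i + 1L], nt)
      if (i > 0L && i < nr) {                 # interior rings: radial too
        h <- min(layer[i], layer[i + 1L])
        r <- r + runif(nt, -jf, jf) * h
      }
      nodes[idx(i, seq(0L, nt - 1L)), ] <- cbind(r * cos(ang),
                                                 r * sin(ang))
    }
    nodes
  }
  elems <- matrix(0L, nrow = 2L * nr * nt, ncol = 3L)
  e <- 0L
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nt) - 1L) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      if ((i + j) %% 2L == 0L) {       # diagonal a-c
        elems[e + 1L, ] <- c(a, c, b)
        elems[e + 2L, ] <- c(a, d, c)
      } else {                          # diagonal b-d
        elems[e + 1L, ] <- c(a, d, b)
        elems[e + 2L, ] <- c(b, d, c)
      }
      e <- e + 2L
    }
  }
  jf <- jitter
  repeat {                              # back off if jitter inverts cells
    nodes <- build(jf)
    if (all(signedAreas(nodes, elems) > 0) || jf < 1e-3) break
    jf <- jf / 2
  }
  tags <- rep("interior", nrow(nodes))
  tags[seq_len(nt)] <- "mural"
  tags[idx(nr, seq(0L, nt - 1L))] <- "perivascular"
  new("TriMesh", nodes = nodes, elements = elems, boundaryTag = tags,
      level = 0L, parentNodeMap = integer(0), geometry = geometry)
}

# undirected edge key (min index, max index)
edgeKeys <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, sep = "_")
}

# per-element edges: (1,2), (2,3), (3,1); returns list of matrices
elementEdges <- function(elements) {
  cbind(c(elements[, 1L], elements[, 2L], elements[, 3L]),
        c(elements[, 2L], elements[, 3L], elements[, 1L]))
}

# longest edge of each element with deterministic tie-break:
# among equal-length edges pick lowest (min idx, max idx) lexicographically
longestEdgeLocal <- function(nodes, elements) {
  m <- nrow(elements)
  pick <- integer(m)
  for (k in 1:3) {
    a <- elements[, k]; b <- elements[, k %% 3L + 1L]
    len <- sqrt(rowSums((nodes[a, , drop = FALSE] -
                         nodes[b, , drop = FALSE])^2))
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (k == 1L) {
      best <- len; bestLo <- lo; bestHi <- hi; pick[] <- 1L
    } else {
      better <- len > best * (1 + 1e-12) |
        (abs(len - best) <= best * 1e-12 &
           (lo < bestLo | (lo == bestLo & hi < bestHi)))
      pick[better] <- k
      best[better] <- len[better]
      bestLo[better] <- lo[better]; bestHi[better] <- hi[better]
    }
  }
  pick
}

#' Refine a mesh by longest-edge bisection
#'
#' Bisects the longest edge of every element, then applies Rivara-style
#' closure bisections until no hanging node remains, so the output is
#' conforming. All parent nodes persist with unchanged coordinates and the
#' parent-to-child index map is recorded; the refinement level is
#' incremented. Midpoints created on a curved boundary edge are projected
#' to the exact circle when \code{project = TRUE} (the default), which
#' keeps the geometric error from compounding across levels; with
#' \code{project = FALSE} the piecewise-linear boundary (and hence total
#' mesh area) is preserved exactly.
#'
#' @param mesh a conforming \code{\linkS4class{TriMesh}}
#' @param project project new boundary nodes to the exact circles?
#' @return the refined \code{\linkS4class{TriMesh}}
#' @examples
#' m0 <- buildAnnulusMesh(domainGeometry(), 64, seed = 1)
#' m1 <- refineLongestEdge(m0)
#' nrow(meshElements(m1)) > nrow(meshElements(m0))
#' @export
refineLongestEdge <- function(mesh, project = TRUE) {
  stopifnot(is(mesh, "TriMesh"))
  nodes <- mesh@nodes
  elems <- mesh@elements
  areas <- signedAreas(nodes, elems)
  if (any(areas <= 1e-30))
    stop(sprintf("refinement error: element %d is degenerate",
                 which(areas <= 1e-30)[1L]))
  m <- nrow(elems)
  longest <- longestEdgeLocal(nodes, elems)
  allEdges <- elementEdges(elems)                 # 3m x 2, element-major
  allKeys <- edgeKeys(allEdges[, 1L], allEdges[, 2L])
  keyOfLongest <- allKeys[(longest - 1L) * m + seq_len(m)]

  # split set: longest edge of every element, plus closure:
  # if any edge of an element is split, its longest edge must be split too
  split <- unique(keyOfLongest)
  repeat {
    hit <- matrix(allKeys %in% split, nrow = m)   # m x 3
    need <- rowSums(hit) > 0L
    add <- setdiff(unique(keyOfLongest[need]), split)
    if (!length(add)) break
    split <- c(split, add)
  }

  # midpoint nodes for every split edge
  splitMat <- do.call(rbind, strsplit(split, "_", fixed = TRUE))
  sa <- as.integer(splitMat[, 1L]); sb <- as.integer(splitMat[, 2L])
  mid <- (nodes[sa, , drop = FALSE] + nodes[sb, , drop = FALSE]) / 2
  tagA <- mesh@boundaryTag[sa]; tagB <- mesh@boundaryTag[sb]
  # an edge lies on a boundary circle iff it is used by exactly one element
  # and both endpoints share that circle's tag
  edgeUse <- table(allKeys)
  onBoundary <- as.integer(edgeUse[split]) == 1L & tagA == tagB &
    tagA != "interior"
  newTag <- ifelse(onBoundary, tagA, "interior")
  if (project && any(onBoundary)) {
    R <- mesh@geometry@R; W <- mesh@geometry@W
    rTarget <- ifelse(newTag == "mural", R, R + W)
    bi <- which(onBoundary)
    rNow <- sqrt(rowSums(mid[bi, , drop = FALSE]^2))
    mid[bi, ] <- mid[bi, , drop = FALSE] * (rTarget[bi] / rNow)
  }
  nOld <- nrow(nodes)
  midIndex <- setNames(nOld + seq_along(split), split)
  newNodes <- rbind(nodes, mid)
  newTags <- c(mesh@boundaryTag, newTag)

  # subdivide element-by-element
  out <- vector("list", m)
  for (e in seq_len(m)) {
    v <- elems[e, ]
    ek <- c(edgeKeys(v[1L], v[2L]), edgeKeys(v[2L], v[3L]),
            edgeKeys(v[3L], v[1L]))
    isSplit <- ek %in% split
    le <- longest[e]                     # index of the longest edge (split)
    # rotate so the longest edge is (A,B) with C opposite
    ord <- switch(le, `1` = c(1L, 2L, 3L), `2` = c(2L, 3L, 1L),
                  `3` = c(3L, 1L, 2L))
    A <- v[ord[1L]]; B <- v[ord[2L]]; C <- v[ord[3L]]
    mAB <- midIndex[[edgeKeys(A, B)]]
    sBC <- ek[ord[2L]] %in% split
    sCA <- ek[ord[3L]] %in% split
    tris <- list(c(A, mAB, C), c(mAB, B, C))   # base bisection
    if (sBC) {                                  # refine sub-tri (mAB,B,C)
      mBC <- midIndex[[edgeKeys(B, C)]]
      tris[[2L]] <- NULL
      tris <- c(tris, list(c(mAB, B, mBC), c(mAB, mBC, C)))
    }
    if (sCA) {                                  # refine sub-tri (A,mAB,C)
      mCA <- midIndex[[edgeKeys(C, A)]]
      tris[[1L]] <- NULL
      tris <- c(tris, list(c(A, mAB, mCA), c(mAB, C, mCA)))
    }
    out[[e]] <- do.call(rbind, tris)
  }
  newElems <- do.call(rbind, out)
  # enforce counter-clockwise orientation
  a2 <- signedAreas(newNodes, newElems)
  flip <- a2 < 0
  if (any(flip))
    newElems[flip, c(2L, 3L)] <- newElems[flip, c(3L, 2L)]
  new("TriMesh", nodes = newNodes, elements = newElems,
      boundaryTag = newTags, level = mesh@level + 1L,
      parentNodeMap = seq_len(nOld), geometry = mesh@geometry)
}

#' Build a nested refinement hierarchy
#'
#' @param geometry a \code{\linkS4class{DomainGeometry}}
#' @param targetElements level-0 element count target
#' @param refinements number of longest-edge refinement passes
#' @param seed mesh-generation seed
#' @param project see \code{\link{refineLongestEdge}}
#' @return list of \code{TriMesh}, levels 0..refinements
#' @export
refinementHierarchy <- function(geometry, targetElements, refinements = 3L,
                                seed = 1L, project = TRUE) {
  meshes <- vector("list", refinements + 1L)
  meshes[[1L]] <- buildAnnulusMesh(geometry, targetElements, seed)
  for (i in seq_len(refinements))
    meshes[[i + 1L]] <- refineLongestEdge(meshes[[i]], project = project)
  meshes
}

#' Node correspondence between nested meshes
#'
#' Composes parent-node maps along the refinement lineage from
#' \code{coarse} to \code{fine}. Every coarse node persists in the fine
#' mesh at exactly the same coordinates, so the returned pairing is exact
#' (no interpolation).
#'
#' @param coarse ancestor \code{\linkS4class{TriMesh}}
#' @param fine a refinement descendant of \code{coarse} (possibly itself)
#' @return two-column integer matrix with columns \code{coarse} and
#'   \code{fine}; one row per coarse node
#' @export
commonNodes <- function(coarse, fine) {
  if (fine@level < coarse@level)
    stop("lineage error: fine mesh has lower level than coarse mesh")
  nC <- nrow(coarse@nodes)
  map <- seq_len(nC)
  # meshes are nested by construction: each refinement keeps parent indices
  # as a prefix, so the composed map is the identity prefix; verify
  # coordinates to catch non-descendant inputs
  if (nC > nrow(fine@nodes))
    stop("lineage error: meshes are not in an ancestry relation")
  dist2 <- rowSums((coarse@nodes - fine@nodes[map, , drop = FALSE])^2)
  if (any(dist2 != 0))
    stop("lineage error: node coordinates do not match along the lineage")
  cbind(coarse = map, fine = map)
}

# test helper: relabel mesh nodes by a permutation (lineage is dropped);
# perm gives the old index stored at each new position
permuteMeshNodes <- function(mesh, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  el <- matrix(inv[mesh@elements], ncol = 3L)
  new("TriMesh", nodes = mesh@nodes[perm, , drop = FALSE],
      elements = el, boundaryTag = mesh@boundaryTag[perm],
      level = 0L, parentNodeMap = integer(0), geometry = mesh@geometry)
}

permuteField <- function(field, perm) {
  newConcentrationField(mesh = permuteMeshNodes(field@mesh, perm),
      C = field@C[perm], B = field@B[perm], time = field@time,
      influx = field@influx, outflux = field@outflux)
}
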