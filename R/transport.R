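# Free/bound drug transport in the arterial wall:
#   dC/dt = Dw lap(C) - ka C (BM - B) + kd B
#   dB/dt =             ka C (BM - B) - kd B
# with a transient release flux on the mural (inner) circle, a perfect
# sink (C = 0) on the perivascular (outer) circle, zero-flux everywhere
# for B, and zero initial conditions.

#' Transport parameters for the balloon delivery model
#'
#' Defaults are the zotarolimus drug-coated-balloon values: diffusivity
#' 1.712e-11 m^2/s, binding capacity 0.356 mol/m^3, Damkohler number
#' 50000, equilibrium dissociation constant 0.0326 mol/m^3, release
#' kinetics A1 = 23.95 kg/m^3 and k1 = 0.009208 1/s, molecular weight
#' 966.21 g/mol, inflation time 30 s, wall thickness 0.5 mm. The
#' association and dissociation rates are derived as
#' \code{ka = Dw*Da/(BM*W^2)}, \code{kd = ka*Kd}. \code{coatingThickness}
#' is the balloon coating volume per unit surface area entering the
#' release-flux law (default 10 micrometres).
#'
#' @param Dw,BM,Da,Kd,A1,k1,ZMW,t0,W,coatingThickness see slot
#'   documentation of \code{\linkS4class{TransportParameters}}
#' @return a \code{\linkS4class{TransportParameters}}
#' @examples
#' p <- transportParameters()
#' p@ka * p@Kd == p@kd
#' @export
transportParameters <- function(Dw = 1.712e-11, BM = 0.356, Da = 5e4,
                                Kd = 0.0326, A1 = 23.95, k1 = 0.009208,
                                ZMW = 966.21, t0 = 30, W = 5e-4,
                                coatingThickness = 1e-5) {
  ka <- Dw * Da / (BM * W^2)
  new("TransportParameters", Dw = Dw, BM = BM, Da = Da, Kd = Kd,
      ka = ka, kd = ka * Kd, A1 = A1, k1 = k1, ZMW = ZMW, t0 = t0,
      W = W, coatingThickness = coatingThickness)
}

#' Solver settings
#'
#' Defaults follow the reference solve: relative tolerance 1e-9, absolute
#' tolerance 1e-6, BDF orders up to 5, end time 1 h.
#'
#' @param rtol,atol,maxOrder,tEnd,nSave see
#'   \code{\linkS4class{SolverSettings}}
#' @return a \code{\linkS4class{SolverSettings}}
#' @export
solverSettings <- function(rtol = 1e-9, atol = 1e-6, maxOrder = 5L,
                           tEnd = 3600, nSave = 121L) {
  new("SolverSettings", rtol = rtol, atol = atol,
      maxOrder = as.integer(maxOrder), tEnd = tEnd,
      nSave = as.integer(nSave))
}

#' Balloon release flux
#'
#' Molar flux of drug entering the tissue through the mural surface while
#' the balloon is inflated:
#' \deqn{J_b(t) = \frac{A_1 k_1 \delta_c}{Z_{MW}} e^{-k_1 t}, \quad
#'   0 \le t \le t_0,}
#' and 0 for \eqn{t > t_0}, where \eqn{\delta_c} is the coating volume per
#' unit balloon surface area (\code{coatingThickness}) and the molecular
#' weight converts the mass-based release amplitude to moles. Positive
#' flux means drug enters the tissue.
#'
#' @param t time since inflation onset (s), scalar or vector, >= 0
#' @param params a \code{\linkS4class{TransportParameters}}
#' @return molar flux in mol m^-2 s^-1
#' @examples
#' p <- transportParameters()
#' balloonFlux(0, p)
#' balloonFlux(p@t0 + 1, p)  # 0 after deflation
#' @export
balloonFlux <- function(t, params) {
  if (any(t < 0)) stop("domain error: t must be >= 0")
  amp <- params@A1 * params@k1 * params@coatingThickness /
    (params@ZMW * 1e-3)                      # g/mol -> kg/mol
  ifelse(t <= params@t0, amp * exp(-params@k1 * t), 0)
}

#' Total drug released per unit mural area (closed form)
#'
#' Integral of \code{\link{balloonFlux}} from 0 to \code{t} (mol m^-2).
#'
#' @inheritParams balloonFlux
#' @export
balloonReleasedMass <- function(t, params) {
  amp <- params@A1 * params@coatingThickness / (params@ZMW * 1e-3)
  tc <- pmin(t, params@t0)
  amp * (1 - exp(-params@k1 * tc))
}

#' Assemble P1 finite-element operators on a mesh
#'
#' Returns the lumped mass matrix (diagonal, entries sum to the mesh
#' area), the stiffness matrix of the Laplacian (symmetric positive
#' semi-definite, constants in its null space) and the lumped boundary
#' mass vector of the mural circle (entries sum to the inner polygonal
#' perimeter; nonzero only on mural nodes).
#'
#' @param mesh a tagged \code{\linkS4class{TriMesh}}
#' @return list with sparse \code{mass} and \code{stiffness} matrices,
#'   numeric \code{muralMass} and \code{perivascularMass} vectors, and the
#'   index vectors \code{mural}, \code{perivascular}
#' @export
assembleOperators <- function(mesh) {
  nodes <- mesh@nodes; elems <- mesh@elements
  if (!any(mesh@boundaryTag == "mural") ||
      !any(mesh@boundaryTag == "perivascular"))
    stop("assembly error: mesh boundary is untagged")
  n <- nrow(nodes); m <- nrow(elems)
  areas <- signedAreas(nodes, elems)
  # P1 stiffness: grad phi_i = (b_i, c_i) / (2A)
  i1 <- elems[, 1L]; i2 <- elems[, 2L]; i3 <- elems[, 3L]
  x <- nodes[, 1L]; y <- nodes[, 2L]
  b1 <- y[i2] - y[i3]; b2 <- y[i3] - y[i1]; b3 <- y[i1] - y[i2]
  c1 <- x[i3] - x[i2]; c2 <- x[i1] - x[i3]; c3 <- x[i2] - x[i1]
  bs <- cbind(b1, b2, b3); cs <- cbind(c1, c2, c3)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- elems[, a]; jj[[k]] <- elems[, b]
    vv[[k]] <- (bs[, a] * bs[, b] + cs[, a] * cs[, b]) / (4 * areas)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(vv), dims = c(n, n))
  # lumped mass: a third of each element's area to each vertex
  ml <- numeric(n)
  third <- areas / 3
  for (a in 1:3) {
    tab <- rowsum(third, elems[, a])
    ml[as.integer(rownames(tab))] <- ml[as.integer(rownames(tab))] + tab[, 1L]
  }
  M <- Matrix::Diagonal(n, ml)
  boundaryMass <- function(tag) {
    bm <- numeric(n)
    edges <- boundaryEdges(mesh)
    sel <- mesh@boundaryTag[edges[, 1L]] == tag &
           mesh@boundaryTag[edges[, 2L]] == tag
    be <- edges[sel, , drop = FALSE]
    if (nrow(be)) {
      len <- sqrt(rowSums((nodes[be[, 1L], , drop = FALSE] -
                           nodes[be[, 2L], , drop = FALSE])^2))
      t1 <- rowsum(len / 2, be[, 1L])
      t2 <- rowsum(len / 2, be[, 2L])
      bm[as.integer(rownames(t1))] <- bm[as.integer(rownames(t1))] + t1[, 1L]
      bm[as.integer(rownames(t2))] <- bm[as.integer(rownames(t2))] + t2[, 1L]
    }
    bm
  }
  list(mass = M, stiffness = K,
       muralMass = boundaryMass("mural"),
       perivascularMass = boundaryMass("perivascular"),
       mural = which(mesh@boundaryTag == "mural"),
       perivascular = which(mesh@boundaryTag == "perivascular"))
}

# edges used by exactly one element
boundaryEdges <- function(mesh) {
  ed <- elementEdges(mesh@elements)
  keys <- edgeKeys(ed[, 1L], ed[, 2L])
  cnt <- table(keys)
  single <- names(cnt)[cnt == 1L]
  mat <- do.call(rbind, strsplit(single, "_", fixed = TRUE))
  cbind(as.integer(mat[, 1L]), as.integer(mat[, 2L]))
}

#' Solve the transient free/bound drug transport problem
#'
#' Method-of-lines P1 finite elements with lumped mass, integrated by the
#' variable-order, variable-step sparse BDF method of
#' \code{deSolve::lsodes}. Free drug diffuses, receives the balloon flux
#' on the mural circle and is held at zero on the perivascular circle
#' (perfect sink); bound drug evolves pointwise by the reversible
#' saturable binding kinetics and does not diffuse. Initial conditions
#' are zero. Negative concentrations are never clipped.
#'
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @param params a \code{\linkS4class{TransportParameters}}
#' @param settings a \code{\linkS4class{SolverSettings}}
#' @param fluxFun optional override of the mural flux function
#'   \code{function(t) -> mol m^-2 s^-1} (defaults to
#'   \code{\link{balloonFlux}})
#' @param initialC,initialB optional initial nodal fields (default zero)
#' @param holdFree verification mode: clamp the free-drug field at its
#'   initial value and evolve only the binding kinetics
#' @param operators optional precomputed \code{\link{assembleOperators}}
#'   result for this mesh
#' @return a \code{\linkS4class{ConcentrationField}} at the end time, with
#'   cumulative mural influx and perivascular outflow accounted on the
#'   save grid
#' @export
solveTransient <- function(mesh, params, settings = solverSettings(),
                           fluxFun = NULL, initialC = NULL,
                           initialB = NULL, holdFree = FALSE,
                           operators = NULL) {
  ops <- if (is.null(operators)) assembleOperators(mesh) else operators
  n <- nrow(mesh@nodes)
  Dw <- params@Dw; ka <- params@ka; kd <- params@kd; BM <- params@BM
  Minv <- 1 / ops$mass@x
  K <- ops$stiffness
  bM <- ops$muralMass
  sink <- ops$perivascular
  free <- setdiff(seq_len(n), sink)
  defaultFlux <- is.null(fluxFun)
  if (defaultFlux) fluxFun <- function(t) balloonFlux(t, params)
  C0 <- if (is.null(initialC)) numeric(n) else initialC
  B0 <- if (is.null(initialB)) numeric(n) else initialB
  C0[sink] <- 0
  y0 <- c(C0, B0)
  rhs <- function(t, yv, p) {
    C <- yv[seq_len(n)]; B <- yv[n + seq_len(n)]
    reac <- ka * C * (BM - B) - kd * B
    dB <- reac
    if (holdFree) {
      dC <- numeric(n)
    } else {
      dC <- Minv * (-Dw * as.numeric(K %*% C) + fluxFun(t) * bM) - reac
      dC[sink] <- 0
    }
    list(c(dC, dB))
  }
  times <- seq(0, settings@tEnd, length.out = max(2L, settings@nSave))
  # make sure the flux discontinuity at t0 is a mesh point of the save grid
  if (params@t0 < settings@tEnd)
    times <- sort(unique(c(times, params@t0)))
  # Jacobian sparsity: diffusion stencil on the C block, pointwise
  # reaction coupling between C and B
  Kp <- methods::as(K, "TsparseMatrix")
  iC <- Kp@i + 1L; jC <- Kp@j + 1L
  keep <- !(iC %in% sink)
  inz <- rbind(cbind(iC[keep], jC[keep]),
               cbind(seq_len(n), seq_len(n)),       # C diagonal (all rows)
               cbind(free, n + free),               # dC/dB
               cbind(n + seq_len(n), seq_len(n)),   # dB/dC
               cbind(n + seq_len(n), n + seq_len(n)))
  inz <- unique(inz)
  inz <- inz[order(inz[, 2L], inz[, 1L]), , drop = FALSE]
  # work-array size must cover the sparse LU fill-in; escalate on demand
  lrw <- 30 * (2L * n) + 30 * nrow(inz)
  sol <- NULL
  for (attempt in 1:4) {
    sol <- tryCatch(
      deSolve::lsodes(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = settings@rtol, atol = settings@atol,
                      maxord = settings@maxOrder, maxsteps = 100000,
                      sparsetype = "sparseusr", inz = inz, lrw = lrw),
      error = function(e) e)
    if (!inherits(sol, "error")) break
    if (!grepl("RWORK|illegal input", conditionMessage(sol)))
      stop(sol)
    lrw <- lrw * 4
  }
  if (inherits(sol, "error")) stop(sol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("convergence error: integrator stopped at t = %.6g s",
                 sol[nrow(sol), 1L]))
  Cend <- sol[nrow(sol), 1L + seq_len(n)]
  Bend <- sol[nrow(sol), 1L + n + seq_len(n)]
  # mass accounting on the save grid:
  # influx: closed form of the flux law when default, quadrature otherwise
  influx <- sum(bM) * if (defaultFlux && !holdFree)
    balloonReleasedMass(settings@tEnd, params)
  else {
    tt <- sol[, 1L]
    fv <- vapply(tt, fluxFun, numeric(1L))
    sum(diff(tt) * (fv[-1L] + fv[-length(fv)]) / 2)
  }
  # outflow through the sink: the Dirichlet rows' discrete reaction force
  # -Dw * K[sink, ] %*% C integrated over the save grid (trapezoid)
  tt <- sol[, 1L]
  Ksink <- K[sink, , drop = FALSE]
  outRate <- vapply(seq_along(tt), function(i) {
    C <- sol[i, 1L + seq_len(n)]
    -sum(Dw * as.numeric(Ksink %*% C))
  }, numeric(1L))
  outflux <- sum(diff(tt) * (outRate[-1L] + outRate[-length(tt)]) / 2)
  newConcentrationField(mesh = mesh, C = unname(Cend),
      B = unname(Bend), time = settings@tEnd,
      influx = if (holdFree) 0 else influx, outflux = outflux)
}

#' Steady diffusion solve with constant mural flux
#'
#' Solves the pure-diffusion steady state (no binding): \code{Dw lap(C) =
#' 0} with constant inward flux \code{q} on the mural circle and a
#' perfect sink on the perivascular circle. Useful as a verification
#' target against the annular log profile
#' \code{C(r) = q R / Dw * log((R+W)/r)}.
#'
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @param Dw diffusivity (m^2/s)
#' @param q constant mural influx (mol m^-2 s^-1)
#' @return nodal concentrations
#' @export
solveSteady <- function(mesh, Dw, q) {
  ops <- assembleOperators(mesh)
  n <- nrow(mesh@nodes)
  sink <- ops$perivascular
  free <- setdiff(seq_len(n), sink)
  K <- Dw * ops$stiffness
  f <- q * ops$muralMass
  C <- numeric(n)
  C[free] <- as.numeric(Matrix::solve(K[free, free], f[free]))
  C
}

#' Discrete drug-mass balance of a solved field
#'
#' Compares the drug content of the tissue, \code{integral (C+B) dA}, with
#' the cumulative mural influx minus the cumulative perivascular outflow
#' recorded during the solve.
#'
#' @param field a \code{\linkS4class{ConcentrationField}} returned by
#'   \code{\link{solveTransient}}
#' @param params the \code{\linkS4class{TransportParameters}} used
#' @return list with \code{content}, \code{influx}, \code{outflux} and the
#'   relative imbalance \code{relError}
#' @export
massBalance <- function(field, params) {
  ops <- assembleOperators(field@mesh)
  content <- sum(ops$mass@x * (field@C + field@B))
  net <- field@influx - field@outflux
  list(content = content, influx = field@influx, outflux = field@outflux,
       relError = abs(content - net) / max(abs(field@influx),
                                           .Machine$double.eps))
}

setMethod("show", "ConcentrationField", function(object) {
  cat(sprintf(
    "ConcentrationField at t = %.6g s on a level-%d mesh (%d nodes)\n",
    object@time, object@mesh@level, length(object@C)))
  cat(sprintf("  free  C: range [%.4g, %.4g] mol/m^3\n",
              min(object@C), max(object@C)))
  cat(sprintf("  bound B: range [%.4g, %.4g] mol/m^3\n",
              min(object@B), max(object@B)))
})
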