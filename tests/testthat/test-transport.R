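params <- transportParameters()

test_that("derived binding rates satisfy their definitions", {
  expect_equal(params@ka, params@Dw * params@Da / (params@BM * params@W^2))
  expect_equal(params@kd, params@ka * params@Kd)
  expect_error(transportParameters(Dw = -1), "positive")
})

test_that("balloon flux releases only during inflation and integrates to the closed form", {
  expect_identical(balloonFlux(params@t0 + 1, params), 0)
  expect_identical(balloonFlux(1e6, params), 0)
  expect_error(balloonFlux(-1, params), "domain")
  # value at t = 0: amplitude of the release law
  amp <- params@A1 * params@k1 * params@coatingThickness /
    (params@ZMW * 1e-3)
  expect_equal(balloonFlux(0, params), amp)
  # non-negative, monotone non-increasing on [0, t0] (dense sampling)
  tt <- seq(0, params@t0, length.out = 2000)
  jb <- balloonFlux(tt, params)
  expect_true(all(jb >= 0))
  expect_true(all(diff(jb) <= 0))
  # numeric quadrature oracle vs the closed-form released mass
  quad <- integrate(balloonFlux, 0, params@t0, params = params,
                    rel.tol = 1e-10)$value
  expect_equal(quad, balloonReleasedMass(params@t0, params),
               tolerance = 1e-8)
  expect_equal(balloonReleasedMass(1e6, params),
               balloonReleasedMass(params@t0, params))
})

test_that("P1 operators have the expected structure", {
  mesh <- buildAnnulusMesh(domainGeometry(), 300, seed = 1)
  ops <- assembleOperators(mesh)
  # constants in the stiffness null space
  expect_lt(max(abs(Matrix::rowSums(ops$stiffness))), 1e-10)
  # mass sums to the polygonal mesh area, close to the annulus area
  polyArea <- sum(meshlift:::signedAreas(nodeCoords(mesh),
                                         meshElements(mesh)))
  expect_equal(sum(ops$mass@x), polyArea, tolerance = 1e-12)
  expect_equal(sum(ops$mass@x), pi * (3.5e-3^2 - 3e-3^2),
               tolerance = 0.01)
  # mural boundary mass sums to the inner perimeter, supported on mural
  expect_equal(sum(ops$muralMass), 2 * pi * 3e-3, tolerance = 0.01)
  expect_true(all(ops$muralMass[boundaryTags(mesh) != "mural"] == 0))
  expect_true(all(ops$muralMass[ops$mural] > 0))
  # untagged boundary is an error
  bad <- mesh
  bad@boundaryTag <- rep("interior", length(bad@boundaryTag))
  expect_error(assembleOperators(bad), "assembly error")
})

test_that("zero flux with zero initial conditions stays identically zero", {
  mesh <- tinyMesh()
  f <- solveTransient(mesh, params,
                      solverSettings(tEnd = 600, nSave = 5L),
                      fluxFun = function(t) 0)
  expect_equal(max(abs(f@C)), 0)
  expect_equal(max(abs(f@B)), 0)
})

test_that("steady annular diffusion matches the log profile to <1% L2", {
  geom <- domainGeometry()
  mesh <- buildAnnulusMesh(geom, 1000, seed = 2)
  off <- transportParameters(Da = 1e-9)      # binding switched off
  f <- solveTransient(mesh, off,
                      solverSettings(rtol = 1e-6, atol = 1e-9,
                                     tEnd = 8e4, nSave = 11L),
                      fluxFun = function(t) 1)
  prof <- analyticProfile("annulusLog",
                          list(q = 1, R = 3e-3, W = 5e-4, Dw = off@Dw))
  Cref <- prof$evaluate(nodeCoords(mesh))
  expect_lt(sqrt(sum((f@C - Cref)^2) / sum(Cref^2)), 0.01)
  # direct steady solve agrees with the relaxed transient
  Cs <- solveSteady(mesh, off@Dw, 1)
  expect_lt(sqrt(sum((Cs - f@C)^2) / sum(Cs^2)), 1e-4)
})

test_that("held-free binding kinetics match the scalar ODE closed form", {
  mesh <- tinyMesh()
  C0 <- rep(0.05, nrow(nodeCoords(mesh)))
  f <- solveTransient(mesh, params,
                      solverSettings(tEnd = 2, nSave = 5L),
                      initialC = C0, holdFree = TRUE)
  prof <- analyticProfile("bindingODE",
                          list(BM = params@BM, Kd = params@Kd,
                               ka = params@ka, kd = params@kd, C = 0.05))
  live <- boundaryTags(mesh) != "perivascular"  # sink clamps C to 0
  Bref <- prof$evaluate(2)
  expect_lt(max(abs(f@B[live] - Bref)) / Bref, 1e-3)
  # equilibrium at long time
  fEq <- solveTransient(mesh, params,
                        solverSettings(tEnd = 2000, nSave = 3L),
                        initialC = C0, holdFree = TRUE)
  expect_equal(max(f@C), 0.05)
  expect_lt(max(abs(fEq@B[live] - params@BM * 0.05 /
                      (params@Kd + 0.05))) / Bref, 1e-3)
})

test_that("drug mass is conserved to within 0.1%", {
  mesh <- buildAnnulusMesh(domainGeometry(), 600, seed = 1)
  f <- solveTransient(mesh, params, solverSettings())
  mb <- massBalance(f, params)
  expect_gt(mb$influx, 0)
  expect_gte(mb$outflux, 0)
  expect_lt(mb$relError, 1e-3)
})

test_that("solution fields are physical at 1 h", {
  f <- solvedHierarchy()$fields[[1]]
  expect_true(all(f@C > -1e-9))
  expect_true(all(f@B > -1e-9 & f@B < params@BM + 1e-9))
  expect_true(all(f@C[boundaryTags(f@mesh) == "perivascular"] == 0))
})

test_that("angular symmetry error shrinks under refinement", {
  h <- solvedHierarchy()
  spreadAtMural <- function(f)
    sd(f@C[boundaryTags(f@mesh) == "mural"])
  expect_lt(spreadAtMural(h$fields[[3]]), spreadAtMural(h$fields[[1]]))
})

test_that("consecutive refinement levels converge monotonically", {
  h <- solvedHierarchy()
  for (kind in c("free", "bound")) {
    v <- function(f) if (kind == "free") f@C else f@B
    diffs <- vapply(1:3, function(i) {
      n <- length(v(h$fields[[i]]))
      rmse(v(h$fields[[i]]), v(h$fields[[i + 1]])[seq_len(n)])
    }, 0)
    expect_true(all(diff(diffs) < 0))
  }
})

test_that("field CSV round-trip preserves the solution", {
  f <- solvedHierarchy()$fields[[1]]
  path <- tempfile(fileext = ".csv")
  writeFieldCsv(f, path)
  back <- readFieldCsv(path, f@mesh, time = f@time)
  expect_equal(back@C, f@C)
  expect_equal(back@B, f@B)
  expect_error(readFieldCsv(path, solvedHierarchy()$meshes[[2]]),
               "alignment")
})
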