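# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

tinyMesh <- function() cached("tinyMesh", {
  buildAnnulusMesh(domainGeometry(), 64, seed = 1)
})

# 200-element hierarchy with analytic log-profile fields (no PDE solve);
# flux chosen so the field magnitude is O(1)
analyticHierarchy <- function() cached("analyticHierarchy", {
  geom <- domainGeometry()
  meshes <- refinementHierarchy(geom, 200, 3, seed = 3)
  prof <- analyticProfile("annulusLog",
                          list(q = 4e-8, R = lumenRadius(geom),
                               W = wallThickness(geom), Dw = 1.712e-11))
  list(meshes = meshes, fields = lapply(meshes, analyticField,
                                        profile = prof),
       profile = prof)
})

# small solved hierarchy for pipeline smoke tests (zotarolimus defaults)
solvedHierarchy <- function() cached("solvedHierarchy", {
  params <- transportParameters()
  meshes <- refinementHierarchy(domainGeometry(), 200, 3, seed = 1)
  fields <- lapply(meshes, solveTransient, params = params,
                   settings = solverSettings())
  list(meshes = meshes, fields = fields, params = params)
})

# reduced default experiment shared between pipeline and acceptance tests
reducedExperiment <- function() cached("reducedExperiment", {
  runExperiment(defaultExperimentConfig(seed = 1))
})

# full printed-density hierarchy references
printedDensityRefs <- function() cached("printedDensityRefs", {
  params <- transportParameters()
  meshes <- refinementHierarchy(domainGeometry(), 5302, 3, seed = 1)
  fields <- lapply(meshes, solveTransient, params = params,
                   settings = solverSettings())
  list(free = referenceRmses(fields, "free"),
       bound = referenceRmses(fields, "bound"),
       elements = vapply(meshes, function(m) nrow(meshElements(m)), 0L))
})

minMeshAngle <- function(mesh) {
  nodes <- nodeCoords(mesh); el <- meshElements(mesh)
  ang <- function(a, b, c) {
    u <- nodes[b, ] - nodes[a, ]; v <- nodes[c, ] - nodes[a, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  mn <- Inf
  for (i in seq_len(nrow(el))) {
    v <- el[i, ]
    mn <- min(mn, ang(v[1], v[2], v[3]), ang(v[2], v[3], v[1]),
              ang(v[3], v[1], v[2]))
  }
  mn
}
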