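test_that("annulus mesh hits the target element count and tags boundaries", {
  geom <- domainGeometry()
  mesh <- buildAnnulusMesh(geom, 5300, seed = 1)
  m <- nrow(meshElements(mesh))
  expect_gt(m, 5300 * 0.8)
  expect_lt(m, 5300 * 1.2)
  tags <- boundaryTags(mesh)
  expect_gt(sum(tags == "mural"), 0)
  expect_gt(sum(tags == "perivascular"), 0)
  r <- sqrt(rowSums(nodeCoords(mesh)^2))
  expect_equal(r[tags == "mural"], rep(3e-3, sum(tags == "mural")))
  expect_equal(r[tags == "perivascular"],
               rep(3.5e-3, sum(tags == "perivascular")))
  # all nodes inside the closed annulus
  expect_true(all(r >= 3e-3 - 1e-12 & r <= 3.5e-3 + 1e-12))
})

test_that("mesh generation is deterministic in the seed", {
  a <- buildAnnulusMesh(domainGeometry(), 300, seed = 7)
  b <- buildAnnulusMesh(domainGeometry(), 300, seed = 7)
  c <- buildAnnulusMesh(domainGeometry(), 300, seed = 8)
  expect_identical(nodeCoords(a), nodeCoords(b))
  expect_false(isTRUE(all.equal(nodeCoords(a), nodeCoords(c))))
})

test_that("invalid geometry is rejected", {
  expect_error(domainGeometry(R = -1), "positive")
  expect_error(domainGeometry(W = 0), "positive")
  expect_error(buildAnnulusMesh(domainGeometry(), 8), ">= 16")
})

test_that("bisecting a single triangle splits its longest edge", {
  # right triangle: longest edge (hypotenuse) between nodes 2 and 3
  nodes <- rbind(c(0, 0), c(2, 0), c(0, 2))
  tri <- new("TriMesh", nodes = nodes,
             elements = matrix(c(1L, 2L, 3L), 1),
             boundaryTag = rep("interior", 3), level = 0L,
             parentNodeMap = integer(0), geometry = domainGeometry())
  ref <- refineLongestEdge(tri)
  expect_equal(nrow(meshElements(ref)), 2L)
  expect_equal(nrow(nodeCoords(ref)), 4L)
  expect_equal(nodeCoords(ref)[4L, ], c(1, 1))  # hypotenuse midpoint
  # both children contain the new node
  expect_true(all(apply(meshElements(ref), 1, function(e) 4L %in% e)))
})

test_that("refinement yields a conforming mesh (no hanging nodes)", {
  mesh <- refineLongestEdge(tinyMesh())
  el <- meshElements(mesh)
  nodes <- nodeCoords(mesh)
  # brute-force edge-use oracle: every edge used by at most 2 elements,
  # and used once only on the domain boundary
  edges <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]),
               pmax(edges[, 1], edges[, 2]))
  use <- table(key)
  expect_true(all(use %in% c(1L, 2L)))
  single <- do.call(rbind, strsplit(names(use)[use == 1L], " "))
  rr <- sqrt(rowSums(nodes^2))
  onCircle <- abs(rr - 3e-3) < 1e-9 | abs(rr - 3.5e-3) < 1e-9
  expect_true(all(onCircle[as.integer(single)]))
  # no node strictly interior to any edge of any element
  set.seed(1)
  for (e in sample(seq_len(nrow(el)), 50)) {
    for (pair in list(el[e, c(1, 2)], el[e, c(2, 3)], el[e, c(3, 1)])) {
      a <- nodes[pair[1], ]; b <- nodes[pair[2], ]
      ab <- b - a; len2 <- sum(ab^2)
      t <- ((t(nodes) - a)[1, ] * ab[1] + (t(nodes) - a)[2, ] * ab[2]) /
        len2
      inside <- t > 1e-9 & t < 1 - 1e-9
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      d2 <- (nodes[, 1] - px)^2 + (nodes[, 2] - py)^2
      expect_false(any(inside & d2 < 1e-24))
    }
  }
})

test_that("refinement is monotone, nested and level-tracked", {
  meshes <- refinementHierarchy(domainGeometry(), 200, 3, seed = 2)
  counts <- vapply(meshes, function(m) nrow(meshElements(m)), 0L)
  nnodes <- vapply(meshes, function(m) nrow(nodeCoords(m)), 0L)
  expect_true(all(diff(counts) > 0))
  expect_true(all(diff(nnodes) > 0))
  expect_equal(vapply(meshes, meshLevel, 0L), 0:3)
  for (i in 1:3) {
    nC <- nnodes[i]
    expect_identical(nodeCoords(meshes[[i]]),
                     nodeCoords(meshes[[i + 1]])[seq_len(nC), ])
    expect_identical(parentNodeMap(meshes[[i + 1]]), seq_len(nC))
  }
  # every parent element's longest edge was bisected: element count at
  # least doubles
  expect_true(all(counts[-1] >= 2 * counts[-4]))
})

test_that("refinement preserves area without projection and converges with it", {
  m0 <- tinyMesh()
  area <- function(m) sum(meshlift:::signedAreas(nodeCoords(m),
                                                 meshElements(m)))
  a0 <- area(m0)
  mNP <- refineLongestEdge(refineLongestEdge(m0, project = FALSE),
                           project = FALSE)
  expect_lt(abs(area(mNP) - a0) / a0, 1e-12)
  trueArea <- pi * (3.5e-3^2 - 3e-3^2)
  mP <- m0; areas <- a0
  for (i in 1:3) { mP <- refineLongestEdge(mP); areas <- c(areas, area(mP)) }
  expect_true(all(diff(areas) >= 0))
  expect_true(all(abs(areas - trueArea) / trueArea <
                  abs(a0 - trueArea) / trueArea + 1e-12))
})

test_that("mesh quality survives three refinements", {
  m0 <- buildAnnulusMesh(domainGeometry(), 200, seed = 5)
  m3 <- refineLongestEdge(refineLongestEdge(refineLongestEdge(m0)))
  expect_gte(minMeshAngle(m3), minMeshAngle(m0) / 2)
})

test_that("degenerate elements are rejected", {
  nodes <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1))
  expect_error(
    new("TriMesh", nodes = nodes,
        elements = matrix(c(1L, 2L, 3L), 1),   # collinear
        boundaryTag = rep("interior", 4), level = 0L,
        parentNodeMap = integer(0), geometry = domainGeometry()),
    "degenerate")
})

test_that("commonNodes composes the lineage and matches coordinates", {
  meshes <- refinementHierarchy(domainGeometry(), 200, 3, seed = 2)
  idp <- commonNodes(meshes[[1]], meshes[[1]])
  expect_identical(idp[, "coarse"], idp[, "fine"])
  p03 <- commonNodes(meshes[[1]], meshes[[4]])
  expect_equal(nrow(p03), nrow(nodeCoords(meshes[[1]])))
  # brute-force nearest-coordinate oracle
  set.seed(1)
  c0 <- nodeCoords(meshes[[1]]); c3 <- nodeCoords(meshes[[4]])
  for (i in sample(nrow(c0), 25)) {
    d2 <- (c3[, 1] - c0[i, 1])^2 + (c3[, 2] - c0[i, 2])^2
    expect_equal(unname(p03[i, "fine"]), which.min(d2))
    expect_equal(min(d2), 0)
  }
  # unrelated meshes fail
  other <- buildAnnulusMesh(domainGeometry(), 200, seed = 9)
  expect_error(commonNodes(other, meshes[[4]]), "lineage")
  expect_error(commonNodes(meshes[[2]], meshes[[1]]), "lineage")
})

test_that("MSH and VTK round-trips preserve the mesh", {
  mesh <- tinyMesh()
  msh <- tempfile(fileext = ".msh")
  writeMeshMsh(mesh, msh)
  back <- readMeshMsh(msh)
  expect_equal(nodeCoords(back), nodeCoords(mesh))
  expect_identical(meshElements(back), meshElements(mesh))
  expect_identical(boundaryTags(back), boundaryTags(mesh))
  vtk <- tempfile(fileext = ".vtk")
  writeMeshVtk(mesh, vtk, pointData = list(C = seq_len(64 + 0) * 0))
  lines <- readLines(vtk)
  expect_identical(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_true(any(grepl("^POINT_DATA", lines)))
})
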