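# Plain-text interchange: Gmsh MSH 2.2 ASCII and legacy VTK for meshes,
# CSV tables for fields, features and training sets, YAML/JSON for
# experiment configuration.

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary tags are stored as the elements' physical group: 1-node point
#' elements with physical tag 1 (mural) or 2 (perivascular), triangles
#' with physical tag 0.
#'
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeMeshMsh <- function(mesh, path) {
  n <- nrow(mesh@nodes); m <- nrow(mesh@elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(n),
                     mesh@nodes[, 1L], mesh@nodes[, 2L]), con)
  writeLines(c("$EndNodes", "$Elements"), con)
  bnd <- which(mesh@boundaryTag != "interior")
  writeLines(as.character(length(bnd) + m), con)
  if (length(bnd)) {
    phys <- ifelse(mesh@boundaryTag[bnd] == "mural", 1L, 2L)
    writeLines(sprintf("%d 15 2 %d %d %d", seq_along(bnd), phys, phys,
                       bnd), con)
  }
  writeLines(sprintf("%d 2 2 0 %d %d %d %d", length(bnd) + seq_len(m),
                     mesh@level, mesh@elements[, 1L],
                     mesh@elements[, 2L], mesh@elements[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh written by \code{\link{writeMeshMsh}}
#'
#' @param path MSH 2.2 ASCII file
#' @param geometry the \code{\linkS4class{DomainGeometry}} of the mesh
#'   (MSH does not store it); inferred from the node radii when omitted
#' @return a \code{\linkS4class{TriMesh}} (level and lineage are not
#'   recoverable from the file; level is taken from the triangle
#'   geometric tag)
#' @export
readMeshMsh <- function(path, geometry = NULL) {
  lines <- readLines(path)
  sec <- function(tag) which(lines == tag)
  i0 <- sec("$Nodes"); i1 <- sec("$EndNodes")
  n <- as.integer(lines[i0 + 1L])
  nod <- utils::read.table(text = lines[(i0 + 2L):(i1 - 1L)])
  nodes <- as.matrix(nod[order(nod[[1L]]), 2:3])
  dimnames(nodes) <- NULL
  e0 <- sec("$Elements"); e1 <- sec("$EndElements")
  rows <- strsplit(lines[(e0 + 2L):(e1 - 1L)], " ", fixed = TRUE)
  tags <- rep("interior", n)
  elems <- list(); lev <- 0L
  for (r in rows) {
    r <- as.integer(r)
    if (r[2L] == 15L) {
      tags[r[length(r)]] <- if (r[4L] == 1L) "mural" else "perivascular"
    } else if (r[2L] == 2L) {
      lev <- r[5L]
      elems[[length(elems) + 1L]] <- r[seq(length(r) - 2L, length(r))]
    }
  }
  elems <- do.call(rbind, elems)
  if (is.null(geometry)) {
    rr <- sqrt(rowSums(nodes^2))
    Rin <- min(rr[tags == "mural"]); Rout <- max(rr[tags == "perivascular"])
    geometry <- domainGeometry(Rin, Rout - Rin)
  }
  new("TriMesh", nodes = nodes, elements = elems, boundaryTag = tags,
      level = as.integer(lev), parentNodeMap = integer(0),
      geometry = geometry)
}

#' Write a mesh (and optional nodal fields) in legacy VTK ASCII format
#'
#' @param mesh a \code{\linkS4class{TriMesh}}
#' @param path output file
#' @param pointData optional named list of per-node numeric vectors
#' @return invisibly, \code{path}
#' @export
writeMeshVtk <- function(mesh, path, pointData = list()) {
  n <- nrow(mesh@nodes); m <- nrow(mesh@elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "meshlift mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh@nodes[, 1L],
                     mesh@nodes[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh@elements[, 1L] - 1L,
                     mesh@elements[, 2L] - 1L,
                     mesh@elements[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  tagNum <- match(mesh@boundaryTag,
                  c("interior", "mural", "perivascular")) - 1L
  pointData <- c(list(boundary_tag = tagNum), pointData)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(pointData)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", pointData[[nm]]), con)
  }
  invisible(path)
}

#' Write a concentration field as a CSV node table
#'
#' Columns: node_id, x, y, C, B.
#'
#' @param field a \code{\linkS4class{ConcentrationField}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeFieldCsv <- function(field, path) {
  df <- data.frame(node_id = seq_along(field@C),
                   x = field@mesh@nodes[, 1L],
                   y = field@mesh@nodes[, 2L],
                   C = field@C, B = field@B)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a concentration field from a CSV node table onto a mesh
#'
#' Accepts tables written by \code{\link{writeFieldCsv}} or any external
#' solver's (x, y, C[, B]) node table whose coordinates match the mesh
#' nodes exactly.
#'
#' @param path CSV file
#' @param mesh the \code{\linkS4class{TriMesh}} the field belongs to
#' @param time field time stamp (s)
#' @return a \code{\linkS4class{ConcentrationField}}
#' @export
readFieldCsv <- function(path, mesh, time = NA_real_) {
  df <- utils::read.csv(path)
  n <- nrow(mesh@nodes)
  if (nrow(df) != n)
    stop("alignment error: field table row count does not match mesh")
  d2 <- (df$x - mesh@nodes[, 1L])^2 + (df$y - mesh@nodes[, 2L])^2
  if (max(d2) > 1e-24)
    stop("alignment error: node coordinates do not match the mesh")
  B <- if ("B" %in% names(df)) df$B else rep(0, n)
  newConcentrationField(mesh = mesh, C = df$C, B = B,
      time = as.numeric(time))
}

#' Write a feature table or training set as CSV
#'
#' Header: node_id, d_1..d_J, yn_1..yn_J, y_self[, target].
#'
#' @param x a \code{\linkS4class{NeighborhoodFeatureTable}} or
#'   \code{\linkS4class{TrainingSet}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeFeaturesCsv <- function(x, path) {
  df <- data.frame(node_id = x@nodeIds, x@X, check.names = FALSE)
  if (is(x, "TrainingSet")) df$target <- x@y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' YAML or JSON; the structure mirrors
#' \code{\link{defaultExperimentConfig}} and missing entries take the
#' defaults at run time.
#'
#' @param path configuration file (.yaml/.yml/.json)
#' @return configuration list
#' @export
readExperimentConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
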