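# Orchestration of the fidelity-augmentation experiment: simulate the
# refinement hierarchy, build neighbourhood features, train the
# level-0 -> level-1 surrogate, deploy it on level-1 features, and
# evaluate against the level-3 truth with k-fold/shuffled
# cross-validation and RMSE references between refinement levels.

#' Root-mean-square error
#'
#' @param a,b numeric vectors of equal length
#' @return \code{sqrt(mean((a - b)^2))}
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25/2)
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("shape error: rmse needs equal-length, non-empty vectors")
  sqrt(mean((a - b)^2))
}

#' Cross-validation configuration
#'
#' @param k fold count (default 5)
#' @param s shuffle count (default 10)
#' @param seed base seed; shuffle i uses \code{seed + i}
#' @return a \code{\linkS4class{CVConfig}}
#' @export
cvConfig <- function(k = 5L, s = 10L, seed = 1L) {
  new("CVConfig", k = as.integer(k), s = as.integer(s),
      seed = as.integer(seed))
}

fieldValues <- function(field, outputKind) {
  if (outputKind == "free") field@C else field@B
}

#' Reference RMSEs between refinement levels
#'
#' \code{rmse03}: RMSE between the level-0 and level-3 solutions over the
#' level-0 node set (exact through node nesting); \code{rmse13}: likewise
#' between levels 1 and 3 over the level-1 node set. These are the
#' discretization-error references the surrogate is judged against.
#'
#' @param fields list of \code{\linkS4class{ConcentrationField}}, one per
#'   refinement level (>= 4 levels)
#' @param outputKind \code{"free"} or \code{"bound"}
#' @return list with \code{rmse03} and \code{rmse13}
#' @export
referenceRmses <- function(fields, outputKind = c("free", "bound")) {
  outputKind <- match.arg(outputKind)
  if (length(fields) < 4L)
    stop("pipeline error: need fields for levels 0..3")
  f0 <- fields[[1L]]; f1 <- fields[[2L]]; f3 <- fields[[4L]]
  p03 <- commonNodes(f0@mesh, f3@mesh)
  p13 <- commonNodes(f1@mesh, f3@mesh)
  y0 <- fieldValues(f0, outputKind); y1 <- fieldValues(f1, outputKind)
  y3 <- fieldValues(f3, outputKind)
  list(rmse03 = rmse(y0[p03[, "coarse"]], y3[p03[, "fine"]]),
       rmse13 = rmse(y1[p13[, "coarse"]], y3[p13[, "fine"]]))
}

canonicalOrder <- function(coords) order(coords[, 1L], coords[, 2L])

#' k-fold, shuffled cross-validation of the surrogate
#'
#' Rows are put in a canonical coordinate order (so results do not depend
#' on node storage order), then for each shuffle the rows are randomly
#' partitioned into k folds of near-equal size (sizes differ by at most
#' one); the model is fitted on k-1 folds and scored by RMSE on the held
#' out fold. Shuffle i seeds the partition with \code{seed + i}.
#'
#' @param train a \code{\linkS4class{TrainingSet}}
#' @param cv a \code{\linkS4class{CVConfig}}
#' @param mode,budget,bounds,groups passed to \code{\link{gpFit}}
#' @return list with matrix \code{folds} (s x k raw RMSEs) and scalar
#'   \code{mean}
#' @export
crossValidate <- function(train, cv = cvConfig(), mode = "grouped",
                          budget = 500, bounds = NULL, groups = NULL) {
  l <- nrow(train@X)
  if (l < cv@k) stop("parameter error: fewer samples than folds")
  ord <- if (nrow(train@coords)) canonicalOrder(train@coords)
         else seq_len(l)
  X <- train@X[ord, , drop = FALSE]
  y <- train@y[ord]
  out <- matrix(NA_real_, cv@s, cv@k)
  for (sh in seq_len(cv@s)) {
    set.seed(cv@seed + sh)
    perm <- sample.int(l)
    foldOf <- integer(l)
    foldOf[perm] <- rep(seq_len(cv@k), length.out = l)
    for (fold in seq_len(cv@k)) {
      hold <- which(foldOf == fold)
      fit <- gpFit(list(X = X[-hold, , drop = FALSE], y = y[-hold]),
                   mode = mode, budget = budget, bounds = bounds,
                   groups = groups)
      pred <- gpPredict(fit$model, X[hold, , drop = FALSE])
      out[sh, fold] <- rmse(pred$mean, y[hold])
    }
  }
  list(folds = out, mean = mean(out))
}

#' Default configuration of the fidelity experiment
#'
#' The documented problem size of the package's end-to-end experiment: a
#' level-0 annulus mesh of about 600 elements refined three times, the
#' zotarolimus transport parameters, fields extracted at 1 h, the
#' cityblock/euclidean/mahalanobis metric sweep over J in {10, 25, 50},
#' 5-fold cross-validation with 3 shuffles, grouped-theta fits with a
#' 300-evaluation DIRECT budget.
#'
#' @param seed base seed for meshing and cross-validation
#' @return nested configuration list accepted by
#'   \code{\link{runExperiment}}
#' @export
defaultExperimentConfig <- function(seed = 1L) {
  list(
    geometry = list(R = 3e-3, W = 5e-4),
    mesh = list(targetElements = 600L, refinements = 3L, seed = seed,
                project = TRUE),
    transport = list(),                 # overrides of transportParameters()
    solver = list(rtol = 1e-9, atol = 1e-6, tEnd = 3600, nSave = 121L),
    metrics = "cityblock",
    Js = c(10L, 25L, 50L),
    outputKinds = c("free", "bound"),
    cv = list(k = 5L, s = 3L, seed = seed),
    fit = list(mode = "grouped", budget = 300L),
    deployBudget = 300L
  )
}

#' Run the full fidelity-augmentation experiment
#'
#' Executes, from a single configuration list: (1) mesh generation and
#' three longest-edge refinements; (2) the transient transport solve at
#' every level; (3) neighbourhood-feature construction at levels 0 and 1;
#' (4) surrogate training on level-0 features with level-1 targets,
#' cross-validated; (5) deployment of a model refit on all pairs to the
#' level-1 features; (6) RMSE of the deployed prediction against the
#' level-3 truth at the level-1 nodes, next to the reference
#' discretization errors rmse03 and rmse13 -- for every (output kind,
#' metric, J) cell.
#'
#' @param config configuration list, see
#'   \code{\link{defaultExperimentConfig}}; missing entries take the
#'   defaults
#' @param fields optional precomputed per-level fields (skips the solves;
#'   used to plug in external solutions or analytic closures)
#' @param verbose print stage progress?
#' @return a \code{\linkS4class{FidelityReport}}
#' @export
runExperiment <- function(config = defaultExperimentConfig(),
                          fields = NULL, verbose = FALSE) {
  cfg <- utils::modifyList(defaultExperimentConfig(), config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline error in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  geom <- domainGeometry(cfg$geometry$R, cfg$geometry$W)
  say("meshing: target %d elements, %d refinements",
      cfg$mesh$targetElements, cfg$mesh$refinements)
  meshes <- stage("mesh", refinementHierarchy(
    geom, cfg$mesh$targetElements, cfg$mesh$refinements,
    seed = cfg$mesh$seed, project = cfg$mesh$project))
  params <- stage("parameters",
                  do.call(transportParameters, cfg$transport))
  if (is.null(fields)) {
    fields <- vector("list", length(meshes))
    for (i in seq_along(meshes)) {
      say("solving level %d (%d nodes)", i - 1L, nrow(meshes[[i]]@nodes))
      st <- do.call(solverSettings, cfg$solver)
      fields[[i]] <- stage(sprintf("solve L%d", i - 1L),
                           solveTransient(meshes[[i]], params, st))
    }
  } else {
    meshes <- lapply(fields, function(f) f@mesh)
  }
  cvc <- cvConfig(cfg$cv$k, cfg$cv$s, cfg$cv$seed)
  Jmax <- max(cfg$Js)
  cells <- list(); raw <- list()
  rmse03 <- rmse13 <- numeric(0)
  for (kind in cfg$outputKinds) {
    refs <- stage("reference RMSEs", referenceRmses(fields, kind))
    rmse03[kind] <- refs$rmse03
    rmse13[kind] <- refs$rmse13
  }
  for (metric in cfg$metrics) {
    say("neighbours (%s): levels 0 and 1, Jmax = %d", metric, Jmax)
    nn0 <- stage("neighbours L0",
                 nearestNeighbors(meshes[[1L]], Jmax, metric))
    nn1 <- stage("neighbours L1",
                 nearestNeighbors(meshes[[2L]], Jmax, metric))
    for (J in cfg$Js) {
      sub <- function(nn) list(index = nn$index[, seq_len(J), drop = FALSE],
                               distance = nn$distance[, seq_len(J),
                                                      drop = FALSE])
      for (kind in cfg$outputKinds) {
        say("cell: %s / %s / J = %d", kind, metric, J)
        feat0 <- buildFeatureTable(fields[[1L]], sub(nn0), J, metric,
                                   kind)
        train <- buildTrainingSet(feat0, fields[[2L]])
        cvRes <- stage("cross-validation",
                       crossValidate(train, cvc, mode = cfg$fit$mode,
                                     budget = cfg$fit$budget,
                                     bounds = cfg$fit$bounds))
        # deployment: refit on all level-0 -> level-1 pairs,
        # predict from the level-1 features, score against level-3 truth
        ordAll <- canonicalOrder(train@coords)
        deploy <- stage("deployment fit", gpFit(
          list(X = train@X[ordAll, , drop = FALSE], y = train@y[ordAll]),
          mode = cfg$fit$mode, budget = cfg$deployBudget,
          bounds = cfg$fit$bounds))
        feat1 <- buildFeatureTable(fields[[2L]], sub(nn1), J, metric,
                                   kind)
        pred <- gpPredict(deploy$model, feat1@X)
        p13 <- commonNodes(meshes[[2L]], meshes[[4L]])
        truth <- fieldValues(fields[[4L]], kind)[p13[, "fine"]]
        predRmse <- rmse(pred$mean[p13[, "coarse"]], truth)
        key <- sprintf("%s_%s_J%d", kind, metric, J)
        cells[[key]] <- data.frame(
          outputKind = kind, metric = metric, J = J,
          rmseCvMean = cvRes$mean, rmsePredVsTruth = predRmse,
          stringsAsFactors = FALSE)
        raw[[key]] <- list(cvFolds = cvRes$folds,
                           thetaHat = deploy$mle@thetaHat,
                           evals = deploy$mle@evals)
      }
    }
  }
  new("FidelityReport", rmse03 = rmse03, rmse13 = rmse13,
      cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
      raw = raw, config = cfg)
}

#' Sweep distance metrics and neighbour counts
#'
#' Runs the experiment over a metric-by-J grid and returns one tidy row
#' per cell with the cross-validated and deployed-prediction RMSEs next
#' to the reference errors.
#'
#' @param metrics character vector of distance metrics
#' @param Js integer vector of neighbour counts
#' @param config base configuration (metrics/Js entries are overridden)
#' @param fields optional precomputed fields, see
#'   \code{\link{runExperiment}}
#' @return data.frame with columns outputKind, metric, J, rmseCvMean,
#'   rmsePredVsTruth, rmse03, rmse13
#' @export
sweepFidelity <- function(metrics, Js, config = defaultExperimentConfig(),
                          fields = NULL) {
  if (!length(metrics) || !length(Js))
    stop("parameter error: metrics and Js must be non-empty")
  bad <- setdiff(metrics, supportedMetrics)
  if (length(bad))
    stop(sprintf("parameter error: unsupported metric '%s'", bad[1L]))
  config$metrics <- metrics
  config$Js <- as.integer(Js)
  res <- runExperiment(config, fields = fields)
  cells <- res@cells
  cells$rmse03 <- res@rmse03[cells$outputKind]
  cells$rmse13 <- res@rmse13[cells$outputKind]
  rownames(cells) <- NULL
  cells
}

setMethod("show", "FidelityReport", function(object) {
  cat("FidelityReport\n")
  for (kind in names(object@rmse03))
    cat(sprintf("  %s drug: rmse03 = %.6g, rmse13 = %.6g\n", kind,
                object@rmse03[kind], object@rmse13[kind]))
  cat(sprintf("  %d surrogate cells:\n", nrow(object@cells)))
  print(object@cells, row.names = FALSE)
})

#' Serialize a fidelity report
#'
#' Writes \code{report.json} (references, cells, resolved configuration)
#' and \code{cells.csv} (tidy per-cell table) into a directory. The JSON
#' is deterministic for a deterministic report.
#'
#' @param report a \code{\linkS4class{FidelityReport}}
#' @param dir output directory (created if needed)
#' @return invisibly, the path to the JSON file
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- report@cells
  cells$rmse03 <- report@rmse03[cells$outputKind]
  cells$rmse13 <- report@rmse13[cells$outputKind]
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  obj <- list(rmse03 = as.list(report@rmse03),
              rmse13 = as.list(report@rmse13),
              cells = cells,
              config = report@config)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
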