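.configError <- function(msg)
  stop(errorCondition(msg, class = c("riskSOM_config_error", "error",
                                     "condition")))

.PIPELINE_STAGES <- c("ri", "interpolate", "som", "cluster", "stats")

#' Default pipeline configuration
#'
#' Returns the full configuration list for [runPipeline()] with its
#' defaults filled in. Unknown keys in a user configuration are
#' rejected.
#'
#' @param outDir output directory.
#' @param seed global seed; every stage derives its own child seed from
#'   it, so the whole run is reproducible.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(outDir = "risksom-out", seed = 1L) {
  list(
    input = list(samples = NULL, towns = NULL, covariates = NULL,
                 panel = NULL),
    simulate = list(nTowns = 253L, nSamples = 1018L,
                    sampleFreeArchetypes = integer(0)),
    kriging = list(cellSize = 0.01, family = "spherical", nLags = 12L,
                   maxDist = NULL, fields = "all"),
    som = list(sizes = NULL, nRows = NULL, nCols = NULL,
               lattice = "hexagonal", init = "linear",
               roughEpochs = 10L, finetuneEpochs = 20L),
    cluster = list(kRange = 2:10, nRestarts = 10L),
    stats = list(posthoc = "tukey", alpha = 0.05),
    seed = as.integer(seed), outDir = outDir,
    stages = .PIPELINE_STAGES)
}

.mergeConfig <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .configError(sprintf("unknown config key(s)%s: %s",
                         if (nzchar(path)) paste0(" under ", path) else "",
                         paste(unknown, collapse = ", ")))
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      .mergeConfig(user[[k]], defaults[[k]], k)
    else user[[k]]
  }
  out
}

#' Assemble the SOM feature matrix
#'
#' Joins the 19 town covariates with the kriged-and-aggregated town risk
#' index into the cases x 20 matrix the SOM trains on. Towns without an
#' RI value (no grid coverage or no samples nearby) are dropped with a
#' warning; an id mismatch above 5\% aborts.
#'
#' @param covariates data.frame with \code{unit_id} and the covariate
#'   columns.
#' @param townRI named numeric vector of town RI values.
#' @return data.frame: \code{unit_id}, the covariates, and \code{RI}.
#' @export
assembleFeatureMatrix <- function(covariates, townRI) {
  covariates <- as.data.frame(covariates)
  if (!"unit_id" %in% names(covariates))
    stop("covariates must have a 'unit_id' column")
  ids <- covariates$unit_id
  matched <- ids %in% names(townRI)
  if (mean(matched) < 0.95)
    stop(sprintf("id mismatch: %.0f%% of towns lack an RI value",
                 100 * mean(!matched)))
  ri <- rep(NA_real_, length(ids))
  ri[matched] <- townRI[ids[matched]]
  drop <- !is.finite(ri)
  if (any(drop))
    warning(sprintf("%d town(s) without RI dropped from feature matrix: %s",
                    sum(drop),
                    paste(utils::head(ids[drop], 5L), collapse = ", ")))
  out <- covariates[!drop, , drop = FALSE]
  out$RI <- ri[!drop]
  rownames(out) <- NULL
  out
}

.writeCsv <- function(x, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(x, p, row.names = FALSE)
  p
}

#' Run the full risk-pattern pipeline
#'
#' Executes, in order: input loading (or synthetic-scene simulation when
#' no input paths are configured), per-sample risk scoring, kriging of
#' the risk surfaces and zonal aggregation to towns, SOM map-size scan
#' and training, codebook clustering with Davies-Bouldin k selection and
#' label projection, and cluster characterization tables. Every stage
#' writes its artifacts under \code{outDir} and the run ends with a JSON
#' manifest of seed, versions and per-file checksums. A stage failure
#' aborts with the stage name; artifacts of completed stages are
#' retained.
#'
#' @param config configuration list (see [defaultPipelineConfig()]);
#'   partial lists are merged over the defaults, unknown keys rejected.
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = list()) {
  cfg <- .mergeConfig(config, defaultPipelineConfig())
  stages <- cfg$stages
  if (!all(stages %in% .PIPELINE_STAGES))
    .configError(sprintf("unknown stage(s): %s",
                         paste(setdiff(stages, .PIPELINE_STAGES),
                               collapse = ", ")))
  upto <- max(match(stages, .PIPELINE_STAGES))
  if (!identical(stages, .PIPELINE_STAGES[seq_len(upto)]))
    .configError("stages must be a contiguous prefix of: ri, interpolate, som, cluster, stats")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  res <- list(config = cfg)
  files <- character(0)
  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = unique(c(class(e)[1L], "riskSOM_stage_error", "error",
                         "condition")))))
  }

  # ---- inputs -----------------------------------------------------------
  runStage("load", function() {
    if (is.null(cfg$input$samples)) {
      scene <- simulateScene(nTowns = cfg$simulate$nTowns,
                             nSamples = cfg$simulate$nSamples,
                             seed = .stringSeed("simulate", seed),
                             sampleFreeArchetypes =
                               cfg$simulate$sampleFreeArchetypes)
      files <<- c(files, sceneToFiles(scene, file.path(cfg$outDir,
                                                       "scene")))
      res$scene <<- scene
      res$samples <<- scene@samples
      res$towns <<- scene@towns
      res$covariates <<- scene@covariates
      res$panel <<- scene@panel
    } else {
      res$samples <<- readSamples(cfg$input$samples)
      res$towns <<- readUnitsGeoJSON(cfg$input$towns)
      res$covariates <<- utils::read.csv(cfg$input$covariates,
                                         stringsAsFactors = FALSE)
      res$panel <<- readPanel(cfg$input$panel)
    }
    invisible(NULL)
  })

  # ---- risk scoring -----------------------------------------------------
  runStage("ri", function() {
    res$risk <<- scoreSamples(res$samples, res$panel)
    files <<- c(files, .writeCsv(res$risk, cfg$outDir, "risk.csv"))
  })
  if (upto < 2L) return(invisible(c(res, list(files = files))))

  # ---- kriging + zonal aggregation -------------------------------------
  runStage("interpolate", function() {
    fields <- if (identical(cfg$kriging$fields, "all"))
      c(paste0("cf_", .PANEL_METALS), "ri") else cfg$kriging$fields
    bb <- do.call(rbind, lapply(res$towns@geometry, .unitBBox))
    cs <- cfg$kriging$cellSize
    x0 <- min(bb[, "xmin"]); y0 <- min(bb[, "ymin"])
    grid <- GridField(x0, y0, cs,
                      ceiling((max(bb[, "ymax"]) - y0) / cs),
                      ceiling((max(bb[, "xmax"]) - x0) / cs))
    townTab <- data.frame(unit_id = res$towns@unitId,
                          stringsAsFactors = FALSE)
    for (f in fields) {
      v <- res$risk[[f]]
      ev <- empiricalVariogram(res$samples$lon, res$samples$lat, v,
                               nLags = cfg$kriging$nLags,
                               maxDist = cfg$kriging$maxDist)
      vm <- fitVariogram(ev, family = cfg$kriging$family)
      g <- suppressWarnings(krigeGrid(res$samples$lon, res$samples$lat,
                                      v, vm, grid = grid))
      files <<- c(files, {
        p <- file.path(cfg$outDir, sprintf("grid_%s.csv", f))
        writeGridCSV(g, p); p
      })
      zm <- zonalMean(g, res$towns)
      townTab[[f]] <- unname(zm[townTab$unit_id])
    }
    res$townIndices <<- townTab
    files <<- c(files, .writeCsv(townTab, cfg$outDir,
                                 "town_indices.csv"))
    res$features <<- assembleFeatureMatrix(
      res$covariates, stats::setNames(townTab$ri, townTab$unit_id))
    files <<- c(files, .writeCsv(res$features, cfg$outDir,
                                 "feature_matrix.csv"))
  })
  if (upto < 3L) return(invisible(c(res, list(files = files))))

  # ---- SOM --------------------------------------------------------------
  runStage("som", function() {
    X <- res$features[, setdiff(names(res$features), "unit_id")]
    somSeed <- .stringSeed("som", seed)
    if (!is.null(cfg$som$nRows)) {
      model <- trainSOM(X, cfg$som$nRows, cfg$som$nCols,
                        lattice = cfg$som$lattice, init = cfg$som$init,
                        roughEpochs = cfg$som$roughEpochs,
                        finetuneEpochs = cfg$som$finetuneEpochs,
                        seed = somSeed)
      scan <- data.frame(nRows = cfg$som$nRows, nCols = cfg$som$nCols,
                         units = cfg$som$nRows * cfg$som$nCols,
                         qe = quantizationError(model, X),
                         te = topographicError(model, X))
    } else {
      sizes <- if (is.null(cfg$som$sizes)) defaultMapSizes()
               else cfg$som$sizes
      sc <- mapSizeScan(X, sizes, lattice = cfg$som$lattice,
                        init = cfg$som$init,
                        roughEpochs = cfg$som$roughEpochs,
                        finetuneEpochs = cfg$som$finetuneEpochs,
                        seed = somSeed)
      model <- sc$model
      scan <- sc$scan
    }
    res$mapQuality <<- scan
    res$som <<- model
    files <<- c(files, .writeCsv(scan, cfg$outDir, "map_quality.csv"))
    cb <- codebookDenormalized(model)
    files <<- c(files, .writeCsv(
      data.frame(unit = seq_len(nrow(cb)), cb), cfg$outDir,
      "codebook.csv"))
    um <- uMatrix(model)
    files <<- c(files, .writeCsv(um$edges, cfg$outDir,
                                 "umatrix_edges.csv"))
    mj <- file.path(cfg$outDir, "som_model.json")
    jsonlite::write_json(
      list(nRows = model@nRows, nCols = model@nCols,
           lattice = model@lattice, varNames = model@varNames,
           normCenter = as.list(model@normCenter),
           normScale = as.list(model@normScale),
           config = model@config[!vapply(model@config, is.null,
                                         logical(1))]),
      mj, auto_unbox = TRUE, digits = NA)
    files <<- c(files, mj)
  })
  if (upto < 4L) return(invisible(c(res, list(files = files))))

  # ---- clustering -------------------------------------------------------
  runStage("cluster", function() {
    sel <- selectK(codebook(res$som), kRange = cfg$cluster$kRange,
                   seed = .stringSeed("cluster", seed),
                   nRestarts = cfg$cluster$nRestarts)
    res$clusters <<- sel
    X <- res$features[, setdiff(names(res$features), "unit_id")]
    towns <- projectLabels(res$som, sel$labels, X)
    res$townClusters <<- stats::setNames(towns, res$features$unit_id)
    files <<- c(files,
                .writeCsv(sel$scan, cfg$outDir, "dbi_scan.csv"),
                .writeCsv(data.frame(unit = seq_along(sel$labels),
                                     cluster = sel$labels),
                          cfg$outDir, "unit_labels.csv"),
                .writeCsv(data.frame(unit_id = res$features$unit_id,
                                     cluster = towns),
                          cfg$outDir, "town_labels.csv"))
  })
  if (upto < 5L) return(invisible(c(res, list(files = files))))

  # ---- cluster characterization ----------------------------------------
  runStage("stats", function() {
    feats <- res$features
    labs <- res$townClusters[feats$unit_id]
    clusters <- seq_len(res$clusters$k)
    covSummary <- clusterSummary(feats, labs, clusters = clusters,
                                 method = cfg$stats$posthoc,
                                 alpha = cfg$stats$alpha)
    files <<- c(files, .writeCsv(
      data.frame(variable = rownames(covSummary$formatted),
                 covSummary$formatted, check.names = FALSE),
      cfg$outDir, "cluster_covariates.csv"))
    # sample-level metal concentrations by the cluster of their town
    smp <- res$samples
    smpClust <- res$townClusters[smp$town_id]
    keep <- !is.na(smpClust)
    metalSummary <- clusterSummary(
      smp[keep, .PANEL_METALS], smpClust[keep], clusters = clusters,
      method = cfg$stats$posthoc, alpha = cfg$stats$alpha)
    files <<- c(files, .writeCsv(
      data.frame(element = rownames(metalSummary$formatted),
                 metalSummary$formatted, check.names = FALSE),
      cfg$outDir, "cluster_metals.csv"))
    ct <- correlationTable(
      feats[, setdiff(names(feats), c("unit_id", "RI"))],
      feats$RI, labs)
    files <<- c(files, .writeCsv(
      data.frame(variable = rownames(ct$rho),
                 formatCorrelationTable(ct), check.names = FALSE),
      cfg$outDir, "cluster_correlations.csv"))
    res$covSummary <<- covSummary
    res$metalSummary <<- metalSummary
    res$correlations <<- ct
  })

  # ---- manifest ---------------------------------------------------------
  manifest <- list(
    seed = seed,
    package = as.character(utils::packageVersion("riskSOM")),
    rversion = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    checksums = as.list(tools::md5sum(sort(unique(files)))))
  mp <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$files <- c(sort(unique(files)), mp)
  invisible(res)
}
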