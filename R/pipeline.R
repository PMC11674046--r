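#' @include stats-report.R localization-score.R presets.R imaging-io.R
NULL

#' Default pipeline configuration
#'
#' The single user-facing configuration surface of
#' \code{\link{runPipeline}}.  All analysis defaults (positivity threshold
#' 1.5, minimum 25 cells per experiment, pooled Student's t, star map with
#' strict inequalities) live here and are echoed into the report.
#'
#' @param conditions character vector of preset names (see
#'   \code{\link{conditionPresets}}) or a named list of preset-shaped
#'   lists.
#' @param reference reference condition.
#' @param nExperiments independent experiments per condition.
#' @param nCells,imageSize scene size per experiment.
#' @param mode "large_cytoplasm" or "clustered".
#' @param ratioThreshold,minContrast,minCells,yfpWindow,tVariant,holm
#'   analysis settings (see the stage functions).
#' @param keepImages also write every simulated scene as TIFF + ground
#'   truth CSV.
#' @return a named list.
#' @export
pipelineConfig <- function(conditions = c("wt", "a541k", "f572a", "k568a",
                                          "k568q", "k568r", "s1055a",
                                          "s1055d", "q742t"),
                           reference = "wt",
                           nExperiments = 3L,
                           nCells = 60L,
                           imageSize = c(360L, 360L),
                           mode = "large_cytoplasm",
                           ratioThreshold = 1.5,
                           minContrast = 2,
                           minCells = 25,
                           yfpWindow = c(60, 5000),
                           tVariant = "pooled",
                           holm = FALSE,
                           keepImages = FALSE) {
    list(conditions = conditions, reference = reference,
         nExperiments = as.integer(nExperiments),
         nCells = as.integer(nCells), imageSize = as.integer(imageSize),
         mode = mode, ratioThreshold = ratioThreshold,
         minContrast = minContrast, minCells = minCells,
         yfpWindow = yfpWindow, tVariant = tVariant, holm = holm,
         keepImages = keepImages)
}

.validatePipelineConfig <- function(config) {
    defaults <- pipelineConfig()
    for (nm in names(config))
        if (!nm %in% names(defaults))
            stop("unknown config field: '", nm, "'")
    cfg <- defaults
    cfg[names(config)] <- config
    conds <- cfg$conditions
    if (is.character(conds)) {
        unknown <- setdiff(conds, names(conditionPresets()))
        if (length(unknown))
            stop("unknown preset condition(s): ",
                 paste(unknown, collapse = ", "))
        conds <- setNames(lapply(conds, identity), conds)
    }
    if (is.null(names(conds)) || any(!nzchar(names(conds))))
        stop("config$conditions must be preset names or a named list")
    if (!cfg$reference %in% names(conds))
        stop("config$reference ('", cfg$reference,
             "') is not among config$conditions")
    if (cfg$nExperiments < 1) stop("config$nExperiments must be >= 1")
    if (!cfg$mode %in% c("large_cytoplasm", "clustered"))
        stop("config$mode must be 'large_cytoplasm' or 'clustered'")
    cfg$conditions <- conds
    cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> segment -> score -> export-assay -> report as
#' one reproducible run.  For every condition and experiment index, two
#' scenes are simulated with deterministically derived seeds: a Cajal-body
#' scene (whose cargo channel carries cargo A) and a nucleolus scene
#' (cargo B).  Each scene is segmented and measured, transfected cells are
#' selected, localization scores are computed for both compartments
#' (normalized to the reference), cargo export is assayed per cell with
#' the YFP expression control, and every condition is compared to the
#' reference by Student's t with star labels.
#'
#' Rerunning with the same config and master seed reproduces every output
#' table byte for byte.
#'
#' @param config a list from \code{\link{pipelineConfig}} (possibly
#'   partial: missing fields take defaults) or the path of a YAML file.
#' @param outDir report directory, created if needed.
#' @param masterSeed integer master seed.
#' @return invisibly, a list with \code{measurements}, \code{scores}
#'   (cb/nol), \code{export} (cargoA/cargoB records + expression
#'   controls), \code{comparisons}, \code{qc} and \code{config}.
#' @examples
#' \donttest{
#' out <- runPipeline(list(conditions = c("wt", "a541k"),
#'                         nExperiments = 2L, nCells = 40L,
#'                         imageSize = c(300L, 300L)),
#'                    file.path(tempdir(), "demo_run"), masterSeed = 1L)
#' out$scores$cb
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        masterSeed = 1L) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .validatePipelineConfig(config)
    conds <- names(cfg$conditions)
    clustered <- cfg$mode == "clustered"
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    meas <- list(cb = list(), nol = list())
    qc <- list()
    logLines <- c(sprintf("nucloc run (package version %s)",
                          as.character(packageVersion("nucloc"))),
                  sprintf("master seed: %d", masterSeed),
                  sprintf("conditions: %s", paste(conds, collapse = ", ")),
                  sprintf("ratio threshold: %g | min cells: %g | t variant: %s | mode: %s",
                          cfg$ratioThreshold, cfg$minCells, cfg$tVariant,
                          cfg$mode))
    for (cond in conds) {
        for (kind in c("cb", "nol")) {
            for (e in seq_len(cfg$nExperiments)) {
                seed <- seedForExperiment(masterSeed,
                                          paste(cond, kind, sep = ":"), e)
                params <- presetSceneParams(
                    cfg$conditions[[cond]], kind,
                    base = list(nCells = cfg$nCells,
                                imageSize = cfg$imageSize,
                                clustered = clustered),
                    seed = seed)
                sc <- simulateScene(params)
                res <- measureScene(sc,
                                    ratioThreshold = cfg$ratioThreshold,
                                    minContrast = cfg$minContrast,
                                    yfpWindow = cfg$yfpWindow)
                cells <- res$cells
                if (nrow(cells)) {
                    cells$condition <- cond
                    cells$experiment_id <- sprintf("exp%02d", e)
                    if (clustered)
                        cells <- computeNTotalRatio(cells,
                                                    cargoFieldMean(sc))
                }
                meas[[kind]][[length(meas[[kind]]) + 1L]] <- cells
                tag <- sprintf("%s_%s_exp%02d", cond, kind, e)
                qc[[tag]] <- c(list(seed = seed), res$qc)
                logLines <- c(logLines,
                    sprintf("%s: seed %d, %d nuclei, %d scored, %d no-focus, %d excluded low, %d excluded high",
                            tag, seed, res$qc$nDetected, nrow(cells),
                            res$qc$nNoFocus,
                            res$qc$nExcludedLow %||% 0L,
                            res$qc$nExcludedHigh %||% 0L))
                if (isTRUE(cfg$keepImages)) {
                    writeScene(sceneImage(sc),
                               file.path(outDir, paste0(tag, ".tif")))
                    writeMeasurements(groundTruth(sc),
                                      file.path(outDir,
                                                paste0(tag, "_truth.csv")))
                }
            }
        }
    }
    cbCells <- do.call(rbind, meas$cb)
    nolCells <- do.call(rbind, meas$nol)

    scores <- list(
        cb = suppressWarnings(scorePipeline(
            cbCells, cfg$reference, "cajal_body", cfg$minCells)),
        nol = suppressWarnings(scorePipeline(
            nolCells, cfg$reference, "nucleolus", cfg$minCells)))

    export <- list(
        cargoA = suppressWarnings(assayCondition(
            cbCells, mode = cfg$mode, cargoName = "cargoA",
            reference = cfg$reference, minCells = cfg$minCells,
            tVariant = cfg$tVariant)),
        cargoB = suppressWarnings(assayCondition(
            nolCells, mode = cfg$mode, cargoName = "cargoB",
            reference = cfg$reference, minCells = cfg$minCells,
            tVariant = cfg$tVariant)))

    ratioCol <- if (clustered) "n_total_ratio" else "nc_ratio"
    perCell <- rbind(
        data.frame(condition = cbCells$condition,
                   metric = "cb_ratio", value = cbCells$compartment_ratio),
        data.frame(condition = nolCells$condition,
                   metric = "nol_ratio",
                   value = nolCells$compartment_ratio),
        data.frame(condition = export$cargoA$records$condition,
                   metric = "cargoA_export",
                   value = export$cargoA$records[[ratioCol]]),
        data.frame(condition = export$cargoB$records$condition,
                   metric = "cargoB_export",
                   value = export$cargoB$records[[ratioCol]]),
        data.frame(condition = cbCells$condition,
                   metric = "yfp_expression", value = cbCells$yfp_nuc_mean))
    perExp <- rbind(
        cbind(attr(scores$cb, "provenance")$per_experiment,
              metric = "cb_pct"),
        cbind(attr(scores$nol, "provenance")$per_experiment,
              metric = "nol_pct"))
    cmp <- list()
    for (m in unique(perCell$metric)) {
        sub <- perCell[perCell$metric == m, , drop = FALSE]
        wide <- data.frame(condition = sub$condition)
        wide[[m]] <- sub$value
        cmp[[m]] <- compareAll(wide, cfg$reference, m,
                               variant = cfg$tVariant)
    }
    for (m in unique(perExp$metric)) {
        sub <- perExp[perExp$metric == m, , drop = FALSE]
        wide <- data.frame(condition = sub$condition)
        wide[[m]] <- sub$pct_positive
        cmp[[m]] <- compareAll(wide, cfg$reference, m,
                               variant = cfg$tVariant)
    }
    comparisons <- do.call(rbind, cmp)
    rownames(comparisons) <- NULL
    if (isTRUE(cfg$holm)) {
        comparisons$p_holm <- p.adjust(comparisons$p_value, "holm")
        comparisons$stars_holm <- starsLabel(comparisons$p_holm)
    }

    writeMeasurements(cbCells, file.path(outDir, "measurements_cb.csv"))
    writeMeasurements(nolCells, file.path(outDir, "measurements_nol.csv"))
    writeMeasurements(scores$cb, file.path(outDir, "scores_cb.csv"))
    writeMeasurements(scores$nol, file.path(outDir, "scores_nol.csv"))
    writeMeasurements(export$cargoA$records,
                      file.path(outDir, "export_cargoA.csv"))
    writeMeasurements(export$cargoB$records,
                      file.path(outDir, "export_cargoB.csv"))
    writeMeasurements(export$cargoA$expressionControl,
                      file.path(outDir, "expression_control_cargoA.csv"))
    writeMeasurements(export$cargoB$expressionControl,
                      file.path(outDir, "expression_control_cargoB.csv"))
    writeMeasurements(comparisons, file.path(outDir, "comparisons.csv"))
    cfgOut <- cfg
    cfgOut$conditions <- conds
    jsonlite::write_json(c(cfgOut, list(masterSeed = masterSeed)),
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(qc, file.path(outDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, file.path(outDir, "run_log.txt"))

    invisible(list(measurements = list(cb = cbCells, nol = nolCells),
                   scores = scores, export = export,
                   comparisons = comparisons, qc = qc, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
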