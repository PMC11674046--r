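#' @include scene-sim.R
NULL

#' Bundled simulation presets for receptor variants
#'
#' Named generating-parameter presets emulating the qualitative phenotypes
#' of a panel of nuclear export receptor variants: the reference ("wt"),
#' NES-binding-groove mutants with differentially impaired Cajal-body
#' localization and nucleolar relocation ("a541k" is the
#' separation-of-function case: near-zero CB localization with preserved
#' nucleolar relocation; "f572a" abolishes nucleolar relocation, abolishes
#' export of cargo A and enhances export of cargo B), acetylation-site
#' variants ("k568a", "k568q", "k568r", all impaired), and
#' phosphorylation-site / species-swap variants ("s1055a", "s1055d",
#' "q742t") indistinguishable from the reference.  Two treatment presets
#' are included: "wt_lmb" (compartment localization abolished by the
#' inhibitor) and "wt_tnfa" (cargo retained in the nucleus independently of
#' export activity).
#'
#' All numeric values are illustrative simulation settings chosen to
#' mirror published phenotypes \emph{directionally}; they are not derived
#' from any measured dataset.
#'
#' Each preset is a list with elements \code{cb} and \code{nol} (parameter
#' overrides for the Cajal-body and nucleolus scenes), and \code{cargoA} /
#' \code{cargoB} (log-normal \code{c(median, gsd)} of the true cargo N/C
#' ratio; cargo A is RanBP1-like, cargo B is p65-like).
#'
#' @return named list of presets.
#' @examples
#' names(conditionPresets())
#' conditionPresets()$a541k$cb
#' @export
conditionPresets <- function() {
    pr <- function(cbFrac, cbRatio, nolFrac, nolRatio, ncA, ncB,
                   exportInsensitive = FALSE)
        list(cb = list(fractionPositive = cbFrac,
                       enrichmentRatio = c(cbRatio, 1.3)),
             nol = list(fractionPositive = nolFrac,
                        enrichmentRatio = c(nolRatio, 1.3)),
             cargoA = c(ncA, 1.35), cargoB = c(ncB, 1.35),
             exportInsensitive = exportInsensitive)
    list(
        wt     = pr(0.65, 3.0, 0.75, 2.6, 0.50, 0.50),
        a541k  = pr(0.02, 1.6, 0.65, 2.4, 1.40, 1.40),
        f572a  = pr(0.10, 2.0, 0.02, 1.5, 1.40, 0.25),
        k568a  = pr(0.18, 2.4, 0.03, 1.5, 1.25, 1.20),
        k568q  = pr(0.10, 2.2, 0.13, 1.8, 1.25, 1.20),
        k568r  = pr(0.11, 2.2, 0.06, 1.6, 1.25, 1.20),
        s1055a = pr(0.65, 3.0, 0.75, 2.6, 0.50, 0.50),
        s1055d = pr(0.65, 3.0, 0.75, 2.6, 0.50, 0.50),
        q742t  = pr(0.65, 3.0, 0.75, 2.6, 0.50, 0.50),
        wt_lmb = pr(0.02, 1.3, 0.03, 1.3, 1.50, 1.50),
        wt_tnfa = pr(0.65, 3.0, 0.75, 2.6, 0.50, 2.50,
                     exportInsensitive = TRUE))
}

#' Build SceneParams for one condition and compartment kind
#'
#' Merges a preset (or an explicit override list) into base scene
#' parameters.  The "cb" scene uses Cajal-body compartment geometry and
#' carries cargo A in its cargo channel; the "nol" scene uses nucleolar
#' geometry and carries cargo B.
#'
#' @param condition preset name (see \code{\link{conditionPresets}}) or a
#'   list shaped like one preset entry.
#' @param kind "cb" or "nol".
#' @param base named list of arguments passed to \code{\link{SceneParams}}
#'   before the preset overrides (e.g. \code{nCells}, \code{imageSize}).
#' @param seed integer seed stored in the result.
#' @return a \code{\linkS4class{SceneParams}}.
#' @export
presetSceneParams <- function(condition, kind = c("cb", "nol"),
                              base = list(), seed = 1L) {
    kind <- match.arg(kind)
    preset <- if (is.list(condition)) condition else {
        all <- conditionPresets()
        if (!condition %in% names(all))
            stop("unknown preset: ", condition)
        all[[condition]]
    }
    args <- base
    args$compartmentKind <- if (kind == "cb") "cajal_body" else "nucleolus"
    over <- preset[[kind]]
    args[names(over)] <- over
    args$cargoNCRatio <- if (kind == "cb") preset$cargoA else preset$cargoB
    args$seed <- as.integer(seed)
    do.call(SceneParams, args)
}

#' Generate a full condition x experiment dataset on disk
#'
#' For every condition in the manifest and every experiment index, derives
#' a seed from the master seed (\code{\link{seedForExperiment}}), simulates
#' a scene, and writes the image (multi-page TIFF + sidecar JSON), the
#' ground-truth table (CSV) and a manifest snapshot (JSON) into
#' \code{outDir}.  Rerunning with the same master seed reproduces the
#' ground-truth tables byte for byte.
#'
#' @param manifest list with elements \code{conditions} (named list of
#'   preset names or preset-shaped lists), \code{nExperiments}, and
#'   optionally \code{kind} ("cb" or "nol", default "cb") and \code{base}
#'   (base SceneParams arguments); or the path of a YAML file with that
#'   structure.
#' @param outDir output directory (created if missing).
#' @param masterSeed integer master seed.
#' @return invisibly, a data.frame indexing the written files.
#' @export
makeConditionSuite <- function(manifest, outDir, masterSeed = 1L) {
    if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
    for (f in c("conditions", "nExperiments"))
        if (is.null(manifest[[f]]))
            stop("manifest is missing the '", f, "' field")
    if (is.null(names(manifest$conditions)) ||
        any(!nzchar(names(manifest$conditions))))
        stop("manifest$conditions must be a named list")
    kind <- if (is.null(manifest$kind)) "cb" else manifest$kind
    base <- if (is.null(manifest$base)) list() else manifest$base
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(outDir, 2) != 0)
        stop("output directory is not writable: ", outDir)
    idx <- list()
    for (cond in names(manifest$conditions)) {
        for (e in seq_len(manifest$nExperiments)) {
            seed <- seedForExperiment(masterSeed,
                                      paste(cond, kind, sep = ":"), e)
            params <- presetSceneParams(manifest$conditions[[cond]], kind,
                                        base = base, seed = seed)
            sc <- simulateScene(params)
            stem <- sprintf("%s_exp%02d", cond, e)
            tifPath <- file.path(outDir, paste0(stem, ".tif"))
            writeScene(sc@image, tifPath)
            gtPath <- file.path(outDir, paste0(stem, "_truth.csv"))
            writeMeasurements(groundTruth(sc), gtPath)
            idx[[length(idx) + 1L]] <-
                data.frame(condition = cond, experiment = e, seed = seed,
                           image = tifPath, truth = gtPath)
        }
    }
    idx <- do.call(rbind, idx)
    jsonlite::write_json(
        list(masterSeed = masterSeed, kind = kind,
             conditions = names(manifest$conditions),
             nExperiments = manifest$nExperiments,
             channels = channelRoles()),
        file.path(outDir, "suite_manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    invisible(idx)
}
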