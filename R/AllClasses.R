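#' @include nucloc-package.R
NULL

#' SceneParams: generative description of one synthetic micrograph
#'
#' An S4 container for every parameter of the synthetic fluorescence scene
#' generator.  A scene holds a field of non-overlapping elliptical cells on
#' a constant background; a subpopulation is "transfected" with a
#' YFP-tagged receptor whose nucleoplasmic level is log-normal, and a
#' condition-dependent fraction of transfected cells enriches the YFP
#' signal in an intranuclear compartment (Cajal bodies or nucleoli).  A
#' marker channel labels the compartments of \emph{all} cells, and a cargo
#' channel partitions between nucleus and cytoplasm according to a per-cell
#' nuclear/cytoplasmic ratio.  All intensities are arbitrary units (a.u.).
#'
#' Log-normal parameters are length-2 vectors \code{c(median, gsd)} where
#' \code{gsd} is the geometric standard deviation (> 1, dimensionless).
#'
#' @slot imageSize integer(2), image height and width in pixels.
#' @slot nCells integer(1), number of cells to place.
#' @slot fractionTransfected proportion of cells carrying the YFP receptor.
#' @slot yfpExpression c(median, gsd) of nucleoplasmic YFP level (a.u.).
#' @slot fractionPositive proportion of transfected cells with compartment
#'   enrichment of the YFP channel.
#' @slot enrichmentRatio c(median, gsd) of the true compartment/nucleoplasm
#'   YFP ratio for positive cells (median must be >= 1); negative cells
#'   have ratio exactly 1.
#' @slot compartmentKind "cajal_body" or "nucleolus".
#' @slot nFociRange integer(2), per-nucleus focus count range.
#' @slot focusRadiusRange numeric(2), focus radius range (px).
#' @slot nucleusRadiusRange,cellRadiusRange numeric(2), radius ranges (px).
#' @slot cargoNCRatio c(median, gsd) of the true nuclear/cytoplasmic cargo
#'   ratio of transfected cells.
#' @slot markerEnrichment marker intensity in the compartment relative to
#'   the nucleoplasm (applies to all cells).
#' @slot backgroundLevel,dnaLevel,markerBase,cargoCytoLevel constant
#'   rendering levels (a.u.).
#' @slot yfpCytoFraction cytoplasmic YFP level as a fraction of the
#'   nucleoplasmic level in transfected cells.
#' @slot untransfectedNCRatio fixed cargo N/C ratio of untransfected cells.
#' @slot noise c(poissonScale, gaussianSD): shot noise scale (photons per
#'   a.u.; Inf disables) and additive read noise SD (a.u.).
#' @slot clustered logical; TRUE emulates cell lines growing in clusters
#'   (small cytoplasm, tangent cells) in which cytoplasm cannot be
#'   delineated and only nuclear/total ratios are meaningful.
#' @slot seed integer RNG seed.
#'
#' @seealso \code{\link{SceneParams}} (constructor),
#'   \code{\link{sampleCellPopulation}}, \code{\link{renderScene}}
#' @name SceneParams-class
#' @rdname SceneParams-class
#' @exportClass SceneParams
setClass("SceneParams", representation(
    imageSize = "integer",
    nCells = "integer",
    fractionTransfected = "numeric",
    yfpExpression = "numeric",
    fractionPositive = "numeric",
    enrichmentRatio = "numeric",
    compartmentKind = "character",
    nFociRange = "integer",
    focusRadiusRange = "numeric",
    nucleusRadiusRange = "numeric",
    cellRadiusRange = "numeric",
    cargoNCRatio = "numeric",
    markerEnrichment = "numeric",
    backgroundLevel = "numeric",
    dnaLevel = "numeric",
    markerBase = "numeric",
    cargoCytoLevel = "numeric",
    yfpCytoFraction = "numeric",
    untransfectedNCRatio = "numeric",
    noise = "numeric",
    clustered = "logical",
    seed = "integer"))

.validSceneParams <- function(object) {
    msg <- character()
    chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
    len2 <- function(x) length(x) == 2 && all(is.finite(x))
    chk(length(object@imageSize) == 2 && all(object@imageSize >= 32),
        "imageSize must be two integers >= 32")
    chk(length(object@nCells) == 1 && object@nCells >= 0,
        "nCells must be a single non-negative integer")
    prop <- c(fractionTransfected = object@fractionTransfected,
              fractionPositive = object@fractionPositive)
    chk(all(prop >= 0 & prop <= 1), "proportions must lie in [0, 1]")
    chk(len2(object@yfpExpression) && all(object@yfpExpression > 0) &&
            object@yfpExpression[2] >= 1,
        "yfpExpression must be c(median > 0, gsd >= 1)")
    chk(len2(object@enrichmentRatio) && object@enrichmentRatio[1] >= 1 &&
            object@enrichmentRatio[2] >= 1,
        "enrichmentRatio must be c(median >= 1, gsd >= 1)")
    chk(object@compartmentKind %in% c("cajal_body", "nucleolus"),
        "compartmentKind must be 'cajal_body' or 'nucleolus'")
    chk(len2(object@cargoNCRatio) && all(object@cargoNCRatio > 0) &&
            object@cargoNCRatio[2] >= 1,
        "cargoNCRatio must be c(median > 0, gsd >= 1)")
    rr <- list(focusRadiusRange = object@focusRadiusRange,
               nucleusRadiusRange = object@nucleusRadiusRange,
               cellRadiusRange = object@cellRadiusRange)
    for (nm in names(rr))
        chk(len2(rr[[nm]]) && all(rr[[nm]] > 0) && rr[[nm]][1] <= rr[[nm]][2],
            sprintf("%s must be an increasing positive range", nm))
    chk(length(object@nFociRange) == 2 && all(object@nFociRange >= 0) &&
            object@nFociRange[1] <= object@nFociRange[2],
        "nFociRange must be a non-negative integer range")
    if (!length(msg)) {
        chk(object@nucleusRadiusRange[2] < object@cellRadiusRange[2],
            "nucleus radii must be smaller than the largest cell radius")
        ## worst case: max foci count at max radius inside the smallest nucleus
        maxFociArea <- object@nFociRange[2] * pi * object@focusRadiusRange[2]^2
        minNucArea <- pi * object@nucleusRadiusRange[1]^2
        chk(maxFociArea < 0.5 * minNucArea,
            "total compartment area may exceed 50% of the nucleus area; reduce nFociRange or focusRadiusRange")
    }
    chk(object@markerEnrichment >= 1, "markerEnrichment must be >= 1")
    lv <- c(object@backgroundLevel, object@dnaLevel, object@markerBase,
            object@cargoCytoLevel)
    chk(all(lv >= 0), "intensity levels must be non-negative")
    chk(object@yfpCytoFraction >= 0 && object@yfpCytoFraction <= 1,
        "yfpCytoFraction must lie in [0, 1]")
    chk(object@untransfectedNCRatio > 0, "untransfectedNCRatio must be > 0")
    chk(length(object@noise) == 2 && object@noise[1] > 0 &&
            object@noise[2] >= 0,
        "noise must be c(poissonScale > 0, gaussianSD >= 0)")
    if (length(msg)) msg else TRUE
}
setValidity("SceneParams", .validSceneParams)

#' Construct scene generator parameters
#'
#' Builds a validated \code{\linkS4class{SceneParams}} object.  Defaults
#' describe a field of ~120 HeLa-like cells on a 640 x 640 px image with a
#' transfected subpopulation whose nucleoplasmic YFP level is log-normal,
#' Cajal-body-like marker foci in every nucleus, and moderate shot + read
#' noise.  Setting \code{compartmentKind = "nucleolus"} switches the focus
#' geometry defaults to fewer, larger bodies (and slightly larger nuclei so
#' that the compartments still occupy well under half of the nucleus).
#'
#' @param imageSize height, width in pixels.
#' @param nCells number of cells.
#' @param fractionTransfected,fractionPositive proportions in [0, 1].
#' @param yfpExpression,enrichmentRatio,cargoNCRatio log-normal parameters
#'   \code{c(median, gsd)}.
#' @param compartmentKind "cajal_body" or "nucleolus".
#' @param nFociRange,focusRadiusRange,nucleusRadiusRange,cellRadiusRange
#'   geometry ranges (px); kind-dependent defaults when \code{NULL}.
#' @param markerEnrichment marker contrast of compartment vs nucleoplasm.
#' @param backgroundLevel,dnaLevel,markerBase,cargoCytoLevel rendering
#'   levels (a.u.).
#' @param yfpCytoFraction cytoplasmic/nucleoplasmic YFP level fraction.
#' @param untransfectedNCRatio cargo N/C ratio of untransfected cells.
#' @param noise \code{c(poissonScale, gaussianSD)}.
#' @param clustered emulate clustered growth (no usable cytoplasm).
#' @param seed integer RNG seed.
#' @return a \code{SceneParams} object.
#' @examples
#' p <- SceneParams(nCells = 40L, imageSize = c(320L, 320L), seed = 7L)
#' p
#' @export
SceneParams <- function(imageSize = c(640L, 640L),
                        nCells = 120L,
                        fractionTransfected = 0.7,
                        yfpExpression = c(200, 1.8),
                        fractionPositive = 0.65,
                        enrichmentRatio = c(3.0, 1.3),
                        compartmentKind = c("cajal_body", "nucleolus"),
                        nFociRange = NULL,
                        focusRadiusRange = NULL,
                        nucleusRadiusRange = NULL,
                        cellRadiusRange = c(14, 18),
                        cargoNCRatio = c(0.5, 1.35),
                        markerEnrichment = 4,
                        backgroundLevel = 20,
                        dnaLevel = 400,
                        markerBase = 150,
                        cargoCytoLevel = 100,
                        yfpCytoFraction = 0.3,
                        untransfectedNCRatio = 2.0,
                        noise = c(1, 2),
                        clustered = FALSE,
                        seed = 1L) {
    compartmentKind <- match.arg(compartmentKind)
    if (compartmentKind == "cajal_body") {
        if (is.null(nFociRange)) nFociRange <- c(1L, 3L)
        if (is.null(focusRadiusRange)) focusRadiusRange <- c(2, 3)
        if (is.null(nucleusRadiusRange)) nucleusRadiusRange <- c(8, 11)
    } else {
        if (is.null(nFociRange)) nFociRange <- c(1L, 2L)
        if (is.null(focusRadiusRange)) focusRadiusRange <- c(3.5, 4.4)
        if (is.null(nucleusRadiusRange)) nucleusRadiusRange <- c(9, 12)
    }
    new("SceneParams",
        imageSize = as.integer(imageSize), nCells = as.integer(nCells),
        fractionTransfected = as.numeric(fractionTransfected),
        yfpExpression = as.numeric(yfpExpression),
        fractionPositive = as.numeric(fractionPositive),
        enrichmentRatio = as.numeric(enrichmentRatio),
        compartmentKind = compartmentKind,
        nFociRange = as.integer(nFociRange),
        focusRadiusRange = as.numeric(focusRadiusRange),
        nucleusRadiusRange = as.numeric(nucleusRadiusRange),
        cellRadiusRange = as.numeric(cellRadiusRange),
        cargoNCRatio = as.numeric(cargoNCRatio),
        markerEnrichment = as.numeric(markerEnrichment),
        backgroundLevel = as.numeric(backgroundLevel),
        dnaLevel = as.numeric(dnaLevel),
        markerBase = as.numeric(markerBase),
        cargoCytoLevel = as.numeric(cargoCytoLevel),
        yfpCytoFraction = as.numeric(yfpCytoFraction),
        untransfectedNCRatio = as.numeric(untransfectedNCRatio),
        noise = as.numeric(noise),
        clustered = isTRUE(clustered),
        seed = as.integer(seed))
}

setMethod("show", "SceneParams", function(object) {
    cat("SceneParams:", object@imageSize[1], "x", object@imageSize[2],
        "px,", object@nCells, "cells\n")
    cat("  compartment:", object@compartmentKind,
        sprintf("(%d-%d foci, r %.1f-%.1f px)", object@nFociRange[1],
                object@nFociRange[2], object@focusRadiusRange[1],
                object@focusRadiusRange[2]), "\n")
    cat(sprintf("  transfected %.0f%%, positive %.0f%% (ratio median %.2f, gsd %.2f)\n",
                100 * object@fractionTransfected,
                100 * object@fractionPositive,
                object@enrichmentRatio[1], object@enrichmentRatio[2]))
    cat(sprintf("  cargo N/C median %.2f (gsd %.2f); noise: poissonScale %.3g, gaussianSD %.3g\n",
                object@cargoNCRatio[1], object@cargoNCRatio[2],
                object@noise[1], object@noise[2]))
    cat("  mode:", if (object@clustered) "clustered" else "large_cytoplasm",
        "| seed:", object@seed, "\n")
    invisible(NULL)
})

#' Scene: a rendered synthetic micrograph with ground truth
#'
#' Holds the 4-channel image (canonical channel order: dna, yfp, marker,
#' cargo), the generating per-cell specifications, ground-truth label masks
#' (nucleus, whole cell, foci) and the generating
#' \code{\linkS4class{SceneParams}}.  Masks are integer matrices sharing
#' the image dimensions; a pixel's label is the \code{cell_id} owning it
#' (for \code{fociMask}, a global focus id; see \code{cellSpecs} for the
#' focus-to-cell map).
#'
#' @slot image numeric array, height x width x 4.
#' @slot nucleusMask,cellMask integer matrices labelled by cell_id.
#' @slot fociMask integer matrix labelled by global focus id.
#' @slot fociTable data.frame: focus_id, cell_id, fy, fx, radius.
#' @slot specs data.frame of per-cell ground truth (one row per cell).
#' @slot params the generating \code{SceneParams}.
#' @name Scene-class
#' @rdname Scene-class
#' @exportClass Scene
setClass("Scene", representation(
    image = "array",
    nucleusMask = "matrix",
    cellMask = "matrix",
    fociMask = "matrix",
    fociTable = "data.frame",
    specs = "data.frame",
    params = "SceneParams"))

setValidity("Scene", function(object) {
    d <- dim(object@image)
    if (length(d) != 3 || d[3] != 4)
        return("image must be a height x width x 4 array")
    for (nm in c("nucleusMask", "cellMask", "fociMask"))
        if (!identical(dim(slot(object, nm)), d[1:2]))
            return(sprintf("%s dimensions differ from the image", nm))
    TRUE
})

setMethod("show", "Scene", function(object) {
    d <- dim(object@image)
    cat("Scene:", d[1], "x", d[2], "px, 4 channels (dna, yfp, marker, cargo)\n")
    cat(" ", nrow(object@specs), "cells,", nrow(object@fociTable),
        "compartment foci,", sum(object@specs$transfected), "transfected,",
        sum(object@specs$positive), "compartment-positive\n")
    invisible(NULL)
})

#' Canonical channel roles
#'
#' The canonical channel order used throughout the package.
#' @return character vector \code{c("dna", "yfp", "marker", "cargo")}.
#' @export
channelRoles <- function() c("dna", "yfp", "marker", "cargo")

#' @describeIn Scene-class the image array (height x width x 4)
#' @param scene a \code{Scene}
#' @export
sceneImage <- function(scene) scene@image

#' @describeIn Scene-class one channel as a matrix
#' @param role one of \code{channelRoles()}
#' @export
sceneChannel <- function(scene, role) {
    i <- match(match.arg(role, channelRoles()), channelRoles())
    scene@image[, , i]
}

#' @describeIn Scene-class per-cell ground-truth specifications
#' @export
cellSpecs <- function(scene) scene@specs

#' @describeIn Scene-class ground-truth nucleus label mask
#' @export
nucleusMask <- function(scene) scene@nucleusMask

#' @describeIn Scene-class ground-truth whole-cell label mask
#' @export
cellMask <- function(scene) scene@cellMask

#' @describeIn Scene-class ground-truth focus label mask
#' @export
fociMask <- function(scene) scene@fociMask

#' @describeIn Scene-class the generating parameters
#' @export
sceneParams <- function(scene) scene@params
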