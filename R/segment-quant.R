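#' @include AllClasses.R
NULL

.asImage <- function(m) EBImage::Image(m)

## per-label pixel index lists, dropping label 0; names are label ids
.labelIndices <- function(labels) {
    idx <- split(seq_along(labels), labels)
    idx[names(idx) != "0"]
}

.safeMean <- function(v) if (length(v)) mean(v) else NA_real_

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold on the DNA stain, hole filling, connected
#' component labelling, area filtering, and (by default) exclusion of
#' objects touching the image border.  Surviving objects are relabelled
#' 1..k in raster order.
#'
#' @param dna 2D non-negative numeric matrix (DNA channel).
#' @param minArea,maxArea area filter in pixels.
#' @param dropEdge drop border-touching nuclei (default TRUE); if FALSE
#'   they are kept and flagged.
#' @return integer label matrix with attributes \code{edgeTouching} (named
#'   logical per retained label) and \code{qc} (list of exclusion tallies).
#'   A blank image (a single intensity class) yields an all-zero mask with
#'   a warning, not an error.
#' @export
segmentNuclei <- function(dna, minArea = 30, maxArea = Inf,
                          dropEdge = TRUE) {
    stopifnot(is.matrix(dna))
    if (any(dna < 0)) stop("dna channel must be non-negative")
    rng <- range(dna)
    qc <- list(nDetected = 0L, nEdge = 0L, nEdgeDropped = 0L,
               nAreaDropped = 0L)
    empty <- function() {
        out <- matrix(0L, nrow(dna), ncol(dna))
        attr(out, "edgeTouching") <- logical(0)
        attr(out, "qc") <- qc
        out
    }
    if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
        warning("blank DNA channel: no nuclei segmented")
        return(empty())
    }
    norm <- (dna - rng[1]) / diff(rng)
    thr <- EBImage::otsu(.asImage(norm), range = c(0, 1))
    bw <- norm > thr
    if (!any(bw)) {
        warning("no pixels above the Otsu threshold")
        return(empty())
    }
    bw <- EBImage::imageData(EBImage::fillHull(.asImage(bw * 1))) > 0
    lab <- EBImage::imageData(EBImage::bwlabel(.asImage(bw * 1)))
    storage.mode(lab) <- "integer"
    ids <- sort(unique(lab[lab > 0]))
    qc$nDetected <- length(ids)
    area <- tabulate(lab, nbins = max(ids))
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    border <- border[border > 0]
    qc$nEdge <- length(border)
    keep <- ids[area[ids] >= minArea & area[ids] <= maxArea]
    qc$nAreaDropped <- length(ids) - length(keep)
    if (dropEdge) {
        qc$nEdgeDropped <- sum(keep %in% border)
        keep <- setdiff(keep, border)
    }
    map <- integer(max(ids, 1L))
    map[keep] <- seq_along(keep)
    out <- matrix(0L, nrow(lab), ncol(lab))
    nz <- lab > 0
    out[nz] <- map[lab[nz]]
    edge <- setNames(keep %in% border, seq_along(keep))
    attr(out, "edgeTouching") <- edge
    attr(out, "qc") <- qc
    out
}

#' Segment cell bodies around segmented nuclei
#'
#' In \code{large_cytoplasm} mode, the cytoplasmic signal of the chosen
#' channel is thresholded (Otsu) into a foreground mask which is then
#' partitioned among nuclei by seeded propagation (a Voronoi-style
#' watershed), so every foreground pixel belongs to exactly one cell.  In
#' \code{clustered} mode no cytoplasm can be delineated and no cell mask
#' is produced; downstream analysis must use nuclear/total ratios.
#'
#' @param channels height x width x 4 array in canonical channel order.
#' @param nucleusLabels integer label matrix from
#'   \code{\link{segmentNuclei}}.
#' @param mode "large_cytoplasm" or "clustered".
#' @param fgChannel channel used to find cell territory ("cargo" default).
#' @return list with \code{mode}, \code{cellLabels} and
#'   \code{cytoplasmLabels} (both NULL in clustered mode).  Labels match
#'   the nucleus labels.
#' @export
segmentCellBodies <- function(channels, nucleusLabels,
                              mode = c("large_cytoplasm", "clustered"),
                              fgChannel = c("cargo", "yfp")) {
    mode <- match.arg(mode)
    if (mode == "clustered")
        return(list(mode = mode, cellLabels = NULL, cytoplasmLabels = NULL))
    fgChannel <- match.arg(fgChannel)
    ch <- channels[, , match(fgChannel, channelRoles())]
    rng <- range(ch)
    if (diff(rng) <= 0) {
        fg <- nucleusLabels > 0
    } else {
        norm <- (ch - rng[1]) / diff(rng)
        thr <- EBImage::otsu(.asImage(norm), range = c(0, 1))
        fg <- (norm > thr) | (nucleusLabels > 0)
    }
    cell <- EBImage::propagate(.asImage(ch / max(ch, 1)),
                               seeds = .asImage(nucleusLabels),
                               mask = .asImage(fg * 1))
    cell <- EBImage::imageData(cell)
    storage.mode(cell) <- "integer"
    cyto <- cell
    cyto[nucleusLabels > 0] <- 0L
    list(mode = mode, cellLabels = cell, cytoplasmLabels = cyto)
}

#' Detect intranuclear compartment foci in the marker channel
#'
#' Per nucleus, foci are connected regions of marker signal above an
#' adaptive threshold (the nucleoplasm median times
#' \code{minContrast}), size-filtered according to the compartment kind.
#' The \emph{selected} focus of each nucleus -- the one quantified for the
#' compartment/nucleoplasm ratio -- is the focus with the highest mean
#' marker intensity, a reproducible proxy for an experimenter picking one
#' clearly visible body per cell.  Cells without any detected focus are a
#' data outcome, tallied in the QC output, not an error.
#'
#' @param marker marker channel matrix.
#' @param nucleusLabels integer label matrix.
#' @param kind "cajal_body" or "nucleolus" (sets the default area filter).
#' @param minContrast threshold multiple of the per-nucleus median
#'   (default 2).
#' @param areaRange focus area filter in pixels; kind defaults:
#'   Cajal body c(5, 120), nucleolus c(15, 250).
#' @return list: \code{fociLabels} (integer matrix, global focus ids),
#'   \code{table} (data.frame focus_id, nucleus, area, marker_mean,
#'   selected), \code{qc} (list with \code{nNucleiNoFocus}).
#' @export
detectCompartments <- function(marker, nucleusLabels,
                               kind = c("cajal_body", "nucleolus"),
                               minContrast = 2, areaRange = NULL) {
    kind <- match.arg(kind)
    if (is.null(areaRange))
        areaRange <- if (kind == "cajal_body") c(5, 120) else c(15, 250)
    nLab <- max(nucleusLabels, 0L)
    emptyTab <- data.frame(focus_id = integer(), nucleus = integer(),
                           area = integer(), marker_mean = numeric(),
                           selected = logical())
    if (nLab == 0L)
        return(list(fociLabels = matrix(0L, nrow(marker), ncol(marker)),
                    table = emptyTab, qc = list(nNucleiNoFocus = 0L)))
    nucIdx <- .labelIndices(nucleusLabels)
    thr <- rep(Inf, nLab)
    for (nm in names(nucIdx))
        thr[as.integer(nm)] <- median(marker[nucIdx[[nm]]]) * minContrast
    thrMap <- matrix(Inf, nrow(marker), ncol(marker))
    nz <- nucleusLabels > 0
    thrMap[nz] <- thr[nucleusLabels[nz]]
    bw <- marker > thrMap
    lab <- EBImage::imageData(EBImage::bwlabel(.asImage(bw * 1)))
    storage.mode(lab) <- "integer"
    out <- matrix(0L, nrow(marker), ncol(marker))
    rows <- list()
    fid <- 0L
    if (max(lab) > 0) {
        compIdx <- .labelIndices(lab)
        for (nm in names(compIdx)) {
            px <- compIdx[[nm]]
            if (length(px) < areaRange[1] || length(px) > areaRange[2])
                next
            owners <- nucleusLabels[px]
            nucleus <- as.integer(names(which.max(table(owners))))
            fid <- fid + 1L
            out[px] <- fid
            rows[[fid]] <- data.frame(focus_id = fid, nucleus = nucleus,
                                      area = length(px),
                                      marker_mean = mean(marker[px]),
                                      selected = FALSE)
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else emptyTab
    if (nrow(tab)) {
        for (nuc in unique(tab$nucleus)) {
            sub <- which(tab$nucleus == nuc)
            tab$selected[sub[which.max(tab$marker_mean[sub])]] <- TRUE
        }
    }
    nNoFocus <- nLab - length(unique(tab$nucleus))
    list(fociLabels = out, table = tab,
         qc = list(nNucleiNoFocus = as.integer(nNoFocus)))
}

#' Measure per-cell intensities and ratios
#'
#' For every segmented nucleus, computes arithmetic means over mask
#' pixels: whole-nucleus YFP (the expression control), YFP in the selected
#' compartment focus, YFP in the nucleoplasm (nucleus minus \emph{all}
#' detected foci, each dilated by a 1-px guard ring), cargo in the nucleus
#' and -- when a cytoplasm mask exists -- cargo in the cytoplasm.  The
#' compartment/nucleoplasm ratio uses the selected focus.  Divisions are
#' guarded: cells whose nucleoplasm mask is empty or zero-mean are flagged
#' invalid with a reason code instead of producing NaN/Inf.
#'
#' @param channels height x width x 4 array in canonical channel order.
#' @param nucleusLabels label matrix from \code{\link{segmentNuclei}}.
#' @param foci result of \code{\link{detectCompartments}}.
#' @param cellBodies result of \code{\link{segmentCellBodies}} or NULL
#'   (clustered mode: cytoplasm means reported as missing).
#' @param satLevel pixels at or above this value are considered saturated
#'   and excluded from means (QC-counted).  Default Inf.
#' @return data.frame, one row per nucleus label: \code{cell_id,
#'   yfp_nuc_mean, compartment_mean, nucleoplasm_mean, compartment_ratio,
#'   cargo_nuc_mean, cargo_cyto_mean, nucleus_area, compartment_area,
#'   n_foci_detected, edge_touching, n_saturated, valid, exclude_reason}.
#' @export
measureCells <- function(channels, nucleusLabels, foci, cellBodies = NULL,
                         satLevel = Inf) {
    stopifnot(length(dim(channels)) == 3, dim(channels)[3] == 4)
    stopifnot(identical(dim(channels)[1:2], dim(nucleusLabels)))
    yfp <- channels[, , 2]; cargo <- channels[, , 4]
    nLab <- max(nucleusLabels, 0L)
    cols <- c("cell_id", "yfp_nuc_mean", "compartment_mean",
              "nucleoplasm_mean", "compartment_ratio", "cargo_nuc_mean",
              "cargo_cyto_mean", "nucleus_area", "compartment_area",
              "n_foci_detected", "edge_touching", "n_saturated", "valid",
              "exclude_reason")
    if (nLab == 0L) {
        out <- data.frame(cell_id = integer(), yfp_nuc_mean = numeric(),
                          compartment_mean = numeric(),
                          nucleoplasm_mean = numeric(),
                          compartment_ratio = numeric(),
                          cargo_nuc_mean = numeric(),
                          cargo_cyto_mean = numeric(),
                          nucleus_area = integer(),
                          compartment_area = integer(),
                          n_foci_detected = integer(),
                          edge_touching = logical(),
                          n_saturated = integer(), valid = logical(),
                          exclude_reason = character())
        return(out[, cols])
    }
    fociLab <- foci$fociLabels
    dil <- if (max(fociLab) > 0)
        EBImage::imageData(EBImage::dilate(
            .asImage((fociLab > 0) * 1),
            EBImage::makeBrush(3, shape = "box"))) > 0
    else matrix(FALSE, nrow(nucleusLabels), ncol(nucleusLabels))
    nucIdx <- .labelIndices(nucleusLabels)
    fociIdx <- .labelIndices(fociLab)
    cytoIdx <- if (!is.null(cellBodies) &&
                   !is.null(cellBodies$cytoplasmLabels))
        .labelIndices(cellBodies$cytoplasmLabels) else NULL
    edgeAttr <- attr(nucleusLabels, "edgeTouching")
    ok <- function(px, ch) px[ch[px] < satLevel]
    res <- vector("list", nLab)
    for (L in seq_len(nLab)) {
        px <- nucIdx[[as.character(L)]]
        if (is.null(px)) px <- integer(0)
        nSat <- sum(yfp[px] >= satLevel) + sum(cargo[px] >= satLevel)
        pxY <- ok(px, yfp); pxC <- ok(px, cargo)
        yfpNuc <- .safeMean(yfp[pxY])
        cargoNuc <- .safeMean(cargo[pxC])
        npPx <- px[!dil[px]]
        npPx <- ok(npPx, yfp)
        npMean <- .safeMean(yfp[npPx])
        sel <- foci$table$focus_id[foci$table$nucleus == L &
                                   foci$table$selected]
        nFoci <- sum(foci$table$nucleus == L)
        compMean <- NA_real_; compArea <- 0L; ratio <- NA_real_
        valid <- TRUE; reason <- ""
        if (!length(px)) {
            valid <- FALSE; reason <- "empty_nucleus"
        } else if (!length(npPx)) {
            valid <- FALSE; reason <- "empty_nucleoplasm"
        } else if (length(sel)) {
            fpx <- ok(fociIdx[[as.character(sel)]], yfp)
            compMean <- .safeMean(yfp[fpx])
            compArea <- length(fpx)
            if (!is.na(npMean) && npMean > 0 && !is.na(compMean)) {
                ratio <- compMean / npMean
            } else {
                valid <- FALSE; reason <- "zero_nucleoplasm_mean"
            }
        } else {
            reason <- "no_focus"
        }
        cyMean <- NA_real_
        if (!is.null(cytoIdx)) {
            cpx <- cytoIdx[[as.character(L)]]
            if (!is.null(cpx)) cyMean <- .safeMean(cargo[ok(cpx, cargo)])
        }
        res[[L]] <- data.frame(
            cell_id = L, yfp_nuc_mean = yfpNuc,
            compartment_mean = compMean, nucleoplasm_mean = npMean,
            compartment_ratio = ratio, cargo_nuc_mean = cargoNuc,
            cargo_cyto_mean = cyMean, nucleus_area = length(px),
            compartment_area = compArea, n_foci_detected = nFoci,
            edge_touching = isTRUE(edgeAttr[as.character(L)]),
            n_saturated = nSat, valid = valid, exclude_reason = reason,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[, cols]
}

#' Classify compartment positivity
#'
#' A cell is compartment-positive when its compartment/nucleoplasm ratio
#' is at or above the threshold (strict \code{>=}; a ratio of exactly the
#' threshold is positive).  Cells without a measurable ratio get NA and
#' are excluded from percentage denominators downstream.  The threshold is
#' recorded as an attribute for provenance.
#'
#' @param measurements data.frame from \code{\link{measureCells}}.
#' @param ratioThreshold positivity threshold (default 1.5).
#' @return the data.frame with a \code{positive} column and attribute
#'   \code{ratio_threshold}.
#' @export
classifyPositive <- function(measurements, ratioThreshold = 1.5) {
    if (!is.finite(ratioThreshold) || ratioThreshold <= 0)
        stop("ratioThreshold must be a positive number")
    measurements$positive <- measurements$compartment_ratio >= ratioThreshold
    attr(measurements, "ratio_threshold") <- ratioThreshold
    measurements
}

#' Select transfected cells by nuclear YFP level
#'
#' Keeps cells whose whole-nucleus YFP mean lies inside the window,
#' mirroring the restriction of analyses to cells expressing low to
#' moderate levels of the tagged receptor: the lower bound removes
#' untransfected cells, the upper bound removes overexpressors.  Counts of
#' both exclusions are attached as attributes.
#'
#' @param measurements data.frame with a \code{yfp_nuc_mean} column.
#' @param window \code{c(low, high)} in a.u., or quantile probabilities
#'   when \code{percentile = TRUE}.
#' @param percentile interpret the window as quantiles of the field's
#'   nuclear YFP distribution.
#' @return the selected subset, with attributes \code{nExcludedLow},
#'   \code{nExcludedHigh} and \code{yfp_window}.
#' @export
selectTransfected <- function(measurements, window = c(60, Inf),
                              percentile = FALSE) {
    if (length(window) != 2 || window[1] >= window[2])
        stop("window must be c(low, high) with low < high")
    w <- window
    if (percentile)
        w <- quantile(measurements$yfp_nuc_mean, probs = window,
                      na.rm = TRUE, names = FALSE)
    y <- measurements$yfp_nuc_mean
    keep <- !is.na(y) & y >= w[1] & y <= w[2]
    out <- measurements[keep, , drop = FALSE]
    if (!nrow(out)) warning("transfection window selected zero cells")
    attr(out, "nExcludedLow") <- sum(!is.na(y) & y < w[1])
    attr(out, "nExcludedHigh") <- sum(!is.na(y) & y > w[2])
    attr(out, "yfp_window") <- w
    out
}

#' Match segmentation labels to ground-truth cell ids
#'
#' Majority-overlap assignment of segmented labels to the generating
#' ground-truth mask of a synthetic scene; used to evaluate segmentation
#' and classification against truth.
#'
#' @param labels integer label matrix (segmentation).
#' @param truthMask integer label matrix (ground truth, e.g.
#'   \code{nucleusMask(scene)}).
#' @return named integer vector: for each segmentation label, the truth
#'   cell id with the largest overlap (0 if none).
#' @export
matchLabelsToTruth <- function(labels, truthMask) {
    ids <- sort(unique(labels[labels > 0]))
    out <- setNames(integer(length(ids)), ids)
    idx <- .labelIndices(labels)
    for (nm in names(idx)) {
        o <- truthMask[idx[[nm]]]
        o <- o[o > 0]
        out[nm] <- if (length(o))
            as.integer(names(which.max(table(o)))) else 0L
    }
    out
}

#' Measure a whole scene in one call
#'
#' Runs the full single-image analysis chain: nucleus segmentation,
#' cell-body segmentation (skipped in clustered mode), compartment
#' detection, per-cell measurement and positivity classification.
#'
#' @param x a \code{\linkS4class{Scene}} or a height x width x 4 array in
#'   canonical channel order.
#' @param compartmentKind "cajal_body" or "nucleolus"; taken from the
#'   scene's parameters when \code{x} is a \code{Scene} and this is NULL.
#' @param mode "large_cytoplasm" or "clustered"; from scene parameters
#'   when NULL.
#' @param ratioThreshold positivity threshold (default 1.5).
#' @param minContrast compartment detection contrast (default 2).
#' @param yfpWindow optional transfection window passed to
#'   \code{\link{selectTransfected}}; NULL keeps all cells.
#' @param satLevel saturation level passed to \code{\link{measureCells}}.
#' @param ... further arguments to \code{\link{segmentNuclei}}.
#' @return list with \code{cells} (measurement data.frame) and \code{qc}
#'   (named list of exclusion tallies and thresholds).
#' @examples
#' p <- SceneParams(nCells = 15L, imageSize = c(256L, 256L), seed = 3L)
#' res <- measureScene(simulateScene(p))
#' head(res$cells)
#' @export
measureScene <- function(x, compartmentKind = NULL, mode = NULL,
                         ratioThreshold = 1.5, minContrast = 2,
                         yfpWindow = NULL, satLevel = Inf, ...) {
    if (is(x, "Scene")) {
        if (is.null(compartmentKind))
            compartmentKind <- sceneParams(x)@compartmentKind
        if (is.null(mode))
            mode <- if (sceneParams(x)@clustered) "clustered"
                    else "large_cytoplasm"
        channels <- sceneImage(x)
    } else {
        channels <- x
        if (is.null(compartmentKind)) compartmentKind <- "cajal_body"
        if (is.null(mode)) mode <- "large_cytoplasm"
    }
    nuc <- segmentNuclei(channels[, , 1], ...)
    bodies <- segmentCellBodies(channels, nuc, mode = mode)
    foci <- detectCompartments(channels[, , 3], nuc,
                               kind = compartmentKind,
                               minContrast = minContrast)
    cells <- measureCells(channels, nuc, foci, cellBodies = bodies,
                          satLevel = satLevel)
    cells <- classifyPositive(cells, ratioThreshold)
    qc <- c(attr(nuc, "qc"), foci$qc,
            list(nInvalid = sum(!cells$valid),
                 nNoFocus = sum(cells$exclude_reason == "no_focus"),
                 ratioThreshold = ratioThreshold,
                 minContrast = minContrast, mode = mode,
                 compartmentKind = compartmentKind))
    if (!is.null(yfpWindow)) {
        cells <- selectTransfected(cells, yfpWindow)
        qc$nExcludedLow <- attr(cells, "nExcludedLow")
        qc$nExcludedHigh <- attr(cells, "nExcludedHigh")
    }
    list(cells = cells, qc = qc)
}
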