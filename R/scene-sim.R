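#' @include AllClasses.R
NULL

## pixel-centre test for an axis-aligned ellipse
.insideEllipse <- function(rows, cols, cy, cx, ry, rx) {
    dy <- (rows - cy) / ry
    dx <- (cols - cx) / rx
    outer(dy^2, dx^2, "+") <= 1
}

#' Sample a synthetic cell population
#'
#' Draws the ground-truth specification of every cell in a scene: ellipse
#' geometry (cells placed by rejection sampling so that no two cells
#' overlap), transfection status, nucleoplasmic YFP level, compartment
#' positivity, true compartment/nucleoplasm enrichment ratio, marker focus
#' geometry, and true cargo nuclear/cytoplasmic levels.  Deterministic
#' given \code{params@seed} (or an explicit \code{seed}).
#'
#' Negative and untransfected cells have \code{true_ratio} exactly 1, so
#' positivity is a property of enrichment, not geometry.  Marker foci are
#' sampled for every cell: compartments exist (and are stained) regardless
#' of receptor enrichment.  In clustered mode, cell bodies shrink to a thin
#' rim around the nucleus and cells may touch (but never overlap).
#'
#' @param params a \code{\linkS4class{SceneParams}}.
#' @param seed optional integer overriding \code{params@seed}.
#' @param maxAttempts placement attempts per cell before giving up.
#' @return a data.frame with one row per cell: \code{cell_id, cy, cx,
#'   nuc_ry, nuc_rx, cell_ry, cell_rx, transfected, yfp_true, positive,
#'   true_ratio, cargo_nuc_true, cargo_cyto_true, n_foci} and a
#'   list-column \code{foci} of matrices (fy, fx, radius).
#' @examples
#' specs <- sampleCellPopulation(SceneParams(nCells = 10L,
#'     imageSize = c(256L, 256L)))
#' head(specs[, c("cell_id", "transfected", "positive", "true_ratio")])
#' @export
sampleCellPopulation <- function(params, seed = NULL, maxAttempts = 1000L) {
    stopifnot(is(params, "SceneParams"))
    validObject(params)
    if (is.null(seed)) seed <- params@seed
    withr::with_seed(as.integer(seed), .samplePopulation(params, maxAttempts))
}

.samplePopulation <- function(params, maxAttempts) {
    n <- params@nCells
    H <- params@imageSize[1]; W <- params@imageSize[2]

    ## --- geometry: rejection-sampled non-overlapping ellipses -----------
    cy <- cx <- nucR <- cellR <- asp <- numeric(n)
    gap <- if (params@clustered) 0 else 1
    if (n > 0) for (i in seq_len(n)) {
        placed <- FALSE
        for (a in seq_len(maxAttempts)) {
            rN <- runif(1, params@nucleusRadiusRange[1],
                        params@nucleusRadiusRange[2])
            rC <- if (params@clustered) rN * 1.12 else
                max(runif(1, params@cellRadiusRange[1],
                          params@cellRadiusRange[2]), rN + 2)
            aa <- runif(1, 0.85, 1.18)
            maxAx <- rC * max(sqrt(aa), 1 / sqrt(aa))
            y <- runif(1, maxAx + 2, H - maxAx - 1)
            x <- runif(1, maxAx + 2, W - maxAx - 1)
            if (i == 1) ok <- TRUE else {
                prevMax <- cellR[seq_len(i - 1)] *
                    pmax(sqrt(asp[seq_len(i - 1)]), 1 / sqrt(asp[seq_len(i - 1)]))
                dd <- sqrt((cy[seq_len(i - 1)] - y)^2 +
                           (cx[seq_len(i - 1)] - x)^2)
                ok <- all(dd > prevMax + maxAx + gap)
            }
            if (ok) {
                cy[i] <- y; cx[i] <- x; nucR[i] <- rN; cellR[i] <- rC
                asp[i] <- aa
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("scene overcrowded: could not place cell ", i, " of ", n,
                 " after ", maxAttempts, " attempts; reduce nCells or ",
                 "cellRadiusRange, or enlarge imageSize")
    }
    nuc_ry <- nucR * sqrt(asp); nuc_rx <- nucR / sqrt(asp)
    cell_ry <- cellR * sqrt(asp); cell_rx <- cellR / sqrt(asp)

    ## --- biology: transfection, expression, enrichment, cargo -----------
    transfected <- runif(n) < params@fractionTransfected
    yfp <- rep(params@backgroundLevel, n)
    yfp[transfected] <- rlnorm(sum(transfected),
                               meanlog = log(params@yfpExpression[1]),
                               sdlog = log(params@yfpExpression[2]))
    positive <- transfected & (runif(n) < params@fractionPositive)
    ratio <- rep(1.0, n)
    ratio[positive] <- rlnorm(sum(positive),
                              meanlog = log(params@enrichmentRatio[1]),
                              sdlog = log(params@enrichmentRatio[2]))
    nc <- rep(params@untransfectedNCRatio, n)
    nc[transfected] <- rlnorm(sum(transfected),
                              meanlog = log(params@cargoNCRatio[1]),
                              sdlog = log(params@cargoNCRatio[2]))
    cargoCyto <- rep(params@cargoCytoLevel, n)
    cargoNuc <- cargoCyto * nc

    ## --- marker foci: always present, strictly inside the nucleus -------
    foci <- vector("list", n)
    nFoci <- integer(n)
    if (n > 0) for (i in seq_len(n)) {
        k <- sample(seq(params@nFociRange[1], params@nFociRange[2]), 1)
        fy <- fx <- fr <- numeric(0)
        for (j in seq_len(k)) {
            for (a in seq_len(50L)) {
                r <- runif(1, params@focusRadiusRange[1],
                           params@focusRadiusRange[2])
                ay <- nuc_ry[i] - r - 1; ax <- nuc_rx[i] - r - 1
                if (ay <= 0 || ax <= 0) break
                th <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
                y <- cy[i] + rho * ay * sin(th)
                x <- cx[i] + rho * ax * cos(th)
                if (!length(fy) ||
                    all(sqrt((fy - y)^2 + (fx - x)^2) > fr + r + 2)) {
                    fy <- c(fy, y); fx <- c(fx, x); fr <- c(fr, r)
                    break
                }
            }
        }
        foci[[i]] <- cbind(fy = fy, fx = fx, radius = fr)
        nFoci[i] <- length(fr)
    }

    out <- data.frame(cell_id = seq_len(n), cy = cy, cx = cx,
                      nuc_ry = nuc_ry, nuc_rx = nuc_rx,
                      cell_ry = cell_ry, cell_rx = cell_rx,
                      transfected = transfected, yfp_true = yfp,
                      positive = positive, true_ratio = ratio,
                      cargo_nuc_true = cargoNuc, cargo_cyto_true = cargoCyto,
                      n_foci = nFoci)
    out$foci <- foci
    out
}

#' Render a noiseless multi-channel scene
#'
#' Rasterizes cell specifications into a piecewise-constant 4-channel image
#' (canonical order dna, yfp, marker, cargo) plus exact ground-truth label
#' masks.  Pixel values are analytically predictable from the specs:
#' \itemize{
#'   \item dna: \code{dnaLevel} inside every nucleus, background elsewhere;
#'   \item yfp: nucleoplasmic level inside the nucleus, with each focus
#'     multiplied by the cell's \code{true_ratio}, and a fixed lower
#'     cytoplasmic level (\code{yfpCytoFraction} of nucleoplasm for
#'     transfected cells, background otherwise);
#'   \item marker: \code{markerBase} in the nucleus, times
#'     \code{markerEnrichment} in every focus, in all cells;
#'   \item cargo: \code{cargo_nuc_true} in the nucleus,
#'     \code{cargo_cyto_true} in the cytoplasm, background outside cells.
#' }
#'
#' @param specs data.frame from \code{\link{sampleCellPopulation}}.
#' @param params the generating \code{\linkS4class{SceneParams}}.
#' @return a \code{\linkS4class{Scene}}.
#' @examples
#' p <- SceneParams(nCells = 5L, imageSize = c(200L, 200L), noise = c(Inf, 0))
#' sc <- renderScene(sampleCellPopulation(p), p)
#' sc
#' @export
renderScene <- function(specs, params) {
    H <- params@imageSize[1]; W <- params@imageSize[2]
    img <- array(params@backgroundLevel, dim = c(H, W, 4))
    nucM <- cellM <- matrix(0L, H, W)
    fociM <- matrix(0L, H, W)
    ft <- list()
    focusId <- 0L
    for (i in seq_len(nrow(specs))) {
        s <- specs[i, ]
        maxAx <- max(s$cell_ry, s$cell_rx)
        r0 <- max(1L, floor(s$cy - maxAx - 1)); r1 <- min(H, ceiling(s$cy + maxAx + 1))
        c0 <- max(1L, floor(s$cx - maxAx - 1)); c1 <- min(W, ceiling(s$cx + maxAx + 1))
        rows <- r0:r1; cols <- c0:c1
        inCell <- .insideEllipse(rows, cols, s$cy, s$cx, s$cell_ry, s$cell_rx)
        inNuc <- .insideEllipse(rows, cols, s$cy, s$cx, s$nuc_ry, s$nuc_rx)
        inCyto <- inCell & !inNuc
        sub <- function(m) m[rows, cols]
        put <- function(ch, mask, val) {
            tmp <- img[rows, cols, ch]; tmp[mask] <- val
            img[rows, cols, ch] <<- tmp
        }
        yfpNp <- if (s$transfected) s$yfp_true else params@backgroundLevel
        yfpCy <- if (s$transfected) params@yfpCytoFraction * s$yfp_true
                 else params@backgroundLevel
        put(1, inNuc, params@dnaLevel)
        put(2, inNuc, yfpNp); put(2, inCyto, yfpCy)
        put(3, inNuc, params@markerBase)
        put(4, inNuc, s$cargo_nuc_true); put(4, inCyto, s$cargo_cyto_true)
        nm <- sub(nucM); nm[inNuc] <- s$cell_id; nucM[rows, cols] <- nm
        cm <- sub(cellM); cm[inCell] <- s$cell_id; cellM[rows, cols] <- cm
        fo <- s$foci[[1]]
        if (length(fo)) for (j in seq_len(nrow(fo))) {
            focusId <- focusId + 1L
            inF <- .insideEllipse(rows, cols, fo[j, "fy"], fo[j, "fx"],
                                  fo[j, "radius"], fo[j, "radius"])
            put(2, inF, yfpNp * s$true_ratio)
            put(3, inF, params@markerBase * params@markerEnrichment)
            fm <- sub(fociM); fm[inF] <- focusId; fociM[rows, cols] <- fm
            ft[[focusId]] <- data.frame(focus_id = focusId,
                                        cell_id = s$cell_id,
                                        fy = fo[j, "fy"], fx = fo[j, "fx"],
                                        radius = fo[j, "radius"])
        }
    }
    fociTable <- if (length(ft)) do.call(rbind, ft) else
        data.frame(focus_id = integer(), cell_id = integer(),
                   fy = numeric(), fx = numeric(), radius = numeric())
    rownames(fociTable) <- NULL
    new("Scene", image = img, nucleusMask = nucM, cellMask = cellM,
        fociMask = fociM, fociTable = fociTable,
        specs = specs, params = params)
}

#' Apply camera noise to an image
#'
#' Mixed Poisson-Gaussian camera model: the output is
#' \code{Poisson(image * poissonScale) / poissonScale + N(0, gaussianSD)},
#' clipped at zero.  The expectation equals the input, so masked means are
#' unbiased estimators of the rendered levels.  \code{poissonScale = Inf}
#' disables shot noise (infinite-photon limit); \code{gaussianSD = 0}
#' disables read noise.
#'
#' @param image non-negative numeric array or matrix.
#' @param noise \code{c(poissonScale, gaussianSD)}.
#' @param seed optional integer seed for reproducibility.
#' @return array of the same shape.
#' @examples
#' x <- matrix(100, 32, 32)
#' y <- applyNoise(x, c(1, 2), seed = 1L)
#' mean(y)
#' @export
applyNoise <- function(image, noise = c(1, 2), seed = NULL) {
    if (length(noise) != 2 || is.na(noise[1]) || is.na(noise[2]) ||
        noise[1] <= 0 || noise[2] < 0)
        stop("noise must be c(poissonScale > 0, gaussianSD >= 0)")
    if (any(image < 0)) stop("image must be non-negative")
    run <- function() {
        out <- image
        if (is.finite(noise[1]))
            out[] <- rpois(length(image), image * noise[1]) / noise[1]
        if (noise[2] > 0)
            out[] <- out + rnorm(length(image), 0, noise[2])
        out[out < 0] <- 0
        out
    }
    if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Simulate one complete scene
#'
#' Convenience wrapper: sample a population, render it, and apply the
#' camera-noise model of \code{params@noise}.  The returned
#' \code{\linkS4class{Scene}} carries the noisy image; the noiseless
#' rendering can be regenerated with \code{\link{renderScene}}.
#'
#' @param params a \code{\linkS4class{SceneParams}}.
#' @param seed optional integer overriding \code{params@seed}; the
#'   population and the noise use deterministically derived sub-seeds.
#' @return a \code{\linkS4class{Scene}} with a noisy image.
#' @export
simulateScene <- function(params, seed = NULL) {
    if (is.null(seed)) seed <- params@seed
    seed <- as.integer(seed)
    specs <- sampleCellPopulation(params, seed = seed)
    sc <- renderScene(specs, params)
    sc@image <- applyNoise(sc@image, params@noise,
                           seed = (seed + 1013904L) %% 2147483629L)
    sc
}

#' Per-cell ground truth as a flat table
#'
#' Scalar ground-truth columns of a scene (foci geometry dropped), suitable
#' for CSV serialization.  Centres are reported as 0-based (row, column)
#' pixel coordinates.
#'
#' @param scene a \code{\linkS4class{Scene}}.
#' @return data.frame, one row per cell.
#' @export
groundTruth <- function(scene) {
    s <- cellSpecs(scene)
    data.frame(cell_id = s$cell_id, row = s$cy - 1, col = s$cx - 1,
               nuc_ry = s$nuc_ry, nuc_rx = s$nuc_rx,
               cell_ry = s$cell_ry, cell_rx = s$cell_rx,
               transfected = s$transfected, yfp_true = s$yfp_true,
               positive = s$positive, true_ratio = s$true_ratio,
               cargo_nuc_true = s$cargo_nuc_true,
               cargo_cyto_true = s$cargo_cyto_true, n_foci = s$n_foci)
}

#' Derive a per-experiment seed from a master seed
#'
#' Stable, documented mixing of (master seed, condition name, experiment
#' index) into a 31-bit seed: the condition name is hashed with a base-31
#' rolling hash modulo 1048573, then combined linearly with the master seed
#' and index modulo 2147483629.  The mapping is fixed across package
#' versions so that archived run manifests stay reproducible.
#'
#' @param masterSeed integer master seed.
#' @param condition character scalar (condition or stage name).
#' @param index integer experiment index.
#' @return a single integer seed in [1, 2147483629].
#' @examples
#' seedForExperiment(1L, "wt", 1L)
#' @export
seedForExperiment <- function(masterSeed, condition, index) {
    h <- 0
    for (code in utf8ToInt(as.character(condition)))
        h <- (h * 31 + code) %% 1048573
    s <- ((masterSeed %% 1048573) * 131071 + (h + 1) * 8191 +
          (index %% 65521) * 524287) %% 2147483629
    as.integer(s + 1)
}
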