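#' @include segment-quant.R
NULL

#' Summarize one condition x experiment
#'
#' Collapses per-cell measurements of a single experiment into the two
#' quantities the localization score is built from: the percentage of
#' classifiable cells that are compartment-positive, and the arithmetic
#' mean compartment/nucleoplasm ratio over all ratio-bearing cells
#' (positive or not; marker staining is independent of receptor
#' enrichment, which keeps the percentage and the ratio statistically
#' decoupled).
#'
#' @param cells per-cell data.frame with \code{positive} and
#'   \code{compartment_ratio} columns (already transfection-selected).
#' @param condition,experimentId identifiers recorded in the output.
#' @param compartmentKind recorded in the output ("cajal_body" or
#'   "nucleolus").
#' @param minCells experiments scoring fewer classifiable cells are
#'   flagged underpowered (kept, warned).  Default 25.
#' @return one-row data.frame: condition, experiment_id, compartment_kind,
#'   n_scored, pct_positive, mean_ratio, underpowered.
#' @examples
#' cells <- data.frame(positive = rep(c(TRUE, FALSE), c(10, 15)),
#'                     compartment_ratio = rep(2, 25))
#' summarizeExperiment(cells, "wt", 1)
#' @export
summarizeExperiment <- function(cells, condition, experimentId,
                                compartmentKind = "cajal_body",
                                minCells = 25) {
    classifiable <- !is.na(cells$positive)
    n <- sum(classifiable)
    if (n == 0)
        stop("no classifiable cells for condition '", condition,
             "', experiment '", experimentId, "'")
    pct <- 100 * sum(cells$positive[classifiable]) / n
    ratios <- cells$compartment_ratio[!is.na(cells$compartment_ratio)]
    under <- n < minCells
    if (under)
        warning("condition '", condition, "', experiment '", experimentId,
                "': only ", n, " cells scored (min ", minCells,
                "); summary flagged underpowered")
    data.frame(condition = as.character(condition),
               experiment_id = as.character(experimentId),
               compartment_kind = compartmentKind,
               n_scored = n, pct_positive = pct,
               mean_ratio = mean(ratios), underpowered = under,
               stringsAsFactors = FALSE)
}

#' Compute the raw composite localization score
#'
#' The raw score of a condition is the mean over experiments of the
#' percentage of compartment-positive cells, multiplied by the mean over
#' experiments of the mean compartment/nucleoplasm ratio (mean of means:
#' every experiment is weighted equally regardless of cell count).
#'
#' @param summaries data.frame of \code{\link{summarizeExperiment}} rows,
#'   all from one condition and compartment kind.
#' @param ratioMode "all_experiments" (default: the ratio factor is the
#'   mean over all experiments) or "representative" (the ratio factor is
#'   taken from the first experiment only).
#' @return the raw score (percent x ratio, dimensionless).
#' @examples
#' s <- data.frame(condition = "wt", compartment_kind = "cajal_body",
#'                 pct_positive = c(80, 60), mean_ratio = c(2, 3))
#' computeRawScore(s)  # 70 * 2.5 = 175
#' @export
computeRawScore <- function(summaries,
                            ratioMode = c("all_experiments",
                                          "representative")) {
    ratioMode <- match.arg(ratioMode)
    if (!nrow(summaries)) stop("no experiment summaries supplied")
    if (length(unique(summaries$condition)) > 1)
        stop("summaries mix several conditions")
    if (length(unique(summaries$compartment_kind)) > 1)
        stop("summaries mix compartment kinds")
    ratio <- if (ratioMode == "representative") summaries$mean_ratio[1]
             else mean(summaries$mean_ratio)
    mean(summaries$pct_positive) * ratio
}

#' Normalize raw scores to a reference condition
#'
#' Scales every condition's raw score so the reference equals exactly 100.
#'
#' @param rawScores named numeric vector of raw scores by condition.
#' @param reference name of the reference condition (must have a raw
#'   score > 0).
#' @return named numeric vector of normalized scores; the reference maps
#'   to 100 exactly.
#' @export
normalizeScores <- function(rawScores, reference) {
    if (!reference %in% names(rawScores))
        stop("reference condition '", reference,
             "' absent from the raw scores")
    ref <- rawScores[[reference]]
    if (!is.finite(ref) || ref <= 0)
        stop("reference raw score is ", ref,
             "; normalization is undefined")
    out <- 100 * rawScores / ref
    out[reference] <- 100
    out
}

#' Localization score pipeline
#'
#' Computes condition-level localization scores from per-cell measurement
#' tables spanning one or more conditions and experiments.  Both the
#' default mean-of-means score and a pooled-cells variant (all cells of a
#' condition pooled before computing percentage and mean ratio) are
#' reported so their discrepancy is visible.
#'
#' @param measurements per-cell data.frame with \code{condition},
#'   \code{experiment_id}, \code{compartment_ratio} and \code{positive}
#'   columns (classified and transfection-selected).
#' @param reference reference condition name (normalized score 100).
#' @param compartmentKind recorded in the output.
#' @param minCells per-experiment minimum (see
#'   \code{\link{summarizeExperiment}}).
#' @param ratioMode see \code{\link{computeRawScore}}.
#' @param nBoot if > 0, number of bootstrap replicates (resampling
#'   experiments, then cells within experiments) for a percentile CI on
#'   the normalized score; an extension beyond the descriptive composite,
#'   off by default.
#' @param bootSeed seed for the bootstrap.
#' @return data.frame with one row per condition: condition,
#'   compartment_kind, n_experiments, n_cells, raw_score,
#'   normalized_score, pooled_raw, pooled_normalized (and boot_lo/boot_hi
#'   when \code{nBoot > 0}); provenance (thresholds, mode, per-experiment
#'   n) in \code{attr(, "provenance")}.
#' @export
scorePipeline <- function(measurements, reference,
                          compartmentKind = "cajal_body", minCells = 25,
                          ratioMode = c("all_experiments",
                                        "representative"),
                          nBoot = 0, bootSeed = 1L) {
    ratioMode <- match.arg(ratioMode)
    if (!reference %in% measurements$condition)
        stop("reference condition '", reference,
             "' missing from the measurements")
    conds <- unique(measurements$condition)
    sumTabs <- list()
    for (cond in conds) {
        sub <- measurements[measurements$condition == cond, , drop = FALSE]
        for (e in unique(sub$experiment_id)) {
            cells <- sub[sub$experiment_id == e, , drop = FALSE]
            sumTabs[[length(sumTabs) + 1L]] <-
                summarizeExperiment(cells, cond, e, compartmentKind,
                                    minCells)
        }
    }
    summaries <- do.call(rbind, sumTabs)
    raw <- pooledRaw <- setNames(numeric(length(conds)), conds)
    nExp <- nCell <- setNames(integer(length(conds)), conds)
    for (cond in conds) {
        s <- summaries[summaries$condition == cond, , drop = FALSE]
        raw[cond] <- computeRawScore(s, ratioMode)
        nExp[cond] <- nrow(s)
        cells <- measurements[measurements$condition == cond, ,
                              drop = FALSE]
        nCell[cond] <- sum(!is.na(cells$positive))
        pct <- 100 * mean(cells$positive[!is.na(cells$positive)])
        mr <- mean(cells$compartment_ratio[!is.na(cells$compartment_ratio)])
        pooledRaw[cond] <- pct * mr
    }
    out <- data.frame(condition = conds, compartment_kind = compartmentKind,
                      n_experiments = nExp[conds], n_cells = nCell[conds],
                      raw_score = raw[conds],
                      normalized_score = normalizeScores(raw, reference)[conds],
                      pooled_raw = pooledRaw[conds],
                      pooled_normalized = normalizeScores(pooledRaw,
                                                          reference)[conds],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (nBoot > 0) {
        ci <- .scoreBootstrap(measurements, reference, compartmentKind,
                              minCells, ratioMode, nBoot, bootSeed)
        out$boot_lo <- ci[out$condition, 1]
        out$boot_hi <- ci[out$condition, 2]
    }
    attr(out, "provenance") <- list(
        reference = reference, min_cells = minCells,
        ratio_mode = ratioMode, n_boot = nBoot,
        per_experiment = summaries)
    out
}

.scoreBootstrap <- function(measurements, reference, compartmentKind,
                            minCells, ratioMode, nBoot, bootSeed) {
    conds <- unique(measurements$condition)
    withr::with_seed(as.integer(bootSeed), {
        reps <- matrix(NA_real_, nBoot, length(conds),
                       dimnames = list(NULL, conds))
        byCond <- split(measurements, measurements$condition)
        for (b in seq_len(nBoot)) {
            raw <- setNames(numeric(length(conds)), conds)
            for (cond in conds) {
                sub <- byCond[[cond]]
                exps <- unique(sub$experiment_id)
                pick <- sample(exps, length(exps), replace = TRUE)
                ss <- lapply(seq_along(pick), function(i) {
                    cells <- sub[sub$experiment_id == pick[i], ,
                                 drop = FALSE]
                    cells <- cells[sample(nrow(cells), nrow(cells),
                                          replace = TRUE), , drop = FALSE]
                    suppressWarnings(summarizeExperiment(
                        cells, cond, i, compartmentKind, minCells))
                })
                raw[cond] <- computeRawScore(do.call(rbind, ss), ratioMode)
            }
            if (raw[reference] > 0)
                reps[b, ] <- normalizeScores(raw, reference)[conds]
        }
        t(apply(reps, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
    })
}

#' Positivity-threshold sensitivity sweep
#'
#' Recomputes the normalized localization scores across a grid of
#' positivity thresholds, exposing how sensitive condition rankings are to
#' the (necessarily arbitrary) operationalization of "visible compartment
#' localization".
#'
#' @param measurements per-cell data.frame (with
#'   \code{compartment_ratio}; positivity is re-derived per threshold).
#' @param reference reference condition.
#' @param thresholds numeric vector of thresholds (default 1.2 to 2.0).
#' @param ... passed to \code{\link{scorePipeline}}.
#' @return data.frame: threshold, condition, normalized_score.
#' @export
thresholdSweep <- function(measurements, reference,
                           thresholds = seq(1.2, 2.0, by = 0.1), ...) {
    out <- list()
    for (th in thresholds) {
        m <- classifyPositive(measurements, th)
        sc <- suppressWarnings(scorePipeline(m, reference, ...))
        out[[length(out) + 1L]] <-
            data.frame(threshold = th, condition = sc$condition,
                       normalized_score = sc$normalized_score,
                       stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
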