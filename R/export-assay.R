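#' @include segment-quant.R
NULL

#' Per-cell nuclear/cytoplasmic cargo ratio
#'
#' N/C ratio = mean nuclear cargo intensity / mean cytoplasmic cargo
#' intensity of the same cell.  Only meaningful where a cytoplasm mask
#' exists: in clustered mode the call is an explicit error, and cells
#' whose cytoplasm mean is missing or non-positive get NA with a reason,
#' never an exception.
#'
#' @param measurements data.frame with \code{cargo_nuc_mean} and
#'   \code{cargo_cyto_mean} columns.
#' @param mode "large_cytoplasm" (default) or "clustered".
#' @return the data.frame with \code{nc_ratio} and
#'   \code{nc_ratio_reason} columns.
#' @examples
#' m <- data.frame(cargo_nuc_mean = 50, cargo_cyto_mean = 100)
#' computeNCRatio(m)$nc_ratio  # 0.5
#' @export
computeNCRatio <- function(measurements,
                           mode = c("large_cytoplasm", "clustered")) {
    mode <- match.arg(mode)
    if (mode == "clustered")
        stop("cytoplasmic intensity is not assessed in clustered mode; ",
             "use computeNTotalRatio()")
    nuc <- measurements$cargo_nuc_mean
    cyto <- measurements$cargo_cyto_mean
    ok <- !is.na(nuc) & !is.na(cyto) & cyto > 0
    measurements$nc_ratio <- ifelse(ok, nuc / cyto, NA_real_)
    measurements$nc_ratio_reason <-
        ifelse(ok, "", ifelse(is.na(cyto), "no_cytoplasm_mask",
                              "non_positive_cytoplasm"))
    measurements
}

#' Per-cell nuclear/total cargo ratio
#'
#' N/total ratio = mean nuclear cargo intensity / mean cargo intensity of
#' the whole micrograph (every pixel, background included), used where
#' individual cytoplasms cannot be delineated.
#'
#' @param measurements data.frame with a \code{cargo_nuc_mean} column.
#' @param fieldMean mean of the entire cargo channel (see
#'   \code{\link{cargoFieldMean}}).
#' @return the data.frame with an \code{n_total_ratio} column.
#' @export
computeNTotalRatio <- function(measurements, fieldMean) {
    if (!is.finite(fieldMean) || fieldMean <= 0)
        stop("fieldMean must be a positive number")
    measurements$n_total_ratio <- measurements$cargo_nuc_mean / fieldMean
    measurements
}

#' Whole-micrograph cargo mean
#'
#' The "total" fluorescence of the field: the mean over every pixel of
#' the cargo channel, including background.
#'
#' @param x a \code{\linkS4class{Scene}} or a height x width x 4 array.
#' @return a single number (a.u.).
#' @export
cargoFieldMean <- function(x) {
    ch <- if (is(x, "Scene")) sceneChannel(x, "cargo") else x[, , 4]
    mean(ch)
}

#' Assay cargo export for a set of conditions
#'
#' Builds per-cell export records (N/C ratio in large-cytoplasm mode,
#' N/total ratio in clustered mode) after transfection selection, together
#' with the expression control: each condition's nuclear YFP distribution
#' is compared to the reference by Student's t test, and conditions whose
#' expression differs at p < 0.05 are flagged non-comparable, since an
#' apparent export difference could then be an expression artifact.
#'
#' @param cells per-cell data.frame spanning conditions, with
#'   \code{condition}, \code{cell_id}, \code{yfp_nuc_mean},
#'   \code{cargo_nuc_mean} and (in large-cytoplasm mode)
#'   \code{cargo_cyto_mean} columns.
#' @param mode "large_cytoplasm" or "clustered".
#' @param cargoName label recorded on each record.
#' @param yfpWindow transfection window (see
#'   \code{\link{selectTransfected}}); NULL keeps all cells.
#' @param fieldMeans named numeric vector of whole-field cargo means per
#'   condition (required in clustered mode).
#' @param reference reference condition for the expression control; NULL
#'   skips the control.
#' @param minCells conditions scoring fewer cells are flagged underpowered
#'   in the control table.  Default 25.
#' @param tVariant t-test variant for the expression control.
#' @return list with \code{records} (per-cell data.frame: cell_id,
#'   condition, cargo_name, mode, yfp_nuc_mean, nc_ratio or
#'   n_total_ratio) and \code{expressionControl} (per-condition
#'   data.frame: n, yfp_mean, t_stat, df, p_value, comparable,
#'   underpowered; NULL when no reference given).
#' @export
assayCondition <- function(cells, mode = c("large_cytoplasm", "clustered"),
                           cargoName = "cargo", yfpWindow = NULL,
                           fieldMeans = NULL, reference = NULL,
                           minCells = 25,
                           tVariant = c("pooled", "welch")) {
    mode <- match.arg(mode)
    tVariant <- match.arg(tVariant)
    if (!is.null(yfpWindow)) {
        parts <- split(cells, cells$condition)
        cells <- do.call(rbind, lapply(parts, selectTransfected,
                                       window = yfpWindow))
        rownames(cells) <- NULL
    }
    if (mode == "large_cytoplasm") {
        cells <- computeNCRatio(cells, mode)
        keep <- c("cell_id", "condition", "yfp_nuc_mean", "nc_ratio")
    } else {
        if (!"n_total_ratio" %in% names(cells)) {
            ## ratios not precomputed per micrograph: use per-condition
            ## field means
            if (is.null(fieldMeans))
                stop("clustered mode requires per-condition fieldMeans ",
                     "or a precomputed n_total_ratio column")
            parts <- split(cells, cells$condition)
            for (cond in names(parts)) {
                if (!cond %in% names(fieldMeans))
                    stop("no field mean for condition '", cond, "'")
                parts[[cond]] <- computeNTotalRatio(parts[[cond]],
                                                    fieldMeans[[cond]])
            }
            cells <- do.call(rbind, parts)
            rownames(cells) <- NULL
        }
        keep <- c("cell_id", "condition", "yfp_nuc_mean", "n_total_ratio")
    }
    records <- cells[, intersect(keep, names(cells)), drop = FALSE]
    records$cargo_name <- cargoName
    records$mode <- mode
    control <- NULL
    if (!is.null(reference)) {
        if (!reference %in% records$condition)
            stop("reference condition '", reference,
                 "' absent from the records")
        refY <- records$yfp_nuc_mean[records$condition == reference]
        rows <- list()
        for (cond in unique(records$condition)) {
            y <- records$yfp_nuc_mean[records$condition == cond]
            tt <- studentT(y, refY, variant = tVariant)
            rows[[cond]] <- data.frame(
                condition = cond, n = length(y), yfp_mean = mean(y),
                t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
                comparable = tt$p_value >= 0.05,
                underpowered = length(y) < minCells,
                stringsAsFactors = FALSE)
            if (length(y) < minCells)
                warning("condition '", cond, "': only ", length(y),
                        " cells in the export assay (min ", minCells, ")")
        }
        control <- do.call(rbind, rows)
        rownames(control) <- NULL
    }
    list(records = records, expressionControl = control)
}
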