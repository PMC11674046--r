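#' @include export-assay.R
NULL

#' Two-sample Student's t test
#'
#' Classic two-sided Student's t test; the default "pooled" variant uses
#' the pooled-variance statistic with n_a + n_b - 2 degrees of freedom,
#' "welch" uses the Welch-Satterthwaite approximation.  Degenerate inputs
#' follow explicit conventions instead of erroring: if both samples have
#' zero variance, p = 1 when the means are equal and p = 0 (flagged
#' degenerate) when they differ.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variant "pooled" (default) or "welch".
#' @return list with \code{t_stat}, \code{df}, \code{p_value},
#'   \code{degenerate}.
#' @examples
#' studentT(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
studentT <- function(a, b, variant = c("pooled", "welch")) {
    variant <- match.arg(variant)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
        stop("each sample needs at least 2 non-missing values")
    df <- length(a) + length(b) - 2
    if (var(a) + var(b) == 0) {
        if (mean(a) == mean(b))
            return(list(t_stat = 0, df = df, p_value = 1,
                        degenerate = FALSE))
        return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = df,
                    p_value = 0, degenerate = TRUE))
    }
    tt <- t.test(a, b, var.equal = (variant == "pooled"))
    list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' Significance star labels
#'
#' Figure-legend mapping with strict inequalities: "****" for p < 0.0001,
#' "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05, else "n.s."
#' (so p = 0.05 exactly is non-significant).
#'
#' @param p numeric vector of p values in [0, 1]; NA/NaN is an error.
#' @return character vector of labels.
#' @examples
#' starsLabel(c(0.04, 0.05, 5e-5))
#' @export
starsLabel <- function(p) {
    if (any(is.na(p))) stop("p values must not be NA/NaN")
    if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
    out <- rep("n.s.", length(p))
    out[p < 0.05] <- "*"
    out[p < 0.01] <- "**"
    out[p < 0.001] <- "***"
    out[p < 0.0001] <- "****"
    out
}

#' Compare every condition to the reference on chosen metrics
#'
#' One Student's t comparison per condition x metric against the reference
#' condition, on per-cell (or per-experiment, for percentage metrics)
#' values.  No multiple-testing correction is applied by default; with
#' \code{holm = TRUE} Holm step-down adjusted p values and re-derived star
#' labels are appended as an extension.
#'
#' @param records data.frame with a \code{condition} column and one
#'   numeric column per metric.
#' @param reference reference condition name.
#' @param metrics character vector of metric column names.
#' @param variant t-test variant (see \code{\link{studentT}}).
#' @param holm append Holm-adjusted p values and stars.
#' @return data.frame: condition, reference, metric, t_stat, df, p_value,
#'   stars, n_condition, n_reference (+ p_holm, stars_holm).
#' @export
compareAll <- function(records, reference, metrics,
                       variant = c("pooled", "welch"), holm = FALSE) {
    variant <- match.arg(variant)
    missingMetrics <- setdiff(metrics, names(records))
    if (length(missingMetrics))
        stop("metric(s) absent from the records: ",
             paste(missingMetrics, collapse = ", "))
    if (!reference %in% records$condition)
        stop("reference condition '", reference, "' absent")
    rows <- list()
    for (metric in metrics) {
        ref <- records[records$condition == reference, metric]
        ref <- ref[!is.na(ref)]
        for (cond in unique(records$condition)) {
            v <- records[records$condition == cond, metric]
            v <- v[!is.na(v)]
            if (length(v) < 2 || length(ref) < 2) next
            tt <- studentT(v, ref, variant = variant)
            rows[[length(rows) + 1L]] <- data.frame(
                condition = cond, reference = reference, metric = metric,
                t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
                stars = starsLabel(tt$p_value),
                n_condition = length(v), n_reference = length(ref),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (holm && !is.null(out)) {
        out$p_holm <- p.adjust(out$p_value, method = "holm")
        out$stars_holm <- starsLabel(out$p_holm)
    }
    out
}
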