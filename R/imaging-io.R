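#' @include AllClasses.R
NULL

.fullPrecision <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
}

#' Write a multi-channel scene image as TIFF
#'
#' Writes one TIFF page per channel (canonical order dna, yfp, marker,
#' cargo) together with a sidecar JSON recording the channel order and the
#' intensity scale.  TIFF samples are stored as 32-bit values on a [0, 1]
#' scale; arbitrary-unit intensities are divided by \code{scale} (by
#' default the image maximum) on write and multiplied back on read, so a
#' round trip is exact to the 32-bit quantization step (better than 1e-9
#' of \code{scale} per pixel).
#'
#' @param image numeric array height x width x channels, non-negative.
#' @param path output TIFF path; the sidecar is written to
#'   \code{<path>.json}.
#' @param scale intensity scale; default \code{max(image)}.
#' @return invisibly, the sidecar metadata list.
#' @seealso \code{\link{readScene}}
#' @export
writeScene <- function(image, path, scale = NULL) {
    stopifnot(length(dim(image)) == 3)
    if (any(image < 0)) stop("image must be non-negative")
    if (is.null(scale)) scale <- max(image, 1e-12)
    pages <- lapply(seq_len(dim(image)[3]),
                    function(i) image[, , i] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    meta <- list(channels = channelRoles()[seq_len(dim(image)[3])],
                 scale = scale, height = dim(image)[1],
                 width = dim(image)[2])
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(meta)
}

#' Read a multi-channel scene image
#'
#' Reads a multi-page TIFF into a height x width x 4 array in canonical
#' channel order (dna, yfp, marker, cargo).  If a sidecar JSON written by
#' \code{\link{writeScene}} is present, stored values are multiplied by its
#' intensity scale; otherwise raw sample values are returned as floats
#' without rescaling (a 16-bit value of 65535 reads back as 65535.0).
#'
#' @param path TIFF path.
#' @param channelMap named integer vector mapping roles to 1-based page
#'   indices, e.g. \code{c(dna = 1, yfp = 2, marker = 3, cargo = 4)}
#'   (the default).  Each requested role must exist in the file.
#' @return numeric array height x width x length(channelMap), channels
#'   ordered as in \code{channelMap}.
#' @export
readScene <- function(path, channelMap = NULL) {
    if (!file.exists(path)) stop("no such image file: ", path)
    if (is.null(channelMap))
        channelMap <- setNames(seq_along(channelRoles()), channelRoles())
    if (is.null(names(channelMap)) || anyDuplicated(channelMap))
        stop("channelMap must be a named vector of distinct page indices")
    side <- paste0(path, ".json")
    scale <- 1
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (!is.null(meta$scale)) scale <- meta$scale
        pages <- tiff::readTIFF(path, all = TRUE)
    } else {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    }
    if (!is.list(pages)) pages <- list(pages)
    for (role in names(channelMap))
        if (channelMap[[role]] > length(pages) || channelMap[[role]] < 1)
            stop("channel role '", role, "' maps to page ",
                 channelMap[[role]], " but the file has only ",
                 length(pages), " page(s)")
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(channelMap)))
    for (i in seq_along(channelMap))
        arr[, , i] <- as.numeric(pages[[channelMap[[i]]]]) * scale
    dimnames(arr) <- list(NULL, NULL, names(channelMap))
    arr
}

#' Write per-cell tables with full float precision
#'
#' RFC-4180 CSV ('.' decimal, UTF-8, header row) with numeric columns
#' serialized at 17 significant digits so that
#' \code{\link{readMeasurements}} recovers every double bit for bit.
#' Column order is preserved.
#'
#' @param records data.frame (may have zero rows; a header-only file is
#'   written and read back as an empty table).
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeMeasurements <- function(records, path) {
    if (!is.data.frame(records)) stop("records must be a data.frame")
    if (any(vapply(records, is.list, logical(1))))
        stop("list columns cannot be serialized; flatten records first")
    out <- records
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- .fullPrecision(out[[j]])
    write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    invisible(path)
}

#' @rdname writeMeasurements
#' @param numericColumns optional character vector of columns to force to
#'   numeric; by default types are inferred from content.
#' @return \code{readMeasurements}: the data.frame.
#' @export
readMeasurements <- function(path, numericColumns = NULL) {
    df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    for (nm in intersect(numericColumns, names(df)))
        df[[nm]] <- as.numeric(df[[nm]])
    for (nm in names(df))
        if (is.character(df[[nm]]) && all(df[[nm]] %in%
                c("TRUE", "FALSE", NA_character_)))
            df[[nm]] <- as.logical(df[[nm]])
    df
}
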