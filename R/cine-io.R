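#' Read a single-slice cine DICOM series
#'
#' Reads every file in a directory as one uncompressed little-endian DICOM
#' frame, orders frames by cardiac phase (trigger time when present on all
#' files, otherwise instance number) and builds a calibrated
#' [CineSequence-class]. The frame interval is taken from the trigger-time
#' spacing, falling back to the FrameTime attribute. Reading fails
#' explicitly when phase information is missing (naming the offending
#' file), when files come from different slice positions, or when the
#' in-plane pixel spacing is anisotropic by more than 1\% — strain is a
#' physical length ratio and silently mixing calibrations would corrupt
#' it.
#'
#' @param directoryPath directory containing the DICOM files of one cine
#'   acquisition (one file per phase)
#' @return a [CineSequence-class]
#' @seealso [readImageStack()] for phantom/TIFF input
#' @export
readDicomSeries <- function(directoryPath) {
    files <- list.files(directoryPath, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) < 2L)
        stop("cine series needs at least 2 frames, found ", length(files),
             " file(s) in ", directoryPath)
    parsed <- lapply(sort(files), .dcmParse)

    spacing <- vapply(parsed, function(p) {
        ps <- .dcmGetNumeric(p, "0028,0030")
        if (length(ps) < 2L || anyNA(ps))
            stop("missing PixelSpacing in ", p$path)
        if (abs(ps[1L] - ps[2L]) > 0.01 * mean(ps))
            stop("anisotropic pixel spacing (", ps[1L], " x ", ps[2L],
                 " mm) in ", p$path)
        mean(ps)
    }, numeric(1))
    if (diff(range(spacing)) > 1e-6)
        stop("inconsistent pixel spacing across the series")

    slice <- vapply(parsed, function(p) {
        s <- .dcmGetNumeric(p, "0020,1041")[1L]
        if (is.na(s)) {
            ipp <- .dcmGetNumeric(p, "0020,0032")
            s <- if (length(ipp) == 3L && !anyNA(ipp)) ipp[3L] else 0
        }
        s
    }, numeric(1))
    if (diff(range(slice)) > 1e-3)
        stop("mixed slice positions in ", directoryPath,
             ": this reader handles a single-slice cine series")

    trig <- vapply(parsed, function(p) .dcmGetNumeric(p, "0018,1060")[1L],
        numeric(1))
    inst <- vapply(parsed, function(p) .dcmGetNumeric(p, "0020,0013")[1L],
        numeric(1))
    if (!anyNA(trig) && !anyDuplicated(trig)) {
        ord <- order(trig)
        interval <- stats::median(diff(sort(trig)))
    } else if (!anyNA(inst) && !anyDuplicated(inst)) {
        ord <- order(inst)
        interval <- .dcmGetNumeric(parsed[[1L]], "0018,1063")[1L]
        if (is.na(interval))
            stop("no temporal calibration: neither trigger times nor a ",
                 "FrameTime attribute in ", parsed[[1L]]$path)
    } else {
        bad <- which(is.na(trig) & is.na(inst))
        bad <- if (length(bad)) parsed[[bad[1L]]]$path else parsed[[1L]]$path
        stop("missing/unusable phase information (no trigger time or ",
             "instance number) in ", bad)
    }
    if (!is.finite(interval) || interval <= 0)
        stop("non-positive frame interval derived from metadata")

    frames <- lapply(parsed[ord], .dcmPixelMatrix)
    cineSequence(frames, pixelSpacing = spacing[1L], frameInterval = interval,
        sourceId = normalizePath(directoryPath))
}

#' Read a cine sequence from a multi-frame image stack
#'
#' Accepts a multi-frame TIFF (any bit depth r-tiff can decode) or an RDS
#' array archive holding a list of matrices or a rows x cols x frames
#' array. Frames keep file order; calibration comes from the arguments
#' because these container formats carry none.
#'
#' @param filePath path to a `.tif`/`.tiff` or `.rds` file
#' @param pixelSpacing mm per pixel
#' @param frameInterval ms between frames
#' @return a [CineSequence-class]
#' @export
readImageStack <- function(filePath, pixelSpacing, frameInterval) {
    ext <- tolower(tools::file_ext(filePath))
    if (ext %in% c("tif", "tiff")) {
        frames <- tiff::readTIFF(filePath, all = TRUE)
        if (!is.list(frames)) frames <- list(frames)
        frames <- lapply(frames, function(f) {
            if (length(dim(f)) == 3L) f <- f[, , 1L]
            f
        })
    } else if (ext == "rds") {
        obj <- readRDS(filePath)
        if (is.array(obj) && length(dim(obj)) == 3L)
            frames <- lapply(seq_len(dim(obj)[3L]), function(i) obj[, , i])
        else if (is.list(obj)) frames <- obj
        else stop("RDS archive must hold a list of matrices or a 3-D array")
    } else stop("unsupported stack format '.", ext, "'")
    if (length(frames) < 2L)
        stop("image stack has fewer than 2 frames")
    cineSequence(frames, pixelSpacing, frameInterval,
        sourceId = normalizePath(filePath))
}

#' Write a cine sequence to a multi-frame image stack
#'
#' TIFF output uses 32-bit pages, so intensities on the [0, 1] scale
#' round-trip to better than 1e-9 (values outside that range are clamped
#' with a warning — the TIFF container normalises to [0, 1]); RDS output
#' is exact for any values.
#'
#' @param x a [CineSequence-class] or list of matrices
#' @param filePath destination `.tif`/`.tiff` or `.rds`
#' @return `filePath`, invisibly
#' @export
writeImageStack <- function(x, filePath) {
    frames <- if (is(x, "CineSequence")) frames(x) else x
    ext <- tolower(tools::file_ext(filePath))
    if (ext %in% c("tif", "tiff")) {
        rng <- range(unlist(lapply(frames, range)))
        if (rng[1] < 0 || rng[2] > 1) {
            warning("TIFF stores intensities on [0, 1]; clamping ",
                "out-of-range values (use an RDS archive for exact storage)")
            frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
        }
        tiff::writeTIFF(frames, filePath, bits.per.sample = 32L)
    } else if (ext == "rds") {
        saveRDS(frames, filePath)
    } else stop("unsupported stack format '.", ext, "'")
    invisible(filePath)
}

#' Read contours from a delineation CSV
#'
#' The file carries one row per border point with columns
#' `frame_index,point_order,x_mm,y_mm,topology`. One [Contour-class] is
#' returned per frame present, points sorted by `point_order`. Duplicate
#' (frame, order) pairs and mixed topology within one file are errors.
#'
#' @param filePath CSV path
#' @return list of [Contour-class], ordered by frame index
#' @export
readContourFile <- function(filePath) {
    df <- utils::read.csv(filePath, stringsAsFactors = FALSE)
    need <- c("frame_index", "point_order", "x_mm", "y_mm", "topology")
    if (!all(need %in% names(df)))
        stop("contour file must have columns ", paste(need, collapse = ","))
    if (anyDuplicated(df[, c("frame_index", "point_order")]))
        stop("duplicate (frame_index, point_order) pair in ", filePath)
    tp <- unique(df$topology)
    if (length(tp) != 1L)
        stop("mixed topology within one contour file: ",
             paste(tp, collapse = ", "))
    frames <- sort(unique(df$frame_index))
    lapply(frames, function(f) {
        sub <- df[df$frame_index == f, ]
        sub <- sub[order(sub$point_order), ]
        contour(cbind(sub$x_mm, sub$y_mm), tp, as.integer(f))
    })
}

#' Write contours to a delineation CSV
#'
#' Inverse of [readContourFile()]; coordinates are written with six
#' decimal places, so a round trip is lossless to 1e-6 mm.
#'
#' @param contoursList non-empty list of [Contour-class]
#' @param filePath destination CSV path
#' @return `filePath`, invisibly
#' @export
writeContourFile <- function(contoursList, filePath) {
    if (is(contoursList, "ContourTrack")) contoursList <- contours(contoursList)
    if (!is.list(contoursList) || length(contoursList) == 0L)
        stop("contour list must be non-empty")
    rows <- lapply(contoursList, function(ct) {
        p <- coords(ct)
        data.frame(frame_index = frameIndex(ct),
            point_order = seq_len(nrow(p)) - 1L,
            x_mm = sprintf("%.6f", p[, 1L]),
            y_mm = sprintf("%.6f", p[, 2L]),
            topology = topology(ct))
    })
    utils::write.csv(do.call(rbind, rows), filePath, row.names = FALSE,
        quote = FALSE)
    invisible(filePath)
}

#' Write a strain curve as CSV (frame, length_mm, strain_percent)
#'
#' @param x a [StrainCurve-class]
#' @param filePath destination CSV path
#' @return `filePath`, invisibly
#' @export
writeStrainCurve <- function(x, filePath) {
    stopifnot(is(x, "StrainCurve"))
    utils::write.csv(data.frame(
        frame = seq_along(x@values) - 1L,
        length_mm = x@lengths,
        strain_percent = x@values), filePath, row.names = FALSE)
    invisible(filePath)
}
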