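#' Construct a CineSequence
#'
#' @param frames list of numeric matrices (one per phase)
#' @param pixelSpacing mm per pixel (isotropic)
#' @param frameInterval ms between phases
#' @param sourceId provenance label
#' @return a [CineSequence-class]
#' @examples
#' cs <- cineSequence(list(matrix(0, 8, 8), matrix(1, 8, 8)), 1, 40)
#' phaseCount(cs)
#' @export
cineSequence <- function(frames, pixelSpacing, frameInterval,
                         sourceId = "unspecified") {
    frames <- lapply(frames, function(f) {
        storage.mode(f) <- "double"
        f
    })
    new("CineSequence", frames = frames, pixelSpacing = as.numeric(pixelSpacing),
        frameInterval = as.numeric(frameInterval), sourceId = sourceId)
}

#' Construct a Contour
#'
#' @param coords n x 2 matrix of (x, y) positions in mm
#' @param topology "open" or "closed"
#' @param frameIndex 0-based cardiac phase
#' @return a [Contour-class]
#' @examples
#' contour(cbind(c(0, 3, 3), c(0, 0, 4)), "open")
#' @export
contour <- function(coords, topology = c("open", "closed"), frameIndex = 0L) {
    topology <- match.arg(topology)
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    colnames(coords) <- c("x", "y")
    new("Contour", coords = coords, topology = topology,
        frameIndex = as.integer(frameIndex))
}

#' Construct feature-tracking parameters
#'
#' Defaults assume roughly 1 mm/pixel in-plane resolution and 30-40 ms
#' temporal resolution, where inter-frame endocardial motion is a few
#' pixels: the search covers it and the smoothing window is the smallest
#' that stabilises noisy matches without flattening real deformation.
#'
#' @param templateHalfWidth half width of the square template, px (>= 3)
#' @param searchRadius search radius, px (bounded by templateHalfWidth + 5)
#' @param smoothingWindow odd window of adjacent contour points (1 = off)
#' @param driftCompensation remove the cyclic-closure residual
#' @param normalRefinement refine matches along the border normal to the
#'   intensity-gradient maximum
#' @return a [TrackingParams-class]
#' @export
trackingParams <- function(templateHalfWidth = 5L, searchRadius = 5L,
                           smoothingWindow = 5L, driftCompensation = TRUE,
                           normalRefinement = TRUE) {
    new("TrackingParams",
        templateHalfWidth = as.integer(templateHalfWidth),
        searchRadius = as.integer(searchRadius),
        smoothingWindow = as.integer(smoothingWindow),
        driftCompensation = isTRUE(driftCompensation),
        normalRefinement = isTRUE(normalRefinement))
}

#' @rdname CineSequence-class
#' @export
setMethod("frames", "CineSequence", function(x) x@frames)

#' @rdname CineSequence-class
#' @export
setMethod("pixelSpacing", "CineSequence", function(x) x@pixelSpacing)

#' @rdname CineSequence-class
#' @export
setMethod("frameInterval", "CineSequence", function(x) x@frameInterval)

#' @rdname CineSequence-class
#' @export
setMethod("phaseCount", "CineSequence", function(x) length(x@frames))

#' @rdname CineSequence-class
#' @export
setMethod("sourceId", "CineSequence", function(x) x@sourceId)

#' @rdname Contour-class
#' @export
setMethod("coords", "Contour", function(x) x@coords)

#' @rdname Contour-class
#' @export
setMethod("topology", "Contour", function(x) x@topology)

#' @rdname Contour-class
#' @export
setMethod("frameIndex", "Contour", function(x) x@frameIndex)

#' @rdname ContourTrack-class
#' @export
setMethod("contours", "ContourTrack", function(x) x@contours)

#' @rdname ContourTrack-class
#' @export
setMethod("trackSource", "ContourTrack", function(x) x@source)

#' @rdname ContourTrack-class
#' @export
setMethod("trackParams", "ContourTrack", function(x) x@params)

#' @rdname ContourTrack-class
#' @export
setMethod("phaseCount", "ContourTrack", function(x) length(x@contours))

#' @rdname ContourTrack-class
#' @export
setMethod("topology", "ContourTrack", function(x) x@contours[[1L]]@topology)

#' @rdname StrainCurve-class
#' @export
setMethod("strainValues", "StrainCurve", function(x) x@values)

#' @rdname StrainCurve-class
#' @export
setMethod("borderLengths", "StrainCurve", function(x) x@lengths)

#' @rdname StrainCurve-class
#' @export
setMethod("referenceFrame", "StrainCurve", function(x) x@referenceFrame)

#' @rdname peakStrain
#' @export
setMethod("peakStrain", "StrainCurve", function(x) max(abs(x@values)))

#' @rdname AgreementReport-class
#' @export
setMethod("nPairs", "AgreementReport", function(x) x@nPairs)

#' @rdname AgreementReport-class
#' @export
setMethod("bias", "AgreementReport", function(x) x@bias)

#' @rdname AgreementReport-class
#' @export
setMethod("limitsOfAgreement", "AgreementReport",
    function(x) c(low = x@loaLow, high = x@loaHigh))

#' @rdname AgreementReport-class
#' @export
setMethod("covPercent", "AgreementReport", function(x) x@covPercent)

setMethod("show", "CineSequence", function(object) {
    d <- dim(object@frames[[1L]])
    cat(sprintf(
        "CineSequence '%s': %d phases of %dx%d px, %.3g mm/px, %.3g ms/frame\n",
        object@sourceId, length(object@frames), d[1L], d[2L],
        object@pixelSpacing, object@frameInterval))
})

setMethod("show", "Contour", function(object) {
    cat(sprintf("Contour (%s): %d points, frame %d, length %.2f mm\n",
        object@topology, nrow(object@coords), object@frameIndex,
        borderLength(object)))
})

setMethod("show", "ContourTrack", function(object) {
    cat(sprintf("ContourTrack (%s, %s): %d points x %d frames\n",
        object@source, topology(object), nrow(object@contours[[1L]]@coords),
        length(object@contours)))
})

setMethod("show", "StrainCurve", function(object) {
    cat(sprintf(
        "StrainCurve (%s): %d frames, reference frame %d, peak %.2f%%\n",
        object@direction, length(object@values), object@referenceFrame,
        peakStrain(object)))
})

setMethod("show", "AgreementReport", function(object) {
    cat(sprintf(
        "AgreementReport: n = %d, bias %.3f, LoA [%.3f, %.3f], COV %.1f%%\n",
        object@nPairs, object@bias, object@loaLow, object@loaHigh,
        object@covPercent))
})

setMethod("show", "SegmentalStrainResult", function(object) {
    cat(sprintf("SegmentalStrainResult: %d segments, peaks %s%%\n",
        object@nSegments,
        paste(sprintf("%.1f", object@perSegmentPeak), collapse = "/")))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec (%s): size %.1f mm, wall %.1f mm, strain %.1f%%, %d phases, noise %.3g, seed %d\n",
        object@geometry, object@edSize, object@wallThickness,
        object@truePeakStrain, object@phaseCount, object@noiseSd, object@seed))
})

setMethod("show", "PhantomOutput", function(object) {
    cat("PhantomOutput\n  ")
    show(object@spec)
    cat("  ")
    show(object@sequence)
    cat("  ")
    show(object@truthStrain)
})

#' @rdname PhantomOutput-class
#' @param x a [PhantomOutput-class]
#' @export
phantomSequence <- function(x) x@sequence

#' @rdname PhantomOutput-class
#' @export
truthTrack <- function(x) x@truthTrack

#' @rdname PhantomOutput-class
#' @export
truthStrain <- function(x) x@truthStrain

#' @rdname PhantomOutput-class
#' @export
phantomSpecOf <- function(x) x@spec

#' @rdname SegmentalStrainResult-class
#' @param x a [SegmentalStrainResult-class]
#' @export
segmentPeaks <- function(x) x@perSegmentPeak

#' @rdname SegmentalStrainResult-class
#' @export
segmentBoundaries <- function(x) x@segmentBoundaries

#' @rdname SegmentalStrainResult-class
#' @export
segmentRefLengths <- function(x) x@segmentRefLengths
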