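#' @rdname CineSequence-class
#' @param object,x a cineStrain object
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname CineSequence-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname CineSequence-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname CineSequence-class
#' @export
setGeneric("phaseCount", function(x) standardGeneric("phaseCount"))

#' @rdname CineSequence-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname Contour-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Contour-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname Contour-class
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname ContourTrack-class
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))

#' @rdname ContourTrack-class
#' @export
setGeneric("trackSource", function(x) standardGeneric("trackSource"))

#' @rdname ContourTrack-class
#' @export
setGeneric("trackParams", function(x) standardGeneric("trackParams"))

#' @rdname StrainCurve-class
#' @export
setGeneric("strainValues", function(x) standardGeneric("strainValues"))

#' @rdname StrainCurve-class
#' @export
setGeneric("borderLengths", function(x) standardGeneric("borderLengths"))

#' @rdname StrainCurve-class
#' @export
setGeneric("referenceFrame", function(x) standardGeneric("referenceFrame"))

#' Absolute peak global strain of a curve
#'
#' The maximum absolute per-frame strain; global strain values are reported
#' as absolute values.
#'
#' @param x a [StrainCurve-class]
#' @return non-negative scalar, percent
#' @export
setGeneric("peakStrain", function(x) standardGeneric("peakStrain"))

#' @rdname AgreementReport-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname AgreementReport-class
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname AgreementReport-class
#' @export
setGeneric("limitsOfAgreement", function(x) standardGeneric("limitsOfAgreement"))

#' @rdname AgreementReport-class
#' @export
setGeneric("covPercent", function(x) standardGeneric("covPercent"))

#' Border length of a contour
#'
#' Sum of Euclidean distances between consecutive points; closed contours
#' add the implied closing segment from the last point back to the first.
#'
#' @param x a [Contour-class] (or an n x 2 coordinate matrix via the
#'   matrix method, treated as open)
#' @return length in mm
#' @export
setGeneric("borderLength", function(x) standardGeneric("borderLength"))
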