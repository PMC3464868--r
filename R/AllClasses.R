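#' @import methods
NULL

#' CineSequence: a single-slice cine acquisition
#'
#' Ordered image frames covering one cardiac cycle for one slice, with
#' physical calibration. Frames are numeric matrices indexed `[row, col]`;
#' physical coordinates are millimetres, 0-based, origin at the centre of
#' the top-left pixel, x along columns and y along rows.
#'
#' @slot frames list of numeric matrices, one per cardiac phase, all of
#'   identical dimension.
#' @slot pixelSpacing isotropic in-plane resolution in mm/pixel (> 0).
#' @slot frameInterval time between consecutive phases in ms (> 0).
#' @slot sourceId free-text provenance label.
#'
#' @seealso [readDicomSeries()], [readImageStack()], [makePhantom()]
#' @export
setClass("CineSequence",
    representation(
        frames = "list",
        pixelSpacing = "numeric",
        frameInterval = "numeric",
        sourceId = "character"
    )
)

setValidity("CineSequence", function(object) {
    msg <- NULL
    if (length(object@frames) < 2L)
        msg <- c(msg, "a cine sequence needs at least 2 frames")
    if (!all(vapply(object@frames, is.matrix, logical(1))))
        msg <- c(msg, "all frames must be numeric matrices")
    dims <- vapply(object@frames, dim, integer(2))
    if (length(object@frames) >= 2L && any(dims != dims[, 1]))
        msg <- c(msg, "all frames must share identical dimensions")
    if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
        object@pixelSpacing <= 0)
        msg <- c(msg, "pixelSpacing must be a positive scalar (mm)")
    if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
        object@frameInterval <= 0)
        msg <- c(msg, "frameInterval must be a positive scalar (ms)")
    if (is.null(msg)) TRUE else msg
})

#' Contour: ordered sub-pixel boundary points for one frame
#'
#' Coordinates are physical millimetres in the [CineSequence-class]
#' convention. Closed contours (short-axis cavity borders) do not repeat
#' the first point; closure is implied and every length computation adds
#' the closing segment explicitly. Open contours are four-chamber-style
#' borders running annulus to annulus.
#'
#' @slot coords n x 2 numeric matrix of (x, y) positions in mm.
#' @slot topology `"open"` or `"closed"`.
#' @slot frameIndex 0-based cardiac phase this contour belongs to.
#' @export
setClass("Contour",
    representation(
        coords = "matrix",
        topology = "character",
        frameIndex = "integer"
    )
)

setValidity("Contour", function(object) {
    msg <- NULL
    p <- object@coords
    if (!is.numeric(p) || ncol(p) != 2L)
        msg <- c(msg, "coords must be an n x 2 numeric matrix")
    if (nrow(p) < 3L)
        msg <- c(msg, "a contour needs at least 3 points")
    if (!object@topology %in% c("open", "closed"))
        msg <- c(msg, "topology must be 'open' or 'closed'")
    if (nrow(p) >= 2L) {
        d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
        if (any(d < 1e-9))
            msg <- c(msg, "consecutive contour points must be distinct")
        if (identical(object@topology, "closed") &&
            sqrt(sum((p[1L, ] - p[nrow(p), ])^2)) < 1e-9)
            msg <- c(msg, "closed contours must not repeat the first point")
    }
    if (length(object@frameIndex) != 1L || object@frameIndex < 0L)
        msg <- c(msg, "frameIndex must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
})

#' TrackingParams: feature-tracking tuning parameters
#'
#' @slot templateHalfWidth half width of the square matching template in
#'   pixels (template is (2w+1) x (2w+1)).
#' @slot searchRadius maximum per-frame displacement searched, in pixels.
#' @slot smoothingWindow odd number of adjacent contour points over which
#'   displacements are moving-averaged (1 disables smoothing).
#' @slot driftCompensation remove the cyclic-closure residual by linear
#'   redistribution across frames.
#' @slot normalRefinement refine each match along the local contour normal
#'   to the intensity-gradient maximum (+/- 2 px).
#' @export
setClass("TrackingParams",
    representation(
        templateHalfWidth = "integer",
        searchRadius = "integer",
        smoothingWindow = "integer",
        driftCompensation = "logical",
        normalRefinement = "logical"
    )
)

setValidity("TrackingParams", function(object) {
    msg <- NULL
    if (object@templateHalfWidth < 3L)
        msg <- c(msg, "templateHalfWidth must be >= 3 px")
    if (object@searchRadius < 1L)
        msg <- c(msg, "searchRadius must be >= 1 px")
    if (object@searchRadius > object@templateHalfWidth + 5L)
        msg <- c(msg, "searchRadius must be <= templateHalfWidth + 5 (bounded search)")
    if (object@smoothingWindow < 1L || object@smoothingWindow %% 2L == 0L)
        msg <- c(msg, "smoothingWindow must be an odd integer >= 1")
    if (is.null(msg)) TRUE else msg
})

#' ContourTrack: materially corresponding contours across all frames
#'
#' Point i denotes the same tissue point in every frame; the frame-0
#' contour equals the initial contour supplied to the tracker (or the
#' reference configuration of a phantom ground truth).
#'
#' @slot contours list of [Contour-class], one per frame, identical point
#'   count and topology, frame indices 0..P-1.
#' @slot params the [TrackingParams-class] used (defaults for ground truth).
#' @slot source `"tracked"` or `"ground_truth"`.
#' @export
setClass("ContourTrack",
    representation(
        contours = "list",
        params = "TrackingParams",
        source = "character"
    )
)

setValidity("ContourTrack", function(object) {
    msg <- NULL
    cs <- object@contours
    if (length(cs) < 2L)
        msg <- c(msg, "a track needs at least 2 frames")
    if (!all(vapply(cs, is, logical(1), "Contour")))
        msg <- c(msg, "contours must all be Contour objects")
    else {
        np <- vapply(cs, function(ct) nrow(ct@coords), integer(1))
        tp <- vapply(cs, function(ct) ct@topology, character(1))
        fi <- vapply(cs, function(ct) ct@frameIndex, integer(1))
        if (length(unique(np)) != 1L)
            msg <- c(msg, "all frames must have the same point count")
        if (length(unique(tp)) != 1L)
            msg <- c(msg, "all frames must share one topology")
        if (!identical(fi, seq_along(cs) - 1L))
            msg <- c(msg, "frame indices must run 0..P-1 in order")
    }
    if (!object@source %in% c("tracked", "ground_truth"))
        msg <- c(msg, "source must be 'tracked' or 'ground_truth'")
    if (is.null(msg)) TRUE else msg
})

#' StrainCurve: per-frame global Lagrangian strain
#'
#' Strain relative to the reference (maximal border length, end-diastole)
#' frame: epsilon_t = 100 * (L_t - L0) / L0. Values are signed (negative
#' for shortening); the reported peak is the absolute value at the extreme
#' length, available through [peakStrain()].
#'
#' @slot values per-frame strain in percent; exactly 0 at the reference
#'   frame.
#' @slot lengths per-frame border length in mm.
#' @slot referenceFrame 0-based index of the reference (L0) frame.
#' @slot direction one of `"border"`, `"longitudinal"`, `"circumferential"`,
#'   `"radial"` (for radial curves `values` are mean radial strain while
#'   `lengths` still carry the border lengths).
#' @export
setClass("StrainCurve",
    representation(
        values = "numeric",
        lengths = "numeric",
        referenceFrame = "integer",
        direction = "character"
    ),
    prototype(direction = "border")
)

setValidity("StrainCurve", function(object) {
    msg <- NULL
    if (length(object@values) != length(object@lengths))
        msg <- c(msg, "values and lengths must have equal length")
    if (length(object@values) < 2L)
        msg <- c(msg, "a strain curve needs at least 2 frames")
    rf <- object@referenceFrame
    if (length(rf) != 1L || rf < 0L || rf >= length(object@values))
        msg <- c(msg, "referenceFrame out of range")
    else if (abs(object@values[rf + 1L]) > 1e-9)
        msg <- c(msg, "strain at the reference frame must be 0")
    if (is.null(msg)) TRUE else msg
})

#' SegmentalStrainResult: per-segment peak strain
#'
#' The reference contour is partitioned into segments of equal arc length;
#' the border-length strain definition is applied to each segment's
#' polyline independently, peaks reported as absolute values.
#'
#' @slot nSegments number of segments (>= 2).
#' @slot perSegmentPeak absolute peak strain per segment, percent.
#' @slot segmentBoundaries arc-length fractions (0..1) delimiting segments
#'   on the reference contour.
#' @slot segmentRefLengths reference (maximal) polyline length per segment,
#'   mm; the length-weighted mean of segment strains approximates the
#'   global peak.
#' @export
setClass("SegmentalStrainResult",
    representation(
        nSegments = "integer",
        perSegmentPeak = "numeric",
        segmentBoundaries = "numeric",
        segmentRefLengths = "numeric"
    )
)

setValidity("SegmentalStrainResult", function(object) {
    msg <- NULL
    if (object@nSegments < 2L)
        msg <- c(msg, "need at least 2 segments")
    if (length(object@perSegmentPeak) != object@nSegments)
        msg <- c(msg, "one peak per segment required")
    if (any(object@perSegmentPeak < -1e-9))
        msg <- c(msg, "segment peaks are absolute values and must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' AgreementReport: Bland-Altman bias/limits and coefficient of variability
#'
#' Limits of agreement are bias +/- 2 * SD of the paired differences
#' (factor 2 exactly); the coefficient of variability is
#' 100 * SD(differences) / |grand mean of all values|.
#'
#' @slot nPairs number of measurement pairs.
#' @slot bias mean of differences a - b, input units.
#' @slot sdDiff sample (n-1) standard deviation of differences.
#' @slot loaLow,loaHigh bias -/+ 2 * sdDiff.
#' @slot covPercent coefficient of variability, percent (NA when the grand
#'   mean is zero).
#' @slot pairMeans,pairDiffs per-pair means and differences, kept for
#'   plotting.
#' @export
setClass("AgreementReport",
    representation(
        nPairs = "integer",
        bias = "numeric",
        sdDiff = "numeric",
        loaLow = "numeric",
        loaHigh = "numeric",
        covPercent = "numeric",
        pairMeans = "numeric",
        pairDiffs = "numeric"
    )
)

setValidity("AgreementReport", function(object) {
    msg <- NULL
    if (object@nPairs < 2L)
        msg <- c(msg, "need at least 2 pairs")
    if (abs((object@loaHigh - object@loaLow) - 4 * object@sdDiff) > 1e-8 *
        max(1, abs(object@sdDiff)))
        msg <- c(msg, "limits of agreement must span 4 * sdDiff")
    if (is.null(msg)) TRUE else msg
})

#' PhantomSpec: synthetic deforming-phantom definition
#'
#' Describes an SSFP-like cine phantom: a bright blood pool bounded by a
#' darker myocardial wall on a dim background, deforming cyclically with a
#' raised-cosine systolic waveform peaking near one third of the cycle.
#' Two geometries are supported: a short-axis ring (closed endocardial
#' border) and a four-chamber "U" (open border, annulus to annulus).
#'
#' @slot geometry `"short_axis_ring"` or `"four_chamber_u"`.
#' @slot edSize end-diastolic endocardial inner radius (ring) or border
#'   arc length (U shape), mm.
#' @slot wallThickness myocardial wall thickness at end-diastole, mm.
#' @slot truePeakStrain prescribed absolute peak shortening of the
#'   endocardial border, percent, in [0, 60).
#' @slot phaseCount number of cardiac phases (>= 8).
#' @slot pixelSpacing mm per pixel.
#' @slot frameInterval ms between phases.
#' @slot textureFeatureCount number of dark intramural texture blobs that
#'   move with the tissue (trabeculation-like features for the tracker).
#' @slot noiseSd per-pixel Gaussian noise SD, relative to a blood-myocardium
#'   contrast of 0.5 on a 0-1 intensity scale.
#' @slot seed RNG seed fixing blob placement and noise.
#' @slot nPoints points in the ground-truth contour track.
#' @export
setClass("PhantomSpec",
    representation(
        geometry = "character",
        edSize = "numeric",
        wallThickness = "numeric",
        truePeakStrain = "numeric",
        phaseCount = "integer",
        pixelSpacing = "numeric",
        frameInterval = "numeric",
        textureFeatureCount = "integer",
        noiseSd = "numeric",
        seed = "integer",
        nPoints = "integer"
    )
)

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    if (!object@geometry %in% c("short_axis_ring", "four_chamber_u"))
        msg <- c(msg, "geometry must be 'short_axis_ring' or 'four_chamber_u'")
    if (object@edSize <= 0) msg <- c(msg, "edSize must be positive")
    if (object@wallThickness <= 0) msg <- c(msg, "wallThickness must be positive")
    if (object@truePeakStrain < 0 || object@truePeakStrain >= 60)
        msg <- c(msg, "truePeakStrain must lie in [0, 60) percent")
    if (object@phaseCount < 8L) msg <- c(msg, "phaseCount must be >= 8")
    if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be positive")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive")
    if (object@textureFeatureCount < 0L)
        msg <- c(msg, "textureFeatureCount must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@nPoints < 24L) msg <- c(msg, "nPoints must be >= 24")
    if (is.null(msg)) TRUE else msg
})

#' PhantomOutput: rendered phantom plus analytic ground truth
#'
#' @slot sequence the rendered [CineSequence-class].
#' @slot truthTrack ground-truth [ContourTrack-class] of materially
#'   corresponding endocardial points.
#' @slot truthStrain ground-truth [StrainCurve-class]; its peak equals the
#'   prescribed strain up to contour discretisation (< 0.1 strain-points).
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomOutput",
    representation(
        sequence = "CineSequence",
        truthTrack = "ContourTrack",
        truthStrain = "StrainCurve",
        spec = "PhantomSpec"
    )
)

#' OutOfPlaneSpec: truncated-cone model of through-plane motion
#'
#' The ventricular cavity is modelled as a truncated cone with radius
#' decreasing linearly from base to apex. A fixed short-axis imaging plane
#' intersects it at a given fraction of the long axis; during systole the
#' tissue moves a prescribed distance toward the apex, so the plane samples
#' tissue that at end-diastole lay more basally (larger circumference).
#'
#' @slot baseRadius,apexRadius cavity radius at base and apex, mm
#'   (base > apex).
#' @slot longAxis base-to-apex length of the cone, mm.
#' @slot sliceLevelFraction position of the imaging plane as a fraction of
#'   the long axis measured from the base, in (0, 1).
#' @slot longitudinalDisplacement systolic apical displacement of tissue at
#'   the slice level, mm (>= 0).
#' @slot trueCs true material circumferential shortening, percent.
#' @export
setClass("OutOfPlaneSpec",
    representation(
        baseRadius = "numeric",
        apexRadius = "numeric",
        longAxis = "numeric",
        sliceLevelFraction = "numeric",
        longitudinalDisplacement = "numeric",
        trueCs = "numeric"
    )
)

setValidity("OutOfPlaneSpec", function(object) {
    msg <- NULL
    if (object@baseRadius <= 0 || object@apexRadius <= 0)
        msg <- c(msg, "radii must be positive")
    if (object@baseRadius <= object@apexRadius)
        msg <- c(msg, "baseRadius must exceed apexRadius (tapering cavity)")
    if (object@longAxis <= 0) msg <- c(msg, "longAxis must be positive")
    if (object@sliceLevelFraction <= 0 || object@sliceLevelFraction >= 1)
        msg <- c(msg, "sliceLevelFraction must lie in (0, 1)")
    if (object@longitudinalDisplacement < 0)
        msg <- c(msg, "longitudinalDisplacement must be >= 0")
    if (is.null(msg)) TRUE else msg
})
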