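# Feature tracking: per-point normalised cross-correlation template
# matching between consecutive frames (2-D tissue tracking on brightness
# inhomogeneity), optional 1-D refinement along the border normal to the
# intensity-gradient maximum, spatial smoothing of displacements across
# adjacent contour points, and optional cyclic drift compensation.

# Parabolic sub-sample refinement of a discrete peak: offset in (-0.5, 0.5)
# from three samples (left, centre, right). Non-concave or degenerate
# triplets return 0.
.parabolicOffset <- function(l, c, r) {
    den <- l - 2 * c + r
    if (!is.finite(den) || den >= -1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (l - r) / den))
}

# One Laplacian smoothing pass: pull each point toward the midpoint of
# its neighbours (open contours keep their endpoints). Suppresses the
# zigzag instability that pure per-point matching develops along feature-
# poor stretches of border, where the match has no tangential anchor.
.laplacianSmooth <- function(pos, closed, lambda = 0.5) {
    n <- nrow(pos)
    if (n < 3L) return(pos)
    nxt <- if (closed) c(2:n, 1L) else c(2:n, n)
    prv <- if (closed) c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
    mid <- (pos[nxt, , drop = FALSE] + pos[prv, , drop = FALSE]) / 2
    out <- (1 - lambda) * pos + lambda * mid
    if (!closed) {
        out[1L, ] <- pos[1L, ]
        out[n, ] <- pos[n, ]
    }
    out
}

# One tracking step: match every contour point from frame A (positions
# pos, 0-based px) into frame B. Returns the per-point displacement in px
# after normal refinement and along-contour smoothing.
.trackStep <- function(A, B, pos, closed, params, frameLabel) {
    h <- params@templateHalfWidth
    R <- params@searchRadius
    m <- 2L * h + 1L
    M <- m + 2L * R
    nS <- (2L * R + 1L)^2
    nPix <- m * m
    # candidate index map: shift (dy, dx) x template pixel (row-major in y)
    shifts <- expand.grid(dy = -R:R, dx = -R:R)
    pixc <- expand.grid(r = seq_len(m), c = seq_len(m))
    idx <- matrix(0L, nS, nPix)
    for (sI in seq_len(nS)) {
        idx[sI, ] <- (shifts$dx[sI] + R + pixc$c - 1L) * M +
            (shifts$dy[sI] + R + pixc$r)
    }
    og <- -h:h
    bg <- -(h + R):(h + R)
    nc <- ncol(B); nr <- nrow(B)
    n <- nrow(pos)
    disp <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
        cx <- pos[i, 1L]; cy <- pos[i, 2L]
        if (cx < h + R + 1 || cx > nc - 2 - h - R ||
            cy < h + R + 1 || cy > nr - 2 - h - R)
            stop(sprintf("tracking point %d left image bounds at frame %s",
                i, frameLabel))
        tmpl <- .bilinear(A, rep(cx + og, each = m), rep(cy + og, times = m))
        if (stats::sd(tmpl) < 1e-8) next  # flat template: fill from neighbours
        G <- .bilinear(B, rep(cx + bg, each = M), rep(cy + bg, times = M))
        C <- matrix(G[idx], nS, nPix)
        Cc <- C - rowMeans(C)
        Tn <- tmpl - mean(tmpl)
        den <- sqrt(rowSums(Cc^2)) * sqrt(sum(Tn^2))
        ncc <- as.vector(Cc %*% Tn) / pmax(den, 1e-12)
        ncc[den < 1e-12] <- -Inf
        # weak quadratic motion prior: inter-frame endocardial motion is a
        # small fraction of the search range, and gain-normalised matching
        # cannot tell the endocardial from the epicardial edge on its own —
        # without the prior an equally good far match can capture a point
        ncc <- ncc - 0.002 * (shifts$dx^2 + shifts$dy^2)
        best <- which.max(ncc)
        nccM <- matrix(ncc, 2L * R + 1L, 2L * R + 1L)
        iy <- (best - 1L) %% (2L * R + 1L) + 1L
        ix <- (best - 1L) %/% (2L * R + 1L) + 1L
        dy <- iy - R - 1L
        dx <- ix - R - 1L
        ddx <- if (ix > 1L && ix < 2L * R + 1L)
            .parabolicOffset(nccM[iy, ix - 1L], nccM[iy, ix], nccM[iy, ix + 1L])
        else 0
        ddy <- if (iy > 1L && iy < 2L * R + 1L)
            .parabolicOffset(nccM[iy - 1L, ix], nccM[iy, ix], nccM[iy + 1L, ix])
        else 0
        disp[i, ] <- c(dx + ddx, dy + ddy)
    }
    # impute flat-template points from their neighbourhood, then smooth
    # the raw match field along the contour: per-point matches carry no
    # tangential anchor on feature-poor border stretches, so unsmoothed
    # matches develop a zigzag random walk
    if (anyNA(disp[, 1L])) {
        fx <- .movingAverage(disp[, 1L], params@smoothingWindow, closed)
        fy <- .movingAverage(disp[, 2L], params@smoothingWindow, closed)
        na <- is.na(disp[, 1L])
        disp[na, 1L] <- fx[na]
        disp[na, 2L] <- fy[na]
    }
    disp <- cbind(.movingAverage(disp[, 1L], params@smoothingWindow, closed),
                  .movingAverage(disp[, 2L], params@smoothingWindow, closed))
    q <- .laplacianSmooth(pos + disp, closed)
    if (params@normalRefinement) {
        # border-edge step: slide each matched point along the (smoothed)
        # contour normal to the intensity-gradient maximum within +/- 2 px.
        # Offsets are applied unsmoothed — this is the step that removes
        # per-point radial error, and averaging opposite-sign corrections
        # across neighbours would cancel it; a light positional smoothing
        # pass afterwards restores spatial coherence.
        nrm <- .contourNormals(q, closed)
        step <- 0.25
        sGrid <- seq(-2, 2, by = step)
        offs <- numeric(n)
        for (i in seq_len(n)) {
            # average the profile over three lines offset along the local
            # tangent: the edge is locally straight, so this suppresses
            # image noise without biasing the edge position
            tx <- nrm[i, 2L]; ty <- -nrm[i, 1L]
            v <- 0
            for (o in c(-2, -1, 0, 1, 2)) {
                px <- q[i, 1L] + sGrid * nrm[i, 1L] + o * tx
                py <- q[i, 2L] + sGrid * nrm[i, 2L] + o * ty
                v <- v + .bilinear(B, px, py)
            }
            v <- v / 5
            g <- abs((v[-(1:2)] - v[seq_len(length(v) - 2L)]) / (2 * step))
            j <- which.max(g)
            if (g[j] < 0.02) next  # no reliable edge under this point
            dj <- if (j > 1L && j < length(g))
                .parabolicOffset(g[j - 1L], g[j], g[j + 1L]) else 0
            offs[i] <- sGrid[j + 1L] + dj * step
        }
        q <- q + offs * nrm
        q <- .laplacianSmooth(q, closed, lambda = 0.5)
    }
    q - pos
}

# Unit normals of a polyline/polygon from central-difference tangents.
.contourNormals <- function(pos, closed) {
    n <- nrow(pos)
    nxt <- if (closed) c(2:n, 1L) else c(2:n, n)
    prv <- if (closed) c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
    tx <- pos[nxt, 1L] - pos[prv, 1L]
    ty <- pos[nxt, 2L] - pos[prv, 2L]
    len <- pmax(sqrt(tx^2 + ty^2), 1e-12)
    cbind(-ty / len, tx / len)
}

#' Track an endocardial contour through a cine cycle
#'
#' Starting from a manually delineated contour on frame 0, each point is
#' followed frame to frame: (a) a square intensity template centred on the
#' point's previous position is matched in the next frame by maximising
#' normalised cross-correlation within the search radius, with parabolic
#' sub-pixel localisation; (b) optionally, the matched position is refined
#' along the local contour normal to the intensity-gradient maximum within
#' +/- 2 px (border-edge tracking); (c) displacements are smoothed by a
#' moving average over adjacent contour points (periodic for closed
#' contours) for spatial coherence; (d) optionally, the residual between
#' the cycle-closed last-frame positions and the initial contour is
#' removed by linear redistribution across frames (cardiac motion is
#' cyclic, so any closure residual is accumulated drift). Tracking is
#' fully deterministic.
#'
#' @param sequence a [CineSequence-class]
#' @param initialContour a [Contour-class] on frame 0, lying within the
#'   image with a margin of at least templateHalfWidth + searchRadius px
#' @param params a [TrackingParams-class]
#' @return a [ContourTrack-class] (`source = "tracked"`); its frame-0
#'   contour equals `initialContour`
#' @export
trackContour <- function(sequence, initialContour, params = trackingParams()) {
    stopifnot(is(sequence, "CineSequence"), is(initialContour, "Contour"),
        is(params, "TrackingParams"))
    validObject(params)
    ps <- pixelSpacing(sequence)
    fr <- frames(sequence)
    P <- length(fr)
    closed <- topology(initialContour) == "closed"
    pos0 <- coords(initialContour) / ps
    posList <- vector("list", P)
    posList[[1L]] <- pos0
    for (t in 2L:P) {
        posList[[t]] <- posList[[t - 1L]] +
            .trackStep(fr[[t - 1L]], fr[[t]], posList[[t - 1L]], closed,
                params, frameLabel = as.character(t - 1L))
    }
    if (params@driftCompensation) {
        wrapPos <- posList[[P]] +
            .trackStep(fr[[P]], fr[[1L]], posList[[P]], closed, params,
                frameLabel = "wrap")
        resid <- wrapPos - pos0
        for (t in 2L:P)
            posList[[t]] <- posList[[t]] - resid * (t - 1) / P
    }
    cts <- lapply(seq_len(P), function(t)
        contour(posList[[t]] * ps, topology(initialContour), t - 1L))
    new("ContourTrack", contours = cts, params = params, source = "tracked")
}

#' Global strain from a contour track
#'
#' Longitudinal (open, four-chamber border) and circumferential (closed,
#' short-axis border) strain apply the border-length strain definition to
#' the tracked per-frame border lengths. Radial strain reports the
#' per-frame mean over points of 100 * (r_t - r_ref) / r_ref, where r is
#' the distance to the cavity centroid of the reference (maximal-area)
#' frame — an endocardial surrogate for wall thickening.
#'
#' @param track a [ContourTrack-class]
#' @param direction `"longitudinal"`, `"circumferential"` or `"radial"`;
#'   longitudinal requires open topology, the others closed
#' @return a [StrainCurve-class]
#' @export
ftGlobalStrain <- function(track,
                           direction = c("longitudinal", "circumferential",
                                         "radial")) {
    stopifnot(is(track, "ContourTrack"))
    direction <- match.arg(direction)
    topo <- topology(track)
    if (direction == "longitudinal" && topo != "open")
        stop("longitudinal strain requires an open (four-chamber) contour")
    if (direction != "longitudinal" && topo != "closed")
        stop(direction, " strain requires a closed (short-axis) contour")
    cts <- contours(track)
    lengths <- vapply(cts, borderLength, numeric(1))
    if (direction != "radial") {
        sc <- .strainFromLengths(lengths, direction)
        return(sc)
    }
    areas <- vapply(cts, function(ct) .polygonArea(coords(ct)), numeric(1))
    ref <- which.max(areas)
    ctr <- .polygonCentroid(coords(cts[[ref]]))
    rRef <- sqrt(rowSums(sweep(coords(cts[[ref]]), 2L, ctr, "-")^2))
    vals <- vapply(cts, function(ct) {
        r <- sqrt(rowSums(sweep(coords(ct), 2L, ctr, "-")^2))
        mean(100 * (r - rRef) / rRef)
    }, numeric(1))
    vals[ref] <- 0
    new("StrainCurve", values = vals, lengths = lengths,
        referenceFrame = as.integer(ref - 1L), direction = "radial")
}

#' Segmental strain from a contour track
#'
#' The reference (maximal-length) contour is partitioned into segments of
#' equal arc length; each border edge is assigned to a segment by the
#' arc-length fraction of its midpoint, so segment polyline lengths sum
#' exactly to the global border length on every frame. Per-segment strain
#' applies the Lagrangian length ratio between the global end-diastolic
#' (maximal total length) and end-systolic (minimal total length) frames;
#' peaks are absolute values. Evaluating every segment between the same
#' two frames keeps segmental strain additive — the mean of segment
#' strains weighted by segment reference length equals the global strain —
#' whereas taking each segment's own temporal extremes would inflate
#' segment peaks under measurement noise.
#'
#' @param track a [ContourTrack-class] with at least 4 x nSegments points
#' @param nSegments number of segments (>= 2, default 6)
#' @return a [SegmentalStrainResult-class]
#' @export
ftSegmentalStrain <- function(track, nSegments = 6L) {
    stopifnot(is(track, "ContourTrack"))
    nSegments <- as.integer(nSegments)
    if (nSegments < 2L) stop("need at least 2 segments")
    cts <- contours(track)
    nPts <- nrow(coords(cts[[1L]]))
    if (nPts < 4L * nSegments)
        stop("too few contour points (", nPts, ") for ", nSegments,
             " segments; need at least ", 4L * nSegments)
    closed <- topology(track) == "closed"
    lengths <- vapply(cts, borderLength, numeric(1))
    ref <- which.max(lengths)
    refEdges <- .edgeLengths(coords(cts[[ref]]), closed)
    cum <- cumsum(refEdges)
    midFrac <- (cum - refEdges / 2) / cum[length(cum)]
    segOf <- pmin(floor(midFrac * nSegments) + 1L, nSegments)
    edgeMat <- vapply(cts, function(ct) .edgeLengths(coords(ct), closed),
        numeric(length(refEdges)))
    sys <- which.min(lengths)
    peaks <- numeric(nSegments)
    refLens <- numeric(nSegments)
    for (k in seq_len(nSegments)) {
        segLen <- colSums(edgeMat[segOf == k, , drop = FALSE])
        peaks[k] <- abs(100 * (segLen[sys] - segLen[ref]) / segLen[ref])
        refLens[k] <- segLen[ref]
    }
    new("SegmentalStrainResult", nSegments = nSegments,
        perSegmentPeak = peaks,
        segmentBoundaries = seq(0, 1, length.out = nSegments + 1L),
        segmentRefLengths = refLens)
}
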