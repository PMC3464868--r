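# Synthetic deforming cardiac phantom: SSFP-like cine frames with an
# analytically known endocardial deformation and ground-truth contour
# track. Intensities before noise: blood pool 1.0, myocardium 0.5,
# background 0.1 (bright-blood contrast); edges are blended over one
# pixel so the border has a well-defined sub-pixel gradient maximum.

.INT_CAVITY <- 1.0
.INT_MYO <- 0.5
.INT_BG <- 0.1

#' Construct a phantom specification
#'
#' Defaults emulate a routine cine acquisition: 25 phases per cycle, 1 mm
#' in-plane resolution, 40 ms frame interval, a 30 mm end-diastolic
#' endocardial radius with an 8 mm wall for the short-axis ring, a 160 mm
#' open border for the four-chamber U shape, 20\% peak border shortening,
#' 40 intramural texture features and moderate image noise.
#'
#' @param geometry `"short_axis_ring"` (closed border) or
#'   `"four_chamber_u"` (open border)
#' @param edInnerRadius end-diastolic endocardial radius, mm (ring only)
#' @param edLength end-diastolic border arc length, mm (U shape only)
#' @param wallThickness myocardial wall thickness, mm
#' @param truePeakStrain prescribed absolute peak border shortening, percent
#' @param phaseCount cardiac phases per cycle
#' @param pixelSpacing mm per pixel
#' @param frameInterval ms per phase
#' @param textureFeatureCount dark intramural blobs moving with the tissue
#' @param noiseSd per-pixel Gaussian noise SD (intensity units)
#' @param seed RNG seed (blob placement and noise)
#' @param nPoints ground-truth contour points
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(geometry = c("short_axis_ring", "four_chamber_u"),
                        edInnerRadius = 30, edLength = 160,
                        wallThickness = 8, truePeakStrain = 20,
                        phaseCount = 25L, pixelSpacing = 1.0,
                        frameInterval = 40, textureFeatureCount = 40L,
                        noiseSd = 0.05, seed = 1L, nPoints = 120L) {
    geometry <- match.arg(geometry)
    edSize <- if (geometry == "short_axis_ring") edInnerRadius else edLength
    new("PhantomSpec", geometry = geometry, edSize = as.numeric(edSize),
        wallThickness = as.numeric(wallThickness),
        truePeakStrain = as.numeric(truePeakStrain),
        phaseCount = as.integer(phaseCount),
        pixelSpacing = as.numeric(pixelSpacing),
        frameInterval = as.numeric(frameInterval),
        textureFeatureCount = as.integer(textureFeatureCount),
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
        nPoints = as.integer(nPoints))
}

# Raised-cosine systolic waveform: 0 at frame 0, 1 at round(P/3)
# (end-systole), back to 0 at the implied frame P (cyclic).
.systolicWaveform <- function(P) {
    ts <- round(P / 3)
    t <- seq_len(P) - 1L
    u <- ifelse(t <= ts, 0.5 * t / ts, 0.5 + 0.5 * (t - ts) / (P - ts))
    0.5 * (1 - cos(2 * pi * u))
}

# Four-chamber U reference curve: two vertical arms of length 3r joined
# by a semicircle of radius r, total arc 6r + pi*r = edLength. Returns
# point and outward (away-from-cavity) normal at arc positions s.
.uGeometry <- function(edLength) {
    r <- edLength / (pi + 6)
    list(r = r, armLength = 3 * r, total = edLength)
}

.uPoint <- function(geom, s) {
    r <- geom$r
    h <- geom$armLength
    pt <- matrix(0, length(s), 2L)
    nrm <- matrix(0, length(s), 2L)
    arm1 <- s <= h
    pt[arm1, ] <- cbind(rep(-r, sum(arm1)), s[arm1])
    nrm[arm1, ] <- cbind(rep(-1, sum(arm1)), rep(0, sum(arm1)))
    arc <- s > h & s <= h + pi * r
    if (any(arc)) {
        a <- pi - (s[arc] - h) / r
        pt[arc, ] <- cbind(r * cos(a), h + r * sin(a))
        nrm[arc, ] <- cbind(cos(a), sin(a))
    }
    arm2 <- s > h + pi * r
    if (any(arm2)) {
        s2 <- s[arm2] - h - pi * r
        pt[arm2, ] <- cbind(rep(r, sum(arm2)), h - s2)
        nrm[arm2, ] <- cbind(rep(1, sum(arm2)), rep(0, sum(arm2)))
    }
    list(points = pt, normals = nrm)
}

# Blend cavity/myocardium/background as a function of signed distance
# from the endocardial border (negative inside the cavity); wall width W,
# edge blend width e centred on each interface. Smoothstep blending gives
# the intensity gradient a unique maximum exactly on the interface, so
# edge localisation is well posed at sub-pixel scale.
.smoothstep <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    x * x * (3 - 2 * x)
}

.edgeProfile <- function(sd, W, e) {
    r1 <- .smoothstep((sd + e / 2) / e)
    r2 <- .smoothstep((sd - (W - e / 2)) / e)
    (1 - r1) * .INT_CAVITY + r1 * ((1 - r2) * .INT_MYO + r2 * .INT_BG)
}

# Minimum distance from points (X, Y) to a polyline (exact
# point-to-segment distance, optionally closed).
.distToPolyline <- function(X, Y, pts, closed = FALSE) {
    if (closed) pts <- rbind(pts, pts[1L, ])
    d2 <- rep(Inf, length(X))
    for (i in seq_len(nrow(pts) - 1L)) {
        ax <- pts[i, 1L]; ay <- pts[i, 2L]
        vx <- pts[i + 1L, 1L] - ax; vy <- pts[i + 1L, 2L] - ay
        L2 <- vx * vx + vy * vy
        if (L2 < 1e-12) next
        t <- pmin(pmax(((X - ax) * vx + (Y - ay) * vy) / L2, 0), 1)
        dx <- X - (ax + t * vx)
        dy <- Y - (ay + t * vy)
        d2 <- pmin(d2, dx * dx + dy * dy)
    }
    sqrt(d2)
}

#' Generate a deforming cine phantom with ground truth
#'
#' Renders an SSFP-like cine sequence of a contracting cavity border. The
#' endocardial border (and the wall, and every embedded texture feature)
#' is scaled per frame by s(t) = 1 - a * w(t), where w is a raised-cosine
#' systolic waveform peaking at round(phaseCount/3) and
#' a = truePeakStrain/100 — a homogeneous (similarity) deformation, so
#' global and segmental truth strain coincide. Dark Gaussian texture blobs
#' (SD 1 mm, amplitude 0.25) are embedded at fixed material positions in
#' the wall and move with the deformation, mimicking trabeculation-like
#' brightness inhomogeneities that feature tracking exploits. Per-pixel
#' Gaussian noise is added last. The same seed reproduces every pixel;
#' the ground truth is analytic and independent of noise.
#'
#' @param spec a [PhantomSpec-class]
#' @return a [PhantomOutput-class] (rendered sequence, ground-truth
#'   contour track of materially corresponding points, ground-truth
#'   strain curve)
#' @examples
#' ph <- makePhantom(phantomSpec(phaseCount = 12L, noiseSd = 0, seed = 7L))
#' peakStrain(truthStrain(ph))  # 20
#' @export
makePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    a <- spec@truePeakStrain / 100
    P <- spec@phaseCount
    s <- 1 - a * .systolicWaveform(P)
    if (min(s) <= 0 || (spec@geometry == "short_axis_ring" &&
        spec@edSize * min(s) <= 0))
        stop("prescribed strain collapses the endocardial border")
    ps <- spec@pixelSpacing
    W <- spec@wallThickness
    e <- 1.5 * ps  # edge blend width: resolvable gradient peak
    margin <- 16  # mm clearance for template + search windows and drift

    if (spec@geometry == "short_axis_ring") {
        R0 <- spec@edSize
        half <- R0 + W + margin
        n <- 2L * as.integer(ceiling(half / ps)) + 1L
        ctr <- c((n - 1) / 2, (n - 1) / 2) * ps
        ang <- 2 * pi * (seq_len(spec@nPoints) - 1L) / spec@nPoints
        ref <- cbind(ctr[1L] + R0 * cos(ang), ctr[2L] + R0 * sin(ang))
        topo <- "closed"
        nx <- n; ny <- n
    } else {
        geom <- .uGeometry(spec@edSize)
        sArc <- seq(0, geom$total, length.out = spec@nPoints)
        up <- .uPoint(geom, sArc)
        width <- 2 * (geom$r + W + margin)
        height <- geom$armLength + geom$r + W + 2 * margin
        nx <- as.integer(ceiling(width / ps)) + 1L
        ny <- as.integer(ceiling(height / ps)) + 1L
        offset <- c((nx - 1) * ps / 2, margin + W)
        ref <- sweep(up$points, 2L, offset, "+")
        refNormals <- up$normals
        ctr <- colMeans(ref)
        topo <- "open"
    }

    # material texture-feature positions in the reference wall
    blobs <- NULL
    blobSd <- 1.0
    blobAmp <- 0.25
    frames <- .withSeed(spec@seed, function() {
        K <- spec@textureFeatureCount
        if (K > 0L) {
            off <- stats::runif(K, 0.25 * W, 0.75 * W)
            if (spec@geometry == "short_axis_ring") {
                th <- stats::runif(K, 0, 2 * pi)
                blobs <<- cbind(ctr[1L] + (R0 + off) * cos(th),
                                ctr[2L] + (R0 + off) * sin(th))
            } else {
                sb <- stats::runif(K, 0, geom$total)
                ub <- .uPoint(geom, sb)
                blobs <<- sweep(ub$points + ub$normals * off, 2L, offset, "+")
            }
        }
        X <- rep((seq_len(nx) - 1L) * ps, each = ny)
        Y <- rep((seq_len(ny) - 1L) * ps, times = nx)
        lapply(seq_len(P), function(t) {
            st <- s[t]
            Wt <- W * st
            if (spec@geometry == "short_axis_ring") {
                r <- sqrt((X - ctr[1L])^2 + (Y - ctr[2L])^2)
                sd <- r - R0 * st
            } else {
                pt <- sweep(sweep(ref, 2L, ctr, "-") * st, 2L, ctr, "+")
                d <- .distToPolyline(X, Y, pt, closed = FALSE)
                poly <- rbind(pt, pt[1L, ])  # close across the open top
                inside <- mgcv::in.out(poly, cbind(X, Y))
                sd <- ifelse(inside, -d, d)
            }
            img <- .edgeProfile(sd, Wt, e)
            if (!is.null(blobs)) {
                bt <- sweep(sweep(blobs, 2L, ctr, "-") * st, 2L, ctr, "+")
                for (k in seq_len(nrow(bt))) {
                    d2 <- (X - bt[k, 1L])^2 + (Y - bt[k, 2L])^2
                    nearby <- d2 < (4 * blobSd)^2
                    img[nearby] <- img[nearby] -
                        blobAmp * exp(-d2[nearby] / (2 * blobSd^2))
                }
            }
            img <- pmin(pmax(img, 0), 1)  # magnitude image, overlapping dips clipped
            m <- matrix(img, nrow = ny, ncol = nx)
            if (spec@noiseSd > 0)
                m <- m + matrix(stats::rnorm(ny * nx, 0, spec@noiseSd), ny, nx)
            m
        })
    })

    truth <- lapply(seq_len(P), function(t) {
        pt <- sweep(sweep(ref, 2L, ctr, "-") * s[t], 2L, ctr, "+")
        contour(pt, topo, t - 1L)
    })
    track <- new("ContourTrack", contours = truth, params = trackingParams(),
        source = "ground_truth")
    seqc <- cineSequence(frames, ps, spec@frameInterval,
        sourceId = sprintf("phantom_%s_seed%d", spec@geometry, spec@seed))
    new("PhantomOutput", sequence = seqc, truthTrack = track,
        truthStrain = ebdStrain(track), spec = spec)
}

#' Construct an out-of-plane motion specification
#'
#' @param baseRadius,apexRadius cavity radius at base/apex, mm (base > apex)
#' @param longAxis base-to-apex cone length, mm
#' @param sliceLevelFraction imaging-plane position from the base as a
#'   fraction of the long axis
#' @param longitudinalDisplacement systolic apical tissue displacement at
#'   the slice level, mm
#' @param trueCs true material circumferential shortening, percent
#' @return an [OutOfPlaneSpec-class]
#' @export
outOfPlaneSpec <- function(baseRadius = 40, apexRadius = 20, longAxis = 80,
                           sliceLevelFraction = 0.5,
                           longitudinalDisplacement = 10, trueCs = 15) {
    new("OutOfPlaneSpec", baseRadius = as.numeric(baseRadius),
        apexRadius = as.numeric(apexRadius), longAxis = as.numeric(longAxis),
        sliceLevelFraction = as.numeric(sliceLevelFraction),
        longitudinalDisplacement = as.numeric(longitudinalDisplacement),
        trueCs = as.numeric(trueCs))
}

#' Circumferential strain bias from through-plane motion
#'
#' The cavity is a truncated cone whose radius falls linearly from base to
#' apex. The imaging plane is fixed in space while the tissue moves toward
#' the apex during systole, so at end-systole the plane intersects tissue
#' that at end-diastole lay more basally and therefore had a larger
#' circumference. The measured circumferential strain compares that
#' tissue's shortened systolic circumference against the original in-plane
#' diastolic circumference, CS = 100 * (diastolic - systolic) / diastolic,
#' which under-reports the true material shortening — more so the larger
#' the displacement.
#'
#' @param spec an [OutOfPlaneSpec-class]
#' @return list with `trueCs` and `measuredCs` (percent)
#' @examples
#' simulateOutOfPlane(outOfPlaneSpec(longitudinalDisplacement = 0))
#' @export
simulateOutOfPlane <- function(spec) {
    stopifnot(is(spec, "OutOfPlaneSpec"))
    validObject(spec)
    radiusAt <- function(z)  # z measured from the base, mm
        spec@baseRadius + (spec@apexRadius - spec@baseRadius) * z / spec@longAxis
    zSlice <- spec@sliceLevelFraction * spec@longAxis
    zOrigin <- zSlice - spec@longitudinalDisplacement
    if (zOrigin < 0)
        stop("slice displaced beyond the base of the ventricle")
    r0 <- radiusAt(zSlice)    # diastolic in-plane radius
    rd <- radiusAt(zOrigin)   # diastolic radius of the tissue seen at systole
    measured <- 100 * (1 - (1 - spec@trueCs / 100) * rd / r0)
    list(trueCs = spec@trueCs, measuredCs = measured)
}
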