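test_that("a static textured sequence is tracked without drift", {
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    f <- frames(phantomSequence(ph))[[1]]
    st <- cineSequence(rep(list(f), 6), 1, 40)
    init <- contours(truthTrack(ph))[[1]]
    tr <- trackContour(st, init)
    for (t in 2:6) {
        err <- sqrt(rowSums((coords(contours(tr)[[t]]) - coords(init))^2))
        expect_lt(max(err), 0.5)
    }
})

test_that("a rigid translation is recovered at the known rate", {
    sq <- translationSequence(shift = 3, nFrames = 8L)
    ang <- 2 * pi * (0:47) / 48
    init <- contour(cbind(90 + 12 * cos(ang), 70 + 12 * sin(ang)), "closed")
    # drift compensation assumes cyclic motion; a pure translation is not
    tr <- trackContour(sq, init, trackingParams(driftCompensation = FALSE))
    for (t in 2:8) {
        d <- coords(contours(tr)[[t]]) - coords(contours(tr)[[t - 1]])
        expect_lt(abs(mean(d[, 1]) - (-3)), 0.5)
        expect_lt(abs(mean(d[, 2])), 0.5)
    }
})

test_that("tracking a contracting ring recovers the systolic border length", {
    ph <- ringPhantom(noiseSd = 0.05, strain = 20, phases = 25L, seed = 3L)
    tr <- trackContour(phantomSequence(ph), contours(truthTrack(ph))[[1]])
    lens <- vapply(contours(tr), borderLength, numeric(1))
    lt <- vapply(contours(truthTrack(ph)), borderLength, numeric(1))
    sys <- which.min(lt)
    expect_lt(abs(lens[sys] - lt[sys]) / lt[sys], 0.02)
    # frame 0 equals the supplied initial contour
    expect_equal(coords(contours(tr)[[1]]),
        coords(contours(truthTrack(ph))[[1]]))
})

test_that("tracking is deterministic", {
    ph <- ringPhantom(noiseSd = 0.05, phases = 12L, seed = 23L)
    t1 <- trackContour(phantomSequence(ph), contours(truthTrack(ph))[[1]])
    t2 <- trackContour(phantomSequence(ph), contours(truthTrack(ph))[[1]])
    expect_identical(lapply(contours(t1), coords),
        lapply(contours(t2), coords))
})

test_that("points in featureless surroundings fall back to their neighbours", {
    # a small circle deep inside the uniform blood pool: every template is
    # flat, so displacements must come from the (zero) smoothed field
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    sq <- phantomSequence(ph)
    ctr <- colMeans(coords(contours(truthTrack(ph))[[1]]))
    ang <- 2 * pi * (0:23) / 24
    init <- contour(cbind(ctr[1] + 6 * cos(ang), ctr[2] + 6 * sin(ang)),
        "closed")
    tr <- trackContour(sq, init, trackingParams(normalRefinement = FALSE))
    err <- sqrt(rowSums((coords(contours(tr)[[5]]) - coords(init))^2))
    expect_lt(max(err), 0.5)
})

test_that("tracking fails loudly when a point leaves the image", {
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    sq <- phantomSequence(ph)
    init <- contour(cbind(c(2, 6, 6, 2), c(2, 2, 6, 6)), "closed")
    expect_error(trackContour(sq, init), "left image bounds")
})

test_that("global strain from tracks respects direction and topology", {
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    tt <- truthTrack(ph)
    expect_equal(peakStrain(ftGlobalStrain(tt, "circumferential")), 20,
        tolerance = 1e-9)
    # for a circle, radius scales with circumference
    expect_equal(peakStrain(ftGlobalStrain(tt, "radial")), 20,
        tolerance = 0.1)
    expect_error(ftGlobalStrain(tt, "longitudinal"), "open")

    phu <- uPhantom(noiseSd = 0, phases = 12L, seed = 22L)
    ttu <- truthTrack(phu)
    expect_equal(peakStrain(ftGlobalStrain(ttu, "longitudinal")), 15,
        tolerance = 1e-9)
    expect_error(ftGlobalStrain(ttu, "circumferential"), "closed")
    expect_error(ftGlobalStrain(ttu, "radial"), "closed")

    # static track: zero strain in every direction
    f0 <- contours(tt)[[1]]
    static <- new("ContourTrack", contours = lapply(0:3, function(t)
        contour(coords(f0), "closed", t)), params = trackingParams(),
        source = "ground_truth")
    expect_equal(peakStrain(ftGlobalStrain(static, "circumferential")), 0)
    expect_equal(peakStrain(ftGlobalStrain(static, "radial")), 0)
})

test_that("segmental strain partitions the border and stays additive", {
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    seg <- ftSegmentalStrain(truthTrack(ph), 6L)
    # homogeneous deformation: every segment equals the global peak
    expect_equal(segmentPeaks(seg), rep(20, 6), tolerance = 1e-9)
    expect_equal(segmentBoundaries(seg), seq(0, 1, by = 1 / 6))
    expect_equal(sum(segmentRefLengths(seg)),
        borderLength(contours(truthTrack(ph))[[1]]), tolerance = 1e-9)

    # tracked: length-weighted mean of segment strains = global strain
    trk <- trackContour(phantomSequence(ringPhantom(noiseSd = 0.05,
        phases = 12L, seed = 23L)),
        contours(truthTrack(ringPhantom(noiseSd = 0.05, phases = 12L,
            seed = 23L)))[[1]])
    s2 <- ftSegmentalStrain(trk, 6L)
    wm <- sum(segmentPeaks(s2) * segmentRefLengths(s2)) /
        sum(segmentRefLengths(s2))
    g <- peakStrain(ftGlobalStrain(trk, "circumferential"))
    expect_lt(abs(wm - g), 0.2)

    expect_error(ftSegmentalStrain(truthTrack(ph), 40L), "too few|at least")
})

test_that("tracking error grows with image noise in expectation", {
    errAt <- function(noise) {
        errs <- vapply(c(31L, 32L), function(sd_) {
            ph <- ringPhantom(noiseSd = noise, phases = 12L, seed = sd_)
            tr <- trackContour(phantomSequence(ph),
                contours(truthTrack(ph))[[1]])
            abs(peakStrain(ftGlobalStrain(tr, "circumferential")) - 20)
        }, numeric(1))
        mean(errs)
    }
    expect_lt(errAt(0), errAt(0.2))
})
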