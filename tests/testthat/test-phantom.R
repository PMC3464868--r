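test_that("ring phantom truth follows similarity scaling of the circle", {
    ph <- ringPhantom(noiseSd = 0, strain = 20, phases = 25L, seed = 3L)
    lens <- vapply(contours(truthTrack(ph)), borderLength, numeric(1))
    # systolic endocardial radius 30 mm * 0.8 = 24 mm
    sys <- which.min(lens)
    ctr <- colMeans(coords(contours(truthTrack(ph))[[1]]))
    r <- sqrt(rowSums(sweep(coords(contours(truthTrack(ph))[[sys]]), 2,
        ctr)^2))
    expect_equal(mean(r), 24, tolerance = 1e-9)
    expect_equal(min(lens) / max(lens), 0.8, tolerance = 1e-12)
    expect_equal(peakStrain(truthStrain(ph)), 20, tolerance = 1e-9)
    # peak shortening at the phase nearest one third of the cycle
    expect_equal(sys - 1L, round(25 / 3))
    expect_equal(strainValues(truthStrain(ph))[sys], -20, tolerance = 1e-9)
})

test_that("truth border lengths match the analytic scaled length", {
    w <- function(P) {
        ts <- round(P / 3); t <- 0:(P - 1)
        u <- ifelse(t <= ts, 0.5 * t / ts, 0.5 + 0.5 * (t - ts) / (P - ts))
        0.5 * (1 - cos(2 * pi * u))
    }
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    s <- 1 - 0.2 * w(12L)
    lens <- vapply(contours(truthTrack(ph)), borderLength, numeric(1))
    expect_true(all(abs(lens - s * 2 * pi * 30) / (s * 2 * pi * 30) < 0.001))

    phu <- uPhantom(noiseSd = 0, phases = 12L, seed = 22L)
    su <- 1 - 0.15 * w(12L)
    lensU <- vapply(contours(truthTrack(phu)), borderLength, numeric(1))
    expect_true(all(abs(lensU - su * 160) / (su * 160) < 0.001))
})

test_that("zero prescribed strain yields an identity deformation", {
    ph <- makePhantom(phantomSpec(truePeakStrain = 0, phaseCount = 8L,
        noiseSd = 0, seed = 2L))
    cts <- contours(truthTrack(ph))
    for (t in 2:8)
        expect_equal(coords(cts[[t]]), coords(cts[[1]]))
    expect_equal(strainValues(truthStrain(ph)), rep(0, 8))
})

test_that("phantom generation is seeded and noise leaves the truth alone", {
    sp <- phantomSpec(phaseCount = 8L, noiseSd = 0.05, seed = 13L,
        edInnerRadius = 20, wallThickness = 6)
    a <- makePhantom(sp)
    b <- makePhantom(sp)
    expect_identical(frames(phantomSequence(a)), frames(phantomSequence(b)))
    sp2 <- phantomSpec(phaseCount = 8L, noiseSd = 0.15, seed = 13L,
        edInnerRadius = 20, wallThickness = 6)
    c2 <- makePhantom(sp2)
    expect_false(identical(frames(phantomSequence(a))[[1]],
        frames(phantomSequence(c2))[[1]]))
    expect_identical(lapply(contours(truthTrack(a)), coords),
        lapply(contours(truthTrack(c2)), coords))
    sp3 <- phantomSpec(phaseCount = 8L, noiseSd = 0.05, seed = 14L,
        edInnerRadius = 20, wallThickness = 6)
    expect_false(identical(frames(phantomSequence(a))[[1]],
        frames(phantomSequence(makePhantom(sp3)))[[1]]))
})

test_that("impossible deformations are rejected", {
    expect_error(phantomSpec(truePeakStrain = 60), "60")
    expect_error(phantomSpec(truePeakStrain = -1), "\\[0, 60\\)")
    expect_error(phantomSpec(phaseCount = 4L), ">= 8")
})

test_that("out-of-plane motion biases measured circumferential strain downward", {
    # no displacement: the plane samples the same tissue at both phases
    eq <- simulateOutOfPlane(outOfPlaneSpec(longitudinalDisplacement = 0))
    expect_equal(eq$measuredCs, eq$trueCs, tolerance = 1e-12)

    # displaced slice on a tapering cavity: measured CS falsely reduced
    ex <- simulateOutOfPlane(outOfPlaneSpec(baseRadius = 40, apexRadius = 20,
        sliceLevelFraction = 0.5, longitudinalDisplacement = 10, trueCs = 15))
    expect_lt(ex$measuredCs, 15)

    # strictly decreasing in displacement, always below the true value
    sweep <- vapply(seq(0, 15, by = 0.5), function(d)
        simulateOutOfPlane(outOfPlaneSpec(longitudinalDisplacement = d,
            trueCs = 15))$measuredCs, numeric(1))
    expect_equal(sweep[1], 15)
    expect_true(all(diff(sweep) < 0))
    expect_true(all(sweep[-1] < 15))

    expect_error(simulateOutOfPlane(outOfPlaneSpec(sliceLevelFraction = 0.1,
        longitudinalDisplacement = 30)), "beyond the base")
    expect_error(outOfPlaneSpec(baseRadius = 20, apexRadius = 30),
        "exceed")
})
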