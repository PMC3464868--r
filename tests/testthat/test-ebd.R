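test_that("Hermite densification reproduces straight and circular borders", {
    # collinear anchors: a shape-preserving interpolant must stay on the line
    ct <- interpolateBorder(cbind(c(0, 1, 2), c(0, 0, 0)), "open", 9L)
    expect_equal(nrow(coords(ct)), 9L)
    expect_equal(coords(ct)[, 2], rep(0, 9), ignore_attr = TRUE)
    expect_equal(borderLength(ct), 2.0, tolerance = 1e-12)

    # 12 anchors on a circle: densified length within 0.5% of 2*pi*R
    ang <- 2 * pi * (0:11) / 12
    circ <- interpolateBorder(cbind(10 * cos(ang), 10 * sin(ang)),
        "closed", 360L)
    expect_lt(abs(borderLength(circ) - 2 * pi * 10) / (2 * pi * 10), 0.005)
})

test_that("interpolateBorder honours its contract at the boundaries", {
    a <- cbind(c(0, 1, 3), c(0, 2, 0))
    expect_equal(coords(interpolateBorder(a, "open", 3L)), a,
        ignore_attr = TRUE)  # interpolant passes through its nodes
    expect_error(interpolateBorder(a, "open", 2L), "at least")
    expect_error(interpolateBorder(cbind(c(0, 0, 1), c(0, 0, 1)),
        "open", 10L), "[Cc]oincident")
    # closed topology: interpolation covers the closing span
    sq <- interpolateBorder(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
        "closed", 80L)
    expect_identical(topology(sq), "closed")
    expect_equal(borderLength(sq), 4, tolerance = 0.02)
})

test_that("border length follows Euclidean sums with implied closure", {
    expect_equal(borderLength(contour(cbind(c(0, 3, 3), c(0, 0, 4)),
        "open")), 7.0)
    expect_equal(borderLength(contour(cbind(c(0, 3, 0), c(0, 0, 4)),
        "closed")), 12.0)
})

test_that("border length is invariant under rigid transforms", {
    set.seed(7)
    p <- cbind(runif(15, 0, 50), runif(15, 0, 50))
    for (topo in c("open", "closed")) {
        L <- borderLength(contour(p, topo))
        for (k in 1:100) {
            th <- runif(1, 0, 2 * pi)
            Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
            q <- sweep(p %*% Rm, 2, runif(2, -100, 100), "+")
            expect_lt(abs(borderLength(contour(q, topo)) - L) / L, 1e-9)
        }
    }
})

test_that("strain from border lengths follows the Lagrangian definition", {
    # squares scaled to lengths 100, 90, 80, 90, 100 mm
    sq <- function(L, f) contour(L / 8 * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
        "closed", f)
    sc <- ebdStrain(lapply(seq_along(c(100, 90, 80, 90, 100)) - 1L,
        function(f) sq(c(100, 90, 80, 90, 100)[f + 1L], f)))
    expect_equal(referenceFrame(sc), 0L)
    expect_equal(strainValues(sc), c(0, -10, -20, -10, 0), tolerance = 1e-12)
    expect_equal(peakStrain(sc), 20.0, tolerance = 1e-12)
    expect_equal(strainValues(sc)[referenceFrame(sc) + 1L], 0)

    # constant lengths: a valid all-zero curve, not an error
    sc0 <- ebdStrain(lapply(0:3, function(f) sq(100, f)))
    expect_equal(strainValues(sc0), rep(0, 4))
    expect_equal(peakStrain(sc0), 0)
})

test_that("strain is invariant to uniform spatial rescaling", {
    ph <- ringPhantom(noiseSd = 0, phases = 12L, seed = 21L)
    cts <- contours(truthTrack(ph))
    sc1 <- ebdStrain(cts)
    scaled <- lapply(cts, function(ct)
        contour(coords(ct) * 3.7, topology(ct), frameIndex(ct)))
    sc2 <- ebdStrain(scaled)
    expect_equal(strainValues(sc2), strainValues(sc1), tolerance = 1e-12)
})

test_that("EBD recovers phantom truth through sparse anchors and densification", {
    for (ph in list(ringPhantom(noiseSd = 0, phases = 12L, seed = 21L),
                    uPhantom(noiseSd = 0, phases = 12L, seed = 22L))) {
        truthPeak <- phantomSpecOf(ph)@truePeakStrain
        dense <- lapply(contours(truthTrack(ph)), function(ct) {
            anchors <- coords(ct)[seq(1, nrow(coords(ct)), by = 10), ]
            interpolateBorder(anchors, topology(ct), 200L, frameIndex(ct))
        })
        expect_lt(abs(peakStrain(ebdStrain(dense)) - truthPeak), 0.1)
        # densification convergence: doubling the point count barely moves it
        dense2 <- lapply(contours(truthTrack(ph)), function(ct) {
            anchors <- coords(ct)[seq(1, nrow(coords(ct)), by = 10), ]
            interpolateBorder(anchors, topology(ct), 400L, frameIndex(ct))
        })
        expect_lt(abs(peakStrain(ebdStrain(dense2)) -
            peakStrain(ebdStrain(dense))), 0.05)
    }
})
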