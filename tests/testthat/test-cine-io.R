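test_that("DICOM series are ordered by trigger time with calibration from metadata", {
    dir <- withr::local_tempdir()
    writeMiniSeries(dir, nFrames = 8L, spacing = 1.0, interval = 40,
        shuffleNames = TRUE)
    cs <- readDicomSeries(dir)
    expect_s4_class(cs, "CineSequence")
    expect_equal(phaseCount(cs), 8L)
    expect_equal(pixelSpacing(cs), 1.0)
    expect_equal(frameInterval(cs), 40)
    # frame k carries marker k at [1,1]; ordering must follow trigger
    # time, not the (reversed) file names
    expect_equal(vapply(frames(cs), function(f) f[1, 1], numeric(1)),
        as.numeric(1:8))
})

test_that("DICOM pixel values round-trip exactly through the reader", {
    dir <- withr::local_tempdir()
    set.seed(5)
    img <- matrix(sample.int(4096L, 16 * 20, replace = TRUE) - 1L, 16, 20)
    writeMiniDicom(file.path(dir, "a.dcm"), img, trigger = 0)
    writeMiniDicom(file.path(dir, "b.dcm"), img + 1L, trigger = 40)
    cs <- readDicomSeries(dir)
    expect_identical(frames(cs)[[1]], matrix(as.numeric(img), 16, 20))
    expect_identical(frames(cs)[[2]], matrix(as.numeric(img + 1L), 16, 20))
})

test_that("DICOM reader falls back to instance numbers and FrameTime", {
    dir <- withr::local_tempdir()
    writeMiniSeries(dir, nFrames = 5L, useTrigger = FALSE, frameTime = 35)
    cs <- readDicomSeries(dir)
    expect_equal(frameInterval(cs), 35)
    expect_equal(vapply(frames(cs), function(f) f[1, 1], numeric(1)),
        as.numeric(1:5))
})

test_that("DICOM reader rejects degenerate or inconsistent series", {
    d1 <- withr::local_tempdir()
    writeMiniDicom(file.path(d1, "only.dcm"), matrix(1L, 8, 8), trigger = 0)
    expect_error(readDicomSeries(d1), "at least 2 frames")

    d2 <- withr::local_tempdir()
    writeMiniDicom(file.path(d2, "a.dcm"), matrix(1L, 8, 8), trigger = 0,
        sliceLoc = 10)
    writeMiniDicom(file.path(d2, "b.dcm"), matrix(1L, 8, 8), trigger = 40,
        sliceLoc = 18)
    expect_error(readDicomSeries(d2), "[Mm]ixed slice positions")

    d3 <- withr::local_tempdir()
    writeMiniDicom(file.path(d3, "a.dcm"), matrix(1L, 8, 8), trigger = 0,
        spacing = c(1.0, 1.1))
    writeMiniDicom(file.path(d3, "b.dcm"), matrix(1L, 8, 8), trigger = 40,
        spacing = c(1.0, 1.1))
    expect_error(readDicomSeries(d3), "[Aa]nisotropic")

    d4 <- withr::local_tempdir()
    writeMiniDicom(file.path(d4, "a.dcm"), matrix(1L, 8, 8))
    writeMiniDicom(file.path(d4, "noinfo.dcm"), matrix(1L, 8, 8),
        instance = NULL, trigger = NULL)
    err <- tryCatch(readDicomSeries(d4), error = conditionMessage)
    expect_match(err, "phase information")
    expect_match(err, "dcm")  # names an offending file
})

test_that("image stacks round-trip through TIFF and RDS", {
    ph <- ringPhantom(noiseSd = 0, phases = 8L, seed = 9L)
    sq <- phantomSequence(ph)

    rds <- withr::local_tempfile(fileext = ".rds")
    writeImageStack(sq, rds)
    back <- readImageStack(rds, pixelSpacing(sq), frameInterval(sq))
    expect_identical(frames(back), frames(sq))

    tif <- withr::local_tempfile(fileext = ".tif")
    writeImageStack(sq, tif)
    back1 <- readImageStack(tif, pixelSpacing(sq), frameInterval(sq))
    expect_equal(phaseCount(back1), phaseCount(sq))
    # 32-bit pages code [0,1] intensities to ~2e-10
    expect_lt(max(abs(frames(back1)[[3]] - frames(sq)[[3]])), 1e-9)
    tif2 <- withr::local_tempfile(fileext = ".tif")
    writeImageStack(back1, tif2)
    back2 <- readImageStack(tif2, pixelSpacing(sq), frameInterval(sq))
    expect_lt(max(abs(frames(back2)[[8]] - frames(back1)[[8]])), 1e-9)

    one <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(matrix(0, 4, 4)), one)
    expect_error(readImageStack(one, 1, 40), "fewer than 2 frames")
})

test_that("contour CSV round-trips losslessly to 1e-6 mm", {
    set.seed(2)
    cts <- lapply(0:24, function(f)
        contour(matrix(runif(12, 0, 100), 6, 2), "closed", f))
    csv <- withr::local_tempfile(fileext = ".csv")
    writeContourFile(cts, csv)
    back <- readContourFile(csv)
    expect_length(back, 25L)
    expect_equal(sort(vapply(back, frameIndex, integer(1))), 0:24)
    for (k in c(1, 13, 25)) {
        expect_equal(coords(back[[k]]), coords(cts[[k]]),
            tolerance = 1e-6, ignore_attr = TRUE)
        expect_identical(topology(back[[k]]), "closed")
    }
    raw <- read.csv(csv)
    expect_true(all(raw$topology == "closed"))
})

test_that("contour CSV reader rejects malformed files", {
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("frame_index,point_order,x_mm,y_mm,topology",
        "0,0,0,0,open", "0,0,1,0,open", "0,1,2,0,open"), csv)
    expect_error(readContourFile(csv), "duplicate")

    csv2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("frame_index,point_order,x_mm,y_mm,topology",
        "0,0,0,0,open", "0,1,1,0,open", "0,2,2,1,open",
        "1,0,0,0,closed", "1,1,1,0,closed", "1,2,2,1,closed"), csv2)
    expect_error(readContourFile(csv2), "[Mm]ixed topology")

    expect_error(writeContourFile(list(), withr::local_tempfile()),
        "non-empty")
})
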