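# Byte-level writer for minimal explicit-VR little-endian DICOM files,
# used to build cine-series fixtures in code at test time.

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

strraw <- function(s) {
    r <- charToRaw(as.character(s))
    if (length(r) %% 2) c(r, charToRaw(" ")) else r
}

dcmElem <- function(group, elem, vr, val) {
    if (length(val) %% 2) val <- c(val, as.raw(0))
    if (vr %in% c("OB", "OW", "UT", "UN", "SQ"))
        c(u16raw(group), u16raw(elem), charToRaw(vr), as.raw(c(0, 0)),
          u32raw(length(val)), val)
    else
        c(u16raw(group), u16raw(elem), charToRaw(vr), u16raw(length(val)), val)
}

writeMiniDicom <- function(path, img, spacing = c(1, 1), trigger = NULL,
                           instance = NULL, sliceLoc = 0, frameTime = NULL,
                           bits = 16L) {
    stopifnot(is.matrix(img))
    out <- c(raw(128), charToRaw("DICM"),
        dcmElem(0x0002, 0x0010, "UI", strraw("1.2.840.10008.1.2.1")))
    if (!is.null(trigger))
        out <- c(out, dcmElem(0x0018, 0x1060, "DS", strraw(trigger)))
    if (!is.null(frameTime))
        out <- c(out, dcmElem(0x0018, 0x1063, "DS", strraw(frameTime)))
    if (!is.null(instance))
        out <- c(out, dcmElem(0x0020, 0x0013, "IS", strraw(instance)))
    if (!is.null(sliceLoc))
        out <- c(out, dcmElem(0x0020, 0x1041, "DS", strraw(sliceLoc)))
    out <- c(out,
        dcmElem(0x0028, 0x0010, "US", u16raw(nrow(img))),
        dcmElem(0x0028, 0x0011, "US", u16raw(ncol(img))),
        dcmElem(0x0028, 0x0030, "DS",
            strraw(paste0(spacing[1], "\\", spacing[2]))),
        dcmElem(0x0028, 0x0100, "US", u16raw(bits)),
        dcmElem(0x0028, 0x0103, "US", u16raw(0L)),
        dcmElem(0x7fe0, 0x0010, "OW",
            writeBin(as.integer(as.vector(t(img))), raw(),
                size = bits %/% 8L, endian = "little")))
    writeBin(out, path)
    invisible(path)
}

# A small cine series on disk: frames carry a distinguishable marker so
# phase ordering can be asserted after shuffled file naming.
writeMiniSeries <- function(dir, nFrames = 8L, spacing = 1.0, interval = 40,
                            shuffleNames = TRUE, useTrigger = TRUE,
                            frameTime = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ord <- if (shuffleNames) rev(seq_len(nFrames)) else seq_len(nFrames)
    for (k in seq_len(nFrames)) {
        img <- matrix(100L + k, 16, 16)
        img[1, 1] <- k  # phase marker
        writeMiniDicom(
            file.path(dir, sprintf("im%02d.dcm", ord[k])), img,
            spacing = c(spacing, spacing),
            trigger = if (useTrigger) (k - 1) * interval else NULL,
            instance = k, sliceLoc = 12.5, frameTime = frameTime)
    }
    dir
}
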