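# Minimal DICOM reader for uncompressed single-frame cine exports.
# Supports implicit and explicit VR little endian; enough of the data
# dictionary for cine geometry, timing and pixel data. Compressed
# transfer syntaxes and undefined-length sequences are rejected.

.dcmU16 <- function(raw, pos) {
    as.integer(raw[pos + 1L]) + 256L * as.integer(raw[pos + 2L])
}

.dcmU32 <- function(raw, pos) {
    as.numeric(raw[pos + 1L]) + 256 * as.numeric(raw[pos + 2L]) +
        65536 * as.numeric(raw[pos + 3L]) + 16777216 * as.numeric(raw[pos + 4L])
}

.dcmString <- function(bytes) {
    bytes <- bytes[bytes != as.raw(0)]  # strip padding NULs
    sub("[ ]+$", "", rawToChar(bytes))
}

.dcmLongVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one file; returns list(tags = named list of raw values, path).
.dcmParse <- function(path) {
    n <- file.size(path)
    if (is.na(n) || n < 8)
        stop("not a readable DICOM file: ", path)
    raw <- readBin(path, "raw", n)
    pos <- 0L
    if (n > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 132L
    # detect explicit VR by peeking at the first element's VR bytes
    peekVr <- function(p) {
        if (p + 6 > n) return(FALSE)
        v <- rawToChar(raw[(p + 5L):(p + 6L)])
        grepl("^[A-Z]{2}$", v)
    }
    mainExplicit <- NA
    metaExplicit <- TRUE
    tags <- list()
    while (pos + 8 <= n) {
        group <- .dcmU16(raw, pos)
        elem <- .dcmU16(raw, pos + 2L)
        inMeta <- group == 2L
        explicit <- if (inMeta) metaExplicit else {
            if (is.na(mainExplicit)) mainExplicit <- peekVr(pos)
            mainExplicit
        }
        if (explicit) {
            vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
            if (vr %in% .dcmLongVRs) {
                len <- .dcmU32(raw, pos + 8L)
                hdr <- 12L
            } else {
                len <- .dcmU16(raw, pos + 6L)
                hdr <- 8L
            }
        } else {
            vr <- NA_character_
            len <- .dcmU32(raw, pos + 4L)
            hdr <- 8L
        }
        if (len >= 4294967295)
            stop("undefined-length element (unsupported) in ", path)
        if (pos + hdr + len > n)
            stop("truncated DICOM element in ", path)
        key <- sprintf("%04x,%04x", group, elem)
        val <- if (len > 0) raw[(pos + hdr + 1L):(pos + hdr + len)] else raw(0)
        tags[[key]] <- val
        if (identical(key, "0002,0010")) {
            ts <- .dcmString(val)
            if (ts == "1.2.840.10008.1.2") mainExplicit <- FALSE
            else if (ts == "1.2.840.10008.1.2.1") mainExplicit <- TRUE
            else stop("unsupported transfer syntax ", ts, " in ", path)
        }
        if (group == 0x7fe0 && elem == 0x0010) break
        pos <- pos + hdr + as.integer(len)
    }
    list(tags = tags, path = path)
}

.dcmGetString <- function(parsed, key) {
    v <- parsed$tags[[key]]
    if (is.null(v)) NA_character_ else .dcmString(v)
}

.dcmGetNumeric <- function(parsed, key) {
    s <- .dcmGetString(parsed, key)
    if (is.na(s) || s == "") return(NA_real_)
    suppressWarnings(as.numeric(strsplit(s, "\\\\")[[1L]]))
}

.dcmGetUS <- function(parsed, key) {
    v <- parsed$tags[[key]]
    if (is.null(v) || length(v) < 2L) return(NA_integer_)
    .dcmU16(v, 0L)
}

# Decode the pixel element into a [row, col] matrix with rescale applied.
.dcmPixelMatrix <- function(parsed) {
    rows <- .dcmGetUS(parsed, "0028,0010")
    cols <- .dcmGetUS(parsed, "0028,0011")
    bits <- .dcmGetUS(parsed, "0028,0100")
    if (is.na(bits)) bits <- 16L
    signedRep <- identical(.dcmGetUS(parsed, "0028,0103"), 1L)
    px <- parsed$tags[["7fe0,0010"]]
    if (is.na(rows) || is.na(cols) || is.null(px))
        stop("missing image geometry or pixel data in ", parsed$path)
    if (!bits %in% c(8L, 16L))
        stop("unsupported bit depth ", bits, " in ", parsed$path)
    sz <- bits %/% 8L
    vals <- readBin(px, "integer", n = rows * cols, size = sz,
        signed = signedRep, endian = "little")
    slope <- .dcmGetNumeric(parsed, "0028,1053")[1L]
    inter <- .dcmGetNumeric(parsed, "0028,1052")[1L]
    out <- as.numeric(vals)
    if (!is.na(slope)) out <- out * slope
    if (!is.na(inter)) out <- out + inter
    matrix(out, nrow = rows, ncol = cols, byrow = TRUE)
}
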