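# Internal numerical helpers shared across modules.

# Bilinear interpolation of img at continuous 0-based pixel coordinates
# (x along columns, y along rows). Coordinates are clamped to the image.
.bilinear <- function(img, x, y) {
    nr <- nrow(img)
    nc <- ncol(img)
    x <- pmin(pmax(x, 0), nc - 1)
    y <- pmin(pmax(y, 0), nr - 1)
    x0 <- pmin(floor(x), nc - 2)
    y0 <- pmin(floor(y), nr - 2)
    fx <- x - x0
    fy <- y - y0
    i00 <- y0 + 1 + x0 * nr
    v00 <- img[i00]
    v10 <- img[i00 + nr]
    v01 <- img[i00 + 1]
    v11 <- img[i00 + nr + 1]
    (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
        (1 - fx) * fy * v01 + fx * fy * v11
}

# Moving average along a contour; periodic wraps, open truncates the
# window at the ends. NAs are ignored; an all-NA window yields 0.
.movingAverage <- function(v, window, periodic) {
    n <- length(v)
    if (window <= 1L || n == 0L) return(v)
    k <- (window - 1L) %/% 2L
    out <- numeric(n)
    for (i in seq_len(n)) {
        if (periodic) {
            idx <- ((i - 1L + (-k:k)) %% n) + 1L
        } else {
            idx <- max(1L, i - k):min(n, i + k)
        }
        m <- mean(v[idx], na.rm = TRUE)
        out[i] <- if (is.nan(m)) 0 else m
    }
    out
}

# Shoelace polygon area (positive) and area centroid for closed contours.
.polygonArea <- function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    abs(sum(x * yn - xn * y)) / 2
}

.polygonCentroid <- function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cr <- x * yn - xn * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(colMeans(p))
    c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Segment lengths of a polyline; closed adds the wrap-around edge.
.edgeLengths <- function(p, closed) {
    q <- if (closed) rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
         else p[-1L, , drop = FALSE]
    base <- if (closed) p else p[-nrow(p), , drop = FALSE]
    sqrt(rowSums((q - base)^2))
}

# Lagrangian strain curve from per-frame border lengths: the reference
# length L0 is the maximum (end-diastole), so strain is the signed
# shortening relative to it.
.strainFromLengths <- function(lengths, direction = "border") {
    ref <- which.max(lengths)
    L0 <- lengths[ref]
    vals <- if (L0 > 0) 100 * (lengths - L0) / L0 else rep(0, length(lengths))
    vals[ref] <- 0
    new("StrainCurve", values = vals, lengths = as.numeric(lengths),
        referenceFrame = as.integer(ref - 1L), direction = direction)
}

# Run fn with a private, seeded RNG stream, restoring user RNG state.
.withSeed <- function(seed, fn) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    fn()
}
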