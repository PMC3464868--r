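# Shared phantom fixtures, built once per test run. The validation suite
# is the package's default study condition (20 phantoms, strains 10-25%,
# noise 0-0.1) and is reused by several acceptance checks.

.fixtures <- new.env(parent = emptyenv())

ringPhantom <- function(noiseSd = 0.05, strain = 20, phases = 25L, seed = 3L) {
    key <- sprintf("ring_%g_%g_%d_%d", noiseSd, strain, phases, seed)
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- makePhantom(phantomSpec(
            truePeakStrain = strain, phaseCount = phases,
            noiseSd = noiseSd, seed = seed))
    .fixtures[[key]]
}

uPhantom <- function(noiseSd = 0.05, strain = 15, phases = 25L, seed = 4L) {
    key <- sprintf("u_%g_%g_%d_%d", noiseSd, strain, phases, seed)
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- makePhantom(phantomSpec("four_chamber_u",
            truePeakStrain = strain, phaseCount = phases,
            noiseSd = noiseSd, seed = seed))
    .fixtures[[key]]
}

defaultSuite <- function() {
    if (is.null(.fixtures$suite))
        .fixtures$suite <- runValidate(validationConfig(seed = 42L))
    .fixtures$suite
}

# Smooth random texture shifted rigidly by `shift` px per frame (image
# content moves toward -x as the frame index grows).
translationSequence <- function(shift = 3, nFrames = 8L, size = 140L,
                                seed = 11L) {
    set.seed(seed)
    n <- size + 10L + shift * nFrames + 10L
    base <- matrix(rnorm(n * n), n, n)
    k <- rep(1, 7) / 7
    base <- apply(base, 2, function(col) stats::filter(col, k, circular = TRUE))
    base <- t(apply(base, 1, function(row) stats::filter(row, k,
        circular = TRUE)))
    base <- (base - min(base)) / diff(range(base))
    idx <- seq_len(size)
    frames <- lapply(seq_len(nFrames) - 1L, function(t)
        base[idx + 10L, idx + 10L + shift * t])
    cineSequence(frames, 1, 40)
}
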