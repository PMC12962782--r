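# Internal numeric helpers shared across modules.

# Centered moving average of window length k (odd); edges shrink to the valid
# part of the window (mean of available points), so total mass is preserved on
# the interior and no artificial zeros are introduced at lag 0.
movingAverage <- function(x, k) {
    stopifnot(k >= 1L, k %% 2L == 1L)
    if (k == 1L || length(x) == 0L) return(x)
    n <- length(x)
    half <- (k - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Half-open binning [a, b): counts of x per bin on a uniform grid starting at
# `origin` with width `width` and `nbins` bins. Values outside are dropped.
binCountsHalfOpen <- function(x, origin, width, nbins) {
    # the 1e-9 bin-relative epsilon keeps values sitting exactly on a bin
    # edge (up to double rounding) in the upper, half-open bin
    idx <- floor((x - origin) / width + 1e-9) + 1
    idx <- idx[idx >= 1 & idx <= nbins]
    tabulate(idx, nbins = nbins)
}

# Run code with a local RNG state seeded from `seed`; restores the caller's
# RNG so generators never perturb the session stream.
withLocalSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

# Derive a bounded substream seed from a top-level seed and a component tag,
# so adding a generator never perturbs existing streams.
substreamSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))
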