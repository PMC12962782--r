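# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair enumeration, textbook normal
# approximation for the rank-sum test, exhaustive sign-flip enumeration for
# the signed-rank test, direct per-lag dot products, and trapezoidal
# quadrature.

# O(n^2) pairwise-lag histogram via full outer difference
bruteACG <- function(times, binWidth, nbins) {
    d <- outer(times, times, "-")
    lags <- d[d > 0]
    idx <- floor(lags / binWidth) + 1
    idx <- idx[idx >= 1 & idx <= nbins]
    tabulate(idx, nbins = nbins)
}

# analytic pair counts for a perfectly regular train with period `period`
regularACGOracle <- function(nSpikes, period, binWidth, nbins) {
    counts <- numeric(nbins)
    m <- 1
    while (m * period < nbins * binWidth) {
        bin <- floor(m * period / binWidth) + 1
        counts[bin] <- counts[bin] + (nSpikes - m)
        m <- m + 1
    }
    counts
}

# one-sided Mann-Whitney U p-value: normal approximation with tie correction
# and continuity correction, from first principles
mwuOracleP <- function(x, y, alternative = c("greater", "less")) {
    alternative <- match.arg(alternative)
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    if (alternative == "greater")
        stats::pnorm((U - mu - 0.5) / sig, lower.tail = FALSE)
    else
        stats::pnorm((U - mu + 0.5) / sig)
}

# exact one-sided (greater) signed-rank p by enumerating all 2^n sign flips;
# requires distinct nonzero |differences| and small n
signedRankExactP <- function(d) {
    stopifnot(length(d) <= 14, all(d != 0), !anyDuplicated(abs(d)))
    r <- rank(abs(d))
    vObs <- sum(r[d > 0])
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vAll <- as.vector(signs %*% r)
    mean(vAll >= vObs)
}

# direct per-lag cross-correlation oracle: cc[k] = sum_t x[t] y[t+k]
directXCorrOracle <- function(x, y, K) {
    n <- length(x)
    vapply(-K:K, function(k) {
        if (k >= 0) sum(x[1:(n - k)] * y[(1 + k):n])
        else sum(x[(1 - k):n] * y[1:(n + k)])
    }, numeric(1))
}

# adjusted Rand index (contingency-table formula)
ariScore <- function(a, b) {
    tab <- table(a, b)
    sumIj <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expected <- sumI * sumJ / choose(sum(tab), 2)
    (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}

# trapezoidal quadrature
trapzOracle <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# construct a TrialPETH directly from a trials x samples matrix
makeTrialPETH <- function(tt, z, fs, label = "synthetic") {
    z <- matrix(z, ncol = length(tt))
    new("TrialPETH", binCenters = tt, zMatrix = z, meanTrace = colMeans(z),
        fs = fs, triggerLabel = label)
}

# construct an Autocorrelogram directly; with smoothing = "none" the values
# are mean-normalized to satisfy the class invariant (all index statistics
# are scale-invariant), any other tag keeps them verbatim
makeACG <- function(norm, binWidth = 5e-4, counts = norm,
                    smoothing = "synthetic") {
    nbins <- length(norm)
    norm <- as.numeric(norm)
    if (identical(smoothing, "none") && mean(norm) > 0)
        norm <- norm / mean(norm)
    new("Autocorrelogram", lags = (seq_len(nbins) - 0.5) * binWidth,
        counts = as.numeric(counts), norm = norm,
        binWidth = binWidth, nSpikesUsed = 2L, smoothing = smoothing)
}

# null task PETH: homogeneous Poisson unit, events on a regular grid
nullPETH <- function(rate = 10, nEvents = 60, seed = 1) {
    tr <- genPoissonTrain(rate, 8 * nEvents + 20, seed = seed)$train
    ev <- EventSeries(10 + 8 * (0:(nEvents - 1)), "null")
    computePETH(tr, ev, c(-0.5, 0.5), 0.01)
}

# four functional response archetypes (both-activated, reward-only,
# punishment-only, both-inhibited), nPer units each, plus Gaussian noise
archetypePanel <- function(noiseSd, seed, nPer = 10, nBins = 20) {
    arche <- rbind(c(rep(2, nBins), rep(2, nBins)),
                   c(rep(2, nBins), rep(-2, nBins)),
                   c(rep(-2, nBins), rep(2, nBins)),
                   c(rep(-2, nBins), rep(-2, nBins)))
    set.seed(seed)
    X <- arche[rep(1:4, each = nPer), ] +
        matrix(rnorm(4 * nPer * 2 * nBins, 0, noiseSd), 4 * nPer)
    list(X = X, truth = rep(1:4, each = nPer), rew = 1:nBins,
         pun = (nBins + 1):(2 * nBins))
}

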