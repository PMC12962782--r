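# Cross-correlation, pupil diameter, peak-triggered averaging, transfer
# entropy.

mkSig <- function(v, fs = 100) {
    CalciumSignal((seq_along(v) - 1) / fs, v, fs)
}

test_that("normalizedXCorr matches the direct per-lag oracle", {
    set.seed(1)
    x <- rnorm(2000)
    y <- as.numeric(stats::filter(rnorm(2000), rep(0.3, 3), sides = 2))
    y[is.na(y)] <- 0
    cc <- normalizedXCorr(mkSig(x), mkSig(y), maxLag = 2, exclude = 0.02)
    xc <- x - mean(x); yc <- y - mean(y)
    oracle <- directXCorrOracle(xc, yc, 200) / sqrt(sum(xc^2) * sum(yc^2))
    expect_equal(cc@values, oracle, tolerance = 1e-9)
})

test_that("self-correlation is 1 at lag 0 and the mask governs the peak", {
    set.seed(2)
    x <- rnorm(6000)
    s <- mkSig(x)
    ccNoMask <- normalizedXCorr(s, s, maxLag = 1, exclude = 0)
    expect_equal(ccNoMask@values[ccNoMask@lags == 0], 1, tolerance = 1e-12)
    expect_lte(max(abs(ccNoMask@values)), 1 + 1e-9)
    expect_equal(ccNoMask@peakLag, 0)

    cc <- normalizedXCorr(s, s, maxLag = 1, exclude = 0.02)
    expect_true(all(abs(cc@lags[cc@excludedMask]) <= 0.02 + 1e-9))
    expect_gt(abs(cc@peakLag), 0.02)  # peak found off the masked center
})

test_that("an imposed lag is recovered at the peak", {
    cp <- genCoupledPair(duration = 120, fs = 100, lag = 0.8, gain = 0.5,
                         noiseSd = 0.3, seed = 6)
    cc <- normalizedXCorr(cp$x, cp$y, maxLag = 10)
    expect_lte(abs(cc@peakLag - 0.8), 2 / 100)
})

test_that("independent white noise stays within the Monte-Carlo CCR bound", {
    for (s in 1:5) {
        set.seed(100 + s)
        n <- 6000
        cc <- normalizedXCorr(mkSig(rnorm(n)), mkSig(rnorm(n)), maxLag = 10)
        expect_lte(max(abs(cc@values)), 5 / sqrt(n))
    }
})

test_that("normalizedXCorr validates inputs", {
    set.seed(3)
    a <- mkSig(rnorm(1000), fs = 100)
    b <- CalciumSignal((0:999) / 50, rnorm(1000), 50)
    expect_error(normalizedXCorr(a, b), "sampling rate")
    z <- mkSig(rep(2, 1000))
    expect_error(normalizedXCorr(a, z, maxLag = 2), "zero-variance")
    expect_error(normalizedXCorr(a, a, maxLag = 8), "twice the maximum lag")
})

test_that("averageCCR averages pointwise and keeps per-session peaks", {
    cp <- genCoupledPair(duration = 60, fs = 50, lag = 0.5, seed = 1)
    cc <- normalizedXCorr(cp$x, cp$y, maxLag = 5)
    out <- averageCCR(list(cc, cc))
    expect_equal(out$average@values, cc@values)
    expect_equal(out$perSession$peak_lag_s, rep(cc@peakLag, 2))

    # mirrored peaks average symmetrically; per-session argmax preserved
    cc2 <- new("CrossCorrelogram", lags = cc@lags, values = rev(cc@values),
               excludedMask = rev(cc@excludedMask),
               peakValue = cc@peakValue, peakLag = -cc@peakLag, fs = cc@fs)
    out2 <- averageCCR(list(cc, cc2), ids = c("a", "b"))
    avg <- out2$average@values
    expect_equal(avg, rev(avg))
    expect_equal(out2$perSession$peak_lag_s, c(cc@peakLag, -cc@peakLag))

    short <- new("CrossCorrelogram", lags = cc@lags[-1],
                 values = cc@values[-1], excludedMask = cc@excludedMask[-1],
                 peakValue = 0, peakLag = 0, fs = cc@fs)
    expect_error(averageCCR(list(cc, short)), "inconsistent lag grids")

    # imposed lag survives session averaging
    ccrs <- lapply(1:10, function(s) {
        cpi <- genCoupledPair(duration = 60, fs = 50, lag = 0.8,
                              noiseSd = 0.5, seed = s)
        normalizedXCorr(cpi$x, cpi$y, maxLag = 5)
    })
    expect_lte(abs(averageCCR(ccrs)$average@peakLag - 0.8), 2 / 50)
})

pupilCoords <- function(centers, radii, theta) {
    t(vapply(seq_along(radii), function(i) {
        r <- radii[i]
        p <- as.vector(vapply(theta, function(a)
            c(centers[1] + r * cos(a), centers[2] + r * sin(a),
              centers[1] - r * cos(a), centers[2] - r * sin(a)),
            numeric(4)))
        c(p, 0, 0, 0, 2 * r)  # eyelid pair
    }, numeric(16)))
}

test_that("pupilDiameter is the mean pair distance and survives rigid motion", {
    th <- c(0.3, 1.2, 2.1)
    co <- pupilCoords(c(10, 5), rep(7, 4), th)
    pl <- PupilLandmarks(seq(0, 3, by = 1), co)
    expect_equal(pupilDiameter(pl)$diameter, rep(14, 4))  # circle: 2r exactly

    # pairs 8, 10, 12 px apart -> mean 10
    co2 <- matrix(0, 1, 16)
    co2[1, ] <- c(0, 0, 8, 0,  0, 0, 0, 10,  0, 0, 12, 0,  0, 0, 0, 5)
    expect_equal(pupilDiameter(PupilLandmarks(0, co2))$diameter, 10)

    # rotation + translation invariance
    set.seed(4)
    base <- pupilCoords(c(0, 0), c(5, 6, 7), th)
    for (k in 1:5) {
        ang <- runif(1, 0, 2 * pi); dx <- rnorm(2, 0, 20)
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
        rot <- base
        for (j in seq(1, 15, by = 2)) {
            xy <- R %*% rbind(base[, j], base[, j + 1]) + dx
            rot[, j] <- xy[1, ]; rot[, j + 1] <- xy[2, ]
        }
        expect_equal(pupilDiameter(PupilLandmarks(0:2, rot))$diameter,
                     pupilDiameter(PupilLandmarks(0:2, base))$diameter,
                     tolerance = 1e-9)
    }
})

test_that("pupilDiameter interpolates missing frames and resamples", {
    co <- pupilCoords(c(0, 0), c(5, 5, 5, 5, 5), c(0.3, 1.2, 2.1))
    co[3, 1] <- NA
    pl <- PupilLandmarks(0:4, co)
    expect_message(d <- pupilDiameter(pl), "interpolated")
    expect_equal(d$diameter, rep(10, 5))
    d2 <- pupilDiameter(pl, targetTimes = seq(0, 4, by = 0.5))
    expect_length(d2$diameter, 9)
})

test_that("peakTriggeredAverage finds the imposed target delay", {
    fs <- 50
    t <- (0:9999) / fs
    set.seed(9)
    x <- numeric(length(t))
    at <- seq(20, 180, by = 12)
    for (a in at) {
        i <- a * fs
        x[i:(i + 2 * fs)] <- x[i:(i + 2 * fs)] +
            5 * exp(-(0:(2 * fs)) / (0.4 * fs))
    }
    x <- x + rnorm(length(t), 0, 0.2)
    target <- c(rep(0, 0.5 * fs), x)[seq_along(x)]  # x delayed by 0.5 s
    sig <- CalciumSignal(t, x, fs)
    pta <- peakTriggeredAverage(sig, target, thresholdSd = 2, minSep = 2)
    expect_gte(pta$n_peaks, 10)
    expect_lte(abs(pta$lags[which.max(pta$average)] - 0.5), 0.1)

    expect_error(peakTriggeredAverage(sig, target, thresholdSd = 50),
                 "zero calcium peaks")
    expect_error(peakTriggeredAverage(sig, target[-1]), "grid")
})

test_that("transfer entropy: deterministic coupling gives the source entropy", {
    set.seed(13)
    x <- rbinom(10000, 1, 0.5)
    y <- c(0L, x[-10000])
    te <- transferEntropy(x, y, nBins = 200)
    hSource <- {
        p <- mean(x)
        -p * log2(p) - (1 - p) * log2(1 - p)
    }
    expect_equal(te$te_xy, hSource, tolerance = 0.02)
    expect_gte(te$te_xy, 9 * te$te_yx)
})

test_that("transfer entropy is symmetric for identical inputs and nonneg", {
    set.seed(5)
    x <- rnorm(2000)
    te <- transferEntropy(x, x, nBins = 16)
    expect_equal(te$te_xy, te$te_yx)
    expect_gte(te$te_xy, 0)
    # independent iid series: both directions near zero (plug-in bias bound)
    for (s in 1:5) {
        set.seed(400 + s)
        te0 <- transferEntropy(rnorm(10000), rnorm(10000), nBins = 8)
        expect_lte(te0$te_xy, 0.05)
        expect_lte(te0$te_yx, 0.05)
    }
})

test_that("transfer entropy is invariant under affine input rescaling", {
    set.seed(7)
    x <- rnorm(3000)
    y <- 0.6 * c(0, x[-3000]) + rnorm(3000, 0, 0.5)
    a <- transferEntropy(x, y, nBins = 12)
    b <- transferEntropy(3 * x - 2, 0.5 * y + 10, nBins = 12)
    expect_equal(a$te_xy, b$te_xy, tolerance = 1e-12)
    expect_equal(a$te_yx, b$te_yx, tolerance = 1e-12)
})

test_that("transfer entropy validates input and supports downsampling", {
    expect_error(transferEntropy(rep(1, 500), rnorm(500), nBins = 8),
                 "zero entropy")
    expect_error(transferEntropy(rnorm(50), rnorm(50)), "at least 100")
    set.seed(2)
    x <- rnorm(4000)
    te <- transferEntropy(x, x, nBins = 8, downsampleHz = 20, fs = 100)
    expect_identical(te$n_samples, 800L)
    expect_equal(cholinphys:::blockAverage(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
})
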