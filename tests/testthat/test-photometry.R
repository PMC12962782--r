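# Isosbestic dF/F preprocessing and trial-level response quantification.

test_that("preprocessDFF cancels a perfectly shared reference", {
    t <- seq(0, 60, by = 0.01)
    flat <- PhotometrySession(t, rep(100, length(t)), rep(100, length(t)))
    cs <- preprocessDFF(flat)
    expect_lt(max(abs(dff(cs))), 1e-9)

    # pure gain difference on a slow drift: OLS absorbs the gain
    drift <- 100 * exp(-t / 300) + 5 * sin(2 * pi * t / 40)
    sess <- PhotometrySession(t, 1.1 * drift, drift)
    expect_lt(max(abs(dff(preprocessDFF(sess)))), 1e-6)
})

test_that("preprocessDFF is invariant to common positive channel scaling", {
    g <- genPhotometry(duration = 60, fs = 100, nTransients = 6, seed = 12)
    a <- preprocessDFF(g$session)
    s2 <- PhotometrySession(timeGrid(g$session), 7.3 * g$session@f465,
                            7.3 * g$session@f405)
    b <- preprocessDFF(s2)
    expect_equal(dff(b), dff(a), tolerance = 1e-9)
})

test_that("preprocessDFF recovers transients and rejects the shared artifact", {
    g <- genPhotometry(duration = 300, fs = 100, seed = 21)
    cs <- preprocessDFF(g$session)
    # ground truth seen through the same deterministic high-pass
    cleanHp <- cholinphys:::.zeroPhaseFilter(g$truth$clean_pct, 100, 0.2,
                                             2L, "high")
    expect_gte(cor(dff(cs), cleanHp), 0.9)
    naive <- (g$session@f465 - mean(g$session@f465)) /
        mean(g$session@f465) * 100
    varNaive <- var(naive - g$truth$clean_pct)
    varDff <- var(dff(cs) - cleanHp)
    expect_gte(1 - varDff / varNaive, 0.8)
})

test_that("preprocessDFF validates its inputs", {
    t <- seq(0, 5, by = 0.01)
    short <- PhotometrySession(t, rnorm(length(t), 100), rnorm(length(t), 90))
    expect_error(preprocessDFF(short), "10 s")
    t2 <- seq(0, 60, by = 0.5)  # 2 Hz sampling
    slow <- PhotometrySession(t2, rnorm(length(t2), 100),
                              rnorm(length(t2), 90))
    expect_error(preprocessDFF(slow), "twice the low-pass")
})

test_that("the filter chain is zero-phase (symmetric transient stays put)", {
    t <- seq(0, 60, by = 0.01)
    bump <- 4 * exp(-((t - 30) / 0.5)^2)
    sess <- PhotometrySession(t, 100 * (1 + bump / 100), rep(100, length(t)) +
                              0.01 * sin(2 * pi * t / 7))
    cs <- preprocessDFF(sess)
    expect_lte(abs(t[which.max(dff(cs))] - 30), 0.01 + 1e-9)
})

test_that("transient amplitude ratios 1:2:4 survive the chain", {
    ratios <- sapply(1:5, function(s) {
        g <- genPhotometry(duration = 240, fs = 100,
                           transientTimes = seq(10, 226, by = 12),
                           amplitudes = c(1, 2, 4), artifactSd = 0.02,
                           noiseSd = 0.02, seed = s)
        cs <- preprocessDFF(g$session)
        idx <- round(g$truth$transient_times * 100) + 1
        # peak above the local pre-onset level (undershoot-robust)
        pk <- vapply(idx, function(i)
            max(dff(cs)[i:(i + 40)]) - mean(dff(cs)[(i - 50):(i - 10)]),
            numeric(1))
        amp <- g$truth$amplitudes
        c(mean(pk[amp == 2]) / mean(pk[amp == 1]),
          mean(pk[amp == 4]) / mean(pk[amp == 1]))
    })
    expect_lt(max(abs(ratios[1, ] / 2 - 1)), 0.15)
    expect_lt(max(abs(ratios[2, ] / 4 - 1)), 0.15)
})

test_that("zscoreToBaseline normalizes each trial to its pre-trigger baseline", {
    fs <- 100
    t <- seq(0, 400, by = 1 / fs)
    # constant trace: zero baseline SD -> trial excluded (error when none left)
    cs0 <- CalciumSignal(t, rep(1.5, length(t)), fs)
    expect_error(suppressWarnings(
        zscoreToBaseline(cs0, 50, window = c(-2, 4))), "no usable trials")

    # post-trigger segment equal to the baseline mean -> z = 0 there
    set.seed(17)
    xb <- rnorm(length(t))
    i0 <- 50 * fs + 1
    xb[i0:(i0 + 4 * fs)] <- mean(xb[(i0 - 2 * fs):(i0 - 1)])
    tpz <- zscoreToBaseline(CalciumSignal(t, xb, fs), 50, window = c(-2, 4))
    expect_lt(max(abs(zMatrix(tpz)[1, binCenters(tpz) >= 0])), 1e-9)

    set.seed(9)
    x <- rnorm(length(t))
    cs <- CalciumSignal(t, x, fs)
    trig <- seq(20, 380, by = 8)[1:45]
    tp <- zscoreToBaseline(cs, trig, window = c(-2, 4), baselinePre = 2)
    bIdx <- binCenters(tp) >= -2 & binCenters(tp) < 0
    expect_lt(abs(mean(zMatrix(tp)[, bIdx])), 0.05)
    expect_lt(abs(mean(apply(zMatrix(tp)[, bIdx], 1, sd)) - 1), 0.1)

    # a sample at baseline mean + 2 SD maps to z = 2
    y <- rep(0, length(t)); y[1:length(t)] <- rnorm(length(t))
    base <- y[(50 * fs - 2 * fs):(50 * fs - 1)]
    y[50 * fs + 10] <- mean(base) + 2 * sd(base)
    cs2 <- CalciumSignal(t, y, fs)
    tp2 <- zscoreToBaseline(cs2, 50 - 1 / fs, window = c(-2, 4))
    expect_equal(zMatrix(tp2)[1, which.min(abs(binCenters(tp2) - 0.1))], 2,
                 tolerance = 1e-9)
})

test_that("session-ITI z-scoring uses one pooled baseline", {
    fs <- 50
    t <- seq(0, 200, by = 1 / fs)
    set.seed(3)
    x <- rnorm(length(t), 5, 2)
    cs <- CalciumSignal(t, x, fs)
    trig <- seq(20, 180, by = 10)
    tp <- zscoreToBaseline(cs, trig, window = c(-2, 4), mode = "session")
    i0 <- vapply(trig, function(tt) which.min(abs(t - tt)), integer(1))
    bIdx <- unlist(lapply(i0, function(i) (i - 2 * fs):(i - 1)))
    manual <- (x[i0[1] - fs] - mean(x[bIdx])) / sd(x[bIdx])
    expect_equal(zMatrix(tp)[1, which.min(abs(binCenters(tp) + 1))], manual,
                 tolerance = 1e-9)
})

test_that("responseMetrics matches analytic FWHM/latency and the scan oracle", {
    fs <- 1000
    tt <- seq(-2, 2, by = 1 / fs)
    m <- 4 * exp(-((tt - 0.4) / 0.1)^2 / 2)    # Gaussian, sigma 100 ms
    tp <- makeTrialPETH(tt, rbind(m, m), fs)
    rm_ <- responseMetrics(tp)
    expect_equal(rm_$latency_s, 0.4, tolerance = 1 / fs + 1e-12)
    expect_equal(rm_$duration_s, 2 * sqrt(2 * log(2)) * 0.1,
                 tolerance = 1 / fs + 1e-12)
    expect_equal(rm_$peak, 4, tolerance = 1e-6)

    # triangular pulse: FWHM = half the base; AUC vs trapezoidal oracle
    tri <- pmax(0, 1 - abs(tt - 0.3) / 0.1)
    tp2 <- makeTrialPETH(tt, rbind(tri, tri), fs)
    rm2 <- responseMetrics(tp2)
    expect_equal(rm2$duration_s, 0.1, tolerance = 1 / fs + 1e-12)
    sel <- tt >= 0.25 - 1e-9 & tt <= 0.35 + 1e-9
    expect_equal(rm2$auc, trapzOracle(tt[sel], tri[sel]), tolerance = 0.01)

    # independent scan oracle on the same array (exact agreement)
    set.seed(11)
    noisy <- abs(stats::filter(rnorm(length(tt)), rep(0.2, 5),
                               sides = 2))
    noisy[is.na(noisy)] <- 0
    tp3 <- makeTrialPETH(tt, rbind(as.numeric(noisy), as.numeric(noisy)), fs)
    rm3 <- responseMetrics(tp3)
    v <- as.numeric(noisy)
    win <- which(tt > 0 & tt <= 1)
    pk <- win[which.max(v[win])]
    expect_identical(rm3$peak, v[pk])
    expect_identical(rm3$latency_s, tt[pk])

    # flat zero trace: degenerate, full-window duration, flagged
    tp4 <- makeTrialPETH(tt, rbind(numeric(length(tt)), numeric(length(tt))),
                         fs)
    rm4 <- responseMetrics(tp4)
    expect_equal(rm4$peak, 0)
    expect_equal(rm4$duration_s, diff(range(tt)))
    expect_equal(rm4$flag, "no positive response")
})

test_that("trialwiseCueTest handles ties, shifts, and matches exact enumeration", {
    tt <- seq(-1, 1, by = 0.01)
    set.seed(5)
    z <- matrix(rnorm(20 * length(tt)), 20)
    tpEq <- makeTrialPETH(tt, z, 100)
    # identical response and baseline maxima per trial -> p = 1
    zSym <- cbind(z[, tt < 0], z[, rev(which(tt < 0))], z[, tt == 1])
    resEq <- trialwiseCueTest(makeTrialPETH(seq(-1, 1, length.out = ncol(zSym)),
                                            zSym, 100))
    expect_equal(resEq$p, 1)
    expect_false(resEq$significant)

    # uniform +1 shift in the response window: significant
    z2 <- z
    z2[, tt >= 0 & tt < 0.5] <- z2[, tt >= 0 & tt < 0.5] + 1
    res2 <- trialwiseCueTest(makeTrialPETH(tt, z2, 100))
    expect_true(res2$significant)
    expect_lt(res2$p, 0.001)

    # exact-distribution oracle on 12 trials with distinct differences
    set.seed(8)
    z3 <- matrix(rnorm(12 * length(tt)), 12)
    tp3 <- makeTrialPETH(tt, z3, 100)
    res3 <- trialwiseCueTest(tp3)
    x <- apply(z3[, tt >= 0 & tt < 0.5], 1, max)
    y <- apply(z3[, tt >= -0.5 & tt < 0], 1, max)
    expect_equal(res3$p, signedRankExactP(x - y), tolerance = 1e-12)

    expect_error(trialwiseCueTest(makeTrialPETH(tt, z[1:5, ], 100)),
                 "at least 10")
})

test_that("trialwiseCueTest is calibrated on null data", {
    tt <- seq(-1, 1, by = 0.02)
    hits <- 0
    for (i in 1:200) {
        set.seed(3000 + i)
        z <- matrix(rnorm(20 * length(tt)), 20)
        if (trialwiseCueTest(makeTrialPETH(tt, z, 50))$significant)
            hits <- hits + 1
    }
    expect_lte(hits / 200, 0.08)  # ~7% band around the nominal 5%
})
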