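# Ground-truth generators: determinism, construction invariants,
# distributional properties, closed-form recoveries.

test_that("every generator is bit-reproducible from its seed", {
    expect_identical(spikeTimes(genPoissonTrain(10, 50, seed = 3)$train),
                     spikeTimes(genPoissonTrain(10, 50, seed = 3)$train))
    expect_identical(spikeTimes(genBurstingTrain(seed = 3, duration = 100)$train),
                     spikeTimes(genBurstingTrain(seed = 3, duration = 100)$train))
    expect_identical(
        spikeTimes(genRegularThetaTrain(duration = 100, seed = 3)$train),
        spikeTimes(genRegularThetaTrain(duration = 100, seed = 3)$train))
    a <- genPhotometry(duration = 30, fs = 50, seed = 3)
    b <- genPhotometry(duration = 30, fs = 50, seed = 3)
    expect_identical(a$session@f465, b$session@f465)
    s1 <- genTaskSession(nTrials = 20, seed = 3)
    s2 <- genTaskSession(nTrials = 20, seed = 3)
    expect_identical(trials(s1$trialTable), trials(s2$trialTable))
    c1 <- genCoupledPair(duration = 30, seed = 3)
    c2 <- genCoupledPair(duration = 30, seed = 3)
    expect_identical(dff(c1$y), dff(c2$y))
    # generators restore the caller's RNG stream
    set.seed(99); before <- runif(1)
    set.seed(99); invisible(genPoissonTrain(10, 10, seed = 1))
    expect_identical(runif(1), before)
})

test_that("Poisson generator honors rate, dead time, and realizability", {
    p <- genPoissonTrain(10, 100, seed = 1)
    expect_true(abs(nSpikes(p$train) - 1000) <= 100)  # ~3 SD Poisson band
    d <- genPoissonTrain(5, 200, deadTime = 0.060, seed = 2)
    expect_gte(min(diff(spikeTimes(d$train))), 0.060)
    expect_error(genPoissonTrain(20, 10, deadTime = 0.06), "unrealizable")
})

test_that("bursting generator produces jittered intra-burst ISIs and merges", {
    b <- genBurstingTrain(burstRate = 0.2, spikesPerBurst = c(2, 2),
                          intraIsi = 0.006, duration = 400, seed = 5)
    isis <- diff(spikeTimes(b$train))
    # intra-burst ISIs live in the 6 ms +/- 10% jitter band (rare shorter
    # gaps can arise from merged overlapping bursts, none did at this rate)
    intra <- isis[isis <= 0.006 * 1.1 + 1e-12]
    expect_gt(length(intra), 10)
    expect_true(all(intra >= 0.006 * 0.9 - 1e-12))
    empty <- genBurstingTrain(burstRate = 0, duration = 100, seed = 1)
    expect_identical(nSpikes(empty$train), 0L)
})

test_that("theta generator at depth 0 matches the Poisson generator (KS on ISIs)", {
    pass <- 0
    for (s in 1:20) {
        a <- genRegularThetaTrain(rate = 8, deadTime = 0.02, depth = 0,
                                  duration = 200, seed = s)$train
        b <- genPoissonTrain(8, 200, deadTime = 0.02, seed = 1000 + s)$train
        p <- suppressWarnings(
            stats::ks.test(diff(spikeTimes(a)), diff(spikeTimes(b))))$p.value
        if (p > 0.01) pass <- pass + 1
    }
    expect_gte(pass, 18)
    m <- genRegularThetaTrain(duration = 300, seed = 4)$train
    expect_gte(min(diff(spikeTimes(m))), 0.060)
})

test_that("theta modulation raises the 100-200 ms ACG band above its flanks", {
    tr <- genRegularThetaTrain(rate = 8, deadTime = 0, depth = 0.8,
                               duration = 600, seed = 2)$train
    acg <- smoothACG(computeACG(tr))
    lags <- acgLags(acg); v <- acgNorm(acg)
    peakBand <- mean(v[lags >= 0.120 & lags < 0.165])  # around 1/7 Hz period
    flanks <- mean(v[(lags >= 0.050 & lags < 0.075) |
                     (lags >= 0.225 & lags < 0.250)])
    expect_gt(peakBand, flanks)
})

test_that("task generator honors contingencies and trial timing", {
    s <- genTaskSession(nTrials = 200, seed = 7)
    tr <- trials(s$trialTable)
    expect_identical(nrow(tr), 200L)
    expect_gte(min(diff(tr$cue_time)), 2.5)
    reward <- tr$outcome == "reward"
    expect_true(all(tr$cue_id[reward] == 1L))
    omission1 <- mean(tr$outcome[tr$cue_id == 1L] == "omission")
    expect_lt(abs(omission1 - 0.1), 0.1)
    delay <- tr$outcome_time - tr$cue_time
    expect_true(all(delay >= 1.4 - 1e-9 & delay <= 1.6 + 1e-9, na.rm = TRUE))
    expect_identical(sum(is.na(tr$outcome_time)),
                     sum(tr$outcome == "omission"))
    # a gain-3 unit's PETH max/baseline ratio lands near 3
    s2 <- genTaskSession(nTrials = 112, responseSpec = list(
        u = list(base_rate = 8, event = "reward", latency = 0,
                 duration = 0.3, gain = 3)), seed = 8)
    peth <- computePETH(s2$trains$u, s2$events$reward, c(-0.5, 0.5), 0.05)
    base <- mean(pethRate(peth)[binCenters(peth) < 0])
    resp <- mean(pethRate(peth)[binCenters(peth) > 0 &
                                binCenters(peth) < 0.3])
    expect_lt(abs(resp / base - 3), 0.6)
})

test_that("photometry generator: null sessions and closed-form transients", {
    # no transients: dF/F output settles at the noise floor
    g0 <- genPhotometry(duration = 120, fs = 100, nTransients = 0,
                        amplitudes = numeric(), noiseSd = 0.05,
                        artifactSd = 0.05, seed = 4)
    cs0 <- preprocessDFF(g0$session)
    expect_lt(sd(dff(cs0)), 0.1)  # (0.05 a.u. on baseline 100 = 0.05%)

    # constant baseline, no artifact/noise, one transient: dF/F peak equals
    # the configured amplitude times the unit kernel peak
    g1 <- genPhotometry(duration = 120, fs = 100, transientTimes = 60,
                        amplitudes = 4, artifactSd = 0, bleachTau = Inf,
                        noiseSd = 0, seed = 1)
    # max over the sampling grid sits a hair below the continuous-time
    # kernel peak of 1 (grid discretization only)
    expect_equal(max(g1$truth$clean_pct), 4, tolerance = 5e-3)
    f465 <- g1$session@f465; f405 <- g1$session@f405
    expect_equal(max((f465 - f405) / f405 * 100), max(g1$truth$clean_pct),
                 tolerance = 1e-9)
    expect_error(genPhotometry(amplitudes = -1), "negative fluorescence")
})

test_that("coupled pair and pupil generators encode their stated lags", {
    c0 <- genCoupledPair(duration = 60, fs = 50, lag = 0, gain = 1,
                         noiseSd = 0, seed = 2)
    cc0 <- normalizedXCorr(c0$x, c0$y, maxLag = 5, exclude = 0)
    expect_equal(cc0@peakLag, 0)
    expect_equal(cc0@peakValue, 1, tolerance = 1e-9)

    cp <- genCoupledPair(duration = 120, fs = 50, lag = 0.8, seed = 6)
    expect_equal(cp$truth$params$lag_s, 0.8)
    cc <- normalizedXCorr(cp$x, cp$y, maxLag = 10)
    expect_lte(abs(cc@peakLag - 0.8), 2 / 50)

    # gain 0: independent pair, no structure above the noise bound
    cN <- genCoupledPair(duration = 120, fs = 50, lag = 0.8, gain = 0,
                         noiseSd = 1, seed = 3)
    ccN <- normalizedXCorr(cN$x, cN$y, maxLag = 10)
    expect_lt(max(abs(ccN@values)), 5 / sqrt(120 * 50))

    # pupil lags calcium by the configured amount
    g <- genPhotometry(duration = 240, fs = 50, nTransients = 15,
                       amplitudes = 4, seed = 9)
    cs <- preprocessDFF(g$session)
    pup <- genPupilCoupled(cs, pupilLag = 0.7, smoothingTau = 0.1,
                           noiseSd = 0.1, seed = 9)
    pta <- peakTriggeredAverage(cs, pup$pupil, thresholdSd = 2, minSep = 1)
    expect_lte(abs(pta$lags[which.max(pta$average)] - 0.7), 0.15)

    # identical-lag degenerate case: pupil equals calcium, TE symmetric
    pup0 <- genPupilCoupled(cs, pupilLag = 0, smoothingTau = 0, noiseSd = 0,
                            seed = 1)
    expect_equal(pup0$pupil, dff(cs))
})
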