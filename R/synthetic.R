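# Seeded ground-truth generators emulating the statistical structure of the
# recordings: bursting / Poisson-like / regular-rhythmic point processes,
# event-locked rate modulation, two-channel photometry with shared artifact
# and bleaching, lag-coupled signal pairs, and calcium-lagged pupil traces.
#
# Every generator returns list(<data>, truth = <SyntheticGroundTruth>) where
# truth is a plain list carrying the generator name, seed and all true
# parameters; regeneration from the same (name, params, seed) is
# bit-identical. Each generator seeds a local RNG stream and restores the
# caller's RNG state.

.truth <- function(generator, seed, ...) {
    list(generator = generator, seed = seed, params = list(...))
}

#' Generate a homogeneous Poisson spike train with absolute dead time
#'
#' Renewal process with inter-spike intervals \code{deadTime + Exp(rate)}, i.e.
#' a Poisson process thinned by an absolute dead time; expected count is about
#' \code{rate * duration / (1 + rate * deadTime)}.
#'
#' @param rate underlying Poisson rate (Hz), positive.
#' @param duration recording length (s).
#' @param deadTime absolute dead time (s), nonnegative; \code{rate * deadTime}
#'   must stay below 1.
#' @param seed integer RNG seed.
#' @param unitId unit label.
#' @return list(train = \linkS4class{SpikeTrain}, truth = ground-truth list).
#' @export
genPoissonTrain <- function(rate, duration, deadTime = 0, seed = 1,
                            unitId = "poisson") {
    stopifnot(rate > 0, duration > 0, deadTime >= 0)
    if (rate * deadTime >= 1)
        stop("unrealizable: rate * deadTime must be < 1")
    times <- withLocalSeed(seed, {
        nGuess <- ceiling(duration * rate / (1 + rate * deadTime) * 1.5 + 50)
        isi <- deadTime + stats::rexp(nGuess, rate)
        tt <- cumsum(isi)
        while (tt[length(tt)] < duration) {
            isi <- deadTime + stats::rexp(nGuess, rate)
            tt <- c(tt, tt[length(tt)] + cumsum(isi))
        }
        tt[tt < duration]
    })
    list(train = SpikeTrain(times, 0, duration, unitId = unitId),
         truth = .truth("poisson_train", seed, rate = rate,
                        duration = duration, dead_time = deadTime))
}

#' Generate a bursting spike train
#'
#' Burst onsets follow a Poisson process; each burst holds \code{k} spikes
#' (k uniform over \code{spikesPerBurst}) at \code{intraIsi} spacing with 10%
#' uniform jitter on each intra-burst interval. Overlapping bursts are merged
#' by dropping near-coincident spikes.
#'
#' @param burstRate burst-event rate (Hz).
#' @param spikesPerBurst integer range \code{c(min, max)} of spikes per burst.
#' @param intraIsi nominal intra-burst inter-spike interval (s).
#' @param duration recording length (s).
#' @param seed integer RNG seed.
#' @param unitId unit label.
#' @return list(train, truth) as in \code{\link{genPoissonTrain}}.
#' @export
genBurstingTrain <- function(burstRate = 0.3, spikesPerBurst = c(3, 6),
                             intraIsi = 0.006, duration = 600, seed = 1,
                             unitId = "bursting") {
    stopifnot(burstRate >= 0, intraIsi > 0, duration > 0)
    times <- withLocalSeed(seed, {
        nB <- stats::rpois(1L, burstRate * duration)
        if (nB == 0L) numeric() else {
            onsets <- sort(stats::runif(nB, 0, duration))
            spikes <- unlist(lapply(onsets, function(on) {
                k <- sample(seq(spikesPerBurst[1L], spikesPerBurst[2L]), 1L)
                isis <- intraIsi * (1 + stats::runif(k - 1L, -0.1, 0.1))
                on + c(0, cumsum(isis))
            }))
            spikes <- sort(spikes[spikes < duration])
            # merge overlapping bursts: drop spikes closer than 0.5 ms
            if (length(spikes) > 1L)
                spikes <- spikes[c(TRUE, diff(spikes) > 5e-4)]
            spikes
        }
    })
    list(train = SpikeTrain(times, 0, duration, unitId = unitId),
         truth = .truth("bursting_train", seed, burst_rate = burstRate,
                        spikes_per_burst = spikesPerBurst,
                        intra_isi = intraIsi, duration = duration))
}

#' Generate a regular rhythmic (theta-modulated) spike train
#'
#' Inhomogeneous Poisson process with rate
#' \code{rate * (1 + depth * cos(2 pi thetaHz t))} (generated by thinning),
#' followed by sequential absolute dead-time enforcement. With
#' \code{depth = 0} this is distributionally identical to
#' \code{\link{genPoissonTrain}}.
#'
#' @param rate mean rate (Hz).
#' @param deadTime absolute dead time (s); the regular-rhythmic phenotype uses
#'   a long (tens of ms) dead time.
#' @param thetaHz modulation frequency (Hz).
#' @param depth modulation depth in [0, 1].
#' @param duration recording length (s).
#' @param seed integer RNG seed.
#' @param unitId unit label.
#' @return list(train, truth) as in \code{\link{genPoissonTrain}}.
#' @export
genRegularThetaTrain <- function(rate = 4, deadTime = 0.060, thetaHz = 7,
                                 depth = 0.8, duration = 900, seed = 1,
                                 unitId = "regular") {
    stopifnot(depth >= 0, depth <= 1, rate > 0)
    if (rate * deadTime >= 1)
        stop("unrealizable: rate * deadTime must be < 1")
    times <- withLocalSeed(seed, {
        rmax <- rate * (1 + depth)
        n <- stats::rpois(1L, rmax * duration)
        cand <- unique(sort(stats::runif(n, 0, duration)))
        keep <- stats::runif(length(cand)) <
            (1 + depth * cos(2 * pi * thetaHz * cand)) / (1 + depth)
        tt <- cand[keep]
        if (deadTime > 0 && length(tt) > 1L) {
            keep <- logical(length(tt)); keep[1L] <- TRUE
            last <- tt[1L]
            for (i in 2L:length(tt)) {
                if (tt[i] - last >= deadTime) { keep[i] <- TRUE; last <- tt[i] }
            }
            tt <- tt[keep]
        }
        tt
    })
    list(train = SpikeTrain(times, 0, duration, unitId = unitId),
         truth = .truth("regular_theta_train", seed, rate = rate,
                        dead_time = deadTime, theta_hz = thetaHz,
                        depth = depth, duration = duration))
}

# inhomogeneous Poisson train with multiplicative event-locked gain windows
.genModulatedTrain <- function(baseRate, duration, windows, gains, seed,
                               unitId) {
    withLocalSeed(seed, {
        rmax <- baseRate * max(1, if (length(gains)) max(gains) else 1)
        n <- stats::rpois(1L, rmax * duration)
        cand <- unique(sort(stats::runif(n, 0, duration)))
        rate <- rep(baseRate, length(cand))
        if (length(gains)) for (w in seq_along(gains)) {
            sel <- cand >= windows[w, 1L] & cand < windows[w, 2L]
            rate[sel] <- baseRate * gains[w]
        }
        keep <- stats::runif(length(cand)) < rate / rmax
        SpikeTrain(cand[keep], 0, duration, unitId = unitId)
    })
}

#' Generate a full Pavlovian task session with responsive units
#'
#' Emulates the two-cue conditioning task: strictly increasing cue times with
#' a consumption gap plus a truncated-exponential foreperiod (2.5-5.5 s),
#' 90%/10% outcome/omission contingencies per cue (cue 1 -> water reward,
#' cue 2 -> air-puff punishment), and outcomes delivered 0.4-0.6 s after the
#' 1 s cue tone ends. Each simulated unit fires as an inhomogeneous Poisson
#' process whose rate is multiplied by \code{gain} inside
#' \code{[latency, latency + duration)} after its assigned trigger events
#' (gain > 1: activation, gain < 1: suppression).
#'
#' @param nTrials number of trials.
#' @param cue2Frac fraction of cue-2 trials.
#' @param rewardProb,punishProb outcome probability given cue 1 / cue 2
#'   (remainder are omissions).
#' @param outcomeDelay range (s) of the post-tone delay before the outcome.
#' @param cueDur cue tone duration (s).
#' @param responseSpec named list, one entry per unit:
#'   \code{list(base_rate, event, latency, duration, gain)} where \code{event}
#'   is one of "cue1", "cue2", "reward", "punishment".
#' @param seed integer RNG seed.
#' @return list with \code{trialTable} (\linkS4class{TrialTable}),
#'   \code{events} (named list of \linkS4class{EventSeries}), \code{trains}
#'   (named list of \linkS4class{SpikeTrain}) and \code{truth}.
#' @export
genTaskSession <- function(nTrials = 100, cue2Frac = 0.5, rewardProb = 0.9,
                           punishProb = 0.9, outcomeDelay = c(0.4, 0.6),
                           cueDur = 1, responseSpec = list(), seed = 1) {
    stopifnot(nTrials >= 1)
    sess <- withLocalSeed(seed, {
        gap <- 3.0  # consumption + no-lick period before the foreperiod
        fore <- pmin(2.5 + stats::rexp(nTrials, 1 / 1.5), 5.5)
        cueTime <- 5 + cumsum(gap + fore) - (gap + fore[1L])
        cueId <- ifelse(stats::runif(nTrials) < cue2Frac, 2L, 1L)
        u <- stats::runif(nTrials)
        outcome <- ifelse(cueId == 1L,
                          ifelse(u < rewardProb, "reward", "omission"),
                          ifelse(u < punishProb, "punishment", "omission"))
        delay <- cueDur + stats::runif(nTrials, outcomeDelay[1L], outcomeDelay[2L])
        outcomeTime <- ifelse(outcome == "omission", NA_real_,
                              cueTime + delay)
        list(cueTime = cueTime, cueId = cueId, outcome = outcome,
             outcomeTime = outcomeTime)
    })
    tt <- TrialTable(sess$cueTime, sess$cueId, sess$outcomeTime, sess$outcome)
    duration <- max(sess$cueTime) + 10
    events <- list(
        cue1 = EventSeries(sess$cueTime[sess$cueId == 1L], "cue1"),
        cue2 = EventSeries(sess$cueTime[sess$cueId == 2L], "cue2"),
        reward = EventSeries(stats::na.omit(
            sess$outcomeTime[sess$outcome == "reward"]), "reward"),
        punishment = EventSeries(stats::na.omit(
            sess$outcomeTime[sess$outcome == "punishment"]), "punishment"))
    trains <- list()
    for (nm in names(responseSpec)) {
        spec <- responseSpec[[nm]]
        ev <- eventTimes(events[[spec$event]])
        windows <- cbind(ev + spec$latency, ev + spec$latency + spec$duration)
        trains[[nm]] <- .genModulatedTrain(
            spec$base_rate, duration, windows,
            rep(spec$gain, length(ev)),
            substreamSeed(seed, nm), unitId = nm)
    }
    list(trialTable = tt, events = events, trains = trains,
         truth = .truth("task_session", seed, n_trials = nTrials,
                        cue2_frac = cue2Frac, reward_prob = rewardProb,
                        punish_prob = punishProb,
                        outcome_delay = outcomeDelay, cue_dur = cueDur,
                        response_spec = responseSpec, duration = duration))
}

#' Generate a laser-pulse optotagging block
#'
#' Pulses of \code{pulseDur} every \code{period} seconds. A "tagged" unit is
#' suppressed from \code{latency} after pulse onset to pulse offset (in-pulse
#' rate \code{inPulseRate}); an untagged control fires unmodulated.
#'
#' @param baseRate baseline firing rate (Hz).
#' @param nPulses number of laser pulses.
#' @param pulseDur pulse duration (s).
#' @param period pulse period (s).
#' @param suppressed logical; simulate an opsin-expressing unit?
#' @param latency suppression onset latency (s) after pulse onset.
#' @param inPulseRate residual rate (Hz) during suppression.
#' @param seed integer RNG seed.
#' @return list(train, laser = \linkS4class{EventSeries}, truth).
#' @export
genOptotagBlock <- function(baseRate = 12, nPulses = 100, pulseDur = 0.2,
                            period = 5, suppressed = TRUE, latency = 0.005,
                            inPulseRate = 0.1, seed = 1) {
    onsets <- 10 + period * (seq_len(nPulses) - 1L)
    duration <- onsets[nPulses] + period
    if (suppressed) {
        windows <- cbind(onsets + latency, onsets + pulseDur)
        gains <- rep(inPulseRate / baseRate, nPulses)
    } else {
        windows <- matrix(numeric(), ncol = 2L)
        gains <- numeric()
    }
    train <- .genModulatedTrain(baseRate, duration, windows, gains,
                                substreamSeed(seed, "optotag"),
                                unitId = if (suppressed) "archt" else "control")
    list(train = train, laser = EventSeries(onsets, "laser_on"),
         truth = .truth("optotag_block", seed, base_rate = baseRate,
                        n_pulses = nPulses, pulse_dur = pulseDur,
                        period = period, suppressed = suppressed,
                        latency = latency, in_pulse_rate = inPulseRate))
}

# double-exponential indicator kernel, normalized to peak 1
.gcampKernel <- function(t, tauRise, tauDecay) {
    k <- exp(-t / tauDecay) - exp(-t / tauRise)
    tpk <- log(tauDecay / tauRise) * tauRise * tauDecay / (tauDecay - tauRise)
    k / (exp(-tpk / tauDecay) - exp(-tpk / tauRise))
}

#' Generate a two-channel photometry session with ground truth
#'
#' Signal model: both channels share a multiplicative bleaching decay, an
#' additive random-walk motion artifact and independent white noise; only the
#' 465 nm channel additionally carries calcium transients (double-exponential
#' indicator kernel, amplitudes in % dF/F). The clean percent transient trace
#' is stored in the truth object.
#'
#' @param duration session length (s).
#' @param fs sampling rate (Hz).
#' @param transientTimes transient onset times (s); \code{NULL} draws
#'   \code{nTransients} uniformly (with 2 s margins).
#' @param nTransients number of transients drawn when \code{transientTimes}
#'   is NULL.
#' @param amplitudes transient amplitudes (% dF/F), recycled over transients.
#' @param tauRise,tauDecay indicator kernel time constants (s).
#' @param artifactSd per-sample step SD of the shared random-walk artifact
#'   (fluorescence units).
#' @param bleachTau bleaching time constant (s); \code{Inf} disables.
#' @param baseline mean fluorescence level (arbitrary units).
#' @param noiseSd independent white-noise SD per channel.
#' @param seed integer RNG seed.
#' @return list(session = \linkS4class{PhotometrySession}, truth); truth holds
#'   \code{clean_pct} (noise-free percent transient trace), \code{artifact},
#'   transient times/amplitudes and all parameters.
#' @export
genPhotometry <- function(duration = 300, fs = 100, transientTimes = NULL,
                          nTransients = 20, amplitudes = 4, tauRise = 0.05,
                          tauDecay = 0.6, artifactSd = 0.05, bleachTau = 600,
                          baseline = 100, noiseSd = 0.05, seed = 1) {
    stopifnot(duration > 10, fs > 0, baseline > 0)
    if (any(amplitudes < 0)) stop("negative fluorescence configured")
    n <- as.integer(round(duration * fs))
    t <- (seq_len(n) - 1L) / fs
    out <- withLocalSeed(seed, {
        tim <- if (is.null(transientTimes))
            sort(stats::runif(nTransients, 2, duration - 2)) else
            sort(transientTimes)
        amp <- rep_len(amplitudes, length(tim))
        clean <- numeric(n)
        for (i in seq_along(tim)) {
            i0 <- as.integer(floor(tim[i] * fs)) + 1L
            span <- i0:min(n, i0 + as.integer(ceiling(8 * tauDecay * fs)))
            clean[span] <- clean[span] +
                amp[i] * .gcampKernel(t[span] - t[i0], tauRise, tauDecay)
        }
        artifact <- if (artifactSd > 0) cumsum(stats::rnorm(n, 0, artifactSd))
                    else numeric(n)
        bleach <- if (is.finite(bleachTau)) exp(-t / bleachTau) else rep(1, n)
        base <- baseline * bleach
        f405 <- base + artifact + stats::rnorm(n, 0, noiseSd)
        f465 <- base * (1 + clean / 100) + artifact + stats::rnorm(n, 0, noiseSd)
        list(f465 = f465, f405 = f405, clean = clean, artifact = artifact,
             times = tim, amps = amp)
    })
    list(session = PhotometrySession(t, out$f465, out$f405, fs = fs),
         truth = c(.truth("photometry", seed, duration = duration, fs = fs,
                          tau_rise = tauRise, tau_decay = tauDecay,
                          artifact_sd = artifactSd, bleach_tau = bleachTau,
                          baseline = baseline, noise_sd = noiseSd),
                   list(transient_times = out$times,
                        amplitudes = out$amps, clean_pct = out$clean,
                        artifact = out$artifact)))
}

# smoothed-noise base trace for coupled-signal generators: white noise
# low-passed by a single-pole filter with time constant tau (s)
.smoothNoise <- function(n, fs, tau, seed) {
    withLocalSeed(seed, {
        a <- exp(-1 / (tau * fs))
        x <- stats::rnorm(n)
        as.numeric(stats::filter(x * sqrt(1 - a^2), a, method = "recursive"))
    })
}

#' Generate a lag-coupled pair of calcium signals
#'
#' \code{y(t) = gain * x(t - lag) + noise}, with x a smoothed-noise calcium-like
#' base trace. The lag is rounded to the nearest sample and the realized value
#' recorded in the truth object.
#'
#' @param duration length (s).
#' @param fs sampling rate (Hz).
#' @param lag imposed lag (s); positive means y lags x.
#' @param gain coupling gain.
#' @param noiseSd independent noise SD added to y.
#' @param baseTau smoothness time constant of the base trace (s).
#' @param seed integer RNG seed.
#' @return list(x, y: \linkS4class{CalciumSignal}; truth with realized
#'   \code{lag_s}).
#' @export
genCoupledPair <- function(duration = 120, fs = 100, lag = 0.8, gain = 1,
                           noiseSd = 0.5, baseTau = 0.3, seed = 1) {
    n <- as.integer(round(duration * fs))
    L <- as.integer(round(lag * fs))
    if (abs(L) / fs != lag)
        lag <- L / fs
    full <- .smoothNoise(n + abs(L), fs, baseTau, substreamSeed(seed, "base"))
    if (L >= 0) {
        x <- full[(L + 1L):(L + n)]
        ylin <- full[1L:n]
    } else {
        x <- full[1L:n]
        ylin <- full[(-L + 1L):(-L + n)]
    }
    noise <- withLocalSeed(substreamSeed(seed, "noise"),
                           stats::rnorm(n, 0, noiseSd))
    y <- gain * ylin + noise
    t <- (seq_len(n) - 1L) / fs
    list(x = CalciumSignal(t, x, fs, list(generator = "coupled_pair")),
         y = CalciumSignal(t, y, fs, list(generator = "coupled_pair")),
         truth = .truth("coupled_pair", seed, duration = duration, fs = fs,
                        lag_s = lag, gain = gain, noise_sd = noiseSd,
                        base_tau = baseTau))
}

#' Generate a pupil trace lag-coupled to a calcium signal
#'
#' The pupil series is a lagged copy of the calcium trace, low-pass smoothed
#' with a single-pole filter of time constant \code{smoothingTau} (pupil
#' dilation is sluggish relative to calcium), plus independent noise. By
#' construction the transfer entropy calcium -> pupil exceeds the reverse.
#'
#' @param calcium a \linkS4class{CalciumSignal}.
#' @param pupilLag lag (s) of the pupil behind calcium, nonnegative.
#' @param smoothingTau pupil low-pass time constant (s); 0 disables.
#' @param noiseSd independent noise SD.
#' @param seed integer RNG seed.
#' @return list(pupil = numeric series on the calcium grid, truth).
#' @export
genPupilCoupled <- function(calcium, pupilLag = 0.7, smoothingTau = 0.2,
                            noiseSd = 0.2, seed = 1) {
    stopifnot(is(calcium, "CalciumSignal"), pupilLag >= 0)
    fs <- samplingRate(calcium)
    x <- dff(calcium)
    n <- length(x)
    L <- as.integer(round(pupilLag * fs))
    lagged <- c(rep(x[1L], L), x)[seq_len(n)]
    if (smoothingTau > 0) {
        a <- exp(-1 / (smoothingTau * fs))
        lagged <- as.numeric(stats::filter(lagged * (1 - a), a,
                                           method = "recursive"))
    }
    noise <- withLocalSeed(substreamSeed(seed, "pupil"),
                           stats::rnorm(n, 0, noiseSd))
    list(pupil = lagged + noise,
         truth = .truth("pupil_coupled", seed, pupil_lag = L / fs,
                        smoothing_tau = smoothingTau, noise_sd = noiseSd))
}
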