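# In vitro current-step metrics: spike detection on voltage sweeps, spike
# delay, burst frequency from the first three post-onset inter-spike
# intervals, and evoked-spike autocorrelograms pooled over sweeps.

#' Detect action potentials in a voltage sweep
#'
#' Upward threshold crossings (default -20 mV), each assigned the time of the
#' local voltage maximum that follows the crossing (until the trace falls
#' back below threshold); events closer than \code{minIsi} are merged.
#'
#' @param sweep a \linkS4class{VoltageSweep} sampled at >= 10 kHz.
#' @param thresholdMv detection threshold (mV).
#' @param minIsi minimum separation of detected spikes (s).
#' @return Numeric vector of spike peak times (s); empty when no crossing.
#' @export
detectSpikes <- function(sweep, thresholdMv = -20, minIsi = 0.001) {
    stopifnot(is(sweep, "VoltageSweep"))
    fs <- 1 / (sweep@t[2L] - sweep@t[1L])
    if (fs < 10000) stop("spike detection needs sampling >= 10 kHz")
    v <- sweep@v
    above <- v >= thresholdMv
    onsets <- which(diff(above) == 1L) + 1L
    if (!length(onsets)) return(numeric())
    ends <- which(diff(above) == -1L)
    peaks <- vapply(onsets, function(i) {
        j <- ends[ends >= i][1L]
        if (is.na(j)) j <- length(v)
        i - 1L + which.max(v[i:j])
    }, integer(1L))
    tt <- sweep@t[peaks]
    if (length(tt) > 1L) tt <- tt[c(TRUE, diff(tt) >= minIsi)]
    tt
}

#' Spike delay of a current-step response
#'
#' Interval between the current-step onset and the peak time of the first
#' action potential inside the step. Returns \code{NA} (a "no-spike" result,
#' distinct from 0) when no spike falls within the step.
#'
#' @param sweep a \linkS4class{VoltageSweep}.
#' @param spikes spike peak times (s), e.g. from \code{\link{detectSpikes}}.
#' @return Delay (s), or \code{NA_real_} when the step evoked no spike.
#' @export
spikeDelay <- function(sweep, spikes) {
    stopifnot(is(sweep, "VoltageSweep"))
    inStep <- spikes[spikes >= sweep@stepOnset & spikes <= sweep@stepOffset]
    if (!length(inStep)) return(NA_real_)
    inStep[1L] - sweep@stepOnset
}

#' Burst frequency from the first three inter-spike intervals
#'
#' The reciprocal of the mean of the three inter-spike intervals following
#' the first spike, i.e. \code{3 / (t4 - t1)}. Returns \code{NA} with fewer
#' than four spikes.
#'
#' @param spikes spike peak times (s) within the step, increasing.
#' @return Burst frequency (Hz), or \code{NA_real_} with < 4 spikes.
#' @export
burstFrequency <- function(spikes) {
    if (length(spikes) < 4L) return(NA_real_)
    3 / (spikes[4L] - spikes[1L])
}

#' Evoked-spike autocorrelogram pooled over sweeps
#'
#' Per-sweep pair-lag histograms are summed over sweeps (no cross-sweep
#' pairs), mean-normalized, and smoothed with a moving average (default 5 ms,
#' the in vitro convention).
#'
#' @param sweepSpikes list of numeric vectors: spike times (s) per sweep.
#' @param binWidth bin width (s); default 1 ms so the 5 ms moving average is
#'   a centered 5-point window.
#' @param maxLag largest lag (s).
#' @param smoothWindow moving-average window (s); must be an odd multiple of
#'   \code{binWidth}.
#' @return An \linkS4class{Autocorrelogram}.
#' @export
evokedACG <- function(sweepSpikes, binWidth = 0.001, maxLag = 0.5,
                      smoothWindow = 0.005) {
    stopifnot(is.list(sweepSpikes))
    nTotal <- sum(lengths(sweepSpikes))
    if (nTotal < 2L) stop("insufficient spikes (need at least 2 across sweeps)")
    nbins <- as.integer(round(maxLag / binWidth))
    counts <- numeric(nbins)
    for (sp in sweepSpikes)
        counts <- counts + .pairLagCounts(sort(sp), binWidth, nbins, maxLag)
    m <- mean(counts)
    norm <- if (m > 0) counts / m else counts
    acg <- new("Autocorrelogram",
               lags = (seq_len(nbins) - 0.5) * binWidth, counts = counts,
               norm = norm, binWidth = binWidth,
               nSpikesUsed = as.integer(nTotal), smoothing = "none")
    k <- round(smoothWindow / binWidth)
    if (k %% 2L == 0L)
        stop("smoothing window must be an odd multiple of the bin width")
    smoothACG(acg, smoothWindow)
}

#' Per-cell in vitro summary
#'
#' Convenience wrapper: detects spikes in every sweep, reports the maximum
#' spike delay and maximum burst frequency over sweeps, and the Burst/Theta
#' Index and refractory period of the evoked ACG.
#'
#' @param sweeps list of \linkS4class{VoltageSweep} objects for one cell.
#' @param config configuration list from \code{\link{analysisConfig}}.
#' @return One-row data.frame: \code{spike_delay_ms, burst_freq_hz,
#'   burst_index, theta_index, refractory_ms}.
#' @export
invitroCellSummary <- function(sweeps, config = analysisConfig()) {
    cf <- config$invitro
    spk <- lapply(sweeps, function(sw)
        detectSpikes(sw, cf$threshold_mv, cf$min_isi))
    delays <- mapply(spikeDelay, sweeps, spk)
    stepSpk <- mapply(function(sw, sp)
        sp[sp >= sw@stepOnset & sp <= sw@stepOffset],
        sweeps, spk, SIMPLIFY = FALSE)
    freqs <- vapply(stepSpk, burstFrequency, numeric(1L))
    acg <- evokedACG(stepSpk, smoothWindow = cf$smooth_window)
    raw <- new("Autocorrelogram", lags = acg@lags, counts = acg@counts,
               norm = acg@counts / mean(acg@counts), binWidth = acg@binWidth,
               nSpikesUsed = acg@nSpikesUsed, smoothing = "none")
    data.frame(
        spike_delay_ms = if (all(is.na(delays))) NA_real_
                         else max(delays, na.rm = TRUE) * 1000,
        burst_freq_hz = if (all(is.na(freqs))) NA_real_
                        else max(freqs, na.rm = TRUE),
        burst_index = burstIndex(acg),
        theta_index = thetaIndex(acg),
        refractory_ms = refractoryPeriod(raw) * 1000)
}
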