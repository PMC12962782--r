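# Autocorrelogram computation and firing-pattern statistics.
#
# The ACG is one-sided (positive lags, half-open bins, zero-lag self-pairs
# excluded) and mean-normalized, so a homogeneous Poisson train is flat near 1.
# The Burst Index contrasts the 0-25 ms maximum against the 180-200 ms mean;
# the Theta Index contrasts a +/-25 ms window around the 5-10 Hz peak
# (100-200 ms lags) against symmetric flanking windows; the relative
# refractory period is the half-height recovery point of the central trough
# after 10 ms smoothing.

# one-sided positive-lag pair histogram: for each spike, later spikes within
# maxLag found by a two-pointer sweep (findInterval), lags binned half-open
.pairLagCounts <- function(times, binWidth, nbins, maxLag) {
    n <- length(times)
    if (n < 2L) return(numeric(nbins))
    hi <- findInterval(times + maxLag, times)
    counts_i <- hi - seq_len(n)
    keep <- counts_i > 0L
    if (!any(keep)) return(numeric(nbins))
    from <- which(keep) + 1L
    js <- sequence(counts_i[keep], from = from)
    lags <- times[js] - rep(times[keep], counts_i[keep])
    as.numeric(binCountsHalfOpen(lags, 0, binWidth, nbins))
}

#' Compute the spike-train autocorrelogram
#'
#' Counts ordered distinct spike pairs by lag into half-open bins
#' \code{[(k-1)w, kw)} for positive lags up to \code{maxLag}, excluding
#' zero-lag self-pairs, and normalizes the counts by their mean over all bins.
#' Trains longer than \code{spikeCap} are truncated to their first
#' \code{spikeCap} spikes (memory guard for very active units).
#'
#' @param train a \linkS4class{SpikeTrain} with at least 2 spikes.
#' @param binWidth bin width (s); default 0.5 ms.
#' @param maxLag largest lag (s); must be at least 10 bins.
#' @param spikeCap maximum number of spikes used; default 50,000.
#' @return An \linkS4class{Autocorrelogram}.
#' @examples
#' tr <- SpikeTrain(c(0, 0.010, 0.020), 0, 1)
#' acg <- computeACG(tr, binWidth = 5e-4, maxLag = 0.05)
#' sum(acgCounts(acg))  # 3 ordered pairs
#' @export
computeACG <- function(train, binWidth = 5e-4, maxLag = 0.5,
                       spikeCap = 50000L) {
    stopifnot(is(train, "SpikeTrain"))
    if (binWidth <= 0) stop("binWidth must be positive")
    if (maxLag < 10 * binWidth) stop("maxLag must be at least 10 bins")
    if (spikeCap < 2) stop("spikeCap must be at least 2")
    times <- spikeTimes(train)
    if (length(times) < 2L) stop("insufficient spikes (need at least 2)")
    if (length(times) > spikeCap) times <- times[seq_len(spikeCap)]
    n <- length(times)
    nbins <- as.integer(round(maxLag / binWidth))
    counts <- .pairLagCounts(times, binWidth, nbins, maxLag)
    m <- mean(counts)
    norm <- if (m > 0) counts / m else counts
    new("Autocorrelogram",
        lags = (seq_len(nbins) - 0.5) * binWidth, counts = counts,
        norm = norm, binWidth = binWidth, nSpikesUsed = as.integer(n),
        smoothing = "none")
}

#' Smooth an autocorrelogram with a centered moving average
#'
#' The window must be an odd multiple of the bin width (e.g. 2.5 ms for five
#' 0.5 ms bins). Edges use shrunken windows (mean of the available points), so
#' no artificial trough is introduced at lag zero.
#'
#' @param acg an \linkS4class{Autocorrelogram}.
#' @param window smoothing window length (s).
#' @return The smoothed \linkS4class{Autocorrelogram}.
#' @export
smoothACG <- function(acg, window = 0.0025) {
    stopifnot(is(acg, "Autocorrelogram"))
    k <- round(window / acg@binWidth)
    if (abs(k * acg@binWidth - window) > 1e-9 || k %% 2L != 1L)
        stop("smoothing window must be an odd multiple of the bin width")
    k <- as.integer(k)
    new("Autocorrelogram",
        lags = acg@lags, counts = movingAverage(acg@counts, k),
        norm = movingAverage(acg@norm, k), binWidth = acg@binWidth,
        nSpikesUsed = acg@nSpikesUsed,
        smoothing = sprintf("%g ms (%d-point) moving average",
                            window * 1000, k))
}

# mean of ACG values whose bin centers fall in the half-open window [lo, hi)
.acgWindowVals <- function(acg, win) {
    sel <- acg@lags >= win[1L] & acg@lags < win[2L]
    if (!any(sel)) stop("ACG does not cover the window [",
                        win[1L], ", ", win[2L], ") s")
    acg@norm[sel]
}

#' Burst Index of an autocorrelogram
#'
#' Difference between the maximum ACG value at short lags (default 0-25 ms)
#' and the mean ACG value at long lags (default 180-200 ms), normalized by the
#' larger of the two, yielding an index in [-1, 1]. Returns 0 when both terms
#' are 0.
#'
#' @param acg an \linkS4class{Autocorrelogram}.
#' @param burstWin short-lag window (s), half-open.
#' @param baseWin long-lag baseline window (s), half-open.
#' @return Numeric Burst Index in [-1, 1].
#' @export
burstIndex <- function(acg, burstWin = c(0, 0.025), baseWin = c(0.180, 0.200)) {
    if (burstWin[2L] > baseWin[1L] && baseWin[2L] > burstWin[1L])
        stop("burst and baseline windows must not overlap")
    maxBurst <- max(.acgWindowVals(acg, burstWin))
    meanBase <- mean(.acgWindowVals(acg, baseWin))
    if (maxBurst == 0 && meanBase == 0) return(0)
    (maxBurst - meanBase) / max(maxBurst, meanBase)
}

#' Theta Index of an autocorrelogram
#'
#' Locates the 5-10 Hz rhythmicity peak as the ACG maximum within the
#' 100-200 ms lag band, averages the ACG over a +/-25 ms window around it, and
#' contrasts this against the mean over two symmetric flanking windows
#' (50-75 ms and 225-250 ms), normalized by the larger of the two means, so
#' the index lies in [-1, 1]. Returns 0 when both terms are 0.
#'
#' @param acg an \linkS4class{Autocorrelogram}, typically smoothed.
#' @param searchWin lag band searched for the theta peak (s).
#' @param peakHalfwidth half-width of the window averaged around the peak (s).
#' @param flankLow,flankHigh flanking reference windows (s), half-open.
#' @return Numeric Theta Index in [-1, 1].
#' @export
thetaIndex <- function(acg, searchWin = c(0.100, 0.200),
                       peakHalfwidth = 0.025,
                       flankLow = c(0.050, 0.075),
                       flankHigh = c(0.225, 0.250)) {
    sel <- acg@lags >= searchWin[1L] & acg@lags < searchWin[2L]
    if (!any(sel)) stop("ACG does not cover the theta search window")
    peakLag <- acg@lags[sel][which.max(acg@norm[sel])]
    peakVals <- .acgWindowVals(acg, c(peakLag - peakHalfwidth,
                                      peakLag + peakHalfwidth))
    flankVals <- c(.acgWindowVals(acg, flankLow), .acgWindowVals(acg, flankHigh))
    mPeak <- mean(peakVals)
    mFlank <- mean(flankVals)
    if (mPeak == 0 && mFlank == 0) return(0)
    (mPeak - mFlank) / max(mPeak, mFlank)
}

#' Relative refractory period from an autocorrelogram
#'
#' Smooths the ACG with a 10 ms moving average, takes the central trough as
#' the smoothed value at the smallest lag and the asymptote as the mean over
#' 180-200 ms, and returns the smallest lag at which the smoothed ACG recovers
#' to half the trough-to-asymptote distance. This is a functional (relative)
#' refractory period, not a biophysical one. Returns 0 when the trough is at
#' or above the asymptote.
#'
#' @param acg an unsmoothed \linkS4class{Autocorrelogram} with bins of at
#'   most 1 ms.
#' @param troughSmooth moving-average window (s) used for trough finding.
#' @param asymptoteWin long-lag window (s) defining the recovered height.
#' @return Refractory period estimate (s).
#' @export
refractoryPeriod <- function(acg, troughSmooth = 0.010,
                             asymptoteWin = c(0.180, 0.200)) {
    stopifnot(is(acg, "Autocorrelogram"))
    if (acg@binWidth > 0.001) stop("refractory estimation needs bins <= 1 ms")
    if (all(acg@counts == 0)) stop("degenerate ACG (all bins zero)")
    k <- as.integer(round(troughSmooth / acg@binWidth))
    if (k %% 2L == 0L) k <- k + 1L
    sm <- movingAverage(acg@norm, k)
    sel <- acg@lags >= asymptoteWin[1L] & acg@lags < asymptoteWin[2L]
    if (!any(sel)) stop("ACG does not cover the asymptote window")
    height <- mean(sm[sel])
    trough <- sm[1L]
    if (trough >= height) return(0)
    level <- trough + 0.5 * (height - trough)
    idx <- which(sm >= level)[1L]
    if (is.na(idx)) return(max(acg@lags))
    acg@lags[idx]
}

#' Classify a unit's firing pattern from its ACG statistics
#'
#' Three phenotypes, mirroring the cholinergic firing-pattern taxonomy:
#' regular rhythmic ("Reg": long refractory period and positive theta
#' rhythmicity), strongly bursting ("Burst-SB": high Burst Index) and
#' Poisson-like bursting ("Burst-PL": the remainder). The boundaries are not
#' universal constants and are exposed as configuration.
#'
#' @param burstIndex,thetaIndex,refractory the three ACG statistics
#'   (\code{refractory} in seconds).
#' @param regRefractoryMin minimum refractory period (s) for the Reg class.
#' @param sbMin minimum Burst Index for the strongly-bursting class.
#' @return A list with \code{label} ("Reg", "Burst-SB" or "Burst-PL") and the
#'   three input statistics.
#' @export
classifyFiringPattern <- function(burstIndex, thetaIndex, refractory,
                                  regRefractoryMin = 0.040, sbMin = 0.4) {
    stopifnot(is.finite(burstIndex), is.finite(thetaIndex),
              is.finite(refractory))
    label <- if (refractory >= regRefractoryMin && thetaIndex > 0) "Reg"
             else if (burstIndex >= sbMin) "Burst-SB"
             else "Burst-PL"
    list(label = label, burst_index = burstIndex, theta_index = thetaIndex,
         refractory_s = refractory)
}

#' Per-unit firing-pattern summary table
#'
#' Convenience wrapper running the full ACG chain on each train: raw ACG,
#' 2.5 ms smoothing for the Burst/Theta Index, refractory estimation on the
#' raw ACG, and classification.
#'
#' @param trains list of \linkS4class{SpikeTrain} objects.
#' @param config configuration list from \code{\link{analysisConfig}}.
#' @return data.frame with one row per unit: \code{unit_id, n_spikes_used,
#'   burst_index, theta_index, refractory_ms, label}.
#' @export
firingPatternTable <- function(trains, config = analysisConfig()) {
    cf <- config$acg
    rows <- lapply(trains, function(tr) {
        acg <- computeACG(tr, cf$bin_width, cf$max_lag, cf$spike_cap)
        sm <- smoothACG(acg, cf$smooth_window)
        bi <- burstIndex(sm, cf$burst_win, cf$base_win)
        ti <- thetaIndex(sm, cf$theta_search, cf$theta_halfwidth,
                         cf$theta_flank_low, cf$theta_flank_high)
        rp <- refractoryPeriod(acg, cf$refractory_smooth, cf$asymptote_win)
        call <- classifyFiringPattern(bi, ti, rp,
                                      cf$reg_refractory_min, cf$sb_min)
        data.frame(unit_id = unitId(tr), n_spikes_used = acg@nSpikesUsed,
                   burst_index = bi, theta_index = ti,
                   refractory_ms = rp * 1000, label = call$label,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
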