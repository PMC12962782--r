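# Peri-event time histograms, event-related response detection, optotagging
# and PCA + hierarchical-clustering functional cell typing.

#' Compute a peri-event time histogram of spike counts
#'
#' Spikes are counted in half-open bins per trial, aligned to each event.
#' Events whose window reaches outside the recording span are dropped (with a
#' message stating the count).
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param events an \linkS4class{EventSeries} with at least one usable event.
#' @param window \code{c(pre, post)} window around each event (s),
#'   \code{pre < 0 <= post}.
#' @param binWidth bin width (s); must divide the window length.
#' @return A \linkS4class{PETH}.
#' @export
computePETH <- function(train, events, window = c(-0.5, 0.5),
                        binWidth = 0.010) {
    stopifnot(is(train, "SpikeTrain"), is(events, "EventSeries"))
    span <- window[2L] - window[1L]
    nbins <- round(span / binWidth)
    if (abs(nbins * binWidth - span) > 1e-9)
        stop("binWidth must divide the window length")
    nbins <- as.integer(nbins)
    ev <- eventTimes(events)
    ok <- ev + window[1L] >= train@tStart & ev + window[2L] <= train@tEnd
    if (sum(!ok))
        message(sum(!ok), " event(s) too close to the recording edges dropped")
    ev <- ev[ok]
    if (!length(ev)) stop("no usable events for PETH")
    times <- spikeTimes(train)
    counts <- t(vapply(ev, function(e)
        binCountsHalfOpen(times, e + window[1L], binWidth, nbins),
        integer(nbins)))
    counts <- matrix(as.numeric(counts), nrow = length(ev))
    new("PETH",
        binCenters = window[1L] + (seq_len(nbins) - 0.5) * binWidth,
        rate = colMeans(counts) / binWidth, perTrialCounts = counts,
        binWidth = binWidth, triggerLabel = events@label)
}

# Gaussian smoothing (sd in bins, kernel truncated at 3 sd, shrink-to-valid
# edge renormalization); used for extremum/window finding only, never for the
# count-based rank tests
.gaussSmooth <- function(x, sdBins) {
    if (sdBins <= 0) return(x)
    half <- max(1L, as.integer(ceiling(3 * sdBins)))
    kern <- stats::dnorm(-half:half, sd = sdBins)
    n <- length(x)
    num <- stats::convolve(x, rev(kern), type = "open")[(half + 1L):(half + n)]
    den <- stats::convolve(rep(1, n), rev(kern),
                           type = "open")[(half + 1L):(half + n)]
    num / den
}

# contiguous half-height window around an extremum: indices (into `idx`) of
# the run of bins around position `pk` staying beyond `level` in direction
# `sign` (+1 activation, -1 inhibition)
.halfHeightRun <- function(vals, pk, level, sign) {
    beyond <- sign * vals >= sign * level
    lo <- pk
    while (lo > 1L && beyond[lo - 1L]) lo <- lo - 1L
    hi <- pk
    while (hi < length(vals) && beyond[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
}

# one direction of the detection procedure; returns NULL if the extremum does
# not exceed (resp. fall below) the baseline
.detectOneDirection <- function(peth, searchIdx, baseIdx, baselineRate, sign,
                                smoothSd = 0) {
    vals <- pethRate(peth)
    if (smoothSd > 0) vals <- .gaussSmooth(vals, smoothSd / peth@binWidth)
    searchVals <- vals[searchIdx]
    pkRel <- if (sign > 0) which.max(searchVals) else which.min(searchVals)
    extremum <- searchVals[pkRel]
    if (sign * (extremum - baselineRate) <= 0) return(NULL)
    level <- baselineRate + 0.5 * (extremum - baselineRate)
    run <- .halfHeightRun(searchVals, pkRel, level, sign)
    respIdx <- searchIdx[run[1L]:run[2L]]
    # matched window around the baseline-period local extremum of same sign
    baseVals <- vals[baseIdx]
    bpkRel <- if (sign > 0) which.max(baseVals) else which.min(baseVals)
    len <- length(respIdx)
    half <- (len - 1L) %/% 2L
    blo <- max(1L, bpkRel - half)
    bhi <- min(length(baseIdx), blo + len - 1L)
    blo <- max(1L, bhi - len + 1L)
    matchIdx <- baseIdx[blo:bhi]
    # rank test on raw per-trial counts (smoothing is window-finding only)
    respCounts <- rowSums(pethCounts(peth)[, respIdx, drop = FALSE])
    baseCounts <- rowSums(pethCounts(peth)[, matchIdx, drop = FALSE])
    p <- stats::wilcox.test(respCounts, baseCounts,
                            alternative = if (sign > 0) "greater" else "less",
                            exact = FALSE, correct = TRUE)$p.value
    bw <- peth@binWidth
    list(extremum_rate = extremum,
         window = c(binCenters(peth)[respIdx[1L]] - bw / 2,
                    binCenters(peth)[respIdx[length(respIdx)]] + bw / 2),
         p = max(p, .Machine$double.xmin))
}

#' Detect event-related activation and inhibition in a PETH
#'
#' Implements the full detection procedure in both directions: (1) the PETH
#' maximum (minimum) within the post-event search window, (2) baseline = mean
#' rate over the pre-event baseline window, (3) response window = contiguous
#' bins around the extremum beyond the half-distance between extremum and
#' baseline (a crossing that never returns is cut at the search-window end),
#' (4) a matched window of equal length around the baseline-period local
#' extremum of the same sign, (5) per-trial spike counts in the two windows
#' compared by a one-sided Mann-Whitney U test (asymmetric null per
#' direction), (6) significance at \code{p < alpha}; if both directions are
#' significant the one whose window starts earlier is the primary response.
#'
#' Extremum location and half-height crossings are found on a Gaussian-
#' smoothed copy of the PETH (\code{smoothSd}) so that single-bin count noise
#' does not truncate the response window; the rank test itself always uses
#' raw per-trial counts.
#'
#' @param peth a \linkS4class{PETH} spanning at least
#'   \code{[-baselineWin, searchWin]}.
#' @param searchWin post-event search window length (s).
#' @param baselineWin pre-event baseline window length (s).
#' @param alpha significance level (default 0.01, keeping false positives low).
#' @param smoothSd Gaussian SD (s) for window finding only; 0 disables.
#' @return A list: \code{direction} and \code{primary} ("activation",
#'   "inhibition" or "none"), \code{window} (s, of the primary response),
#'   \code{peak_or_trough_rate}, \code{baseline_rate} (Hz), \code{p_value}
#'   (of the primary direction), and per-direction details
#'   \code{p_activation}, \code{p_inhibition}, \code{window_activation},
#'   \code{window_inhibition}.
#' @export
detectEventResponse <- function(peth, searchWin = 0.5, baselineWin = 0.5,
                                alpha = 0.01, smoothSd = 0.02) {
    stopifnot(is(peth, "PETH"))
    bc <- binCenters(peth)
    searchIdx <- which(bc > 0 & bc <= searchWin)
    baseIdx <- which(bc >= -baselineWin & bc < 0)
    if (!length(searchIdx) || !length(baseIdx))
        stop("PETH must span [-baselineWin, searchWin]")
    baselineRate <- mean(pethRate(peth)[baseIdx])
    act <- .detectOneDirection(peth, searchIdx, baseIdx, baselineRate, +1,
                               smoothSd)
    inh <- .detectOneDirection(peth, searchIdx, baseIdx, baselineRate, -1,
                               smoothSd)
    pAct <- if (is.null(act)) 1 else act$p
    pInh <- if (is.null(inh)) 1 else inh$p
    sigAct <- pAct < alpha
    sigInh <- pInh < alpha
    primary <- if (sigAct && sigInh) {
        if (act$window[1L] <= inh$window[1L]) "activation" else "inhibition"
    } else if (sigAct) "activation" else if (sigInh) "inhibition" else "none"
    pick <- switch(primary, activation = act, inhibition = inh, NULL)
    list(direction = primary, primary = primary,
         window = if (is.null(pick)) c(NA_real_, NA_real_) else pick$window,
         peak_or_trough_rate = if (is.null(pick)) NA_real_
                               else pick$extremum_rate,
         baseline_rate = baselineRate,
         p_value = if (is.null(pick)) min(pAct, pInh, 1) else pick$p,
         p_activation = pAct, p_inhibition = pInh,
         window_activation = if (is.null(act)) c(NA_real_, NA_real_)
                             else act$window,
         window_inhibition = if (is.null(inh)) c(NA_real_, NA_real_)
                             else inh$window)
}

#' Optogenetic-tagging classification of a unit
#'
#' A unit is tagged as opsin-expressing if (a) its mean firing rate during the
#' laser pulses (from \code{latencyMax} after onset to pulse offset) stays at
#' or below \code{maxRate}, and (b) its suppression onset latency is below
#' \code{latencyMax}, where the latency is the first time the pulse-aligned
#' PETH (1 ms bins, 5-point smoothed) falls below half the pre-pulse baseline
#' rate. The baseline is the mean rate over \code{baselinePre} seconds before
#' pulse onset.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param laser an \linkS4class{EventSeries} of pulse onsets (>= 10 pulses).
#' @param pulseDur laser pulse duration (s).
#' @param latencyMax maximum suppression latency (s) for tagging.
#' @param maxRate maximum in-pulse rate (Hz) for tagging.
#' @param baselinePre pre-pulse baseline window length (s).
#' @return A list: \code{tagged} (logical), \code{latency_s},
#'   \code{in_pulse_rate}, \code{baseline_rate}, \code{flag} ("" or
#'   "silent unit").
#' @export
optotag <- function(train, laser, pulseDur = 0.2, latencyMax = 0.010,
                    maxRate = 0.5, baselinePre = 1.0) {
    stopifnot(is(train, "SpikeTrain"), is(laser, "EventSeries"))
    if (length(eventTimes(laser)) < 10L) stop("need at least 10 laser pulses")
    peth <- computePETH(train, laser, window = c(-baselinePre, pulseDur),
                        binWidth = 0.001)
    bc <- binCenters(peth)
    baselineRate <- mean(pethRate(peth)[bc < 0])
    if (baselineRate == 0)
        return(list(tagged = FALSE, latency_s = NA_real_,
                    in_pulse_rate = 0, baseline_rate = 0,
                    flag = "silent unit"))
    inIdx <- bc >= latencyMax & bc < pulseDur
    inPulseRate <- mean(pethRate(peth)[inIdx])
    sm <- movingAverage(pethRate(peth), 5L)
    postIdx <- which(bc >= 0)
    below <- which(sm[postIdx] < 0.5 * baselineRate)
    latency <- if (length(below)) bc[postIdx[below[1L]]] - peth@binWidth / 2
               else NA_real_
    tagged <- inPulseRate <= maxRate && !is.na(latency) && latency < latencyMax
    list(tagged = tagged, latency_s = latency, in_pulse_rate = inPulseRate,
         baseline_rate = baselineRate, flag = "")
}

#' Functional cell typing by PCA and hierarchical clustering
#'
#' Projects each unit's z-scored reward and punishment response vectors onto
#' the first three principal components and cuts a Ward-linkage hierarchical
#' clustering of the scores at \code{nClusters} (default 4) clusters. The
#' cluster whose mean response is positive after both rewards and punishments
#' is labeled "putative-cholinergic" (the only functional class activated by
#' both); remaining clusters get heuristic "glutamatergic-like" (punishment-
#' but not reward-activated) or "GABAergic-like" labels.
#'
#' @param responses numeric matrix, one row per unit: concatenated z-scored
#'   reward and punishment PETHs.
#' @param rewardCols,punishCols column indices of the post-reward and
#'   post-punishment response bins.
#' @param nClusters number of clusters (default 4).
#' @param linkage hclust linkage method (default "ward.D2", Euclidean
#'   distance).
#' @return data.frame with one row per unit: \code{pc1, pc2, pc3, cluster,
#'   putative_class}.
#' @export
clusterCellTypes <- function(responses, rewardCols, punishCols,
                             nClusters = 4L, linkage = "ward.D2") {
    responses <- as.matrix(responses)
    if (nrow(responses) < nClusters)
        stop("need at least ", nClusters, " units")
    if (any(!is.finite(responses))) stop("responses must be finite")
    pca <- stats::prcomp(responses, center = TRUE, scale. = FALSE)
    if (ncol(pca$x) < 3L || pca$sdev[3L] < 1e-12)
        stop("response covariance has rank < 3; provide more units or bins")
    scores <- pca$x[, 1:3, drop = FALSE]
    hc <- stats::hclust(stats::dist(scores), method = linkage)
    cluster <- stats::cutree(hc, k = nClusters)
    klass <- character(nClusters)
    for (k in seq_len(nClusters)) {
        m <- colMeans(responses[cluster == k, , drop = FALSE])
        rew <- mean(m[rewardCols])
        pun <- mean(m[punishCols])
        klass[k] <- if (rew > 0 && pun > 0) "putative-cholinergic"
                    else if (pun > 0) "glutamatergic-like"
                    else "GABAergic-like"
    }
    data.frame(pc1 = scores[, 1L], pc2 = scores[, 2L], pc3 = scores[, 3L],
               cluster = as.integer(cluster),
               putative_class = klass[cluster],
               stringsAsFactors = FALSE)
}
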