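# Cross-signal analyses: normalized cross-correlation with common-mode
# rejection, session averaging, pupil diameter from tracked landmarks,
# calcium-peak-triggered averaging, and plug-in transfer entropy on
# discretized series.

#' Normalized cross-correlation between two calcium signals
#'
#' Computes the raw cross-covariance of the (by default mean-centered)
#' signals at every lag within \code{+/-maxLag} and normalizes by
#' \eqn{\sqrt{R_{xx}(0) R_{yy}(0)}} (the zero-lag autocorrelations, i.e. the
#' signal magnitudes). The central \code{+/-exclude} window is masked as
#' common-mode before peak finding. Positive lag means the second signal lags
#' the first (x leads y).
#'
#' @param x,y \linkS4class{CalciumSignal} objects with identical sampling
#'   rate and length.
#' @param maxLag largest lag (s).
#' @param exclude half-width (s) of the central common-mode exclusion window.
#' @param center mean-center the signals first? (Photometry offsets are
#'   arbitrary; the choice is recorded implicitly by the argument.)
#' @return A \linkS4class{CrossCorrelogram}.
#' @export
normalizedXCorr <- function(x, y, maxLag = 10, exclude = 0.020,
                            center = TRUE) {
    stopifnot(is(x, "CalciumSignal"), is(y, "CalciumSignal"))
    if (abs(samplingRate(x) - samplingRate(y)) > 1e-9)
        stop("signals must share a sampling rate")
    xv <- dff(x)
    yv <- dff(y)
    if (length(xv) != length(yv)) stop("signals must have equal length")
    fs <- samplingRate(x)
    K <- as.integer(round(maxLag * fs))
    if (length(xv) < 2L * K)
        stop("signals must be at least twice the maximum lag long")
    if (center) {
        xv <- xv - mean(xv)
        yv <- yv - mean(yv)
    }
    if (sum(xv^2) == 0 || sum(yv^2) == 0) stop("zero-variance signal")
    # FFT cross-correlation: cc[k] = sum_t x[t] y[t+k], k = -K..K
    n <- length(xv)
    nf <- stats::nextn(n + K, 2)
    X <- stats::fft(c(xv, numeric(nf - n)))
    Y <- stats::fft(c(yv, numeric(nf - n)))
    cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nf
    pos <- cc[1:(K + 1L)]            # k = 0..K
    neg <- cc[(nf - K + 1L):nf]      # k = -K..-1
    vals <- c(neg, pos) / sqrt(sum(xv^2) * sum(yv^2))
    lags <- (-K:K) / fs
    mask <- if (exclude > 0) abs(lags) <= exclude + 1e-12
            else rep(FALSE, length(lags))
    pk <- which(vals == max(vals[!mask]) & !mask)[1L]
    new("CrossCorrelogram", lags = lags, values = vals,
        excludedMask = mask, peakValue = vals[pk], peakLag = lags[pk],
        fs = fs)
}

#' Average cross-correlograms across sessions
#'
#' Pointwise mean over sessions honoring the exclusion masks (a lag masked in
#' any session is masked in the average), plus a per-session table of maximal
#' correlation and its lag.
#'
#' @param ccrs list of \linkS4class{CrossCorrelogram} objects on identical
#'   lag grids.
#' @param ids optional session/animal labels for the table.
#' @return A list: \code{average} (\linkS4class{CrossCorrelogram}) and
#'   \code{perSession} (data.frame \code{id, peak_value, peak_lag_s}).
#' @export
averageCCR <- function(ccrs, ids = NULL) {
    stopifnot(length(ccrs) >= 1L)
    lag0 <- ccrs[[1L]]@lags
    for (cc in ccrs)
        if (length(cc@lags) != length(lag0) ||
            max(abs(cc@lags - lag0)) > 1e-12)
            stop("inconsistent lag grids")
    vals <- rowMeans(vapply(ccrs, function(cc) cc@values,
                            numeric(length(lag0))))
    mask <- Reduce(`|`, lapply(ccrs, function(cc) cc@excludedMask))
    pk <- which(vals == max(vals[!mask]) & !mask)[1L]
    if (is.null(ids)) ids <- paste0("session", seq_along(ccrs))
    tab <- data.frame(id = ids,
                      peak_value = vapply(ccrs, function(cc) cc@peakValue,
                                          numeric(1L)),
                      peak_lag_s = vapply(ccrs, function(cc) cc@peakLag,
                                          numeric(1L)),
                      stringsAsFactors = FALSE)
    avg <- new("CrossCorrelogram", lags = lag0, values = vals,
               excludedMask = mask, peakValue = vals[pk],
               peakLag = lag0[pk], fs = ccrs[[1L]]@fs)
    list(average = avg, perSession = tab)
}

#' Pupil diameter from tracked landmarks
#'
#' Diameter per frame = mean Euclidean distance of the three diagonal
#' pupil-edge point pairs. Frames with a missing landmark are dropped and
#' linearly interpolated over (with a message); optionally the series is
#' interpolated onto a target time grid (e.g. the photometry grid).
#'
#' @param landmarks a \linkS4class{PupilLandmarks}.
#' @param targetTimes optional time grid (s) to interpolate onto.
#' @return A list: \code{t} (time grid), \code{diameter} (pixels).
#' @export
pupilDiameter <- function(landmarks, targetTimes = NULL) {
    stopifnot(is(landmarks, "PupilLandmarks"))
    co <- landmarks@coords
    d <- unname(sqrt((co[, "P1_x"] - co[, "P1p_x"])^2 +
               (co[, "P1_y"] - co[, "P1p_y"])^2) +
          sqrt((co[, "P2_x"] - co[, "P2p_x"])^2 +
               (co[, "P2_y"] - co[, "P2p_y"])^2) +
          sqrt((co[, "P3_x"] - co[, "P3p_x"])^2 +
               (co[, "P3_y"] - co[, "P3p_y"])^2)) / 3
    ok <- is.finite(d)
    if (!any(ok)) stop("no frame has complete pupil landmarks")
    if (any(!ok)) {
        message(sum(!ok), " frame(s) with missing landmarks interpolated over")
        d <- stats::approx(landmarks@t[ok], d[ok], xout = landmarks@t,
                           rule = 2)$y
    }
    if (!is.null(targetTimes))
        return(list(t = targetTimes,
                    diameter = stats::approx(landmarks@t, d,
                                             xout = targetTimes, rule = 2)$y))
    list(t = landmarks@t, diameter = d)
}

#' Average a target series around calcium transient peaks
#'
#' Detects local maxima of the z-scored calcium signal above a threshold (SD
#' units) with a minimum separation, then averages the target series in a
#' window around each detected peak (activity-triggered average, e.g. of
#' pupil diameter).
#'
#' @param signal a \linkS4class{CalciumSignal} (trigger source).
#' @param target numeric series on the same grid as \code{signal}.
#' @param thresholdSd peak threshold in SD units of the z-scored signal.
#' @param minSep minimum peak separation (s).
#' @param window \code{c(pre, post)} averaging window (s) around each peak.
#' @return A list: \code{lags} (s), \code{average}, \code{n_peaks},
#'   \code{peak_times} (s).
#' @export
peakTriggeredAverage <- function(signal, target, thresholdSd = 2, minSep = 1,
                                 window = c(-2, 4)) {
    stopifnot(is(signal, "CalciumSignal"))
    x <- dff(signal)
    if (length(target) != length(x))
        stop("target must be on the signal's grid")
    fs <- samplingRate(signal)
    z <- (x - mean(x)) / stats::sd(x)
    n <- length(z)
    cand <- which(z > thresholdSd &
                  z >= c(-Inf, z[-n]) & z >= c(z[-1L], -Inf))
    if (!length(cand))
        stop("zero calcium peaks detected; lower thresholdSd")
    # enforce separation greedily by descending amplitude
    cand <- cand[order(z[cand], decreasing = TRUE)]
    sepSamp <- minSep * fs
    peaks <- integer()
    for (i in cand)
        if (!length(peaks) || all(abs(peaks - i) >= sepSamp))
            peaks <- c(peaks, i)
    peaks <- sort(peaks)
    iPre <- as.integer(round(window[1L] * fs))
    iPost <- as.integer(round(window[2L] * fs))
    usable <- peaks[peaks + iPre >= 1L & peaks + iPost <= n]
    if (!length(usable)) stop("no peak has a full averaging window")
    segs <- vapply(usable, function(i) target[(i + iPre):(i + iPost)],
                   numeric(iPost - iPre + 1L))
    list(lags = (iPre:iPost) / fs, average = rowMeans(segs),
         n_peaks = length(usable),
         peak_times = timeGrid(signal)[usable])
}

# block-average downsampling by integer factor (trailing remainder dropped)
blockAverage <- function(x, factor) {
    if (factor <= 1L) return(x)
    n <- (length(x) %/% factor) * factor
    colMeans(matrix(x[seq_len(n)], nrow = factor))
}

# plug-in counts lookup: count of each element's key within the vector
.keyCounts <- function(key) {
    f <- factor(key)
    tabulate(f)[as.integer(f)]
}

#' Transfer entropy between two discretized time series
#'
#' Both series are z-scored, optionally block-average downsampled, and
#' discretized into \code{nBins} equal-width bins spanning their own
#' [min, max]. The plug-in transfer entropy
#' \deqn{TE(x \to y) = \sum p(y_t, y_{past}, x_{past})
#'   \log_2 \frac{p(y_t | y_{past}, x_{past})}{p(y_t | y_{past})}}
#' is computed with empirical probabilities in both directions, with a past
#' of \code{historyLen} samples. Note that the plug-in estimator is biased
#' upward at small sample counts relative to the number of occupied bins;
#' with many bins treat the values comparatively (between directions), not as
#' absolute information rates.
#'
#' @param x,y numeric series of equal length (or
#'   \linkS4class{CalciumSignal}s).
#' @param nBins number of discretization bins (default 200).
#' @param historyLen past length in samples (default 1).
#' @param downsampleHz target rate for block-average downsampling; requires
#'   \code{fs}. NULL disables.
#' @param fs sampling rate of the inputs (Hz); taken from the signals when
#'   they are \linkS4class{CalciumSignal}s.
#' @return A list: \code{te_xy}, \code{te_yx} (bits), \code{n_bins},
#'   \code{history_len}, \code{n_samples}.
#' @export
transferEntropy <- function(x, y, nBins = 200L, historyLen = 1L,
                            downsampleHz = NULL, fs = NULL) {
    if (is(x, "CalciumSignal")) { fs <- samplingRate(x); x <- dff(x) }
    if (is(y, "CalciumSignal")) y <- dff(y)
    if (length(x) != length(y)) stop("series must have equal length")
    if (!is.null(downsampleHz)) {
        if (is.null(fs)) stop("downsampling requires fs")
        fac <- max(1L, as.integer(round(fs / downsampleHz)))
        x <- blockAverage(x, fac)
        y <- blockAverage(y, fac)
    }
    if (length(x) < 100L * historyLen)
        stop("need at least 100 x historyLen samples after downsampling")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero entropy source (constant series)")
    disc <- function(v) {
        v <- (v - mean(v)) / stats::sd(v)
        b <- floor((v - min(v)) / (max(v) - min(v)) * nBins) + 1L
        pmin(b, as.integer(nBins))
    }
    dx <- disc(x)
    dy <- disc(y)
    pastKey <- function(d, L) {
        n <- length(d)
        idx <- seq_len(n - L)
        key <- as.character(d[idx + L - 1L])
        if (L > 1L) for (j in (L - 2L):0L)
            key <- paste(key, d[idx + j], sep = ".")
        key
    }
    teDir <- function(src, tgt) {
        L <- as.integer(historyLen)
        n <- length(tgt)
        yt <- tgt[(L + 1L):n]
        yp <- pastKey(tgt, L)
        xp <- pastKey(src, L)
        cFull <- .keyCounts(paste(yt, yp, xp, sep = "|"))
        cYpXp <- .keyCounts(paste(yp, xp, sep = "|"))
        cYtYp <- .keyCounts(paste(yt, yp, sep = "|"))
        cYp <- .keyCounts(yp)
        max(0, mean(log2((cFull * cYp) / (cYpXp * cYtYp))))
    }
    list(te_xy = teDir(dx, dy), te_yx = teDir(dy, dx),
         n_bins = as.integer(nBins), history_len = as.integer(historyLen),
         n_samples = length(dx))
}
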