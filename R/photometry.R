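# Fiber-photometry preprocessing (isosbestic dF/F correction) and trial-level
# response quantification.
#
# Chain order: (1) zero-phase low-pass of both channels at 20 Hz, (2) OLS fit
# of the 405 nm isosbestic channel to the 465 nm calcium channel (gain +
# offset over the whole session), (3) dF/F = (f465 - f405_fitted) /
# f405_fitted * 100, (4) zero-phase 0.2 Hz high-pass to remove slow baseline
# decay. Trial traces are then z-scored to a pre-cue (or ITI) baseline.

#' TrialPETH: trial-aligned, z-scored signal matrix
#'
#' @slot binCenters numeric sample times relative to the trigger (s).
#' @slot zMatrix numeric matrix (trials x samples) of z-scored traces.
#' @slot meanTrace numeric column mean of \code{zMatrix}.
#' @slot fs numeric sampling rate (Hz).
#' @slot triggerLabel character trigger label.
#' @exportClass TrialPETH
setClass("TrialPETH",
    representation(binCenters = "numeric", zMatrix = "matrix",
                   meanTrace = "numeric", fs = "numeric",
                   triggerLabel = "character"))

setValidity("TrialPETH", function(object) {
    msg <- character()
    if (ncol(object@zMatrix) != length(object@binCenters))
        msg <- c(msg, "zMatrix must have one column per sample")
    if (length(object@meanTrace) != length(object@binCenters))
        msg <- c(msg, "meanTrace must have one value per sample")
    if (nrow(object@zMatrix) > 0L &&
        max(abs(colMeans(object@zMatrix) - object@meanTrace)) > 1e-9)
        msg <- c(msg, "meanTrace must equal colMeans(zMatrix)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TrialPETH", function(object) {
    cat("TrialPETH ('", object@triggerLabel, "'): ", nrow(object@zMatrix),
        " trials x ", length(object@binCenters), " samples @ ",
        format(object@fs), " Hz\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("binCenters", "TrialPETH", function(object) object@binCenters)

#' @rdname accessors
#' @export
setGeneric("meanTrace", function(object) standardGeneric("meanTrace"))
#' @rdname accessors
#' @export
setMethod("meanTrace", "TrialPETH", function(object) object@meanTrace)

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setMethod("zMatrix", "TrialPETH", function(object) object@zMatrix)

.zeroPhaseFilter <- function(x, fs, cutoffHz, order, type) {
    bf <- signal::butter(order, cutoffHz / (fs / 2), type = type)
    signal::filtfilt(bf, x)
}

#' Preprocess a photometry session into a dF/F calcium signal
#'
#' Runs the full correction chain: zero-phase Butterworth low-pass of both
#' channels, least-squares fit of the isosbestic 405 nm channel to the 465 nm
#' channel (gain + offset over the whole session; gain-only when the 405 nm
#' channel is essentially constant), \code{dF/F = (f465 - f405fit)/f405fit *
#' 100} to cancel motion artifacts and autofluorescence, and a zero-phase
#' high-pass to remove slow bleaching decay. All parameters are recorded in
#' the result's provenance.
#'
#' @param session a \linkS4class{PhotometrySession}, at least 10 s long.
#' @param lowpassHz low-pass cutoff (Hz).
#' @param highpassHz high-pass cutoff (Hz) applied to dF/F.
#' @param lowpassOrder,highpassOrder Butterworth orders.
#' @return A \linkS4class{CalciumSignal} (dF/F in percent).
#' @export
preprocessDFF <- function(session, lowpassHz = 20, highpassHz = 0.2,
                          lowpassOrder = 4L, highpassOrder = 2L) {
    stopifnot(is(session, "PhotometrySession"))
    fs <- samplingRate(session)
    if (diff(range(timeGrid(session))) < 10)
        stop("session must be at least 10 s long")
    if (fs < 2 * lowpassHz)
        stop("sampling rate must exceed twice the low-pass cutoff")
    if (all(session@f405 == 0)) stop("isosbestic channel is identically zero")
    f465 <- .zeroPhaseFilter(session@f465, fs, lowpassHz, lowpassOrder, "low")
    f405 <- .zeroPhaseFilter(session@f405, fs, lowpassHz, lowpassOrder, "low")
    if (stats::var(f405) < 1e-12 * mean(f405)^2) {
        # constant reference: gain-only fit (intercept would be collinear)
        gain <- sum(f465 * f405) / sum(f405^2)
        fitted <- gain * f405
        coefs <- c(intercept = 0, gain = gain)
    } else {
        fit <- stats::lm.fit(cbind(1, f405), f465)
        fitted <- fit$fitted.values
        coefs <- c(intercept = fit$coefficients[1L],
                   gain = fit$coefficients[2L])
    }
    if (any(fitted <= 0))
        stop("isosbestic fit nonpositive; check channel scaling or bleaching")
    dffPct <- (f465 - fitted) / fitted * 100
    dffPct <- .zeroPhaseFilter(dffPct, fs, highpassHz, highpassOrder, "high")
    CalciumSignal(timeGrid(session), dffPct, fs,
                  provenance = list(lowpass_hz = lowpassHz,
                                    highpass_hz = highpassHz,
                                    lowpass_order = lowpassOrder,
                                    highpass_order = highpassOrder,
                                    isosbestic_fit = coefs))
}

#' Trial-align and baseline z-score a calcium signal
#'
#' Extracts a window around each trigger and z-scores it either per trial
#' (mean/SD of that trial's pre-trigger baseline) or per session (mean/SD
#' pooled over all trials' inter-trial baseline windows). Trials whose
#' baseline SD is zero are excluded with a warning (per-trial mode).
#'
#' @param signal a \linkS4class{CalciumSignal}.
#' @param triggers trigger times: numeric vector, \linkS4class{EventSeries},
#'   or \linkS4class{TrialTable} (cue times).
#' @param window \code{c(pre, post)} extraction window around the trigger (s).
#' @param baselinePre baseline length (s) before the trigger.
#' @param mode "per-trial" or "session".
#' @param label trigger label stored in the result.
#' @return A \linkS4class{TrialPETH}.
#' @export
zscoreToBaseline <- function(signal, triggers, window = c(-2, 4),
                             baselinePre = 2, mode = c("per-trial", "session"),
                             label = "trigger") {
    stopifnot(is(signal, "CalciumSignal"))
    mode <- match.arg(mode)
    if (is(triggers, "EventSeries")) {
        label <- triggers@label
        triggers <- eventTimes(triggers)
    } else if (is(triggers, "TrialTable")) {
        triggers <- trials(triggers)$cue_time
    }
    fs <- samplingRate(signal)
    t <- timeGrid(signal)
    x <- dff(signal)
    iPre <- as.integer(round(window[1L] * fs))
    iPost <- as.integer(round(window[2L] * fs))
    iBase <- as.integer(round(baselinePre * fs))
    rel <- (iPre:iPost) / fs
    rows <- list()
    kept <- numeric()
    for (tt in triggers) {
        i0 <- which.min(abs(t - tt))
        lo <- i0 + iPre
        hi <- i0 + iPost
        b0 <- i0 - iBase
        if (lo < 1L || hi > length(x) || b0 < 1L) {
            warning("trigger at ", signif(tt, 6), " s outside recording; dropped")
            next
        }
        seg <- x[lo:hi]
        if (mode == "per-trial") {
            base <- x[b0:(i0 - 1L)]
            if (stats::sd(base) == 0) {
                warning("trigger at ", signif(tt, 6),
                        " s: baseline SD is zero; trial excluded")
                next
            }
            seg <- (seg - mean(base)) / stats::sd(base)
        }
        rows[[length(rows) + 1L]] <- seg
        kept <- c(kept, tt)
    }
    if (!length(rows)) stop("no usable trials")
    z <- do.call(rbind, rows)
    if (mode == "session") {
        baseIdx <- unlist(lapply(kept, function(tt) {
            i0 <- which.min(abs(t - tt))
            (i0 - iBase):(i0 - 1L)
        }))
        mu <- mean(x[baseIdx])
        sdv <- stats::sd(x[baseIdx])
        if (sdv == 0) stop("session baseline SD is zero")
        z <- (z - mu) / sdv
    }
    new("TrialPETH", binCenters = rel, zMatrix = z, meanTrace = colMeans(z),
        fs = fs, triggerLabel = label)
}

#' Response metrics of a trial-averaged calcium trace
#'
#' On the mean trace: peak = maximum within the post-trigger response window,
#' latency = its time, duration = width between the half-maximum crossings
#' searched outward from the peak (the trace edge when a side never crosses),
#' and AUC = sum of the samples between the crossings divided by the sampling
#' rate. The half-maximum reference level is 0 (the baseline is zero by
#' construction after z-scoring), so crossings are at 0.5 * peak.
#'
#' @param peth a \linkS4class{TrialPETH} spanning at least
#'   \code{[-baselineWin, responseWin]}.
#' @param responseWin response window length (s) after the trigger.
#' @param baselineWin baseline window length (s) before the trigger (span
#'   check only).
#' @return A list: \code{peak} (z), \code{latency_s}, \code{duration_s},
#'   \code{auc} (z·s), \code{flag} ("" or "no positive response").
#' @export
responseMetrics <- function(peth, responseWin = 1, baselineWin = 2) {
    stopifnot(is(peth, "TrialPETH"))
    tt <- binCenters(peth)
    if (tt[1L] > -baselineWin || tt[length(tt)] < responseWin)
        stop("TrialPETH must span [-baselineWin, responseWin]")
    m <- meanTrace(peth)
    sel <- which(tt > 0 & tt <= responseWin)
    pk <- sel[which.max(m[sel])]
    peak <- m[pk]
    latency <- tt[pk]
    flag <- if (peak <= 0) "no positive response" else ""
    level <- 0.5 * peak
    # outward search for half-maximum crossings, interpolated between samples
    lo <- pk
    while (lo > 1L && m[lo - 1L] >= level) lo <- lo - 1L
    hi <- pk
    while (hi < length(m) && m[hi + 1L] >= level) hi <- hi + 1L
    tLeft <- if (lo == 1L) tt[1L] else
        tt[lo - 1L] + (tt[lo] - tt[lo - 1L]) *
            (level - m[lo - 1L]) / (m[lo] - m[lo - 1L])
    tRight <- if (hi == length(m)) tt[length(m)] else
        tt[hi] + (tt[hi + 1L] - tt[hi]) *
            (level - m[hi]) / (m[hi + 1L] - m[hi])
    inWin <- tt >= tLeft & tt <= tRight
    list(peak = peak, latency_s = latency, duration_s = tRight - tLeft,
         auc = sum(m[inWin]) / peth@fs, flag = flag)
}

#' Trialwise response test against baseline fluctuations
#'
#' Per trial, takes the maximum of the z-scored trace in the response window
#' and the maximum in the pre-trigger baseline window, and tests response >
#' baseline with a one-sided paired Wilcoxon signed-rank test. Latency and
#' duration quantification is gated on significance (mirrored by the
#' \code{quantify} flag).
#'
#' @param peth a \linkS4class{TrialPETH} with at least 10 trials.
#' @param respWin response window \code{c(lo, hi)} (s).
#' @param baseWin baseline window \code{c(lo, hi)} (s).
#' @param alpha significance level.
#' @return A list: \code{significant}, \code{p}, \code{n_trials},
#'   \code{quantify} (same as significant).
#' @export
trialwiseCueTest <- function(peth, respWin = c(0, 0.5), baseWin = c(-0.5, 0),
                             alpha = 0.05) {
    stopifnot(is(peth, "TrialPETH"))
    z <- zMatrix(peth)
    if (nrow(z) < 10L) stop("need at least 10 trials")
    tt <- binCenters(peth)
    ri <- tt >= respWin[1L] & tt < respWin[2L]
    bi <- tt >= baseWin[1L] & tt < baseWin[2L]
    x <- apply(z[, ri, drop = FALSE], 1L, max)
    y <- apply(z[, bi, drop = FALSE], 1L, max)
    d <- x - y
    p <- if (all(d == 0)) 1 else
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "greater")$p.value)
    list(significant = p < alpha, p = p, n_trials = nrow(z),
         quantify = p < alpha)
}
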