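#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core data containers. All timestamps are seconds (double); all intervals in
# the public API are half-open [a, b) so that bins tile without double
# counting.
# ---------------------------------------------------------------------------

#' SpikeTrain: ordered spike timestamps of one unit
#'
#' Holds the spike times of a single sorted unit together with the recording
#' span. Times are seconds, strictly increasing, and must fall inside
#' \code{[tStart, tEnd]}.
#'
#' @slot unitId character label of the unit.
#' @slot times numeric vector of spike times (s), strictly increasing.
#' @slot tStart,tEnd numeric recording span (s), \code{tEnd > tStart}.
#'
#' @exportClass SpikeTrain
setClass("SpikeTrain",
    representation(unitId = "character", times = "numeric",
                   tStart = "numeric", tEnd = "numeric"))

setValidity("SpikeTrain", function(object) {
    msg <- character()
    if (length(object@unitId) != 1L) msg <- c(msg, "unitId must be a single string")
    if (length(object@tStart) != 1L || length(object@tEnd) != 1L ||
        !is.finite(object@tStart) || !is.finite(object@tEnd))
        msg <- c(msg, "tStart/tEnd must be single finite numbers")
    else {
        if (object@tEnd <= object@tStart) msg <- c(msg, "tEnd must exceed tStart")
        if (length(object@times)) {
            if (any(!is.finite(object@times))) msg <- c(msg, "spike times must be finite")
            else {
                if (any(diff(object@times) <= 0))
                    msg <- c(msg, "spike times must be strictly increasing")
                if (object@times[1L] < object@tStart ||
                    object@times[length(object@times)] > object@tEnd)
                    msg <- c(msg, "spike times must lie within [tStart, tEnd]")
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times numeric spike times (s), strictly increasing.
#' @param tStart,tEnd recording span (s).
#' @param unitId unit label.
#' @return A \linkS4class{SpikeTrain} object.
#' @examples
#' SpikeTrain(c(0.1, 0.2, 0.5), tStart = 0, tEnd = 1)
#' @export
SpikeTrain <- function(times, tStart, tEnd, unitId = "unit") {
    new("SpikeTrain", unitId = as.character(unitId),
        times = as.numeric(times), tStart = as.numeric(tStart),
        tEnd = as.numeric(tEnd))
}

#' EventSeries: timestamps of one event type
#'
#' @slot label character event label (e.g. "cue1", "reward", "laser_on").
#' @slot times numeric event times (s), nondecreasing.
#' @exportClass EventSeries
setClass("EventSeries", representation(label = "character", times = "numeric"))

setValidity("EventSeries", function(object) {
    msg <- character()
    if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
    if (length(object@times) && (any(!is.finite(object@times)) ||
        any(diff(object@times) < 0)))
        msg <- c(msg, "event times must be finite and nondecreasing")
    if (length(msg)) msg else TRUE
})

#' Construct an EventSeries
#' @param times numeric event times (s), nondecreasing.
#' @param label event label.
#' @return An \linkS4class{EventSeries} object.
#' @export
EventSeries <- function(times, label = "event") {
    new("EventSeries", label = as.character(label), times = as.numeric(times))
}

#' TrialTable: per-trial cue and outcome structure
#'
#' One row per trial of a two-cue Pavlovian conditioning session. Cue times are
#' strictly increasing; outcome times, when present, follow their cue; omission
#' trials carry no outcome time.
#'
#' @slot trials data.frame with columns \code{cue_time} (s), \code{cue_id}
#'   (1 or 2), \code{outcome_time} (s or NA) and \code{outcome} (one of
#'   "reward", "punishment", "omission").
#' @exportClass TrialTable
setClass("TrialTable", representation(trials = "data.frame"))

setValidity("TrialTable", function(object) {
    tr <- object@trials
    need <- c("cue_time", "cue_id", "outcome_time", "outcome")
    if (!all(need %in% names(tr)))
        return(paste("trials must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(tr)) {
        if (any(diff(tr$cue_time) <= 0))
            msg <- c(msg, "cue_time must be strictly increasing")
        if (!all(tr$cue_id %in% c(1L, 2L)))
            msg <- c(msg, "cue_id must be 1 or 2")
        if (!all(tr$outcome %in% c("reward", "punishment", "omission")))
            msg <- c(msg, "outcome must be reward/punishment/omission")
        om <- tr$outcome == "omission"
        if (any(om & !is.na(tr$outcome_time)))
            msg <- c(msg, "omission trials must have no outcome_time")
        ok <- !om & !is.na(tr$outcome_time)
        if (any(!om & is.na(tr$outcome_time)))
            msg <- c(msg, "non-omission trials need an outcome_time")
        if (any(ok) && any(tr$outcome_time[ok] <= tr$cue_time[ok]))
            msg <- c(msg, "outcome_time must follow cue_time")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TrialTable
#' @param cue_time numeric cue onset times (s), strictly increasing.
#' @param cue_id integer cue identity (1 or 2).
#' @param outcome_time numeric outcome delivery times (s); NA on omission trials.
#' @param outcome character: "reward", "punishment" or "omission".
#' @return A \linkS4class{TrialTable}.
#' @export
TrialTable <- function(cue_time, cue_id, outcome_time, outcome) {
    new("TrialTable", trials = data.frame(
        cue_time = as.numeric(cue_time), cue_id = as.integer(cue_id),
        outcome_time = as.numeric(outcome_time), outcome = as.character(outcome),
        stringsAsFactors = FALSE))
}

#' PhotometrySession: paired two-channel fluorescence traces
#'
#' Raw (demodulated) fiber-photometry traces: the calcium-dependent 465 nm
#' channel and the isosbestic 405 nm motion/autofluorescence reference, on a
#' uniform time grid.
#'
#' @slot t numeric uniform time grid (s).
#' @slot f465,f405 numeric fluorescence traces (arbitrary units).
#' @slot fs numeric sampling rate (Hz).
#' @exportClass PhotometrySession
setClass("PhotometrySession",
    representation(t = "numeric", f465 = "numeric", f405 = "numeric",
                   fs = "numeric"))

setValidity("PhotometrySession", function(object) {
    msg <- character()
    n <- length(object@t)
    if (n < 2L) msg <- c(msg, "need at least 2 samples")
    if (length(object@f465) != n || length(object@f405) != n)
        msg <- c(msg, "f465/f405 must match the time grid length")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (n >= 2L) {
        dt <- diff(object@t)
        if (any(abs(dt - dt[1L]) > 1e-9 * max(abs(dt[1L]), 1)))
            msg <- c(msg, "time grid must be uniform (1e-9 relative tolerance)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PhotometrySession
#' @param t uniform time grid (s).
#' @param f465 calcium-dependent channel trace.
#' @param f405 isosbestic channel trace.
#' @param fs sampling rate (Hz); inferred from the grid when missing.
#' @return A \linkS4class{PhotometrySession}.
#' @export
PhotometrySession <- function(t, f465, f405, fs = NULL) {
    if (is.null(fs)) fs <- 1 / stats::median(diff(t))
    new("PhotometrySession", t = as.numeric(t), f465 = as.numeric(f465),
        f405 = as.numeric(f405), fs = as.numeric(fs))
}

#' CalciumSignal: a preprocessed dF/F trace
#'
#' @slot t numeric time grid (s).
#' @slot dff numeric dF/F trace (percent), finite.
#' @slot fs numeric sampling rate (Hz).
#' @slot provenance list of the preprocessing parameters applied.
#' @exportClass CalciumSignal
setClass("CalciumSignal",
    representation(t = "numeric", dff = "numeric", fs = "numeric",
                   provenance = "list"))

setValidity("CalciumSignal", function(object) {
    msg <- character()
    if (length(object@dff) != length(object@t))
        msg <- c(msg, "dff must match the time grid length")
    if (any(!is.finite(object@dff))) msg <- c(msg, "dff must be finite")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct a CalciumSignal
#' @param t time grid (s).
#' @param dff dF/F trace (percent).
#' @param fs sampling rate (Hz).
#' @param provenance list of preprocessing parameters.
#' @return A \linkS4class{CalciumSignal}.
#' @export
CalciumSignal <- function(t, dff, fs, provenance = list()) {
    new("CalciumSignal", t = as.numeric(t), dff = as.numeric(dff),
        fs = as.numeric(fs), provenance = provenance)
}

#' PupilLandmarks: tracked pupil-edge and eyelid coordinates
#'
#' Per video frame, three diagonal pupil-edge point pairs (P1,P1'), (P2,P2'),
#' (P3,P3') and one eyelid pair (L1,L1'), as planar pixel coordinates.
#'
#' @slot t numeric frame times (s), nondecreasing.
#' @slot coords numeric matrix, one row per frame, 16 columns named
#'   \code{P1_x, P1_y, P1p_x, P1p_y, ..., L1_x, L1_y, L1p_x, L1p_y}.
#' @exportClass PupilLandmarks
setClass("PupilLandmarks", representation(t = "numeric", coords = "matrix"))

.pupilCols <- as.vector(t(outer(
    c("P1", "P1p", "P2", "P2p", "P3", "P3p", "L1", "L1p"),
    c("x", "y"), paste, sep = "_")))

setValidity("PupilLandmarks", function(object) {
    msg <- character()
    if (nrow(object@coords) != length(object@t))
        msg <- c(msg, "coords must have one row per frame")
    if (ncol(object@coords) != 16L || !identical(colnames(object@coords), .pupilCols))
        msg <- c(msg, "coords needs the 16 canonical landmark columns")
    if (length(object@t) > 1L && any(diff(object@t) < 0))
        msg <- c(msg, "frame times must be nondecreasing")
    if (length(msg)) msg else TRUE
})

#' Construct a PupilLandmarks object
#' @param t frame times (s), nondecreasing.
#' @param coords numeric matrix with columns P1_x..L1p_y (see class docs);
#'   rows may contain NA for frames where a landmark was lost.
#' @return A \linkS4class{PupilLandmarks}.
#' @export
PupilLandmarks <- function(t, coords) {
    coords <- as.matrix(coords)
    colnames(coords) <- .pupilCols
    new("PupilLandmarks", t = as.numeric(t), coords = coords)
}

#' Autocorrelogram: binned spike-pair lag histogram
#'
#' One-sided ACG (positive lags only, zero-lag self-pairs excluded). The
#' normalized values divide the raw pair counts by their mean over all bins, so
#' a Poisson train has a flat ACG near 1.
#'
#' @slot lags numeric bin centers (s), strictly increasing.
#' @slot counts numeric raw (or sweep-summed) pair counts per bin.
#' @slot norm numeric mean-normalized values (mean over bins = 1).
#' @slot binWidth numeric bin width (s).
#' @slot nSpikesUsed integer number of spikes entering the histogram.
#' @slot smoothing character descriptor of any applied moving average.
#' @exportClass Autocorrelogram
setClass("Autocorrelogram",
    representation(lags = "numeric", counts = "numeric", norm = "numeric",
                   binWidth = "numeric", nSpikesUsed = "integer",
                   smoothing = "character"))

setValidity("Autocorrelogram", function(object) {
    msg <- character()
    n <- length(object@lags)
    if (length(object@counts) != n || length(object@norm) != n)
        msg <- c(msg, "lags, counts and norm must have equal length")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (n > 1L && any(diff(object@lags) <= 0))
        msg <- c(msg, "lags must be strictly increasing")
    # shrink-to-valid edge smoothing moves the mean slightly, so the
    # mean-normalization invariant is only enforced on unsmoothed ACGs
    if (n > 0L && identical(object@smoothing, "none") &&
        mean(object@norm) > 0 && abs(mean(object@norm) - 1) > 1e-9)
        msg <- c(msg, "norm must be mean-normalized (mean 1)")
    if (length(msg)) msg else TRUE
})

#' PETH: peri-event time histogram of spike counts
#'
#' @slot binCenters numeric bin centers relative to the trigger (s).
#' @slot rate numeric mean firing rate per bin (Hz).
#' @slot perTrialCounts numeric matrix (trials x bins) of spike counts.
#' @slot binWidth numeric bin width (s).
#' @slot triggerLabel character trigger event label.
#' @exportClass PETH
setClass("PETH",
    representation(binCenters = "numeric", rate = "numeric",
                   perTrialCounts = "matrix", binWidth = "numeric",
                   triggerLabel = "character"))

setValidity("PETH", function(object) {
    msg <- character()
    if (ncol(object@perTrialCounts) != length(object@binCenters))
        msg <- c(msg, "perTrialCounts must have one column per bin")
    if (length(object@binCenters) != length(object@rate))
        msg <- c(msg, "rate must have one value per bin")
    if (nrow(object@perTrialCounts) > 0L) {
        expect <- colMeans(object@perTrialCounts) / object@binWidth
        if (max(abs(expect - object@rate)) > 1e-9)
            msg <- c(msg, "rate must equal mean(perTrialCounts)/binWidth")
    }
    if (length(msg)) msg else TRUE
})

#' CrossCorrelogram: normalized cross-correlation over lags
#'
#' Values are the cross-covariance of the (optionally mean-centered) signals
#' normalized by \eqn{\sqrt{R_{xx}(0) R_{yy}(0)}}. A central window around zero
#' lag can be masked as common-mode; the peak is located on unmasked bins only.
#' Positive lag means the second signal lags the first (first leads).
#'
#' @slot lags numeric lags (s), symmetric around 0.
#' @slot values numeric normalized correlation values.
#' @slot excludedMask logical TRUE where bins were masked as common-mode.
#' @slot peakValue,peakLag numeric peak on unmasked bins.
#' @slot fs numeric sampling rate (Hz).
#' @exportClass CrossCorrelogram
setClass("CrossCorrelogram",
    representation(lags = "numeric", values = "numeric",
                   excludedMask = "logical", peakValue = "numeric",
                   peakLag = "numeric", fs = "numeric"))

setValidity("CrossCorrelogram", function(object) {
    msg <- character()
    n <- length(object@lags)
    if (length(object@values) != n || length(object@excludedMask) != n)
        msg <- c(msg, "lags, values, excludedMask must have equal length")
    if (length(msg)) msg else TRUE
})

#' VoltageSweep: one current-step intracellular voltage trace
#'
#' @slot t numeric uniform time grid (s).
#' @slot v numeric membrane potential (mV).
#' @slot stepOnset,stepOffset numeric current-step window (s).
#' @slot stepAmplitude numeric injected current (pA).
#' @exportClass VoltageSweep
setClass("VoltageSweep",
    representation(t = "numeric", v = "numeric", stepOnset = "numeric",
                   stepOffset = "numeric", stepAmplitude = "numeric"))

setValidity("VoltageSweep", function(object) {
    msg <- character()
    if (length(object@v) != length(object@t))
        msg <- c(msg, "v must match the time grid length")
    if (length(object@t) >= 2L) {
        dt <- diff(object@t)
        if (any(abs(dt - dt[1L]) > 1e-9 * max(abs(dt[1L]), 1)))
            msg <- c(msg, "time grid must be uniform")
    }
    if (object@stepOnset >= object@stepOffset)
        msg <- c(msg, "stepOnset must precede stepOffset")
    if (object@stepOnset < object@t[1L] || object@stepOffset > object@t[length(object@t)])
        msg <- c(msg, "step window must lie within the sweep")
    if (length(msg)) msg else TRUE
})

#' Construct a VoltageSweep
#' @param t uniform time grid (s).
#' @param v membrane potential (mV).
#' @param stepOnset,stepOffset current-step window (s).
#' @param stepAmplitude injected current (pA).
#' @return A \linkS4class{VoltageSweep}.
#' @export
VoltageSweep <- function(t, v, stepOnset, stepOffset, stepAmplitude = NA_real_) {
    new("VoltageSweep", t = as.numeric(t), v = as.numeric(v),
        stepOnset = as.numeric(stepOnset), stepOffset = as.numeric(stepOffset),
        stepAmplitude = as.numeric(stepAmplitude))
}

# ---------------------------------------------------------------------------
# Accessor generics
# ---------------------------------------------------------------------------

#' Accessors for cholinphys data classes
#'
#' Small accessor generics for the core containers: \code{spikeTimes},
#' \code{unitId}, \code{eventTimes}, \code{trials}, \code{nSpikes},
#' \code{samplingRate}, \code{dff}, \code{timeGrid}, \code{acgLags},
#' \code{acgNorm}, \code{pethRate}.
#'
#' @param object a cholinphys data object.
#' @return The accessed slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(object) object@unitId)

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(object) length(object@times))

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setMethod("eventTimes", "EventSeries", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "TrialTable", function(object) object@trials)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhotometrySession", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "CalciumSignal", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "CrossCorrelogram", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setMethod("timeGrid", "PhotometrySession", function(object) object@t)
#' @rdname accessors
#' @export
setMethod("timeGrid", "CalciumSignal", function(object) object@t)

#' @rdname accessors
#' @export
setGeneric("dff", function(object) standardGeneric("dff"))
#' @rdname accessors
#' @export
setMethod("dff", "CalciumSignal", function(object) object@dff)

#' @rdname accessors
#' @export
setGeneric("acgLags", function(object) standardGeneric("acgLags"))
#' @rdname accessors
#' @export
setMethod("acgLags", "Autocorrelogram", function(object) object@lags)

#' @rdname accessors
#' @export
setGeneric("acgCounts", function(object) standardGeneric("acgCounts"))
#' @rdname accessors
#' @export
setMethod("acgCounts", "Autocorrelogram", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("acgNorm", function(object) standardGeneric("acgNorm"))
#' @rdname accessors
#' @export
setMethod("acgNorm", "Autocorrelogram", function(object) object@norm)

#' @rdname accessors
#' @export
setGeneric("pethRate", function(object) standardGeneric("pethRate"))
#' @rdname accessors
#' @export
setMethod("pethRate", "PETH", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("pethCounts", function(object) standardGeneric("pethCounts"))
#' @rdname accessors
#' @export
setMethod("pethCounts", "PETH", function(object) object@perTrialCounts)

#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setMethod("binCenters", "PETH", function(object) object@binCenters)

# ---------------------------------------------------------------------------
# show() methods
# ---------------------------------------------------------------------------

setMethod("show", "SpikeTrain", function(object) {
    cat("SpikeTrain '", object@unitId, "': ", length(object@times),
        " spikes in [", format(object@tStart), ", ", format(object@tEnd),
        "] s (mean rate ",
        format(round(length(object@times) / (object@tEnd - object@tStart), 3)),
        " Hz)\n", sep = "")
})

setMethod("show", "EventSeries", function(object) {
    cat("EventSeries '", object@label, "': ", length(object@times),
        " events\n", sep = "")
})

setMethod("show", "TrialTable", function(object) {
    tr <- object@trials
    cat("TrialTable: ", nrow(tr), " trials (",
        sum(tr$cue_id == 1L), " cue1 / ", sum(tr$cue_id == 2L), " cue2; ",
        paste(sprintf("%s=%d", names(table(tr$outcome)), table(tr$outcome)),
              collapse = ", "), ")\n", sep = "")
})

setMethod("show", "PhotometrySession", function(object) {
    cat("PhotometrySession: ", length(object@t), " samples @ ",
        format(object@fs), " Hz (", format(round(diff(range(object@t)), 1)),
        " s)\n", sep = "")
})

setMethod("show", "CalciumSignal", function(object) {
    cat("CalciumSignal: ", length(object@t), " samples @ ", format(object@fs),
        " Hz; dF/F range [", format(round(min(object@dff), 3)), ", ",
        format(round(max(object@dff), 3)), "] %\n", sep = "")
})

setMethod("show", "Autocorrelogram", function(object) {
    cat("Autocorrelogram: ", length(object@lags), " bins of ",
        format(object@binWidth * 1000), " ms up to ",
        format(max(object@lags) * 1000), " ms; ", object@nSpikesUsed,
        " spikes used; smoothing: ", object@smoothing, "\n", sep = "")
})

setMethod("show", "PETH", function(object) {
    cat("PETH ('", object@triggerLabel, "'): ", nrow(object@perTrialCounts),
        " trials x ", length(object@binCenters), " bins of ",
        format(object@binWidth * 1000), " ms\n", sep = "")
})

setMethod("show", "CrossCorrelogram", function(object) {
    cat("CrossCorrelogram: lags within ±", format(max(object@lags)),
        " s; peak ", format(round(object@peakValue, 4)), " at ",
        format(round(object@peakLag, 4)), " s (",
        sum(object@excludedMask), " bins masked)\n", sep = "")
})

setMethod("show", "PupilLandmarks", function(object) {
    cat("PupilLandmarks: ", length(object@t), " frames\n", sep = "")
})

setMethod("show", "VoltageSweep", function(object) {
    cat("VoltageSweep: ", length(object@t), " samples; step [",
        format(object@stepOnset), ", ", format(object@stepOffset), "] s, ",
        format(object@stepAmplitude), " pA\n", sep = "")
})
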