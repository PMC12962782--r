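# Readers and writers for the plain-text formats the pipeline touches.
# Dialect: comma-separated, header row, UTF-8, '.' decimal (Doric-style);
# trial tables are tab-separated. Numbers are written with 17 significant
# digits so a write/read round trip is lossless for doubles.

.fmtNum <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- "NA"
    out
}

#' Read spike trains from plain-text files
#'
#' Accepts either a single-column file of timestamps (one unit) or a
#' long-format CSV with columns \code{unit_id,time} (several units). Unsorted
#' timestamps are sorted with a warning; a timestamp outside
#' \code{[tStart, tEnd]} is a validation error.
#'
#' @param path file path.
#' @param tStart,tEnd recording span (s).
#' @return A named list of \linkS4class{SpikeTrain} objects.
#' @export
readSpikeTrains <- function(path, tStart, tEnd) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    long <- length(first) == 1L && grepl(",", first) &&
        grepl("unit_id", first, fixed = TRUE)
    if (long) {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        if (!all(c("unit_id", "time") %in% names(df)))
            stop("long-format spike CSV needs columns unit_id,time")
        bad <- which(is.na(suppressWarnings(as.numeric(df$time))))
        if (length(bad))
            stop("nonnumeric timestamp at data line ", bad[1L], " of ", path)
        df$time <- as.numeric(df$time)
        groups <- split(df$time, df$unit_id)
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(trimws(lines))]
        # tolerate an optional single-word header
        if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))))
            lines <- lines[-1L]
        vals <- suppressWarnings(as.numeric(lines))
        if (anyNA(vals))
            stop("nonnumeric timestamp at line ", which(is.na(vals))[1L],
                 " of ", path)
        nm <- sub("\\.[^.]*$", "", basename(path))
        groups <- stats::setNames(list(vals), nm)
    }
    out <- lapply(names(groups), function(id) {
        times <- groups[[id]]
        if (is.unsorted(times, strictly = TRUE)) {
            warning("spike times of unit '", id, "' were not sorted; sorting")
            times <- sort(times)
        }
        if (length(times) && (times[1L] < tStart || times[length(times)] > tEnd))
            stop("unit '", id, "': spike time outside [tStart, tEnd]")
        SpikeTrain(times, tStart, tEnd, unitId = id)
    })
    stats::setNames(out, names(groups))
}

#' Write spike trains as a long-format CSV
#'
#' @param trains list of \linkS4class{SpikeTrain} objects.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSpikeTrains <- function(trains, path) {
    rows <- unlist(lapply(trains, function(tr)
        paste(unitId(tr), .fmtNum(spikeTimes(tr)), sep = ",")))
    writeLines(c("unit_id,time", rows), path)
    invisible(path)
}

#' Read a two-channel photometry session from CSV
#'
#' Expects columns \code{time,f465,f405} (names configurable through
#' \code{config$io}). The sampling rate is inferred from the median time step;
#' a nonuniform grid (e.g. dropped samples) is linearly resampled onto a
#' uniform grid with a message.
#'
#' @param path CSV file path.
#' @param config configuration list from \code{\link{analysisConfig}}.
#' @return A \linkS4class{PhotometrySession}.
#' @export
readPhotometry <- function(path, config = analysisConfig()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cols <- c(config$io$time_col, config$io$f465_col, config$io$f405_col)
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("photometry CSV is missing column(s): ", paste(miss, collapse = ", "))
    t <- as.numeric(df[[cols[1L]]])
    f465 <- as.numeric(df[[cols[2L]]])
    f405 <- as.numeric(df[[cols[3L]]])
    if (length(t) < 2L) stop("photometry session needs at least 2 samples")
    dt <- stats::median(diff(t))
    fs <- 1 / dt
    if (any(abs(diff(t) - dt) > 1e-9 * dt)) {
        tu <- seq(t[1L], t[length(t)], by = dt)
        message("nonuniform photometry grid: resampled ", length(t),
                " -> ", length(tu), " samples at ", signif(fs, 6), " Hz")
        f465 <- stats::approx(t, f465, xout = tu)$y
        f405 <- stats::approx(t, f405, xout = tu)$y
        t <- tu
    }
    PhotometrySession(t, f465, f405, fs = fs)
}

#' Write a photometry session to CSV
#' @param session a \linkS4class{PhotometrySession}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePhotometry <- function(session, path) {
    writeLines(c("time,f465,f405",
                 paste(.fmtNum(session@t), .fmtNum(session@f465),
                       .fmtNum(session@f405), sep = ",")), path)
    invisible(path)
}

#' Read a trial table from TSV
#'
#' Tab-separated with header \code{cue_time, cue_id, outcome_time, outcome};
#' \code{outcome_time} is empty or NA on omission trials.
#'
#' @param path TSV file path.
#' @return A \linkS4class{TrialTable}.
#' @export
readTrialTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("cue_time", "cue_id", "outcome_time", "outcome")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("trial TSV is missing column(s): ", paste(miss, collapse = ", "))
    TrialTable(df$cue_time, df$cue_id, as.numeric(df$outcome_time), df$outcome)
}

#' Write a trial table to TSV
#' @param trialTable a \linkS4class{TrialTable}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrialTable <- function(trialTable, path) {
    tr <- trials(trialTable)
    writeLines(c("cue_time\tcue_id\toutcome_time\toutcome",
                 paste(.fmtNum(tr$cue_time), tr$cue_id,
                       .fmtNum(tr$outcome_time), tr$outcome, sep = "\t")), path)
    invisible(path)
}

#' Read pupil landmark coordinates from CSV
#'
#' Expects a \code{time} column plus the 16 landmark coordinate columns
#' \code{P1_x,P1_y,P1p_x,...,L1p_y} (three diagonal pupil-edge pairs and the
#' eyelid pair).
#'
#' @param path CSV file path.
#' @return A \linkS4class{PupilLandmarks}.
#' @export
readPupilLandmarks <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("time", .pupilCols), names(df))
    if (length(miss))
        stop("pupil CSV is missing column(s): ", paste(miss, collapse = ", "))
    PupilLandmarks(df$time, as.matrix(df[, .pupilCols]))
}

#' Write pupil landmarks to CSV
#' @param landmarks a \linkS4class{PupilLandmarks}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePupilLandmarks <- function(landmarks, path) {
    body <- apply(cbind(landmarks@t, landmarks@coords), 1L,
                  function(r) paste(.fmtNum(r), collapse = ","))
    writeLines(c(paste(c("time", .pupilCols), collapse = ","), body), path)
    invisible(path)
}

#' Sanity-check trial timing against the task's minimum inter-trial interval
#'
#' Trials whose cue follows the previous cue by less than \code{minIti} are
#' flagged (attribute \code{"flagged"} on the returned object, plus a warning);
#' the table itself is returned unchanged. An outcome time on an omission
#' trial is a validation error.
#'
#' @param trialTable a \linkS4class{TrialTable} or a data.frame with the same
#'   columns.
#' @param minIti minimum inter-cue interval (s); the task enforced 2.5 s of
#'   no licking before a new trial.
#' @return The input \linkS4class{TrialTable} with an integer attribute
#'   \code{"flagged"} listing offending trial indices (empty when all pass).
#' @export
validateTrials <- function(trialTable, minIti = 2.5) {
    if (is.data.frame(trialTable)) {
        om <- trialTable$outcome == "omission"
        if (any(om & !is.na(trialTable$outcome_time)))
            stop("omission trial has an outcome_time")
        trialTable <- TrialTable(trialTable$cue_time, trialTable$cue_id,
                                 trialTable$outcome_time, trialTable$outcome)
    }
    tr <- trials(trialTable)
    if (!nrow(tr)) stop("trial table is empty")
    flagged <- which(c(FALSE, diff(tr$cue_time) < minIti))
    if (length(flagged))
        warning("trial(s) ", paste(flagged, collapse = ", "),
                " start within ", minIti, " s of the previous cue")
    attr(trialTable, "flagged") <- as.integer(flagged)
    trialTable
}
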