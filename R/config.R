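#' Analysis configuration
#'
#' All tunables of the pipeline in one hierarchical list, keyed by module.
#' Defaults reproduce the published analysis parameters (0.5 ms ACG bins with a
#' 2.5 ms smoothing window, Burst Index windows 0-25 and 180-200 ms, 500 ms
#' response/baseline windows at alpha 0.01, 20 Hz low-pass and 0.2 Hz high-pass
#' photometry filters, +/-10 s cross-correlation window with +/-20 ms exclusion,
#' 200 transfer-entropy bins, ...). Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param ... named overrides, either top-level module lists
#'   (e.g. \code{acg = list(bin_width = 0.001)}) or nothing for the defaults.
#' @return Nested named list of configuration values.
#' @examples
#' cfg <- analysisConfig(acg = list(bin_width = 0.001))
#' cfg$acg$bin_width
#' @export
analysisConfig <- function(...) {
    defaults <- list(
        io = list(
            min_iti = 2.5,
            time_col = "time", f465_col = "f465", f405_col = "f405"
        ),
        acg = list(
            bin_width = 0.0005, max_lag = 0.5, spike_cap = 50000L,
            smooth_window = 0.0025,
            burst_win = c(0, 0.025), base_win = c(0.180, 0.200),
            theta_search = c(0.100, 0.200), theta_halfwidth = 0.025,
            theta_flank_low = c(0.050, 0.075), theta_flank_high = c(0.225, 0.250),
            refractory_smooth = 0.010, asymptote_win = c(0.180, 0.200),
            reg_refractory_min = 0.040, sb_min = 0.4
        ),
        responses = list(
            peth_bin = 0.010, search_win = 0.5, baseline_win = 0.5,
            alpha = 0.01,
            optotag_pulse_dur = 0.2, optotag_latency_max = 0.010,
            optotag_max_rate = 0.5, optotag_baseline_pre = 1.0,
            n_clusters = 4L, linkage = "ward.D2"
        ),
        photometry = list(
            lowpass_hz = 20, highpass_hz = 0.2,
            lowpass_order = 4L, highpass_order = 2L,
            baseline_pre = 2, response_win = 1,
            trialwise_resp_win = c(0, 0.5), trialwise_base_win = c(-0.5, 0),
            trialwise_alpha = 0.05
        ),
        coupling = list(
            max_lag = 10, exclude = 0.020, center = TRUE,
            te_bins = 200L, te_history = 1L, te_downsample_hz = 20,
            peak_threshold_sd = 2, peak_min_sep = 1, pta_win = c(-2, 4)
        ),
        invitro = list(
            threshold_mv = -20, min_isi = 0.001, smooth_window = 0.005
        ),
        anatomy = list(
            density_mode = "mean_probability", threshold = 0.5
        )
    )
    mergeConfig(defaults, list(...), path = "")
}

# Recursive merge with unknown-key rejection.
mergeConfig <- function(base, override, path) {
    if (!length(override)) return(base)
    if (is.null(names(override)) || any(names(override) == ""))
        stop("config overrides must be named (at '", path, "')")
    for (key in names(override)) {
        if (!key %in% names(base))
            stop("unknown config key: '",
                 if (nzchar(path)) paste0(path, ".", key) else key, "'")
        if (is.list(base[[key]]) && is.list(override[[key]])) {
            base[[key]] <- mergeConfig(base[[key]], override[[key]],
                                       paste0(path, if (nzchar(path)) ".", key))
        } else {
            base[[key]] <- override[[key]]
        }
    }
    base
}

#' Read an analysis configuration from a YAML file
#'
#' The file mirrors the hierarchy of \code{\link{analysisConfig}}; keys present
#' in the file override the defaults, unknown keys raise an error.
#'
#' @param path path to a YAML file.
#' @return Nested configuration list (defaults merged with the file).
#' @export
readAnalysisConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    do.call(analysisConfig, raw)
}
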