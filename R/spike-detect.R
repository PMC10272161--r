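#' Spike detector configuration
#'
#' @param lowpass_hz zero-phase low-pass cutoff applied before detection.
#' @param highpass_hz high-pass cutoff of the detection band (removes slow
#'   membrane-potential drift before thresholding).
#' @param k_mad threshold in units of the MAD of the band-passed trace.
#' @param min_threshold_mv absolute floor on the detection threshold, so a
#'   noiseless trace does not yield a zero threshold.
#' @param refractory_s minimum separation between detections.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(lowpass_hz = 2000, highpass_hz = 100,
                            k_mad = 6, min_threshold_mv = 0.5,
                            refractory_s = 0.002) {
  structure(list(lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 k_mad = k_mad, min_threshold_mv = min_threshold_mv,
                 refractory_s = refractory_s),
            class = "detector_config")
}

# Zero-phase Butterworth filter helper (filtfilt doubles the effective
# order). The median is removed before filtering to suppress the edge
# transient a DC offset would otherwise produce, and restored for low-pass
# output so absolute voltages are preserved.
butter_filtfilt <- function(x, rate_hz, cutoff_hz, type, order = 2) {
  w <- cutoff_hz / (rate_hz / 2)
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  bf <- signal::butter(order, w, type = type)
  med <- median(x)
  out <- as.numeric(signal::filtfilt(bf, x - med))
  if (identical(type, "low")) out <- out + med
  out
}

# The low-pass trace used both for detection and for waveform measurements.
filtered_trace <- function(trace, cfg = detector_config()) {
  butter_filtfilt(trace$samples$v_mv, trace$rate_hz, cfg$lowpass_hz, "low")
}

#' Detect spikes in a voltage trace
#'
#' Zero-phase low-pass filters the trace, removes slow drift with a
#' zero-phase high-pass, and takes local maxima of the band-passed signal
#' that exceed `k_mad` times its MAD (with an absolute floor). Detections
#' closer than the refractory window are resolved in favor of the larger
#' peak. The reported spike time is the waveform peak of the low-passed
#' trace near the threshold crossing.
#'
#' @param trace an `al_trace` (see [generate_voltage_trace()]) or any list
#'   with `samples` (`time_s`, `v_mv`) and `rate_hz`.
#' @param cfg a [detector_config()].
#' @return A tibble with `time_s` (sorted ascending) and `peak_mv`
#'   (low-passed peak value). Flat or all-NA traces yield zero rows with a
#'   warning, not an error.
#' @export
detect_spikes <- function(trace, cfg = detector_config()) {
  v <- trace$samples$v_mv
  t <- trace$samples$time_s
  rate <- trace$rate_hz
  if (all(!is.finite(v)) || length(v) < 64 || diff(range(v[is.finite(v)])) == 0) {
    warn("Flat or invalid trace: no spikes detected.")
    return(tibble(time_s = numeric(0), peak_mv = numeric(0)))
  }
  v[!is.finite(v)] <- median(v[is.finite(v)])
  lp <- butter_filtfilt(v, rate, cfg$lowpass_hz, "low")
  bp <- butter_filtfilt(lp, rate, cfg$highpass_hz, "high")
  thr <- max(cfg$k_mad * mad(bp), cfg$min_threshold_mv)
  n <- length(bp)
  is_peak <- c(FALSE, bp[2:(n - 1)] > bp[1:(n - 2)] &
                 bp[2:(n - 1)] >= bp[3:n], FALSE) & bp > thr
  cand <- which(is_peak)
  # a genuine spike is also depolarized above baseline on the low-passed
  # trace; this rejects band-pass rebounds after deep AHPs
  cand <- cand[lp[cand] > median(lp) + thr]
  if (length(cand) == 0) {
    return(tibble(time_s = numeric(0), peak_mv = numeric(0)))
  }
  # enforce refractory window, keeping the larger peak
  keep <- logical(length(cand))
  ord <- order(bp[cand], decreasing = TRUE)
  taken <- numeric(0)
  ref_n <- cfg$refractory_s * rate
  for (j in ord) {
    if (!any(abs(cand[j] - taken) < ref_n)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  cand <- sort(cand[keep])
  # refine to the low-passed waveform peak within +-0.5 ms
  half <- as.integer(round(0.0005 * rate))
  peak_idx <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(lp[lo:hi]) - 1L)
  }, integer(1))
  peak_idx <- unique(peak_idx)
  tibble(time_s = t[peak_idx], peak_mv = lp[peak_idx])
}

#' Label spikes as isolated or burst
#'
#' A spike is isolated when no other spike lies within `window_s` on either
#' side. The boundary is part of the window: a neighbor at exactly
#' `window_s` makes the spike a burst spike.
#'
#' @param spike_times sorted numeric spike times (s).
#' @param window_s isolation window, default 0.2 s.
#' @return Character vector (`"isolated"`/`"burst"`) parallel to the input.
#' @examples
#' classify_isolated(c(0, 0.5, 0.55, 1.0))
#' @export
classify_isolated <- function(spike_times, window_s = 0.2) {
  n <- length(spike_times)
  if (n == 0) return(character(0))
  if (is.unsorted(spike_times, strictly = FALSE)) {
    abort("`spike_times` must be sorted ascending.")
  }
  if (n == 1) return("isolated")
  gap_prev <- c(Inf, diff(spike_times))
  gap_next <- c(diff(spike_times), Inf)
  ifelse(gap_prev > window_s & gap_next > window_s, "isolated", "burst")
}
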