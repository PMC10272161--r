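# The four electrophysiological features of a recorded cell, measured on the
# low-passed trace: spike amplitude, spike half-width, after-hyperpolarization
# amplitude (on a 5-500 Hz band-passed trace), and isolated-spike fraction.

# index of the sample nearest a spike time
spike_index <- function(time_s, rate_hz) pmax(1L, round(time_s * rate_hz) + 1L)

# Peak and trough geometry for one spike on a filtered trace.
# Returns peak value, left trough, right trough (mins within +-search_s).
spike_geometry <- function(lp, i, rate_hz, search_s = 0.010) {
  n <- length(lp)
  w <- round(search_s * rate_hz)
  peak <- lp[i]
  left <- min(lp[max(1L, i - w):i])
  right <- min(lp[i:min(n, i + w)])
  c(peak = peak, left = left, right = right)
}

# maximal runs of burst-labeled spikes (consecutive under the isolation gap)
burst_groups <- function(spike_times, labels, window_s = 0.2) {
  idx <- which(labels == "burst")
  if (length(idx) == 0) return(list())
  splits <- cumsum(c(1, diff(spike_times[idx]) > window_s))
  split(idx, splits)
}

#' Spike amplitude of a cell
#'
#' Per spike, the distance between the waveform peak and the deeper of the
#' two troughs found within 10 ms on either side. Averaged over isolated
#' spikes when the cell has any; otherwise each burst contributes the mean
#' of its first and last spike's amplitude and the burst values are
#' averaged.
#'
#' @param trace an `al_trace`.
#' @param spike_times detected spike times (s), sorted.
#' @param labels optional isolation labels; computed with
#'   [classify_isolated()] if missing.
#' @param cfg [detector_config()] controlling the measurement filter.
#' @return Amplitude in mV, or `NA_real_` if there are no spikes.
#' @export
spike_amplitude <- function(trace, spike_times, labels = NULL,
                            cfg = detector_config()) {
  if (length(spike_times) == 0) return(NA_real_)
  labels <- labels %||% classify_isolated(spike_times)
  lp <- filtered_trace(trace, cfg)
  idx <- spike_index(spike_times, trace$rate_hz)
  amp_one <- function(i) {
    g <- spike_geometry(lp, i, trace$rate_hz)
    max(g["peak"] - g["left"], g["peak"] - g["right"])
  }
  iso <- which(labels == "isolated")
  if (length(iso) > 0) return(mean(vapply(idx[iso], amp_one, numeric(1))))
  groups <- burst_groups(spike_times, labels)
  mean(vapply(groups, function(g) {
    mean(c(amp_one(idx[g[1]]), amp_one(idx[g[length(g)]])))
  }, numeric(1)))
}

#' Spike half-width of a cell
#'
#' Full width of the spike at half its height, the height being measured
#' from the deeper of the two troughs; crossings are located by linear
#' interpolation between samples. Averaged over isolated spikes.
#'
#' @inheritParams spike_amplitude
#' @return Half-width in ms, or `NA_real_` with no isolated spikes.
#' @export
spike_half_width <- function(trace, spike_times, labels = NULL,
                             cfg = detector_config()) {
  labels <- labels %||% classify_isolated(spike_times)
  iso <- which(labels == "isolated")
  if (length(iso) == 0) return(NA_real_)
  lp <- filtered_trace(trace, cfg)
  rate <- trace$rate_hz
  idx <- spike_index(spike_times, trace$rate_hz)
  w <- round(0.010 * rate)
  hw_one <- function(i) {
    g <- spike_geometry(lp, i, rate)
    level <- g["peak"] - (g["peak"] - min(g["left"], g["right"])) / 2
    # walk out from the peak to the first crossing on each side
    n <- length(lp)
    li <- i
    while (li > max(1L, i - w) && lp[li] > level) li <- li - 1L
    ri <- i
    while (ri < min(n, i + w) && lp[ri] > level) ri <- ri + 1L
    if (lp[li] > level || lp[ri] > level) return(NA_real_)
    tl <- li + (level - lp[li]) / (lp[li + 1L] - lp[li])
    tr <- ri - 1L + (lp[ri - 1L] - level) / (lp[ri - 1L] - lp[ri])
    (tr - tl) / rate * 1000
  }
  vals <- vapply(idx[iso], hw_one, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' After-hyperpolarization amplitude of a cell
#'
#' On a 5--500 Hz zero-phase band-passed trace, each isolated spike
#' contributes the minimum of the membrane potential within 10 ms after the
#' spike minus its mean in the 20--70 ms post-spike window. Occasional
#' positive per-spike values are dropped, and the remaining values averaged;
#' spikes without 70 ms of post-spike trace are skipped.
#'
#' @inheritParams spike_amplitude
#' @param band band-pass edges in Hz.
#' @return AHP amplitude in mV (`<= 0`), or `NA_real_` when no isolated
#'   spike yields a negative value.
#' @export
ahp_amplitude <- function(trace, spike_times, labels = NULL,
                          band = c(5, 500), cfg = detector_config()) {
  labels <- labels %||% classify_isolated(spike_times)
  iso <- which(labels == "isolated")
  if (length(iso) == 0) return(NA_real_)
  rate <- trace$rate_hz
  bp <- butter_filtfilt(trace$samples$v_mv, rate, band, "pass")
  idx <- spike_index(spike_times, rate)
  n <- length(bp)
  vals <- vapply(idx[iso], function(i) {
    i70 <- i + round(0.070 * rate)
    if (i70 > n) return(NA_real_)
    dip <- min(bp[i:(i + round(0.010 * rate))])
    ref <- mean(bp[(i + round(0.020 * rate)):i70])
    dip - ref
  }, numeric(1))
  vals <- vals[is.finite(vals) & vals < 0]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Isolated-spike fraction
#'
#' @param labels isolation labels from [classify_isolated()].
#' @return Fraction of spikes labeled isolated, or `NA_real_` with zero
#'   spikes.
#' @export
isolated_fraction <- function(labels) {
  if (length(labels) == 0) return(NA_real_)
  mean(labels == "isolated")
}

#' Extract the four electrophysiological features of a cell
#'
#' Runs spike detection and isolation labeling on a trace and aggregates
#' [spike_amplitude()], [spike_half_width()], [ahp_amplitude()] and
#' [isolated_fraction()] over the whole recording. Spikes inside
#' `exclude_window` (e.g. the odor-response interval) can be removed first,
#' which mirrors the control of recomputing the features without odor-evoked
#' spikes. Missing features propagate as `NA`, never as zero.
#'
#' @param trace an `al_trace`.
#' @param cfg a [detector_config()].
#' @param exclude_window optional `c(start, end)` seconds; spikes in the
#'   half-open window are dropped before feature computation.
#' @param cell_id optional id copied into the output.
#' @return One-row tibble: `cell_id`, `amplitude_mv`, `half_width_ms`,
#'   `ahp_mv`, `isolated_fraction`, `n_spikes`.
#' @export
extract_features <- function(trace, cfg = detector_config(),
                             exclude_window = NULL, cell_id = NULL) {
  det <- detect_spikes(trace, cfg)
  st <- det$time_s
  if (!is.null(exclude_window) && length(st) > 0) {
    stopifnot(length(exclude_window) == 2)
    st <- st[st < exclude_window[1] | st >= exclude_window[2]]
  }
  labels <- classify_isolated(st)
  tibble(
    cell_id = cell_id %||% (trace$meta$cell_id %||% NA_character_),
    amplitude_mv = if (length(st)) spike_amplitude(trace, st, labels, cfg) else NA_real_,
    half_width_ms = if (length(st)) spike_half_width(trace, st, labels, cfg) else NA_real_,
    ahp_mv = if (length(st)) ahp_amplitude(trace, st, labels, cfg = cfg) else NA_real_,
    isolated_fraction = isolated_fraction(labels),
    n_spikes = length(st)
  )
}

#' Spike-triggered average of another trace
#'
#' Mean of segments of `other_trace` aligned on trigger spike times, e.g.
#' the membrane potential of one neuron triggered on spikes of a
#' simultaneously recorded neuron. Triggers whose window extends beyond the
#' trace are dropped.
#'
#' @param trigger_times spike times (s) of the trigger cell.
#' @param other_trace an `al_trace` whose voltage is averaged.
#' @param window_s `c(before, after)` seconds around each trigger,
#'   default +-50 ms.
#' @return A tibble `lag_s`, `v_mv` with attribute `n_triggers`.
#' @export
spike_triggered_average <- function(trigger_times, other_trace,
                                    window_s = c(-0.05, 0.05)) {
  rate <- other_trace$rate_hz
  v <- other_trace$samples$v_mv
  n <- length(v)
  i0 <- round(window_s[1] * rate)
  i1 <- round(window_s[2] * rate)
  idx <- spike_index(trigger_times, rate)
  idx <- idx[idx + i0 >= 1 & idx + i1 <= n]
  if (length(idx) == 0) abort("No trigger spike lies fully inside the trace.")
  seg <- vapply(idx, function(i) v[(i + i0):(i + i1)], numeric(i1 - i0 + 1))
  out <- tibble(lag_s = (i0:i1) / rate, v_mv = rowMeans(seg))
  attr(out, "n_triggers") <- length(idx)
  out
}

#' Compare spike counts between two epochs across trials
#'
#' Paired two-sided Wilcoxon signed-rank test on per-trial spike counts in
#' two half-open time intervals, as used to test whether current injection
#' in one neuron of a pair raises firing of the other during the injection
#' epoch relative to the preceding second.
#'
#' @param spikes an `al_spikes` tibble (or any tibble with `trial`,
#'   `time_s`) for a single cell.
#' @param epoch_a,epoch_b `c(start, end)` seconds, half-open.
#' @return One-row tibble: per-epoch mean counts, `statistic`, `p_value`,
#'   `n_trials`.
#' @export
compare_epochs <- function(spikes, epoch_a, epoch_b) {
  counts <- spikes |>
    group_by(trial) |>
    summarise(a = count_in_window(.data$time_s, epoch_a[1], epoch_a[2]),
              b = count_in_window(.data$time_s, epoch_b[1], epoch_b[2]),
              .groups = "drop")
  if (nrow(counts) < 6) {
    warn("Fewer than 6 trials: the two-sided signed-rank test cannot reach p < 0.05.")
  }
  sr <- signed_rank_test(counts$b, counts$a)
  tibble(mean_count_a = mean(counts$a), mean_count_b = mean(counts$b),
         statistic = sr$statistic, p_value = sr$p_value,
         n_trials = nrow(counts))
}
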