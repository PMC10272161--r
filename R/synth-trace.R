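#' Cell parameter sets for the synthetic voltage-trace generator
#'
#' Bundles the per-cell quantities the generator needs: the target values of
#' the four electrophysiological features (spike amplitude, half-width,
#' after-hyperpolarization depth, isolated-spike fraction), the spontaneous
#' firing rate, and the additive noise level. Defaults emulate the two broad
#' antennal-lobe classes: projection neurons (PNs) fire faster spontaneously
#' with smaller, wider spikes, shallow AHP and few isolated spikes; local
#' neurons (LNs) fire slower with larger, narrower spikes, deep AHP and a
#' high isolated fraction. Spontaneous rates and the PN isolated fraction
#' follow the group means of the recorded populations (9.5 Hz, 2.6 Hz, 0.04);
#' waveform magnitudes are physiologically typical values chosen to respect
#' the printed PN/LN directionality.
#'
#' @param class_label `"PN"` or `"LN"`; selects the default regime.
#' @param spike_amplitude_mv target peak-to-deeper-trough spike amplitude (mV).
#' @param spike_halfwidth_ms target full width at half height (ms).
#' @param ahp_depth_mv target after-hyperpolarization amplitude (mV, negative).
#' @param isolated_fraction target fraction of spikes with no neighbor within
#'   200 ms on either side, in `[0, 1]`.
#' @param baseline_rate_hz spontaneous firing rate (spikes/s).
#' @param noise_sd_mv SD of additive Gaussian noise (mV).
#' @param baseline_mv resting membrane potential (mV).
#'
#' @return A list of class `cell_params`.
#' @examples
#' cell_params("PN")
#' cell_params("LN", noise_sd_mv = 1)
#' @export
cell_params <- function(class_label = c("PN", "LN"),
                        spike_amplitude_mv = NULL,
                        spike_halfwidth_ms = NULL,
                        ahp_depth_mv = NULL,
                        isolated_fraction = NULL,
                        baseline_rate_hz = NULL,
                        noise_sd_mv = 0.5,
                        baseline_mv = -55) {
  class_label <- match.arg(class_label)
  def <- if (class_label == "PN") {
    list(amp = 15, hw = 1.4, ahp = -2, iso = 0.04, rate = 9.5)
  } else {
    list(amp = 30, hw = 0.7, ahp = -6, iso = 0.60, rate = 2.6)
  }
  p <- list(
    class_label        = class_label,
    spike_amplitude_mv = spike_amplitude_mv %||% def$amp,
    spike_halfwidth_ms = spike_halfwidth_ms %||% def$hw,
    ahp_depth_mv       = ahp_depth_mv %||% def$ahp,
    isolated_fraction  = isolated_fraction %||% def$iso,
    baseline_rate_hz   = baseline_rate_hz %||% def$rate,
    noise_sd_mv        = noise_sd_mv,
    baseline_mv        = baseline_mv
  )
  assert_scalar_number(p$isolated_fraction, "isolated_fraction", 0, 1)
  assert_scalar_number(p$baseline_rate_hz, "baseline_rate_hz", 0)
  assert_scalar_number(p$noise_sd_mv, "noise_sd_mv", 0)
  if (p$ahp_depth_mv > 0) abort("`ahp_depth_mv` must be <= 0 (a depth).")
  if (p$spike_amplitude_mv <= 2 * abs(p$ahp_depth_mv)) {
    abort("`spike_amplitude_mv` must exceed twice the AHP depth for a well-defined half-width.")
  }
  structure(p, class = "cell_params")
}

#' Analytic spike template
#'
#' Biphasic waveform used by the trace generator: a Gaussian depolarizing
#' peak followed by a delayed alpha-like after-hyperpolarization lobe. The
#' parameterization is chosen so the downstream feature definitions recover
#' the inputs: the peak-to-deeper-trough distance equals `amplitude_mv`, the
#' full width at half height (height measured from the trough baseline)
#' equals `halfwidth_ms`, and the AHP minimum (within 10 ms of the peak)
#' equals `ahp_mv`. The AHP lobe starts `ahp_onset_ms` after the peak, so it
#' does not distort the half-width, and decays essentially to zero before the
#' 20--70 ms post-spike window used as the AHP reference level.
#'
#' @param t_s times relative to the spike peak (s).
#' @param amplitude_mv peak-to-trough amplitude (mV).
#' @param halfwidth_ms full width at half height (ms).
#' @param ahp_mv AHP depth (mV, `<= 0`).
#' @param ahp_peak_ms time from AHP onset to the AHP minimum (ms).
#' @param ahp_onset_ms delay between spike peak and AHP onset (ms).
#' @return Voltage values (mV) relative to baseline.
#' @examples
#' t <- seq(-0.005, 0.03, by = 5e-5)
#' v <- spike_template(t, 15, 1.4, -2)
#' @export
spike_template <- function(t_s, amplitude_mv, halfwidth_ms, ahp_mv,
                           ahp_peak_ms = 4, ahp_onset_ms = 1.5) {
  d <- abs(ahp_mv)
  p <- amplitude_mv - d            # Gaussian peak height above baseline
  if (p <= d) abort("amplitude must exceed twice the AHP depth.")
  # FWHM at level (p - d)/2 above baseline: halfwidth = 2*sigma*sqrt(2*log(2p/(p-d)))
  sigma_s <- (halfwidth_ms / 1000) / (2 * sqrt(2 * log(2 * p / (p - d))))
  v <- p * exp(-t_s^2 / (2 * sigma_s^2))
  if (d > 0) {
    u <- (t_s - ahp_onset_ms / 1000) / (ahp_peak_ms / 1000)
    ahp <- ifelse(u > 0, -d * u^2 * exp(2 * (1 - u)), 0)
    v <- v + ahp
  }
  v
}

#' Generate spike times from a two-state (isolated/burst) renewal process
#'
#' Events are drawn as a renewal process whose inter-event gaps are at least
#' 250 ms (exponential waiting time plus the margin), so single-spike events
#' are guaranteed isolated under the 200 ms criterion. Each event is either a
#' single isolated spike or a burst of 2--5 spikes with 10--30 ms
#' inter-spike intervals (so burst spikes are never isolated). The
#' single-spike probability is solved from `isolated_fraction` and the event
#' rate from `baseline_rate_hz`, so the empirical isolated fraction and the
#' firing rate converge to their targets.
#'
#' @param params a [cell_params()] object.
#' @param duration_s recording duration (s).
#' @param seed integer seed.
#' @return A tibble with `time_s` (sorted) and the generating `event_id`.
#' @export
generate_spike_times <- function(params, duration_s, seed = 1) {
  stopifnot(inherits(params, "cell_params"))
  assert_scalar_number(duration_s, "duration_s", min = 1e-9)
  f <- params$isolated_fraction
  mean_burst <- mean(2:5)                      # 3.5
  p_single <- f * mean_burst / (1 - f + f * mean_burst)
  spikes_per_event <- p_single + (1 - p_single) * mean_burst
  rate <- params$baseline_rate_hz
  if (rate == 0) return(tibble(time_s = numeric(0), event_id = integer(0)))
  event_rate <- rate / spikes_per_event
  margin <- 0.25
  if (1 / event_rate <= margin + 0.01) {
    abort("`baseline_rate_hz` too high to respect the 250 ms isolation margin.")
  }
  lambda <- 1 / (1 / event_rate - margin)
  with_seed(seed, {
    t_cur <- stats::rexp(1, lambda)            # first event: no margin needed
    times <- numeric(0); events <- integer(0); ev <- 0L
    while (t_cur < duration_s) {
      ev <- ev + 1L
      if (runif(1) < p_single) {
        spk <- t_cur
      } else {
        len <- sample(2:5, 1)
        isis <- runif(len - 1, 0.010, 0.030)
        spk <- t_cur + c(0, cumsum(isis))
      }
      spk <- spk[spk < duration_s]
      times <- c(times, spk)
      events <- c(events, rep(ev, length(spk)))
      t_cur <- max(spk, t_cur) + margin + stats::rexp(1, lambda)
    }
    tibble(time_s = times, event_id = events)
  })
}

#' Generate a synthetic intracellular voltage trace
#'
#' Places analytic spike templates at event times from the two-state renewal
#' process (or at user-supplied times) on a constant baseline, and adds
#' Gaussian noise, emulating a membrane-potential recording sampled at
#' 20 kHz. The ground-truth spike times are returned alongside the trace so
#' detector and feature tests can score recovery.
#'
#' @param params a [cell_params()] object.
#' @param duration_s trial duration (s), default 10.
#' @param trial_meta named list carried as metadata (`cell_id`, `odor`,
#'   `trial`, ...).
#' @param seed integer seed.
#' @param rate_hz sampling rate, fixed default 20000.
#' @param spike_times optional numeric vector overriding the generated
#'   ground-truth spike times (s).
#' @return A list of class `al_trace` with elements `samples` (tibble
#'   `time_s`, `v_mv`), `rate_hz`, `truth` (tibble of ground-truth spike
#'   times), `params`, and `meta`.
#' @examples
#' tr <- generate_voltage_trace(cell_params("LN"), duration_s = 2, seed = 7)
#' nrow(tr$samples)
#' @export
generate_voltage_trace <- function(params, duration_s = 10, trial_meta = list(),
                                   seed = 1, rate_hz = 20000,
                                   spike_times = NULL) {
  stopifnot(inherits(params, "cell_params"))
  assert_scalar_number(duration_s, "duration_s", min = 1e-9)
  assert_scalar_number(rate_hz, "rate_hz", min = 1)
  if (is.null(spike_times)) {
    truth <- generate_spike_times(params, duration_s,
                                  seed = derive_seed(seed, "spike-times"))
    spike_times <- truth$time_s
  } else {
    stopifnot(is.numeric(spike_times), all(spike_times >= 0),
              all(spike_times <= duration_s))
    spike_times <- sort(spike_times)
    truth <- tibble(time_s = spike_times, event_id = seq_along(spike_times))
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  v <- rep(params$baseline_mv, n)
  half_support <- 0.040                        # template support: +-40 ms
  for (ts in spike_times) {
    i0 <- max(1L, floor((ts - half_support) * rate_hz) + 1L)
    i1 <- min(n, ceiling((ts + half_support) * rate_hz) + 1L)
    idx <- i0:i1
    v[idx] <- v[idx] + spike_template(t[idx] - ts,
                                      params$spike_amplitude_mv,
                                      params$spike_halfwidth_ms,
                                      params$ahp_depth_mv)
  }
  if (params$noise_sd_mv > 0) {
    v <- v + with_seed(derive_seed(seed, "trace-noise"),
                       rnorm(n, 0, params$noise_sd_mv))
  }
  structure(
    list(samples = tibble(time_s = t, v_mv = v),
         rate_hz = rate_hz,
         truth = truth,
         params = params,
         meta = trial_meta),
    class = "al_trace"
  )
}

#' @export
print.al_trace <- function(x, ...) {
  cat(sprintf("<al_trace> %.3f s at %g kHz, %d ground-truth spikes\n",
              nrow(x$samples) / x$rate_hz, x$rate_hz / 1000, nrow(x$truth)))
  invisible(x)
}
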