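#' Tuning specification for the population-response generator
#'
#' Describes a population of cells, a panel of odors, and the mean
#' odor-evoked rate change of every cell-odor pair. Responses are modeled as
#' a step increase (or decrease) of the firing rate inside the response
#' window, with optional per-pair onset delays, on top of a per-cell
#' spontaneous rate. This emulates trial-structured recordings where the
#' odor valve opens at 2 s for 1 s and the evoked response is scored in the
#' 2.1--4.1 s window.
#'
#' @param n_cells number of cells.
#' @param odor_names character vector of odor names (non-empty).
#' @param tuning_hz `n_cells x n_odors` matrix of mean rate changes (Hz)
#'   during the response window. Default 0 (no tuning).
#' @param baseline_hz per-cell spontaneous rates (recycled), default 9.5 Hz.
#' @param response_window seconds, default `c(2.0, 4.1)` (valve at 2 s; the
#'   evoked rate persists through the scored 2.1--4.1 s window).
#' @param onset_delay_s optional `n_cells x n_odors` matrix of extra onset
#'   delays (s, `>= 0`) added to the window start.
#' @param trial_noise `"poisson"` (counts drawn per bin), `"gaussian"`
#'   (rate jittered by `gaussian_sd` before rounding) or `"none"`
#'   (deterministic expected counts, for separability oracles).
#' @param gaussian_sd SD (Hz) for `trial_noise = "gaussian"`.
#' @param duration_s trial duration, default 10.
#' @param bin_s internal rate discretization, default 0.1 s.
#' @return A list of class `tuning_spec`.
#' @export
tuning_spec <- function(n_cells, odor_names, tuning_hz = NULL,
                        baseline_hz = 9.5, response_window = c(2.0, 4.1),
                        onset_delay_s = NULL,
                        trial_noise = c("poisson", "gaussian", "none"),
                        gaussian_sd = 1, duration_s = 10, bin_s = 0.1) {
  trial_noise <- match.arg(trial_noise)
  if (length(odor_names) == 0) abort("`odor_names` must be non-empty.")
  n_odors <- length(odor_names)
  if (is.null(tuning_hz)) tuning_hz <- matrix(0, n_cells, n_odors)
  tuning_hz <- as.matrix(tuning_hz)
  stopifnot(nrow(tuning_hz) == n_cells, ncol(tuning_hz) == n_odors)
  if (!is.null(onset_delay_s)) {
    onset_delay_s <- as.matrix(onset_delay_s)
    stopifnot(all(onset_delay_s >= 0),
              nrow(onset_delay_s) == n_cells, ncol(onset_delay_s) == n_odors)
  }
  baseline_hz <- rep_len(baseline_hz, n_cells)
  stopifnot(all(baseline_hz >= 0), duration_s >= response_window[2])
  structure(
    list(n_cells = n_cells, odor_names = odor_names, tuning_hz = tuning_hz,
         baseline_hz = baseline_hz, response_window = response_window,
         onset_delay_s = onset_delay_s, trial_noise = trial_noise,
         gaussian_sd = gaussian_sd, duration_s = duration_s, bin_s = bin_s),
    class = "tuning_spec"
  )
}

#' Generate trial-structured population spike times
#'
#' Draws spike times for every (cell, odor, trial) from a piecewise-constant
#' rate: per-cell background everywhere, plus the cell-odor tuning inside
#' the response window (delayed by the pair's onset delay, if any). Counts
#' per discretization bin follow the spec's trial-noise model; spike times
#' are uniform within their bin. Rates are clamped at zero, so inhibitory
#' tuning cannot produce negative rates.
#'
#' @param spec a [tuning_spec()].
#' @param n_trials trials per cell-odor pair (`>= 2`).
#' @param seed integer seed.
#' @return A tibble of class `al_spikes` with columns `cell_id`, `odor`,
#'   `trial`, `time_s`, and attributes `duration_s`, `odor_onset_s`, and
#'   `spec` (the generating ground truth).
#' @examples
#' spec <- tuning_spec(4, c("a", "b"),
#'                     tuning_hz = matrix(c(10, 0, 0, 10, 5, 5, 0, 0), 4, 2))
#' spk <- generate_population_responses(spec, n_trials = 3, seed = 1)
#' @export
generate_population_responses <- function(spec, n_trials = 7, seed = 1) {
  stopifnot(inherits(spec, "tuning_spec"))
  if (n_trials < 2) abort("`n_trials` must be >= 2.")
  n_bins <- round(spec$duration_s / spec$bin_s)
  bin_start <- (seq_len(n_bins) - 1) * spec$bin_s
  n_c <- spec$n_cells
  n_o <- length(spec$odor_names)
  cells <- sprintf("cell_%03d", seq_len(n_c))
  # per (cell, odor) binned rate, vectorized: mu[bin, ci, oi]
  mu <- array(0, dim = c(n_bins, n_c, n_o))
  for (oi in seq_len(n_o)) {
    w0 <- spec$response_window[1] +
      if (is.null(spec$onset_delay_s)) rep(0, n_c) else spec$onset_delay_s[, oi]
    w1 <- spec$response_window[2]
    for (ci in seq_len(n_c)) {
      rate <- rep(spec$baseline_hz[ci], n_bins)
      in_win <- bin_start >= w0[ci] & bin_start < w1
      rate[in_win] <- rate[in_win] + spec$tuning_hz[ci, oi]
      mu[, ci, oi] <- pmax(rate, 0) * spec$bin_s
    }
  }
  # expand over trials: index order bin (fastest), cell, odor, trial
  mu_all <- rep(as.vector(mu), n_trials)
  out <- with_seed(derive_seed(seed, "population"), {
    counts <- switch(spec$trial_noise,
      poisson  = rpois(length(mu_all), mu_all),
      gaussian = pmax(0L, as.integer(round(
        mu_all + rnorm(length(mu_all), 0, spec$gaussian_sd * spec$bin_s)))),
      none     = as.integer(round(mu_all))
    )
    total <- sum(counts)
    bin_idx <- rep(rep(seq_len(n_bins), n_c * n_o * n_trials), counts)
    ci_idx <- rep(rep(rep(seq_len(n_c), each = n_bins), n_o * n_trials), counts)
    oi_idx <- rep(rep(rep(seq_len(n_o), each = n_bins * n_c), n_trials), counts)
    tr_idx <- rep(rep(seq_len(n_trials), each = n_bins * n_c * n_o), counts)
    times <- bin_start[bin_idx] + runif(total, 0, spec$bin_s)
    tibble(cell_id = cells[ci_idx], odor = spec$odor_names[oi_idx],
           trial = tr_idx, time_s = times) |>
      arrange(.data$cell_id, .data$odor, .data$trial, .data$time_s)
  })
  structure(out,
            class = c("al_spikes", class(tibble())),
            duration_s = spec$duration_s, odor_onset_s = 2.0, spec = spec)
}

as_al_spikes <- function(x, duration_s = 10, odor_onset_s = 2.0) {
  stopifnot(all(c("cell_id", "odor", "trial", "time_s") %in% names(x)))
  structure(as_tibble(x), class = c("al_spikes", class(tibble())),
            duration_s = duration_s, odor_onset_s = odor_onset_s)
}
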