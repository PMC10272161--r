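#' Generate synthetic two-choice olfactometer experiments
#'
#' Emulates T-maze assays in which 18--20 female mosquitoes are released and
#' choose between an odorized and a control arm. The number of responders is
#' binomial in the released count, the odor-arm count binomial in the
#' responders, and the chamber covariates (temperature, relative humidity)
#' are drawn inside the valid ranges (25--30 degC, 45--80% RH) unless an
#' experiment is designated out-of-range, which lets tests exercise the
#' validity filter.
#'
#' @param n_experiments number of experiments.
#' @param odor odor label attached to every experiment.
#' @param n_released released mosquitoes per experiment; a single value or a
#'   range `c(lo, hi)` sampled uniformly (default `c(18, 20)`).
#' @param p_odor_arm probability that a responder chooses the odorized arm.
#' @param p_respond probability that a released mosquito responds (enters a
#'   side arm).
#' @param p_out_of_range probability that an experiment's covariates are
#'   drawn outside the valid ranges.
#' @param seed integer seed.
#' @return A tibble with one row per experiment: `experiment`, `odor`,
#'   `n_released`, `n_odor_arm`, `n_control_arm`, `n_nonresponding`,
#'   `temperature_c`, `humidity_rh`, `odor_side`.
#' @examples
#' generate_behavior_counts(3, "1-octen-3-ol", p_odor_arm = 0.3, seed = 1)
#' @export
generate_behavior_counts <- function(n_experiments, odor = "odor",
                                     n_released = c(18, 20),
                                     p_odor_arm = 0.5, p_respond = 0.8,
                                     p_out_of_range = 0, seed = 1) {
  assert_scalar_number(p_odor_arm, "p_odor_arm", 0, 1)
  assert_scalar_number(p_respond, "p_respond", 0, 1)
  assert_scalar_number(p_out_of_range, "p_out_of_range", 0, 1)
  stopifnot(n_experiments >= 1)
  if (length(n_released) == 1) n_released <- rep(n_released, 2)
  with_seed(derive_seed(seed, "behavior"), {
    released <- sample(n_released[1]:n_released[2], n_experiments, replace = TRUE)
    responders <- rbinom(n_experiments, released, p_respond)
    n_odor <- rbinom(n_experiments, responders, p_odor_arm)
    out_of_range <- runif(n_experiments) < p_out_of_range
    temp <- ifelse(out_of_range, sample(c(23, 32), n_experiments, TRUE),
                   runif(n_experiments, 25.5, 29.5))
    rh <- ifelse(out_of_range, sample(c(40, 85), n_experiments, TRUE),
                 runif(n_experiments, 50, 75))
    tibble(
      experiment = seq_len(n_experiments),
      odor = odor,
      n_released = released,
      n_odor_arm = n_odor,
      n_control_arm = responders - n_odor,
      n_nonresponding = released - responders,
      temperature_c = temp,
      humidity_rh = rh,
      odor_side = sample(c("left", "right"), n_experiments, replace = TRUE)
    )
  })
}
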