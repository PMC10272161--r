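#' Generate a feature-level PN/LN cohort
#'
#' Samples the four electrophysiological features directly around the PN
#' and LN class regimes (the same targets [cell_params()] gives the trace
#' generator), bypassing trace synthesis. This is the fast path for
#' experiments that need many cells or many seeded cohorts — e.g. clustering
#' parameter-recovery over repeated draws — while
#' [generate_voltage_trace()] plus [extract_features()] exercises the full
#' measurement chain on fewer cells. Class labels are carried as ground
#' truth, and the default relative spread reflects the separation at which
#' the two classes are recoverable but not trivially so.
#'
#' @param n_pn,n_ln cells per class.
#' @param rel_sd relative SD of each feature around its class mean,
#'   default 0.08.
#' @param seed integer seed.
#' @return A tibble with `cell_id`, the four feature columns,
#'   `truth_label`, and `quality` (= 5).
#' @examples
#' generate_feature_cohort(5, 3, seed = 1)
#' @export
generate_feature_cohort <- function(n_pn = 30, n_ln = 15, rel_sd = 0.08,
                                    seed = 1) {
  assert_scalar_number(rel_sd, "rel_sd", min = 0)
  pn <- cell_params("PN"); ln <- cell_params("LN")
  draw <- function(n, p, prefix) {
    tibble(
      cell_id = sprintf("%s_%02d", prefix, seq_len(n)),
      amplitude_mv = rnorm(n, p$spike_amplitude_mv,
                           p$spike_amplitude_mv * rel_sd),
      half_width_ms = rnorm(n, p$spike_halfwidth_ms,
                            p$spike_halfwidth_ms * rel_sd),
      ahp_mv = rnorm(n, p$ahp_depth_mv, abs(p$ahp_depth_mv) * rel_sd),
      isolated_fraction = pmin(1, pmax(0, rnorm(
        n, p$isolated_fraction,
        max(0.03, p$isolated_fraction * rel_sd * 2)))),
      truth_label = p$class_label,
      quality = 5
    )
  }
  with_seed(derive_seed(seed, "feature-cohort"), {
    bind_rows(draw(n_pn, pn, "PN"), draw(n_ln, ln, "LN"))
  })
}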