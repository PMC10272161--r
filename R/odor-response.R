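# Odor-evoked rate changes, the signed-rank responder criterion, activated
# fractions, and response-vector correlations. All windows are half-open
# [a, b): background [0, 2) s, response [2.1, 4.1) s (the odor valve opens
# at 2 s for 1 s; the extra 100 ms allows for odor transit, and the 2 s
# response window captures responses outlasting the stimulus).

#' Odor-evoked firing-rate change of one trial
#'
#' Spike count in the response window divided by its length, minus the same
#' for the background window. Windows are half-open.
#'
#' @param spike_times numeric spike times of one trial (s).
#' @param background,response `c(start, end)` seconds.
#' @param duration_s trial duration; must cover the response window.
#' @return Rate change in Hz.
#' @examples
#' trial_rate_change(c(runif(10, 0, 2), runif(30, 2.1, 4.1)))
#' @export
trial_rate_change <- function(spike_times, background = c(0, 2.0),
                              response = c(2.1, 4.1), duration_s = 10) {
  if (duration_s < response[2]) {
    abort(sprintf("Trial duration %.2f s is shorter than the response window end %.2f s.",
                  duration_s, response[2]))
  }
  count_in_window(spike_times, response[1], response[2]) / diff(response) -
    count_in_window(spike_times, background[1], background[2]) / diff(background)
}

# per-(cell, odor, trial) rate changes for a spike table
trial_rate_changes <- function(spikes, background = c(0, 2.0),
                               response = c(2.1, 4.1)) {
  duration <- attr(spikes, "duration_s") %||% 10
  spikes |>
    group_by(.data$cell_id, .data$odor, .data$trial) |>
    summarise(dr_hz = trial_rate_change(.data$time_s, background, response,
                                        duration),
              .groups = "drop")
}

#' Mean odor response per cell-odor pair
#'
#' Trial rate changes averaged over all trials available for the pair.
#' Pairs never tested are simply absent from the output (no implicit
#' zeros).
#'
#' @param spikes an `al_spikes` tibble (`cell_id`, `odor`, `trial`,
#'   `time_s`, attribute `duration_s`).
#' @param background,response scoring windows (s), half-open.
#' @return Tibble `cell_id`, `odor`, `mean_dr_hz`, `n_trials`.
#' @export
mean_response <- function(spikes, background = c(0, 2.0),
                          response = c(2.1, 4.1)) {
  trial_rate_changes(spikes, background, response) |>
    group_by(.data$cell_id, .data$odor) |>
    summarise(mean_dr_hz = mean(.data$dr_hz), n_trials = n(),
              .groups = "drop")
}

#' Responder criterion for cell-odor pairs
#'
#' The response window is split into two 1-s bins; the firing rate of each
#' bin is compared across trials to the same trials' background rate with
#' the exact paired two-sided Wilcoxon signed-rank test. A pair responds if
#' either bin's p-value is below `alpha`. The direction is `"excited"` or
#' `"inhibited"` by the sign of the significant bins' median rate
#' difference, `"mixed"` when the two bins are significant with opposite
#' signs, and `"none"` for non-responders. Pairs with fewer than 6 trials
#' cannot reach p < 0.05 and are reported non-responding with a warning.
#' No multiple-testing correction is applied across pairs.
#'
#' @param spikes an `al_spikes` tibble.
#' @param alpha significance level, default 0.05.
#' @param background background window (s).
#' @param bins list of the two response bins (s), default
#'   `list(c(2.1, 3.1), c(3.1, 4.1))`.
#' @return Tibble `cell_id`, `odor`, `p_bin1`, `p_bin2`, `responding`,
#'   `direction`, `n_trials`.
#' @export
responder_test <- function(spikes, alpha = 0.05, background = c(0, 2.0),
                           bins = list(c(2.1, 3.1), c(3.1, 4.1))) {
  rates <- spikes |>
    group_by(.data$cell_id, .data$odor, .data$trial) |>
    summarise(
      bg = count_in_window(.data$time_s, background[1], background[2]) /
        diff(background),
      b1 = count_in_window(.data$time_s, bins[[1]][1], bins[[1]][2]) /
        diff(bins[[1]]),
      b2 = count_in_window(.data$time_s, bins[[2]][1], bins[[2]][2]) /
        diff(bins[[2]]),
      .groups = "drop")
  few <- 0L
  out <- rates |>
    group_by(.data$cell_id, .data$odor) |>
    summarise(
      n_trials = n(),
      p_bin1 = signed_rank_stat(.data$b1, .data$bg)$p_value,
      p_bin2 = signed_rank_stat(.data$b2, .data$bg)$p_value,
      d1 = median(.data$b1 - .data$bg),
      d2 = median(.data$b2 - .data$bg),
      .groups = "drop")
  if (any(out$n_trials < 6)) {
    warn(sprintf("%d cell-odor pair(s) have fewer than 6 trials; reported non-responding.",
                 sum(out$n_trials < 6)))
  }
  out |>
    mutate(
      s1 = .data$p_bin1 < alpha & .data$n_trials >= 6,
      s2 = .data$p_bin2 < alpha & .data$n_trials >= 6,
      responding = .data$s1 | .data$s2,
      direction = dplyr::case_when(
        !.data$responding ~ "none",
        .data$s1 & .data$s2 & sign(.data$d1) != sign(.data$d2) ~ "mixed",
        (.data$s1 & .data$d1 < 0) | (!.data$s1 & .data$d2 < 0) ~ "inhibited",
        TRUE ~ "excited")) |>
    select("cell_id", "odor", "p_bin1", "p_bin2", "responding",
           "direction", "n_trials")
}

#' Fraction of tested odors to which each cell responds
#'
#' Cells tested with fewer than `min_odors` odors are excluded (listed in
#' the `excluded` attribute, not an error). With `by` set to a cell
#' metadata column (e.g. glomerulus), cell fractions are averaged over the
#' cells sharing each value, as done for homotypic PNs.
#'
#' @param responders output of [responder_test()].
#' @param min_odors minimum odors tested per cell, default 5.
#' @param cells optional tibble of cell metadata (`cell_id`, ...).
#' @param by optional column of `cells` to average within.
#' @return Tibble of fractions (per cell, or per `by` group).
#' @export
fraction_odors_responded <- function(responders, min_odors = 5,
                                     cells = NULL, by = NULL) {
  per_cell <- responders |>
    group_by(.data$cell_id) |>
    summarise(n_odors = n(), fraction = mean(.data$responding),
              .groups = "drop")
  excluded <- filter(per_cell, .data$n_odors < min_odors)
  per_cell <- filter(per_cell, .data$n_odors >= min_odors)
  if (!is.null(by)) {
    if (is.null(cells)) abort("`cells` metadata needed for `by` grouping.")
    per_cell <- per_cell |>
      left_join(cells, by = "cell_id") |>
      group_by(.data[[by]]) |>
      summarise(fraction = mean(.data$fraction), n_cells = n(),
                .groups = "drop")
  }
  attr(per_cell, "excluded") <- excluded
  per_cell
}

#' Fraction of cells activated by each odor
#'
#' Responding cells over tested cells per odor, computed separately per
#' cell class when `cells` provides a `class_label`.
#'
#' @param responders output of [responder_test()].
#' @param cells optional tibble `cell_id`, `class_label`.
#' @return Tibble `odor` (and `class_label`), `fraction`, `n_tested`.
#' @export
fraction_cells_activated <- function(responders, cells = NULL) {
  x <- responders
  if (!is.null(cells)) x <- left_join(x, cells, by = "cell_id")
  grp <- if ("class_label" %in% names(x)) c("odor", "class_label") else "odor"
  x |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(fraction = mean(.data$responding), n_tested = n(),
              .groups = "drop")
}

#' Correlation between PN and LN activated fractions across odors
#'
#' Tests whether odors that recruit many PNs also recruit many LNs, i.e.
#' whether some odors elicit more widespread antennal-lobe activity.
#'
#' @param fractions output of [fraction_cells_activated()] with a
#'   `class_label` column containing `"PN"` and `"LN"`.
#' @return One-row tibble `r`, `p_value`, `n_odors`.
#' @export
pn_ln_fraction_correlation <- function(fractions) {
  wide <- fractions |>
    select("odor", "class_label", "fraction") |>
    pivot_wider(names_from = "class_label", values_from = "fraction") |>
    filter(is.finite(.data$PN), is.finite(.data$LN))
  if (nrow(wide) < 3) abort("Need at least 3 odors tested in both classes.")
  ct <- stats::cor.test(wide$PN, wide$LN)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_odors = nrow(wide))
}

#' Pairwise correlations of cells' odor-response vectors
#'
#' For cells tested with the full odor panel, computes the Pearson
#' correlation of every pair of response vectors and compares two groups of
#' pairs (e.g. homotypic vs heterotypic PNs, via a `group` labeling of the
#' cells) with a two-sided rank-sum test. Pairs with a constant response
#' vector are excluded and listed in the `excluded_pairs` attribute.
#'
#' @param responses output of [mean_response()].
#' @param panel character vector of odors every cell must have been tested
#'   with.
#' @param groups named character vector (names = cell ids) labeling cells
#'   (e.g. by glomerulus); pairs sharing a label are "within", others
#'   "between".
#' @return A list of class `al_response_cor`: `pairs` tibble (`cell_a`,
#'   `cell_b`, `r`, `pair`), `group_means`, `p_value` (within vs between).
#' @export
response_vector_correlations <- function(responses, panel, groups = NULL) {
  wide <- responses |>
    filter(.data$odor %in% panel) |>
    select("cell_id", "odor", "mean_dr_hz") |>
    pivot_wider(names_from = "odor", values_from = "mean_dr_hz")
  incomplete <- wide$cell_id[!complete.cases(wide[panel])]
  missing_odor <- setdiff(panel, names(wide))
  if (length(missing_odor) || length(incomplete)) {
    abort(sprintf("Cells not tested with the full panel: %s",
                  paste(c(incomplete, missing_odor), collapse = ", ")))
  }
  x <- as.matrix(wide[panel])
  rownames(x) <- wide$cell_id
  up <- which(upper.tri(diag(nrow(x))), arr.ind = TRUE)
  r <- vapply(seq_len(nrow(up)), function(i) {
    a <- x[up[i, 1], ]; b <- x[up[i, 2], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  pairs <- tibble(cell_a = rownames(x)[up[, 1]],
                  cell_b = rownames(x)[up[, 2]], r = r)
  if (!is.null(groups)) {
    pairs$pair <- ifelse(groups[pairs$cell_a] == groups[pairs$cell_b],
                         "within", "between")
  } else {
    pairs$pair <- NA_character_
  }
  excluded <- filter(pairs, !is.finite(.data$r))
  pairs <- filter(pairs, is.finite(.data$r))
  gm <- NULL; p <- NA_real_
  if (!is.null(groups)) {
    gm <- pairs |>
      group_by(.data$pair) |>
      summarise(mean_r = mean(.data$r), sd_r = sd(.data$r), n = n(),
                .groups = "drop")
    w <- pairs$r[pairs$pair == "within"]
    b <- pairs$r[pairs$pair == "between"]
    if (length(w) > 0 && length(b) > 0) {
      p <- suppressWarnings(wilcox.test(w, b)$p.value)
    }
  }
  structure(list(pairs = pairs, group_means = gm, p_value = p),
            class = "al_response_cor", excluded_pairs = excluded)
}

#' @export
print.al_response_cor <- function(x, ...) {
  cat(sprintf("<al_response_cor> %d pairs; within-vs-between p = %s\n",
              nrow(x$pairs), format(x$p_value, digits = 3)))
  if (!is.null(x$group_means)) print(x$group_means)
  invisible(x)
}
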