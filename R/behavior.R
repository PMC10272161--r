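# Two-choice olfactometer preference indices, experiment validity
# filtering, per-odor significance, and the behavior-PN correlation.

#' Preference index of a two-arm choice experiment
#'
#' `(N_odor - N_control) / (N_odor + N_control)`, in `[-1, 1]`; positive
#' means attraction to the odorized arm. Vectorized; experiments with no
#' responder in either arm are undefined (`NA`).
#'
#' @param n_odor,n_control mosquito counts in the odorized and control arm.
#' @return Numeric preference indices.
#' @examples
#' preference_index(10, 5)   # 1/3
#' @export
preference_index <- function(n_odor, n_control) {
  stopifnot(all(n_odor >= 0, na.rm = TRUE), all(n_control >= 0, na.rm = TRUE))
  total <- n_odor + n_control
  ifelse(total > 0, (n_odor - n_control) / total, NA_real_)
}

#' Filter behavioral experiments by validity criteria
#'
#' Keeps experiments with at least `min_responders` responding mosquitoes
#' (those that entered either side arm) and chamber covariates inside the
#' valid ranges; bounds are inclusive at both ends. Excluded experiments
#' and their reasons are recorded in the `exclusions` attribute.
#'
#' @param experiments tibble with `n_odor_arm`, `n_control_arm`,
#'   `temperature_c`, `humidity_rh` (see [generate_behavior_counts()]).
#' @param min_responders minimum responding count, default 5.
#' @param temp_range,humidity_range inclusive valid ranges, defaults
#'   25--30 degC and 45--80% RH.
#' @return The valid subset, with attribute `exclusions`.
#' @export
validity_filter <- function(experiments, min_responders = 5,
                            temp_range = c(25, 30),
                            humidity_range = c(45, 80)) {
  responders <- experiments$n_odor_arm + experiments$n_control_arm
  reason <- dplyr::case_when(
    responders < min_responders ~ sprintf("responders %d < %d", responders,
                                          min_responders),
    experiments$temperature_c < temp_range[1] |
      experiments$temperature_c > temp_range[2] ~
      sprintf("temperature %.1f out of range", experiments$temperature_c),
    experiments$humidity_rh < humidity_range[1] |
      experiments$humidity_rh > humidity_range[2] ~
      sprintf("humidity %.1f out of range", experiments$humidity_rh),
    TRUE ~ NA_character_)
  keep <- is.na(reason)
  out <- experiments[keep, , drop = FALSE]
  attr(out, "exclusions") <- mutate(experiments[!keep, , drop = FALSE],
                                    reason = reason[!keep])
  out
}

#' Per-odor preference index and significance
#'
#' Mean preference index over valid experiments of one odor, with the
#' exact two-sided signed-rank test of the per-experiment PIs against
#' zero. Fewer than 6 experiments cannot reach p < 0.05; the mean is
#' still reported but the p-value is `NA` with a warning.
#'
#' @param pis numeric per-experiment preference indices for one odor.
#' @return One-row tibble: `mean_pi`, `sd_pi`, `p_value`, `n`.
#' @export
odor_pi_test <- function(pis) {
  pis <- pis[is.finite(pis)]
  n <- length(pis)
  if (n < 6) {
    warn(sprintf("Only %d experiments; the signed-rank test cannot reach p < 0.05.", n))
    return(tibble(mean_pi = mean(pis), sd_pi = sd(pis),
                  p_value = NA_real_, n = n))
  }
  sr <- signed_rank_test(pis, 0)
  tibble(mean_pi = mean(pis), sd_pi = sd(pis), p_value = sr$p_value, n = n)
}

#' PN-response distance between two odors
#'
#' Concatenates the mean responses of the PNs recorded with both odors and
#' returns `1 - R` (Pearson), the population distance used against the
#' behavioral PI difference. Optionally a seeded random subsample of the
#' common PNs is used.
#'
#' @param responses output of [mean_response()] (columns `cell_id`,
#'   `odor`, `mean_dr_hz`).
#' @param odor_a,odor_b odor names.
#' @param n_subsample optional number of common PNs to subsample.
#' @param seed integer seed for the subsample.
#' @param min_common minimum common PNs, default 3; pairs below it return
#'   `NA` distance (skipped, not an error).
#' @return One-row tibble: `odor_a`, `odor_b`, `pn_distance`,
#'   `n_common_pns`.
#' @export
behavior_pn_distance <- function(responses, odor_a, odor_b,
                                 n_subsample = NULL, seed = 1,
                                 min_common = 3) {
  wide <- responses |>
    filter(.data$odor %in% c(odor_a, odor_b)) |>
    select("cell_id", "odor", "mean_dr_hz") |>
    pivot_wider(names_from = "odor", values_from = "mean_dr_hz")
  if (!all(c(odor_a, odor_b) %in% names(wide))) {
    return(tibble(odor_a = odor_a, odor_b = odor_b,
                  pn_distance = NA_real_, n_common_pns = 0L))
  }
  wide <- filter(wide, is.finite(.data[[odor_a]]), is.finite(.data[[odor_b]]))
  n_common <- nrow(wide)
  if (!is.null(n_subsample) && n_subsample < n_common) {
    idx <- with_seed(derive_seed(seed, paste(odor_a, odor_b, sep = "|")),
                     sample.int(n_common, n_subsample))
    wide <- wide[idx, ]
  } else if (!is.null(n_subsample) && n_subsample > n_common) {
    return(tibble(odor_a = odor_a, odor_b = odor_b,
                  pn_distance = NA_real_, n_common_pns = n_common))
  }
  if (nrow(wide) < min_common ||
      sd(wide[[odor_a]]) == 0 || sd(wide[[odor_b]]) == 0) {
    return(tibble(odor_a = odor_a, odor_b = odor_b,
                  pn_distance = NA_real_, n_common_pns = n_common))
  }
  tibble(odor_a = odor_a, odor_b = odor_b,
         pn_distance = 1 - cor(wide[[odor_a]], wide[[odor_b]]),
         n_common_pns = n_common)
}

#' Correlation between behavioral preference differences and PN distances
#'
#' For every odor pair, the absolute difference of mean preference indices
#' is correlated (Pearson) with the PN-response distance `1 - R` over the
#' PNs common to the pair. Pairs with too few common PNs or undefined
#' distance are skipped and listed in the `skipped` attribute.
#'
#' @param pi_table tibble `odor`, `mean_pi` (one row per odor).
#' @param responses output of [mean_response()].
#' @param n_subsample,seed optional per-pair common-PN subsampling, see
#'   [behavior_pn_distance()].
#' @return A list of class `al_behavior_cor`: `r`, `p_value`, `n_pairs`,
#'   `pair_stats` tibble.
#' @export
behavior_pn_correlation <- function(pi_table, responses, n_subsample = NULL,
                                    seed = 1) {
  odors <- pi_table$odor
  if (length(odors) < 3) abort("Need at least 3 odors.")
  combs <- utils::combn(odors, 2)
  stats_tbl <- list_rbind(map(seq_len(ncol(combs)), function(i) {
    behavior_pn_distance(responses, combs[1, i], combs[2, i],
                         n_subsample = n_subsample, seed = seed)
  }))
  pi_of <- setNames(pi_table$mean_pi, pi_table$odor)
  stats_tbl <- mutate(stats_tbl,
                      delta_pi = abs(unname(pi_of[.data$odor_a]) -
                                       unname(pi_of[.data$odor_b])))
  ok <- is.finite(stats_tbl$pn_distance) & is.finite(stats_tbl$delta_pi)
  used <- stats_tbl[ok, ]
  if (nrow(used) < 3 || sd(used$delta_pi) == 0 || sd(used$pn_distance) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(used$delta_pi, used$pn_distance)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(r = r, p_value = p, n_pairs = nrow(used),
                 pair_stats = used),
            class = "al_behavior_cor", skipped = stats_tbl[!ok, ])
}

#' @export
print.al_behavior_cor <- function(x, ...) {
  cat(sprintf("<al_behavior_cor> R = %s, p = %s over %d odor pairs\n",
              format(x$r, digits = 3), format(x$p_value, digits = 3),
              x$n_pairs))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.al_behavior_cor <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_pairs = x$n_pairs)
}

#' Behavior-PN correlation versus PN population size
#'
#' Recomputes the behavior-PN correlation with each odor pair's common PNs
#' subsampled to `n`, averaging over seeded repeats, for every `n` in
#' `n_grid`; pairs with fewer than `n` common PNs are ignored at that `n`.
#' The trend is summarized as the Pearson correlation of the mean curve
#' with `n`.
#'
#' @param pi_table tibble `odor`, `mean_pi`.
#' @param responses output of [mean_response()].
#' @param n_grid PN counts to evaluate.
#' @param repeats subsampling repeats per count, default 20.
#' @param seed integer seed.
#' @return A list of class `al_behavior_curve`: `curve` tibble (`n_pns`,
#'   `mean_r`, `n_pairs`), `trend_r`.
#' @export
correlation_vs_npns <- function(pi_table, responses, n_grid, repeats = 20,
                                seed = 1) {
  stopifnot(all(n_grid >= 1))
  rows <- list_rbind(map(n_grid, function(nn) {
    rs <- map(seq_len(repeats), function(rep_i) {
      bc <- behavior_pn_correlation(pi_table, responses, n_subsample = nn,
                                    seed = derive_seed(seed, paste0("npns", nn, "_", rep_i)))
      tibble(r = bc$r, n_pairs = bc$n_pairs)
    }) |> list_rbind()
    tibble(n_pns = nn, mean_r = mean(rs$r, na.rm = TRUE),
           n_pairs = round(mean(rs$n_pairs)))
  }))
  ok <- is.finite(rows$mean_r)
  if (!any(ok)) {
    warn("No population size yielded a defined correlation.")
    trend <- NA_real_
  } else if (sum(ok) >= 3 && sd(rows$mean_r[ok]) > 0) {
    trend <- unname(cor(rows$n_pns[ok], rows$mean_r[ok]))
  } else {
    trend <- NA_real_
  }
  structure(list(curve = rows, trend_r = trend),
            class = "al_behavior_curve")
}

#' @export
print.al_behavior_curve <- function(x, ...) {
  cat(sprintf("<al_behavior_curve> %d sizes, trend r = %s\n",
              nrow(x$curve), format(x$trend_r, digits = 3)))
  invisible(x)
}
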