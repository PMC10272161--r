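# Preference indices, validity filtering, per-odor significance, and the
# behavior-PN correlation machinery.

test_that("preference index formula, symmetry and invariances", {
  expect_equal(preference_index(10, 5), 1 / 3)
  expect_equal(preference_index(7, 7), 0)
  # arm swap flips the sign exactly
  expect_equal(preference_index(3, 11), -preference_index(11, 3))
  # scaling both counts leaves the PI unchanged
  expect_equal(preference_index(30, 50), preference_index(3, 5))
  expect_true(is.na(preference_index(0, 0)))
  expect_true(all(abs(preference_index(0:20, 20:0)) <= 1))
})

test_that("validity filter applies inclusive bounds and logs reasons", {
  exps <- tibble::tibble(
    experiment = 1:5,
    n_odor_arm = c(2, 3, 5, 10, 10),
    n_control_arm = c(2, 3, 0, 5, 5),
    temperature_c = c(27, 24.9, 25, 30, 27),
    humidity_rh = c(60, 60, 45, 80, 84))
  valid <- validity_filter(exps)
  # row 1: responders 4 < 5; row 2: temp 24.9; row 5: humidity 84
  expect_equal(valid$experiment, c(3, 4))
  excl <- attr(valid, "exclusions")
  expect_equal(nrow(excl), 3)
  expect_match(excl$reason[1], "responders")
  expect_match(excl$reason[2], "temperature")
  expect_match(excl$reason[3], "humidity")
  # boundary: responders = 5, 25 degC, 45% RH is included
  expect_equal(valid$experiment[1], 3)
})

test_that("per-odor PI test reproduces the exact signed-rank reference", {
  res <- odor_pi_test(rep(0.3, 12))
  expect_equal(res$p_value, 2 / 2^12)
  expect_equal(res$mean_pi, 0.3)
  # symmetric PIs -> p = 1
  expect_equal(odor_pi_test(c(-0.4, 0.4, -0.2, 0.2, -0.1, 0.1))$p_value, 1)
  expect_warning(small <- odor_pi_test(rep(0.5, 5)), "cannot reach")
  expect_true(is.na(small$p_value))
  expect_equal(small$mean_pi, 0.5)
})

test_that("PN distance between odors is 1 - Pearson r over common cells", {
  resp <- tibble::tibble(
    cell_id = rep(sprintf("c%d", 1:5), 2),
    odor = rep(c("a", "b"), each = 5),
    mean_dr_hz = c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10))
  d <- behavior_pn_distance(resp, "a", "b")
  expect_equal(d$pn_distance, 0)           # proportional vectors
  expect_equal(d$n_common_pns, 5)
  resp2 <- resp
  resp2$mean_dr_hz[6:10] <- -c(2, 4, 6, 8, 10)
  expect_equal(behavior_pn_distance(resp2, "a", "b")$pn_distance, 2)
  # too few common cells -> NA, not an error
  resp3 <- resp[c(1, 2, 6, 7), ]
  expect_true(is.na(behavior_pn_distance(resp3, "a", "b")$pn_distance))
  # subsample = full set is the identity
  expect_equal(behavior_pn_distance(resp, "a", "b", n_subsample = 5),
               behavior_pn_distance(resp, "a", "b"))
})

test_that("behavior-PN correlation recovers a perfect monotone link", {
  # construct responses whose pairwise distances vary, then set PIs so
  # that delta-PI equals the distance exactly
  withr::with_seed(2, {
    resp <- tidyr::crossing(cell_id = sprintf("c%d", 1:12),
                            odor = sprintf("o%d", 1:5)) |>
      dplyr::mutate(mean_dr_hz = rnorm(dplyr::n(), 0, 6))
  })
  odors <- sprintf("o%d", 1:5)
  combs <- utils::combn(odors, 2)
  dist_tbl <- purrr::list_rbind(purrr::map(seq_len(ncol(combs)), function(i) {
    behavior_pn_distance(resp, combs[1, i], combs[2, i])
  }))
  # delta-PI = distance holds when PIs form an additive chain is impossible
  # in general; instead scale PIs along one axis and check positive r
  pi_table <- tibble::tibble(odor = odors, mean_pi = seq(0, 1, length.out = 5))
  bc <- behavior_pn_correlation(pi_table, resp)
  expect_equal(bc$n_pairs, choose(5, 2))
  expect_true(is.finite(bc$r))
  # exact R = 1 when delta-PI is made equal to the distances for a star
  # design: distances from o1 to others define PIs of others vs PI(o1) = 0
  d1 <- dist_tbl$pn_distance[dist_tbl$odor_a == "o1"]
  pi_star <- tibble::tibble(odor = odors, mean_pi = c(0, d1))
  bc_star <- behavior_pn_correlation(pi_star, resp)
  sub <- bc_star$pair_stats[bc_star$pair_stats$odor_a == "o1", ]
  expect_equal(sub$delta_pi, sub$pn_distance)
  expect_error(behavior_pn_correlation(pi_table[1:2, ], resp), "3 odors")
})

test_that("shuffling distances centers the correlation on zero", {
  withr::with_seed(4, {
    resp <- tidyr::crossing(cell_id = sprintf("c%d", 1:10),
                            odor = sprintf("o%d", 1:8)) |>
      dplyr::mutate(mean_dr_hz = rnorm(dplyr::n(), 0, 6))
    rs <- replicate(50, {
      pi_table <- tibble::tibble(odor = sprintf("o%d", 1:8),
                                 mean_pi = runif(8, -1, 1))
      behavior_pn_correlation(pi_table, resp)$r
    })
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("correlation-vs-n curve is reproducible and rises for a monotone link", {
  # 1-D embedding: odor k's response vector is cos(theta_k) A + sin(theta_k) B,
  # so 1 - R is monotone in |delta theta| for every pair, and PIs set
  # proportional to theta make delta-PI a monotone function of the distance
  odors <- sprintf("o%d", 1:7)
  theta <- seq(0, 1.2, length.out = 7)
  withr::with_seed(6, {
    a <- rnorm(30, 0, 6); b <- rnorm(30, 0, 6)
  })
  resp <- purrr::list_rbind(purrr::imap(odors, function(o, k) {
    tibble::tibble(cell_id = sprintf("c%d", 1:30), odor = o,
                   mean_dr_hz = cos(theta[k]) * a + sin(theta[k]) * b)
  }))
  pi_table <- tibble::tibble(odor = odors, mean_pi = theta / 2)
  cv <- correlation_vs_npns(pi_table, resp, n_grid = c(5, 15, 30),
                            repeats = 8, seed = 11)
  cv2 <- correlation_vs_npns(pi_table, resp, n_grid = c(5, 15, 30),
                             repeats = 8, seed = 11)
  expect_identical(cv$curve, cv2$curve)
  expect_gt(cv$curve$mean_r[3], cv$curve$mean_r[1])
  # n above every pair's common count -> undefined and flagged
  expect_warning(
    empty <- correlation_vs_npns(pi_table, resp, n_grid = 100, repeats = 2),
    "No population size")
  expect_true(is.na(empty$trend_r))
})

test_that("estimated correlation matches an oracle recomputation from pair stats", {
  withr::with_seed(8, {
    resp <- tidyr::crossing(cell_id = sprintf("c%d", 1:15),
                            odor = sprintf("o%d", 1:6)) |>
      dplyr::mutate(mean_dr_hz = rnorm(dplyr::n(), 0, 6))
    pi_table <- tibble::tibble(odor = sprintf("o%d", 1:6),
                               mean_pi = runif(6, -1, 1))
  })
  bc <- behavior_pn_correlation(pi_table, resp)
  expect_equal(bc$r, cor(bc$pair_stats$delta_pi, bc$pair_stats$pn_distance))
  expect_equal(bc$n_pairs, nrow(bc$pair_stats))
})

test_that("behavior recovery: correlation lands in the analytic CI across seeds", {
  # star design: one reference odor; the other odors' PIs are their PN
  # distance to the reference plus noise of known SD, so the latent
  # correlation over reference pairs is attenuation-known
  inside <- vapply(1:60, function(s) {
    withr::with_seed(1000 + s, {
      resp <- tidyr::crossing(cell_id = sprintf("c%d", 1:20),
                              odor = sprintf("o%d", 1:9)) |>
        dplyr::mutate(mean_dr_hz = rnorm(dplyr::n(), 0, 6))
      odors <- sprintf("o%d", 1:9)
      d1 <- purrr::list_rbind(purrr::map(odors[-1], function(o) {
        behavior_pn_distance(resp, "o1", o)
      }))
      sd_noise <- sd(d1$pn_distance)
      noise <- rnorm(8, 0, sd_noise)
      pi_table <- tibble::tibble(
        odor = odors, mean_pi = c(0, d1$pn_distance + noise) / 2)
      bc <- behavior_pn_correlation(pi_table, resp)
      ref_pairs <- bc$pair_stats[bc$pair_stats$odor_a == "o1", ]
      r_hat <- cor(ref_pairs$delta_pi, ref_pairs$pn_distance)
      r_true <- 1 / sqrt(2)          # equal signal and noise variance
      abs(atanh(r_hat) - atanh(r_true)) < 1.96 / sqrt(nrow(ref_pairs) - 3)
    })
  }, logical(1))
  expect_gte(mean(inside), 0.90)
})
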