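# Spike detection, isolation labeling, the four features, the
# spike-triggered average and the epoch comparison.

test_that("detector recovers noiseless template spikes exactly", {
  times <- seq(0.5, 9.5, by = 1)          # 10 spikes, well separated
  p <- cell_params("PN", noise_sd_mv = 0)
  tr <- generate_voltage_trace(p, duration_s = 10, seed = 1,
                               spike_times = times)
  det <- detect_spikes(tr)
  expect_equal(nrow(det), 10)
  expect_true(all(abs(det$time_s - times) <= 0.00025))
})

test_that("two spikes 2 ms apart are both detected with a 1 ms refractory", {
  p <- cell_params("LN", noise_sd_mv = 0)
  tr <- generate_voltage_trace(p, duration_s = 2, seed = 1,
                               spike_times = c(1.0, 1.002))
  det <- detect_spikes(tr, detector_config(refractory_s = 0.001))
  expect_equal(nrow(det), 2)
})

test_that("detection degrades gracefully but stays reliable at the default noise", {
  times <- seq(0.4, 9.6, by = 0.4)
  p <- cell_params("PN", noise_sd_mv = 0.5)
  tr <- generate_voltage_trace(p, duration_s = 10, seed = 2,
                               spike_times = times)
  det <- detect_spikes(tr)
  hits <- sum(vapply(times, function(ts) any(abs(det$time_s - ts) < 0.001),
                     logical(1)))
  expect_gte(hits / length(times), 0.99)                 # recall
  expect_lte(nrow(det) - hits, 1)                        # false alarms
})

test_that("isolation labeling follows the 200 ms rule with exclusive boundary", {
  expect_equal(classify_isolated(c(0, 0.5, 0.55, 1.0)),
               c("isolated", "burst", "burst", "isolated"))
  expect_equal(classify_isolated(1.23), "isolated")
  # neighbors at exactly 200 ms count as within the window -> all burst
  expect_true(all(classify_isolated(seq(0, 1, by = 0.2)) == "burst"))
  # brute-force check over random trains
  withr::with_seed(5, {
    for (i in 1:10) {
      st <- sort(runif(30, 0, 10))
      lab <- classify_isolated(st)
      oracle <- vapply(seq_along(st), function(j) {
        d <- abs(st[-j] - st[j])
        if (all(d > 0.2)) "isolated" else "burst"
      }, character(1))
      expect_identical(lab, oracle)
    }
  })
  expect_equal(isolated_fraction(classify_isolated(c(0, 0.5, 0.55, 1.0))), 0.5)
  expect_equal(isolated_fraction(character(0)), NA_real_)
})

test_that("features recover generator targets on noiseless single spikes", {
  for (cls in c("PN", "LN")) {
    p <- cell_params(cls, noise_sd_mv = 0)
    tr <- generate_voltage_trace(p, duration_s = 2, seed = 1,
                                 spike_times = 1.0)
    st <- detect_spikes(tr)$time_s
    expect_equal(length(st), 1)
    tol <- if (cls == "PN") 0.01 else 0.05
    expect_lt(abs(spike_amplitude(tr, st) - p$spike_amplitude_mv) /
                p$spike_amplitude_mv, tol)
    expect_lt(abs(spike_half_width(tr, st) - p$spike_halfwidth_ms) /
                p$spike_halfwidth_ms, 0.05)
    expect_lt(abs(ahp_amplitude(tr, st) - p$ahp_depth_mv) /
                abs(p$ahp_depth_mv), 0.05)
  }
})

test_that("feature directionality between regimes matches the class contrast", {
  fp <- extract_features(generate_voltage_trace(cell_params("PN"),
                                                duration_s = 10, seed = 31))
  fl <- extract_features(generate_voltage_trace(cell_params("LN"),
                                                duration_s = 30, seed = 32))
  expect_lt(fp$amplitude_mv, fl$amplitude_mv)     # PN spikes smaller
  expect_gt(fp$half_width_ms, fl$half_width_ms)   # PN spikes wider
  expect_gt(fp$ahp_mv, fl$ahp_mv)                 # PN AHP shallower (less negative)
  expect_lt(fp$isolated_fraction, fl$isolated_fraction)
})

test_that("features are DC-invariant and amplitude/AHP scale linearly", {
  p <- cell_params("LN", noise_sd_mv = 0)
  tr <- generate_voltage_trace(p, duration_s = 3, seed = 7,
                               spike_times = c(0.8, 1.6, 2.4))
  st <- detect_spikes(tr)$time_s
  amp0 <- spike_amplitude(tr, st)
  hw0 <- spike_half_width(tr, st)
  ahp0 <- ahp_amplitude(tr, st)
  # DC offset
  tr_dc <- tr; tr_dc$samples$v_mv <- tr$samples$v_mv + 12.3
  expect_equal(spike_amplitude(tr_dc, st), amp0, tolerance = 1e-9)
  expect_equal(spike_half_width(tr_dc, st), hw0, tolerance = 1e-9)
  expect_equal(ahp_amplitude(tr_dc, st), ahp0, tolerance = 1e-9)
  # scaling (about the baseline)
  tr_sc <- tr; tr_sc$samples$v_mv <- 2 * tr$samples$v_mv
  expect_equal(spike_amplitude(tr_sc, st), 2 * amp0, tolerance = 1e-6)
  expect_equal(ahp_amplitude(tr_sc, st), 2 * ahp0, tolerance = 1e-6)
})

test_that("all-burst cells fall back to the burst amplitude path", {
  p <- cell_params("LN", noise_sd_mv = 0)
  # two bursts of three spikes, 20 ms ISI: nothing is isolated
  times <- c(1.0, 1.02, 1.04, 2.0, 2.02, 2.04)
  tr <- generate_voltage_trace(p, duration_s = 3, seed = 1,
                               spike_times = times)
  st <- detect_spikes(tr)$time_s
  expect_equal(length(st), 6)
  labels <- classify_isolated(st)
  expect_true(all(labels == "burst"))
  amp <- spike_amplitude(tr, st, labels)
  expect_lt(abs(amp - p$spike_amplitude_mv) / p$spike_amplitude_mv, 0.10)
  # half-width and AHP need isolated spikes -> missing, not zero
  expect_true(is.na(spike_half_width(tr, st, labels)))
  expect_true(is.na(ahp_amplitude(tr, st, labels)))
})

test_that("extract_features honors the exclusion window", {
  p <- cell_params("LN", noise_sd_mv = 0)
  tr <- generate_voltage_trace(p, duration_s = 6, seed = 3,
                               spike_times = c(1, 2.5, 3.2, 5))
  full <- extract_features(tr)
  excl_none <- extract_features(tr, exclude_window = c(5.9, 5.95))
  expect_equal(full, excl_none)
  excl_all <- extract_features(tr, exclude_window = c(0, 6))
  expect_true(is.na(excl_all$amplitude_mv))
  expect_equal(excl_all$n_spikes, 0)
  excl_win <- extract_features(tr, exclude_window = c(2, 4))
  expect_equal(excl_win$n_spikes, 2)
})

test_that("spike-triggered average recovers constants and the self template", {
  p <- cell_params("PN", noise_sd_mv = 0)
  tr <- generate_voltage_trace(p, duration_s = 4, seed = 1,
                               spike_times = c(1, 2, 3))
  # constant other trace -> flat STA at the constant
  const <- tr
  const$samples$v_mv <- rep(-40, nrow(tr$samples))
  sta_c <- spike_triggered_average(c(1, 2, 3), const)
  expect_true(all(abs(sta_c$v_mv + 40) < 1e-12))
  expect_equal(attr(sta_c, "n_triggers"), 3)
  # self-triggered STA shows the spike template peak
  sta_s <- spike_triggered_average(c(1, 2, 3), tr, window_s = c(-0.01, 0.01))
  peak <- max(sta_s$v_mv) - p$baseline_mv
  expect_lt(abs(peak - (p$spike_amplitude_mv - abs(p$ahp_depth_mv))) /
              peak, 0.02)
  expect_error(spike_triggered_average(10, tr), "inside the trace")
})

test_that("STA of independent noise shrinks roughly as 1/sqrt(n)", {
  p <- cell_params("PN", baseline_rate_hz = 0, noise_sd_mv = 1)
  tr <- generate_voltage_trace(p, duration_s = 60, seed = 13)
  sta_small <- spike_triggered_average(seq(1, 5, by = 0.5), tr)
  sta_big <- spike_triggered_average(seq(1, 59, by = 0.25), tr)
  sd_small <- sd(sta_small$v_mv)
  sd_big <- sd(sta_big$v_mv)
  ratio <- sd_small / sd_big
  expected <- sqrt(length(seq(1, 59, by = 0.25)) / length(seq(1, 5, by = 0.5)))
  expect_gt(ratio, expected * 0.5)
  expect_lt(ratio, expected * 2)
})

test_that("epoch comparison matches the exact signed-rank references", {
  # 15 trials, epoch b has one extra spike each trial
  spk <- purrr::list_rbind(purrr::map(1:15, function(tr_i) {
    tibble::tibble(cell_id = "c1", odor = "none", trial = tr_i,
                   time_s = c(6.5, 7.2, 7.7))
  }))
  res <- compare_epochs(spk, epoch_a = c(6, 7), epoch_b = c(7, 8))
  expect_equal(res$p_value, 2 / 2^15)
  expect_equal(res$mean_count_b - res$mean_count_a, 1)
  # identical epochs -> p = 1
  res2 <- compare_epochs(spk, epoch_a = c(7, 8), epoch_b = c(7, 8))
  expect_equal(res2$p_value, 1)
  # 7 trials all positive -> 0.015625
  spk7 <- dplyr::filter(spk, trial <= 7)
  expect_equal(compare_epochs(spk7, c(6, 7), c(7, 8))$p_value, 2 / 2^7)
})
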