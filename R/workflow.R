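# One-command end-to-end synthetic runs: synthesize -> features -> typing ->
# responses -> decoding -> behavior, with a single seed and a YAML-able
# config, producing a directory of CSV outputs plus a provenance sidecar.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: 200 ms isolation window,
#' quality threshold 3, background 0--2 s and response 2.1--4.1 s windows,
#' two 1-s responder bins at alpha 0.05, 8 x 250 ms decoder bins with the
#' first trial dropped, population-size grid 5..60 by 5 with 10 repeats,
#' behavior subsampling with 20 repeats, 0.5 um skeleton resampling.
#' Override any entry via `...`; stages can be disabled through the
#' `stages` vector.
#'
#' @param seed global seed fanned out to per-stage substreams.
#' @param ... named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    stages = c("features", "typing", "responses", "decoding", "morphology",
               "behavior"),
    # synthetic cohort sizes
    n_pn_traces = 12, n_ln_traces = 8, trace_duration_s = 10,
    n_cells_population = 64, n_odors = 6, n_trials = 7,
    tuning_sd_hz = 8, tuning_sparsity = 0.35,
    n_skeleton_types = 4, clones_per_type = 3, skeleton_jitter_um = 0.5,
    n_behavior_experiments = 12,
    # analysis parameters
    isolation_window_s = 0.2, min_quality = 3, detector_k = 6,
    alpha = 0.05, min_odors = 5,
    background = c(0, 2), response = c(2.1, 4.1),
    decoder_bin_s = 0.25, drop_first_trial = TRUE, decoder_trials = 6,
    ncells_grid = seq(5, 60, by = 5), ncells_repeats = 10,
    behavior_repeats = 20, resample_spacing_um = 0.5,
    nblast_sigma = 3, nblast_gamma = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config entries: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   the path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# Polynomial rolling hash of the YAML dump: cheap provenance tag.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic study cohort with the configured seed and runs
#' every enabled stage: voltage traces -> spike features -> cell typing;
#' population spike tables -> odor-response statistics -> decoding;
#' skeletons -> similarity; behavior counts -> preference indices and the
#' behavior-PN correlation. Each stage writes CSV outputs into `out_dir`,
#' and a `run.json` sidecar records the config, its hash, and the stage
#' list, so a rerun with the same config is reproducible.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list of stage results; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("al_run_")) {
  stopifnot(inherits(cfg, "run_config"))
  # preflight: every enabled stage must have its inputs producible
  needs <- list(typing = "features", behavior = "responses")
  for (st in intersect(names(needs), cfg$stages)) {
    if (!needs[[st]] %in% cfg$stages) {
      abort(sprintf("Stage `%s` needs stage `%s` to be enabled.",
                    st, needs[[st]]))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  seed <- cfg$seed

  if ("features" %in% cfg$stages) {
    n_cells <- cfg$n_pn_traces + cfg$n_ln_traces
    classes <- rep(c("PN", "LN"), c(cfg$n_pn_traces, cfg$n_ln_traces))
    feats <- list_rbind(map(seq_len(n_cells), function(i) {
      tr <- generate_voltage_trace(
        cell_params(classes[i]), duration_s = cfg$trace_duration_s,
        trial_meta = list(cell_id = sprintf("%s_%02d", classes[i], i)),
        seed = derive_seed(seed, paste0("trace", i)))
      extract_features(tr, detector_config(k_mad = cfg$detector_k))
    }))
    feats$truth_label <- classes
    feats$quality <- 5
    res$features <- feats
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  }

  if ("typing" %in% cfg$stages) {
    if (is.null(res$features)) abort("Stage `typing` needs stage `features`.")
    fm <- res$features |>
      quality_filter(cfg$min_quality) |>
      normalize_features() |>
      impute_missing()
    res$clustering <- cluster_cells(fm, k = 2)
    res$feature_cor <- pairwise_feature_correlations(fm)
    write.csv(tidy(res$clustering), file.path(out_dir, "clusters.csv"),
              row.names = FALSE)
  }

  if ("responses" %in% cfg$stages || "decoding" %in% cfg$stages) {
    odors <- sprintf("odor_%d", seq_len(cfg$n_odors))
    tuning <- with_seed(derive_seed(seed, "tuning"), {
      m <- matrix(rnorm(cfg$n_cells_population * cfg$n_odors, 0,
                        cfg$tuning_sd_hz),
                  cfg$n_cells_population, cfg$n_odors)
      mask <- matrix(runif(length(m)) < cfg$tuning_sparsity, nrow(m))
      m * mask
    })
    spec <- tuning_spec(cfg$n_cells_population, odors, tuning_hz = tuning,
                        baseline_hz = 9.5)
    spikes <- generate_population_responses(spec, n_trials = cfg$n_trials,
                                            seed = derive_seed(seed, "popn"))
    res$spikes <- spikes
  }

  if ("responses" %in% cfg$stages) {
    res$responses <- mean_response(spikes, cfg$background, cfg$response)
    res$responders <- responder_test(spikes, alpha = cfg$alpha,
                                     background = cfg$background)
    res$activated <- fraction_cells_activated(res$responders)
    write.csv(res$responses, file.path(out_dir, "responses.csv"),
              row.names = FALSE)
    write.csv(res$responders, file.path(out_dir, "responders.csv"),
              row.names = FALSE)
  }

  if ("decoding" %in% cfg$stages) {
    tensor <- build_decoder_tensor(
      res$spikes, n_trials = cfg$decoder_trials,
      drop_first_trial = cfg$drop_first_trial, bin_s = cfg$decoder_bin_s,
      response = cfg$response, background = cfg$background)
    res$accuracy_curve <- accuracy_vs_duration(tensor)
    res$ncells_curve <- accuracy_vs_ncells(
      tensor, n_grid = cfg$ncells_grid, repeats = cfg$ncells_repeats,
      seed = derive_seed(seed, "ncells"))
    psth <- build_psth_matrix(res$spikes)
    res$trajectories <- pca_trajectories(psth)
    write.csv(res$accuracy_curve, file.path(out_dir, "accuracy_curve.csv"),
              row.names = FALSE)
    write.csv(res$ncells_curve$curve, file.path(out_dir, "accuracy_ncells.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(res$trajectories),
              file.path(out_dir, "trajectories.csv"), row.names = FALSE)
  }

  if ("morphology" %in% cfg$stages) {
    sks <- generate_skeletons(cfg$n_skeleton_types, cfg$clones_per_type,
                              jitter_sd = cfg$skeleton_jitter_um,
                              seed = derive_seed(seed, "skel"))
    res$similarity <- similarity_analysis(
      sks, spacing = cfg$resample_spacing_um, sigma = cfg$nblast_sigma,
      gamma = cfg$nblast_gamma)
    write.csv(tidy(res$similarity), file.path(out_dir, "similarity.csv"),
              row.names = FALSE)
  }

  if ("behavior" %in% cfg$stages) {
    if (is.null(res$responses)) abort("Stage `behavior` needs stage `responses`.")
    odors <- sort(unique(res$responses$odor))
    # odor-arm bias tied to the population response so the correlation is real
    pop_mean <- res$responses |>
      group_by(.data$odor) |>
      summarise(m = mean(.data$mean_dr_hz), .groups = "drop")
    bias <- 0.5 + 0.3 * tanh(pop_mean$m / 10)
    beh <- list_rbind(map(seq_along(odors), function(i) {
      generate_behavior_counts(cfg$n_behavior_experiments, odor = odors[i],
                               p_odor_arm = bias[i],
                               seed = derive_seed(seed, paste0("beh", i)))
    }))
    beh <- validity_filter(beh)
    beh$pi <- preference_index(beh$n_odor_arm, beh$n_control_arm)
    pi_table <- beh |>
      group_by(.data$odor) |>
      dplyr::reframe(odor_pi_test(.data$pi)) |>
      rename(p_value_pi = "p_value")
    res$pi_table <- pi_table
    res$behavior_cor <- behavior_pn_correlation(
      rename(pi_table, mean_pi = "mean_pi"), res$responses)
    write.csv(pi_table, file.path(out_dir, "preference_indices.csv"),
              row.names = FALSE)
  }

  sidecar <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                  stages_run = cfg$stages,
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(sidecar, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$out_dir <- out_dir
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] and assembles a plain-text
#' report with the feature group means, clustering accuracy, responder
#' fractions, decoding accuracy curves, preference indices and the
#' behavior-PN correlation. Missing stages are marked as gaps rather than
#' failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path optional output file for the report text.
#' @return The report lines, invisibly; written to `path` when given.
#' @export
make_report <- function(run_dir, path = NULL) {
  if (!file.exists(file.path(run_dir, "run.json"))) {
    abort("`run_dir` does not look like a pipeline run (no run.json).")
  }
  meta <- jsonlite::read_json(file.path(run_dir, "run.json"))
  lines <- c(sprintf("Antennal-lobe pipeline run %s", meta$config_hash),
             sprintf("seed: %s", meta$config$seed), "")
  section <- function(file, title, fmt) {
    f <- file.path(run_dir, file)
    if (!file.exists(f)) return(sprintf("[%s: stage not run]", title))
    c(title, fmt(read.csv(f)), "")
  }
  lines <- c(
    lines,
    section("features.csv", "Electrophysiological features", function(d) {
      agg <- stats::aggregate(d[c("amplitude_mv", "half_width_ms", "ahp_mv",
                                  "isolated_fraction")],
                              by = list(class = d$truth_label), FUN = mean,
                              na.rm = TRUE)
      utils::capture.output(print(agg, digits = 3))
    }),
    section("clusters.csv", "Cell typing", function(d) {
      acc <- mean(d$cluster_label == d$truth_label, na.rm = TRUE)
      sprintf("clustering accuracy vs truth: %.3f over %d cells", acc, nrow(d))
    }),
    section("responders.csv", "Odor responses", function(d) {
      sprintf("responding cell-odor pairs: %d of %d (%.2f)",
              sum(d$responding), nrow(d), mean(d$responding))
    }),
    section("accuracy_curve.csv", "Odor decoding", function(d) {
      sprintf("k = %d bins (%d ms): accuracy %.3f",
              d$k_bins, d$duration_ms, d$accuracy)
    }),
    section("similarity.csv", "Morphological similarity", function(d) {
      agg <- stats::aggregate(d$score, by = list(pair = d$pair), FUN = mean)
      sprintf("%s mean normalized score: %.3f", agg$pair, agg$x)
    }),
    section("preference_indices.csv", "Behavior", function(d) {
      sprintf("%s: PI %.3f (p = %.3g, n = %d)", d$odor, d$mean_pi,
              d$p_value_pi, d$n)
    })
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
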