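# Population-level odor coding: trial-averaged PSTH matrix and PCA
# trajectories, and the leave-one-trial-out nearest-centroid odor decoder on
# background-subtracted 250 ms response bins.

# spike counts per time bin for one trial's spike times
bin_counts <- function(times, edges) {
  if (length(times) == 0) return(integer(length(edges) - 1L))
  tabulate(findInterval(times, edges, rightmost.closed = FALSE,
                        left.open = FALSE),
           nbins = length(edges) - 1L)[seq_len(length(edges) - 1L)]
}

#' Odor-concatenated trial-averaged PSTH matrix
#'
#' For every cell-odor pair, the trial-averaged firing rate in `bin_s` bins
#' over `window`, minus the pair's trial-averaged background rate (first
#' 2 s). The per-odor binned vectors are stacked odor by odor, giving a
#' matrix with `n_odors * n_bins` rows and one column per cell (e.g.
#' 6 odors x 60 bins = 360 rows by 64 cells).
#'
#' @param spikes an `al_spikes` tibble; every cell must be tested with
#'   every odor in `odors`.
#' @param odors odor panel (default: all odors present, sorted).
#' @param bin_s bin width (s), default 0.1.
#' @param window time window (s), default `c(0, 6)`.
#' @param background background window for rate subtraction.
#' @return Numeric matrix with rownames `<odor>.bin<i>` and columns the
#'   cells; attributes `odors`, `n_bins`, `bin_s`.
#' @export
build_psth_matrix <- function(spikes, odors = NULL, bin_s = 0.1,
                              window = c(0, 6), background = c(0, 2)) {
  odors <- odors %||% sort(unique(spikes$odor))
  cells <- sort(unique(spikes$cell_id))
  have <- distinct(spikes, .data$cell_id, .data$odor)
  need <- crossing(cell_id = cells, odor = odors)
  miss <- dplyr::anti_join(need, have, by = c("cell_id", "odor"))
  if (nrow(miss) > 0) {
    abort(paste0("Missing cell-odor pair(s): ",
                 paste(paste(miss$cell_id, miss$odor, sep = "/"),
                       collapse = ", ")))
  }
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  psth <- spikes |>
    filter(.data$odor %in% odors) |>
    group_by(.data$cell_id, .data$odor) |>
    dplyr::reframe({
      per_trial <- split(.data$time_s, .data$trial)
      counts <- vapply(per_trial, bin_counts, integer(n_bins), edges = edges)
      bg <- vapply(per_trial, count_in_window, numeric(1),
                   a = background[1], b = background[2]) / diff(background)
      tibble(bin = seq_len(n_bins),
             rate = rowMeans(counts) / bin_s - mean(bg))
    })
  mat <- matrix(0, nrow = length(odors) * n_bins, ncol = length(cells),
                dimnames = list(
                  paste0(rep(odors, each = n_bins), ".bin",
                         rep(seq_len(n_bins), length(odors))),
                  cells))
  for (i in seq_len(nrow(psth))) {
    r <- (match(psth$odor[i], odors) - 1L) * n_bins + psth$bin[i]
    mat[r, psth$cell_id[i]] <- psth$rate[i]
  }
  structure(mat, odors = odors, n_bins = n_bins, bin_s = bin_s,
            window = window)
}

#' PCA odor trajectories of the population response
#'
#' Column-centered (per-cell) principal component analysis of the PSTH
#' matrix; each row (a time bin of one odor) is projected on the first
#' `n_components` components and regrouped into per-odor time series. With
#' background-subtracted rates, pre-odor bins sit near the origin and the
#' trajectories diverge after odor onset.
#'
#' @param mat matrix from [build_psth_matrix()].
#' @param n_components number of components to keep, default 3 (fewer, with
#'   a warning, when the matrix rank is lower).
#' @return A tibble of class `al_trajectories`: `odor`, `bin`, `time_s`,
#'   `PC1..PCk`, with attribute `variance_explained`.
#' @export
pca_trajectories <- function(mat, n_components = 3) {
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pos_var <- sum(pc$sdev > 1e-10)
  if (pos_var < n_components) {
    warn(sprintf("Matrix rank %d < %d components requested; returning %d.",
                 pos_var, n_components, min(k, pos_var)))
    k <- min(k, max(1L, pos_var))
  }
  odors <- attr(mat, "odors")
  n_bins <- attr(mat, "n_bins")
  bin_s <- attr(mat, "bin_s") %||% 0.1
  window <- attr(mat, "window") %||% c(0, 6)
  out <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out$odor <- rep(odors, each = n_bins)
  out$bin <- rep(seq_len(n_bins), length(odors))
  out$time_s <- window[1] + (out$bin - 0.5) * bin_s
  out <- select(out, "odor", "bin", "time_s", dplyr::starts_with("PC"))
  structure(out, class = c("al_trajectories", class(tibble())),
            variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Build the decoder tensor of binned population responses
#'
#' Per trial and odor, firing rates in eight 250 ms bins of the response
#' window, background-subtracted with the same trial's first-2-s rate, for
#' every cell. Columns are bin-major: the first `n_cells` columns hold bin
#' 1 of every cell, the next `n_cells` bin 2, and so on — so truncating to
#' the first `k * n_cells` columns uses the first `k` bins. The first trial
#' is dropped by default (odor delivery differed slightly on trial 1) and
#' the next `n_trials` trials are used.
#'
#' @param spikes an `al_spikes` tibble with all cells tested on all odors.
#' @param odors odor panel (default all).
#' @param n_trials trials kept per pair, default 6.
#' @param drop_first_trial drop trial 1 before taking `n_trials`.
#' @param bin_s decoder bin width, default 0.25 s.
#' @param response response window, default `c(2.1, 4.1)` (8 bins).
#' @param background background window for subtraction.
#' @return A list of class `al_tensor`: `data` array
#'   `[trial, odor, cell-bin column]`, `cells`, `odors`, `n_bins`.
#' @export
build_decoder_tensor <- function(spikes, odors = NULL, n_trials = 6,
                                 drop_first_trial = TRUE, bin_s = 0.25,
                                 response = c(2.1, 4.1),
                                 background = c(0, 2)) {
  odors <- odors %||% sort(unique(spikes$odor))
  cells <- sort(unique(spikes$cell_id))
  trials_avail <- sort(unique(spikes$trial))
  trials_use <- if (drop_first_trial) {
    setdiff(trials_avail, min(trials_avail))
  } else trials_avail
  if (length(trials_use) < n_trials) {
    abort(sprintf("Need %d trials%s but only %d available.",
                  n_trials,
                  if (drop_first_trial) " after dropping the first" else "",
                  length(trials_use)))
  }
  trials_use <- trials_use[seq_len(n_trials)]
  edges <- seq(response[1], response[2], by = bin_s)
  n_bins <- length(edges) - 1L
  n_c <- length(cells); n_o <- length(odors)
  # vectorized binning: tabulate spike (bin, cell, odor, trial) codes
  keep <- spikes$odor %in% odors & spikes$trial %in% trials_use
  ts <- spikes$time_s[keep]
  ci <- match(spikes$cell_id[keep], cells)
  oi <- match(spikes$odor[keep], odors)
  ti <- match(spikes$trial[keep], trials_use)
  base3 <- (ci - 1L) + (oi - 1L) * n_c + (ti - 1L) * n_c * n_o
  bin <- findInterval(ts, edges, left.open = FALSE)
  in_resp <- bin >= 1L & ts < response[2]
  counts <- tabulate(bin[in_resp] + base3[in_resp] * n_bins,
                     nbins = n_bins * n_c * n_o * n_trials)
  in_bg <- ts >= background[1] & ts < background[2]
  bg <- tabulate(base3[in_bg] + 1L, nbins = n_c * n_o * n_trials) /
    diff(background)
  rate <- array(counts / bin_s, dim = c(n_bins, n_c, n_o, n_trials)) -
    rep(array(bg, dim = c(n_c, n_o, n_trials)), each = n_bins)
  # columns are bin-major blocks with cells contiguous inside each block
  r <- aperm(rate, c(2, 1, 3, 4))          # (cell, bin, odor, trial)
  dim(r) <- c(n_c * n_bins, n_o, n_trials)
  arr <- aperm(r, c(3, 2, 1))
  dimnames(arr) <- list(NULL, odors, NULL)
  structure(list(data = arr, cells = cells, odors = odors, n_bins = n_bins,
                 trials = trials_use, bin_s = bin_s),
            class = "al_tensor")
}

#' @export
print.al_tensor <- function(x, ...) {
  cat(sprintf("<al_tensor> %d trials x %d odors x (%d cells * %d bins)\n",
              dim(x$data)[1], length(x$odors), length(x$cells), x$n_bins))
  invisible(x)
}

#' Leave-one-trial-out nearest-centroid odor classification
#'
#' Each trial in turn is the test trial; for every odor a template is the
#' centroid of the remaining (training) trials over the first `k_bins`
#' bins' columns. A test response scores a hit when its Euclidean distance
#' is smallest to its own odor's template; exact distance ties are resolved
#' toward the lowest odor index (deterministic). Accuracy is averaged over
#' test odors within a fold, then over folds.
#'
#' @param tensor an `al_tensor` from [build_decoder_tensor()].
#' @param k_bins number of leading bins used, in `[1, n_bins]`.
#' @param cell_subset optional indices (into `tensor$cells`) restricting the
#'   population.
#' @return A list of class `al_decoder`: `accuracy`, `folds` tibble
#'   (`fold`, `odor`, `predicted`, `hit`), `k_bins`, `n_cells`.
#' @export
loo_classify <- function(tensor, k_bins, cell_subset = NULL) {
  stopifnot(inherits(tensor, "al_tensor"))
  if (k_bins < 1 || k_bins > tensor$n_bins) {
    abort(sprintf("`k_bins` must be in [1, %d].", tensor$n_bins))
  }
  n_cells_all <- length(tensor$cells)
  cell_subset <- cell_subset %||% seq_len(n_cells_all)
  cols <- as.vector(vapply(seq_len(k_bins), function(b) {
    (b - 1L) * n_cells_all + cell_subset
  }, integer(length(cell_subset))))
  x <- tensor$data[, , cols, drop = FALSE]
  n_trials <- dim(x)[1]
  n_odors <- dim(x)[2]
  rows <- list()
  for (f in seq_len(n_trials)) {
    train <- x[-f, , , drop = FALSE]
    templates <- apply(train, c(2, 3), mean)        # odor x feature
    for (o in seq_len(n_odors)) {
      test <- x[f, o, ]
      d <- sqrt(rowSums((templates - matrix(test, n_odors, length(test),
                                            byrow = TRUE))^2))
      pred <- which(d == min(d))[1]                 # tie -> lowest odor index
      rows[[length(rows) + 1L]] <- tibble(
        fold = f, odor = tensor$odors[o],
        predicted = tensor$odors[pred], hit = as.integer(pred == o))
    }
  }
  folds <- list_rbind(rows)
  per_fold <- folds |>
    group_by(.data$fold) |>
    summarise(accuracy = mean(.data$hit), .groups = "drop")
  structure(list(accuracy = mean(per_fold$accuracy), folds = folds,
                 per_fold = per_fold, k_bins = k_bins,
                 n_cells = length(cell_subset)),
            class = "al_decoder")
}

#' @export
print.al_decoder <- function(x, ...) {
  cat(sprintf("<al_decoder> k = %d bins, %d cells: accuracy %.3f\n",
              x$k_bins, x$n_cells, x$accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.al_decoder <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.al_decoder <- function(x, ...) {
  tibble(accuracy = x$accuracy, k_bins = x$k_bins, n_cells = x$n_cells,
         n_folds = nrow(x$per_fold))
}

#' Classification accuracy versus response duration
#'
#' Runs [loo_classify()] for cumulative bin counts `k = 1..n_bins` (250 ms
#' steps of response duration).
#'
#' @param tensor an `al_tensor`.
#' @return A tibble of class `al_decoder_curve`: `k_bins`, `duration_ms`,
#'   `accuracy`, plus per-fold accuracies nested in attribute `folds`.
#' @export
accuracy_vs_duration <- function(tensor) {
  res <- map(seq_len(tensor$n_bins), function(k) loo_classify(tensor, k))
  out <- tibble(
    k_bins = seq_len(tensor$n_bins),
    duration_ms = seq_len(tensor$n_bins) * tensor$bin_s * 1000,
    accuracy = map_dbl(res, "accuracy"))
  attr(out, "folds") <- list_rbind(imap(res, function(r, k) {
    mutate(r$per_fold, k_bins = k)
  }))
  class(out) <- c("al_decoder_curve", class(tibble()))
  out
}

#' Classification accuracy versus population size
#'
#' For each population size in `n_grid`, repeats the leave-one-trial-out
#' classification on seeded random cell subsets and averages the accuracy;
#' the trend is summarized as the Pearson correlation between mean accuracy
#' and population size. Uses the first `k_bins` bins (default 3, i.e.
#' 750 ms of response).
#'
#' @param tensor an `al_tensor`.
#' @param n_grid population sizes, default `seq(5, 60, by = 5)`; sizes
#'   exceeding the population are skipped with a warning.
#' @param repeats random subsets per size, default 10.
#' @param k_bins leading bins used, default 3.
#' @param seed integer seed.
#' @return A list of class `al_ncells_curve`: `curve` tibble (`n_cells`,
#'   `mean_accuracy`), `points` (per repeat), `trend_r`, `trend_p`.
#' @export
accuracy_vs_ncells <- function(tensor, n_grid = seq(5, 60, by = 5),
                               repeats = 10, k_bins = 3, seed = 1) {
  n_pop <- length(tensor$cells)
  if (any(n_grid > n_pop)) {
    warn(sprintf("Skipping population sizes > %d cells.", n_pop))
    n_grid <- n_grid[n_grid <= n_pop]
  }
  points <- with_seed(derive_seed(seed, "ncells"), {
    list_rbind(map(n_grid, function(nn) {
      list_rbind(map(seq_len(repeats), function(rep_i) {
        subset <- sort(sample.int(n_pop, nn))
        tibble(n_cells = nn, repeat_i = rep_i,
               accuracy = loo_classify(tensor, k_bins, subset)$accuracy)
      }))
    }))
  })
  curve <- points |>
    group_by(.data$n_cells) |>
    summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop")
  trend_r <- NA_real_; trend_p <- NA_real_
  if (nrow(curve) >= 3 && sd(curve$mean_accuracy) > 0) {
    ct <- stats::cor.test(curve$n_cells, curve$mean_accuracy)
    trend_r <- unname(ct$estimate); trend_p <- ct$p.value
  }
  structure(list(curve = curve, points = points, trend_r = trend_r,
                 trend_p = trend_p, k_bins = k_bins),
            class = "al_ncells_curve")
}

#' @export
print.al_ncells_curve <- function(x, ...) {
  cat(sprintf("<al_ncells_curve> %d sizes, trend r = %s\n",
              nrow(x$curve), format(x$trend_r, digits = 3)))
  invisible(x)
}
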