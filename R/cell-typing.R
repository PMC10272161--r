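# Unsupervised PN/LN typing from the four electrophysiological features:
# quality filtering, per-feature z-scoring, similarity-weighted imputation,
# pairwise feature correlations, and Ward hierarchical clustering.

feature_cols <- c("amplitude_mv", "half_width_ms", "ahp_mv", "isolated_fraction")

check_feature_tbl <- function(features) {
  missing <- setdiff(feature_cols, names(features))
  if (length(missing)) {
    abort(paste0("Feature table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(features)
}

#' Keep cells above a recording-quality threshold
#'
#' Cells carry a manually assigned quality index on a 0--5 scale; only cells
#' with quality strictly greater than the threshold are analyzed.
#'
#' @param features tibble with a `quality` column.
#' @param min_quality strict lower bound, default 3.
#' @return The filtered tibble (warning when empty).
#' @export
quality_filter <- function(features, min_quality = 3) {
  if (!"quality" %in% names(features)) abort("`features` needs a `quality` column.")
  out <- filter(features, .data$quality > min_quality)
  if (nrow(out) == 0) warn("No cell passes the quality filter.")
  out
}

#' Z-score the four electrophysiological features
#'
#' Each feature column is centered and scaled so that over the non-missing
#' cells its mean is 0 and its sample SD (n - 1 denominator) is 1; missing
#' entries stay missing.
#'
#' @param features tibble with the four feature columns (`amplitude_mv`,
#'   `half_width_ms`, `ahp_mv`, `isolated_fraction`).
#' @return The tibble with normalized feature columns.
#' @export
normalize_features <- function(features) {
  check_feature_tbl(features)
  for (col in feature_cols) {
    v <- features[[col]]
    ok <- is.finite(v)
    if (sum(ok) < 2) abort(sprintf("Column `%s` has fewer than 2 non-missing values.", col))
    s <- sd(v[ok])
    if (s == 0) abort(sprintf("Column `%s` has zero variance; cannot z-score.", col))
    features[[col]] <- (v - mean(v[ok])) / s
  }
  features
}

#' Impute missing features by similarity-weighted reference averaging
#'
#' The reference set is the cells with all four features present. For a cell
#' with missing entries, its Pearson correlation to every reference cell is
#' computed on the features it does have; negative similarities are clipped
#' to zero, and each missing feature is filled with the similarity-weighted
#' mean of the reference cells' values. When no weight is positive, or when
#' the cell has fewer than two available features (so a correlation is
#' undefined), the unweighted reference mean is used and the fallback is
#' recorded in the `imputation_log` attribute.
#'
#' @param features normalized feature tibble (see [normalize_features()]).
#' @return The completed tibble; non-missing entries are untouched.
#'   Attribute `imputation_log` lists each filled entry.
#' @export
impute_missing <- function(features) {
  check_feature_tbl(features)
  x <- as.matrix(features[feature_cols])
  complete <- complete.cases(x)
  if (!any(!complete)) return(features)
  if (!any(complete)) abort("No complete reference cells available for imputation.")
  ref <- x[complete, , drop = FALSE]
  log <- list()
  for (i in which(!complete)) {
    avail <- which(is.finite(x[i, ]))
    if (length(avail) == 0) abort(sprintf("Row %d has no available features.", i))
    if (length(avail) >= 2) {
      sims <- apply(ref[, avail, drop = FALSE], 1,
                    function(r) suppressWarnings(cor(r, x[i, avail])))
      sims[!is.finite(sims)] <- 0
      w <- pmax(sims, 0)
    } else {
      w <- rep(0, nrow(ref))
    }
    fallback <- sum(w) == 0
    if (fallback) w <- rep(1, nrow(ref))
    for (j in setdiff(seq_along(feature_cols), avail)) {
      x[i, j] <- sum(w * ref[, j]) / sum(w)
      log[[length(log) + 1L]] <- tibble(
        row = i, feature = feature_cols[j], value = x[i, j],
        fallback_unweighted = fallback)
    }
  }
  for (j in seq_along(feature_cols)) features[[feature_cols[j]]] <- x[, j]
  attr(features, "imputation_log") <- list_rbind(log)
  features
}

#' Pairwise feature-vector correlations between cells
#'
#' Pearson correlation between every pair of cells' four-feature vectors,
#' the electrophysiological similarity used to compare the PN and LN
#' populations. Pairs involving a constant feature vector have undefined
#' correlation and are excluded from group means.
#'
#' @param features complete (post-imputation) feature tibble; a
#'   `truth_label` column, when present, defines the pair groups
#'   (PN-PN, LN-LN, PN-LN).
#' @return A list of class `al_feature_cor`: `matrix` (cell x cell),
#'   `pairs` (tibble `cell_a`, `cell_b`, `r`, `pair_type`), `group_means`.
#' @export
pairwise_feature_correlations <- function(features) {
  check_feature_tbl(features)
  x <- as.matrix(features[feature_cols])
  if (any(!is.finite(x))) abort("Feature matrix must be complete; run impute_missing() first.")
  ids <- features$cell_id %||% sprintf("cell_%03d", seq_len(nrow(x)))
  cm <- suppressWarnings(cor(t(x)))
  dimnames(cm) <- list(ids, ids)
  lab <- features$truth_label %||% rep(NA_character_, nrow(x))
  up <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble(
    cell_a = ids[up[, 1]], cell_b = ids[up[, 2]],
    r = cm[up],
    pair_type = ifelse(is.na(lab[up[, 1]]) | is.na(lab[up[, 2]]), NA_character_,
                       paste(pmin(lab[up[, 1]], lab[up[, 2]]),
                             pmax(lab[up[, 1]], lab[up[, 2]]), sep = "-"))
  )
  gm <- pairs |>
    filter(is.finite(.data$r), !is.na(.data$pair_type)) |>
    group_by(.data$pair_type) |>
    summarise(mean_r = mean(.data$r), sd_r = sd(.data$r), n = n(),
              .groups = "drop")
  structure(list(matrix = cm, pairs = pairs, group_means = gm),
            class = "al_feature_cor")
}

#' @export
print.al_feature_cor <- function(x, ...) {
  cat(sprintf("<al_feature_cor> %d cells\n", nrow(x$matrix)))
  print(x$group_means)
  invisible(x)
}

#' Cluster cells into PN-enriched and LN-enriched groups
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances of the normalized four-feature vectors) cut at `k` clusters.
#' When true labels are present, clusters are named by their majority label
#' (ties broken toward PN, the larger class) and the recovery accuracy is
#' the fraction of cells whose cluster label matches their own.
#'
#' @param features complete normalized feature tibble.
#' @param k number of clusters, default 2 (the PN/LN split).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return An object of class `al_clustering`: `assignment` tibble
#'   (`cell_id`, `cluster`, `cluster_label`, `truth_label`), `hclust`, `k`,
#'   `accuracy` (`NA` without labels).
#' @export
cluster_cells <- function(features, k = 2, linkage = "ward.D2") {
  check_feature_tbl(features)
  x <- as.matrix(features[feature_cols])
  if (any(!is.finite(x))) abort("Feature matrix must be complete; run impute_missing() first.")
  if (k > nrow(x)) abort("`k` exceeds the number of cells.")
  ids <- features$cell_id %||% sprintf("cell_%03d", seq_len(nrow(x)))
  rownames(x) <- ids
  hc <- hclust(dist(x), method = linkage)
  cl <- cutree(hc, k = k)
  truth <- features$truth_label %||% rep(NA_character_, nrow(x))
  cluster_label <- rep(NA_character_, k)
  if (!all(is.na(truth))) {
    for (g in seq_len(k)) {
      tab <- table(truth[cl == g])
      if (length(tab) == 0) next
      top <- names(tab)[tab == max(tab)]
      cluster_label[g] <- if ("PN" %in% top) "PN" else top[1]
    }
  }
  assignment <- tibble(cell_id = ids, cluster = unname(cl),
                       cluster_label = cluster_label[cl],
                       truth_label = truth)
  accuracy <- if (all(is.na(truth))) NA_real_ else {
    mean(assignment$cluster_label == assignment$truth_label, na.rm = TRUE)
  }
  structure(list(assignment = assignment, hclust = hc, k = k,
                 accuracy = accuracy),
            class = "al_clustering")
}

#' @export
print.al_clustering <- function(x, ...) {
  cat(sprintf("<al_clustering> %d cells in %d clusters; accuracy %s\n",
              nrow(x$assignment), x$k,
              ifelse(is.na(x$accuracy), "n/a", sprintf("%.3f", x$accuracy))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.al_clustering <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.al_clustering <- function(x, ...) {
  tibble(n_cells = nrow(x$assignment), k = x$k, accuracy = x$accuracy)
}

#' Within- versus between-subclass similarity
#'
#' Compares pairwise feature correlations of cells inside a focal subclass
#' with pairs of cells from different subclasses (two-sided rank-sum test),
#' the analysis that shows e.g. pan-glomerular LNs to be an
#' electrophysiologically homogeneous group.
#'
#' @param fc an `al_feature_cor` from [pairwise_feature_correlations()].
#' @param subclass named character vector (names = cell ids) of subclass
#'   labels.
#' @param focal the focal subclass label.
#' @return One-row tibble: within/between means and SDs, pair counts,
#'   `p_value`.
#' @export
subclass_homogeneity <- function(fc, subclass, focal) {
  stopifnot(inherits(fc, "al_feature_cor"))
  sa <- subclass[fc$pairs$cell_a]
  sb <- subclass[fc$pairs$cell_b]
  ok <- !is.na(sa) & !is.na(sb) & is.finite(fc$pairs$r)
  within <- fc$pairs$r[ok & sa == focal & sb == focal]
  between <- fc$pairs$r[ok & sa != sb]
  if (length(within) < 1 || length(between) < 1) {
    abort("Need at least one within-subclass and one between-subclass pair.")
  }
  p <- suppressWarnings(wilcox.test(within, between)$p.value)
  tibble(focal = focal,
         mean_within = mean(within), sd_within = sd(within),
         n_within = length(within),
         mean_between = mean(between), sd_between = sd(between),
         n_between = length(between),
         p_value = p)
}
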