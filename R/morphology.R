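# Neuron-skeleton machinery: SWC I/O, 0.5 um resampling, Strahler ordering,
# lateral-horn axon pruning, dotprops conversion, and normalized
# NBLAST-style pairwise similarity.

#' Read / write SWC neuron skeletons
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments,
#' coordinates in micrometers, one root with parent `-1`. Reading validates
#' that node ids are unique, that exactly one root exists, and that parent
#' links form a tree (no cycles, no forward references to missing nodes);
#' violations raise an error naming the offending line.
#'
#' @param path file path.
#' @param skeleton for `write_swc()`, an `al_skeleton` tibble (`node_id`,
#'   `type`, `x`, `y`, `z`, `radius`, `parent_id`).
#' @return `read_swc()` returns an `al_skeleton` tibble; `write_swc()`
#'   returns the path invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0) abort("SWC file has no data lines.")
  fields <- strsplit(trimws(lines[body]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) {
    abort(sprintf("SWC line %d does not have 7 columns.", body[bad[1]]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(!is.finite(m))) {
    abort(sprintf("SWC line %d has a non-numeric field.",
                  body[which(rowSums(!is.finite(m)) > 0)[1]]))
  }
  sk <- tibble(node_id = as.integer(m[, 1]), type = as.integer(m[, 2]),
               x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
               parent_id = as.integer(m[, 7]))
  dup <- duplicated(sk$node_id)
  if (any(dup)) {
    abort(sprintf("Duplicate node id %d at SWC line %d.",
                  sk$node_id[dup][1], body[which(dup)[1]]))
  }
  validate_skeleton(sk, lines_at = body)
  structure(sk, class = c("al_skeleton", class(tibble())))
}

validate_skeleton <- function(sk, lines_at = NULL) {
  roots <- which(sk$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("Skeleton must have exactly one root (parent -1); found %d.",
                  length(roots)))
  }
  missing_parent <- !(sk$parent_id %in% c(-1L, sk$node_id))
  if (any(missing_parent)) {
    i <- which(missing_parent)[1]
    abort(sprintf("Node %d references missing parent %d%s.",
                  sk$node_id[i], sk$parent_id[i],
                  if (!is.null(lines_at)) sprintf(" (line %d)", lines_at[i]) else ""))
  }
  # cycle check: every node must reach the root
  parent_of <- setNames(sk$parent_id, sk$node_id)
  n <- nrow(sk)
  for (start in sk$node_id) {
    cur <- start; steps <- 0L
    while (parent_of[[as.character(cur)]] != -1L) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) abort(sprintf("Cycle in parent links involving node %d.", start))
    }
  }
  invisible(sk)
}

#' @rdname read_swc
#' @export
write_swc <- function(skeleton, path) {
  stopifnot(all(c("node_id", "type", "x", "y", "z", "radius", "parent_id")
                %in% names(skeleton)))
  header <- c("# SWC export", "# id type x y z radius parent")
  rows <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                  skeleton$node_id, skeleton$type, skeleton$x, skeleton$y,
                  skeleton$z, skeleton$radius, skeleton$parent_id)
  writeLines(c(header, rows), path)
  invisible(path)
}

# Euclidean length of all parent-child edges.
#' Total cable length of a skeleton
#' @param skeleton an `al_skeleton` tibble.
#' @return Length in micrometers.
#' @export
cable_length <- function(skeleton) {
  idx <- match(skeleton$parent_id, skeleton$node_id)
  has <- !is.na(idx)
  sum(sqrt((skeleton$x[has] - skeleton$x[idx[has]])^2 +
           (skeleton$y[has] - skeleton$y[idx[has]])^2 +
           (skeleton$z[has] - skeleton$z[idx[has]])^2))
}

#' Resample a skeleton to a maximum inter-node spacing
#'
#' Subdivides every parent-child edge longer than `spacing` by inserting
#' evenly spaced collinear nodes, so all edges end up no longer than
#' `spacing` while every original node — in particular branch points, end
#' points and the root — is preserved exactly and the total cable length is
#' unchanged. This controls for neuron size before dotprops conversion
#' (0.5 um default spacing).
#'
#' @param skeleton an `al_skeleton` tibble.
#' @param spacing maximum edge length (um), default 0.5.
#' @return The resampled `al_skeleton`.
#' @export
resample_skeleton <- function(skeleton, spacing = 0.5) {
  assert_scalar_number(spacing, "spacing", min = 1e-12)
  sk <- skeleton
  idx <- match(sk$parent_id, sk$node_id)
  next_id <- max(sk$node_id) + 1L
  new_rows <- list()
  new_parent <- sk$parent_id
  for (i in seq_len(nrow(sk))) {
    pi <- idx[i]
    if (is.na(pi)) next
    dx <- sk$x[i] - sk$x[pi]; dy <- sk$y[i] - sk$y[pi]; dz <- sk$z[i] - sk$z[pi]
    len <- sqrt(dx^2 + dy^2 + dz^2)
    if (len <= spacing) next
    n_seg <- ceiling(len / spacing)
    fr <- seq_len(n_seg - 1L) / n_seg
    ids <- next_id + seq_len(n_seg - 1L) - 1L
    next_id <- next_id + n_seg - 1L
    new_rows[[length(new_rows) + 1L]] <- tibble(
      node_id = ids, type = sk$type[i],
      x = sk$x[pi] + fr * dx, y = sk$y[pi] + fr * dy, z = sk$z[pi] + fr * dz,
      radius = sk$radius[pi] + fr * (sk$radius[i] - sk$radius[pi]),
      parent_id = c(sk$node_id[pi], ids[-length(ids)])
    )
    new_parent[i] <- ids[length(ids)]
  }
  sk$parent_id <- new_parent
  out <- bind_rows(sk, list_rbind(new_rows))
  structure(out, class = c("al_skeleton", class(tibble())),
            cell_id = attr(skeleton, "cell_id"),
            label = attr(skeleton, "label"))
}

#' Strahler order of every node
#'
#' Leaves have order 1; a parent whose children attain a common maximum
#' order `m` more than once gets `m + 1`, otherwise the maximum. Orders are
#' assigned per node segment-wise: a node inherits the order of the branch
#' it lies on.
#'
#' @param skeleton an `al_skeleton` tibble.
#' @return Integer vector of orders parallel to the rows.
#' @export
strahler_order <- function(skeleton) {
  n <- nrow(skeleton)
  idx <- match(skeleton$parent_id, skeleton$node_id)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(idx[i])) children[[idx[i]]] <- c(children[[idx[i]]], i)
  }
  order_out <- rep(NA_integer_, n)
  # iterative post-order traversal from the root
  root <- which(skeleton$parent_id == -1L)
  stack <- root
  post <- integer(0)
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(post, cur)
    stack <- c(stack, children[[cur]])
  }
  for (i in rev(post)) {
    ch <- children[[i]]
    if (length(ch) == 0) {
      order_out[i] <- 1L
    } else {
      co <- order_out[ch]
      m <- max(co)
      order_out[i] <- if (sum(co == m) >= 2L) m + 1L else m
    }
  }
  order_out
}

# children list helper
skeleton_children <- function(skeleton) {
  idx <- match(skeleton$parent_id, skeleton$node_id)
  ch <- vector("list", nrow(skeleton))
  for (i in seq_len(nrow(skeleton))) {
    if (!is.na(idx[i])) ch[[idx[i]]] <- c(ch[[idx[i]]], i)
  }
  ch
}

#' Isolate the lateral-horn axonal branches of a projection neuron
#'
#' Reproduces the two-step axon isolation used before morphological
#' similarity scoring: (1) all cable proximal to the most lateral branch
#' point is removed, keeping the subtree distal to it (the lateral-horn
#' arborization); (2) within that subtree, nodes on the maximal-Strahler
#' cable (the central tract) are pruned away, leaving only the axonal
#' branches. The medial-to-lateral direction is a named axis of the
#' template space.
#'
#' @param skeleton an `al_skeleton` tibble.
#' @param axis which coordinate increases laterally: `"+x"` (default),
#'   `"-x"`, `"+y"`, `"-y"`, `"+z"`, `"-z"`.
#' @param fallback what to do when the neuron has no branch point or
#'   pruning would empty it: `"error"` (default) or `"whole"` (return the
#'   unpruned subtree).
#' @return An `al_skeleton` tibble of the surviving nodes. Orphaned
#'   branches each keep their own root (`parent_id = -1`); the result is a
#'   forest meant for dotprops conversion, flagged with attribute
#'   `pruned = TRUE`.
#' @export
prune_to_lh_axon <- function(skeleton, axis = "+x",
                             fallback = c("error", "whole")) {
  fallback <- match.arg(fallback)
  ax <- match.arg(substr(axis, 2, 2), c("x", "y", "z"))
  sgn <- if (substr(axis, 1, 1) == "-") -1 else 1
  lat <- sgn * skeleton[[ax]]
  ch <- skeleton_children(skeleton)
  branch_pts <- which(lengths(ch) >= 2L)
  if (length(branch_pts) == 0 || diff(range(lat)) < 1e-9) {
    if (fallback == "whole") return(skeleton)
    abort("No lateral branch point found; check the medial-to-lateral axis or use fallback = \"whole\".")
  }
  bp <- branch_pts[which.max(lat[branch_pts])]
  # subtree distal to bp
  keep <- logical(nrow(skeleton))
  stack <- bp
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    keep[cur] <- TRUE
    stack <- c(stack, ch[[cur]])
  }
  sub <- skeleton[keep, ]
  sub$parent_id[!(sub$parent_id %in% sub$node_id)] <- -1L
  orders <- strahler_order_forest(sub)
  max_o <- max(orders)
  out <- sub[orders < max_o, , drop = FALSE]
  if (nrow(out) == 0) {
    if (fallback == "whole") {
      out <- sub
    } else {
      abort("Strahler pruning emptied the neuron; consider fallback = \"whole\" or flipping the axis.")
    }
  }
  out$parent_id[!(out$parent_id %in% out$node_id)] <- -1L
  structure(out, class = c("al_skeleton", class(tibble())),
            cell_id = attr(skeleton, "cell_id"),
            label = attr(skeleton, "label"), pruned = TRUE)
}

# Strahler order tolerant of multiple roots (forest), used after pruning.
strahler_order_forest <- function(skeleton) {
  n <- nrow(skeleton)
  ch <- skeleton_children(skeleton)
  roots <- which(!(skeleton$parent_id %in% skeleton$node_id) |
                   skeleton$parent_id == -1L)
  order_out <- rep(NA_integer_, n)
  post <- integer(0)
  stack <- roots
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(post, cur)
    stack <- c(stack, ch[[cur]])
  }
  for (i in rev(post)) {
    co <- order_out[ch[[i]]]
    if (length(co) == 0) order_out[i] <- 1L
    else {
      m <- max(co)
      order_out[i] <- if (sum(co == m) >= 2L) m + 1L else m
    }
  }
  order_out
}

#' Convert a skeleton to dotprops (points plus unit tangents)
#'
#' Represents the (resampled) skeleton as a point cloud with a unit tangent
#' per point, the dominant direction (first principal component) of each
#' point's `k` nearest neighbors. Tangent signs are arbitrary; all scoring
#' uses absolute dot products.
#'
#' @param skeleton an `al_skeleton` tibble with at least `k_neighbors`
#'   nodes.
#' @param k_neighbors neighborhood size (including the point itself),
#'   default 5.
#' @return A list of class `al_dotprops`: `points` (n x 3 matrix),
#'   `tangents` (n x 3 unit rows).
#' @export
to_dotprops <- function(skeleton, k_neighbors = 5) {
  pts <- as.matrix(skeleton[, c("x", "y", "z")])
  n <- nrow(pts)
  if (n < k_neighbors) {
    abort(sprintf("Need at least k_neighbors = %d points; have %d.",
                  k_neighbors, n))
  }
  tangents <- matrix(0, n, 3)
  # brute-force kNN in chunks to bound memory
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(pts^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(pts)
    for (i in seq_len(e - s + 1L)) {
      nb <- order(d2[i, ])[seq_len(k_neighbors)]
      pc <- pts[nb, , drop = FALSE]
      pc <- sweep(pc, 2, colMeans(pc))
      v <- svd(pc, nu = 0, nv = 1)$v[, 1]
      tangents[s + i - 1L, ] <- v / sqrt(sum(v^2))
    }
  }
  structure(list(points = pts, tangents = tangents), class = "al_dotprops")
}

#' @export
print.al_dotprops <- function(x, ...) {
  cat(sprintf("<al_dotprops> %d points\n", nrow(x$points)))
  invisible(x)
}

#' NBLAST-style similarity between two dotprops
#'
#' The raw score sums, over query points, a kernel of the distance to the
#' nearest target point and the absolute dot product of their tangents:
#' `exp(-d^2 / (2 sigma^2)) * |dot|^gamma`. The normalized score divides
#' the raw query-to-target score by the query's self-match, so a self
#' comparison scores exactly 1; scores are asymmetric in general. A
#' user-supplied `scoring_fn(dist, absdot)` may replace the kernel (e.g. an
#' externally trained scoring table).
#'
#' @param query,target `al_dotprops` objects.
#' @param sigma distance scale of the kernel (um), default 3.
#' @param gamma exponent of the tangent alignment term, default 1.
#' @param scoring_fn optional `function(dist, absdot)` returning per-point
#'   scores.
#' @param normalize divide by the query self-match (default `TRUE`).
#' @return A single numeric score.
#' @export
nblast_score <- function(query, target, sigma = 3, gamma = 1,
                         scoring_fn = NULL, normalize = TRUE) {
  stopifnot(inherits(query, "al_dotprops"), inherits(target, "al_dotprops"))
  if (nrow(target$points) == 0) abort("Empty target dotprops.")
  raw <- nblast_raw(query, target, sigma, gamma, scoring_fn)
  if (!normalize) return(raw)
  self <- nblast_raw(query, query, sigma, gamma, scoring_fn)
  raw / self
}

nblast_raw <- function(query, target, sigma, gamma, scoring_fn) {
  qp <- query$points; tp <- target$points
  n <- nrow(qp)
  total <- 0
  chunk <- max(1L, floor(2e6 / nrow(tp)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(qp[s:e, , drop = FALSE]^2), rowSums(tp^2), "+") -
      2 * qp[s:e, , drop = FALSE] %*% t(tp)
    d2[d2 < 0] <- 0
    nn <- max.col(-d2, ties.method = "first")
    d <- sqrt(d2[cbind(seq_len(e - s + 1L), nn)])
    absdot <- abs(rowSums(query$tangents[s:e, , drop = FALSE] *
                            target$tangents[nn, , drop = FALSE]))
    total <- total + if (is.null(scoring_fn)) {
      sum(exp(-d^2 / (2 * sigma^2)) * absdot^gamma)
    } else {
      sum(scoring_fn(d, absdot))
    }
  }
  total
}

#' Pairwise morphological similarity of a set of skeletons
#'
#' Preprocesses every skeleton (resampling to `spacing`, optional
#' lateral-horn pruning, dotprops conversion), computes all normalized
#' pairwise NBLAST scores, and compares homotypic pairs (same label, e.g.
#' same glomerulus) with heterotypic pairs using a two-sided rank-sum test.
#' The headline per-pair statistic is the mean of the two directed scores;
#' a z-scored matrix (mean 0, SD 1 over off-diagonal entries) is returned
#' for display.
#'
#' @param skeletons list of `al_skeleton` tibbles; labels are taken from
#'   the `label` attribute unless `labels` is given.
#' @param labels optional character vector of group labels.
#' @param spacing resampling spacing (um), default 0.5.
#' @param prune apply [prune_to_lh_axon()] first (default `FALSE`).
#' @param axis lateral axis for pruning.
#' @param sigma,gamma,scoring_fn kernel parameters, see [nblast_score()].
#' @param k_neighbors dotprops neighborhood size.
#' @return A list of class `al_similarity`: `matrix` (directed normalized
#'   scores), `sym_matrix` (mean of both directions), `zscore_matrix`,
#'   `pairs` tibble, `group_means`, `p_value`, `n_homotypic`,
#'   `n_heterotypic`.
#' @export
similarity_analysis <- function(skeletons, labels = NULL, spacing = 0.5,
                                prune = FALSE, axis = "+x", sigma = 3,
                                gamma = 1, scoring_fn = NULL,
                                k_neighbors = 5) {
  n <- length(skeletons)
  if (n < 2) abort("Need at least two skeletons.")
  labels <- labels %||% vapply(skeletons, function(s) {
    attr(s, "label") %||% NA_character_
  }, character(1))
  if (length(unique(labels)) < 2) {
    abort("Need at least two label groups for a homotypic/heterotypic comparison.")
  }
  ids <- vapply(seq_len(n), function(i) {
    attr(skeletons[[i]], "cell_id") %||% sprintf("neuron_%02d", i)
  }, character(1))
  dps <- map(skeletons, function(s) {
    s <- resample_skeleton(s, spacing)
    if (prune) s <- prune_to_lh_axon(s, axis = axis)
    to_dotprops(s, k_neighbors)
  })
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  selfs <- map_dbl(dps, function(d) nblast_raw(d, d, sigma, gamma, scoring_fn))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) 1 else {
        nblast_raw(dps[[i]], dps[[j]], sigma, gamma, scoring_fn) / selfs[i]
      }
    }
  }
  sym <- (m + t(m)) / 2
  off <- sym[upper.tri(sym)]
  z <- (sym - mean(off)) / sd(off)
  up <- which(upper.tri(sym), arr.ind = TRUE)
  pairs <- tibble(
    neuron_a = ids[up[, 1]], neuron_b = ids[up[, 2]],
    score = sym[up],
    pair = ifelse(labels[up[, 1]] == labels[up[, 2]],
                  "homotypic", "heterotypic"))
  gm <- pairs |>
    group_by(.data$pair) |>
    summarise(mean_score = mean(.data$score), sd_score = sd(.data$score),
              n = n(), .groups = "drop")
  hom <- pairs$score[pairs$pair == "homotypic"]
  het <- pairs$score[pairs$pair == "heterotypic"]
  p <- if (length(hom) && length(het)) {
    suppressWarnings(wilcox.test(hom, het)$p.value)
  } else NA_real_
  structure(list(matrix = m, sym_matrix = sym, zscore_matrix = z,
                 pairs = pairs, group_means = gm, p_value = p,
                 n_homotypic = length(hom), n_heterotypic = length(het)),
            class = "al_similarity")
}

#' @export
print.al_similarity <- function(x, ...) {
  cat(sprintf("<al_similarity> %d neurons; homotypic vs heterotypic p = %s\n",
              nrow(x$matrix), format(x$p_value, digits = 3)))
  print(x$group_means)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.al_similarity <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.al_similarity <- function(x, ...) {
  hm <- x$group_means
  tibble(
    n_neurons = nrow(x$matrix),
    homotypic_mean = hm$mean_score[hm$pair == "homotypic"],
    heterotypic_mean = hm$mean_score[hm$pair == "heterotypic"],
    p_value = x$p_value
  )
}

#' Summaries of an LN-by-glomerulus innervation matrix
#'
#' Column means give the fraction of local neurons innervating each
#' landmark glomerulus; row sums give the number of landmark glomeruli each
#' LN innervates.
#'
#' @param mat logical (or 0/1) matrix, LNs in rows, glomeruli in columns,
#'   with dimnames.
#' @return A list: `glomerulus_fractions` tibble, `ln_counts` tibble.
#' @export
innervation_summary <- function(mat) {
  mat <- as.matrix(mat)
  if (length(mat) == 0) abort("Empty innervation matrix.")
  storage.mode(mat) <- "double"
  if (!all(mat %in% c(0, 1))) abort("Innervation matrix must be boolean.")
  list(
    glomerulus_fractions = tibble(
      glomerulus = colnames(mat) %||% sprintf("g%02d", seq_len(ncol(mat))),
      fraction = unname(colMeans(mat)),
      n_ln = nrow(mat)),
    ln_counts = tibble(
      ln_id = rownames(mat) %||% sprintf("LN%02d", seq_len(nrow(mat))),
      n_glomeruli = unname(rowSums(mat)))
  )
}
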