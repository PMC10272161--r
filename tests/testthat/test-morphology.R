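# SWC I/O, resampling geometry, Strahler ordering, lateral pruning,
# dotprops tangents and the normalized NBLAST similarity.

test_that("SWC round-trip is identity and malformed files are rejected", {
  sk <- random_tree_skeleton(20, seed = 1)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, f)
  back <- read_swc(f)
  expect_equal(as.data.frame(back), as.data.frame(sk), tolerance = 1e-6)
  # read-write-read identity
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(back, f2)
  expect_equal(as.data.frame(read_swc(f2)), as.data.frame(back))
  # node count equals data line count
  expect_equal(nrow(back),
               sum(!grepl("^\\s*#", readLines(f)) & nzchar(readLines(f))))
  # 3-node chain has depth 2
  chain <- straight_segment(10, n_nodes = 3)
  f3 <- withr::local_tempfile(fileext = ".swc")
  write_swc(chain, f3)
  expect_equal(max(strahler_order(read_swc(f3))), 1)
  # malformed inputs
  f4 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 2", "2 0 1 0 0 1 1"), f4)   # cycle, no root
  expect_error(read_swc(f4), "root")
  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 5"), f4)  # missing parent
  expect_error(read_swc(f4), "missing parent")
  writeLines(c("1 0 0 0 0 1 -1", "1 0 1 0 0 1 1"), f4)  # duplicate id
  expect_error(read_swc(f4), "Duplicate")
  writeLines("1 0 0 0 0 1", f4)                          # 6 columns
  expect_error(read_swc(f4), "7 columns")
})

test_that("resampling a straight 10 um segment at 0.5 um gives 21 nodes", {
  seg <- straight_segment(10)
  rs <- resample_skeleton(seg, 0.5)
  expect_equal(nrow(rs), 21)
  expect_equal(cable_length(rs), 10)
  # already finer than the spacing: no-op
  fine <- resample_skeleton(seg, 0.5)
  expect_equal(nrow(resample_skeleton(fine, 0.5)), nrow(fine))
})

test_that("resampling preserves cable length and branch/end points on random trees", {
  for (s in 1:5) {
    sk <- random_tree_skeleton(15, seed = s)
    rs <- resample_skeleton(sk, 0.5)
    expect_lt(abs(cable_length(rs) - cable_length(sk)) /
                cable_length(sk), 0.01)
    # all original nodes survive with identical coordinates
    orig <- rs[match(sk$node_id, rs$node_id), ]
    expect_equal(orig$x, sk$x)
    # every edge is no longer than the spacing
    idx <- match(rs$parent_id, rs$node_id)
    has <- !is.na(idx)
    edge <- sqrt((rs$x[has] - rs$x[idx[has]])^2 +
                   (rs$y[has] - rs$y[idx[has]])^2 +
                   (rs$z[has] - rs$z[idx[has]])^2)
    expect_lte(max(edge), 0.5 + 1e-9)
  }
})

test_that("Strahler order matches the recursive oracle on random trees", {
  # unbranched path: all ones
  expect_equal(strahler_order(straight_segment(10, 5)), rep(1L, 5))
  # two leaves merging: junction side gets order 2
  y <- structure(tibble::tibble(
    node_id = 1:4, type = 0L,
    x = c(0, 1, 2, 2), y = c(0, 0, 1, -1), z = 0, radius = 1,
    parent_id = c(-1L, 1L, 2L, 2L)), class = c("al_skeleton",
                                               class(tibble::tibble())))
  expect_equal(strahler_order(y), c(2L, 2L, 1L, 1L))
  # full binary tree of depth d: root order d + 1
  build_binary <- function(depth) {
    rows <- list(tibble::tibble(node_id = 1L, type = 0L, x = 0, y = 0,
                                z = 0, radius = 1, parent_id = -1L))
    nid <- 1L
    frontier <- 1L
    for (d in seq_len(depth)) {
      nxt <- integer(0)
      for (p in frontier) {
        for (k in 1:2) {
          nid <- nid + 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            node_id = nid, type = 0L, x = d, y = nid / 10, z = 0,
            radius = 1, parent_id = p)
          nxt <- c(nxt, nid)
        }
      }
      frontier <- nxt
    }
    structure(purrr::list_rbind(rows),
              class = c("al_skeleton", class(tibble::tibble())))
  }
  for (d in 1:4) {
    expect_equal(max(strahler_order(build_binary(d))), d + 1L)
  }
  # random trees up to 50 nodes vs brute-force recursion
  for (s in 1:10) {
    sk <- random_tree_skeleton(sample(5:50, 1), seed = 100 + s)
    expect_identical(strahler_order(sk), strahler_oracle(sk))
  }
})

test_that("lateral pruning keeps the tuft and drops the central tract", {
  sks <- generate_skeletons(1, 1, jitter_sd = 0, seed = 3)
  sk <- sks[[1]]
  pruned <- prune_to_lh_axon(sk)
  expect_gt(nrow(pruned), 0)
  expect_lt(nrow(pruned), nrow(sk))
  # everything proximal to the most lateral branch point is gone:
  # the medial side branch (y-extended early trunk nodes) does not survive
  expect_gt(min(pruned$x), 0.2 * max(sk$x))
  # no surviving node carries the isolated axon's maximal Strahler order
  ch <- mozal:::skeleton_children(sk)
  bp <- which(lengths(ch) >= 2)
  bp_lat <- bp[which.max(sk$x[bp])]
  keep <- logical(nrow(sk)); stack <- bp_lat
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    keep[cur] <- TRUE; stack <- c(stack, ch[[cur]])
  }
  sub <- sk[keep, ]
  sub$parent_id[!(sub$parent_id %in% sub$node_id)] <- -1L
  max_order <- max(mozal:::strahler_order_forest(sub))
  surviving_orders <- mozal:::strahler_order_forest(sub)[
    match(pruned$node_id, sub$node_id)]
  expect_true(all(surviving_orders < max_order))
  # degenerate neuron at a single coordinate errors (or falls back)
  flat <- straight_segment(0, 5)
  expect_error(prune_to_lh_axon(flat), "axis")
  expect_equal(nrow(prune_to_lh_axon(flat, fallback = "whole")), 5)
})

test_that("dotprops tangents follow local geometry", {
  line <- resample_skeleton(straight_segment(20), 0.5)
  dp <- to_dotprops(line)
  expect_equal(nrow(dp$points), nrow(line))
  expect_true(all(abs(abs(dp$tangents[, 1]) - 1) < 1e-9))
  expect_equal(sqrt(rowSums(dp$tangents^2)), rep(1, nrow(line)))
  # densely sampled circle: tangents perpendicular to radius within 5 deg
  th <- seq(0, 2 * pi, length.out = 200)[-1]
  circ <- structure(tibble::tibble(
    node_id = seq_along(th), type = 0L,
    x = 10 * cos(th), y = 10 * sin(th), z = 0, radius = 1,
    parent_id = c(-1L, seq_len(length(th) - 1L))),
    class = c("al_skeleton", class(tibble::tibble())))
  dpc <- to_dotprops(circ)
  radial <- cbind(cos(th), sin(th), 0)
  cosang <- abs(rowSums(dpc$tangents * radial))
  expect_lt(max(cosang), sin(5 * pi / 180))
  expect_error(to_dotprops(straight_segment(10, 3), k_neighbors = 5),
               "at least")
})

test_that("normalized NBLAST self-score is 1 and decays with distance", {
  sk <- generate_skeletons(1, 1, seed = 5)[[1]]
  dp <- to_dotprops(resample_skeleton(sk, 0.5))
  expect_equal(nblast_score(dp, dp), 1.0)
  # identical copy translated 1 mm away scores at the kernel floor
  far <- dp
  far$points[, 1] <- far$points[, 1] + 1000
  expect_lt(nblast_score(dp, far), 1e-6)
  # rigid motion of both neurons leaves raw scores unchanged
  rot <- matrix(c(cos(0.7), -sin(0.7), 0, sin(0.7), cos(0.7), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  move <- function(d) {
    d$points <- d$points %*% t(rot) + matrix(c(5, -3, 2), nrow(d$points), 3,
                                             byrow = TRUE)
    d$tangents <- d$tangents %*% t(rot)
    d
  }
  sk2 <- generate_skeletons(2, 1, seed = 6)[[2]]
  dp2 <- to_dotprops(resample_skeleton(sk2, 0.5))
  raw <- mozal:::nblast_raw(dp, dp2, sigma = 3, gamma = 1, scoring_fn = NULL)
  raw_moved <- mozal:::nblast_raw(move(dp), move(dp2), sigma = 3, gamma = 1,
                                  scoring_fn = NULL)
  expect_equal(raw_moved, raw, tolerance = 1e-9)
})

test_that("jittered clones outscore unrelated trees for any monotone kernel", {
  sks <- generate_skeletons(2, 2, jitter_sd = 0.25, seed = 7)
  dps <- lapply(sks, function(s) to_dotprops(resample_skeleton(s, 0.5)))
  kernels <- list(
    NULL,                                                  # default Gaussian
    function(d, a) exp(-d / 2) * a,                        # exponential
    function(d, a) (d < 5) * a                             # hard cutoff
  )
  for (k in kernels) {
    clone <- nblast_score(dps[[1]], dps[[2]], scoring_fn = k)
    unrelated <- nblast_score(dps[[1]], dps[[3]], scoring_fn = k)
    expect_gt(clone, unrelated)
  }
})

test_that("similarity analysis separates homotypic from heterotypic pairs", {
  sks <- generate_skeletons(3, 3, jitter_sd = 0.3, seed = 8)
  res <- similarity_analysis(sks, spacing = 1)
  expect_equal(unname(diag(res$matrix)), rep(1, 9))
  gm <- res$group_means
  expect_gt(gm$mean_score[gm$pair == "homotypic"],
            gm$mean_score[gm$pair == "heterotypic"])
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n_homotypic, 3 * 3)
  expect_equal(res$n_heterotypic, choose(9, 2) - 9)
  # z-scored display matrix is standardized over off-diagonal entries
  off <- res$zscore_matrix[upper.tri(res$zscore_matrix)]
  expect_equal(mean(off), 0, tolerance = 1e-9)
  expect_equal(sd(off), 1, tolerance = 1e-9)
  expect_equal(glance(res)$homotypic_mean,
               gm$mean_score[gm$pair == "homotypic"])
  # a single label group cannot be compared
  expect_error(similarity_analysis(generate_skeletons(1, 3, seed = 9)),
               "two label groups")
  expect_error(similarity_analysis(sks[1]), "two skeletons")
})

test_that("innervation summary reduces to column means and row sums", {
  withr::with_seed(10, {
    m <- matrix(runif(41 * 14) < 0.5, 41, 14,
                dimnames = list(sprintf("LN%02d", 1:41),
                                sprintf("G%02d", 1:14)))
  })
  s <- innervation_summary(m)
  expect_equal(s$glomerulus_fractions$fraction, unname(colMeans(m)))
  expect_equal(s$ln_counts$n_glomeruli, unname(rowSums(m)))
  expect_equal(innervation_summary(matrix(1, 2, 3))$glomerulus_fractions$fraction,
               rep(1, 3))
  one <- matrix(c(1, 1, 1, rep(0, 11)), 1, 14)
  expect_equal(innervation_summary(one)$ln_counts$n_glomeruli, 3)
  expect_error(innervation_summary(matrix(numeric(0), 0, 0)), "Empty")
  expect_error(innervation_summary(matrix(2, 2, 2)), "boolean")
})
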