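# Shared fixtures built in code at test time.

# A small separable PN/LN feature table around the class regimes, for
# typing tests that do not need the full trace pipeline.
make_feature_cohort <- function(n_pn = 20, n_ln = 10, sd = 0.08, seed = 1) {
  generate_feature_cohort(n_pn, n_ln, rel_sd = sd, seed = seed)
}

# Disjoint one-hot tuning: cell i responds only to odor i (cyclically).
one_hot_tuning <- function(n_cells, n_odors, gain_hz = 30) {
  m <- matrix(0, n_cells, n_odors)
  for (i in seq_len(n_cells)) m[i, ((i - 1) %% n_odors) + 1] <- gain_hz
  m
}

# A tiny hand-checkable skeleton: straight 10 um segment on the x axis.
straight_segment <- function(length_um = 10, n_nodes = 2) {
  structure(
    tibble::tibble(
      node_id = seq_len(n_nodes), type = c(1L, rep(0L, n_nodes - 1L)),
      x = seq(0, length_um, length.out = n_nodes), y = 0, z = 0,
      radius = 0.5,
      parent_id = c(-1L, seq_len(n_nodes - 1L))
    ),
    class = c("al_skeleton", class(tibble::tibble()))
  )
}

# Recursive brute-force Strahler oracle, independent of the package's
# iterative implementation.
strahler_oracle <- function(sk) {
  children_of <- function(id) sk$node_id[sk$parent_id == id]
  rec <- function(id) {
    ch <- children_of(id)
    if (length(ch) == 0) return(1L)
    co <- vapply(ch, rec, integer(1))
    m <- max(co)
    if (sum(co == m) >= 2L) m + 1L else m
  }
  vapply(sk$node_id, rec, integer(1))
}

# Random tree skeleton with n nodes (each non-root node attaches to a
# uniformly chosen earlier node).
random_tree_skeleton <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
    structure(
      tibble::tibble(
        node_id = seq_len(n), type = 0L,
        x = runif(n, 0, 50), y = runif(n, 0, 50), z = runif(n, 0, 50),
        radius = 0.5, parent_id = parent
      ),
      class = c("al_skeleton", class(tibble::tibble()))
    )
  })
}

# Exact signed-rank two-sided p by explicit enumeration over all 2^n sign
# assignments (oracle; only for small n).
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
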