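#' Generate synthetic neuron skeletons as jittered homotypic clones
#'
#' Builds `n_types` random rooted trees ("type" archetypes, each carrying a
#' pseudo-glomerulus label) and, for each, `clones_per_type` copies whose
#' node coordinates are independently jittered with isotropic Gaussian noise.
#' Clones of a type share topology exactly, emulating pairs of homotypic
#' projection neurons whose axonal arbors are similar but not identical.
#' Each archetype is a medial-to-lateral trunk along +x ending in a branched
#' lateral tuft (so the lateral-horn pruning operation has the structure it
#' expects), plus a medial side branch.
#'
#' @param n_types number of archetypes (pseudo-glomeruli).
#' @param clones_per_type clones per archetype (`>= 1`).
#' @param jitter_sd coordinate jitter SD (micrometers, `>= 0`).
#' @param seed integer seed.
#' @param trunk_length_um,tuft_points trunk cable length and number of tuft
#'   branch tips of each archetype.
#' @return A list of `al_skeleton` tibbles; each has attributes `cell_id`,
#'   `label` (pseudo-glomerulus `type_<k>`), and `clone`.
#' @examples
#' sks <- generate_skeletons(2, 2, jitter_sd = 0.25, seed = 1)
#' attr(sks[[1]], "label")
#' @export
generate_skeletons <- function(n_types, clones_per_type, jitter_sd = 0.25,
                               seed = 1, trunk_length_um = 60,
                               tuft_points = 6) {
  if (clones_per_type < 1) abort("`clones_per_type` must be >= 1.")
  assert_scalar_number(jitter_sd, "jitter_sd", min = 0)
  stopifnot(n_types >= 1)
  archetypes <- with_seed(derive_seed(seed, "skeleton-types"), {
    map(seq_len(n_types), function(k) {
      random_pn_archetype(trunk_length_um, tuft_points)
    })
  })
  out <- list()
  with_seed(derive_seed(seed, "skeleton-jitter"), {
    for (k in seq_len(n_types)) {
      for (cl in seq_len(clones_per_type)) {
        sk <- archetypes[[k]]
        if (jitter_sd > 0) {
          n <- nrow(sk)
          sk$x <- sk$x + rnorm(n, 0, jitter_sd)
          sk$y <- sk$y + rnorm(n, 0, jitter_sd)
          sk$z <- sk$z + rnorm(n, 0, jitter_sd)
        }
        out[[length(out) + 1L]] <- structure(
          sk,
          class = c("al_skeleton", class(tibble())),
          cell_id = sprintf("type%02d_clone%02d", k, cl),
          label = sprintf("type_%02d", k),
          clone = cl
        )
      }
    }
  })
  out
}

# One archetype: trunk along +x with a medial side branch, then a random
# branched tuft at the lateral end.
random_pn_archetype <- function(trunk_length_um, tuft_points) {
  step <- 2
  n_trunk <- max(3L, round(trunk_length_um / step))
  nodes <- tibble(
    node_id = seq_len(n_trunk),
    type = c(1L, rep(0L, n_trunk - 1L)),
    x = (seq_len(n_trunk) - 1) * step,
    y = 0, z = 0, radius = 0.5,
    parent_id = c(-1L, seq_len(n_trunk - 1L))
  )
  # medial side branch off an early trunk node (pruned away downstream)
  side_from <- 2L
  n_side <- 4L
  side <- tibble(
    node_id = n_trunk + seq_len(n_side),
    type = 0L,
    x = nodes$x[side_from] + runif(1, -1, 1),
    y = seq_len(n_side) * step, z = runif(1, -1, 1),
    radius = 0.5,
    parent_id = c(side_from, n_trunk + seq_len(n_side - 1L))
  )
  nodes <- bind_rows(nodes, side)
  # lateral tuft: random tips sprouting from the trunk end and from each other
  tip_anchor <- n_trunk
  for (i in seq_len(tuft_points)) {
    from <- if (i <= 2) tip_anchor else sample(tip_anchor:nrow(nodes), 1)
    dir <- c(runif(1, 0.3, 1), runif(1, -1, 1), runif(1, -1, 1))
    dir <- dir / sqrt(sum(dir^2))
    len <- runif(1, 8, 16)
    n_seg <- max(2L, round(len / step))
    base <- unlist(nodes[nodes$node_id == from, c("x", "y", "z")])
    seg <- tibble(
      node_id = nrow(nodes) + seq_len(n_seg),
      type = 0L,
      x = base[1] + dir[1] * seq_len(n_seg) * step,
      y = base[2] + dir[2] * seq_len(n_seg) * step,
      z = base[3] + dir[3] * seq_len(n_seg) * step,
      radius = 0.4,
      parent_id = c(from, nrow(nodes) + seq_len(n_seg - 1L))
    )
    nodes <- bind_rows(nodes, seg)
  }
  nodes
}
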