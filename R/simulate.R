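#' Random unrooted binary topology
#'
#' Draws a topology by random sequential leaf attachment (via
#' [ape::rtopology()]), with leaves labelled `t1..tn`. Branch lengths are
#' not generated.
#'
#' @param n_taxa Number of leaves, at least 4.
#' @param seed Optional integer seed.
#' @return An unrooted binary `phylo` with `n_taxa - 3` non-trivial splits.
#' @export
random_topology <- function(n_taxa, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 4) {
    stop("random_topology: n_taxa must be an integer >= 4", call. = FALSE)
  }
  draw <- function() {
    tr <- ape::rtopology(as.integer(n_taxa), rooted = FALSE, br = NULL)
    normalize_topology(tr)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply random subtree-prune-and-regraft moves
#'
#' One SPR move prunes a uniformly chosen subtree and regrafts it on a
#' uniformly chosen eligible edge elsewhere, keeping the tree binary on the
#' same leaf set (via [phangorn::rSPR()]). On very small trees (4 leaves) a
#' move can regenerate the same quartet. Randomness comes from R's RNG
#' stream, so surrounding `set.seed()` (or the simulators' `seed` argument)
#' makes moves reproducible.
#'
#' @param t An unrooted binary `phylo` with at least 4 leaves.
#' @param n_moves Number of successive SPR moves (default 1).
#' @return A `phylo` on the same leaf set.
#' @export
random_spr <- function(t, n_moves = 1L) {
  if (!inherits(t, "phylo")) {
    stop("random_spr: expected a 'phylo' object", call. = FALSE)
  }
  if (length(t$tip.label) < 4L) {
    stop("random_spr: need at least 4 leaves", call. = FALSE)
  }
  if (n_moves < 1L) stop("random_spr: n_moves must be >= 1", call. = FALSE)
  out <- phangorn::rSPR(t, moves = as.integer(n_moves))
  normalize_topology(out)
}

#' Simulate a unimodal SPR-walk chain
#'
#' Emulates the topology component of an MCMC run without data: starting
#' from a random topology, each successive sample is the previous one after
#' a fixed number of random SPR moves. More moves per step mean less
#' autocorrelated samples and a larger effective sample size; a single move
#' per step on a large tree gives a strongly autocorrelated chain.
#'
#' @param n_taxa Leaves per tree (default 50, the reference simulation
#'   design).
#' @param n_samples Chain length (default 1000).
#' @param sprs_per_step SPR moves between successive samples (>= 1).
#' @param seed Integer seed; the whole chain is reproducible from it.
#' @return A [tree_sample].
#' @export
simulate_unimodal <- function(n_taxa = 50L, n_samples = 1000L,
                              sprs_per_step = 1L, seed = NULL) {
  if (n_samples < 20) {
    stop("simulate_unimodal: n_samples must be at least 20", call. = FALSE)
  }
  if (sprs_per_step < 1) {
    stop("simulate_unimodal: sprs_per_step must be >= 1", call. = FALSE)
  }
  run <- function() {
    trees <- vector("list", n_samples)
    trees[[1L]] <- random_topology(n_taxa)
    for (i in seq_len(n_samples - 1L)) {
      trees[[i + 1L]] <- random_spr(trees[[i]], sprs_per_step)
    }
    trees
  }
  trees <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tree_sample(trees, source = sprintf(
    "simulate_unimodal(n_taxa=%d, n_samples=%d, sprs_per_step=%d, seed=%s)",
    n_taxa, n_samples, sprs_per_step, format(seed)))
}

#' Simulate a bimodal two-set switching chain
#'
#' Emulates an MCMC exploring a bimodal posterior, e.g. from concatenating
#' loci with different histories. Two distantly related sets of
#' `set_size` trees are built: set 1 is seeded with a random topology, set
#' 2's seed is that tree after `seed_separation_moves` SPR moves, and each
#' set is filled with satellites `within_set_moves` SPR moves from its seed.
#' The chain starts in set 1; at every step it switches set with probability
#' `switch_prob` and then draws a tree uniformly (with replacement) from the
#' current set. `switch_prob = 0` never reveals set 2, so the sample is
#' indistinguishable from perfect mixing over set 1; `switch_prob = 0.5`
#' makes set membership an i.i.d. fair coin.
#'
#' @param n_taxa Leaves per tree (default 50).
#' @param n_samples Chain length (default 1000).
#' @param switch_prob Probability in `[0, 0.5]` of switching sets at each
#'   step.
#' @param set_size Trees per set (default 10).
#' @param seed_separation_moves SPR moves separating the two set seeds
#'   (default 50).
#' @param within_set_moves SPR moves from a set's seed to each satellite
#'   (default 1).
#' @param seed Integer seed.
#' @return A [tree_sample]; the per-generation set membership (1 or 2) is
#'   stored in its `set_membership` attribute.
#' @export
simulate_bimodal <- function(n_taxa = 50L, n_samples = 1000L, switch_prob,
                             set_size = 10L, seed_separation_moves = 50L,
                             within_set_moves = 1L, seed = NULL) {
  if (switch_prob < 0 || switch_prob > 0.5) {
    stop("simulate_bimodal: switch_prob must be in [0, 0.5]", call. = FALSE)
  }
  if (n_samples < 20) {
    stop("simulate_bimodal: n_samples must be at least 20", call. = FALSE)
  }
  run <- function() {
    seed1 <- random_topology(n_taxa)
    seed2 <- random_spr(seed1, seed_separation_moves)
    fill_set <- function(seed_tree) {
      c(list(seed_tree),
        lapply(seq_len(set_size - 1L), function(i) {
          random_spr(seed_tree, within_set_moves)
        }))
    }
    sets <- list(fill_set(seed1), fill_set(seed2))
    membership <- integer(n_samples)
    pick <- integer(n_samples)
    current <- 1L
    for (i in seq_len(n_samples)) {
      if (i > 1L && stats::runif(1) < switch_prob) {
        current <- 3L - current
      }
      membership[i] <- current
      pick[i] <- sample.int(set_size, 1L)
    }
    list(trees = lapply(seq_len(n_samples),
                        function(i) sets[[membership[i]]][[pick[i]]]),
         membership = membership)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ts <- tree_sample(out$trees, source = sprintf(
    paste0("simulate_bimodal(n_taxa=%d, n_samples=%d, switch_prob=%g, ",
           "set_size=%d, seed_separation_moves=%d, within_set_moves=%d, seed=%s)"),
    n_taxa, n_samples, switch_prob, set_size, seed_separation_moves,
    within_set_moves, format(seed)))
  attr(ts, "set_membership") <- out$membership
  ts
}
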