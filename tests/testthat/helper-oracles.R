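# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals: splits are
# enumerated by deleting edges of an igraph graph and reading off connected
# components; path matrices come from igraph shortest paths; the
# approximate-ESS ratio r is an explicit double loop over the defining sums.

quartet <- function(newick) ape::unroot(ape::read.tree(text = newick))

q_ab_cd <- function() quartet("((A,B),(C,D));")
q_ac_bd <- function() quartet("((A,C),(B,D));")
q_ad_bc <- function() quartet("((A,D),(B,C));")

maybe_unroot <- function(tree) {
  if (ape::is.rooted(tree)) ape::unroot(tree) else tree
}

# multiPhylo -> plain list, resolving compressed tip labels
phylo_list <- function(trees) {
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  unclass(trees)
}

# Non-trivial splits via graph components after removing each internal edge.
bf_splits <- function(tree) {
  tree <- maybe_unroot(tree)
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  labs <- sort(tree$tip.label, method = "radix")
  keys <- character(0)
  first_tip <- match(labs[1L], tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    gg <- igraph::delete_edges(g, igraph::get_edge_ids(g, tree$edge[e, ]))
    comp <- igraph::components(gg)$membership
    # canonical side: the one not containing the lexicographically first leaf
    side <- which(comp[seq_len(n)] == comp[first_tip])
    other <- setdiff(seq_len(n), side)
    if (length(other) >= 2 && length(other) <= n - 2) {
      keys <- c(keys, paste(sort(match(tree$tip.label[other], labs)),
                            collapse = "."))
    }
  }
  unique(keys)
}

bf_rf <- function(t1, t2) {
  s1 <- bf_splits(t1)
  s2 <- bf_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

bf_path_matrix <- function(tree) {
  tree <- maybe_unroot(tree)
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  d <- igraph::distances(g)[seq_len(n), seq_len(n)]
  ord <- order(tree$tip.label, method = "radix")
  d <- d[ord, ord]
  dimnames(d) <- list(tree$tip.label[ord], tree$tip.label[ord])
  d
}

bf_path_difference <- function(t1, t2) {
  m1 <- bf_path_matrix(t1)
  m2 <- bf_path_matrix(t2)
  stopifnot(identical(rownames(m1), rownames(m2)))
  sqrt(sum((m1[upper.tri(m1)] - m2[upper.tri(m2)])^2))
}

# Literal double loop over every sample pair (i, j), i < j: each pair
# contributes its expected squared distance once — f(k) at lag k = j - i
# when k < m, D at lag >= m — normalised by 2 N^2 D.
bf_r <- function(fk, D, m, N) {
  total <- 0
  for (i in seq_len(N - 1)) {
    for (j in seq.int(i + 1, N)) {
      k <- j - i
      total <- total + if (k < m) fk[k] else D
    }
  }
  total / (2 * N^2 * D)
}

# Empirical mean squared distance at one lag, straight from pairwise calls.
bf_lag_msd <- function(sample, k, metric_name = "path_difference") {
  trees <- sample$trees
  N <- sample$N
  vals <- vapply(seq_len(N - k), function(i) {
    pairwise_distance(trees[[i]], trees[[i + k]],
                      distance_metric(metric_name))^2
  }, numeric(1))
  mean(vals)
}

# A small NEXUS fixture with a translate table, and its newick equivalent.
write_nexus_fixture <- function(path) {
  writeLines(c(
    "#NEXUS",
    "BEGIN TREES;",
    "  TRANSLATE",
    "    1 A,",
    "    2 B,",
    "    3 C,",
    "    4 D,",
    "    5 E;",
    "  TREE tree1 = [&U] ((1,2),(3,4),5);",
    "  TREE tree2 = [&U] ((1,3),(2,4),5);",
    "  TREE tree3 = [&U] ((1,2),(3,5),4);",
    "END;"
  ), path)
  path
}

nexus_fixture_newicks <- c(
  "((A,B),(C,D),E);",
  "((A,C),(B,D),E);",
  "((A,B),(C,E),D);"
)

split_set_of <- function(tree) sort(bf_splits(tree))
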