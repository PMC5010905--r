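# Internal cached representation of a tree_sample for bulk distance work.
#
# Chains are often highly redundant (a bimodal switching chain revisits the
# same 20 topologies for 1,000 generations), so trees are first deduplicated
# by their newick string. Each unique topology is then represented either by
# its leaf-pair path-length vector (path difference: pair distances become
# vectorized row operations) or by its set of split keys mapped to integer
# ids (Robinson-Foulds). When the number of unique topologies is small, the
# full unique-by-unique distance matrix is precomputed once and every pair
# lookup becomes a table access.

MAX_UNIQUE_FOR_MATRIX <- 256L

sample_rep <- function(sample, metric) {
  metric <- as_metric(metric)
  check_tree_sample(sample, caller = "sample_rep")
  trees <- unclass(sample$trees)
  key <- vapply(trees, function(t) ape::write.tree(t), character(1))
  ukey <- unique(key)
  uid <- match(key, ukey)
  utrees <- trees[match(ukey, key)]
  nu <- length(utrees)
  rep <- list(metric = metric, N = sample$N, uid = uid, nu = nu,
              labels = sample$labels)
  if (metric$name == "path_difference") {
    rep$X <- t(vapply(utrees, path_vector, numeric(choose(length(sample$labels), 2)),
                      labels = sample$labels))
  } else {
    rep$splits <- lapply(utrees, tree_splits, labels = sample$labels)
  }
  if (nu <= MAX_UNIQUE_FOR_MATRIX) {
    rep$U2 <- unique_sqdist_matrix(rep)
  }
  rep
}

# nu x nu matrix of squared distances between unique topologies.
unique_sqdist_matrix <- function(rep) {
  nu <- rep$nu
  if (!is.null(rep$X)) {
    return(as.matrix(stats::dist(rep$X))^2)
  }
  U <- matrix(0, nu, nu)
  for (i in seq_len(nu)) {
    si <- rep$splits[[i]]
    for (j in seq_len(nu)) {
      if (j <= i) next
      U[i, j] <- U[j, i] <- rf_from_splits(si, rep$splits[[j]])^2
    }
  }
  U
}

# Squared distances for index pairs (i[t], j[t]); i, j are vectors of
# positions in the original chain.
pair_sqdist <- function(rep, i, j) {
  ui <- rep$uid[i]
  uj <- rep$uid[j]
  if (!is.null(rep$U2)) {
    return(rep$U2[cbind(ui, uj)])
  }
  if (!is.null(rep$X)) {
    d <- rep$X[ui, , drop = FALSE] - rep$X[uj, , drop = FALSE]
    return(rowSums(d * d))
  }
  out <- numeric(length(ui))
  for (t in seq_along(ui)) {
    if (ui[t] == uj[t]) next
    out[t] <- rf_from_splits(rep$splits[[ui[t]]], rep$splits[[uj[t]]])^2
  }
  out
}

# Mean and mean-squared distance over all overlapping pairs at lag k.
lag_summary <- function(rep, k) {
  N <- rep$N
  stopifnot(k >= 1L, k < N)
  d2 <- pair_sqdist(rep, seq_len(N - k), seq.int(k + 1L, N))
  c(mean_distance = mean(sqrt(d2)), mean_squared_distance = mean(d2),
    n_pairs = N - k)
}
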