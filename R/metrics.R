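#' Choose a topological distance metric
#'
#' The two supported metrics are topology-only: branch lengths are ignored
#' because they are continuous parameters that conventional trace/ESS tools
#' already handle. The path difference has a much larger range of attainable
#' values than Robinson-Foulds and discriminates tree pairs better, which is
#' why it is the package default for ESS estimation.
#'
#' @param name `"path_difference"` (alias `"pd"`) or `"robinson_foulds"`
#'   (alias `"rf"`).
#' @param squared If `TRUE`, [pairwise_distance()] and [topology_trace()]
#'   report squared distances. Squaring is a monotone transform, so it never
#'   changes which pairs rank as equally distant.
#' @return A `distance_metric` object.
#' @export
distance_metric <- function(name = c("path_difference", "robinson_foulds", "pd", "rf"),
                            squared = FALSE) {
  name <- match.arg(name)
  name <- switch(name, pd = "path_difference", rf = "robinson_foulds", name)
  structure(list(name = name, squared = isTRUE(squared)),
            class = "distance_metric")
}

as_metric <- function(metric) {
  if (inherits(metric, "distance_metric")) return(metric)
  if (is.character(metric) && length(metric) == 1L) return(distance_metric(metric))
  stop("expected a distance_metric or a metric name", call. = FALSE)
}

#' @export
print.distance_metric <- function(x, ...) {
  cat("<distance_metric> ", x$name, if (x$squared) " (squared)", "\n", sep = "")
  invisible(x)
}

# ---- split enumeration -----------------------------------------------------

# Canonical keys for the non-trivial unrooted splits of a tree: each internal
# edge bipartitions the leaves; the side not containing the first label (in
# the reference lexicographic order) is encoded as a sorted index string.
tree_splits <- function(tree, labels = NULL) {
  tree <- normalize_topology(tree)
  if (is.null(labels)) labels <- sort_labels(tree$tip.label)
  n <- length(labels)
  if (n < 4L) return(character(0))
  tipidx <- match(tree$tip.label, labels)
  if (anyNA(tipidx)) stop("tree_splits: leaf set mismatch", call. = FALSE)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(po$edge)
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- tipidx[i]
  parent <- po$edge[, 1L]
  child <- po$edge[, 2L]
  for (e in seq_along(parent)) {
    below[[parent[e]]] <- c(below[[parent[e]]], below[[child[e]]])
  }
  keys <- character(0)
  for (e in seq_along(parent)) {
    ch <- child[e]
    if (ch <= n) next                 # trivial (single-leaf) split
    s <- below[[ch]]
    if (length(s) > n - 2L) next      # root-side pseudo-split
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    keys <- c(keys, paste(sort(s), collapse = "."))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two topologies
#'
#' The number of non-trivial unrooted splits (bipartitions) present in
#' exactly one of the two trees. For binary trees on `n` leaves the maximum
#' is `2(n - 3)`.
#'
#' @param t1,t2 `phylo` objects on the same leaf set (at least 4 leaves).
#' @return A non-negative integer.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' robinson_foulds(t1, t2)  # 2: the single internal split of each differs
#' @export
robinson_foulds <- function(t1, t2) {
  labels <- check_pair(t1, t2, "robinson_foulds")
  s1 <- tree_splits(t1, labels)
  s2 <- tree_splits(t2, labels)
  rf_from_splits(s1, s2)
}

rf_from_splits <- function(s1, s2) {
  length(s1) + length(s2) - 2L * sum(s1 %in% s2)
}

# ---- path-length matrices --------------------------------------------------

#' Leaf-pair path-length matrix of a topology
#'
#' Entry `(i, j)` is the number of edges on the unique path between leaves
#' `i` and `j` in the unrooted tree. Rows and columns are ordered
#' lexicographically by leaf label, so matrices from trees on the same leaf
#' set can be subtracted directly.
#'
#' @param t A `phylo` object with at least 4 leaves.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
leaf_path_matrix <- function(t) {
  t <- normalize_topology(t)
  n <- length(t$tip.label)
  if (n < 4L) stop("leaf_path_matrix: need at least 4 leaves", call. = FALSE)
  t$edge.length <- rep(1, nrow(t$edge))
  d <- ape::dist.nodes(t)[seq_len(n), seq_len(n)]
  ord <- order(t$tip.label, method = "radix")
  d <- d[ord, ord]
  dimnames(d) <- list(t$tip.label[ord], t$tip.label[ord])
  storage.mode(d) <- "integer"
  d
}

# Upper-triangle vector of the path matrix, in a fixed leaf order.
path_vector <- function(tree, labels) {
  m <- leaf_path_matrix(tree)
  if (!identical(rownames(m), labels)) {
    stop("path_vector: leaf set mismatch", call. = FALSE)
  }
  as.numeric(m[upper.tri(m)])
}

#' Path difference between two topologies
#'
#' The Euclidean norm of the difference between the two trees' leaf-pair
#' path-length matrices (path lengths in edges, branch lengths ignored):
#' `sqrt(sum_{i<j} (p1(i,j) - p2(i,j))^2)`.
#'
#' @inheritParams robinson_foulds
#' @return A non-negative real number.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' path_difference(t1, t2)  # 2
#' @export
path_difference <- function(t1, t2) {
  labels <- check_pair(t1, t2, "path_difference")
  v1 <- path_vector(normalize_topology(t1), labels)
  v2 <- path_vector(normalize_topology(t2), labels)
  sqrt(sum((v1 - v2)^2))
}

#' Distance between two topologies under a chosen metric
#'
#' @inheritParams robinson_foulds
#' @param metric A [distance_metric()] (or metric name). When the metric's
#'   `squared` flag is set the squared distance is returned.
#' @return A non-negative real number.
#' @export
pairwise_distance <- function(t1, t2, metric = distance_metric("path_difference")) {
  metric <- as_metric(metric)
  d <- switch(metric$name,
    path_difference = path_difference(t1, t2),
    robinson_foulds = as.numeric(robinson_foulds(t1, t2))
  )
  if (metric$squared) d^2 else d
}

check_pair <- function(t1, t2, caller) {
  if (!inherits(t1, "phylo") || !inherits(t2, "phylo")) {
    stop(caller, ": both arguments must be 'phylo' objects", call. = FALSE)
  }
  l1 <- sort_labels(t1$tip.label)
  l2 <- sort_labels(t2$tip.label)
  if (!identical(l1, l2)) {
    bad <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop(caller, ": leaf sets differ; offending labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(l1) < 4L) {
    stop(caller, ": need at least 4 leaves", call. = FALSE)
  }
  l1
}
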