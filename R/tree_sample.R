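#' An ordered sample of tree topologies from one MCMC chain
#'
#' A `tree_sample` wraps an [ape::multiPhylo] object holding `N` unrooted
#' topologies on a shared leaf set, in the order they were sampled. Branch
#' lengths and node support values are dropped on construction: all
#' downstream diagnostics treat the topology as the parameter of interest and
#' ignore continuous quantities, which can be assessed with conventional
#' trace/ESS tools.
#'
#' @param trees A list of `phylo` objects or a `multiPhylo`. Rooted trees are
#'   unrooted silently; polytomies are accepted.
#' @param source Free-text provenance (file path or simulator settings),
#'   stored for reporting.
#'
#' @return An object of class `tree_sample`: a list with elements `trees`
#'   (`multiPhylo`, unrooted, no branch lengths), `N` (number of samples),
#'   `labels` (leaf labels in lexicographic order) and `source`.
#'
#' @examples
#' ts <- simulate_unimodal(n_taxa = 8, n_samples = 25, sprs_per_step = 1, seed = 1)
#' ts
#' @export
tree_sample <- function(trees, source = "unknown") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) {
    stop("tree_sample: no trees supplied", call. = FALSE)
  }
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) {
      stop("tree_sample: element ", i, " is not a 'phylo' object", call. = FALSE)
    }
    normalize_topology(tr, index = i)
  })
  labels <- sort_labels(trees[[1L]]$tip.label)
  if (anyDuplicated(labels)) {
    stop("tree_sample: duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(trees)) {
    li <- sort_labels(trees[[i]]$tip.label)
    if (!identical(li, labels)) {
      bad <- c(setdiff(li, labels), setdiff(labels, li))
      stop("tree_sample: tree ", i, " has a different leaf set; offending labels: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  structure(
    list(trees = trees, N = length(trees), labels = labels, source = source),
    class = "tree_sample"
  )
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("<tree_sample>\n")
  cat("  samples: ", x$N, "\n", sep = "")
  cat("  leaves:  ", length(x$labels), " (", paste(utils::head(x$labels, 4), collapse = ", "),
      if (length(x$labels) > 4) ", ..." else "", ")\n", sep = "")
  cat("  source:  ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
length.tree_sample <- function(x) x$N

# Strip branch lengths / node labels and unroot; leaves a clean topology.
normalize_topology <- function(tr, index = NA_integer_) {
  tr$edge.length <- NULL
  tr$node.label <- NULL
  if (length(tr$tip.label) < 3L) {
    stop("tree ", index, ": fewer than 3 leaves", call. = FALSE)
  }
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

# Deterministic, locale-independent lexicographic order.
sort_labels <- function(x) sort(x, method = "radix")

check_tree_sample <- function(sample, min_n = 1L, caller = "topoess") {
  if (!inherits(sample, "tree_sample")) {
    stop(caller, ": expected a 'tree_sample' object", call. = FALSE)
  }
  if (sample$N < min_n) {
    stop(caller, ": need at least ", min_n, " sampled trees, got ", sample$N,
         call. = FALSE)
  }
  invisible(sample)
}
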