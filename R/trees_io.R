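#' Read a posterior sample of trees from a file
#'
#' Reads newick (one `;`-terminated tree per line) or NEXUS (`trees` block,
#' optional `translate` table) files into a [tree_sample], applying burn-in
#' removal. Branch lengths and support values are parsed but discarded;
#' rooted trees are unrooted, since all distances here are defined on
#' unrooted topologies.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @param burnin_fraction Fraction in `[0, 1)` of initial trees to discard;
#'   `floor(burnin_fraction * total)` trees are dropped from the front.
#'   Defaults to 0: deposited posterior samples are normally already
#'   post-burn-in.
#'
#' @return A [tree_sample] with the retained trees in file order.
#' @seealso [write_tree_sample()]
#' @export
read_tree_sample <- function(path, format = c("newick", "nexus"),
                             burnin_fraction = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("read_tree_sample: file not found: ", path, call. = FALSE)
  }
  if (!is.numeric(burnin_fraction) || length(burnin_fraction) != 1L ||
      is.na(burnin_fraction) || burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("read_tree_sample: burnin_fraction must be a single number in [0, 1)",
         call. = FALSE)
  }
  trees <- switch(format,
    newick = read_newick_lines(path),
    nexus = read_nexus_trees(path)
  )
  total <- length(trees)
  if (total == 0L) {
    stop("read_tree_sample: no trees found in ", path, call. = FALSE)
  }
  drop <- floor(burnin_fraction * total)
  if (drop >= total) {
    stop("read_tree_sample: burn-in removed every tree (", total, " parsed)",
         call. = FALSE)
  }
  trees <- trees[seq.int(drop + 1L, total)]
  tree_sample(trees, source = path)
}

read_newick_lines <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    tr <- tryCatch(
      ape::read.tree(text = lines[[i]]),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo")) {
      stop("read_tree_sample: malformed newick at tree ", i, call. = FALSE)
    }
    tr
  })
}

read_nexus_trees <- function(path) {
  trees <- tryCatch(
    ape::read.nexus(path),
    error = function(e) {
      stop("read_tree_sample: failed to parse NEXUS file: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (inherits(trees, "phylo")) trees <- list(trees)
  # translate tables make read.nexus store tip labels once, compressed
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  unclass(trees)
}

#' Write a posterior sample of trees to a file
#'
#' Newick output has one `;`-terminated tree per line; NEXUS output carries a
#' `translate` table. The round trip `read(write(sample))` reproduces the
#' ordered sequence of unrooted split sets.
#'
#' @param sample A [tree_sample].
#' @param path Output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  check_tree_sample(sample, min_n = 1L, caller = "write_tree_sample")
  ok <- tryCatch({
    switch(format,
      newick = ape::write.tree(sample$trees, file = path),
      nexus = ape::write.nexus(sample$trees, file = path, translate = TRUE)
    )
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop("write_tree_sample: could not write to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Drop initial samples from a chain
#'
#' @param sample A [tree_sample].
#' @param burnin_fraction Fraction in `[0, 1)`; `floor(burnin_fraction * N)`
#'   leading trees are removed, preserving the order of the rest.
#' @return A [tree_sample].
#' @export
apply_burnin <- function(sample, burnin_fraction) {
  check_tree_sample(sample, caller = "apply_burnin")
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("apply_burnin: burnin_fraction must be in [0, 1)", call. = FALSE)
  }
  drop <- floor(burnin_fraction * sample$N)
  if (drop == 0L) return(sample)
  if (drop >= sample$N) {
    stop("apply_burnin: burn-in would remove every tree", call. = FALSE)
  }
  tree_sample(unclass(sample$trees)[seq.int(drop + 1L, sample$N)],
              source = paste0(sample$source, " [burnin ", burnin_fraction, "]"))
}
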