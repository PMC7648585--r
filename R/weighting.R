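#' Topology weighting of a window tree
#'
#' The weighting of a tree over k taxon groups decomposes it into the
#' (2k-5)!! single-tip-per-group unrooted topologies: each combination
#' of one tip per group induces one topology, and a topology's weight is
#' the proportion of combinations inducing it. [weight_exact()]
#' enumerates the full product space; [weight_sampled()] draws uniform
#' combinations until the 95% Wilson score interval around every weight
#' is narrower than `max_ci_width` (full width).
#'
#' @name topology-weighting
NULL

.topo_cache <- new.env(parent = emptyenv())

#' Cached topology census for a group label set
#'
#' @param group_labels k >= 4 group names.
#' @return list with `topologies` (the [enumerate_topologies()] list),
#'   `ids`, and an internal signature-to-index lookup.
#' @export
topology_table <- function(group_labels) {
  labels <- sort(group_labels)
  key <- paste(labels, collapse = ",")
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  topos <- enumerate_topologies(labels)
  sig <- vapply(topos, function(t) paste(t$splits, collapse = "."), "")
  tab <- list(topologies = topos,
              ids = vapply(topos, `[[`, "", "id"),
              labels = labels,
              lookup = stats::setNames(seq_along(topos), sig))
  .topo_cache[[key]] <- tab
  tab
}

# For each combination (row of `combos`: per-group indices into
# `groups[[g]]`), the index of its induced topology in topology_table.
# Vectorized over combinations; duplicate rows are resolved once.
combo_topology_index <- function(tree, groups, combos, tab) {
  glabs <- tab$labels
  k <- length(glabs)
  tipidx <- lapply(glabs, function(g) {
    idx <- match(groups[[g]], tree$tip.label)
    if (anyNA(idx)) stop("group '", g, "' has tip(s) absent from tree")
    idx
  })
  M <- tree_split_matrix(tree)
  ncomb <- nrow(combos)
  C <- vapply(seq_len(k), function(j) tipidx[[j]][combos[, j]],
              integer(ncomb))
  if (is.null(dim(C))) C <- matrix(C, nrow = 1L)
  pow2 <- 2^(0:(k - 1))
  full <- as.integer(2^k - 1)
  pc <- popcount_table(k)
  E <- nrow(M)
  codes <- matrix(0L, ncomb, E)
  for (e in seq_len(E)) {
    codes[, e] <- as.integer(matrix(M[e, ][C], ncomb) %*% pow2)
  }
  sz <- matrix(pc[codes + 1L], ncomb, E)
  canon <- matrix(ifelse(bitwAnd(codes, 1L) == 1L,
                         bitwXor(codes, full), codes), ncomb, E)
  canon[sz < 2L | sz > k - 2L] <- -1L  # trivial restriction, ignore
  rowkey <- do.call(paste, c(as.data.frame(canon), sep = ","))
  first <- which(!duplicated(rowkey))
  sig <- vapply(first, function(i) {
    v <- canon[i, ]
    paste(sort(unique(v[v >= 0L])), collapse = ".")
  }, "")
  idx_first <- unname(tab$lookup[sig])
  if (anyNA(idx_first)) stop("internal error: unmatched topology signature")
  idx_first[match(rowkey, rowkey[first])]
}

new_weighting <- function(weights, tab, mode, n_sampled = 0L,
                          ci_width = NULL, seed = NA_integer_,
                          converged = TRUE) {
  structure(list(weights = stats::setNames(weights, tab$ids),
                 group_labels = tab$labels,
                 mode = mode, n_sampled = as.integer(n_sampled),
                 ci_width = ci_width, seed = seed, converged = converged),
            class = "weighting")
}

#' @export
print.weighting <- function(x, ...) {
  top <- sort(x$weights, decreasing = TRUE)[1:3]
  cat(sprintf("weighting (%s%s): %d topologies over %d groups; top weights %s\n",
              x$mode,
              if (x$mode == "sampled") sprintf(", n=%d, converged=%s",
                                               x$n_sampled, x$converged) else "",
              length(x$weights), length(x$group_labels),
              paste(sprintf("%.3f", top), collapse = ", ")))
  invisible(x)
}

#' Exact topology weighting by full enumeration
#'
#' @param tree an `ape::phylo` window tree (binary).
#' @param groups named list: group name -> tip labels (>= 1 tip each,
#'   all present in the tree).
#' @return a `weighting` object; weights sum to 1 over the full census.
#' @export
weight_exact <- function(tree, groups) {
  check_groups(groups)
  tab <- topology_table(names(groups))
  sizes <- lengths(groups[tab$labels])
  combos <- as.matrix(expand.grid(lapply(sizes, seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
  idx <- combo_topology_index(tree, groups, combos, tab)
  counts <- tabulate(idx, nbins = length(tab$ids))
  new_weighting(counts / nrow(combos), tab, "exact")
}

check_groups <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    stop("group(s) with zero tips: ", paste(names(groups)[empty], collapse = ", "))
  }
}

#' Full width of the Wilson score interval
#'
#' Well behaved at observed proportions of 0 and 1, where the normal
#' approximation collapses to zero width; at n = 100 the Wilson full
#' width at p-hat = 0 is about 0.037.
#'
#' @param x successes (vectorized).
#' @param n trials.
#' @param level confidence level.
#' @return numeric vector of interval full widths.
#' @export
wilson_width <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  2 * z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
}

#' Topology weighting by iterative subtree sampling
#'
#' Draws batches of uniform tip combinations (with replacement) and
#' stops when the Wilson interval full width for every topology's
#' weight is below `max_ci_width`, or after `max_iter` batches (then
#' `converged` is `FALSE`).
#'
#' @inheritParams weight_exact
#' @param ci_level confidence level of the stopping interval.
#' @param max_ci_width stop when every interval's full width is below
#'   this.
#' @param batch combinations drawn between convergence checks.
#' @param max_iter maximum number of batches.
#' @param seed integer seed (recorded in the result).
#' @return a `weighting` object with `n_sampled`, `ci_width`, `seed`,
#'   `converged`.
#' @export
weight_sampled <- function(tree, groups, ci_level = 0.95,
                           max_ci_width = 0.05, batch = 100L,
                           max_iter = 1000L, seed = 1L) {
  check_groups(groups)
  stopifnot(batch >= 1L)
  tab <- topology_table(names(groups))
  sizes <- lengths(groups[tab$labels])
  k <- length(sizes)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  counts <- integer(length(tab$ids))
  n <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    combos <- vapply(sizes, function(s) sample.int(s, batch, replace = TRUE),
                     integer(batch))
    if (batch == 1L) combos <- matrix(combos, nrow = 1L)
    idx <- combo_topology_index(tree, groups, combos, tab)
    counts <- counts + tabulate(idx, nbins = length(counts))
    n <- n + batch
    widths <- wilson_width(counts, n, ci_level)
    if (all(widths < max_ci_width)) {
      converged <- TRUE
      break
    }
  }
  new_weighting(counts / n, tab, "sampled", n_sampled = n,
                ci_width = stats::setNames(widths, tab$ids),
                seed = as.integer(seed), converged = converged)
}

#' Weighting with automatic mode choice
#'
#' Complete enumeration when the product of group sizes is at most
#' `max_exact`; iterative sampling otherwise.
#'
#' @inheritParams weight_sampled
#' @param max_exact combination-count ceiling for exact mode.
#' @param ... passed to [weight_sampled()] in sampling mode.
#' @return a `weighting` object.
#' @export
topology_weights <- function(tree, groups, max_exact = 1e5, seed = 1L, ...) {
  if (prod(lengths(groups)) <= max_exact) {
    weight_exact(tree, groups)
  } else {
    weight_sampled(tree, groups, seed = seed, ...)
  }
}

#' Kolmogorov distance between two weightings
#'
#' Maximum absolute difference of cumulative weights in the canonical
#' enumeration order; used to compare sampled against exact weightings.
#'
#' @param w1,w2 `weighting` objects over the same group labels.
#' @return numeric in \[0, 1\].
#' @export
kolmogorov_distance <- function(w1, w2) {
  stopifnot(identical(names(w1$weights), names(w2$weights)))
  max(abs(cumsum(w1$weights) - cumsum(w2$weights)))
}
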