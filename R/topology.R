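#' Canonical unrooted topologies over taxon groups
#'
#' A `topology` is an unrooted, strictly binary, leaf-labeled tree shape
#' with an order-invariant identity. Internally it is represented by its
#' set of nontrivial bipartitions: group labels are sorted, each split
#' is encoded as a bitmask over the sorted labels (canonicalized to the
#' side that excludes the first label), and the identity string is the
#' sorted mask set. A set of bipartitions determines an unrooted tree
#' uniquely, so two topologies are isomorphic iff their `id` strings are
#' equal.
#'
#' @param x a newick string or an `ape::phylo` tree; branch lengths are
#'   ignored, only the leaf-labeled shape is kept.
#' @return An object of class `topology` with fields `labels` (sorted),
#'   `splits` (sorted integer masks), `id`, and `newick` (a
#'   representative newick string).
#' @export
topology <- function(x) {
  if (inherits(x, "topology")) return(x)
  if (is.character(x)) x <- ape::read.tree(text = x)
  if (!inherits(x, "phylo")) stop("topology() expects a newick string or a phylo tree")
  labels <- sort(x$tip.label)
  k <- length(labels)
  if (k < 4L) stop("topologies need >= 4 labels to be informative")
  M <- tree_split_matrix(x)
  masks <- unique(vapply(seq_len(nrow(M)), function(e) {
    side <- x$tip.label[M[e, ]]
    canon_mask(label_mask(side, labels), k)
  }, numeric(1)))
  new_topology(labels, masks)
}

new_topology <- function(labels, masks) {
  k <- length(labels)
  masks <- sort(unique(as.integer(masks)))
  if (length(masks) != k - 3L) {
    stop(sprintf("not a binary unrooted topology on %d labels (%d nontrivial splits, expected %d)",
                 k, length(masks), k - 3L))
  }
  tp <- structure(list(labels = labels, splits = masks,
                       id = paste0(paste(labels, collapse = ","), "|",
                                   paste(masks, collapse = ".")),
                       newick = NULL),
                  class = "topology")
  tp$newick <- topology_newick(tp)
  tp
}

topology_from_sets <- function(sides, labels) {
  labels <- sort(labels)
  k <- length(labels)
  masks <- vapply(sides, function(s) canon_mask(label_mask(s, labels), k),
                  numeric(1))
  new_topology(labels, masks)
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$newick, "\n")
  invisible(x)
}

#' @export
`==.topology` <- function(e1, e2) e1$id == e2$id

# --- bitmask helpers ------------------------------------------------------

label_mask <- function(side, labels) {
  idx <- match(side, labels)
  if (anyNA(idx)) stop("unknown label(s): ", paste(side[is.na(idx)], collapse = ", "))
  sum(2^(idx - 1L))
}

# canonical side: the one excluding labels[1] (bit 0 clear)
canon_mask <- function(mask, k) {
  mask <- as.integer(mask)
  if (bitwAnd(mask, 1L) == 1L) bitwXor(mask, as.integer(2^k - 1)) else mask
}

mask_labels <- function(mask, labels) {
  labels[bitwAnd(bitwShiftR(as.integer(mask), seq_along(labels) - 1L), 1L) == 1L]
}

popcount_table <- function(k) {
  vapply(0:(2^k - 1), function(m) sum(bitwAnd(bitwShiftR(m, 0:(k - 1)), 1L)),
         integer(1))
}

# membership matrix (internal edges x tips) of a tree's bipartitions;
# may contain the same unrooted split twice for a rooted representation
tree_split_matrix <- function(tr) {
  ntip <- length(tr$tip.label)
  pp <- ape::prop.part(tr)
  M <- t(vapply(pp, function(s) {
    v <- logical(ntip); v[s] <- TRUE; v
  }, logical(ntip)))
  sz <- rowSums(M)
  M[sz >= 2L & sz <= ntip - 2L, , drop = FALSE]
}

# --- newick reconstruction from split sets --------------------------------

topology_newick <- function(tp) {
  labels <- tp$labels
  k <- length(labels)
  full <- as.integer(2^k - 1)
  root_mask <- bitwXor(full, 1L)  # everything but labels[1]
  sets <- c(tp$splits, as.integer(2^(seq_len(k) - 1L)))  # splits + singletons
  sets <- setdiff(unique(sets), root_mask)
  subtree <- function(mask) {
    if (sum(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L)) == 1L) {
      return(mask_labels(mask, labels))
    }
    inside <- sets[vapply(sets, function(s) {
      s != mask && bitwAnd(s, mask) == s
    }, logical(1))]
    maximal <- inside[vapply(inside, function(s) {
      !any(vapply(inside, function(t) t != s && bitwAnd(s, t) == s, logical(1)))
    }, logical(1))]
    paste0("(", paste(vapply(maximal, subtree, character(1)), collapse = ","), ")")
  }
  paste0("(", labels[1], ",", subtree(root_mask), ");")
}

#' Convert a topology to an ape phylo tree
#'
#' @param tp a [topology()].
#' @return an unrooted `ape::phylo` with unit branch lengths.
#' @export
as_phylo <- function(tp) {
  tr <- ape::read.tree(text = tp$newick)
  tr$edge.length <- rep(1, nrow(tr$edge))
  ape::unroot(tr)
}

# --- enumeration ----------------------------------------------------------

#' Enumerate all unrooted binary topologies on a label set
#'
#' Generates the (2k-5)!! distinct unrooted leaf-labeled binary shapes
#' by sequential leaf insertion (each new label onto every edge), in a
#' deterministic order. For six groups this yields the full census of
#' 105 topologies.
#'
#' @param labels k >= 4 group names.
#' @return list of [topology()] objects, pairwise distinct by `id`.
#' @export
enumerate_topologies <- function(labels) {
  labels <- sort(labels)
  k <- length(labels)
  if (k < 4L) stop("need >= 4 labels: no informative unrooted shapes below 4")
  # nested-list trees over labels[2..k], rooted on the pendant edge of labels[1]
  trees <- list(labels[2])
  for (idx in 3:k) {
    trees <- unlist(lapply(trees, insert_leaf_everywhere, lab = labels[idx]),
                    recursive = FALSE)
  }
  lapply(trees, nested_to_topology, labels = labels)
}

insert_leaf_everywhere <- function(tr, lab) {
  out <- list(list(tr, lab))  # insert on the edge above the root
  if (is.list(tr)) {
    for (ci in 1:2) {
      for (sub in insert_leaf_everywhere(tr[[ci]], lab)) {
        t2 <- tr
        t2[[ci]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

nested_to_topology <- function(tr, labels) {
  k <- length(labels)
  sets <- list()
  walk <- function(node) {
    if (!is.list(node)) return(node)
    leaves <- c(walk(node[[1]]), walk(node[[2]]))
    sets[[length(sets) + 1L]] <<- leaves
    leaves
  }
  walk(tr)
  sizes <- lengths(sets)
  topology_from_sets(sets[sizes >= 2L & sizes <= k - 2L], labels)
}

# --- target-set construction ----------------------------------------------

#' Shared-ancestry target topologies for a focal pair
#'
#' Given the species topology on the four non-focal groups and a focal
#' pair of comimetic groups, returns the topologies in which (a) the
#' focal pair forms a cherry and (b) the remaining four groups retain
#' the species topology. Built constructively: the cherry is attached
#' to each of the five edges of the four-group species tree, giving
#' exactly five six-group topologies.
#'
#' @param species_tree a [topology()] on exactly 4 groups.
#' @param focal_pair two group names, disjoint from the species tree's.
#' @return list of 5 [topology()] objects, deterministic order (pendant
#'   attachments in sorted group order, internal edge last).
#' @export
shared_ancestry_set <- function(species_tree, focal_pair) {
  species_tree <- topology(species_tree)
  if (length(species_tree$labels) != 4L) {
    stop("species_tree must be on exactly 4 groups")
  }
  if (length(focal_pair) != 2L ||
      any(focal_pair %in% species_tree$labels)) {
    stop("focal_pair must be two group names disjoint from the species tree")
  }
  g4 <- species_tree$labels
  pair_side <- mask_labels(species_tree$splits[1], g4)
  other_side <- setdiff(g4, pair_side)
  labels6 <- sort(c(g4, focal_pair))
  opposite <- function(x) if (x %in% pair_side) other_side else pair_side
  res <- lapply(g4, function(x) {
    topology_from_sets(list(focal_pair, c(focal_pair, x), opposite(x)),
                       labels6)
  })
  res[[5]] <- topology_from_sets(list(focal_pair, pair_side, other_side),
                                 labels6)
  res
}

#' Restrict a topology to a label subset
#'
#' Prunes the other labels and suppresses degree-2 vertices, working
#' directly on the bipartition sets.
#'
#' @param tp a [topology()].
#' @param keep labels to retain (>= 4).
#' @return the induced [topology()] on `keep`.
#' @export
restrict_topology <- function(tp, keep) {
  keep <- sort(keep)
  if (!all(keep %in% tp$labels)) stop("keep labels must be a subset of the topology's labels")
  kk <- length(keep)
  if (kk < 4L) stop("restriction needs >= 4 labels")
  sides <- lapply(tp$splits, function(m) intersect(mask_labels(m, tp$labels), keep))
  sides <- c(sides, lapply(sides, function(s) setdiff(keep, s)))
  sizes <- lengths(sides)
  sides <- sides[sizes >= 2L & sizes <= kk - 2L]
  topology_from_sets(sides, keep)
}

#' Induced topology of a tip choice within a tree
#'
#' Selects one tip per group, prunes all other tips, suppresses
#' degree-2 vertices, drops branch lengths, and canonicalizes. Computed
#' directly from the tree's bipartitions restricted to the chosen tips.
#'
#' @param tree an `ape::phylo` (binary).
#' @param tip_choice named character vector: group name -> tip label.
#' @return a [topology()] on the group names.
#' @export
induced_topology <- function(tree, tip_choice) {
  groups <- sort(names(tip_choice))
  k <- length(groups)
  tidx <- match(tip_choice[groups], tree$tip.label)
  if (anyNA(tidx)) {
    stop("chosen tip(s) absent from tree: ",
         paste(tip_choice[groups][is.na(tidx)], collapse = ", "))
  }
  M <- tree_split_matrix(tree)
  masks <- integer(0)
  for (e in seq_len(nrow(M))) {
    inside <- M[e, tidx]
    sz <- sum(inside)
    if (sz >= 2L && sz <= k - 2L) {
      masks <- c(masks, canon_mask(sum(2^(which(inside) - 1L)), k))
    }
  }
  new_topology(groups, unique(masks))
}
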