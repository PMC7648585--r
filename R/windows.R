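#' Sliding SNP-index windows
#'
#' Windows are defined in SNP-index space: starts at 0, `step`,
#' 2\code{step}, ... and only full-size windows are emitted (a trailing
#' partial window yields no tree). Consecutive windows overlap by
#' `size - step` sites.
#'
#' @param n_sites number of (filtered) sites on the scaffold.
#' @param size window size in SNPs.
#' @param step slide in SNPs; `0 < step <= size`.
#' @return data.frame with 0-based half-open `snp_start`, `snp_end`
#'   columns, one row per window.
#' @export
make_windows <- function(n_sites, size = 100L, step = 25L) {
  stopifnot(size > 0, step > 0, step <= size)
  starts <- seq(0L, max(0L, n_sites - size), by = step)
  starts <- starts[starts + size <= n_sites]
  data.frame(snp_start = as.integer(starts),
             snp_end = as.integer(starts + size))
}

#' Per-sample data-sufficiency rule for a window
#'
#' A window gets a tree only if every tip has at least
#' `min_snps_per_sample` non-missing calls inside it.
#'
#' @param hm a `haplotype_matrix` (see [pseudo_haploidize()]).
#' @param w one row of [make_windows()] output (list or data.frame row).
#' @param min_snps_per_sample minimum non-missing calls per tip.
#' @return logical.
#' @export
window_passes <- function(hm, w, min_snps_per_sample = 30L) {
  idx <- (w$snp_start + 1L):w$snp_end
  ok <- colSums(!is.na(hm$hap[idx, , drop = FALSE]))
  all(ok >= min_snps_per_sample)
}

#' Pairwise Hamming-proportion distances within a window
#'
#' `d(i, j)` is the proportion of sites, among those non-missing in both
#' tips within the window, at which the alleles differ. No
#' substitution-model correction is applied: the distances feed a
#' topology-only analysis. A tip pair with zero comparable sites makes
#' the window degenerate.
#'
#' @inheritParams window_passes
#' @return symmetric numeric matrix with tip ids as dimnames.
#' @export
pairwise_distances <- function(hm, w) {
  idx <- (w$snp_start + 1L):w$snp_end
  H <- hm$hap[idx, , drop = FALSE]
  m <- ncol(H)
  D <- matrix(0, m, m, dimnames = list(hm$tips, hm$tips))
  obs <- !is.na(H)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      both <- obs[, i] & obs[, j]
      nb <- sum(both)
      if (nb == 0L) {
        stop(degenerate_window_error(hm$tips[i], hm$tips[j]))
      }
      d <- sum(H[both, i] != H[both, j]) / nb
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

degenerate_window_error <- function(tip_i, tip_j) {
  structure(class = c("degenerate_window", "error", "condition"),
            list(message = sprintf(
              "no pairwise-complete sites for tips '%s' and '%s'",
              tip_i, tip_j),
              call = NULL))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); negative branch-length
#' estimates are clamped to 0. The output is an unrooted, strictly
#' binary `phylo`.
#'
#' @param dm symmetric distance matrix with zero diagonal, >= 4 tips.
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm) < 4L) stop("neighbor joining needs >= 4 tips for topology analysis")
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Build one tree per passing window
#'
#' Applies [window_passes()], computes [pairwise_distances()], and runs
#' [neighbor_joining()] for every window. Degenerate windows (a tip pair
#' with no comparable sites) are skipped and logged in the `failed`
#' column.
#'
#' @inheritParams window_passes
#' @param windows data.frame from [make_windows()].
#' @return list with `trees` (list of `phylo` or `NULL`) and `windows`
#'   (the input data.frame plus logical `passed` and `failed` columns).
#' @export
build_window_forest <- function(hm, windows, min_snps_per_sample = 30L) {
  trees <- vector("list", nrow(windows))
  passed <- logical(nrow(windows))
  failed <- logical(nrow(windows))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    if (!window_passes(hm, w, min_snps_per_sample)) next
    passed[k] <- TRUE
    tr <- tryCatch(neighbor_joining(pairwise_distances(hm, w)),
                   degenerate_window = function(e) NULL)
    if (is.null(tr)) {
      failed[k] <- TRUE
      passed[k] <- FALSE
    } else {
      trees[[k]] <- tr
    }
  }
  windows$passed <- passed
  windows$failed <- failed
  list(trees = trees, windows = windows)
}

#' Ingest externally built per-window newick trees
#'
#' One newick string per passing window, in window order. Tip labels
#' must match the expected tip set exactly and trees must be strictly
#' binary (polytomies are rejected).
#'
#' @param path newick file, one tree per line.
#' @param tips expected tip labels.
#' @return list of unrooted `phylo` trees.
#' @export
read_newick_stream <- function(path, tips) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(seq_along(trees), function(k) {
    tr <- trees[[k]]
    unknown <- setdiff(tr$tip.label, tips)
    if (length(unknown) > 0L) {
      stop(sprintf("tree %d: unknown tip label(s): %s",
                   k, paste(unknown, collapse = ", ")))
    }
    if (length(setdiff(tips, tr$tip.label)) > 0L) {
      stop(sprintf("tree %d: missing tip label(s): %s",
                   k, paste(setdiff(tips, tr$tip.label), collapse = ", ")))
    }
    if (!ape::is.binary(ape::unroot(tr))) {
      stop(sprintf("tree %d: polytomy rejected (trees must be strictly binary)", k))
    }
    ape::unroot(tr)
  })
}
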