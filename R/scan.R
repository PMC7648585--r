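#' Comparison specification for a shared-ancestry scan
#'
#' A comparison names six taxon groups, the species topology on the four
#' non-focal groups, and the focal comimetic pair. The five target
#' topologies (focal pair monophyletic, other four groups as in the
#' species tree) are derived once and cached in the object.
#'
#' @param name comparison name.
#' @param groups named list of six: group name -> sample ids.
#' @param species_tree a [topology()] on the four non-focal groups, or
#'   on all six (it is then restricted to the non-focal four).
#' @param focal_pair the two comimetic group names.
#' @return An object of class `comparison_spec` with `target_ids` and
#'   `target_set` fields.
#' @export
comparison_spec <- function(name, groups, species_tree, focal_pair) {
  if (length(groups) != 6L) stop("a comparison uses exactly six taxon groups")
  if (!all(focal_pair %in% names(groups))) stop("focal_pair must name two groups")
  species_tree <- topology(species_tree)
  nonfocal <- setdiff(names(groups), focal_pair)
  if (length(species_tree$labels) == 6L) {
    species_tree <- restrict_topology(species_tree, nonfocal)
  }
  if (!setequal(species_tree$labels, nonfocal)) {
    stop("species_tree must cover the four non-focal groups")
  }
  target_set <- shared_ancestry_set(species_tree, focal_pair)
  structure(list(name = name, groups = groups,
                 species_tree = species_tree,
                 focal_pair = sort(focal_pair),
                 target_set = target_set,
                 target_ids = vapply(target_set, `[[`, "", "id")),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("comparison '%s': focal pair %s vs species tree %s (%d target topologies)\n",
              x$name, paste(x$focal_pair, collapse = "+"),
              x$species_tree$newick, length(x$target_ids)))
  invisible(x)
}

#' Summed weight of the shared-ancestry target topologies
#'
#' 0 means no sampled/enumerated subtree showed the focal pair
#' monophyletic with the species arrangement of the other groups; 1
#' means all of them did.
#'
#' @param weighting a `weighting` (see [weight_exact()]).
#' @param spec a [comparison_spec()].
#' @return proportion in \[0, 1\].
#' @export
target_signal <- function(weighting, spec) {
  w <- weighting$weights[spec$target_ids]
  if (anyNA(w)) stop("weighting does not cover the comparison's topology set")
  sum(w)
}

#' Smooth a raw per-window track across overlapping windows
#'
#' With windows of `size` SNPs sliding by `step`, each step-sized
#' stretch of the scaffold is covered by up to `size/step` windows; its
#' smoothed value is the mean of the raw values of all windows fully
#' covering it (fewer at scaffold edges; no padding). Windows with `NA`
#' raw values (no tree) do not contribute.
#'
#' @param raw numeric vector, one value per window.
#' @param windows data.frame from [make_windows()].
#' @param step slide used to build the windows (inferred from the
#'   window starts when more than one window is present).
#' @return data.frame with per-region 0-based half-open `snp_start`,
#'   `snp_end`, `smoothed`, and `n_covering` columns.
#' @export
smooth_track <- function(raw, windows, step = NULL) {
  stopifnot(length(raw) == nrow(windows))
  if (nrow(windows) == 0L) {
    return(data.frame(snp_start = integer(0), snp_end = integer(0),
                      smoothed = numeric(0), n_covering = integer(0)))
  }
  if (is.null(step)) {
    step <- if (nrow(windows) > 1L) windows$snp_start[2] - windows$snp_start[1]
            else windows$snp_end[1] - windows$snp_start[1]
  }
  max_end <- max(windows$snp_end)
  r_starts <- seq(min(windows$snp_start), max_end - step, by = step)
  sm <- numeric(length(r_starts))
  ncov <- integer(length(r_starts))
  for (r in seq_along(r_starts)) {
    rs <- r_starts[r]
    cov <- windows$snp_start <= rs & windows$snp_end >= rs + step
    vals <- raw[cov]
    vals <- vals[!is.na(vals)]
    ncov[r] <- length(vals)
    sm[r] <- if (length(vals) > 0L) mean(vals) else NA_real_
  }
  data.frame(snp_start = as.integer(r_starts),
             snp_end = as.integer(r_starts + step),
             smoothed = sm, n_covering = ncov)
}

#' Build a genomic weighting track for one scaffold
#'
#' Attaches genomic coordinates (1-based positions of the first and
#' last SNP of each step-sized region) to a smoothed track.
#'
#' @inheritParams smooth_track
#' @param pos 1-based positions of the scaffold's filtered SNPs.
#' @param scaffold scaffold id.
#' @return data.frame of class `weighting_track`: region coordinates in
#'   SNP-index and genomic space, smoothed values, coverage counts.
#' @export
weighting_track <- function(raw, windows, pos, scaffold, step = NULL) {
  tr <- smooth_track(raw, windows, step)
  tr$gstart <- pos[tr$snp_start + 1L]
  tr$gend <- pos[pmin(tr$snp_end, length(pos))]
  tr$scaffold <- rep(scaffold, nrow(tr))
  class(tr) <- c("weighting_track", "data.frame")
  tr
}

#' Call peaks of shared ancestry on a smoothed track
#'
#' Maximal runs of at least `min_regions` consecutive regions with
#' smoothed value >= `threshold`, reported as 1-based inclusive genomic
#' intervals from the first SNP of the first region to the last SNP of
#' the last region, with the run's maximum smoothed value as height.
#'
#' @param track a [weighting_track()] (or any data.frame with
#'   `scaffold`, `gstart`, `gend`, `smoothed` columns).
#' @param threshold smoothed-value threshold in (0, 1].
#' @param min_regions minimum run length in regions.
#' @return data.frame with `scaffold`, `start`, `end`, `height`,
#'   `n_regions` columns.
#' @export
call_peaks <- function(track, threshold = 1.0, min_regions = 1L) {
  stopifnot(threshold > 0, threshold <= 1)
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), height = numeric(0),
                      n_regions = integer(0))
  if (nrow(track) == 0L) return(empty)
  out <- lapply(split(seq_len(nrow(track)), track$scaffold), function(ii) {
    tt <- track[ii, ]
    above <- !is.na(tt$smoothed) & tt$smoothed >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_regions)
    if (length(keep) == 0L) return(NULL)
    data.frame(scaffold = tt$scaffold[1],
               start = tt$gstart[run_start[keep]],
               end = tt$gend[run_end[keep]],
               height = vapply(keep, function(q) {
                 max(tt$smoothed[run_start[q]:run_end[q]])
               }, numeric(1)),
               n_regions = r$lengths[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Run the full shared-ancestry scan on a genotype matrix
#'
#' Pipeline: pseudo-haploidize, build sliding windows per scaffold,
#' apply the per-sample data-sufficiency rule, build a neighbor-joining
#' tree per passing window, compute the topology weighting (exact when
#' the combination count allows, sampled otherwise), sum the target
#' topologies, smooth across overlapping windows, and call peaks.
#' Apply [filter_genotypes()] first; this function scans the matrix it
#' is given.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param spec a [comparison_spec()]; its groups must map onto `gm`'s
#'   samples via the taxon map (group -> sample ids).
#' @param seed seed for pseudo-haploidization and any sampled
#'   weightings.
#' @param window_size,step window size and slide in SNPs.
#' @param min_snps_per_sample window data-sufficiency threshold.
#' @param threshold,min_regions peak-calling parameters.
#' @param max_exact exact-weighting combination ceiling.
#' @param ... passed to [weight_sampled()] in sampling mode.
#' @return list with `track` (all scaffolds), `peaks`, `windows`
#'   (per-window metadata incl. `raw` target signal), and `hm`.
#' @export
scan_shared_ancestry <- function(gm, spec, seed = 1L,
                                 window_size = 100L, step = 25L,
                                 min_snps_per_sample = 30L,
                                 threshold = 0.95, min_regions = 1L,
                                 max_exact = 1e5, ...) {
  hm <- pseudo_haploidize(gm, seed)
  groups <- spec$groups
  miss <- setdiff(unlist(groups), hm$tips)
  if (length(miss) > 0L) {
    stop("comparison samples absent from matrix: ", paste(miss, collapse = ", "))
  }
  scaffolds <- unique(hm$scaffold)
  tracks <- list()
  winlist <- list()
  for (sc in scaffolds) {
    ii <- which(hm$scaffold == sc)
    sub <- list(scaffold = hm$scaffold[ii], pos = hm$pos[ii],
                hap = hm$hap[ii, , drop = FALSE], tips = hm$tips,
                taxon = hm$taxon, seed = hm$seed)
    class(sub) <- "haplotype_matrix"
    windows <- make_windows(length(ii), window_size, step)
    forest <- build_window_forest(sub, windows, min_snps_per_sample)
    raw <- rep(NA_real_, nrow(windows))
    for (k in seq_len(nrow(windows))) {
      tr <- forest$trees[[k]]
      if (is.null(tr)) next
      w <- topology_weights(tr, groups, max_exact = max_exact,
                            seed = seed + k, ...)
      raw[k] <- target_signal(w, spec)
    }
    wd <- forest$windows
    wd$raw <- raw
    wd$scaffold <- rep(sc, nrow(wd))
    wd$gstart <- sub$pos[wd$snp_start + 1L]
    wd$gend <- sub$pos[pmin(wd$snp_end, length(sub$pos))]
    winlist[[sc]] <- wd
    if (nrow(windows) > 0L) {
      tracks[[sc]] <- weighting_track(raw, windows, sub$pos, sc, step)
    }
  }
  track <- if (length(tracks) > 0L) do.call(rbind, tracks) else
    weighting_track(numeric(0), make_windows(0), integer(0), character(0))
  rownames(track) <- NULL
  windows <- do.call(rbind, winlist)
  rownames(windows) <- NULL
  list(track = track,
       peaks = call_peaks(track, threshold, min_regions),
       windows = windows,
       comparison = spec$name)
}
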