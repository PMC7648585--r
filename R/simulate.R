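#' Configuration for the block-wise introgression simulator
#'
#' The simulator emulates the statistical structure the scan assumes: a
#' two-clade species tree with incomplete-lineage-sorting (ILS) noise,
#' near-identical within-group samples, and narrow implanted
#' introgression tracts in which two non-sister groups are forced
#' monophyletic. The genome is a sequence of blocks; each block draws
#' one genealogy (the species topology with probability `1 - ils_rate`,
#' otherwise uniform over the alternatives; the forced shared-ancestry
#' topology inside tracts), drops Poisson(`branch_scale`) mutations on
#' each of its 2k-3 branches under infinite sites within the block, and
#' adds Poisson(`hap_scale`) private mutations per haplotype. Diploid
#' genotypes pair two independently simulated haplotypes per sample.
#'
#' @param groups named integer vector: samples per group (six groups).
#' @param species_tree a [topology()] on the six group names; default
#'   is two clades of three (the first three names against the rest).
#' @param block_snps candidate site slots per block; blocks span
#'   `block_snps` bp so slot i of block b sits at position
#'   `(b-1)*block_snps + i`.
#' @param n_blocks number of blocks.
#' @param ils_rate probability a background block's genealogy deviates
#'   from the species topology.
#' @param tracts list of `list(recipient=, donor=, blocks=c(from, to))`
#'   (1-based inclusive block indices). Inside a tract the genealogy is
#'   the species topology with the recipient re-attached as sister to
#'   the donor. Overlapping tracts are an error.
#' @param branch_scale expected mutations per genealogy branch per
#'   block.
#' @param hap_scale expected private mutations per haplotype per block
#'   (creates within-group variation and heterozygosity).
#' @param missing_rate per-call probability of a missing genotype.
#' @param low_dp_rate per-call probability of sub-threshold read depth
#'   (DP drawn from 0..4, below the default masking threshold).
#' @param scaffold scaffold id of the simulated sequence.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(groups = stats::setNames(rep(3L, 6),
                                                       c("melW", "melE", "melS",
                                                         "silvA", "silvB", "silvC")),
                              species_tree = NULL,
                              block_snps = 100L, n_blocks = 200L,
                              ils_rate = 0.2, tracts = list(),
                              branch_scale = 3, hap_scale = 0.5,
                              missing_rate = 0.02, low_dp_rate = 0.02,
                              scaffold = "scaffold_sim") {
  stopifnot(length(groups) == 6L, !is.null(names(groups)),
            all(groups >= 1L), block_snps >= 1L, n_blocks >= 1L,
            ils_rate >= 0, ils_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            low_dp_rate >= 0, low_dp_rate <= 1)
  gl <- names(groups)
  if (is.null(species_tree)) {
    species_tree <- topology(sprintf("((%s,(%s,%s)),(%s,(%s,%s)));",
                                     gl[1], gl[2], gl[3], gl[4], gl[5], gl[6]))
  } else {
    species_tree <- topology(species_tree)
    if (!setequal(species_tree$labels, gl)) {
      stop("species_tree labels must equal the group names")
    }
  }
  used <- integer(0)
  for (tr in tracts) {
    stopifnot(all(c("recipient", "donor", "blocks") %in% names(tr)),
              tr$recipient %in% gl, tr$donor %in% gl,
              tr$blocks[1] >= 1L, tr$blocks[2] <= n_blocks,
              tr$blocks[1] <= tr$blocks[2])
    bl <- tr$blocks[1]:tr$blocks[2]
    if (any(bl %in% used)) stop("overlapping tract specs")
    used <- c(used, bl)
  }
  structure(list(groups = groups, species_tree = species_tree,
                 block_snps = as.integer(block_snps),
                 n_blocks = as.integer(n_blocks),
                 ils_rate = ils_rate, tracts = tracts,
                 branch_scale = branch_scale, hap_scale = hap_scale,
                 missing_rate = missing_rate, low_dp_rate = low_dp_rate,
                 scaffold = scaffold),
            class = "simulation_config")
}

# species topology with `recipient` re-attached as sister to `donor`
forced_topology <- function(species_tree, recipient, donor) {
  rest <- setdiff(species_tree$labels, recipient)
  base <- restrict_topology(species_tree, rest)
  sides <- lapply(base$splits, function(m) {
    s <- mask_labels(m, base$labels)
    if (donor %in% s) c(s, recipient) else s
  })
  comp <- lapply(base$splits, function(m) {
    s <- setdiff(base$labels, mask_labels(m, base$labels))
    if (donor %in% s) c(s, recipient) else s
  })
  topology_from_sets(c(sides, comp, list(c(recipient, donor))),
                     species_tree$labels)
}

#' Simulate genotypes with implanted introgression tracts
#'
#' See [simulation_config()] for the model. Fully determined by `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()]), and `truth`: a list
#'   with `blocks` (per-block genealogy id, tract flag, genomic span,
#'   SNP count) and `tracts` (implanted tract intervals in genomic
#'   coordinates with the forced topology id).
#' @export
simulate_introgression <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  gl <- names(config$groups)
  k <- length(gl)
  sorted_gl <- sort(gl)
  tab <- topology_table(gl)
  species_idx <- match(config$species_tree$id, tab$ids)

  # genealogy branch sides: one per unrooted edge = k pendant + k-3 internal
  topo_sides <- lapply(tab$topologies, function(tp) {
    c(lapply(seq_len(k), function(i) sorted_gl[i]),
      lapply(tp$splits, mask_labels, labels = sorted_gl))
  })

  block_topo <- integer(config$n_blocks)
  is_tract <- logical(config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    block_topo[b] <- if (stats::runif(1) < config$ils_rate) {
      sample(setdiff(seq_along(tab$ids), species_idx), 1L)
    } else species_idx
  }
  tract_rows <- list()
  for (tr in config$tracts) {
    ft <- forced_topology(config$species_tree, tr$recipient, tr$donor)
    fi <- match(ft$id, tab$ids)
    bl <- tr$blocks[1]:tr$blocks[2]
    block_topo[bl] <- fi
    is_tract[bl] <- TRUE
    tract_rows[[length(tract_rows) + 1L]] <-
      data.frame(scaffold = config$scaffold,
                 start = (tr$blocks[1] - 1L) * config$block_snps + 1L,
                 end = tr$blocks[2] * config$block_snps,
                 recipient = tr$recipient, donor = tr$donor,
                 topology_id = ft$id)
  }

  n_samples <- sum(config$groups)
  sample_ids <- unlist(lapply(gl, function(g) {
    paste0(g, "_s", seq_len(config$groups[[g]]))
  }))
  sample_group <- rep(gl, config$groups)
  hap_group <- rep(sample_group, each = 2L)
  n_hap <- 2L * n_samples

  pos_list <- list()
  a1_list <- list()
  a2_list <- list()
  n_snps_block <- integer(config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    sides <- topo_sides[[block_topo[b]]]
    n_mut <- stats::rpois(length(sides), config$branch_scale)
    derived <- rep(sides, n_mut)
    hap_mut <- stats::rpois(n_hap, config$hap_scale)
    priv <- unlist(lapply(which(hap_mut > 0L), function(h) {
      rep(list(-h), hap_mut[h])  # negative = private to one haplotype
    }), recursive = FALSE)
    derived <- c(derived, priv)
    M <- length(derived)
    if (M == 0L) {
      n_snps_block[b] <- 0L
      next
    }
    if (M > config$block_snps) {
      derived <- derived[sample.int(M, config$block_snps)]
      M <- config$block_snps
    }
    slots <- sort(sample.int(config$block_snps, M))
    derived <- derived[sample.int(M)]  # random mutation-to-slot pairing
    H <- matrix(0L, M, n_hap)
    for (i in seq_len(M)) {
      d <- derived[[i]]
      if (is.numeric(d) && length(d) == 1L && d < 0) {
        H[i, -d] <- 1L
      } else {
        H[i, hap_group %in% d] <- 1L
      }
    }
    pos_list[[b]] <- (b - 1L) * config$block_snps + slots
    a1_list[[b]] <- H[, seq(1L, n_hap, by = 2L), drop = FALSE]
    a2_list[[b]] <- H[, seq(2L, n_hap, by = 2L), drop = FALSE]
    n_snps_block[b] <- M
  }
  pos <- unlist(pos_list)
  a1 <- do.call(rbind, a1_list)
  a2 <- do.call(rbind, a2_list)
  n <- length(pos)

  dp <- matrix(stats::rpois(n * n_samples, 30) + 5L, n, n_samples)
  gq <- matrix(99L, n, n_samples)
  low <- matrix(stats::runif(n * n_samples) < config$low_dp_rate, n, n_samples)
  dp[low] <- sample(0:4, sum(low), replace = TRUE)
  miss <- matrix(stats::runif(n * n_samples) < config$missing_rate, n, n_samples)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  dp[miss] <- 0L
  gq[miss] <- 0L

  gm <- genotype_matrix(rep(config$scaffold, n), pos, a1, a2, dp, gq,
                        sample_ids,
                        stats::setNames(sample_group, sample_ids),
                        ref = rep("A", n), alt = rep("T", n))
  blocks <- data.frame(block = seq_len(config$n_blocks),
                       scaffold = config$scaffold,
                       start = (seq_len(config$n_blocks) - 1L) * config$block_snps + 1L,
                       end = seq_len(config$n_blocks) * config$block_snps,
                       topology_id = tab$ids[block_topo],
                       is_tract = is_tract,
                       n_snps = n_snps_block)
  tracts <- if (length(tract_rows) > 0L) do.call(rbind, tract_rows) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               recipient = character(0), donor = character(0),
               topology_id = character(0))
  list(gm = gm, truth = list(blocks = blocks, tracts = tracts,
                             config = config, seed = as.integer(seed)))
}

#' Write a genotype matrix as VCF text
#'
#' Emits a VCF v4.2 with GT:DP:GQ FORMAT fields; byte-identical for a
#' given matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ancestryscan-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
             con)
  for (sc in unique(gm$scaffold)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", sc,
                       max(gm$pos[gm$scaffold == sc])), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", gm$samples),
                   collapse = "\t"), con)
  n <- n_sites(gm)
  gt <- matrix(".", n, length(gm$samples))
  obs <- !is.na(gm$a1)
  gt[obs] <- paste0(gm$a1[obs], "/", gm$a2[obs])
  gt[!obs] <- "./."
  cells <- matrix(paste0(gt, ":", gm$dp, ":", gm$gq), n)
  ref <- if (is.null(gm$ref)) rep("A", n) else gm$ref
  alt <- if (is.null(gm$alt)) rep("T", n) else gm$alt
  lines <- paste(gm$scaffold, gm$pos, ".", ref, alt, ".", "PASS", ".",
                 "GT:DP:GQ", apply(cells, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Score recovery of implanted tracts
#'
#' @param elements data.frame of called elements (or peaks) with
#'   `scaffold`, `start`, `end`.
#' @param truth the `truth` list from [simulate_introgression()] (or a
#'   tract data.frame).
#' @return list: `recall` (fraction of truth tracts overlapped by at
#'   least one element), `precision` (fraction of elements overlapping
#'   a tract; `NaN` with `no_elements = TRUE` when none were called),
#'   `boundary_error` (mean absolute offset in bp of matched element
#'   edges from tract edges), `n_elements`, `n_tracts`.
#' @export
recovery_report <- function(elements, truth) {
  tracts <- if (is.data.frame(truth)) truth else truth$tracts
  overlaps <- function(a, b) {
    a$scaffold == b$scaffold & a$start <= b$end & a$end >= b$start
  }
  n_el <- nrow(elements)
  n_tr <- nrow(tracts)
  tract_hit <- logical(n_tr)
  el_hit <- logical(n_el)
  offsets <- numeric(0)
  for (i in seq_len(n_tr)) {
    for (j in seq_len(n_el)) {
      if (tracts$scaffold[i] == elements$scaffold[j] &&
          tracts$start[i] <= elements$end[j] &&
          tracts$end[i] >= elements$start[j]) {
        tract_hit[i] <- TRUE
        el_hit[j] <- TRUE
        offsets <- c(offsets, abs(elements$start[j] - tracts$start[i]),
                     abs(elements$end[j] - tracts$end[i]))
      }
    }
  }
  list(recall = if (n_tr > 0L) mean(tract_hit) else NA_real_,
       precision = if (n_el > 0L) mean(el_hit) else NaN,
       no_elements = n_el == 0L,
       boundary_error = if (length(offsets) > 0L) mean(offsets) else NA_real_,
       n_elements = n_el, n_tracts = n_tr)
}

#' Simulate, scan, and score in one call
#'
#' End-to-end experiment: simulate genotypes, apply the full filter
#' cascade, run the shared-ancestry scan for the comparison implied by
#' the first tract (or a supplied focal pair), delimit elements from
#' the peaks, and score recovery against the truth set.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed driving the simulation and the scan.
#' @param threshold peak-calling threshold on the smoothed track.
#' @param focal_pair focal groups for the comparison; defaults to the
#'   first tract's (recipient, donor) or, with no tracts, the two
#'   groups whose monophyly the species tree does not imply (first
#'   group of each clade).
#' @param ... further arguments to [scan_shared_ancestry()].
#' @return list with `report` (see [recovery_report()]), `elements`,
#'   `scan`, `truth`.
#' @export
recovery_experiment <- function(config = simulation_config(), seed = 1L,
                                threshold = 0.9, focal_pair = NULL, ...) {
  sim <- simulate_introgression(config, seed)
  if (is.null(focal_pair)) {
    focal_pair <- if (length(config$tracts) > 0L) {
      c(config$tracts[[1]]$recipient, config$tracts[[1]]$donor)
    } else {
      st <- config$species_tree
      side <- mask_labels(st$splits[length(st$splits)], st$labels)
      c(sort(side)[1], sort(setdiff(st$labels, side))[1])
    }
  }
  gm <- filter_genotypes(sim$gm)
  groups <- split(sim$gm$samples, sim$gm$taxon)[names(config$groups)]
  spec <- comparison_spec("simulated", groups,
                          restrict_topology(config$species_tree,
                                            setdiff(names(config$groups),
                                                    focal_pair)),
                          focal_pair)
  scan <- scan_shared_ancestry(gm, spec, seed = seed,
                               threshold = threshold, ...)
  elements <- delimit_elements(intersect_peaks(list(simulated = scan$peaks)))
  list(report = recovery_report(elements, sim$truth),
       elements = elements, scan = scan, truth = sim$truth)
}
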