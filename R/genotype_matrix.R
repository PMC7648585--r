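#' Genotype matrix construction
#'
#' A `genotype_matrix` holds diploid SNP calls for one or more scaffolds:
#' per-site coordinates, per-call allele indices (two integer matrices,
#' `NA` = missing), per-call read depth and genotype quality, and a
#' sample-to-taxon map. Sites are rows, samples are columns. Coordinates
#' are 1-based inclusive throughout.
#'
#' @param scaffold character vector of scaffold ids, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each scaffold.
#' @param a1,a2 integer matrices (sites x samples) of allele indices
#'   (0 = REF, 1 = first ALT, ...); `NA` for missing calls. A call is
#'   missing iff both `a1` and `a2` are `NA`.
#' @param dp,gq integer matrices (sites x samples) of read depth and
#'   phred-scaled genotype quality; absent values are 0.
#' @param samples character vector of sample ids (column order).
#' @param taxon named character vector mapping every sample id to a taxon
#'   label.
#' @param ref,alt per-site REF allele and comma-separated ALT alleles
#'   (kept for VCF provenance; the scan itself works on allele indices).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(scaffold, pos, a1, a2, dp, gq, samples, taxon,
                            ref = NULL, alt = NULL) {
  n <- length(pos)
  m <- length(samples)
  stopifnot(length(scaffold) == n,
            all(dim(a1) == c(n, m)), all(dim(a2) == c(n, m)),
            all(dim(dp) == c(n, m)), all(dim(gq) == c(n, m)))
  if (!all(samples %in% names(taxon))) {
    stop("taxon map must cover every sample id")
  }
  ord_ok <- unlist(lapply(split(pos, factor(scaffold, unique(scaffold))),
                          function(p) !is.unsorted(p, strictly = TRUE)),
                   use.names = FALSE)
  if (!all(ord_ok)) stop("positions must be strictly increasing within scaffold")
  # a call is either fully missing or fully observed
  bad <- xor(is.na(a1), is.na(a2))
  if (any(bad)) stop("half-missing diploid calls are not allowed")
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  storage.mode(dp) <- "integer"; storage.mode(gq) <- "integer"
  structure(list(scaffold = as.character(scaffold), pos = as.integer(pos),
                 a1 = a1, a2 = a2, dp = dp, gq = gq,
                 samples = as.character(samples),
                 taxon = taxon[samples],
                 ref = ref, alt = alt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d scaffold%s), %.1f%% missing\n",
              n_sites(x), length(x$samples), length(unique(x$scaffold)),
              if (length(unique(x$scaffold)) == 1L) "" else "s",
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Number of sites in a genotype or haplotype matrix
#' @param x a `genotype_matrix` or `haplotype_matrix`.
#' @return integer site count.
#' @export
n_sites <- function(x) length(x$pos)

subset_sites <- function(gm, keep) {
  gm$scaffold <- gm$scaffold[keep]
  gm$pos <- gm$pos[keep]
  for (f in c("a1", "a2", "dp", "gq")) {
    gm[[f]] <- gm[[f]][keep, , drop = FALSE]
  }
  if (!is.null(gm$ref)) gm$ref <- gm$ref[keep]
  if (!is.null(gm$alt)) gm$alt <- gm$alt[keep]
  gm
}

#' Read SNP genotypes from a multi-sample VCF
#'
#' Loads biallelic and multiallelic SNP records (single-base REF and ALT
#' alleles); other records are skipped and counted in the `n_skipped`
#' attribute. Per-call DP and GQ are captured where present; absent
#' values are treated as 0.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param taxon named character vector mapping sample id to taxon; if
#'   `NULL`, each sample is its own taxon.
#' @param region optional `"scaffold"` or `"scaffold:start-end"` string
#'   (1-based inclusive). An absent scaffold yields an empty matrix with
#'   a warning.
#' @return A [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, taxon = NULL, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  is_base <- function(x) nchar(x) == 1L & x %in% c("A", "C", "G", "T")
  alt_ok <- vapply(strsplit(alt, ",", fixed = TRUE),
                   function(a) length(a) >= 1L && all(is_base(a)),
                   logical(1))
  snp <- is_base(ref) & alt_ok
  n_skipped <- sum(!snp)

  keep <- snp
  if (!is.null(region)) {
    rg <- parse_region(region)
    if (!rg$scaffold %in% chrom) {
      warning("region scaffold '", rg$scaffold, "' absent from VCF")
      keep <- rep(FALSE, length(keep))
    } else {
      keep <- keep & chrom == rg$scaffold &
        pos >= rg$start & pos <= rg$end
    }
  }

  gt <- vcfR::extract.gt(v, "GT")[keep, , drop = FALSE]
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))[keep, , drop = FALSE]
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))[keep, , drop = FALSE]
  dp[is.na(dp)] <- 0
  gq[is.na(gq)] <- 0
  al <- parse_gt(gt)
  samples <- colnames(gt)
  if (is.null(taxon)) taxon <- stats::setNames(samples, samples)
  gm <- genotype_matrix(chrom[keep], pos[keep], al$a1, al$a2,
                        dp, gq, samples, taxon,
                        ref = ref[keep], alt = alt[keep])
  attr(gm, "n_skipped") <- n_skipped
  gm
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0L) stop("malformed region: ", region)
  list(scaffold = m[2],
       start = if (m[4] == "") 1L else as.integer(m[4]),
       end = if (m[5] == "") .Machine$integer.max else as.integer(m[5]))
}

# "0/1", "0|1", "./." etc. -> two integer allele matrices
parse_gt <- function(gt) {
  dims <- dim(gt)
  g <- as.vector(gt)
  g[is.na(g)] <- "./."
  a1 <- suppressWarnings(as.integer(sub("^([0-9.]+)[/|].*$", "\\1", g)))
  a2 <- suppressWarnings(as.integer(sub("^.*[/|]([0-9.]+)$", "\\1", g)))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  list(a1 = matrix(a1, dims[1], dims[2]),
       a2 = matrix(a2, dims[1], dims[2]))
}

#' Read a two-column sample-to-taxon map
#'
#' @param path TSV with columns sample id and taxon label (no header).
#' @return named character vector (names are sample ids).
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample", "taxon"),
                           colClasses = "character")
  stats::setNames(tab$taxon, tab$sample)
}

#' Mask low-confidence genotype calls
#'
#' Calls with read depth below `min_depth` or genotype quality below
#' `min_gq` are set to missing (strict less-than thresholds, so DP = 5 /
#' GQ = 20 survive the defaults). Idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth,min_gq non-negative integer thresholds.
#' @return the masked `genotype_matrix`.
#' @export
mask_low_quality <- function(gm, min_depth = 5L, min_gq = 20L) {
  stopifnot(min_depth >= 0, min_gq >= 0)
  drop <- gm$dp < min_depth | gm$gq < min_gq
  gm$a1[drop] <- NA_integer_
  gm$a2[drop] <- NA_integer_
  gm
}

#' Remove sites below a minor-allele count threshold
#'
#' The minor-allele count is taken over observed allele copies (two per
#' non-missing diploid call): the count of the rarest observed allele.
#' Monomorphic sites have minor count 0 and are removed at any positive
#' threshold. This is the count reading of the study panel's
#' "frequency below 2/53" rule, which stays well-defined when calls are
#' missing.
#'
#' @param gm a [genotype_matrix()].
#' @param min_minor_allele_count sites with minor-allele count strictly
#'   below this are removed.
#' @return the filtered `genotype_matrix` (site order preserved).
#' @export
filter_mac <- function(gm, min_minor_allele_count = 2L) {
  stopifnot(min_minor_allele_count >= 0)
  mac <- site_mac(gm)
  subset_sites(gm, mac >= min_minor_allele_count)
}

site_mac <- function(gm) {
  n <- n_sites(gm)
  vapply(seq_len(n), function(i) {
    al <- c(gm$a1[i, ], gm$a2[i, ])
    al <- al[!is.na(al)]
    if (length(al) == 0L) return(0L)
    counts <- tabulate(al + 1L)
    counts <- counts[counts > 0L]
    if (length(counts) < 2L) 0L else as.integer(min(counts))
  }, integer(1))
}

#' Remove sites with excess missing data
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_fraction sites whose missing-call fraction across
#'   all samples exceeds this (strictly) are removed.
#' @return the filtered `genotype_matrix`.
#' @export
filter_missingness <- function(gm, max_missing_fraction = 0.10) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- rowMeans(is.na(gm$a1))
  subset_sites(gm, miss <= max_missing_fraction)
}

#' Apply the full site-filtering cascade
#'
#' Convenience wrapper: quality masking, then the minor-allele-count
#' filter, then the missingness filter, in that order.
#'
#' @inheritParams mask_low_quality
#' @inheritParams filter_mac
#' @inheritParams filter_missingness
#' @return the filtered `genotype_matrix`.
#' @export
filter_genotypes <- function(gm, min_depth = 5L, min_gq = 20L,
                             min_minor_allele_count = 2L,
                             max_missing_fraction = 0.10) {
  gm <- mask_low_quality(gm, min_depth, min_gq)
  gm <- filter_mac(gm, min_minor_allele_count)
  filter_missingness(gm, max_missing_fraction)
}
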