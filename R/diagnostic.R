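#' Contrast between two phenotype-defined taxon groups
#'
#' @param name contrast name.
#' @param group_a,group_b disjoint sets of taxon labels.
#' @param excluded_taxa taxa dropped entirely (e.g. a taxon known to
#'   have evolved the phenotype independently).
#' @param required_taxa taxa whose every sample must have a call at a
#'   qualifying site.
#' @param max_missing_fraction missingness cap across the contrast's
#'   samples.
#' @return An object of class `group_contrast`.
#' @export
group_contrast <- function(name, group_a, group_b,
                           excluded_taxa = character(0),
                           required_taxa = character(0),
                           max_missing_fraction = 0.20) {
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("group_a and group_b must be disjoint")
  }
  if (length(intersect(excluded_taxa, c(group_a, group_b))) > 0L) {
    stop("excluded_taxa must be disjoint from both groups")
  }
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 excluded_taxa = excluded_taxa,
                 required_taxa = required_taxa,
                 max_missing_fraction = max_missing_fraction),
            class = "group_contrast")
}

#' Diagnostically fixed SNPs between two phenotype groups
#'
#' A site qualifies iff (i) its missing-call fraction across the
#' contrast's samples (both groups, excluded taxa removed) is at most
#' `max_missing_fraction`; (ii) every sample of every required taxon
#' has a non-missing call; and (iii) all alleles observed in group A
#' equal one allele and all observed in group B a different one.
#' "Fixed" is evaluated on observed calls only; a heterozygous call
#' disqualifies a site because it exposes both alleles in one group.
#'
#' @param gm a [genotype_matrix()].
#' @param contrast a [group_contrast()].
#' @return data.frame of qualifying SNPs sorted by position: `scaffold`,
#'   `pos`, `allele_a`, `allele_b`, `n_observed_a`, `n_observed_b`.
#' @export
diagnostic_fixed_snps <- function(gm, contrast) {
  taxa <- gm$taxon
  sa <- gm$samples[taxa %in% setdiff(contrast$group_a, contrast$excluded_taxa)]
  sb <- gm$samples[taxa %in% setdiff(contrast$group_b, contrast$excluded_taxa)]
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("empty contrast group after exclusions")
  }
  sreq <- gm$samples[taxa %in% contrast$required_taxa]
  ci <- match(c(sa, sb), gm$samples)

  miss <- is.na(gm$a1[, ci, drop = FALSE])
  ok_miss <- rowMeans(miss) <= contrast$max_missing_fraction
  ok_req <- if (length(sreq) > 0L) {
    rowSums(is.na(gm$a1[, match(sreq, gm$samples), drop = FALSE])) == 0L
  } else TRUE

  range_a <- allele_range(gm, sa)
  range_b <- allele_range(gm, sb)
  fixed <- !is.na(range_a$min) & !is.na(range_b$min) &
    range_a$min == range_a$max & range_b$min == range_b$max &
    range_a$min != range_b$min
  keep <- which(ok_miss & ok_req & fixed)
  out <- data.frame(scaffold = gm$scaffold[keep], pos = gm$pos[keep],
                    allele_a = range_a$min[keep],
                    allele_b = range_b$min[keep],
                    n_observed_a = range_a$n_obs[keep],
                    n_observed_b = range_b$n_obs[keep])
  out[order(out$scaffold, out$pos), , drop = FALSE]
}

# per-site min/max observed allele index and observed-call count over a
# sample set (min == max iff a single allele is observed)
allele_range <- function(gm, samples) {
  si <- match(samples, gm$samples)
  cols <- c(as.data.frame(gm$a1[, si, drop = FALSE]),
            as.data.frame(gm$a2[, si, drop = FALSE]))
  mn <- suppressWarnings(do.call(pmin, c(cols, list(na.rm = TRUE))))
  mx <- suppressWarnings(do.call(pmax, c(cols, list(na.rm = TRUE))))
  mn[is.infinite(mn)] <- NA_integer_
  mx[is.infinite(mx)] <- NA_integer_
  list(min = mn, max = mx,
       n_obs = rowSums(!is.na(gm$a1[, si, drop = FALSE])))
}

#' Cluster diagnostic SNPs by genomic gap
#'
#' Single-linkage: consecutive SNPs at most `max_gap` bp apart (on the
#' same scaffold) join a cluster.
#'
#' @param snps data.frame with `scaffold` and `pos`, sorted by position.
#' @param max_gap maximum gap in bp.
#' @return data.frame with `scaffold`, `start`, `end`, `n_snps`.
#' @export
cluster_snps <- function(snps, max_gap = 5000) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0))
  if (nrow(snps) == 0L) return(empty)
  out <- lapply(split(snps$pos, snps$scaffold), function(p) {
    if (is.unsorted(p)) stop("snps must be sorted by position")
    cl <- cumsum(c(TRUE, diff(p) > max_gap))
    data.frame(start = tapply(p, cl, min), end = tapply(p, cl, max),
               n_snps = as.integer(table(cl)))
  })
  res <- do.call(rbind, Map(function(sc, df) {
    df$scaffold <- sc
    df[, c("scaffold", "start", "end", "n_snps")]
  }, names(out), out))
  rownames(res) <- NULL
  res[order(res$scaffold, res$start), , drop = FALSE]
}
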