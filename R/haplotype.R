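#' Resolve diploid calls to one tip per individual
#'
#' Tree building uses one sequence per individual. Homozygous calls map
#' to their allele; heterozygous calls are resolved to one of the two
#' alleles by a fair coin derived from `(seed, site index, sample index)`
#' via a multiplicative-congruential hash, so the result is independent
#' of processing order and of which other sites or samples are present.
#' Missing stays missing.
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed recorded in the result.
#' @return An object of class `haplotype_matrix`: fields `scaffold`,
#'   `pos`, `hap` (sites x tips integer allele matrix, `NA` missing),
#'   `tips`, `taxon`, `seed`.
#' @export
pseudo_haploidize <- function(gm, seed) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  hap <- gm$a1
  het <- which(!is.na(gm$a1) & gm$a1 != gm$a2)
  if (length(het) > 0L) {
    n <- nrow(gm$a1)
    i <- ((het - 1L) %% n) + 1L   # site index
    j <- ((het - 1L) %/% n) + 1L  # sample index
    take2 <- cell_coin(seed, i, j)
    hap[het[take2]] <- gm$a2[het[take2]]
  }
  structure(list(scaffold = gm$scaffold, pos = gm$pos, hap = hap,
                 tips = gm$samples, taxon = gm$taxon,
                 seed = as.integer(seed)),
            class = "haplotype_matrix")
}

# Fair coin per (seed, i, j), order-independent. Lehmer-style mixing
# modulo the Mersenne prime 2^31 - 1; all products stay below 2^53 so
# double arithmetic is exact.
cell_coin <- function(seed, i, j) {
  p <- 2147483647
  a <- 48271
  x <- (abs(as.numeric(seed)) %% p)
  x <- (x * a + as.numeric(i)) %% p
  x <- (x * a + as.numeric(j)) %% p
  x <- (x * a) %% p
  x <- (x * a) %% p
  x >= p / 2
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d sites x %d tips, seed %d\n",
              length(x$pos), length(x$tips), x$seed))
  invisible(x)
}
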