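# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# Write a small VCF from a character matrix of "GT:DP:GQ" cells.
write_fixture_vcf <- function(path, chrom, pos, ref, alt, cells, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            "GT:DP:GQ", cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Genotype matrix built directly, bypassing VCF I/O. `gt` is a character
# matrix like "0/0", "0/1", "./."; dp/gq default to high-confidence.
toy_gm <- function(gt, taxon = NULL, pos = NULL, scaffold = "scf1",
                   dp = NULL, gq = NULL) {
  n <- nrow(gt)
  m <- ncol(gt)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(m))
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(dp)) dp <- matrix(30L, n, m)
  if (is.null(gq)) gq <- matrix(99L, n, m)
  if (is.null(taxon)) taxon <- stats::setNames(samples, samples)
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))), n, m)
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))), n, m)
  genotype_matrix(rep(scaffold, n), pos, a1, a2, dp, gq, samples, taxon)
}

# 12-tip tree with two tips per group a..f and monophyletic groups.
monophyletic_tree <- function() {
  ape::read.tree(text = paste0(
    "(((a1,a2),((b1,b2),(c1,c2))),((d1,d2),((e1,e2),(f1,f2))));"))
}

# Same, but tip f2 has migrated to be sister of the a-clade: choosing f2
# yields one fixed non-species topology, choosing f1 the species one.
migrant_tree <- function() {
  ape::read.tree(text = paste0(
    "((((a1,a2),f2),(b1,b2)),(c1,c2),((d1,d2),((e1,e2),f1)));"))
}

two_per_group <- function() {
  stats::setNames(lapply(letters[1:6], function(g) paste0(g, 1:2)),
                  letters[1:6])
}

# Random unrooted binary tree on 2 tips per group (labels a1..f2).
random_group_tree <- function(seed) {
  set.seed(seed)
  tr <- ape::rtree(12, rooted = FALSE)
  tr$tip.label <- sample(paste0(rep(letters[1:6], each = 2), 1:2))
  tr
}

# Small simulation config used by several tests: 40 blocks, one 8-block
# tract, defaults otherwise.
small_sim_config <- function(...) {
  simulation_config(n_blocks = 40L,
                    tracts = list(list(recipient = "melW", donor = "silvA",
                                       blocks = c(17L, 24L))),
                    ...)
}
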