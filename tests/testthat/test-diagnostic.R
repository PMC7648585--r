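contrast_fixture <- function() {
  # 10 samples, 5 taxa (2 each): taxA/taxB = phenotype group A,
  # taxC/taxD = group B, taxE excluded
  samples <- paste0("s", 1:10)
  taxon <- stats::setNames(rep(c("taxA", "taxB", "taxC", "taxD", "taxE"),
                               each = 2), samples)
  gt <- matrix("0/0", 6, 10, dimnames = list(NULL, samples))
  gt[1, 5:8] <- "1/1"              # fixed A=0 vs B=1, complete
  gt[2, 5:8] <- "1/1"; gt[2, 1] <- "0/1"  # het in group A exposes allele 0
  gt[3, 5:8] <- "1/1"; gt[3, c(1, 5)] <- "./."  # 2/8 = 25% missing
  gt[4, 5:8] <- "1/1"; gt[4, 1] <- "./."        # 1/8 = 12.5% missing
  gt[5, 5:8] <- "2/2"              # multiallelic fixed difference
  # site 6 monomorphic
  list(gm = toy_gm(gt, taxon = taxon),
       contrast = group_contrast("AvB", c("taxA", "taxB"), c("taxC", "taxD"),
                                 excluded_taxa = "taxE"))
}

test_that("diagnostic fixed SNPs honor fixation, heterozygotes, and missingness", {
  fx <- contrast_fixture()
  snps <- diagnostic_fixed_snps(fx$gm, fx$contrast)
  # site 1: fixed; site 2: het disqualifies; site 3: 25% > 20% missing;
  # site 4: fixed with tolerable missingness; site 5: fixed 0 vs 2
  expect_equal(snps$pos, fx$gm$pos[c(1, 4, 5)])
  expect_equal(snps$allele_a, c(0L, 0L, 0L))
  expect_equal(snps$allele_b, c(1L, 1L, 2L))
  expect_equal(snps$n_observed_a[2], 3L)
  # required-presence taxa: site 4 has a missing taxA call
  ct2 <- group_contrast("AvB", c("taxA", "taxB"), c("taxC", "taxD"),
                        excluded_taxa = "taxE", required_taxa = "taxA")
  snps2 <- diagnostic_fixed_snps(fx$gm, ct2)
  expect_equal(snps2$pos, fx$gm$pos[c(1, 5)])
  # relaxing the missingness cap only grows the set
  ct3 <- fx$contrast
  ct3$max_missing_fraction <- 0.30
  snps3 <- diagnostic_fixed_snps(fx$gm, ct3)
  expect_true(all(snps$pos %in% snps3$pos))
  expect_true(fx$gm$pos[3] %in% snps3$pos)
  expect_error(diagnostic_fixed_snps(fx$gm, group_contrast("e", "taxE", "taxC",
                                                           excluded_taxa = character(0))),
               NA)
  expect_error(
    diagnostic_fixed_snps(fx$gm, group_contrast("none", "nope", "taxC")),
    "empty")
})

test_that("diagnostic scan matches a brute-force per-site re-scan of the VCF text", {
  # write a randomized fixture VCF, then verify with an independent
  # line-by-line predicate on the raw text
  set.seed(5)
  samples <- paste0("s", 1:10)
  taxon <- stats::setNames(rep(c("tA", "tB", "tC", "tD", "tE"), each = 2),
                           samples)
  n <- 60
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * 10, TRUE,
                      prob = c(.45, .1, .35, .1)), n, 10)
  cells <- matrix(paste0(gt, ":30:99"), n, 10)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path, rep("scf1", n), seq_len(n) * 100L,
                    rep("A", n), rep("T", n), cells, samples)
  gm <- read_vcf(path, taxon = taxon)
  contrast <- group_contrast("AB_CD", c("tA", "tB"), c("tC", "tD"),
                             excluded_taxa = "tE")
  got <- diagnostic_fixed_snps(gm, contrast)

  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  oracle <- integer(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    calls <- sub(":.*", "", f[10:19])
    a <- calls[1:4]   # tA, tB samples
    b <- calls[5:8]   # tC, tD samples
    alleles <- function(x) {
      u <- unlist(strsplit(x[x != "./."], "/"))
      unique(u)
    }
    miss_frac <- mean(c(a, b) == "./.")
    if (miss_frac > 0.20) next
    ua <- alleles(a)
    ub <- alleles(b)
    if (length(ua) == 1L && length(ub) == 1L && ua != ub) {
      oracle <- c(oracle, as.integer(f[2]))
    }
  }
  expect_equal(got$pos, oracle)

  # permuting samples within a taxon leaves the set unchanged
  perm <- c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L)
  gmp <- gm
  gmp$a1 <- gm$a1[, perm]; gmp$a2 <- gm$a2[, perm]
  gmp$dp <- gm$dp[, perm]; gmp$gq <- gm$gq[, perm]
  gmp$samples <- gm$samples[perm]; gmp$taxon <- gm$taxon[perm]
  expect_equal(diagnostic_fixed_snps(gmp, contrast)$pos, got$pos)
})

test_that("SNP clustering is single-linkage with a gap threshold", {
  expect_equal(nrow(cluster_snps(data.frame(scaffold = character(0),
                                            pos = integer(0)))), 0L)
  snps <- data.frame(scaffold = "scf1", pos = c(100L, 1100L, 9000L))
  cl <- cluster_snps(snps, max_gap = 5000)
  expect_equal(cl$start, c(100L, 9000L))
  expect_equal(cl$end, c(1100L, 9000L))
  expect_equal(cl$n_snps, c(2L, 1L))
  cl_all <- cluster_snps(snps, max_gap = Inf)
  expect_equal(nrow(cl_all), 1L)
  expect_equal(cl_all$n_snps, 3L)
  # clusters never span scaffolds
  snps2 <- data.frame(scaffold = c("s1", "s2"), pos = c(100L, 150L))
  expect_equal(nrow(cluster_snps(snps2, max_gap = 5000)), 2L)
})
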