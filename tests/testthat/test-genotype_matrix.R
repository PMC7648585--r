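test_that("read_vcf loads SNPs, honors regions, and skips non-SNP records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  cells <- matrix("0/1:30:99", 6, 3)
  cells[2, ] <- c("0/0:25:99", "1/1:31:80", "./.:0:0")
  write_fixture_vcf(path,
                    chrom = rep("scf1", 6),
                    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
                    ref = c("A", "C", "G", "ATT", "T", "A"),
                    alt = c("T", "G", "A", "A", "C", "G,T"),
                    cells = cells,
                    samples = c("s1", "s2", "s3"))

  gm <- read_vcf(path)
  # independent text scan: SNP records have single-base REF and ALTs
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  flds <- strsplit(lines, "\t")
  is_snp <- vapply(flds, function(f) {
    nchar(f[4]) == 1L &&
      all(nchar(strsplit(f[5], ",")[[1]]) == 1L)
  }, logical(1))
  expect_equal(n_sites(gm), sum(is_snp))
  expect_equal(attr(gm, "n_skipped"), sum(!is_snp))
  expect_equal(length(gm$samples), 3L)
  # multiallelic record retained with allele indices preserved
  expect_equal(gm$pos, c(100L, 200L, 300L, 500L, 600L))
  # missing call parsed as NA; DP/GQ captured
  expect_true(is.na(gm$a1[2, 3]))
  expect_equal(gm$dp[2, 2], 31L)
  expect_equal(gm$gq[2, 2], 80L)

  gm2 <- read_vcf(path, region = "scf1:150-450")
  expect_equal(gm2$pos, c(200L, 300L))
  expect_warning(gm3 <- read_vcf(path, region = "nope:1-10"),
                 "absent")
  expect_equal(n_sites(gm3), 0L)
  expect_error(read_vcf(file.path(tempdir(), "absent.vcf")), "cannot read")
})

test_that("mask_low_quality uses strict thresholds and is idempotent", {
  gt <- matrix(c("0/1", "0/1", "0/1", "0/1"), 2, 2)
  dp <- matrix(c(4L, 5L, 30L, 30L), 2, 2)
  gq <- matrix(c(99L, 20L, 19L, 99L), 2, 2)
  gm <- toy_gm(gt, dp = dp, gq = gq)
  masked <- mask_low_quality(gm)
  expect_true(is.na(masked$a1[1, 1]))   # DP 4 < 5
  expect_false(is.na(masked$a1[2, 1]))  # DP 5, GQ 20: boundary retained
  expect_true(is.na(masked$a1[1, 2]))   # GQ 19 < 20
  expect_false(is.na(masked$a1[2, 2]))
  expect_identical(mask_low_quality(masked), masked)
  # masking never reduces missingness
  expect_true(all(is.na(masked$a1[is.na(gm$a1)])))
})

test_that("filter_mac counts minor-allele copies over observed calls", {
  # 53 samples: site 1 has one heterozygote (count 1), site 2 one
  # hom-alt (count 2), site 3 monomorphic
  gt <- matrix("0/0", 3, 53)
  gt[1, 1] <- "0/1"
  gt[2, 1] <- "1/1"
  gm <- toy_gm(gt)
  kept <- filter_mac(gm)
  expect_equal(kept$pos, gm$pos[2])
  expect_equal(n_sites(filter_mac(gm, 0L)), 3L)
})

test_that("filter_missingness removes sites with >10% missing across samples", {
  gt <- matrix("0/1", 3, 53)
  gt[1, 1:6] <- "./."  # 6/53 = 11.3% > 10%
  gt[2, 1:5] <- "./."  # 5/53 = 9.4%
  gm <- toy_gm(gt)
  kept <- filter_missingness(gm)
  expect_equal(kept$pos, gm$pos[2:3])
  expect_equal(n_sites(filter_missingness(gm, 1)), 3L)
})

test_that("site filters commute with sample permutation and are monotone", {
  set.seed(42)
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 30 * 10, TRUE,
                      prob = c(.5, .2, .2, .1)), 30, 10)
  gm <- toy_gm(gt)
  perm <- sample(10)
  permute <- function(g, p) {
    g$a1 <- g$a1[, p]; g$a2 <- g$a2[, p]
    g$dp <- g$dp[, p]; g$gq <- g$gq[, p]
    g$samples <- g$samples[p]; g$taxon <- g$taxon[p]
    g
  }
  for (f in list(function(g) filter_mac(g),
                 function(g) filter_missingness(g, 0.2))) {
    expect_identical(f(permute(gm, perm))$pos, permute(f(gm), perm)$pos)
  }
  # missingness threshold monotonicity: t1 <= t2 => site subset
  p1 <- filter_missingness(gm, 0.05)$pos
  p2 <- filter_missingness(gm, 0.20)$pos
  expect_true(all(p1 %in% p2))
  # mac/missingness never add sites
  expect_lte(n_sites(filter_mac(gm)), n_sites(gm))
})

test_that("pseudo_haploidize copies homozygotes, is deterministic, and is fair", {
  gt <- matrix(c("0/0", "1/1", "0/0", "1/1"), 2, 2)
  gm <- toy_gm(gt)
  hm <- pseudo_haploidize(gm, 7L)
  expect_equal(hm$hap, gm$a1)
  # heterozygous fairness: 10,000 het calls, allele-0 fraction ~ 0.5
  gt2 <- matrix("0/1", 100, 100)
  gm2 <- toy_gm(gt2)
  h1 <- pseudo_haploidize(gm2, 1L)
  expect_identical(pseudo_haploidize(gm2, 1L)$hap, h1$hap)
  frac0 <- mean(h1$hap == 0L)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac0 - 0.5), 3 * se)
  # different seed gives a different resolution
  expect_false(identical(pseudo_haploidize(gm2, 2L)$hap, h1$hap))
  # missing propagates
  gt2[1, 1] <- "./."
  expect_true(is.na(pseudo_haploidize(toy_gm(gt2), 1L)$hap[1, 1]))
})
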