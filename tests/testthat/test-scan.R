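make_spec <- function() {
  groups <- stats::setNames(lapply(letters[1:6], function(g) paste0(g, 1:2)),
                            letters[1:6])
  comparison_spec("test", groups, topology("((b,c),(d,e));"),
                  focal_pair = c("a", "f"))
}

test_that("comparison spec derives the 5-topology target set", {
  spec <- make_spec()
  expect_length(spec$target_ids, 5L)
  expect_equal(spec$focal_pair, c("a", "f"))
  # six-group species tree accepted via restriction
  spec2 <- comparison_spec("test2", spec$groups,
                           topology("((a,(b,c)),(f,(d,e)));"),
                           focal_pair = c("a", "f"))
  expect_setequal(spec2$target_ids, spec$target_ids)
  expect_error(comparison_spec("bad", spec$groups[1:5],
                               topology("((b,c),(d,e));"), c("a", "f")),
               "six")
})

test_that("target signal sums the five target weights", {
  spec <- make_spec()
  tab <- topology_table(letters[1:6])
  # all weight on one target topology
  w1 <- rep(0, 105)
  names(w1) <- tab$ids
  w1[spec$target_ids[1]] <- 1
  wobj <- structure(list(weights = w1, mode = "exact"), class = "weighting")
  expect_equal(target_signal(wobj, spec), 1)
  # uniform weighting -> 5/105
  wu <- structure(list(weights = stats::setNames(rep(1 / 105, 105), tab$ids),
                       mode = "exact"), class = "weighting")
  expect_equal(target_signal(wu, spec), 5 / 105)
  # zero weight on all targets
  w0 <- rep(0, 105)
  names(w0) <- tab$ids
  w0[setdiff(tab$ids, spec$target_ids)[1]] <- 1
  expect_equal(target_signal(structure(list(weights = w0), class = "weighting"),
                             spec), 0)
})

test_that("smoothing averages all covering windows with edge handling", {
  # 7 windows of size 100, step 25
  windows <- make_windows(250L)
  expect_equal(nrow(windows), 7L)
  raw <- c(0, 0, 1, 1, 1, 0, 0)
  sm <- smooth_track(raw, windows)
  # first region covered by window 1 only
  expect_equal(sm$smoothed[1], raw[1])
  expect_equal(sm$n_covering[1], 1L)
  # interior region starting at SNP 75 is covered by windows 1-4;
  # region starting at SNP 100 by windows 2-5 -> mean 0.75
  expect_equal(sm$smoothed[sm$snp_start == 100], 0.75)
  expect_equal(sm$n_covering[sm$snp_start == 100], 4L)
  # constant raw -> constant smoothed
  smc <- smooth_track(rep(0.3, 7), windows)
  expect_true(all(smc$smoothed == 0.3))
  # bounds: min(raw) <= smoothed <= max(raw)
  set.seed(3)
  rr <- stats::runif(7)
  smr <- smooth_track(rr, windows)
  expect_true(all(smr$smoothed >= min(rr) & smr$smoothed <= max(rr)))
  # NA windows are excluded from the mean
  raw_na <- raw
  raw_na[2] <- NA
  sm_na <- smooth_track(raw_na, windows)
  expect_equal(sm_na$smoothed[sm_na$snp_start == 100], mean(c(1, 1, 1)))
})

test_that("peak calling reports maximal runs as genomic intervals", {
  pos <- seq(10L, by = 10L, length.out = 250L)
  windows <- make_windows(250L)
  zero <- weighting_track(rep(0, 7), windows, pos, "scf")
  expect_equal(nrow(call_peaks(zero, 1.0)), 0L)

  tr <- weighting_track(c(0, 0, 1, 1, 1, 1, 0), windows, pos, "scf")
  # smoothed == 1 only where every covering window is 1: an interior
  # region needs 4 consecutive full windows; hand-check places that at
  # the region spanning SNP indices 125-150 (windows 3-6)
  pk <- call_peaks(tr, 1.0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$height, 1)
  expect_equal(pk$start, pos[126])
  expect_equal(pk$end, pos[150])

  # two runs above 0.9 separated by a sub-threshold gap
  raw2 <- c(1, 1, 0, 0, 1, 1, 1)
  t2 <- weighting_track(raw2, windows, pos, "scf")
  pk2 <- call_peaks(t2, 0.9)
  sm <- t2$smoothed
  runs <- rle(!is.na(sm) & sm >= 0.9)
  expect_equal(nrow(pk2), sum(runs$values))
  expect_equal(nrow(pk2), 2L)
  # raising the threshold never increases peak-covered length
  len <- function(p) if (nrow(p) == 0L) 0 else sum(p$end - p$start + 1)
  expect_lte(len(call_peaks(t2, 0.95)), len(call_peaks(t2, 0.9)))
  expect_lte(len(call_peaks(t2, 1.0)), len(call_peaks(t2, 0.95)))
  # min_regions suppresses single-region peaks
  expect_equal(nrow(call_peaks(t2, 0.9, min_regions = 100L)), 0L)
})

test_that("scan pipeline produces a full-weight plateau for a migrant segment", {
  # 250 sites x 12 samples with hierarchical structure matching the
  # species tree ((a,(b,c)),((d,e),f)); in sites 101-250 the f samples
  # carry the a haplotype (an implanted shared-ancestry tract)
  n <- 250
  base <- matrix("0/0", n, 12)
  colnames(base) <- paste0(rep(letters[1:6], each = 2), 1:2)
  patterns <- list("a", "b", "c", "d", "e", "f",
                   c("b", "c"), c("d", "e"),
                   c("a", "b", "c"), c("d", "e", "f"))
  for (i in seq_len(n)) {
    gs <- patterns[[(i - 1L) %% 10L + 1L]]
    cols <- which(rep(letters[1:6], each = 2) %in% gs)
    base[i, cols] <- "1/1"
  }
  tract <- 101:250
  base[tract, 11:12] <- base[tract, 1:2]
  taxon <- stats::setNames(rep(letters[1:6], each = 2), colnames(base))
  gm <- toy_gm(base, taxon = taxon, pos = seq_len(n) * 10L)
  groups <- split(gm$samples, gm$taxon)
  spec <- comparison_spec("mig", groups, topology("((b,c),(d,e));"),
                          focal_pair = c("a", "f"))
  res <- scan_shared_ancestry(gm, spec, seed = 1L, threshold = 1.0)
  expect_equal(nrow(res$windows), 7L)
  raw <- res$windows$raw
  # windows 5-7 (SNPs 101-200, 126-225, 151-250) lie inside the tract
  expect_equal(raw[5:7], rep(1, 3))
  # window 1 (SNPs 1-100) is fully outside and species-concordant
  expect_equal(raw[1], 0)
  pk <- res$peaks
  expect_gte(nrow(pk), 1L)
  # the plateau reaches the last SNP and stays inside/near the tract
  expect_equal(max(pk$end), 2500)
  expect_true(all(pk$end >= 1010))
  expect_true(all(pk$height == 1))
})
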