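test_that("dosage calls follow the nearest-class rule with depth guards", {
  ref <- rbind(c(10, 5, 3, 4, 0, 1, 6))
  alt <- rbind(c(0, 5, 1, 1, 9, 7, 2))
  cnt <- make_counts(ref, alt)
  d <- call_dosages(cnt, min_depth = 5, min_het_alt = 2)
  expect_equal(unname(d[1, 1]), 1.0)    # pure reference -> AAAA
  expect_equal(unname(d[1, 2]), 0.5)    # 5/5 -> AABB
  expect_true(is.na(d[1, 3]))           # depth 4 < 5 -> missing
  expect_equal(unname(d[1, 4]), 1.0)    # 1 alt read cannot support AAAB
  expect_equal(unname(d[1, 5]), 0)      # all alternate -> BBBB
  expect_equal(unname(d[1, 6]), 0.25)   # ref fraction 1/8 = 0.125 -> ABBB bin
  expect_equal(unname(d[1, 7]), 0.75)   # ref fraction 6/8 -> AAAB
})

test_that("class bin edges sit at 0.125/0.375/0.625/0.875 of the ref fraction", {
  # depth 1000 lets us place the fraction just either side of each edge
  fr <- c(0.124, 0.126, 0.374, 0.376, 0.624, 0.626, 0.874, 0.876)
  ref <- rbind(round(fr * 1000))
  alt <- rbind(1000 - ref[1, ])
  d <- call_dosages(make_counts(ref, alt), min_depth = 5, min_het_alt = 2)
  expect_equal(unname(d[1, ]), c(0, 0.25, 0.25, 0.5, 0.5, 0.75, 0.75, 1))
})

test_that("dosage calling recovers simulated truth at high depth", {
  tr <- simulate_cohort(n_samples = 40, n_loci = 150, seed = 13)
  cnt <- simulate_reads(tr, mean_depth = 150, error_rate = 0, seed = 14)
  d <- call_dosages(cnt)
  ok <- !is.na(d)
  expect_gte(mean(d[ok] == tr$dosage[ok]), 0.99)
  expect_gt(mean(ok), 0.999)
})

test_that("variant filters implement the alternate-support, missingness and MAF rules", {
  # locus 1: all reference (MAF 0)         -> maf_fail
  # locus 2: 5 of 10 samples missing       -> missing_fail
  # locus 3: only alt carrier has 4 reads  -> alt_support_fail
  # locus 4: codes 1/.75/.5 complete       -> retained (MAF 0.25)
  n <- 10
  d <- matrix(1, n, 4)
  d[, 2] <- c(rep(NA, 5), 1, 1, 0.5, 0.5, 0.5)
  d[, 3] <- c(0.5, rep(1, n - 1))
  d[, 4] <- rep(c(1, 0.75, 0.5), length.out = n)
  ref <- matrix(10L, n, 4); alt <- matrix(0L, n, 4)
  # locus 1 passes alternate support in the reads so MAF is the first failure
  alt[1, 1] <- 5L; ref[1, 1] <- 5L
  alt[, 2] <- c(rep(0, 5), 0, 0, 6, 6, 6); ref[, 2] <- 10 - alt[, 2]
  alt[1, 3] <- 4L; ref[1, 3] <- 4L
  alt[, 4] <- round(10 * (1 - d[, 4])); ref[, 4] <- 10L - alt[, 4]
  cnt <- make_counts(ref, alt)
  dm <- make_dosages(d)
  out <- filter_variants(dm, cnt)
  pl <- out$report$per_locus
  expect_equal(pl$retained, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(pl$maf_fail[1])
  expect_true(pl$missing_fail[2])
  expect_true(pl$alt_support_fail[3])
  expect_equal(colnames(out$dosages), colnames(dm)[4])
  # MAF of the retained locus clears the 5% threshold
  expect_equal(min(mean(d[, 4]), 1 - mean(d[, 4])), 0.225)
  # and the hand-worked three-sample case: codes 1, 0.75, 0.5
  p_bar <- mean(c(1, 0.75, 0.5))
  expect_equal(min(p_bar, 1 - p_bar), 0.25)
})

test_that("exactly 50% missing is removed and alt fraction below 0.4 fails", {
  n <- 10
  d <- matrix(rep(c(1, 0.5), each = n / 2), n, 2)
  ref <- matrix(5L, n, 2); alt <- matrix(5L, n, 2)
  # locus 1 misses exactly half
  d[1:5, 1] <- NA
  # locus 2: alt reads plentiful but fraction 0.3 < 0.4 everywhere
  alt[, 2] <- 6L; ref[, 2] <- 14L
  out <- filter_variants(make_dosages(d), make_counts(ref, alt))
  expect_true(out$report$per_locus$missing_fail[1])
  expect_true(out$report$per_locus$fraction_fail[2])
})

test_that("tightening any filter threshold never increases survivors", {
  for (s in 1:5) {
    tr <- simulate_cohort(n_samples = 30, n_loci = 80, seed = 600 + s)
    cnt <- simulate_reads(tr, mean_depth = 8, error_rate = 0.01, seed = s)
    d <- apply_missingness(call_dosages(cnt), 0.25, seed = s)
    base <- sum(filter_variants(d, cnt)$report$per_locus$retained)
    tighter <- c(
      sum(filter_variants(d, cnt, min_alt_reads_any = 8)$report$per_locus$retained),
      sum(filter_variants(d, cnt, min_alt_fraction_any = 0.6)$report$per_locus$retained),
      sum(filter_variants(d, cnt, max_missing = 0.3)$report$per_locus$retained),
      sum(filter_variants(d, cnt, min_maf = 0.2)$report$per_locus$retained))
    expect_true(all(tighter <= base))
  }
})

test_that("filter report attributes each dropped locus to exactly one reason", {
  for (s in 1:5) {
    tr <- simulate_cohort(n_samples = 25, n_loci = 60, seed = 700 + s)
    cnt <- simulate_reads(tr, mean_depth = 6, error_rate = 0.01, seed = s)
    d <- apply_missingness(call_dosages(cnt), 0.3, seed = s)
    rep <- filter_variants(d, cnt)$report
    pl <- rep$per_locus
    reasons <- as.matrix(pl[, c("depth_fail", "alt_support_fail",
                                "fraction_fail", "missing_fail", "maf_fail")])
    expect_true(all(rowSums(reasons) + pl$retained == 1))
    expect_equal(sum(pl$retained), nrow(pl) - sum(reasons))
    expect_equal(unname(rep$counts["after_maf"]), sum(pl$retained))
  }
})

test_that("density bins tile chromosomes half-open from position 1", {
  lay <- tiny_layout(len = c(300000, 130000))
  # positions 1 and 100000 share bin 1 (half-open [1, 100001))
  loci <- data.frame(chrom = "1", pos = c(1L, 100000L, 100001L))
  b <- density_bins(loci, lay, bin_bp = 1e5)
  expect_equal(b$n_snps[b$chrom == "1"], c(2, 1, 0))
  expect_equal(b$n_snps[b$chrom == "2"], c(0, 0))
  # conservation under arbitrary input
  tr <- simulate_cohort(n_samples = 5, n_loci = 200, seed = 1)
  bb <- density_bins(tr$loci, tr$layout, bin_bp = 1e5)
  agg <- tapply(bb$n_snps, bb$chrom, sum)
  obs <- table(tr$loci$chrom)
  expect_equal(as.vector(agg[names(obs)]), as.vector(obs, mode = "integer"))
  expect_equal(sum(bb$n_snps), nrow(tr$loci))
  # zero loci and out-of-bounds locus
  empty <- density_bins(loci[0, ], lay, bin_bp = 1e5)
  expect_true(all(empty$n_snps == 0))
  expect_error(density_bins(data.frame(chrom = "2", pos = 200000L), lay, 1e5),
               "2:200000")
})
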