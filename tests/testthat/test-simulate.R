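test_that("all four simulation stages are seed-deterministic", {
  t1 <- simulate_cohort(n_samples = 10, n_loci = 50, seed = 7)
  t2 <- simulate_cohort(n_samples = 10, n_loci = 50, seed = 7)
  expect_identical(t1, t2)
  r1 <- simulate_reads(t1, mean_depth = 10, seed = 3)
  r2 <- simulate_reads(t1, mean_depth = 10, seed = 3)
  expect_identical(r1, r2)
  p1 <- simulate_phenotypes(t1, "dense", seed = 5)
  p2 <- simulate_phenotypes(t1, "dense", seed = 5)
  expect_identical(p1, p2)
  m1 <- apply_missingness(t1$dosage, 0.3, seed = 9)
  m2 <- apply_missingness(t1$dosage, 0.3, seed = 9)
  expect_identical(m1, m2)
  # a different seed changes the draw
  expect_false(identical(t1$dosage,
                         simulate_cohort(n_samples = 10, n_loci = 50,
                                         seed = 8)$dosage))
})

test_that("simulated dosages are legal codes placed inside gene intervals", {
  tr <- simulate_cohort(n_samples = 25, n_loci = 120, seed = 2)
  expect_true(all(tr$dosage %in% c(0, 0.25, 0.5, 0.75, 1)))
  gi <- tr$layout$gene_intervals
  inside <- vapply(seq_len(nrow(tr$loci)), function(i) {
    any(gi$chrom == tr$loci$chrom[i] &
          gi$start <= tr$loci$pos[i] & gi$end >= tr$loci$pos[i])
  }, logical(1))
  expect_true(all(inside))
  expect_equal(length(tr$true_effects), ncol(tr$dosage))
})

test_that("cohort generation rejects degenerate arguments", {
  expect_error(simulate_cohort(n_samples = 1, n_loci = 10), "n_samples")
  expect_error(simulate_cohort(n_samples = 10, n_loci = 1), "n_loci")
  expect_error(simulate_cohort(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_cohort(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("fixed maf_range yields allele frequencies within binomial noise", {
  tr <- simulate_cohort(n_samples = 10, n_loci = 50,
                        maf_range = c(0.5, 0.5), seed = 7)
  alt_freq <- 1 - colMeans(tr$dosage)
  # 40 allele draws per locus; 3.9 SD two-sided bound leaves ~0.5% of loci
  se <- sqrt(0.25 / 40)
  expect_gt(mean(abs(alt_freq - 0.5) <= 3.9 * se), 0.95)
})

test_that("loci sharing a founder block are in much higher LD than loci apart", {
  deltas <- vapply(1:20, function(s) {
    tr <- high_ld_cohort(80, 60, seed = s)
    C <- suppressWarnings(stats::cor(tr$dosage))^2
    same <- outer(tr$loci$chrom, tr$loci$chrom, "==")
    diag(C) <- NA
    mean(C[same], na.rm = TRUE) - mean(C[!same], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(deltas), 0.5)
  expect_true(all(deltas > 0))
})

test_that("read counts conserve depth and follow the dosage-coded alt fraction", {
  tr <- simulate_cohort(n_samples = 15, n_loci = 60, seed = 11)
  cnt <- simulate_reads(tr, mean_depth = 8, error_rate = 0.02, seed = 1)
  expect_true(all(cnt$ref >= 0 & cnt$alt >= 0))
  # depth conservation is structural: ref is depth - alt by construction;
  # check the Poisson mean instead
  expect_equal(mean(cnt$ref + cnt$alt), 8, tolerance = 0.05)

  # AAAA with no error never shows alternate reads
  pure <- tr
  pure$dosage[] <- 1
  cp <- simulate_reads(pure, mean_depth = 20, error_rate = 0, seed = 2)
  expect_true(all(cp$alt == 0))

  # AABB at huge depth: alt fraction converges to 0.5
  half <- tr
  half$dosage[] <- 0.5
  ch <- simulate_reads(half, mean_depth = 10000, error_rate = 0, seed = 3)
  frac <- ch$alt / (ch$ref + ch$alt)
  expect_true(all(abs(frac - 0.5) < 4 / sqrt(10000)))

  # pooled error rate on homozygous-reference truth
  ce <- simulate_reads(pure, mean_depth = 25, error_rate = 0.01, seed = 4)
  n_reads <- sum(ce$ref + ce$alt)
  pooled <- sum(ce$alt) / n_reads
  expect_lt(abs(pooled - 0.01), 3 * sqrt(0.01 * 0.99 / n_reads))

  expect_error(simulate_reads(tr, mean_depth = 10, error_rate = 0.5), "error_rate")
  expect_error(simulate_reads(tr, mean_depth = 0), "mean_depth")
})

test_that("phenotypes realize the target heritability", {
  # exact case: h2 = 1 means zero residuals
  tr <- simulate_cohort(n_samples = 40, n_loci = 80, seed = 5)
  ph <- simulate_phenotypes(tr, "dense", h2 = 1, seed = 1)
  expect_equal(stats::cor(ph$pheno$trait, ph$genetic_values), 1)
  expect_equal(stats::var(ph$pheno$trait - 50 - ph$genetic_values), 0)

  # sampling case: realized h2 near target across seeds
  h2r <- vapply(1:10, function(s) {
    tr <- simulate_cohort(n_samples = 500, n_loci = 200, h2_target = 0.8,
                          seed = 5000 + s)
    ph <- simulate_phenotypes(tr, "dense", seed = s)
    stats::var(ph$genetic_values) / stats::var(ph$pheno$trait)
  }, numeric(1))
  expect_true(all(h2r > 0.72 & h2r < 0.88))
  expect_lt(abs(mean(h2r) - 0.8), 0.05)

  # sparse architecture zeroes all but n_qtl effects
  sp <- simulate_phenotypes(tr, "sparse", n_qtl = 3, seed = 2)
  expect_equal(sum(sp$effects != 0), 3)
  expect_equal(unname(which(sp$effects != 0)), sp$qtl)

  # degenerate: all effects zero
  dead <- tr
  dead$true_effects[] <- 0
  expect_error(simulate_phenotypes(dead, "dense", seed = 1), "variance")
  expect_error(simulate_phenotypes(tr, "dense", h2 = 0), "h2")
  expect_error(simulate_phenotypes(tr, "dense", h2 = 1.2), "h2")
})

test_that("missingness masking is MCAR at the requested rate", {
  tr <- simulate_cohort(n_samples = 100, n_loci = 100, seed = 3)
  expect_identical(apply_missingness(tr$dosage, 0, seed = 1), tr$dosage)
  m <- apply_missingness(tr$dosage, 0.2, seed = 1)
  expect_true(sum(is.na(m)) >= 1600 && sum(is.na(m)) <= 2400)
  # values that survive are unchanged
  keep <- !is.na(m)
  expect_identical(m[keep], tr$dosage[keep])
  # extreme but legal rate still succeeds; rate 1 does not
  small <- tr$dosage[1:10, 1:10]
  attr(small, "loci") <- tr$loci[1:10, ]
  expect_silent(apply_missingness(small, 0.99, seed = 2))
  expect_error(apply_missingness(small, 1, seed = 2), "rate")
})
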