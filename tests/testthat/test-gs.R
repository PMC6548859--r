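# Shared small regression problem for sampler tests.
make_problem <- function(n, m, seed, h2 = 0.8) {
  set.seed(seed)
  Z <- matrix(sample(c(0, 0.25, 0.5, 0.75, 1), n * m, replace = TRUE), n, m)
  colnames(Z) <- sprintf("m%03d", seq_len(m))
  v <- rnorm(m)
  g <- drop(Z %*% v)
  e <- rnorm(n, 0, sqrt(var(g) * (1 - h2) / h2))
  list(Z = Z, y = g + e + 10, v = v, g = g)
}

test_that("configuration validates its invariants", {
  expect_error(gs_config(burn_in = 500, n_iter = 500), "burn_in")
  expect_error(gs_config(prob_in = 0), "prob_in")
  expect_error(gs_config(h2_prior = 0), "h2_prior")
  expect_error(gs_config(h2_prior = 1.1), "h2_prior")
  cfg <- gs_config("BayesB", prob_in = 0.01)
  expect_equal(cfg$model, "BayesB")
})

test_that("the chain is seed-deterministic and rejects bad inputs", {
  p <- make_problem(25, 10, seed = 1)
  cfg <- gs_config(n_iter = 500, burn_in = 100, seed = 42)
  f1 <- gs_fit(p$Z, p$y, cfg)
  f2 <- gs_fit(p$Z, p$y, cfg)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$mu, f2$mu)
  expect_error(gs_fit(p$Z, rep(1, 25), cfg), "constant")
  expect_error(gs_fit(p$Z, p$y[-1], cfg), "length")
  Zna <- p$Z; Zna[1, 1] <- NA
  expect_error(gs_fit(Zna, p$y, cfg), "missing")
})

test_that("monomorphic markers get zero effect and the intercept tracks the mean", {
  set.seed(3)
  Z <- matrix(0, 30, 5)
  colnames(Z) <- sprintf("m%d", 1:5)
  y <- rnorm(30, 20)
  cfg <- gs_config(n_iter = 2000, burn_in = 500, seed = 1)
  expect_warning(fit <- gs_fit(Z, y, cfg), "monomorphic")
  expect_equal(fit$effects, rep(0, 5))
  expect_equal(fit$mu, mean(y), tolerance = 0.05)
  # predictions are then the constant mu
  expect_equal(unname(gs_predict(fit, Z)), rep(fit$mu, 30))
})

test_that("with pinned variances the posterior mean matches the ridge solution", {
  set.seed(42)
  Z <- matrix(runif(200), 20, 10)
  colnames(Z) <- sprintf("m%02d", 1:10)
  y <- rnorm(20, Z %*% rnorm(10))
  s2v <- 0.5; s2e <- 1
  cfg <- gs_config("BayesA", n_iter = 6000, burn_in = 1000, seed = 5,
                   var_marker_fixed = s2v, var_e_fixed = s2e)
  fit <- gs_fit(Z, y, cfg)
  Zc <- scale(Z, scale = FALSE)
  ridge <- drop(solve(crossprod(Zc) + diag(s2e / s2v, 10),
                      crossprod(Zc, y - mean(y))))
  expect_true(all(abs(fit$effects - ridge) < 3 * pmax(fit$effects_sd, 1e-9)))
  # and should in fact be much closer than the 3-SD bound
  expect_lt(max(abs(fit$effects - ridge)), 0.5 * max(fit$effects_sd))
})

test_that("BayesB with inclusion probability 1 reproduces the BayesA chain", {
  p <- make_problem(30, 20, seed = 7)
  fa <- gs_fit(p$Z, p$y, gs_config("BayesA", n_iter = 1500, burn_in = 300,
                                   seed = 9))
  fb <- gs_fit(p$Z, p$y, gs_config("BayesB", prob_in = 1, n_iter = 1500,
                                   burn_in = 300, seed = 9))
  expect_equal(fa$effects, fb$effects, tolerance = 1e-12)
  expect_equal(fa$mu, fb$mu, tolerance = 1e-12)
})

test_that("sampled variances stay positive along the whole chain", {
  p <- make_problem(25, 15, seed = 11)
  for (model in c("BayesA", "BayesB")) {
    fit <- gs_fit(p$Z, p$y, gs_config(model, prob_in = 0.2, n_iter = 800,
                                      burn_in = 100, seed = 2))
    expect_true(all(fit$trace[, "var_e"] > 0))
    expect_true(all(fit$trace[, "var_g"] >= 0))
    expect_true(all(fit$inclusion_prob >= 0 & fit$inclusion_prob <= 1))
    expect_equal(fit$effects_sq, fit$effects^2)
  }
})

test_that("rescaling the phenotype rescales intercept and effects", {
  p <- make_problem(30, 12, seed = 13)
  cfg <- gs_config(n_iter = 1500, burn_in = 300, seed = 4)
  f1 <- gs_fit(p$Z, p$y, cfg)
  f2 <- gs_fit(p$Z, 10 * p$y, cfg)
  # the chain is exactly scale-equivariant draw by draw under a shared seed
  expect_equal(f2$effects, 10 * f1$effects, tolerance = 1e-8)
  expect_equal(f2$mu, 10 * f1$mu, tolerance = 1e-8)
})

test_that("prediction aligns markers, maps rows, and recovers noiseless traits", {
  p <- make_problem(300, 100, seed = 17, h2 = 1 - 1e-12)
  tr <- simulate_cohort(n_samples = 300, n_loci = 100, seed = 17)
  ph <- simulate_phenotypes(tr, "dense", h2 = 1, seed = 1)
  cfg <- gs_config(h2_prior = 0.99, n_iter = 2500, burn_in = 500, seed = 3)
  fit <- suppressWarnings(gs_fit(tr$dosage, ph$pheno$trait, cfg))
  gebv <- gs_predict(fit, tr$dosage)
  expect_gt(stats::cor(gebv, ph$pheno$trait), 0.99)
  # duplicating a sample row duplicates its GEBV
  Zdup <- tr$dosage[c(1, 1, 2), ]
  gd <- gs_predict(fit, Zdup)
  expect_equal(gd[1], gd[2])
  # marker mismatch errors and names the missing loci
  expect_error(gs_predict(fit, tr$dosage[, -1]), colnames(tr$dosage)[1],
               fixed = TRUE)
  # column order must not matter when names are present
  perm <- sample(ncol(tr$dosage))
  expect_equal(gs_predict(fit, tr$dosage[, perm]), gebv)
})

test_that("the marker-effect table is coordinate-sorted with squared effects", {
  tr <- simulate_cohort(n_samples = 30, n_loci = 40, seed = 19)
  ph <- simulate_phenotypes(tr, "dense", seed = 2)
  fit <- suppressWarnings(
    gs_fit(tr$dosage, ph$pheno$trait,
           gs_config(n_iter = 500, burn_in = 100, seed = 5)))
  tab <- manhattan_table(fit)
  expect_equal(nrow(tab), 40)
  expect_equal(tab$effect_sq, tab$effect^2)
  o <- order(match(tab$chrom, unique(tab$chrom)), tab$pos)
  expect_equal(o, seq_len(nrow(tab)))
  # a hand value: squaring is elementwise
  expect_equal(manhattan_table(fit)$effect_sq[7], fit$effects[
    order(match(fit$loci$chrom, unique(fit$loci$chrom)), fit$loci$pos)][7]^2)
})

test_that("a single simulated QTL tops the squared-effect scan in its LD block", {
  hits <- vapply(1:10, function(s) {
    tr <- high_ld_cohort(150, 80, seed = 900 + s)
    ph <- simulate_phenotypes(tr, "sparse", n_qtl = 1, h2 = 0.8, seed = s)
    fit <- suppressWarnings(
      gs_fit(tr$dosage, ph$pheno$trait,
             gs_config("BayesA", h2_prior = 0.8, n_iter = 1500,
                       burn_in = 300, seed = s)))
    top <- which.max(fit$effects_sq)
    r2 <- suppressWarnings(
      stats::cor(tr$dosage[, ph$qtl], tr$dosage[, top]))^2
    isTRUE(top == ph$qtl || r2 > 0.8)
  }, logical(1))
  expect_gte(sum(hits), 8)
})
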