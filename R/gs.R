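#' Configuration for Bayesian whole-genome regression
#'
#' Bundles the sampler settings for [gs_fit()]. `prob_in` is the prior
#' probability that a marker has a NON-zero effect (BayesB only; BayesA
#' ignores it). The marker-variance prior is scaled from a trait
#' heritability: the marker prior scale is
#' S0 = h2_prior * var(y) * (df_marker + 2) / MSx (prior mode
#' h2_prior * var(y) / MSx) with MSx the summed column variances of Z,
#' divided additionally by `prob_in` for BayesB so the expected genetic
#' variance is preserved under sparsity. The residual prior scale is
#' (1 - h2_prior) * var(y) * (df_residual + 2).
#'
#' @param model `"BayesA"` or `"BayesB"`.
#' @param prob_in prior inclusion probability (default 0.1; typical grid
#'   0.1, 0.05, 0.01, 0.005).
#' @param n_iter total Gibbs iterations (default 12000).
#' @param burn_in iterations discarded (default 1000).
#' @param df_marker,df_residual prior degrees of freedom (default 5 each).
#' @param h2_prior trait heritability used to scale the priors.
#' @param seed RNG seed for the chain.
#' @param var_marker_fixed,var_e_fixed optional test hooks: pin the common
#'   marker variance and/or the residual variance to a fixed value instead of
#'   sampling them (used to check the sampler against the closed-form ridge
#'   solution). `NULL` (default) samples both.
#' @return A `gs_config` list.
#' @export
gs_config <- function(model = c("BayesA", "BayesB"), prob_in = 0.1,
                      n_iter = 12000, burn_in = 1000, df_marker = 5,
                      df_residual = 5, h2_prior = 0.5, seed = 1,
                      var_marker_fixed = NULL, var_e_fixed = NULL) {
  model <- match.arg(model)
  n_iter <- check_count(n_iter, "n_iter", min = 2)
  burn_in <- check_count(burn_in, "burn_in", min = 0)
  if (burn_in >= n_iter) stop_invalid("`burn_in` must be smaller than `n_iter`")
  check_fraction(prob_in, "prob_in", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(h2_prior, "h2_prior", lo = 0, hi = 1, lo_open = TRUE)
  if (!(df_marker > 0) || !(df_residual > 0)) {
    stop_invalid("degrees of freedom must be positive")
  }
  structure(list(model = model, prob_in = prob_in, n_iter = n_iter,
                 burn_in = burn_in, df_marker = df_marker,
                 df_residual = df_residual, h2_prior = h2_prior,
                 seed = as.integer(seed),
                 var_marker_fixed = var_marker_fixed,
                 var_e_fixed = var_e_fixed),
            class = "gs_config")
}

#' Fit BayesA/BayesB whole-genome regression by Gibbs sampling
#'
#' Fits y = mu + Z v + e with marker effects v under the BayesA prior
#' (per-marker variances, scaled-inverse-chi-squared) or the BayesB
#' spike-and-slab prior (each marker in the model with prior probability
#' `prob_in`). Columns of Z are centred before sampling (better mixing); the
#' reported intercept is mapped back to the original scale so that
#' `mu + Z %*% effects` predicts on raw dosage codes. Posterior summaries are
#' means over the post-burn-in iterations, with no thinning.
#'
#' @param Z samples x markers matrix of reference-allele-frequency codes,
#'   complete (impute first).
#' @param y numeric phenotype vector, length `nrow(Z)`.
#' @param config a [gs_config()].
#' @return A `gs_fit` list: `mu`, `effects`, `effects_sd` (posterior SDs),
#'   `effects_sq` (squared posterior-mean effects), `inclusion_prob`,
#'   `var_e`, `var_g` (posterior means), `trace` (per-iteration mu,
#'   sigma2_e, realised var(Zv)), `config`, `loci` (locus table if Z carried
#'   one), `marker_ids`.
#' @export
gs_fit <- function(Z, y, config = gs_config()) {
  stopifnot(is.matrix(Z), inherits(config, "gs_config"))
  if (anyNA(Z)) stop_invalid("Z contains missing values; impute first")
  if (length(y) != nrow(Z)) stop_invalid("length(y) must equal nrow(Z)")
  if (anyNA(y)) stop_invalid("y contains missing values")
  if (nrow(Z) < 2) stop_invalid("need at least 2 samples")
  vy <- stats::var(y)
  if (vy == 0) stop_invalid("constant phenotype: nothing to fit")

  col_var <- apply(Z, 2, stats::var)
  if (any(col_var == 0)) {
    warning(sprintf("%d monomorphic marker column(s); effects fixed at 0",
                    sum(col_var == 0)))
  }
  msx <- sum(col_var)
  if (msx == 0) msx <- 1  # all-constant Z: prior scale is irrelevant
  # total prior scales of the scaled-inverse-chi-squared priors: the marker
  # prior mode is h2_prior * var(y) / MSx (per-marker share of the genetic
  # variance), inflated by 1/prob_in for BayesB so sparsity preserves the
  # expected genetic variance
  S0 <- config$h2_prior * vy * (config$df_marker + 2) / msx
  if (config$model == "BayesB") S0 <- S0 / config$prob_in
  Se0 <- (1 - config$h2_prior) * vy * (config$df_residual + 2)
  if (Se0 <= 0) Se0 <- 1e-8 * vy  # h2_prior = 1: vague residual scale

  cmeans <- colMeans(Z)
  Zc <- sweep(Z, 2, cmeans)
  res <- with_seed(config$seed, {
    gibbs_wgr(Zc, as.numeric(y), config$n_iter, config$burn_in,
              config$model == "BayesB", config$prob_in,
              config$df_marker, config$df_residual, S0, Se0,
              if (is.null(config$var_marker_fixed)) -1 else config$var_marker_fixed,
              if (is.null(config$var_e_fixed)) -1 else config$var_e_fixed)
  })
  effects <- as.numeric(res$effects)
  mu <- res$mu - sum(cmeans * effects)  # intercept on the raw-Z scale
  trace <- res$trace
  colnames(trace) <- c("mu", "var_e", "var_g")
  structure(list(mu = mu, effects = effects,
                 effects_sd = as.numeric(res$effects_sd),
                 effects_sq = effects^2,
                 inclusion_prob = as.numeric(res$inclusion_prob),
                 var_e = res$var_e, var_g = res$var_g,
                 trace = trace, config = config,
                 loci = attr(Z, "loci", exact = TRUE),
                 marker_ids = colnames(Z)),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit (%s): %d markers, mu = %.3f, var_g = %.3f, var_e = %.3f\n",
              x$config$model, length(x$effects), x$mu, x$var_g, x$var_e))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' GEBV = mu + Z_new effects. Markers are aligned by column name when both
#' the fit and `Z_new` carry them; a marker present in the fit but absent
#' from `Z_new` is an error.
#'
#' @param fit a [gs_fit()] result.
#' @param Z_new samples x markers matrix on the same dosage coding.
#' @return named numeric vector of GEBVs.
#' @export
gs_predict <- function(fit, Z_new) {
  stopifnot(inherits(fit, "gs_fit"), is.matrix(Z_new))
  if (!is.null(fit$marker_ids) && !is.null(colnames(Z_new))) {
    missing <- setdiff(fit$marker_ids, colnames(Z_new))
    if (length(missing)) {
      stop_invalid(sprintf("markers absent from Z_new: %s%s",
                           paste(utils::head(missing, 5), collapse = ", "),
                           if (length(missing) > 5) ", ..." else ""))
    }
    Z_new <- Z_new[, fit$marker_ids, drop = FALSE]
  } else if (ncol(Z_new) != length(fit$effects)) {
    stop_invalid("Z_new has a different number of markers than the fit")
  }
  drop(fit$mu + Z_new %*% fit$effects)
}

#' Per-locus squared marker effects for Manhattan plotting
#'
#' Squaring the posterior-mean effects sharpens the contrast between markers
#' of small and large effect; the table is sorted by genomic coordinate.
#'
#' @param fit a [gs_fit()].
#' @param loci data.frame `chrom`, `pos` aligned with the fit's markers
#'   (default: the locus table carried by the training matrix).
#' @return data.frame `chrom`, `pos`, `effect`, `effect_sq`
#'   (+ `inclusion_prob` for BayesB), sorted by (chrom, pos).
#' @export
manhattan_table <- function(fit, loci = fit$loci) {
  stopifnot(inherits(fit, "gs_fit"))
  if (is.null(loci)) stop_invalid("no locus table available")
  if (nrow(loci) != length(fit$effects)) {
    stop_invalid("locus table does not align with the fitted markers")
  }
  out <- data.frame(chrom = loci$chrom, pos = loci$pos,
                    effect = fit$effects, effect_sq = fit$effects_sq,
                    stringsAsFactors = FALSE)
  if (fit$config$model == "BayesB") out$inclusion_prob <- fit$inclusion_prob
  out <- out[order(match(out$chrom, unique(loci$chrom)), out$pos), ]
  rownames(out) <- NULL
  out
}
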