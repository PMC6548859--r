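#' K-fold cross-validated genomic prediction accuracy
#'
#' Samples are split into `k` random folds of near-equal size (sizes differ
#' by at most 1). Each fold is predicted from a model trained on the
#' remaining folds; the fold's accuracy is the Pearson correlation between
#' its held-out GEBVs and observed phenotypes. The summary is the mean fold
#' accuracy with SE = sd(fold accuracies)/sqrt(k), plus the prediction-bias
#' slope computed on the pooled out-of-fold GEBVs.
#'
#' @param Z samples x markers dosage matrix, complete.
#' @param y phenotype vector.
#' @param config a [gs_config()]; each fold's chain uses a seed derived from
#'   `seed` so folds are independent but reproducible.
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition and the per-fold chains.
#' @return A `cv_result` list: `fold_assignments`, `fold_accuracies`,
#'   `mean_accuracy`, `se_accuracy`, `bias_slope`, `pooled_gebvs` (one
#'   held-out GEBV per sample), `k`, `config`.
#' @export
kfold_cv <- function(Z, y, config = gs_config(), k = 5, seed = 1) {
  stopifnot(is.matrix(Z))
  k <- check_count(k, "k", min = 2)
  n <- nrow(Z)
  if (n < k) stop_invalid("need at least k samples")
  if (length(y) != n) stop_invalid("length(y) must equal nrow(Z)")
  folds <- with_seed(seed, {
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    sample(rep(seq_len(k), times = sizes))
  })
  gebv <- rep(NA_real_, n)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (stats::var(y[test]) == 0) {
      stop_invalid(sprintf("fold %d has constant phenotype; accuracy undefined", f))
    }
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919 * f) %% .Machine$integer.max)
    fit <- gs_fit(Z[!test, , drop = FALSE], y[!test], cfg)
    gebv[test] <- gs_predict(fit, Z[test, , drop = FALSE])
    acc[f] <- stats::cor(gebv[test], y[test])
  }
  names(gebv) <- rownames(Z)
  structure(list(fold_assignments = stats::setNames(folds, rownames(Z)),
                 fold_accuracies = acc,
                 mean_accuracy = mean(acc),
                 se_accuracy = stats::sd(acc) / sqrt(k),
                 bias_slope = bias_slope(y, gebv),
                 pooled_gebvs = gebv, k = k, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s, %d-fold): accuracy %.3f (SE %.3f), bias %.2f\n",
              x$config$model, x$k, x$mean_accuracy, x$se_accuracy,
              x$bias_slope))
  invisible(x)
}

#' Prediction-bias slope
#'
#' Ordinary least-squares slope of observed phenotype on predicted GEBV,
#' pooled across folds. A slope of 1 means no bias; slopes above 1 indicate
#' underprediction (the spread of GEBVs is too small, typically from
#' shrinkage in small reference populations), below 1 overprediction.
#'
#' @param observed phenotype vector.
#' @param predicted GEBV vector of the same length (>= 3, non-constant).
#' @return the OLS slope.
#' @export
bias_slope <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop_invalid("observed and predicted must have equal length >= 3")
  }
  if (stats::var(predicted) == 0) {
    stop_invalid("constant predictions: bias slope undefined")
  }
  unname(stats::coef(stats::lm(observed ~ predicted))[2])
}

#' Maximum potential prediction accuracy from heritability
#'
#' The accuracy of predicting phenotype from true genetic merit is bounded by
#' sqrt(h2); this is the ceiling against which realised CV accuracies are
#' judged.
#'
#' @param h2 heritability (or vector of them) in \[0, 1\].
#' @param digits decimals for display rounding; `NULL` returns the exact
#'   value.
#' @return sqrt(h2), rounded to `digits` (default 2, the usual display form).
#' @export
max_potential_accuracy <- function(h2, digits = 2) {
  if (!is.numeric(h2) || any(!is.finite(h2)) || any(h2 < 0 | h2 > 1)) {
    stop_invalid("`h2` must lie in [0, 1]")
  }
  out <- sqrt(h2)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
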