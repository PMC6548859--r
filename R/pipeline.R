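#' Pipeline configuration
#'
#' Collects every stage's parameters with the pipeline defaults, validating
#' ranges up front so a bad setting fails before any stage runs. The object
#' round-trips through JSON (`write(read(c)) == c`).
#'
#' @param n_samples,n_loci synthetic cohort size (defaults 181 x 2000).
#' @param mean_depth,error_rate read simulation settings (defaults 15, 0.01).
#' @param missing_rate MCAR masking rate before imputation (default 0.2).
#' @param h2 trait heritability for simulation and for the GS prior scale.
#' @param architecture `"dense"` or `"sparse"` trait architecture.
#' @param n_qtl causal loci when sparse.
#' @param min_depth,min_het_alt dosage-calling thresholds (defaults 5, 2).
#' @param min_alt_reads_any,min_alt_fraction_any,max_missing,min_maf variant
#'   filters (defaults 5, 0.4, 0.5, 0.05).
#' @param k_neighbors,n_loci_ld imputation parameters (defaults 11, 17).
#' @param model,prob_in,n_iter,burn_in GS sampler settings.
#' @param k_folds cross-validation folds (default 5).
#' @param bin_bp SNP-density bin width (default 1e5).
#' @param seed master seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_samples = 181, n_loci = 2000, mean_depth = 15,
                            error_rate = 0.01, missing_rate = 0.2, h2 = 0.8,
                            architecture = "dense", n_qtl = 2,
                            min_depth = 5, min_het_alt = 2,
                            min_alt_reads_any = 5, min_alt_fraction_any = 0.4,
                            max_missing = 0.5, min_maf = 0.05,
                            k_neighbors = 11, n_loci_ld = 17,
                            model = "BayesA", prob_in = 0.1, n_iter = 12000,
                            burn_in = 1000, k_folds = 5, bin_bp = 1e5,
                            seed = 1) {
  cfg <- list(n_samples = n_samples, n_loci = n_loci, mean_depth = mean_depth,
              error_rate = error_rate, missing_rate = missing_rate, h2 = h2,
              architecture = architecture, n_qtl = n_qtl,
              min_depth = min_depth, min_het_alt = min_het_alt,
              min_alt_reads_any = min_alt_reads_any,
              min_alt_fraction_any = min_alt_fraction_any,
              max_missing = max_missing, min_maf = min_maf,
              k_neighbors = k_neighbors, n_loci_ld = n_loci_ld,
              model = model, prob_in = prob_in, n_iter = n_iter,
              burn_in = burn_in, k_folds = k_folds, bin_bp = bin_bp,
              seed = seed)
  # validation: reuse the constructors that own each parameter
  check_count(n_samples, "n_samples", min = 2)
  check_count(n_loci, "n_loci", min = 2)
  check_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  check_fraction(error_rate, "error_rate", hi = 0.5, hi_open = TRUE)
  gs_config(model = model, prob_in = prob_in, n_iter = n_iter,
            burn_in = burn_in, h2_prior = h2, seed = seed)
  check_count(k_folds, "k_folds", min = 2)
  if (!(bin_bp > 0)) stop_invalid("`bin_bp` must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> read simulation -> dosage calling -> variant filtering ->
#' LD-kNN imputation -> k-fold genomic selection CV -> marker-effect scan ->
#' Nei distance + neighbour-joining tree -> SNP density bins. Every declared
#' output is written under `out_dir` and is re-readable by the package's own
#' readers; `log.txt` echoes every parameter actually used. Re-running with
#' the same config yields byte-identical JSON results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the paths
#'   of the written files.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("spudgs_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed

  layout <- potato_layout(seed = seed)
  truth <- stage("simulate", simulate_cohort(
    n_samples = config$n_samples, n_loci = config$n_loci, layout = layout,
    h2_target = config$h2, seed = seed))
  counts <- stage("simulate_reads", simulate_reads(
    truth, mean_depth = config$mean_depth, error_rate = config$error_rate,
    seed = seed + 1))
  phen <- stage("simulate_phenotypes", simulate_phenotypes(
    truth, architecture = config$architecture, n_qtl = config$n_qtl,
    seed = seed + 2))

  called <- stage("call_dosages", call_dosages(
    counts, min_depth = config$min_depth, min_het_alt = config$min_het_alt))
  called <- apply_missingness(called, rate = config$missing_rate,
                              seed = seed + 3)
  filt <- stage("filter", filter_variants(
    called, counts, min_alt_reads_any = config$min_alt_reads_any,
    min_alt_fraction_any = config$min_alt_fraction_any,
    max_missing = config$max_missing, min_maf = config$min_maf))
  counts_kept <- filt$report$per_locus$retained
  imputed <- stage("impute", impute_ldknn(
    filt$dosages, k_neighbors = config$k_neighbors,
    n_loci_ld = config$n_loci_ld))

  y <- phen$pheno[[2]]
  gcfg <- gs_config(model = config$model, prob_in = config$prob_in,
                    n_iter = config$n_iter, burn_in = config$burn_in,
                    h2_prior = config$h2, seed = seed + 4)
  cv <- stage("gs_cv", kfold_cv(imputed, y, gcfg, k = config$k_folds,
                                seed = seed + 5))
  fit <- stage("gs_fit", gs_fit(imputed, y, gcfg))
  effects <- manhattan_table(fit)

  D <- stage("diversity", nei_distance(imputed))
  tree <- stage("nj", neighbor_joining(D))
  dens <- stage("density", density_bins(loci_info(imputed), layout,
                                        bin_bp = config$bin_bp))

  paths$vcf <- file.path(out_dir, "genotypes.vcf")
  write_vcf(paths$vcf, called, counts = counts, layout = layout,
            filter_report = filt$report)
  paths$pheno <- file.path(out_dir, "phenotypes.csv")
  write_phenotypes(phen, paths$pheno)
  paths$truth <- file.path(out_dir, "truth.json")
  write_truth_json(truth, paths$truth)
  paths$filter_report <- file.path(out_dir, "filter_report.tsv")
  utils::write.table(filt$report$per_locus, paths$filter_report,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  paths$cv <- file.path(out_dir, "cv_result.json")
  jsonlite::write_json(list(
    model = config$model, k = cv$k,
    fold_accuracies = cv$fold_accuracies,
    mean_accuracy = cv$mean_accuracy, se_accuracy = cv$se_accuracy,
    bias_slope = cv$bias_slope), paths$cv, auto_unbox = TRUE, digits = NA)
  paths$gebv <- file.path(out_dir, "gebv.csv")
  utils::write.csv(data.frame(sample_id = names(cv$pooled_gebvs),
                              gebv = unname(cv$pooled_gebvs),
                              fold = unname(cv$fold_assignments)),
                   paths$gebv, row.names = FALSE, quote = FALSE)
  paths$effects <- file.path(out_dir, "marker_effects.tsv")
  utils::write.table(effects, paths$effects, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths$dist <- file.path(out_dir, "nei_distance.tsv")
  utils::write.table(D, paths$dist, sep = "\t", quote = FALSE)
  paths$tree <- file.path(out_dir, "nj_tree.nwk")
  write_newick(tree, paths$tree)
  paths$density <- file.path(out_dir, "snp_density.tsv")
  utils::write.table(dens, paths$density, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths$config <- file.path(out_dir, "config.json")
  write_pipeline_config(config, paths$config)
  paths$log <- file.path(out_dir, "log.txt")
  writeLines(c(
    sprintf("spudgs %s | R %s", as.character(utils::packageVersion("spudgs")),
            paste(R.version$major, R.version$minor, sep = ".")),
    "parameters:",
    sprintf("  %s = %s", names(config),
            vapply(config, function(x) paste(format(x), collapse = ","),
                   character(1))),
    sprintf("loci surviving filters: %d / %d",
            sum(counts_kept), length(counts_kept)),
    sprintf("cv mean accuracy: %.4f (se %.4f), bias %.4f",
            cv$mean_accuracy, cv$se_accuracy, cv$bias_slope)
  ), paths$log)

  invisible(list(truth = truth, counts = counts, phenotypes = phen,
                 called = called, filtered = filt, imputed = imputed,
                 cv = cv, fit = fit, effects = effects, distance = D,
                 tree = tree, density = dens, paths = paths,
                 out_dir = out_dir))
}
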