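#' Simulate a tetraploid cultivar cohort with known dosage truth
#'
#' Generates an LD-structured biallelic dosage matrix for an autotetraploid
#' cohort. Loci are placed inside the layout's gene intervals. Within each LD
#' block (loci falling in the same `ld_block_bp` window of a chromosome) a
#' small pool of founder haplotypes is drawn, and every sample receives four
#' independent haplotype copies from that pool, so nearby loci are correlated
#' while loci in different blocks are independent. Dosage codes are
#' reference-allele frequencies in \{0, 0.25, 0.5, 0.75, 1\} (AABB = 0.5).
#'
#' Per-locus alternate-allele frequencies are drawn uniformly from
#' `maf_range` and realised in the founder pool by stochastic rounding, so the
#' population frequency matches the draw up to the pool's granularity plus
#' binomial sampling noise across the cohort's 4 * n_samples allele draws.
#'
#' @param n_samples number of cultivars (default 181).
#' @param n_loci number of biallelic loci (default 2000).
#' @param layout a [genome_layout()]; default [potato_layout()].
#' @param ld_block_bp LD block width in bp (default 1e6).
#' @param maf_range numeric `(low, high)` with `0 < low <= high <= 0.5`:
#'   range of per-locus alternate-allele frequencies.
#' @param n_founders founder haplotypes per block (default 4; 2 gives very
#'   strong LD).
#' @param h2_target narrow-sense heritability carried into phenotype
#'   simulation (default 0.8).
#' @param seed RNG seed.
#' @return A `sim_truth` list: `dosage` (n_samples x n_loci matrix of codes,
#'   no missingness, with a `loci` attribute), `loci` table, `true_effects`
#'   (per-locus additive effects, standard normal draws), `h2_target`,
#'   `layout`, `seed`.
#' @export
simulate_cohort <- function(n_samples = 181, n_loci = 2000,
                            layout = potato_layout(), ld_block_bp = 1e6,
                            maf_range = c(0.05, 0.5), n_founders = 4,
                            h2_target = 0.8, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  n_loci <- check_count(n_loci, "n_loci", min = 2)
  check_count(n_founders, "n_founders", min = 2)
  if (!inherits(layout, "genome_layout")) stop_invalid("`layout` must be a genome_layout")
  if (nrow(layout$gene_intervals) == 0L) stop_invalid("layout has no gene intervals")
  stopifnot(length(maf_range) == 2L)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5)) {
    stop_invalid("`maf_range` must satisfy 0 < low <= high <= 0.5")
  }
  if (!(ld_block_bp > 0)) stop_invalid("`ld_block_bp` must be positive")
  check_fraction(h2_target, "h2_target", lo = 0, hi = 1, lo_open = TRUE)

  with_seed(seed, {
    gi <- layout$gene_intervals
    widths <- gi$end - gi$start + 1
    # place loci uniformly over gene bases
    iv <- sample.int(nrow(gi), n_loci, replace = TRUE, prob = widths)
    pos <- gi$start[iv] + floor(stats::runif(n_loci) * widths[iv])
    loci <- data.frame(chrom = gi$chrom[iv], pos = as.integer(pos),
                       stringsAsFactors = FALSE)
    o <- order(match(loci$chrom, layout$chromosomes$name), loci$pos)
    loci <- loci[o, , drop = FALSE]
    # de-duplicate positions by nudging (keeps loci distinct within a gene)
    dup <- duplicated(paste(loci$chrom, loci$pos))
    while (any(dup)) {
      loci$pos[dup] <- loci$pos[dup] + 1L
      loci <- loci[order(match(loci$chrom, layout$chromosomes$name), loci$pos), ]
      dup <- duplicated(paste(loci$chrom, loci$pos))
    }
    rownames(loci) <- NULL
    loci$ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
    loci$alt <- vapply(loci$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))

    block <- paste0(loci$chrom, "_", (loci$pos - 1) %/% ld_block_bp)
    samples <- sprintf("cv%03d", seq_len(n_samples))

    alt_freq <- stats::runif(n_loci, maf_range[1], maf_range[2])
    dosage <- matrix(0, n_samples, n_loci,
                     dimnames = list(samples, locus_ids(loci)))
    for (b in unique(block)) {
      j <- which(block == b)
      # founder haplotypes: per locus, n_alt founders carry the alt allele,
      # n_alt = stochastic rounding of freq * n_founders
      target <- alt_freq[j] * n_founders
      n_alt <- floor(target) + (stats::runif(length(j)) < (target - floor(target)))
      H <- matrix(0L, n_founders, length(j))
      for (t in seq_along(j)) {
        if (n_alt[t] > 0) H[sample.int(n_founders, n_alt[t]), t] <- 1L
      }
      # each sample draws 4 haplotype copies from the pool
      draws <- matrix(sample.int(n_founders, 4L * n_samples, replace = TRUE),
                      n_samples, 4L)
      alt_count <- H[draws[, 1], , drop = FALSE] + H[draws[, 2], , drop = FALSE] +
        H[draws[, 3], , drop = FALSE] + H[draws[, 4], , drop = FALSE]
      dosage[, j] <- 1 - alt_count / 4  # code = reference-allele frequency
    }
    true_effects <- stats::rnorm(n_loci)

    structure(list(dosage = set_loci(dosage, loci), loci = loci,
                   true_effects = true_effects, h2_target = h2_target,
                   layout = layout, seed = as.integer(seed)),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d samples x %d loci, h2_target = %.2f, seed = %d\n",
              nrow(x$dosage), ncol(x$dosage), x$h2_target, x$seed))
  invisible(x)
}

#' Simulate sequencing read counts from true dosages
#'
#' Per cell, total depth is Poisson(`mean_depth`) and alternate reads are
#' Binomial(depth, f) with f = (1 - d) * (1 - error_rate) + d * error_rate,
#' where d is the dosage code (reference-allele frequency); the alternate
#' fraction of a cell is 1 - code, perturbed by symmetric base error.
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param mean_depth mean sequencing depth per locus per sample (default 15).
#' @param error_rate per-read probability of reading the other allele
#'   (default 0.01; must be < 0.5).
#' @param seed RNG seed.
#' @return A `read_counts` list: integer matrices `ref` and `alt`
#'   (samples x loci), `loci` table, with `ref + alt` equal to the simulated
#'   depth in every cell.
#' @export
simulate_reads <- function(truth, mean_depth = 15, error_rate = 0.01, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!(mean_depth > 0)) stop_invalid("`mean_depth` must be positive")
  check_fraction(error_rate, "error_rate", lo = 0, hi = 0.5, hi_open = TRUE)
  d <- truth$dosage
  with_seed(seed, {
    depth <- matrix(stats::rpois(length(d), mean_depth), nrow(d), ncol(d))
    alt_p <- (1 - d) * (1 - error_rate) + d * error_rate
    alt <- matrix(stats::rbinom(length(d), depth, alt_p), nrow(d), ncol(d))
    ref <- depth - alt
    dimnames(ref) <- dimnames(alt) <- dimnames(d)
    structure(list(ref = set_loci(ref, truth$loci), alt = alt,
                   loci = truth$loci),
              class = "read_counts")
  })
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("read_counts: %d samples x %d loci, mean depth %.1f\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' Simulate additive polygenic phenotypes
#'
#' Phenotypes follow y = mu + Z v + e with Z the dosage codes and v the
#' cohort's true additive effects (all loci for `dense`; all but `n_qtl`
#' zeroed for `sparse`). Environmental noise is scaled so that the realised
#' ratio var(Zv)/var(y) targets the cohort's `h2_target` (or `h2` if given).
#'
#' @param truth a `sim_truth`.
#' @param architecture `"dense"` or `"sparse"`.
#' @param n_qtl number of causal loci for the sparse architecture.
#' @param h2 heritability target; defaults to `truth$h2_target`.
#' @param mu population trait mean (default 50, an arbitrary scale origin).
#' @param trait name for the trait column (default "trait").
#' @param seed RNG seed.
#' @return A `phenotype_table` list: `pheno` (data.frame `sample_id`, trait),
#'   `h2` (named per-trait target), `effects` (the effect vector actually
#'   used), `genetic_values` (Zv), `qtl` (indices of non-zero effects).
#' @export
simulate_phenotypes <- function(truth, architecture = c("dense", "sparse"),
                                n_qtl = 2, h2 = NULL, mu = 50,
                                trait = "trait", seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  architecture <- match.arg(architecture)
  if (is.null(h2)) h2 <- truth$h2_target
  check_fraction(h2, "h2", lo = 0, hi = 1, lo_open = TRUE)
  m <- ncol(truth$dosage)
  with_seed(seed, {
    v <- truth$true_effects
    qtl <- seq_len(m)
    if (architecture == "sparse") {
      n_qtl <- check_count(n_qtl, "n_qtl", min = 1)
      if (n_qtl > m) stop_invalid("`n_qtl` exceeds the number of loci")
      # causal loci must segregate in the cohort
      poly <- which(apply(truth$dosage, 2, stats::var) > 0)
      if (length(poly) < n_qtl) stop_invalid("fewer polymorphic loci than n_qtl")
      qtl <- sort(as.integer(sample(poly, n_qtl)))
      keep <- rep(FALSE, m); keep[qtl] <- TRUE
      v <- ifelse(keep, v, 0)
    }
    g <- drop(truth$dosage %*% v)
    var_g <- stats::var(g)
    if (var_g == 0) stop_invalid("genetic variance is zero; heritability undefined")
    var_e <- var_g * (1 - h2) / h2
    e <- if (var_e > 0) stats::rnorm(length(g), 0, sqrt(var_e)) else rep(0, length(g))
    y <- mu + g + e
    pheno <- data.frame(sample_id = rownames(truth$dosage), y,
                        stringsAsFactors = FALSE)
    names(pheno)[2] <- trait
    structure(list(pheno = pheno, h2 = stats::setNames(h2, trait),
                   effects = v, genetic_values = g, qtl = qtl),
              class = "phenotype_table")
  })
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples, traits: %s\n",
              nrow(x$pheno), paste(names(x$h2), collapse = ", ")))
  invisible(x)
}

#' Mask dosage cells missing completely at random
#'
#' Each cell is set to `NA` independently with probability `rate`. The input
#' truth remains available for imputation scoring. `rate` close to 1 is
#' allowed (the call succeeds); whether the resulting matrix survives the
#' missingness filter is downstream's concern.
#'
#' @param dosages samples x loci dosage matrix.
#' @param rate missingness probability in \[0, 1).
#' @param seed RNG seed.
#' @return The matrix with masked cells set to `NA`.
#' @export
apply_missingness <- function(dosages, rate = 0.2, seed = 1) {
  stopifnot(is.matrix(dosages))
  check_fraction(rate, "rate", lo = 0, hi = 1, hi_open = TRUE)
  if (rate == 0) return(dosages)
  with_seed(seed, {
    mask <- stats::runif(length(dosages)) < rate
    dosages[mask] <- NA_real_
    dosages
  })
}
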