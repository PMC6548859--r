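#' Call five-class tetraploid dosage genotypes from read counts
#'
#' Each cell's genotype class (AAAA, AAAB, AABB, ABBB, BBBB) is the legal
#' reference-allele frequency \{1, 0.75, 0.5, 0.25, 0\} nearest to the
#' observed reference fraction ref/(ref+alt), with class boundaries at
#' \{0.125, 0.375, 0.625, 0.875\} — the maximum-likelihood assignment under
#' symmetric binomial read error. Two depth rules guard the call:
#' cells with total depth below `min_depth` are missing, and a cell whose
#' alternate support is positive but below `min_het_alt` reads cannot be
#' called heterozygous — it is assigned homozygous reference instead.
#'
#' @param counts a `read_counts` object (or list with `ref`, `alt`, `loci`).
#' @param min_depth minimum total reads to call a genotype (default 5).
#' @param min_het_alt minimum alternate reads to call a heterozygous class
#'   (default 2).
#' @return samples x loci dosage matrix (codes in \{0,.25,.5,.75,1\} or `NA`),
#'   locus table attached.
#' @export
call_dosages <- function(counts, min_depth = 5, min_het_alt = 2) {
  min_depth <- check_count(min_depth, "min_depth", min = 1)
  min_het_alt <- check_count(min_het_alt, "min_het_alt", min = 1)
  ref <- counts$ref; alt <- counts$alt
  stopifnot(is.matrix(ref), is.matrix(alt), all(dim(ref) == dim(alt)))
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    stop_invalid("read depths must be non-negative")
  }
  total <- ref + alt
  ref_frac <- ifelse(total > 0, ref / total, NA_real_)
  # nearest legal class via the fixed bin edges
  idx <- findInterval(ref_frac, c(0.125, 0.375, 0.625, 0.875)) + 1L
  code <- DOSAGE_CODES[idx]
  code <- matrix(code, nrow(ref), ncol(ref))
  # alt reads present but too few to support a heterozygous call
  weak_het <- alt >= 1 & alt < min_het_alt & code %in% c(0.25, 0.5, 0.75)
  code[weak_het] <- 1
  code[total < min_depth] <- NA_real_
  dimnames(code) <- dimnames(ref)
  set_loci(code, counts$loci)
}

#' Filter variants on alternate support, missingness, and MAF
#'
#' A locus survives iff all of:
#' \enumerate{
#'   \item at least one sample has `>= min_alt_reads_any` alternate reads
#'     *and* an alternate fraction `>= min_alt_fraction_any` at that sample
#'     (alternate-support rule: "more than four reads" read strictly, so the
#'     default is 5);
#'   \item its fraction of missing genotypes is `< max_missing` (loci with
#'     50\% or more missing data are removed under the default);
#'   \item its minor allele frequency is `> min_maf` (loci at 5\% or less are
#'     removed under the default), with MAF = min(p, 1-p) for p the mean
#'     dosage code over non-missing samples.
#' }
#'
#' The report attributes each dropped locus to its first failing rule, in the
#' order depth (no callable genotype at all), alternate read support,
#' alternate fraction, missingness, MAF — so the per-reason counts are
#' exclusive and sum to the number of dropped loci.
#'
#' @param dosages samples x loci dosage matrix (from [call_dosages()]).
#' @param counts the matching `read_counts` (for the alternate-support rule).
#' @param min_alt_reads_any,min_alt_fraction_any,max_missing,min_maf filter
#'   thresholds; defaults 5, 0.4, 0.5, 0.05.
#' @return list with `dosages` (surviving loci only) and `report`
#'   (a `filter_report`: per-locus logical columns `depth_fail`,
#'   `alt_support_fail`, `fraction_fail`, `missing_fail`, `maf_fail`,
#'   `retained`, plus `counts`, the surviving tally after each stage).
#' @export
filter_variants <- function(dosages, counts, min_alt_reads_any = 5,
                            min_alt_fraction_any = 0.4, max_missing = 0.5,
                            min_maf = 0.05) {
  stopifnot(is.matrix(dosages))
  if (length(dosages) == 0L) stop_invalid("empty dosage matrix")
  check_count(min_alt_reads_any, "min_alt_reads_any", min = 0)
  check_fraction(min_alt_fraction_any, "min_alt_fraction_any")
  check_fraction(max_missing, "max_missing", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(min_maf, "min_maf", lo = 0, hi = 0.5)
  alt <- counts$alt; total <- counts$ref + counts$alt
  stopifnot(all(dim(alt) == dim(dosages)))

  n <- nrow(dosages)
  n_obs <- colSums(!is.na(dosages))
  depth_fail <- n_obs == 0L

  has_alt_reads <- colSums(alt >= min_alt_reads_any) > 0L
  frac <- ifelse(total > 0, alt / total, 0)
  has_alt_support <- colSums(alt >= min_alt_reads_any &
                               frac >= min_alt_fraction_any) > 0L
  alt_support_fail <- !depth_fail & !has_alt_reads
  fraction_fail <- !depth_fail & has_alt_reads & !has_alt_support

  miss_frac <- 1 - n_obs / n
  missing_fail <- !depth_fail & !alt_support_fail & !fraction_fail &
    miss_frac >= max_missing

  p_bar <- colMeans(dosages, na.rm = TRUE)
  maf <- pmin(p_bar, 1 - p_bar)
  maf[n_obs == 0L] <- NA_real_
  maf_fail <- !depth_fail & !alt_support_fail & !fraction_fail &
    !missing_fail & !(maf > min_maf)

  retained <- !(depth_fail | alt_support_fail | fraction_fail |
                  missing_fail | maf_fail)
  loci <- loci_info(dosages)
  per_locus <- data.frame(
    locus = colnames(dosages), chrom = loci$chrom, pos = loci$pos,
    depth_fail = depth_fail, alt_support_fail = alt_support_fail,
    fraction_fail = fraction_fail, missing_fail = missing_fail,
    maf_fail = maf_fail, retained = retained,
    stringsAsFactors = FALSE
  )
  rownames(per_locus) <- NULL
  m <- ncol(dosages)
  counts_tbl <- c(
    input = m,
    after_depth = m - sum(depth_fail),
    after_alt_support = m - sum(depth_fail | alt_support_fail | fraction_fail),
    after_missing = m - sum(depth_fail | alt_support_fail | fraction_fail |
                              missing_fail),
    after_maf = sum(retained)
  )
  report <- structure(list(per_locus = per_locus, counts = counts_tbl),
                      class = "filter_report")
  kept <- set_loci(dosages[, retained, drop = FALSE],
                   loci[retained, , drop = FALSE])
  list(dosages = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print(x$counts)
  invisible(x)
}

#' Count SNPs in fixed-width bins along each chromosome
#'
#' Bins are half-open windows `[start, start + bin_bp)` tiling each chromosome
#' from position 1, so position `bin_bp` itself still falls in the first bin.
#' Counts over all bins of a chromosome sum to the number of loci on it.
#'
#' @param loci data.frame with `chrom` and `pos` (1-based).
#' @param layout a [genome_layout()] providing chromosome lengths.
#' @param bin_bp bin width in bp (default 1e5, i.e. 100 kb).
#' @return data.frame `chrom`, `bin` (1-based index), `start`, `end`
#'   (inclusive bounds of the window), `n_snps`, one row per bin per
#'   chromosome including empty bins.
#' @export
density_bins <- function(loci, layout, bin_bp = 1e5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!(bin_bp > 0)) stop_invalid("`bin_bp` must be positive")
  chroms <- layout$chromosomes
  if (nrow(loci) > 0) {
    len <- stats::setNames(chroms$length, chroms$name)
    bad <- !(loci$chrom %in% chroms$name) | loci$pos > len[loci$chrom] |
      loci$pos < 1
    if (any(bad)) {
      stop_invalid(sprintf("locus outside chromosome bounds: %s",
                           paste(locus_ids(loci[bad, , drop = FALSE])[
                             seq_len(min(3, sum(bad)))], collapse = ", ")))
    }
  }
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    nb <- ceiling(chroms$length[i] / bin_bp)
    counts <- integer(nb)
    on_chrom <- loci$pos[loci$chrom == chroms$name[i]]
    if (length(on_chrom)) {
      b <- (on_chrom - 1) %/% bin_bp + 1
      tb <- table(b)
      counts[as.integer(names(tb))] <- as.integer(tb)
    }
    data.frame(chrom = chroms$name[i], bin = seq_len(nb),
               start = (seq_len(nb) - 1) * bin_bp + 1,
               end = pmin(seq_len(nb) * bin_bp, chroms$length[i]),
               n_snps = counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
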