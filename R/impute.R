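#' Rank loci by linkage disequilibrium with a target locus
#'
#' LD is the squared Pearson correlation of dosage codes across samples
#' jointly observed at both loci. Loci with fewer than two joint observations
#' are excluded. Ties in r-squared are broken by genomic coordinate
#' (chromosome, then position), so the ranking is deterministic.
#'
#' @param dosages samples x loci dosage matrix (NAs allowed).
#' @param target_locus column index or name of the target locus.
#' @return data.frame `locus` (column index), `id`, `r2`, sorted by
#'   decreasing `r2`; the target itself is excluded.
#' @export
ld_rank <- function(dosages, target_locus) {
  stopifnot(is.matrix(dosages))
  if (is.character(target_locus)) {
    target_locus <- match(target_locus, colnames(dosages))
  }
  if (is.na(target_locus) || target_locus < 1 || target_locus > ncol(dosages)) {
    stop_invalid("`target_locus` not found")
  }
  x <- dosages[, target_locus]
  v <- stats::var(x, na.rm = TRUE)
  if (is.na(v) || v == 0) {
    stop_invalid("target locus is monomorphic (zero variance); LD undefined")
  }
  others <- setdiff(seq_len(ncol(dosages)), target_locus)
  joint <- colSums(!is.na(dosages[, others, drop = FALSE]) & !is.na(x))
  keep <- others[joint >= 2]
  if (!length(keep)) {
    stop_invalid("no locus shares >= 2 observed samples with the target")
  }
  r <- suppressWarnings(
    stats::cor(x, dosages[, keep, drop = FALSE], use = "pairwise.complete.obs")
  )
  r2 <- drop(r)^2
  r2[is.na(r2)] <- 0  # monomorphic partner over the joint samples
  loci <- loci_info(dosages)
  ord <- order(-r2, match(loci$chrom[keep], unique(loci$chrom)), loci$pos[keep])
  data.frame(locus = keep[ord],
             id = colnames(dosages)[keep][ord],
             r2 = unname(r2[ord]),
             stringsAsFactors = FALSE)
}

#' Impute missing dosages by LD k-nearest neighbours
#'
#' For each locus with missing cells: (1) rank all other loci by squared
#' Pearson correlation with it (over jointly observed samples); (2) keep the
#' top `n_loci_ld` (default 17); (3) for each sample missing at the locus,
#' compute its Euclidean distance to every sample observed there over the
#' selected loci, normalised by the number of jointly observed loci so
#' residual missingness does not penalise a sample; (4) impute the mean code
#' of the `k_neighbors` (default 11) closest observed samples. Fewer observed
#' samples than k falls back to using all of them. Ties in distance are
#' broken by sample order; the procedure is deterministic.
#'
#' Imputed values are left continuous in \[0, 1\] (means of legal codes), the
#' reference-allele-frequency coding consumed by genomic selection.
#'
#' @param dosages samples x loci dosage matrix with NAs; every locus must
#'   have at least one observed sample.
#' @param k_neighbors number of nearest neighbour samples (default 11).
#' @param n_loci_ld number of highest-LD loci used for the distance
#'   (default 17).
#' @return complete samples x loci matrix, locus table preserved.
#' @export
impute_ldknn <- function(dosages, k_neighbors = 11, n_loci_ld = 17) {
  stopifnot(is.matrix(dosages))
  k_neighbors <- check_count(k_neighbors, "k_neighbors", min = 1)
  n_loci_ld <- check_count(n_loci_ld, "n_loci_ld", min = 1)
  miss_loci <- which(colSums(is.na(dosages)) > 0L)
  if (!length(miss_loci)) return(dosages)
  none_obs <- colSums(!is.na(dosages)) == 0L
  if (any(none_obs)) {
    stop_invalid(sprintf("locus with no observed genotype: %s",
                         paste(colnames(dosages)[none_obs][1:min(3, sum(none_obs))],
                               collapse = ", ")))
  }
  out <- dosages
  obs <- !is.na(dosages)
  # full pairwise LD once; columns with zero variance yield NA -> r2 0
  r <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[is.na(r2)] <- 0
  joint <- crossprod(obs)  # pairwise joint-observation counts
  loci <- loci_info(dosages)
  chrom_rank <- match(loci$chrom, unique(loci$chrom))

  for (L in miss_loci) {
    cand <- setdiff(which(joint[, L] >= 2), L)
    if (!length(cand)) {
      # no informative partner: fall back to the locus mean
      out[!obs[, L], L] <- mean(dosages[, L], na.rm = TRUE)
      next
    }
    ord <- cand[order(-r2[cand, L], chrom_rank[cand], loci$pos[cand])]
    sel <- ord[seq_len(min(n_loci_ld, length(ord)))]
    G <- dosages[, sel, drop = FALSE]
    observed_s <- which(obs[, L])
    missing_s <- which(!obs[, L])
    for (s in missing_s) {
      diffs <- sweep(G[observed_s, , drop = FALSE], 2, G[s, ], "-")
      sq <- diffs^2
      n_cmp <- rowSums(!is.na(sq))
      d2 <- rowSums(sq, na.rm = TRUE) / n_cmp
      d2[n_cmp == 0] <- Inf  # nothing jointly observed: least preferred
      nb <- observed_s[order(d2, observed_s)][seq_len(min(k_neighbors,
                                                          length(observed_s)))]
      out[s, L] <- mean(dosages[nb, L])
    }
  }
  out
}
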