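#' Genome layout: chromosomes and gene intervals
#'
#' A genome layout holds the chromosome names and lengths plus a set of gene
#' intervals (1-based, inclusive) in which simulated transcript SNPs are
#' placed. Layouts validate their own geometry: positive lengths, intervals
#' inside their chromosome, and non-overlapping intervals after merging.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param gene_intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return An object of class `genome_layout` (a list with the two tables,
#'   gene intervals sorted and merged).
#' @export
genome_layout <- function(chromosomes, gene_intervals) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(gene_intervals),
            all(c("chrom", "start", "end") %in% names(gene_intervals)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) {
    stop_invalid("duplicate chromosome names in layout")
  }
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0)) {
    stop_invalid("chromosome lengths must be positive")
  }
  gi <- gene_intervals
  gi$chrom <- as.character(gi$chrom)
  if (nrow(gi) == 0L) stop_invalid("layout must contain at least one gene interval")
  if (any(!gi$chrom %in% chromosomes$name)) {
    stop_invalid("gene interval on unknown chromosome")
  }
  if (any(gi$start < 1) || any(gi$end < gi$start)) {
    stop_invalid("gene intervals must satisfy 1 <= start <= end")
  }
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(gi$end > len[gi$chrom])) {
    stop_invalid("gene interval extends beyond its chromosome")
  }
  gi <- merge_intervals(gi)
  structure(list(chromosomes = chromosomes, gene_intervals = gi),
            class = "genome_layout")
}

# Sort and merge overlapping/adjacent intervals per chromosome.
merge_intervals <- function(gi) {
  gi <- gi[order(gi$chrom, gi$start, gi$end), , drop = FALSE]
  out <- lapply(split(gi, gi$chrom), function(g) {
    keep_start <- g$start[1]
    keep_end <- g$end[1]
    starts <- integer(0); ends <- integer(0)
    if (nrow(g) > 1) {
      for (i in 2:nrow(g)) {
        if (g$start[i] <= keep_end + 1) {
          keep_end <- max(keep_end, g$end[i])
        } else {
          starts <- c(starts, keep_start); ends <- c(ends, keep_end)
          keep_start <- g$start[i]; keep_end <- g$end[i]
        }
      }
    }
    starts <- c(starts, keep_start); ends <- c(ends, keep_end)
    data.frame(chrom = g$chrom[1], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %d gene intervals, %.1f Mb total\n",
              nrow(x$chromosomes), nrow(x$gene_intervals),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Potato (Solanum tuberosum) chromosome summary
#'
#' Per-chromosome lengths, annotated gene counts, and filtered transcript-SNP
#' counts for the 12 chromosomes of the DM v4.03 potato reference as used for
#' the default simulated layout and for density-table arithmetic.
#'
#' @return data.frame with columns `chrom`, `length`, `genes`, `snps`.
#' @export
potato_chromosomes <- function() {
  data.frame(
    chrom  = as.character(1:12),
    length = c(88663952, 48614681, 62290286, 72208621, 52070158, 59532096,
               56760843, 56938457, 61540751, 59756223, 45475667, 61165649),
    genes  = c(4692, 3214, 3601, 3441, 2642, 3295, 2711, 2698, 3012, 2847,
               2423, 2906),
    snps   = c(13446, 12771, 10468, 13921, 13437, 14444, 15455, 14963, 15236,
               18552, 17689, 23466),
    stringsAsFactors = FALSE
  )
}

#' SNPs-per-gene and totals for a chromosome summary table
#'
#' Recomputes the derived columns of the per-chromosome SNP distribution
#' table: the SNPs/gene ratio per chromosome (1 decimal) and the genome-wide
#' gene and SNP totals.
#'
#' @param tab data.frame with columns `genes` and `snps`
#'   (default [potato_chromosomes()]).
#' @return list with `per_chrom` (input plus `snps_per_gene`), `total_genes`,
#'   `total_snps`.
#' @export
chromosome_summary <- function(tab = potato_chromosomes()) {
  stopifnot(all(c("genes", "snps") %in% names(tab)))
  tab$snps_per_gene <- round(tab$snps / tab$genes, 1)
  list(per_chrom = tab,
       total_genes = sum(tab$genes),
       total_snps = sum(tab$snps))
}

#' Default simulated potato genome layout
#'
#' Builds a [genome_layout()] with the 12 potato chromosome lengths and
#' randomly placed gene intervals. Gene density increases toward chromosome
#' ends (a uniform/reflected-Beta mixture) to echo the telomeric enrichment
#' of transcript SNPs seen in real data; this is cosmetic and can be turned
#' off with `telomeric_bias = FALSE`.
#'
#' @param genes_per_chrom integer vector of gene counts per chromosome
#'   (default: the annotated potato counts, scaled by `gene_scale`).
#' @param gene_scale fraction of the full gene complement to draw
#'   (default 0.1; the full ~37k intervals are rarely needed at desk scale).
#' @param gene_length typical gene interval length in bp (default 3000).
#' @param telomeric_bias place genes preferentially near chromosome ends.
#' @param seed RNG seed for interval placement.
#' @return A `genome_layout`.
#' @export
potato_layout <- function(genes_per_chrom = NULL, gene_scale = 0.1,
                          gene_length = 3000, telomeric_bias = TRUE,
                          seed = 1) {
  chroms <- potato_chromosomes()
  if (is.null(genes_per_chrom)) {
    genes_per_chrom <- pmax(1L, as.integer(round(chroms$genes * gene_scale)))
  }
  stopifnot(length(genes_per_chrom) == nrow(chroms))
  gi <- with_seed(seed, {
    pieces <- lapply(seq_len(nrow(chroms)), function(i) {
      n <- genes_per_chrom[i]
      L <- chroms$length[i]
      u <- if (telomeric_bias) {
        # half uniform, half concentrated at either end (reflected Beta)
        b <- stats::rbeta(n, 0.5, 2)
        refl <- ifelse(stats::runif(n) < 0.5, b, 1 - b)
        ifelse(stats::runif(n) < 0.5, stats::runif(n), refl)
      } else {
        stats::runif(n)
      }
      start <- pmax(1, pmin(L - gene_length, floor(u * (L - gene_length)) + 1))
      data.frame(chrom = chroms$chrom[i], start = start,
                 end = pmin(L, start + gene_length - 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  genome_layout(data.frame(name = chroms$chrom, length = chroms$length,
                           stringsAsFactors = FALSE), gi)
}
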