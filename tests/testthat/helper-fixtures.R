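# Small in-code fixtures shared across test files.

# A locus table with sequential positions on one or more chromosomes.
make_loci <- function(n, chrom = "1", start = 1000, step = 1000) {
  data.frame(chrom = rep(chrom, length.out = n),
             pos = as.integer(start + step * (seq_len(n) - 1)),
             ref = rep("A", n), alt = rep("T", n),
             stringsAsFactors = FALSE)
}

# Wrap ref/alt matrices as the read_counts structure the callers expect.
make_counts <- function(ref, alt, loci = make_loci(ncol(ref))) {
  rownames(ref) <- rownames(alt) <- sprintf("s%02d", seq_len(nrow(ref)))
  colnames(ref) <- colnames(alt) <- paste0(loci$chrom, ":", loci$pos)
  attr(ref, "loci") <- loci
  structure(list(ref = ref, alt = alt, loci = loci), class = "read_counts")
}

# A dosage matrix with the locus table attached.
make_dosages <- function(mat, loci = make_loci(ncol(mat))) {
  rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  colnames(mat) <- paste0(loci$chrom, ":", loci$pos)
  attr(mat, "loci") <- loci
  mat
}

# A tiny two-chromosome layout for geometry tests.
tiny_layout <- function(len = c(1e6, 5e5)) {
  genome_layout(
    data.frame(name = c("1", "2"), length = len),
    data.frame(chrom = c("1", "1", "2"),
               start = c(1000, 200000, 1000),
               end = c(50000, 260000, 100000))
  )
}

# High-LD cohort: two founder haplotypes per chromosome-wide block.
high_ld_cohort <- function(n_samples, n_loci, seed) {
  simulate_cohort(n_samples = n_samples, n_loci = n_loci, n_founders = 2,
                  ld_block_bp = 1e8, seed = seed)
}
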