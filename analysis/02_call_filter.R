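#!/usr/bin/env Rscript
# Stage 2: dosage calling and variant filtering.
#
# Reads the raw read-count VCF, calls five-class dosages (minimum depth 5,
# two alternate reads to call a heterozygote), masks 20% of calls at random
# to emulate real missingness, then applies the variant filters: alternate
# support (>= 5 alt reads at >= 0.4 fraction in at least one sample),
# missingness (< 50%), and MAF (> 5%). Writes the filtered genotype VCF, the
# per-locus filter report, and 100-kb SNP density bins of the surviving loci.

library(spudgs)

out <- "results"
cfg <- read_pipeline_config("results/cohort/config.json")
raw <- read_vcf("results/cohort/genotypes_raw.vcf")

called <- call_dosages(raw$counts, min_depth = cfg$min_depth,
                       min_het_alt = cfg$min_het_alt)
called <- apply_missingness(called, rate = cfg$missing_rate,
                            seed = cfg$seed + 3)
flt <- filter_variants(called, raw$counts,
                       min_alt_reads_any = cfg$min_alt_reads_any,
                       min_alt_fraction_any = cfg$min_alt_fraction_any,
                       max_missing = cfg$max_missing, min_maf = cfg$min_maf)

layout <- potato_layout(seed = cfg$seed)
write_vcf(file.path(out, "genotypes_filtered.vcf"), flt$dosages,
          layout = layout)
write.table(flt$report$per_locus, file.path(out, "filter_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
dens <- density_bins(attr(flt$dosages, "loci"), layout, bin_bp = cfg$bin_bp)
write.table(dens, file.path(out, "snp_density_100kb.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("filter cascade (loci surviving each stage):\n")
print(flt$report$counts)
cat(sprintf("missing genotype fraction after masking: %.3f\n",
            mean(is.na(called))))
per_chrom <- tapply(dens$n_snps, dens$chrom, sum)
cat("retained SNPs per chromosome:\n")
print(per_chrom[order(as.integer(names(per_chrom)))])
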