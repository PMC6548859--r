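#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default synthetic tetraploid cultivar cohort — 181 cultivars,
# 2,000 transcript SNPs on the 12 potato chromosomes, LD from per-block
# founder haplotypes — plus Poisson/binomial sequencing read counts and an
# additive dense trait at h2 = 0.8. Writes the raw evidence (ploidy-4 VCF
# with AD), the phenotype CSV, and the truth sidecar used by later stages
# for scoring.

library(spudgs)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- pipeline_config()  # the study defaults; seed 1

layout <- potato_layout(seed = cfg$seed)
truth <- simulate_cohort(n_samples = cfg$n_samples, n_loci = cfg$n_loci,
                         layout = layout, h2_target = cfg$h2, seed = cfg$seed)
counts <- simulate_reads(truth, mean_depth = cfg$mean_depth,
                         error_rate = cfg$error_rate, seed = cfg$seed + 1)
phen <- simulate_phenotypes(truth, cfg$architecture, seed = cfg$seed + 2)

write_vcf(file.path(out, "genotypes_raw.vcf"), truth$dosage, counts = counts,
          layout = layout)
write_phenotypes(phen, file.path(out, "phenotypes.csv"))
write_truth_json(truth, file.path(out, "truth.json"))
write_pipeline_config(cfg, file.path(out, "config.json"))

class_tab <- table(factor(truth$dosage, levels = c(0, 0.25, 0.5, 0.75, 1)))
cat(sprintf("cohort: %d cultivars x %d loci, mean depth %.1f\n",
            nrow(truth$dosage), ncol(truth$dosage),
            mean(counts$ref + counts$alt)))
cat("dosage class frequencies (BBBB..AAAA):\n")
print(round(prop.table(class_tab), 3))
cat(sprintf("realized trait heritability: %.3f\n",
            var(phen$genetic_values) / var(phen$pheno$trait)))
cat(sprintf("outputs in %s\n", out))
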