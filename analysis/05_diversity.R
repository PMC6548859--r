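#!/usr/bin/env Rscript
# Stage 5: genetic diversity and relatedness.
#
# Nei's standard genetic distance between all cultivars on the imputed
# frequency-coded genotypes, an unrooted neighbour-joining dendrogram, and a
# replicate check: a cultivar re-sequenced from the same truth should sit
# far below the cohort's typical pairwise distance.

library(spudgs)

cfg <- read_pipeline_config("results/cohort/config.json")
geno <- read.delim("results/genotypes_imputed.tsv", check.names = FALSE)
Z <- t(as.matrix(geno[, -1]))
colnames(Z) <- geno$locus

D <- nei_distance(Z)
tree <- neighbor_joining(D)
write_newick(tree, "results/nj_tree.nwk")

off <- D[upper.tri(D)]
cat(sprintf("Nei distance over %d cultivar pairs: mean %.3f, max %.3f\n",
            length(off), mean(off), max(off)))

# replicate experiment: re-sequence cultivar 1 from the same dosage truth
truth <- read_truth_json("results/cohort/truth.json")
raw <- read_vcf("results/cohort/genotypes_raw.vcf")
tr_obj <- structure(list(dosage = raw$dosages, loci = raw$loci,
                         true_effects = truth$true_effects,
                         h2_target = truth$h2_target, layout = NULL,
                         seed = truth$seed), class = "sim_truth")
rep_counts <- simulate_reads(tr_obj, mean_depth = 30,
                             error_rate = cfg$error_rate,
                             seed = cfg$seed + 99)
rep_dos <- call_dosages(rep_counts)[1, colnames(Z), drop = FALSE]
rep_dos[is.na(rep_dos)] <- colMeans(Z)[is.na(rep_dos)]
rownames(rep_dos) <- "replicate"
D2 <- nei_distance(rbind(Z, rep_dos))
rep_d <- D2[rownames(Z)[1], "replicate"]
cat(sprintf("replicate distance %.3f vs cohort 5th percentile %.3f\n",
            rep_d, quantile(off, 0.05)))

writeLines(c("metric\tvalue",
             sprintf("mean_pairwise_distance\t%.6f", mean(off)),
             sprintf("max_pairwise_distance\t%.6f", max(off)),
             sprintf("replicate_distance\t%.6f", rep_d),
             sprintf("cohort_5th_percentile\t%.6f", quantile(off, 0.05))),
           "results/diversity_summary.tsv")
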