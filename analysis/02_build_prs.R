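#!/usr/bin/env Rscript
# Stage 2: build the schizophrenia PRS from the files written by stage 1.
#
# Reads the genotype VCF and summary-statistics TSV back from disk (the
# same path external data would take), applies variant QC, harmonizes
# alleles and strand, selects the p-value threshold by AUC against the
# schizophrenia label, prunes by LD, scores every individual, and writes
# the model, its provenance, and the per-individual scores.

suppressPackageStartupMessages(library(prsinteract))

dir <- "results/data"
stopifnot(file.exists(file.path(dir, "genotypes.vcf")))

cat("Reading genotypes and summary statistics...\n")
geno <- read_genotypes(file.path(dir, "genotypes.vcf"))$genotypes
ss <- read_sumstats(file.path(dir, "sumstats.tsv"))$sumstats
cohort <- read_tsv(file.path(dir, "cohort.tsv"))

cat("Building the PRS (QC -> harmonize -> threshold by AUC -> prune)...\n")
pb <- build_prs(geno, ss, cohort$scz_status)
cat("  QC drops: ", paste(names(pb$qc$drops), pb$qc$drops, sep = "=",
                          collapse = ", "), "\n")
cat("  harmonization drops: ",
    paste(names(pb$harmonization$drops), pb$harmonization$drops, sep = "=",
          collapse = ", "), "\n")
cat("  AUC by threshold: ",
    paste(names(pb$selection$auc_map), round(pb$selection$auc_map, 4),
          sep = ": ", collapse = ", "), "\n")
cat(sprintf("  selected p < %g; %d variants in the final model\n",
            pb$model$p_threshold, nrow(pb$model$entries)))

scores <- score_individuals(geno, pb$model)
auc <- concordance_auc(scores, cohort$scz_status)
cat(sprintf("  PRS AUC for schizophrenia status: %.3f (%d cases, %d controls)\n",
            auc$auc, auc$n_cases, auc$n_controls))

write_prs_model(pb$model, "results/prs_model.tsv")
write_tsv(data.frame(sample_id = names(scores), prs = unname(scores)),
          "results/prs_scores.tsv")
cat("Wrote results/prs_model.tsv and results/prs_scores.tsv\n")
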