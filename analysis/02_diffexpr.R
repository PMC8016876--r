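#!/usr/bin/env Rscript
# Dual-model differential expression: linear regression on log2(CPM) and
# NB/hurdle regression on rounded CPB, age + sex as the only covariates;
# consensus = significant (p < 0.01) in both families with matching sign.

library(sarcotx)

counts <- read_tsv_matrix("results/gene_counts.tsv")
samples <- read_sample_table("results/samples.tsv")
truth <- utils::read.delim("results/truth_genes.tsv")

fits <- fit_age_models(counts, samples)
cons <- consensus(fits$linear, fits$nb_family, alpha = 0.01)

write_tsv_table(fits$linear, "results/fits_linear.tsv")
write_tsv_table(fits$nb_family, "results/fits_nb_family.tsv")
write_tsv_table(fits$exclusions, "results/exclusions.tsv")
write_tsv_table(cons, "results/consensus.tsv")
write_tsv_table(top_features(fits$linear, 20, "up"),
                "results/top20_linear_up.tsv")
write_tsv_table(top_features(fits$nb_family, 20, "up"),
                "results/top20_nb_up.tsv")

lin_sig <- sum(fits$linear$p_wald < 0.01, na.rm = TRUE)
nb_sig <- sum(fits$nb_family$p_wald < 0.01, na.rm = TRUE)
cat(sprintf("unexpressed removed: %d; linear fits: %d; NB-family fits: %d (%d hurdle)\n",
            fits$n_unexpressed, nrow(fits$linear), nrow(fits$nb_family),
            sum(fits$nb_family$model == "zanb")))
cat(sprintf("significant p<0.01: linear %d, NB family %d, consensus %d (%d up, %d down)\n",
            lin_sig, nb_sig, sum(cons$in_consensus, na.rm = TRUE),
            sum(cons$direction == "up", na.rm = TRUE),
            sum(cons$direction == "down", na.rm = TRUE)))
tr <- merge(cons, truth[, c("gene_id", "true_beta_age")],
            by.x = "feature_id", by.y = "gene_id")
pos <- tr$true_beta_age != 0
cat(sprintf("truth check: %d/%d true age-associated genes in consensus, %d false positives\n",
            sum(tr$in_consensus & pos, na.rm = TRUE), sum(pos),
            sum(tr$in_consensus & !pos, na.rm = TRUE)))
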