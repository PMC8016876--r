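#!/usr/bin/env Rscript
# mRNA-protein integration: per-gene correlation distribution, age-beta
# vs age-beta scatter for the age-significant mRNAs, and the random-set
# control.

library(sarcotx)

counts <- read_tsv_matrix("results/gene_counts.tsv")
protein <- read_tsv_matrix("results/protein_abundance.tsv")
samples <- read_sample_table("results/samples.tsv")
linear <- utils::read.delim("results/fits_linear.tsv")

l2 <- to_cpm(counts, log2 = TRUE, pseudo = 1)
pc <- pairwise_correlation(l2, protein)
write_tsv_table(pc$pairs, "results/protein_mrna_corr.tsv")
write_tsv_table(pc$histogram, "results/protein_mrna_corr_hist.tsv")
cat(sprintf("protein-mRNA pairs: %d; correlation mean %.3f, sd %.3f, skewness %.2f\n",
            pc$summary$n, pc$summary$mean, pc$summary$sd, pc$summary$skewness))

sig <- linear$feature_id[linear$converged & linear$p_wald < 0.01]
bb <- beta_vs_beta(linear, protein, samples$age, samples$sex, subset = sig)
write_tsv_table(bb$table, "results/beta_vs_beta.tsv")
cat(sprintf("age-beta correlation (protein vs mRNA): all %d pairs r=%.3f; %d age-significant mRNAs r=%.3f\n",
            nrow(bb$table), bb$r_full, sum(bb$table$in_subset), bb$r_subset))

rnd <- random_set_control(bb$table, k = sum(bb$table$in_subset),
                          seed = 20260905)
cat(sprintf("random same-size control: r=%.3f (subset beats it: %s)\n",
            rnd$r_beta, bb$r_subset > rnd$r_beta))
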