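#!/usr/bin/env Rscript
# Presentation statistics: volcano tables for all three model families,
# z-scored heat-map input for the consensus genes (complete linkage,
# 1 - Pearson distance), and a young-vs-old Kruskal-Wallis validation of
# the top consensus gene's relative expression.

library(sarcotx)

counts <- read_tsv_matrix("results/gene_counts.tsv")
samples <- read_sample_table("results/samples.tsv")
linear <- utils::read.delim("results/fits_linear.tsv")
nbfam <- utils::read.delim("results/fits_nb_family.tsv")
cons <- utils::read.delim("results/consensus.tsv")

v_lin <- volcano_table(linear, alpha = 0.01)
v_nb <- volcano_table(nbfam[nbfam$model == "nb", ], alpha = 0.01)
v_hz <- volcano_table(nbfam[nbfam$model == "zanb", ], alpha = 0.01)
write_tsv_table(v_lin, "results/volcano_linear.tsv")
write_tsv_table(v_nb, "results/volcano_nb.tsv")
write_tsv_table(v_hz, "results/volcano_zanb.tsv")
cat(sprintf("volcano classes (linear): %d up, %d down, %d ns\n",
            sum(v_lin$class == "up"), sum(v_lin$class == "down"),
            sum(v_lin$class == "ns")))

cg <- cons$feature_id[cons$in_consensus %in% TRUE]
l2 <- to_cpm(counts[cg, , drop = FALSE], lib_size = colSums(counts),
             log2 = TRUE, pseudo = 1)
ord <- order(samples$age)
hm <- zscore_cluster(l2[, ord])
write_tsv_matrix(hm$z, "results/heatmap_zscores.tsv")
cat(sprintf("heat-map input: %d consensus genes clustered (%d constant rows flagged)\n",
            nrow(hm$z), length(hm$constant_rows)))

# RT-qPCR-style validation analog: relative expression of the top
# consensus gene against a stably expressed reference, 5 young vs 5 old
top_gene <- cons$feature_id[order(cons$p_linear)][1]
flat <- linear$feature_id[order(abs(linear$beta_age))]
ref_gene <- setdiff(flat, top_gene)[1]
grp <- age_groups(samples$age)
young_idx <- which(grp == "young")
old_idx <- which(grp == "old")
young <- young_idx[order(samples$age[young_idx])][1:5]
old <- old_idx[order(samples$age[old_idx], decreasing = TRUE)][1:5]
rel <- relative_expression(counts[top_gene, c(young, old)],
                           counts[ref_gene, c(young, old)])
kw <- kruskal_wallis(rel[1:5], rel[6:10])
cat(sprintf("validation analog: %s relative to %s, 5 young vs 5 old: H=%.3f, p=%.4f\n",
            top_gene, ref_gene, kw$H, kw$p))
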