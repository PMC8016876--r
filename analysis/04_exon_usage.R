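#!/usr/bin/env Rscript
# Group-wise differential exon usage between young (20-34) and old (65+)
# donors, and its intersection with the continuous-age DTU hits.

library(sarcotx)

exons <- read_tsv_matrix("results/exon_counts.tsv")
exon2gene <- utils::read.delim("results/exon2gene.tsv")
samples <- read_sample_table("results/samples.tsv")
dtu <- utils::read.delim("results/dtu.tsv")
truth_ex <- utils::read.delim("results/truth_exons.tsv")

grp <- age_groups(samples$age)
cat(sprintf("groups: %d young (20-34), %d old (65+), %d mid-aged dropped\n",
            sum(grp == "young", na.rm = TRUE), sum(grp == "old", na.rm = TRUE),
            sum(is.na(grp))))

ex <- exon_usage_test(exons, exon2gene, grp, fdr_threshold = 0.1)
write_tsv_table(ex$results, "results/exon_usage.tsv")
write_tsv_table(ex$skipped, "results/exon_usage_skipped.tsv")

cat(sprintf("exons tested: %d; significant at FDR<0.1: %d (in %d genes)\n",
            nrow(ex$results), sum(ex$results$significant),
            length(unique(ex$results$gene_id[ex$results$significant]))))
m <- merge(ex$results, truth_ex, by = "exon_id")
skipping <- unique(m$gene_id.x[m$true_usage_slope != 0])
detected <- unique(m$gene_id.x[m$significant])
cat(sprintf("truth check: %d/%d genes with simulated exon skipping detected\n",
            length(intersect(skipping, detected)), length(skipping)))
shared <- intersect_with_dtu(ex, dtu, fdr_threshold = 0.1, dtu_alpha = 0.01)
write_tsv_table(shared, "results/dtu_exon_shared_genes.tsv")
cat(sprintf("genes significant in both exon usage (FDR<0.1) and DTU (p<0.01): %d\n",
            nrow(shared)))
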