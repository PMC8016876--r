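# sarcotx

Age-association analysis for bulk RNA-seq of human skeletal muscle across
the adult lifespan: per-gene differential expression by two model families
fit in parallel, differential transcript usage, group-wise differential
exon usage, and mRNA–protein correlation — with a synthetic-data generator
carrying full ground truth, so the entire pipeline is testable end to end
without any external dataset.

It is written for transcriptomics analysts working with healthy-aging
cohort designs (tens of donors, continuous age, minimal covariates) who
want the whole filtering/modelling cascade as tested, reusable functions
rather than a one-off script.

## The model

For each gene *g* with counts *y<sub>gs</sub>* in sample *s* (age
*a<sub>s</sub>* in years, sex *x<sub>s</sub>* ∈ {0,1}):

* **Linear family** — on log2(CPM), genes with ≥10 samples at
  log2(CPM) ≥ −3:

  log2(CPM<sub>gs</sub>) = α<sub>g</sub> + β<sub>g</sub> a<sub>s</sub> + γ<sub>g</sub> x<sub>s</sub> + ε<sub>gs</sub>,  Wald t test on β<sub>g</sub>

* **Negative binomial family** — on counts per billion rounded to
  integers (CPB), genes with ≥10 samples at CPB ≥ 125, excluding genes
  with zero CPB in >50 samples or median CPB < 630:

  CPB<sub>gs</sub> ~ NB(μ<sub>gs</sub>, θ<sub>g</sub>),  log μ<sub>gs</sub> = α<sub>g</sub> + β<sub>g</sub> a<sub>s</sub> + γ<sub>g</sub> x<sub>s</sub>

  Zero-free genes use a standard NB GLM; genes with ≥1 zero CPB use a
  zero-adjusted hurdle: logit P(zero) on age + sex, plus a zero-truncated
  NB on the positive counts (the count component supplies the gene's
  reported β and p, treating zeros as structural).

* **Consensus** — genes with p < 0.01 in *both* families and matching
  sign of β, labelled up/down.

Both thresholds trace to the same physical quantity: 10 reads in an
80-million-read library is log2(CPM) = −3 and CPB = 125 exactly.

Downstream: isoform usage percentages (100 × transcript / gene total)
regressed on age for differential transcript usage; an exon-vs-rest NB
interaction LRT with per-sample fixed effects for young/old differential
exon usage (BH FDR < 0.1); per-gene Pearson correlation and
β(protein)–β(mRNA) comparison against a random-set control for the
proteomic layer; z-score/complete-linkage heat-map input,
volcano tables and Kruskal–Wallis young-vs-old comparisons for reporting.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated cohort
(2000 genes, 53 donors aged 22–83, 10% of genes with a ±0.02/yr
log-scale age effect, ground truth recorded):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diffexpr.R
Rscript analysis/03_dtu.R
Rscript analysis/04_exon_usage.R
Rscript analysis/05_protein.R
Rscript analysis/06_report.R
```

which prints (tables under `results/`):

```
cohort: 53 samples, ages 23-82 (median 55), 30 male
genes: 2000 (200 age-associated, 100 with structural zeros)
unexpressed removed: 0; linear fits: 2000; NB-family fits: 1973 (73 hurdle)
significant p<0.01: linear 224, NB family 246, consensus 220 (163 up, 57 down)
truth check: 186/200 true age-associated genes in consensus, 34 false positives
DTU significant at p<0.05: 659; at p<0.01: 494
truth check: 455/458 drifting isoforms significant at 0.05
isoforms with significant usage change but flat absolute level: 368
exons tested: 10926; significant at FDR<0.1: 1184 (in 299 genes)
genes significant in both exon usage (FDR<0.1) and DTU (p<0.01): 27
protein-mRNA pairs: 1000; correlation mean 0.114, sd 0.278, skewness 0.84
age-beta correlation (protein vs mRNA): all 1000 pairs r=0.684; 200 age-significant mRNAs r=0.875
random same-size control: r=0.614 (subset beats it: TRUE)
validation analog: G01666 relative to G00629, 5 young vs 5 old: H=6.818, p=0.0090
```

Reading the key numbers: 186 of the 200 genes simulated with a true age
effect reach the dual-model consensus; the 34 extra calls reflect the
compositional push-down that CPM normalization exerts on null genes when
most true effects point up (discussed in the methods vignette). The 368
isoforms whose *share* of their gene changes while their *absolute* level
stays flat illustrate why transcript usage is analysed on the percentage
scale. The age-significant mRNAs correlate with their proteins' age
coefficients (r = 0.875) well above a random gene set of the same size
(r = 0.614).

The methods vignette (`vignettes/muscle-aging-pipeline.Rmd`) documents
the models, the filtering cascade, every tunable threshold and the
generator's assumptions.

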