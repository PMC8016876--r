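test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(frac_age_assoc = 1.2), "proportion")
  expect_error(sim_config(age_range = c(80, 30)), "min < max")
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(protein_corr_target = 1.5), "protein_corr_target")
})

test_that("the same seed reproduces every generator output bit-identically", {
  cfg <- sim_config(n_genes = 60, seed = 99)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$true_beta_age, b$truth$true_beta_age)
  ia <- suppressWarnings(simulate_isoforms(a))
  ib <- suppressWarnings(simulate_isoforms(b))
  expect_identical(ia$iso_counts, ib$iso_counts)
  pa <- simulate_proteins(a)
  pb <- simulate_proteins(b)
  expect_identical(pa$protein, pb$protein)
})

test_that("null-effect genes have empirical means at their baseline", {
  cfg <- sim_config(n_samples = 500, n_genes = 40, frac_age_assoc = 0,
                    baseline_mean_range = c(50, 50),
                    dispersion_range = c(5, 5),
                    frac_structural_zero_genes = 0, library_size = NULL,
                    seed = 5)
  sim <- simulate_counts(cfg)
  se <- sqrt((50 + 50^2 / 5) / 500)
  expect_true(all(abs(rowMeans(sim$counts) - 50) < 3 * se))
})

test_that("counts obey the NB moment identity var = mu + mu^2/size", {
  # independent moment calculation at n = 2000 draws per gene
  for (k in c(2, 10)) {
    cfg <- sim_config(n_samples = 2000, n_genes = 12, frac_age_assoc = 0,
                      baseline_mean_range = c(50, 50),
                      dispersion_range = c(k, k),
                      frac_structural_zero_genes = 0, library_size = NULL,
                      seed = 20 + k)
    sim <- simulate_counts(cfg)
    expected_var <- 50 + 50^2 / k
    vr <- apply(sim$counts, 1, var)
    # sampling tolerance: var of the sample variance for NB
    expect_true(all(abs(vr / expected_var - 1) < 0.25))
    expect_lt(abs(median(vr) / expected_var - 1), 0.1)
  }
})

test_that("age effects produce the configured log-linear trend", {
  cfg <- sim_config(n_samples = 800, n_genes = 30, frac_age_assoc = 1,
                    frac_positive = 1, beta_age_effect = 0.02,
                    baseline_mean_range = c(200, 200),
                    frac_structural_zero_genes = 0, library_size = NULL,
                    seed = 31)
  sim <- simulate_counts(cfg)
  old <- sim$samples$age > 70
  young <- sim$samples$age < 35
  ratio <- rowMeans(sim$counts[, old]) / rowMeans(sim$counts[, young])
  expected <- exp(0.02 * (mean(sim$samples$age[old]) -
                            mean(sim$samples$age[young])))
  expect_true(all(abs(log(ratio) - log(expected)) < 0.3))
})

test_that("structural zeros are masked as recorded in the truth table", {
  sim <- small_sim(seed = 7, frac_structural_zero_genes = 0.2)
  zg <- which(sim$truth$is_structural_zero)
  expect_gt(length(zg), 0)
  for (g in zg) {
    masked <- sim$truth$zero_samples[[g]]
    expect_true(all(sim$counts[g, masked] == 0))
  }
  expect_true(all(lengths(sim$truth$zero_samples[-zg]) == 0))
})

test_that("non-finite NB means fail with a diagnostic naming the gene", {
  cfg <- sim_config(n_genes = 10, beta_age_effect = 50, frac_age_assoc = 1,
                    seed = 3)
  expect_error(simulate_counts(cfg), "G000")
})

test_that("isoform splits conserve gene counts and degenerate cases hold", {
  sim <- small_sim(seed = 11)
  iso <- suppressWarnings(simulate_isoforms(sim))
  totals <- rowsum(iso$iso_counts, iso$tx2gene$gene_id)
  expect_identical(unname(totals[rownames(sim$counts), ]),
                   unname(sim$counts))
  expect_true(all(iso$iso_counts >= 0))
  # single-transcript genes carry the gene counts verbatim
  ntx <- table(iso$tx2gene$gene_id)
  singles <- names(ntx)[ntx == 1]
  for (g in head(singles, 3)) {
    tx <- iso$tx2gene$transcript_id[iso$tx2gene$gene_id == g]
    expect_identical(unname(iso$iso_counts[tx, ]), unname(sim$counts[g, ]))
  }
})

test_that("zero-drift symmetric splits give ~50% usage per transcript", {
  set.seed(202)
  gene_counts <- rnbinom(400, mu = 400, size = 10)
  parts <- sarcotx:::split_gene_counts(gene_counts, ages = runif(400, 22, 83),
                                       base_props = c(0.5, 0.5),
                                       drift_slope = 0, drift_part = 1,
                                       age_mid = 52.5)
  expect_identical(unname(colSums(parts)), as.numeric(gene_counts))
  usage <- rowSums(parts) / sum(gene_counts)
  expect_true(all(abs(usage - 0.5) < 0.01))
})

test_that("a drift slope that escapes the simplex is clamped with a warning", {
  expect_warning(
    sarcotx:::split_gene_counts(rep(100L, 20), ages = seq(22, 83, length = 20),
                                base_props = c(0.97, 0.03), drift_slope = 0.5,
                                drift_part = 1, age_mid = 52.5),
    "clamped")
})

test_that("protein generator hits its correlation target", {
  # noiseless limit: target 1 gives correlation exactly 1
  sim1 <- small_sim(seed = 13, n_genes = 40, protein_corr_target = 1)
  pr1 <- simulate_proteins(sim1, coupled_genes = rownames(sim1$counts)[1:10])
  l2 <- to_cpm(sim1$counts, log2 = TRUE, pseudo = 1)
  for (g in pr1$coupled_genes)
    expect_equal(cor(l2[g, ], pr1$protein[g, ]), 1, tolerance = 1e-12)

  # independence: target 0 leaves correlations scattered around 0
  sim0 <- small_sim(seed = 14, n_genes = 200, protein_corr_target = 0)
  pr0 <- simulate_proteins(sim0, coupled_genes = character(0), n_proteins = 200)
  l20 <- to_cpm(sim0$counts, log2 = TRUE, pseudo = 1)
  r0 <- sapply(rownames(pr0$protein), function(g) cor(l20[g, ], pr0$protein[g, ]))
  expect_lt(abs(mean(r0)), 0.05)

  # calibration: target 0.6 at n = 500 recovered within +-0.05
  cfg <- sim_config(n_samples = 500, n_genes = 150, protein_corr_target = 0.6,
                    seed = 15)
  simc <- simulate_counts(cfg)
  prc <- simulate_proteins(simc, coupled_genes = rownames(simc$counts)[1:100])
  l2c <- to_cpm(simc$counts, log2 = TRUE, pseudo = 1)
  rc <- sapply(prc$coupled_genes, function(g) cor(l2c[g, ], prc$protein[g, ]))
  expect_lt(abs(mean(rc) - 0.6), 0.05)
})

test_that("tables round-trip through the tab-separated writers", {
  sim <- small_sim(seed = 17, n_genes = 20)
  tmp <- tempfile(fileext = ".tsv")
  write_tsv_matrix(sim$counts, tmp)
  back <- read_tsv_matrix(tmp)
  expect_equal(unname(back), unname(sim$counts))
  expect_identical(rownames(back), rownames(sim$counts))
  tmp2 <- tempfile(fileext = ".tsv")
  write_tsv_table(sim$samples, tmp2)
  st <- read_sample_table(tmp2)
  expect_equal(st$age, sim$samples$age, tolerance = 1e-12)
})
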