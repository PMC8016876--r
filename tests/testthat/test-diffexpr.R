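test_that("fit_linear matches the closed-form normal-equations oracle", {
  fx <- ols_fixture()
  f <- fit_linear(fx$y, fx$age, fx$sex)
  o <- ols_oracle(fx$y, fx$age, fx$sex)
  expect_equal(f$beta_age, o$beta[2], tolerance = 1e-8)
  expect_equal(f$se_age, o$se[2], tolerance = 1e-8)
  expect_equal(f$p_wald, o$p[2], tolerance = 1e-8)
  expect_equal(f$beta_sex, o$beta[3], tolerance = 1e-8)
})

test_that("noiseless and degenerate linear fits behave as declared", {
  age <- seq(20, 90, by = 10)
  sex <- rep(c(0, 1), 4)
  f <- fit_linear(0.1 * age, age, sex)
  expect_equal(f$beta_age, 0.1, tolerance = 1e-10)
  expect_equal(f$p_wald, 0)  # zero residual SS, nonzero slope
  fc <- fit_linear(rep(2.5, 8), age, sex)
  expect_equal(fc$beta_age, 0)
  expect_equal(fc$p_wald, 1)
  # rank-deficient design: constant age
  fr <- fit_linear(rnorm(8), rep(50, 8), sex)
  expect_false(fr$converged)
  expect_identical(fr$exclusion_reason, "rank_deficient")
})

test_that("sentinel samples are excluded from a gene's linear fit", {
  fx <- ols_fixture()
  y <- fx$y
  y[c(2, 5)] <- -Inf
  f <- fit_linear(y, fx$age, fx$sex)
  keep <- is.finite(y)
  o <- ols_oracle(y[keep], fx$age[keep], fx$sex[keep])
  expect_equal(f$beta_age, o$beta[2], tolerance = 1e-8)
  expect_equal(f$n_used, 6L)
  expect_error(fit_linear(y, fx$age, fx$sex, drop_nonfinite = FALSE),
               "non-finite")
})

test_that("the matrix fast path agrees with per-gene linear fits", {
  set.seed(404)
  n <- 30
  age <- runif(n, 22, 83)
  sex <- rbinom(n, 1, 0.5)
  mat <- matrix(rnorm(20 * n), 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  mat[3, 5] <- -Inf   # one sentinel row exercises the slow path
  all_fits <- fit_linear_all(mat, age, sex)
  for (i in c(1, 3, 20)) {
    f <- fit_linear(mat[i, ], age, sex)
    expect_equal(all_fits$beta_age[i], f$beta_age, tolerance = 1e-12)
    expect_equal(all_fits$p_wald[i], f$p_wald, tolerance = 1e-12)
  }
  expect_identical(all_fits$feature_id, rownames(mat))
})

test_that("NB fit recovers a binary-covariate log fold change", {
  set.seed(42)
  n <- 400
  grp <- rep(c(0, 1), each = n / 2)
  sex <- rep(c(0, 1), n / 2)
  y <- rnbinom(n, mu = ifelse(grp == 1, 40, 20), size = 10)
  y[y == 0] <- 1L
  f <- fit_nb(y, grp, sex)
  # independent oracle: log link with one binary covariate fits the
  # group-mean ratio
  oracle <- log(mean(y[grp == 1]) / mean(y[grp == 0]))
  expect_true(f$converged)
  expect_equal(f$beta_age, oracle, tolerance = 0.02)
  expect_equal(f$beta_age, log(2), tolerance = 0.15)
})

test_that("equal counts give a flat NB fit and zeros are refused", {
  age <- runif(30, 22, 83)
  sex <- rbinom(30, 1, 0.5)
  f <- fit_nb(rep(50L, 30), age, sex)
  expect_true(f$converged)
  expect_equal(f$beta_age, 0, tolerance = 1e-8)
  expect_error(fit_nb(c(0L, rep(5L, 29)), age, sex), "hurdle")
})

test_that("hurdle refuses zero-free input and the routing partition is exact", {
  age <- runif(30, 22, 83)
  sex <- rbinom(30, 1, 0.5)
  expect_error(fit_hurdle(rep(5L, 30), age, sex), "fit_nb")
  sim <- small_sim(seed = 43, frac_structural_zero_genes = 0.15)
  fits <- fit_age_models(sim$counts, sim$samples)
  cpb <- to_cpb(sim$counts)
  routed <- c(fits$routed_nb, fits$routed_zanb)
  expect_false(any(duplicated(routed)))            # exactly one branch each
  has_zero <- rowSums(cpb[routed, , drop = FALSE] == 0) > 0
  expect_identical(sort(names(which(has_zero))), sort(fits$routed_zanb))
  expect_identical(sort(names(which(!has_zero))), sort(fits$routed_nb))
})

test_that("hurdle zero component recovers a 2x2 table log odds ratio", {
  # young: 2/10 zero, old: 8/10 zero, zero pattern identical across sex
  grp <- rep(c(0, 1), each = 10)
  sex <- rep(c(0, 1), 10)
  zero <- c(rep(c(TRUE, FALSE), c(1, 4)), rep(c(TRUE, FALSE), c(1, 4)),
            rep(c(TRUE, FALSE), c(4, 1)), rep(c(TRUE, FALSE), c(4, 1)))
  set.seed(77)
  y <- ifelse(zero, 0L, rnbinom(20, mu = 300, size = 10) + 1L)
  f <- fit_hurdle(y, grp, sex)
  # odds of a zero: young 2:8, old 8:2 -> OR 16
  expect_gt(f$zero_beta_age, 0)
  expect_equal(f$zero_beta_age, log(16), tolerance = 1e-4)
})

test_that("hurdle count component recovers an age trend with age-independent zeros", {
  set.seed(55)
  n <- 200
  age <- runif(n, 22, 83)
  sex <- rbinom(n, 1, 0.5)
  mu <- 150 * exp(0.025 * (age - 52.5))
  y <- rnbinom(n, mu = mu, size = 8)
  while (any(y == 0)) y[y == 0] <- rnbinom(sum(y == 0), mu = mu[y == 0], size = 8)
  y[sample(n, 50)] <- 0L                      # structural, age-independent
  f <- fit_hurdle(y, age, sex)
  expect_true(f$converged)
  expect_lt(abs(f$beta_age - 0.025), 2 * f$se_age)
})

test_that("hurdle count component matches an independent truncated-NB fitter", {
  skip_if_not_installed("glmmTMB")
  set.seed(60)
  n <- 120
  age <- runif(n, 22, 83)
  sex <- rbinom(n, 1, 0.5)
  mu <- 100 * exp(0.02 * (age - 52.5))
  y <- rnbinom(n, mu = mu, size = 6)
  while (any(y == 0)) y[y == 0] <- rnbinom(sum(y == 0), mu = mu[y == 0], size = 6)
  y[sample(n, 30)] <- 0L
  ours <- fit_hurdle(y, age, sex)
  pos <- y > 0
  d <- data.frame(y = y[pos], age = age[pos], sex = sex[pos])
  tmb <- glmmTMB::glmmTMB(y ~ age + sex, data = d,
                          family = glmmTMB::truncated_nbinom2())
  cf <- summary(tmb)$coefficients$cond
  expect_equal(ours$beta_age, cf["age", "Estimate"], tolerance = 1e-3)
  expect_equal(ours$se_age, cf["age", "Std. Error"], tolerance = 0.02)
})

test_that("hurdle excludes genes with too few positive observations", {
  age <- runif(20, 22, 83); sex <- rbinom(20, 1, 0.5)
  y <- c(rep(0L, 17), 5L, 8L, 9L)
  f <- fit_hurdle(y, age, sex)
  expect_false(f$converged)
  expect_identical(f$exclusion_reason, "too_few_positive")
})

test_that("consensus is the signed intersection of both families", {
  lin <- rbind(
    fit_row_stub("gA", "linear", beta = 0.02, p = 0.005),
    fit_row_stub("gB", "linear", beta = 0.02, p = 0.005),
    fit_row_stub("gC", "linear", beta = -0.02, p = 0.001),
    fit_row_stub("gD", "linear", beta = 0.02, p = 0.5))
  nbf <- rbind(
    fit_row_stub("gA", "nb", beta = 0.03, p = 0.005),
    fit_row_stub("gB", "nb", beta = -0.03, p = 0.004),   # sign conflict
    fit_row_stub("gC", "zanb", beta = -0.01, p = 0.009),
    fit_row_stub("gD", "nb", beta = 0.03, p = 0.005))
  cons <- consensus(lin, nbf, alpha = 0.01)
  expect_identical(cons$in_consensus[match(c("gA", "gB", "gC", "gD"),
                                           cons$feature_id)],
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(cons$direction[cons$feature_id == "gA"], "up")
  expect_identical(cons$direction[cons$feature_id == "gC"], "down")
  # consensus is a subset of each family's significant set
  expect_true(all(cons$significant_linear[cons$in_consensus]))
  expect_true(all(cons$significant_nb_family[cons$in_consensus]))
})

test_that("features fit in a single family are never in the consensus", {
  lin <- fit_row_stub("only_linear", "linear", beta = 0.1, p = 1e-6)
  nbf <- fit_row_stub("only_nb", "nb", beta = 0.1, p = 1e-6)
  cons <- consensus(lin, nbf, alpha = 0.01)
  expect_false(any(cons$in_consensus))
})

test_that("top-k ranking breaks ties by p, then |beta|, then id", {
  fits <- rbind(
    fit_row_stub("g3", "linear", beta = 0.5, p = 0.01),
    fit_row_stub("g1", "linear", beta = 0.2, p = 0.01),
    fit_row_stub("g2", "linear", beta = 0.5, p = 0.01),
    fit_row_stub("g0", "linear", beta = 0.1, p = 0.001))
  top <- top_features(fits, k = 3)
  expect_identical(top$feature_id, c("g0", "g2", "g3"))
  expect_identical(top_features(fits, k = 4, direction = "up")$feature_id[1],
                   "g0")
})

test_that("power and direction concordance on synthetic truth", {
  cfg <- sim_config(n_genes = 300, frac_age_assoc = 0.15,
                    beta_age_effect = 0.02,
                    baseline_mean_range = c(200, 200), seed = 67)
  sim <- simulate_counts(cfg)
  fits <- fit_age_models(sim$counts, sim$samples)
  cons <- consensus(fits$linear, fits$nb_family, alpha = 0.01)
  tr <- merge(cons, sim$truth[, c("gene_id", "true_beta_age")],
              by.x = "feature_id", by.y = "gene_id")
  pos <- tr$true_beta_age != 0
  expect_gte(mean(tr$in_consensus[pos], na.rm = TRUE), 0.5)
  hit <- tr$in_consensus %in% TRUE & pos
  agree <- sign(tr$beta_linear[hit]) == sign(tr$true_beta_age[hit]) &
    sign(tr$beta_nb[hit]) == sign(tr$true_beta_age[hit])
  expect_gte(mean(agree), 0.95)
})
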