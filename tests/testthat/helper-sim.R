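# Shared fixtures, built in code at test time.

# A small cohort: quick to simulate and fit, large enough for the filters
# and both model branches to engage.
small_sim <- function(seed = 101, n_genes = 150, ...) {
  simulate_counts(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Deterministic 8-sample design used by the closed-form OLS oracle tests.
ols_fixture <- function() {
  set.seed(808)
  age <- seq(20, 90, by = 10)
  sex <- rep(c(0, 1), 4)
  y <- 1.5 + 0.04 * age - 0.3 * sex + rnorm(8, sd = 0.5)
  list(y = y, age = age, sex = sex)
}

# Independent normal-equations OLS oracle: solve(X'X) X'y directly, with
# classical SE/t/p formulas -- no shared code with fit_linear's QR path.
ols_oracle <- function(y, age, sex) {
  X <- cbind(1, age, sex)
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- length(y) - 3
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  list(beta = unname(beta), se = unname(se),
       p = unname(2 * pt(-abs(tval), df)))
}

# Minimal converged fit row for consensus/ranking tests.
fit_row_stub <- function(id, model, beta, p) {
  data.frame(feature_id = id, model = model, beta_age = beta,
             se_age = 0.01, p_wald = p, beta_sex = 0, theta = NA_real_,
             n_used = 53L, converged = TRUE,
             exclusion_reason = NA_character_, note = NA_character_,
             zero_beta_age = NA_real_, zero_se_age = NA_real_,
             zero_p = NA_real_, stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force complete-linkage agglomeration on a distance matrix:
# returns the merge heights in order and the partition after each merge.
complete_linkage_brute <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}
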