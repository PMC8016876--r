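#' @keywords internal
# Common result-row constructor so all three model families share a schema.
fit_row <- function(feature_id = NA_character_, model, beta_age = NA_real_,
                    se_age = NA_real_, p_wald = NA_real_, beta_sex = NA_real_,
                    theta = NA_real_, n_used = NA_integer_, converged = FALSE,
                    exclusion_reason = NA_character_, note = NA_character_,
                    zero_beta_age = NA_real_, zero_se_age = NA_real_,
                    zero_p = NA_real_) {
  data.frame(feature_id = feature_id, model = model, beta_age = beta_age,
             se_age = se_age, p_wald = p_wald, beta_sex = beta_sex,
             theta = theta, n_used = as.integer(n_used), converged = converged,
             exclusion_reason = exclusion_reason, note = note,
             zero_beta_age = zero_beta_age, zero_se_age = zero_se_age,
             zero_p = zero_p, stringsAsFactors = FALSE)
}

#' Per-gene linear age model on log2(CPM)
#'
#' Ordinary least squares of `y` on intercept + age + sex. Two-sided Wald
#' p-value for the age coefficient from the t distribution with `n - 3`
#' degrees of freedom. Samples at the `-Inf` sentinel (zero counts under a
#' zero pseudo-count) are excluded from the fit rather than floored, so an
#' arbitrary imputation floor cannot dominate the slope; set
#' `drop_nonfinite = FALSE` to refuse such inputs instead.
#'
#' @param y Numeric response vector (log2CPM for one gene).
#' @param age,sex Numeric covariates, same length as `y`; sex coded 0/1.
#' @param feature_id Optional id carried into the result row.
#' @param drop_nonfinite Drop non-finite `y` entries before fitting.
#' @return One-row data.frame (see [fit_age_models()] for the schema).
#' @export
fit_linear <- function(y, age, sex, feature_id = NA_character_,
                       drop_nonfinite = TRUE) {
  stopifnot(length(y) == length(age), length(y) == length(sex))
  keep <- is.finite(y)
  if (!drop_nonfinite && !all(keep)) stop("non-finite response values")
  y <- y[keep]; age <- age[keep]; sex <- sex[keep]
  n <- length(y)
  if (n < 4)
    return(fit_row(feature_id, "linear", n_used = n,
                   exclusion_reason = "too_few_samples"))
  X <- cbind(`(Intercept)` = 1, age = age, sex = sex)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    return(fit_row(feature_id, "linear", n_used = n,
                   exclusion_reason = "rank_deficient"))
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  b_age <- beta[["age"]]
  se_age <- se[2]
  if (rss <= 1e-12 * max(1, sum(y^2)) || !is.finite(se_age)) {
    # perfect fit up to floating point: zero residual variance
    b_age <- if (abs(b_age) < 1e-10) 0 else b_age
    se_age <- 0
    p <- if (b_age == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(b_age / se_age), df)
  }
  fit_row(feature_id, "linear", beta_age = b_age, se_age = se_age,
          p_wald = p, beta_sex = beta[["sex"]], n_used = n, converged = TRUE)
}

#' Linear age model for every row of a matrix
#'
#' Rows with all-finite values share one QR decomposition of the design;
#' rows containing sentinel (`-Inf`) entries fall back to per-row fits on
#' their finite samples.
#'
#' @param mat Feature x sample matrix of log2(CPM) values.
#' @inheritParams fit_linear
#' @return data.frame, one row per feature.
#' @export
fit_linear_all <- function(mat, age, sex) {
  stopifnot(ncol(mat) == length(age))
  complete <- rowSums(!is.finite(mat)) == 0
  out <- vector("list", 2)
  if (any(complete)) {
    X <- cbind(1, age, sex)
    qx <- qr(X)
    Y <- t(mat[complete, , drop = FALSE])
    beta <- qr.coef(qx, Y)                       # 3 x G
    res <- Y - X %*% beta
    n <- nrow(X); df <- n - 3L
    rss <- colSums(res^2)
    sigma2 <- rss / df
    d2 <- chol2inv(qr.R(qx))[2, 2]
    se_age <- sqrt(pmax(sigma2 * d2, 0))
    b_age <- beta[2, ]
    p <- 2 * stats::pt(-abs(b_age / se_age), df)
    degen <- rss <= 1e-12 * pmax(1, colSums(Y^2)) | !is.finite(se_age)
    b_age[degen & abs(b_age) < 1e-10] <- 0
    se_age[degen] <- 0
    p[degen] <- ifelse(b_age[degen] == 0, 1, 0)
    out[[1]] <- data.frame(feature_id = rownames(mat)[complete],
                           model = "linear", beta_age = b_age,
                           se_age = se_age, p_wald = p, beta_sex = beta[3, ],
                           theta = NA_real_, n_used = n, converged = TRUE,
                           exclusion_reason = NA_character_,
                           note = NA_character_, zero_beta_age = NA_real_,
                           zero_se_age = NA_real_, zero_p = NA_real_,
                           stringsAsFactors = FALSE)
  }
  if (any(!complete)) {
    rows <- lapply(which(!complete), function(i)
      fit_linear(mat[i, ], age, sex, feature_id = rownames(mat)[i]))
    out[[2]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(rownames(mat))) {
    res <- res[match(rownames(mat), res$feature_id), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Standard negative binomial age model for a zero-free gene
#'
#' NB GLM with log link on intercept + age + sex, gene-wise dispersion by
#' maximum likelihood ([MASS::glm.nb]); two-sided Wald z test for the age
#' coefficient. Genes containing any zero take the hurdle branch instead
#' ([fit_hurdle()]); this function refuses them so the routing partition
#' is exact. If the ML dispersion fit fails (e.g. under-dispersed,
#' near-constant counts) the gene is refit as Poisson and flagged in
#' `note`.
#'
#' @param y Positive integer response (rounded CPB for one gene).
#' @inheritParams fit_linear
#' @return One-row data.frame.
#' @export
fit_nb <- function(y, age, sex, feature_id = NA_character_) {
  stopifnot(length(y) == length(age))
  if (any(y == 0))
    stop("fit_nb requires strictly positive counts; zero-bearing genes take fit_hurdle")
  dat <- data.frame(y = y, age = age, sex = sex)
  warn <- NULL
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ age + sex, data = dat),
      warning = function(w) {
        warn <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  note <- NA_character_
  theta <- NA_real_
  if (is.null(fit)) {
    fit <- tryCatch(stats::glm(y ~ age + sex, family = stats::poisson(),
                               data = dat),
                    error = function(e) NULL)
    if (is.null(fit))
      return(fit_row(feature_id, "nb", n_used = length(y),
                     exclusion_reason = "fit_failure"))
    note <- "poisson_fallback"
    theta <- Inf
  } else {
    theta <- fit$theta
    if (!is.null(warn)) note <- warn
  }
  if (!isTRUE(fit$converged))
    return(fit_row(feature_id, "nb", n_used = length(y), note = note,
                   exclusion_reason = "non_convergence"))
  cf <- stats::coef(summary(fit))
  fit_row(feature_id, "nb",
          beta_age = cf["age", 1], se_age = cf["age", 2],
          p_wald = 2 * stats::pnorm(-abs(cf["age", 1] / cf["age", 2])),
          beta_sex = cf["sex", 1], theta = theta, n_used = length(y),
          converged = TRUE, note = note)
}

# Zero-truncated NB log-likelihood for the hurdle count component.
trunc_nb_nll <- function(par, X, y) {
  beta <- par[seq_len(ncol(X))]
  theta <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta))
  if (any(!is.finite(mu)) || theta > 1e8) return(1e10)
  lp0 <- theta * (log(theta) - log(theta + mu))   # log P(Y = 0)
  ll <- stats::dnbinom(y, mu = mu, size = theta, log = TRUE) - log1p(-exp(lp0))
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

# Ridge-penalized logistic fit used when the zero component separates.
penalized_logit <- function(X, z, lambda = 0.5) {
  nll <- function(b) {
    v <- -(2 * z - 1) * drop(X %*% b)
    sum(ifelse(v > 30, v, log1p(exp(v)))) + lambda * sum(b[-1]^2)
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e)
    rep(NA_real_, ncol(X)))
  list(coef = opt$par, se = se)
}

#' Zero-adjusted (hurdle) negative binomial age model
#'
#' Two-part model for genes whose rounded CPB contains one or more zeros,
#' appropriate when those zeros are structural (true absence) rather than
#' sampling zeros: a logistic regression of the zero/non-zero indicator on
#' intercept + age + sex, plus a zero-truncated NB regression of the
#' positive counts on the same covariates (maximum likelihood via BFGS,
#' moment-based start, dispersion bounded away from degeneracy). The
#' gene's reported `beta_age`/`p_wald` come from the truncated-count
#' component -- it models expression level, the same target as the linear
#' model -- while the zero component's coefficients are reported alongside
#' (`zero_beta_age`, `zero_se_age`, `zero_p`).
#'
#' @param y Non-negative integer response containing at least one zero and
#'   at least one positive value.
#' @inheritParams fit_linear
#' @param min_positive Minimum number of positive observations; genes
#'   below it are excluded with a reason.
#' @return One-row data.frame with `model = "zanb"`.
#' @export
fit_hurdle <- function(y, age, sex, feature_id = NA_character_,
                       min_positive = 5L) {
  stopifnot(length(y) == length(age))
  if (!any(y == 0))
    stop("fit_hurdle requires at least one zero; zero-free genes take fit_nb")
  pos <- y > 0
  if (sum(pos) < min_positive)
    return(fit_row(feature_id, "zanb", n_used = length(y),
                   exclusion_reason = "too_few_positive"))

  X <- cbind(1, age = age, sex = sex)
  note <- NA_character_

  # zero/non-zero component
  sep <- FALSE
  zfit <- withCallingHandlers(
    stats::glm(pos ~ age + sex, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) {
    pl <- penalized_logit(X, as.numeric(pos))
    # sign flipped: model P(zero) so the age coefficient reads as zero odds
    z_b <- -pl$coef[2]; z_se <- pl$se[2]
    note <- "zero_component_separation_penalized"
  } else {
    cf <- stats::coef(summary(zfit))
    z_b <- -cf["age", 1]; z_se <- cf["age", 2]
  }
  z_p <- if (is.finite(z_se) && z_se > 0)
    2 * stats::pnorm(-abs(z_b / z_se)) else NA_real_

  # zero-truncated count component
  yp <- y[pos]; Xp <- X[pos, , drop = FALSE]
  start_fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(yp ~ Xp[, 2] + Xp[, 3])),
    error = function(e) NULL)
  if (is.null(start_fit)) {
    sp <- tryCatch(stats::glm(yp ~ Xp[, 2] + Xp[, 3], family = stats::poisson()),
                   error = function(e) NULL)
    if (is.null(sp))
      return(fit_row(feature_id, "zanb", n_used = length(y), note = note,
                     exclusion_reason = "fit_failure",
                     zero_beta_age = z_b, zero_se_age = z_se, zero_p = z_p))
    b0 <- stats::coef(sp)
    mu_hat <- mean(yp)
    th0 <- max(mu_hat^2 / max(stats::var(yp) - mu_hat, 1e-4), 0.1)
  } else {
    b0 <- stats::coef(start_fit)
    th0 <- start_fit$theta
  }
  par0 <- c(b0, log(min(max(th0, 1e-4), 1e6)))
  opt <- tryCatch(
    stats::optim(par0, trunc_nb_nll, X = Xp, y = yp, method = "BFGS",
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0)
    return(fit_row(feature_id, "zanb", n_used = length(y), note = note,
                   exclusion_reason = "non_convergence",
                   zero_beta_age = z_b, zero_se_age = z_se, zero_p = z_p))
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e)
    rep(NA_real_, length(par0)))
  b_age <- opt$par[2]; se_age <- se[2]
  if (!is.finite(se_age) || se_age <= 0)
    return(fit_row(feature_id, "zanb", n_used = length(y), note = note,
                   exclusion_reason = "singular_information",
                   zero_beta_age = z_b, zero_se_age = z_se, zero_p = z_p))
  fit_row(feature_id, "zanb", beta_age = b_age, se_age = se_age,
          p_wald = 2 * stats::pnorm(-abs(b_age / se_age)),
          beta_sex = opt$par[3], theta = exp(opt$par[4]),
          n_used = length(y), converged = TRUE, note = note,
          zero_beta_age = z_b, zero_se_age = z_se, zero_p = z_p)
}

#' Full per-gene age-association cascade
#'
#' Runs the whole differential-expression pipeline on a raw count matrix:
#' (1) remove features unexpressed in every sample; (2) linear branch --
#' log2(CPM) with zero pseudo-count, keep features with at least
#' `min_samples` values `>= log2cpm_threshold`, fit [fit_linear()] per
#' gene; (3) count branch -- rounded CPB, keep features with at least
#' `min_samples` values `>= cpb_threshold`, apply [nb_exclusion_filter()],
#' then route each remaining gene by the presence of a zero CPB value:
#' zero-free genes to [fit_nb()], zero-bearing genes to [fit_hurdle()].
#' Every exclusion is logged with its stage and reason.
#'
#' @param counts Raw feature x sample count matrix.
#' @param samples data.frame with columns `age` and `sex` aligned to the
#'   columns of `counts`.
#' @param lib_size Library sizes; default column sums.
#' @param log2cpm_threshold,cpb_threshold,min_samples Expression filters
#'   (defaults -3 / 125 in at least 10 samples).
#' @param max_zero_samples,median_floor NB-branch exclusion rules
#'   (defaults 50 zeros / median 630).
#' @return List: `linear` and `nb_family` fit tables, `exclusions`
#'   (feature_id, stage, reason), `n_unexpressed`, and the routing masks.
#' @export
fit_age_models <- function(counts, samples, lib_size = colSums(counts),
                           log2cpm_threshold = -3, cpb_threshold = 125,
                           min_samples = 10L, max_zero_samples = 50L,
                           median_floor = 630) {
  stopifnot(ncol(counts) == nrow(samples))
  age <- samples$age; sex <- samples$sex
  excl_df <- function(ids, stage, reason) data.frame(
    feature_id = ids, stage = rep_len(stage, length(ids)),
    reason = rep_len(reason, length(ids)), stringsAsFactors = FALSE)
  de <- drop_unexpressed(counts)
  excl <- list(excl_df(de$removed_ids, "unexpressed", "all_zero"))
  cts <- de$counts

  l2 <- to_cpm(cts, lib_size, log2 = TRUE, pseudo = 0)
  lin_keep <- filter_min_samples(l2, log2cpm_threshold, min_samples)
  excl <- c(excl, list(excl_df(rownames(cts)[!lin_keep], "linear_filter",
                               "below_log2cpm_threshold")))
  linear <- fit_linear_all(l2[lin_keep, , drop = FALSE], age, sex)

  cpb <- to_cpb(cts, lib_size)
  cpb_keep <- filter_min_samples(cpb, cpb_threshold, min_samples)
  excl <- c(excl, list(excl_df(rownames(cts)[!cpb_keep], "nb_filter",
                               "below_cpb_threshold")))
  cpb_f <- cpb[cpb_keep, , drop = FALSE]
  nx <- nb_exclusion_filter(cpb_f, max_zero_samples, median_floor)
  excl <- c(excl, list(excl_df(nx$feature_id[!nx$keep], "nb_exclusion",
                               nx$reason[!nx$keep])))
  cpb_f <- cpb_f[nx$keep, , drop = FALSE]

  has_zero <- rowSums(cpb_f == 0) > 0
  nb_rows <- lapply(which(!has_zero), function(i)
    fit_nb(cpb_f[i, ], age, sex, feature_id = rownames(cpb_f)[i]))
  hz_rows <- lapply(which(has_zero), function(i)
    fit_hurdle(cpb_f[i, ], age, sex, feature_id = rownames(cpb_f)[i]))
  nb_family <- do.call(rbind, c(nb_rows, hz_rows))
  if (is.null(nb_family)) nb_family <- fit_row(character(0), character(0))[0, ]
  rownames(nb_family) <- NULL

  exclusions <- do.call(rbind, excl)
  list(linear = linear, nb_family = nb_family, exclusions = exclusions,
       n_unexpressed = de$n_removed,
       routed_zanb = rownames(cpb_f)[has_zero],
       routed_nb = rownames(cpb_f)[!has_zero])
}

#' Consensus of the linear and negative binomial model families
#'
#' A gene is in the consensus set when its age coefficient is significant
#' (`p < alpha`) in both the linear family and the NB family (standard or
#' zero-adjusted) with the same sign; the direction label (up/down) is the
#' shared sign. Genes fit in only one family, or with discordant signs,
#' are not eligible.
#'
#' @param linear,nb_family Fit tables from [fit_age_models()].
#' @param alpha Significance threshold, default 0.01 (a conservative cut
#'   retaining only the strongest age associations).
#' @return data.frame per shared feature: betas and p-values from both
#'   families, `significant_linear`, `significant_nb_family`,
#'   `in_consensus`, `direction` ("up"/"down", NA outside the consensus).
#' @export
consensus <- function(linear, nb_family, alpha = 0.01) {
  lin <- linear[linear$converged, c("feature_id", "beta_age", "p_wald")]
  nbf <- nb_family[nb_family$converged,
                   c("feature_id", "model", "beta_age", "p_wald")]
  names(lin)[2:3] <- c("beta_linear", "p_linear")
  names(nbf)[3:4] <- c("beta_nb", "p_nb")
  m <- merge(lin, nbf, by = "feature_id", all = TRUE)
  m$significant_linear <- !is.na(m$p_linear) & m$p_linear < alpha
  m$significant_nb_family <- !is.na(m$p_nb) & m$p_nb < alpha
  sign_ok <- !is.na(m$beta_linear) & !is.na(m$beta_nb) &
    sign(m$beta_linear) == sign(m$beta_nb) & sign(m$beta_linear) != 0
  m$in_consensus <- m$significant_linear & m$significant_nb_family & sign_ok
  m$direction <- ifelse(m$in_consensus,
                        ifelse(m$beta_linear > 0, "up", "down"),
                        NA_character_)
  m[order(m$feature_id), , drop = FALSE]
}

#' Top-k features ranked by significance
#'
#' Ties broken by ascending p, then descending `|beta_age|`, then
#' lexicographic feature id.
#'
#' @param fits A fit table with `feature_id`, `beta_age`, `p_wald`.
#' @param k Number of rows to return.
#' @param direction Optional "up"/"down" restriction on the beta sign.
#' @return The top `k` rows of `fits`.
#' @export
top_features <- function(fits, k = 20L, direction = NULL) {
  f <- fits[fits$converged & !is.na(fits$p_wald), , drop = FALSE]
  if (!is.null(direction)) {
    f <- switch(direction,
                up = f[f$beta_age > 0, , drop = FALSE],
                down = f[f$beta_age < 0, , drop = FALSE],
                stop("direction must be 'up' or 'down'"))
  }
  ord <- order(f$p_wald, -abs(f$beta_age), f$feature_id)
  utils::head(f[ord, , drop = FALSE], k)
}
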