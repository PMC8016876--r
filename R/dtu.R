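#' Isoform-usage percentages within each gene
#'
#' Converts transcript-level counts into each isoform's percentage of its
#' gene's total counts per sample: `usage = 100 * transcript / gene
#' total`. Samples in which a gene has zero total counts are flagged
#' missing (`NA`) for all of that gene's transcripts. For genes with
#' positive totals the usages of a gene's transcripts sum to 100 by
#' construction, and are invariant to any per-sample rescaling of the
#' counts.
#'
#' @param iso_counts Transcript x sample count matrix.
#' @param tx2gene data.frame with columns `transcript_id`/`feature_id` and
#'   `gene_id`; every transcript in `iso_counts` must map to exactly one
#'   gene.
#' @return List: `usage` (transcript x sample percentage matrix, NA where
#'   the gene total is zero), `tx2gene` (aligned to the usage rows),
#'   `gene_totals` (gene x sample matrix).
#' @export
usage_percentages <- function(iso_counts, tx2gene) {
  idcol <- intersect(c("transcript_id", "feature_id"), names(tx2gene))[1]
  if (is.na(idcol)) stop("tx2gene needs a transcript_id/feature_id column")
  map <- tx2gene[[idcol]]
  missing_tx <- setdiff(rownames(iso_counts), map)
  if (length(missing_tx))
    stop("unmapped transcript(s): ",
         paste(utils::head(missing_tx, 5), collapse = ", "))
  gene <- tx2gene$gene_id[match(rownames(iso_counts), map)]
  totals <- rowsum(iso_counts, gene)
  tot_per_tx <- totals[match(gene, rownames(totals)), , drop = FALSE]
  usage <- 100 * iso_counts / tot_per_tx
  usage[tot_per_tx == 0] <- NA_real_
  dimnames(usage) <- dimnames(iso_counts)
  list(usage = usage,
       tx2gene = data.frame(transcript_id = rownames(iso_counts),
                            gene_id = gene, stringsAsFactors = FALSE),
       gene_totals = totals)
}

# OLS of y on intercept + age only (no sex column, so no rank deficiency).
ols_age_only <- function(y, age) {
  X <- cbind(1, age)
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  r <- y - drop(X %*% beta)
  df <- length(y) - 2L
  rss <- sum(r^2)
  sigma2 <- rss / df
  se <- sqrt(pmax(sigma2 * chol2inv(qr.R(qx))[2, 2], 0))
  if (rss <= 1e-12 * max(1, sum(y^2)) || !is.finite(se)) {
    b <- if (abs(beta[2]) < 1e-10) 0 else beta[2]
    se <- 0
    p <- if (b == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(beta[2] / se), df)
    b <- beta[2]
  }
  data.frame(beta_age = b, se_age = se, p_wald = p, converged = TRUE)
}

#' Differential transcript usage: per-isoform regression of usage on age
#'
#' Ordinary least squares of each transcript's usage percentage on
#' intercept + age (and sex by default when supplied, for consistency with
#' the gene-level models); two-sided Wald test on the age slope
#' (percentage points per year). Samples flagged missing (zero gene total)
#' are dropped per transcript; transcripts with fewer than `min_samples`
#' usable samples are skipped with a reason. The exploratory default
#' threshold is 0.05; pass `alpha = 0.01` for a genome-wide scan at the
#' conservative cut.
#'
#' @param usage A [usage_percentages()] result (or a bare usage matrix).
#' @param age,sex Covariates aligned to the columns; omit `sex` (or set
#'   `include_sex = FALSE`) for the age-only model.
#' @param alpha Significance threshold for the `significant` flag.
#' @param min_samples Minimum usable samples per transcript.
#' @param include_sex Include sex as a covariate.
#' @return data.frame per transcript: gene_id, usage_beta_age
#'   (percentage points/year), usage_se, usage_p, n_used, significant,
#'   skipped_reason.
#' @export
usage_regression <- function(usage, age, sex = NULL, alpha = 0.05,
                             min_samples = 10L, include_sex = !is.null(sex)) {
  um <- if (is.list(usage)) usage$usage else usage
  gene <- if (is.list(usage)) usage$tx2gene$gene_id else
    rep(NA_character_, nrow(um))
  if (include_sex && is.null(sex))
    stop("sex covariate requested but not supplied")
  rows <- lapply(seq_len(nrow(um)), function(i) {
    y <- um[i, ]
    keep <- !is.na(y)
    if (sum(keep) < min_samples)
      return(data.frame(transcript_id = rownames(um)[i], gene_id = gene[i],
                        usage_beta_age = NA_real_, usage_se = NA_real_,
                        usage_p = NA_real_, n_used = sum(keep),
                        significant = FALSE,
                        skipped_reason = "too_few_samples",
                        stringsAsFactors = FALSE))
    f <- if (include_sex) fit_linear(y[keep], age[keep], sex[keep])
         else ols_age_only(y[keep], age[keep])
    data.frame(transcript_id = rownames(um)[i], gene_id = gene[i],
               usage_beta_age = f$beta_age, usage_se = f$se_age,
               usage_p = f$p_wald, n_used = sum(keep),
               significant = isTRUE(f$converged) & !is.na(f$p_wald) &
                 f$p_wald < alpha,
               skipped_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Absolute-scale transcript regression on log2(TPM + 1)
#'
#' The companion to [usage_regression()]: per-transcript OLS of
#' log2(TPM + 1) on intercept + age (+ sex), enabling the contrast between
#' an isoform's share of its gene (which may drift with age) and its
#' absolute abundance (which may stay flat when the gene total moves in
#' step).
#'
#' @param log2tpm1 Transcript x sample matrix on the log2(TPM + 1) scale
#'   ([to_log2tpm1()]), or a non-negative TPM matrix if
#'   `already_log = FALSE`.
#' @inheritParams usage_regression
#' @param already_log Whether the input is already log2(TPM + 1).
#' @return data.frame per transcript: abs_beta_age (log2(TPM+1)/year),
#'   abs_se, abs_p.
#' @export
abs_regression <- function(log2tpm1, age, sex = NULL, already_log = TRUE,
                           include_sex = !is.null(sex)) {
  m <- if (already_log) log2tpm1 else to_log2tpm1(log2tpm1)
  if (any(m < 0)) stop("log2(TPM + 1) values must be non-negative")
  if (include_sex) {
    f <- fit_linear_all(m, age, sex)
    out <- data.frame(transcript_id = f$feature_id, abs_beta_age = f$beta_age,
                      abs_se = f$se_age, abs_p = f$p_wald,
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(m)), function(i) {
      f <- ols_age_only(m[i, ], age)
      data.frame(transcript_id = rownames(m)[i], abs_beta_age = f$beta_age,
                 abs_se = f$se_age, abs_p = f$p_wald, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
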