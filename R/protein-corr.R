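#' Per-gene mRNA-protein correlation across samples
#'
#' Correlates each gene's protein abundance vector with its mRNA vector
#' (log2CPM) across the shared samples. Pairs with fewer than 3 shared
#' samples are excluded; zero-variance vectors yield an undefined `r` and
#' are flagged. Pearson by default (the correlations are compared with
#' linear regression coefficients downstream); Spearman available.
#'
#' @param mrna Gene x sample matrix of mRNA abundances (log scale).
#' @param protein Gene x sample matrix of relative protein abundances
#'   (log scale); `log_input = TRUE` applies log2 on entry for matrices
#'   supplied on the raw scale.
#' @param method "pearson" or "spearman".
#' @param log_input Log2-transform the protein matrix on input.
#' @return List: `pairs` (gene_id, r, n_shared, flag), `summary` (n, mean,
#'   sd, skewness of the defined correlations), `histogram` (bin mids and
#'   counts over [-1, 1]).
#' @export
pairwise_correlation <- function(mrna, protein,
                                 method = c("pearson", "spearman"),
                                 log_input = FALSE) {
  method <- match.arg(method)
  if (log_input) protein <- base::log2(protein)
  genes <- intersect(rownames(mrna), rownames(protein))
  if (!length(genes)) stop("no shared gene ids between mrna and protein")
  samp <- intersect(colnames(mrna), colnames(protein))
  if (length(samp) < 3) stop("fewer than 3 shared samples")
  rows <- lapply(genes, function(g) {
    x <- mrna[g, samp]; y <- protein[g, samp]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3)
      return(data.frame(gene_id = g, r = NA_real_, n_shared = sum(ok),
                        flag = "too_few_samples", stringsAsFactors = FALSE))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(gene_id = g, r = NA_real_, n_shared = sum(ok),
                        flag = "zero_variance", stringsAsFactors = FALSE))
    data.frame(gene_id = g, r = stats::cor(x[ok], y[ok], method = method),
               n_shared = sum(ok), flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  r <- pairs$r[!is.na(pairs$r)]
  skew <- if (length(r) > 2 && stats::sd(r) > 0)
    mean((r - mean(r))^3) / stats::sd(r)^3 else NA_real_
  h <- graphics::hist(r, breaks = seq(-1, 1, by = 0.1), plot = FALSE)
  list(pairs = pairs,
       summary = list(n = length(r), mean = mean(r), sd = stats::sd(r),
                      skewness = skew),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Age-coefficient scatter: protein beta vs mRNA beta
#'
#' Fits the same linear age model used for mRNA ([fit_linear()], intercept
#' + age + sex) to each gene's protein abundance, pairs the two age
#' coefficients per gene, and reports their correlation -- for the full
#' protein-matched set and for a caller-supplied subset (typically the
#' mRNAs significantly associated with age).
#'
#' @param mrna_fits Linear fit table for the mRNAs ([fit_age_models()]
#'   `$linear`), providing `feature_id` and `beta_age`.
#' @param protein Gene x sample protein matrix.
#' @param age,sex Covariates over the protein columns.
#' @param subset Optional gene ids defining the highlighted subset.
#' @return List: `table` (gene_id, mrna_beta_age, protein_beta_age,
#'   in_subset), `r_full`, `r_subset` (NA when no subset given),
#'   `n_dropped` (genes in `mrna_fits` without protein data).
#' @export
beta_vs_beta <- function(mrna_fits, protein, age, sex, subset = NULL) {
  pf <- fit_linear_all(protein, age, sex)
  m <- merge(data.frame(feature_id = mrna_fits$feature_id,
                        mrna_beta_age = mrna_fits$beta_age,
                        stringsAsFactors = FALSE),
             data.frame(feature_id = pf$feature_id,
                        protein_beta_age = pf$beta_age,
                        stringsAsFactors = FALSE),
             by = "feature_id")
  n_dropped <- nrow(mrna_fits) - nrow(m)
  m$in_subset <- m$feature_id %in% subset
  ok <- stats::complete.cases(m[, c("mrna_beta_age", "protein_beta_age")])
  r_full <- if (sum(ok) > 2)
    stats::cor(m$mrna_beta_age[ok], m$protein_beta_age[ok]) else NA_real_
  sub_ok <- ok & m$in_subset
  r_subset <- if (sum(sub_ok) > 2)
    stats::cor(m$mrna_beta_age[sub_ok], m$protein_beta_age[sub_ok]) else NA_real_
  names(m)[1] <- "gene_id"
  list(table = m, r_full = r_full, r_subset = r_subset, n_dropped = n_dropped)
}

#' Random gene-set control for correlation summaries
#'
#' Samples `k` rows uniformly without replacement from a pairs/beta table
#' and recomputes the same summaries, providing the null contrast for a
#' highlighted subset (does the age-significant subset correlate better
#' than a random set of the same size?). The seed is recorded in the
#' output so a draw is reproducible.
#'
#' @param pairs A data.frame of per-gene records; numeric columns `r`,
#'   or the beta pair `mrna_beta_age`/`protein_beta_age`, are summarized
#'   when present.
#' @param k Subset size; must not exceed `nrow(pairs)`.
#' @param seed Integer seed for the draw.
#' @return List: `genes` (sampled ids when a gene_id column exists),
#'   `subset` (the sampled rows), `mean_r`, `r_beta` (NA when the
#'   relevant columns are absent), `k`, `seed`.
#' @export
random_set_control <- function(pairs, k, seed = 1L) {
  if (k > nrow(pairs)) stop("k exceeds the number of available pairs")
  set.seed(seed)
  idx <- sample.int(nrow(pairs), k)
  sub <- pairs[idx, , drop = FALSE]
  mean_r <- if ("r" %in% names(sub)) mean(sub$r, na.rm = TRUE) else NA_real_
  r_beta <- if (all(c("mrna_beta_age", "protein_beta_age") %in% names(sub))) {
    ok <- stats::complete.cases(sub[, c("mrna_beta_age", "protein_beta_age")])
    if (sum(ok) > 2)
      stats::cor(sub$mrna_beta_age[ok], sub$protein_beta_age[ok]) else NA_real_
  } else NA_real_
  list(genes = if ("gene_id" %in% names(sub)) sub$gene_id else NULL,
       subset = sub, mean_r = mean_r, r_beta = r_beta, k = k, seed = seed)
}
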