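#' Volcano-plot table from a fit set
#'
#' Classifies every converged fit by significance and effect direction:
#' "up" (`p < alpha`, positive age beta), "down" (negative), "ns"
#' otherwise. `-log10(p)` is capped at `cap` so p = 0 stays plottable.
#'
#' @param fits Fit table with `feature_id`, `beta_age`, `p_wald`,
#'   `converged`.
#' @param alpha Significance threshold.
#' @param cap Ceiling for `-log10(p)`.
#' @return data.frame: feature_id, beta_age, neg_log10_p, class.
#' @export
volcano_table <- function(fits, alpha = 0.01, cap = 300) {
  f <- fits[fits$converged & !is.na(fits$p_wald), , drop = FALSE]
  nlp <- pmin(-base::log10(f$p_wald), cap)
  cls <- rep("ns", nrow(f))
  cls[f$p_wald < alpha & f$beta_age > 0] <- "up"
  cls[f$p_wald < alpha & f$beta_age < 0] <- "down"
  data.frame(feature_id = f$feature_id, beta_age = f$beta_age,
             neg_log10_p = nlp, class = cls, stringsAsFactors = FALSE)
}

#' Row-wise z-scores with correlation-distance complete-linkage clustering
#'
#' Standardizes each row to mean 0, sample (n-1) SD 1, then orders rows by
#' complete-linkage hierarchical clustering on the distance `1 - Pearson
#' correlation` between rows -- the transform behind the heat-map of
#' age-associated genes. Constant rows cannot be standardized; they are
#' flagged and placed last. Deterministic given the input: ties are
#' resolved by input row index (the ordering [stats::hclust] inherits from
#' the distance layout), and leaf order is the standard recursive
#' left-subtree-first traversal.
#'
#' @param mat Feature x sample matrix with at least 2 samples.
#' @return List: `z` (z-scored matrix in clustered order, constant rows
#'   last and untouched), `order` (row indices of the input), `hclust`
#'   (the tree over the non-constant rows, NULL if fewer than 2),
#'   `constant_rows` (ids).
#' @export
zscore_cluster <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  sds <- apply(mat, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  z <- mat
  z[!const, ] <- t(scale(t(mat[!const, , drop = FALSE])))
  hc <- NULL
  ord_var <- which(!const)
  if (sum(!const) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(mat[!const, , drop = FALSE])))
    hc <- stats::hclust(d, method = "complete")
    ord_var <- which(!const)[hc$order]
  }
  ord <- c(ord_var, which(const))
  list(z = z[ord, , drop = FALSE], order = ord, hclust = hc,
       constant_rows = rownames(mat)[const])
}

#' Two-sided Kruskal-Wallis comparison of two groups
#'
#' Rank-based H statistic with ties correction; p-value from the
#' chi-square distribution with 1 degree of freedom (two groups). Used for
#' small-sample young-vs-old validation comparisons where a parametric
#' test's assumptions are not defensible. When every value is identical
#' the statistic is 0 and p = 1.
#'
#' @param values_young,values_old Numeric vectors, at least 2 values each.
#' @return List: `H`, `p`.
#' @export
kruskal_wallis <- function(values_young, values_old) {
  if (length(values_young) < 2 || length(values_old) < 2)
    stop("need at least 2 values per group")
  all_v <- c(values_young, values_old)
  if (length(unique(all_v)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(list(values_young, values_old))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Relative expression against a reference transcript
#'
#' Elementwise target/reference ratio (e.g. a transcript's qPCR level
#' relative to the GAPDH housekeeping mRNA). Zero or negative reference
#' entries cannot normalize anything and are flagged missing.
#'
#' @param target_values,reference_values Numeric vectors, same length.
#' @return Numeric vector of ratios, NA where the reference is not
#'   strictly positive (with a warning).
#' @export
relative_expression <- function(target_values, reference_values) {
  stopifnot(length(target_values) == length(reference_values))
  bad <- !(reference_values > 0)
  out <- target_values / reference_values
  if (any(bad)) {
    out[bad] <- NA_real_
    warning(sum(bad), " reference value(s) not strictly positive; flagged missing")
  }
  out
}
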