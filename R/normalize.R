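#' Counts per million, optionally log2-transformed
#'
#' `CPM[g, s] = counts[g, s] / library_size[s] * 1e6`. With `log2 = TRUE`
#' and `pseudo = 0`, zero counts map to `-Inf` -- a sentinel below any
#' finite threshold, so such samples always fail `>=` expression filters;
#' a positive pseudo-count gives finite values for plotting. The default
#' `pseudo = 0` is what makes the printed filter threshold exact: 10 reads
#' in an 80-million-read library give CPM 0.125 and log2(CPM) = -3.
#'
#' @param counts Non-negative feature x sample matrix.
#' @param lib_size Per-sample library sizes (total aligned reads); default
#'   column sums of `counts`.
#' @param log2 Return log2(CPM + pseudo) instead of CPM.
#' @param pseudo Non-negative pseudo-count added before the log.
#' @return Numeric matrix, same shape as `counts`, with attribute `unit`
#'   ("CPM" or "log2CPM") and `pseudo`.
#' @export
to_cpm <- function(counts, lib_size = colSums(counts), log2 = FALSE, pseudo = 0) {
  check_counts(counts)
  if (any(lib_size <= 0)) {
    bad <- colnames(counts)[lib_size <= 0]
    stop("zero or negative library size for sample(s): ",
         paste(bad, collapse = ", "))
  }
  if (pseudo < 0) stop("pseudo must be non-negative")
  res <- sweep(counts, 2, lib_size, "/") * 1e6
  if (log2) res <- base::log2(res + pseudo)
  structure(res, unit = if (log2) "log2CPM" else "CPM", pseudo = pseudo)
}

#' Counts per billion, rounded to the nearest integer
#'
#' `CPB[g, s] = round(counts[g, s] / library_size[s] * 1e9)` with a
#' half-up tie rule (87.5 -> 88), producing the non-negative integers a
#' negative binomial regression requires. Rounding on the CPB rather than
#' the CPM scale keeps the relative rounding error small.
#'
#' @inheritParams to_cpm
#' @return Numeric matrix of whole numbers with attribute `unit =
#'   "CPB_rounded"`.
#' @export
to_cpb <- function(counts, lib_size = colSums(counts)) {
  check_counts(counts)
  if (any(lib_size <= 0)) {
    bad <- colnames(counts)[lib_size <= 0]
    stop("zero or negative library size for sample(s): ",
         paste(bad, collapse = ", "))
  }
  res <- floor(sweep(counts, 2, lib_size, "/") * 1e9 + 0.5)
  structure(res, unit = "CPB_rounded")
}

#' Transcripts per million from counts and effective lengths
#'
#' `TPM[t, s] = rate / sum_t(rate) * 1e6` with `rate = counts / length`.
#' [to_log2tpm1()] applies the `log2(TPM + 1)` transform used for
#' absolute-scale transcript regressions. When no quantifier-supplied TPM
#' table is available, effective lengths must be provided.
#'
#' @inheritParams to_cpm
#' @param eff_length Per-feature effective lengths (positive).
#' @return Numeric matrix with attribute `unit`.
#' @export
to_tpm <- function(counts, eff_length) {
  check_counts(counts)
  if (length(eff_length) != nrow(counts) || any(eff_length <= 0))
    stop("eff_length must be positive and match the number of features")
  rate <- counts / eff_length
  res <- sweep(rate, 2, colSums(rate), "/") * 1e6
  res[, colSums(rate) == 0] <- 0
  structure(res, unit = "TPM")
}

#' @rdname to_tpm
#' @param tpm A TPM matrix (non-negative).
#' @export
to_log2tpm1 <- function(tpm) {
  if (any(tpm < 0)) stop("negative TPM values")
  structure(base::log2(tpm + 1), unit = "log2TPM1")
}

#' Remove features with zero counts in every sample
#'
#' @param counts Feature x sample count matrix.
#' @return List: `counts` (retained rows), `n_removed`, `removed_ids`.
#' @export
drop_unexpressed <- function(counts) {
  check_counts(counts)
  keep <- rowSums(counts) > 0
  list(counts = counts[keep, , drop = FALSE],
       n_removed = sum(!keep),
       removed_ids = rownames(counts)[!keep])
}

#' Minimum-expression filter: at least `min_samples` samples at or above a
#' threshold
#'
#' The inclusive `>=` comparison matches the filter as printed: features
#' with at least ten log2(CPM) values of >= -3 (linear branch) or at least
#' ten CPB values of >= 125 (count branch) are retained. `-Inf` sentinel
#' entries (zero counts under a zero pseudo-count) fail every threshold.
#'
#' @param values Normalized feature x sample matrix.
#' @param threshold Scalar threshold.
#' @param min_samples Minimum number of samples meeting it.
#' @return Logical vector, one entry per feature (TRUE = retained).
#' @export
filter_min_samples <- function(values, threshold, min_samples = 10L) {
  if (min_samples > ncol(values))
    stop("min_samples exceeds the number of samples")
  rowSums(values >= threshold) >= min_samples
}

#' Exclusion filter for the negative binomial branch
#'
#' Excludes features whose rounded CPB is zero in more than
#' `max_zero_samples` samples (overabundant zeros prevent model
#' construction) or whose median CPB falls below `median_floor` (very low
#' expression). Each exclusion carries its reason.
#'
#' @param cpb Rounded-CPB feature x sample matrix ([to_cpb()]).
#' @param max_zero_samples Zero-count sample cap; default 50.
#' @param median_floor Median CPB floor; default 630.
#' @return data.frame: feature_id, keep, reason ("excess_zeros",
#'   "low_median", or NA when kept).
#' @export
nb_exclusion_filter <- function(cpb, max_zero_samples = 50L, median_floor = 630) {
  n_zero <- rowSums(cpb == 0)
  med <- apply(cpb, 1, stats::median)
  reason <- rep(NA_character_, nrow(cpb))
  reason[med < median_floor] <- "low_median"
  reason[n_zero > max_zero_samples] <- "excess_zeros"
  data.frame(feature_id = rownames(cpb),
             keep = is.na(reason),
             reason = reason,
             stringsAsFactors = FALSE)
}

check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}

#' Read a transcript-to-gene (or exon-to-gene) map
#'
#' @param path Two-column tab-separated file (feature_id, gene_id), with or
#'   without a header.
#' @return data.frame with columns named after the first row if it looks
#'   like a header, else `feature_id`, `gene_id`.
#' @export
read_feature_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature map needs two columns")
  df <- df[, 1:2]
  if (identical(tolower(df[1, 2]), "gene_id")) {
    names(df) <- as.character(df[1, ])
    df <- df[-1, , drop = FALSE]
  } else names(df) <- c("feature_id", "gene_id")
  rownames(df) <- NULL
  df
}
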