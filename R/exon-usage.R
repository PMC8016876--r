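#' Group-wise differential exon usage test
#'
#' For each exon of each multi-exon gene, builds the two-part response
#' (this-exon count, rest-of-gene count) per sample and fits a negative
#' binomial GLM with per-sample fixed effects, a `bin` term distinguishing
#' the exon from the rest of its gene, and a group:bin interaction
#' indicator. The sample effects absorb each sample's gene total (which
#' carries the gene-level biological variability shared by both parts), so
#' the interaction isolates a change in the exon's *share* of the gene
#' between groups; it is tested by likelihood ratio against the
#' no-interaction model with the dispersion shared between the two fits
#' (ML-estimated on the full model). P-values are Benjamini-Hochberg
#' adjusted across all exons tested in the run; an exon is called
#' significant at `fdr < fdr_threshold` (default 0.1).
#'
#' Skipped with a reason: genes with a single exon, and genes whose total
#' counts are zero throughout one group. Samples with a zero gene total
#' are dropped for that gene's exons. If the NB dispersion fit fails
#' (e.g. equal counts), the exon is tested with a Poisson likelihood and
#' flagged in `note`.
#'
#' @param exon_counts Exon x sample count matrix.
#' @param exon2gene data.frame with columns `exon_id`/`feature_id` and
#'   `gene_id`.
#' @param groups Character/factor vector over samples with two levels
#'   (e.g. "young"/"old"); samples with `NA` group are dropped.
#' @param fdr_threshold FDR cut for the `significant` flag.
#' @param annotation Optional data.frame keyed by exon_id with coordinate
#'   columns (chrom, start, end, strand), carried into the result; use
#'   [read_exon_annotation()] to load one (coordinates are normalized to
#'   0-based half-open).
#' @return List: `results` (data.frame per tested exon: gene_id, exon_id,
#'   mean usage per group, lr_stat, p, fdr, significant, note) and
#'   `skipped` (exon_id/gene_id with reasons).
#' @export
exon_usage_test <- function(exon_counts, exon2gene, groups,
                            fdr_threshold = 0.1, annotation = NULL) {
  idcol <- intersect(c("exon_id", "feature_id"), names(exon2gene))[1]
  if (is.na(idcol)) stop("exon2gene needs an exon_id/feature_id column")
  map_ids <- exon2gene[[idcol]]
  missing_ex <- setdiff(rownames(exon_counts), map_ids)
  if (length(missing_ex))
    stop("unmapped exon(s): ", paste(utils::head(missing_ex, 5), collapse = ", "))
  gene <- exon2gene$gene_id[match(rownames(exon_counts), map_ids)]

  use <- !is.na(groups)
  grp <- factor(groups[use])
  if (nlevels(grp) != 2) stop("groups must have exactly two levels")
  if (any(table(grp) < 2)) stop("need at least 2 samples per group")
  cts <- exon_counts[, use, drop = FALSE]
  n <- ncol(cts)

  totals <- rowsum(cts, gene)
  res_rows <- list(); skip_rows <- list()
  for (g in rownames(totals)) {
    ex_idx <- which(gene == g)
    if (length(ex_idx) < 2) {
      skip_rows[[length(skip_rows) + 1L]] <- data.frame(
        gene_id = g, exon_id = rownames(cts)[ex_idx],
        reason = "single_exon_gene", stringsAsFactors = FALSE)
      next
    }
    tot <- totals[g, ]
    if (any(tapply(tot, grp, sum) == 0)) {
      skip_rows[[length(skip_rows) + 1L]] <- data.frame(
        gene_id = g, exon_id = rownames(cts)[ex_idx],
        reason = "zero_group_total", stringsAsFactors = FALSE)
      next
    }
    keep_s <- tot > 0
    ns <- sum(keep_s)
    grp_g <- grp[keep_s]
    for (i in ex_idx) {
      exon <- cts[i, keep_s]
      rest <- tot[keep_s] - exon
      y <- c(exon, rest)
      bin <- factor(rep(c("exon", "rest"), each = ns), c("rest", "exon"))
      samp <- factor(rep(seq_len(ns), 2))
      # 1-df interaction: exon bin in the second group
      inter <- as.numeric(bin == "exon" & rep(grp_g, 2) == levels(grp)[2])
      d <- data.frame(y = y, samp = samp, bin = bin, inter = inter)
      t_full <- tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ samp + bin + inter, data = d)),
        error = function(e) NULL)
      note <- NA_character_
      if (!is.null(t_full)) {
        fam <- MASS::negative.binomial(t_full$theta)
      } else {
        fam <- stats::poisson()
        note <- "poisson_likelihood"
      }
      f_full <- tryCatch(
        suppressWarnings(stats::glm(y ~ samp + bin + inter, family = fam,
                                    data = d)),
        error = function(e) NULL)
      f_red <- tryCatch(
        suppressWarnings(stats::glm(y ~ samp + bin, family = fam, data = d)),
        error = function(e) NULL)
      if (is.null(f_full) || is.null(f_red)) {
        skip_rows[[length(skip_rows) + 1L]] <- data.frame(
          gene_id = g, exon_id = rownames(cts)[i], reason = "fit_failure",
          stringsAsFactors = FALSE)
        next
      }
      lr <- max(f_red$deviance - f_full$deviance, 0)
      p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
      usage <- exon / tot[keep_s]
      mu <- tapply(usage, grp_g, mean, na.rm = TRUE)
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        gene_id = g, exon_id = rownames(cts)[i],
        mean_usage_1 = mu[[1]], mean_usage_2 = mu[[2]],
        lr_stat = lr, p = p, note = note, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res_rows)
  if (!is.null(results)) {
    names(results)[names(results) == "mean_usage_1"] <-
      paste0("mean_usage_", levels(grp)[1])
    names(results)[names(results) == "mean_usage_2"] <-
      paste0("mean_usage_", levels(grp)[2])
    results$fdr <- stats::p.adjust(results$p, method = "BH")
    results$significant <- results$fdr < fdr_threshold
    if (!is.null(annotation)) {
      idx <- match(results$exon_id, annotation$exon_id)
      for (col in setdiff(names(annotation), c("exon_id", "gene_id")))
        results[[col]] <- annotation[[col]][idx]
    }
    rownames(results) <- NULL
  } else {
    results <- data.frame()
  }
  skipped <- if (length(skip_rows)) do.call(rbind, skip_rows) else data.frame()
  list(results = results, skipped = skipped)
}

#' Genes shared between exon-usage and transcript-usage hits
#'
#' Intersects the genes with significant differential exon usage (at
#' `fdr_threshold`) with the genes owning a transcript whose usage changes
#' significantly with age (at `dtu_alpha`); both thresholds are
#' parameters, since group-wise exon results and continuous-age DTU are
#' commonly screened at different stringencies.
#'
#' @param exon_res An [exon_usage_test()] result (or its `results` table).
#' @param dtu_res A [usage_regression()] result table.
#' @param fdr_threshold FDR cut applied to the exon results.
#' @param dtu_alpha P-value cut applied to the transcript-usage results.
#' @return data.frame of shared genes with the best (smallest) exon FDR
#'   and transcript usage p per gene.
#' @export
intersect_with_dtu <- function(exon_res, dtu_res, fdr_threshold = 0.1,
                               dtu_alpha = 0.01) {
  er <- if (is.list(exon_res) && !is.data.frame(exon_res)) exon_res$results
        else exon_res
  if (!nrow(er)) return(data.frame(gene_id = character(0)))
  ex_genes <- unique(er$gene_id[er$fdr < fdr_threshold])
  dt <- dtu_res[!is.na(dtu_res$usage_p) & dtu_res$usage_p < dtu_alpha, ,
                drop = FALSE]
  dtu_genes <- unique(dt$gene_id)
  shared <- intersect(ex_genes, dtu_genes)
  if (!length(shared)) return(data.frame(gene_id = character(0)))
  best_fdr <- vapply(shared, function(g) min(er$fdr[er$gene_id == g]), 0)
  best_p <- vapply(shared, function(g) min(dt$usage_p[dt$gene_id == g]), 0)
  out <- data.frame(gene_id = shared, exon_fdr = best_fdr,
                    dtu_usage_p = best_p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Read exon annotation from BED or a flattened exon table
#'
#' BED input (no header, columns chrom/start/end/name[/score/strand]) is
#' already 0-based half-open; a flattened tab-separated table with a
#' header (gene_id, exon_id, chrom, start, end, strand) is assumed
#' 1-based inclusive and converted, so exported coordinates are uniformly
#' 0-based half-open.
#'
#' @param path Input file.
#' @param format "bed" or "table"; guessed from the extension by default.
#' @return data.frame: exon_id, gene_id (NA for BED without one), chrom,
#'   start, end, strand.
#' @export
read_exon_annotation <- function(path, format = c("auto", "bed", "table")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "table"
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(exon_id = if (ncol(df) >= 4) df[[4]] else
                        sprintf("exon%05d", seq_len(nrow(df))),
                      gene_id = NA_character_,
                      chrom = df[[1]], start = df[[2]], end = df[[3]],
                      strand = if (ncol(df) >= 6) df[[6]] else "*",
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "exon_id", "chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("exon table missing columns: ", paste(miss, collapse = ", "))
    out <- data.frame(exon_id = df$exon_id, gene_id = df$gene_id,
                      chrom = df$chrom, start = df$start - 1L, end = df$end,
                      strand = if ("strand" %in% names(df)) df$strand else "*",
                      stringsAsFactors = FALSE)
  }
  out
}
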