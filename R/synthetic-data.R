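#' Simulation configuration for the synthetic muscle-aging cohort
#'
#' Builds the parameter set for [simulate_counts()] and its companions.
#' Defaults emulate the study design the pipeline targets: 53 healthy donors
#' aged 22--83 years, bulk RNA-seq counts that follow a negative binomial
#' distribution with gene-wise dispersion, a minority of genes whose
#' log-scale expression drifts linearly with age (most of them upward),
#' a small set of genes with structural (true) zeros, isoform-usage
#' proportions that drift with age, and protein abundances coupled to their
#' mRNA at a tunable correlation.
#'
#' @param n_samples Number of donors.
#' @param age_range Length-2 numeric, youngest and oldest age in years.
#' @param n_genes Number of genes.
#' @param frac_age_assoc Proportion of genes given a non-zero age effect.
#' @param beta_age_effect Magnitude of the true per-year log-scale age
#'   coefficient for age-associated genes.
#' @param frac_positive Proportion of age-associated genes whose effect is
#'   positive (expression rises with age).
#' @param dispersion_range Range of the NB size parameter `k`
#'   (variance = mu + mu^2/k); drawn uniformly per gene.
#' @param baseline_mean_range Range of expected counts at mid-cohort age
#'   (log-uniform per gene), before library-size scaling.
#' @param frac_structural_zero_genes Proportion of genes given a structural
#'   zero pattern (a fixed random subset of samples forced to zero).
#' @param zero_frac_range Range of the per-gene fraction of samples masked
#'   to zero for structural-zero genes.
#' @param library_size Target reads per sample; expected counts are scaled
#'   by one global factor so mean per-sample totals approximate this.
#'   `NULL` disables scaling (baseline means are then used as-is).
#' @param n_transcripts_per_gene Integer range of isoforms per gene.
#' @param frac_usage_drift Proportion of multi-isoform genes whose usage
#'   proportions drift with age.
#' @param usage_drift_magnitude Usage drift, percentage points per year,
#'   applied to the drifting isoform (sign drawn at random).
#' @param n_exons_per_gene Integer range of exon bins per gene.
#' @param frac_exon_skip Proportion of genes given one exon whose usage
#'   share changes with age (exon skipping/inclusion).
#' @param exon_skip_magnitude Exon-usage drift, percentage points per year.
#' @param protein_corr_target Target Pearson correlation between protein
#'   abundance and log2(CPM+1) for protein-coupled genes; in [-1, 1].
#' @param beta_sex_effect Log-scale sex effect (0/1 coding, 0 = reference);
#'   0 by default, so age and sex are independent signals.
#' @param ages Optional fixed age vector (overrides uniform draws) for
#'   exactly reproducible examples.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   bit-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 53,
                       age_range = c(22, 83),
                       n_genes = 2000,
                       frac_age_assoc = 0.1,
                       beta_age_effect = 0.02,
                       frac_positive = 0.92,
                       dispersion_range = c(2, 20),
                       baseline_mean_range = c(20, 500),
                       frac_structural_zero_genes = 0.05,
                       zero_frac_range = c(0.2, 0.6),
                       library_size = 5e6,
                       n_transcripts_per_gene = c(1, 4),
                       frac_usage_drift = 0.1,
                       usage_drift_magnitude = 0.3,
                       n_exons_per_gene = c(3, 8),
                       frac_exon_skip = 0.1,
                       exon_skip_magnitude = 0.4,
                       protein_corr_target = 0.6,
                       beta_sex_effect = 0,
                       ages = NULL,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
    n_genes = as.integer(n_genes), frac_age_assoc = frac_age_assoc,
    beta_age_effect = beta_age_effect, frac_positive = frac_positive,
    dispersion_range = as.numeric(dispersion_range),
    baseline_mean_range = as.numeric(baseline_mean_range),
    frac_structural_zero_genes = frac_structural_zero_genes,
    zero_frac_range = as.numeric(zero_frac_range),
    library_size = library_size,
    n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
    frac_usage_drift = frac_usage_drift,
    usage_drift_magnitude = usage_drift_magnitude,
    n_exons_per_gene = as.integer(n_exons_per_gene),
    frac_exon_skip = frac_exon_skip,
    exon_skip_magnitude = exon_skip_magnitude,
    protein_corr_target = protein_corr_target,
    beta_sex_effect = beta_sex_effect,
    ages = ages, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c("frac_age_assoc", "frac_positive", "frac_structural_zero_genes",
             "frac_usage_drift", "frac_exon_skip")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a proportion in [0, 1]", p))
  }
  if (cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must satisfy min < max")
  if (!is.null(cfg$library_size) && cfg$library_size <= 0)
    stop("library_size must be positive")
  if (abs(cfg$protein_corr_target) > 1)
    stop("protein_corr_target must lie in [-1, 1]")
  if (cfg$n_samples < 4) stop("need at least 4 samples")
  if (any(cfg$dispersion_range <= 0)) stop("dispersion_range must be > 0")
  if (any(cfg$baseline_mean_range <= 0)) stop("baseline_mean_range must be > 0")
  if (!is.null(cfg$ages) && length(cfg$ages) != cfg$n_samples)
    stop("'ages' must have length n_samples")
  invisible(cfg)
}

#' Simulate a gene-level count matrix with known ground truth
#'
#' Counts are drawn per gene and sample from a negative binomial
#' distribution, `counts[g, s] ~ NB(mu = m_g * exp(b_g * (age_s - mid) +
#' c_g * sex_s), size = k_g)`, where `m_g` is the gene's baseline mean at
#' mid-cohort age, `b_g` its per-year log-scale age effect (0 for
#' non-age-associated genes), and `k_g` its dispersion (size). Expected
#' counts are rescaled by one global factor so that mean per-sample totals
#' approximate `library_size`. Structural-zero genes have a fixed random
#' subset of samples forced to zero; the mask is recorded in the truth
#' table.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_data` with elements `counts` (integer gene
#'   x sample matrix), `samples` (data.frame: sample_id, age, sex, group),
#'   and `truth` (data.frame of per-gene generating parameters; the
#'   structural-zero mask is the list column `zero_samples`).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  G <- config$n_genes

  ages <- if (is.null(config$ages)) {
    stats::runif(n, config$age_range[1], config$age_range[2])
  } else as.numeric(config$ages)
  sex <- stats::rbinom(n, 1, 0.5)
  if (length(unique(sex)) == 1L) sex[1] <- 1L - sex[1]
  sample_id <- sprintf("S%03d", seq_len(n))
  gene_id <- sprintf("G%05d", seq_len(G))

  lo <- log(config$baseline_mean_range)
  baseline <- exp(stats::runif(G, lo[1], lo[2]))
  size <- stats::runif(G, config$dispersion_range[1], config$dispersion_range[2])

  n_assoc <- round(config$frac_age_assoc * G)
  assoc <- sample.int(G, n_assoc)
  beta_age <- numeric(G)
  if (n_assoc > 0) {
    sgn <- ifelse(stats::runif(n_assoc) < config$frac_positive, 1, -1)
    beta_age[assoc] <- sgn * config$beta_age_effect
  }
  beta_sex <- rep(config$beta_sex_effect, G)

  mid <- mean(config$age_range)
  eta <- outer(beta_age, ages - mid) + outer(beta_sex, sex)
  mu <- baseline * exp(eta)
  bad <- !is.finite(mu) | mu > 1e12
  if (any(bad)) {
    g <- gene_id[which(rowSums(bad) > 0)[1]]
    stop(sprintf("non-finite or overflowing NB mean for gene %s (|beta * age| too large)", g))
  }
  if (!is.null(config$library_size)) {
    mu <- mu * (config$library_size / mean(colSums(mu)))
  }

  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = size), nrow = G,
                   dimnames = list(gene_id, sample_id))

  n_zero_genes <- round(config$frac_structural_zero_genes * G)
  zero_genes <- if (n_zero_genes > 0) sample.int(G, n_zero_genes) else integer(0)
  zero_samples <- vector("list", G)
  for (g in zero_genes) {
    frac <- stats::runif(1, config$zero_frac_range[1], config$zero_frac_range[2])
    m <- max(1L, round(frac * n))
    idx <- sort(sample.int(n, m))
    counts[g, idx] <- 0L
    zero_samples[[g]] <- sample_id[idx]
  }

  samples <- data.frame(sample_id = sample_id, age = ages, sex = sex,
                        group = NA_character_, stringsAsFactors = FALSE)
  samples$group <- age_groups(ages)

  truth <- data.frame(
    gene_id = gene_id,
    baseline_mean = baseline,
    scaled_mean = if (is.null(config$library_size)) baseline else
      baseline * (config$library_size / mean(colSums(baseline * exp(eta)))),
    true_beta_age = beta_age,
    true_beta_sex = beta_sex,
    true_dispersion = size,
    is_structural_zero = seq_len(G) %in% zero_genes,
    stringsAsFactors = FALSE)
  truth$zero_samples <- I(zero_samples)

  structure(list(counts = counts, samples = samples, truth = truth,
                 config = config), class = "sim_data")
}

#' Assign young/old group labels from continuous age
#'
#' @param age Numeric ages in years.
#' @param young Length-2 inclusive range for the young group.
#' @param old Length-2 inclusive range for the old group.
#' @return Character vector: "young", "old", or `NA` for ages in neither
#'   range.
#' @export
age_groups <- function(age, young = c(20, 34), old = c(65, Inf)) {
  out <- rep(NA_character_, length(age))
  out[age >= young[1] & age <= young[2]] <- "young"
  out[age >= old[1] & age <= old[2]] <- "old"
  out
}

# Draw G integers uniformly from [rng[1], rng[2]], safe for degenerate
# ranges (sample() would reinterpret a scalar as 1:n).
sample_int_range <- function(rng, G) {
  vals <- seq(rng[1], rng[2])
  if (length(vals) == 1L) rep(vals, G) else sample(vals, G, replace = TRUE)
}

# Multinomial split of gene counts across parts whose proportions drift
# linearly with age (percentage points/year on the drifting part, the rest
# rescaled to keep the simplex). Shared by the isoform and exon simulators.
split_gene_counts <- function(gene_counts, ages, base_props, drift_slope,
                              drift_part, age_mid) {
  K <- length(base_props)
  n <- length(gene_counts)
  parts <- matrix(0L, nrow = K, ncol = n)
  if (K == 1L) {
    parts[1, ] <- gene_counts
    return(parts)
  }
  clamped <- FALSE
  for (s in seq_len(n)) {
    p <- base_props
    if (drift_slope != 0) {
      p1 <- base_props[drift_part] + drift_slope / 100 * (ages[s] - age_mid)
      if (p1 < 1e-6 || p1 > 1 - 1e-6) {
        p1 <- min(max(p1, 1e-6), 1 - 1e-6)
        clamped <- TRUE
      }
      rest <- base_props[-drift_part]
      p[-drift_part] <- rest * (1 - p1) / sum(rest)
      p[drift_part] <- p1
    }
    if (gene_counts[s] > 0)
      parts[, s] <- stats::rmultinom(1, gene_counts[s], p)
  }
  if (clamped)
    warning("usage drift drove a proportion outside [0, 1]; clamped to the simplex")
  parts
}

#' Simulate isoform-level counts by age-drifting multinomial splits
#'
#' Each gene's count in each sample is split across its isoforms with
#' proportions that drift linearly with age for drift-selected genes
#' (clamped to the simplex with a warning if the slope would leave it).
#' Transcript counts sum to the gene count in every sample by construction.
#'
#' @param sim A `sim_data` object from [simulate_counts()].
#' @param config The [sim_config()] used (defaults to the one stored in
#'   `sim`).
#' @param drift_genes Optional character vector of gene ids to receive
#'   usage drift; default: a random `frac_usage_drift` share of the
#'   multi-isoform genes.
#' @param seed Seed for this stage; default `config$seed + 1`.
#' @return List: `iso_counts` (transcript x sample matrix), `tx2gene`
#'   (data.frame transcript_id, gene_id), `truth` (per-transcript base
#'   usage and true usage slope in percentage points/year, including the
#'   implied compensating slopes of non-drifting isoforms).
#' @export
simulate_isoforms <- function(sim, config = sim$config, drift_genes = NULL,
                              seed = config$seed + 1L) {
  stopifnot(inherits(sim, "sim_data"))
  set.seed(seed)
  counts <- sim$counts
  ages <- sim$samples$age
  mid <- mean(config$age_range)
  G <- nrow(counts)
  n_tx <- sample_int_range(config$n_transcripts_per_gene, G)

  multi <- rownames(counts)[n_tx > 1]
  if (is.null(drift_genes)) {
    n_drift <- round(config$frac_usage_drift * length(multi))
    drift_genes <- if (n_drift > 0) sample(multi, n_drift) else character(0)
  } else {
    drift_genes <- intersect(drift_genes, multi)
  }

  iso_list <- vector("list", G)
  tx_rows <- vector("list", G)
  for (g in seq_len(G)) {
    K <- n_tx[g]
    gid <- rownames(counts)[g]
    tx_id <- sprintf("%s.T%d", gid, seq_len(K))
    props <- stats::rgamma(K, shape = 2)
    props <- props / sum(props)
    slope <- 0
    part <- which.max(props)
    if (gid %in% drift_genes) {
      slope <- config$usage_drift_magnitude * sample(c(-1, 1), 1)
      # drift the major isoform so the linear trend has room before clamping
    }
    iso_list[[g]] <- split_gene_counts(counts[g, ], ages, props, slope, part, mid)
    tx_slope <- if (slope == 0) rep(0, K) else {
      s <- rep(-slope * 1, K)  # placeholder, filled below
      s[-part] <- -slope * props[-part] / sum(props[-part])
      s[part] <- slope
      s
    }
    tx_rows[[g]] <- data.frame(transcript_id = tx_id, gene_id = gid,
                               base_usage = 100 * props,
                               true_usage_slope = tx_slope,
                               stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, tx_rows)
  iso_counts <- do.call(rbind, iso_list)
  rownames(iso_counts) <- truth$transcript_id
  colnames(iso_counts) <- colnames(counts)
  list(iso_counts = iso_counts,
       tx2gene = truth[, c("transcript_id", "gene_id")],
       truth = truth)
}

#' Simulate exon-level counts with age-dependent exon skipping
#'
#' Identical machinery to [simulate_isoforms()], but splitting each gene
#' across exon bins; skip-selected genes get one exon whose usage share
#' declines (or rises) linearly with age, emulating an exon splicing out
#' (or in) in older muscle.
#'
#' @inheritParams simulate_isoforms
#' @param skip_genes Optional gene ids to receive the skipping exon;
#'   default: a random `frac_exon_skip` share of genes.
#' @param seed Seed for this stage; default `config$seed + 3`.
#' @return List: `exon_counts`, `exon2gene` (exon_id, gene_id), `truth`
#'   (per-exon base usage and true usage slope, percentage points/year).
#' @export
simulate_exons <- function(sim, config = sim$config, skip_genes = NULL,
                           seed = config$seed + 3L) {
  stopifnot(inherits(sim, "sim_data"))
  set.seed(seed)
  counts <- sim$counts
  ages <- sim$samples$age
  mid <- mean(config$age_range)
  G <- nrow(counts)
  n_ex <- sample_int_range(config$n_exons_per_gene, G)

  if (is.null(skip_genes)) {
    n_skip <- round(config$frac_exon_skip * G)
    skip_genes <- if (n_skip > 0) sample(rownames(counts), n_skip) else character(0)
  }

  ex_list <- vector("list", G)
  ex_rows <- vector("list", G)
  for (g in seq_len(G)) {
    K <- n_ex[g]
    gid <- rownames(counts)[g]
    ex_id <- sprintf("%s.E%03d", gid, seq_len(K))
    props <- stats::rgamma(K, shape = 5)
    props <- props / sum(props)
    slope <- 0
    part <- which.max(props)
    if (gid %in% skip_genes)
      slope <- config$exon_skip_magnitude * sample(c(-1, 1), 1)
    ex_list[[g]] <- split_gene_counts(counts[g, ], ages, props, slope, part, mid)
    ex_slope <- rep(0, K)
    if (slope != 0) {
      ex_slope[-part] <- -slope * props[-part] / sum(props[-part])
      ex_slope[part] <- slope
    }
    ex_rows[[g]] <- data.frame(exon_id = ex_id, gene_id = gid,
                               base_usage = 100 * props,
                               true_usage_slope = ex_slope,
                               stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, ex_rows)
  exon_counts <- do.call(rbind, ex_list)
  rownames(exon_counts) <- truth$exon_id
  colnames(exon_counts) <- colnames(counts)
  list(exon_counts = exon_counts,
       exon2gene = truth[, c("exon_id", "gene_id")],
       truth = truth)
}

#' Simulate protein abundances coupled to mRNA at a target correlation
#'
#' For coupled genes the protein vector is `r * z + sqrt(1 - r^2) * e`,
#' where `z` is the standardized log2(CPM+1) of the gene's mRNA, `e`
#' standard Gaussian noise and `r = protein_corr_target`, so the expected
#' Pearson correlation with the mRNA equals the target (exactly 1 when the
#' target is 1). Remaining proteins are independent Gaussian noise.
#'
#' @inheritParams simulate_isoforms
#' @param coupled_genes Gene ids whose proteins track their mRNA; default:
#'   the age-associated genes from the simulation truth.
#' @param n_proteins Total number of proteins (coupled genes plus a random
#'   complement of uncoupled genes); default `min(n_genes, 1000)`.
#' @param seed Seed for this stage; default `config$seed + 2`.
#' @return List: `protein` (gene x sample matrix of relative log-scale
#'   abundances), `coupled_genes`, `target` (the generating correlation).
#' @export
simulate_proteins <- function(sim, config = sim$config, coupled_genes = NULL,
                              n_proteins = min(config$n_genes, 1000L),
                              seed = config$seed + 2L) {
  stopifnot(inherits(sim, "sim_data"))
  r <- config$protein_corr_target
  if (abs(r) > 1) stop("protein_corr_target must lie in [-1, 1]")
  set.seed(seed)
  if (is.null(coupled_genes))
    coupled_genes <- sim$truth$gene_id[sim$truth$true_beta_age != 0]
  coupled_genes <- intersect(coupled_genes, rownames(sim$counts))
  pool <- setdiff(rownames(sim$counts), coupled_genes)
  n_extra <- max(0L, n_proteins - length(coupled_genes))
  extra <- if (n_extra > 0) sample(pool, min(n_extra, length(pool))) else character(0)
  genes <- c(coupled_genes, extra)

  z <- to_cpm(sim$counts[genes, , drop = FALSE], log2 = TRUE, pseudo = 1)
  n <- ncol(z)
  prot <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, colnames(sim$counts)))
  for (g in coupled_genes) {
    zg <- z[g, ]
    sdg <- stats::sd(zg)
    zg <- if (sdg > 0) (zg - mean(zg)) / sdg else zg * 0
    prot[g, ] <- r * zg + sqrt(1 - r^2) * prot[g, ]
  }
  list(protein = prot, coupled_genes = coupled_genes, target = r)
}

#' Write and read simulation outputs as plain text
#'
#' Matrices go to tab-separated feature x sample tables with a header row
#' of sample ids; the sample table and truth tables are tab-separated; the
#' configuration is written as `key: value` lines.
#'
#' @param x Matrix or data.frame to write.
#' @param path Output file.
#' @return `write_tsv_matrix`/`write_tsv_table` invisibly return `path`;
#'   readers return the parsed object.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_tsv_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname sim_io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname sim_io
#' @export
write_sim_config <- function(config, path) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","), "")
  writeLines(sprintf("%s: %s", names(flat), flat), path)
  invisible(path)
}
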