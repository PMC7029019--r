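#' Configuration for the synthetic multi-omics generator
#'
#' Defines a two-group study in which a single per-sample latent factor
#' induces correlation across three omics blocks: a continuous gene block, a
#' positive metabolite block and a compositional OTU count block. Defaults
#' emulate the shapes of a fasting-intervention mouse study: 10 + 11 samples,
#' 36 genes, 26 metabolites, 50 taxa of which 17 respond to the latent
#' factor, and a strong (near-separable) group shift on the latent scale.
#'
#' @param n_per_group integer vector of group sizes, default `c(10, 11)`.
#' @param group_effect latent mean shift between groups in latent-factor SD
#'   units. Default 4: a near-separable effect (Bayes error ~2%) matching
#'   studies where each block predicts group membership with 90-100% accuracy.
#' @param n_genes,n_metabolites continuous feature counts (36, 26).
#' @param n_taxa,n_informative_taxa OTU counts (50, 17).
#' @param n_informative informative features per continuous block (10).
#' @param loading per-feature coefficient on the latent factor for
#'   informative features (2).
#' @param noise_sd residual SD per continuous feature (1); must be > 0.
#' @param taxa_loading latent-factor coefficient on informative taxa
#'   log-abundances (2).
#' @param library_size_mean,library_size_cv log-normal library-size model
#'   (mean 35000, coefficient of variation 0.1) so a rarefaction depth of
#'   28257 is feasible.
#' @param time_levels number of nuisance timepoints cycled over samples (2).
#' @param time_shift additive shift per timepoint step on every feature's
#'   baseline scale (0.5); a nuisance covariate, orthogonal to group.
#' @param seed integer seed.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_per_group = c(10L, 11L),
                         group_effect = 4,
                         n_genes = 36L, n_metabolites = 26L,
                         n_taxa = 50L, n_informative_taxa = 17L,
                         n_informative = 10L,
                         loading = 2,
                         noise_sd = 1,
                         taxa_loading = 2,
                         library_size_mean = 35000,
                         library_size_cv = 0.1,
                         time_levels = 2L,
                         time_shift = 0.5,
                         seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group), group_effect = group_effect,
              n_genes = as.integer(n_genes), n_metabolites = as.integer(n_metabolites),
              n_taxa = as.integer(n_taxa),
              n_informative_taxa = as.integer(n_informative_taxa),
              n_informative = as.integer(n_informative),
              loading = loading, noise_sd = noise_sd, taxa_loading = taxa_loading,
              library_size_mean = library_size_mean, library_size_cv = library_size_cv,
              time_levels = as.integer(time_levels), time_shift = time_shift,
              seed = as.integer(seed))
  if (length(cfg$n_per_group) != 2 || any(cfg$n_per_group < 1)) {
    stop("n_per_group must give two positive group sizes")
  }
  if (cfg$n_genes < 1 || cfg$n_metabolites < 1 || cfg$n_taxa < 2) {
    stop("non-positive block dimensions")
  }
  if (cfg$n_informative > min(cfg$n_genes, cfg$n_metabolites)) {
    stop("n_informative exceeds a continuous block's feature count")
  }
  if (cfg$n_informative_taxa > cfg$n_taxa) {
    stop("n_informative_taxa exceeds n_taxa")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$library_size_mean <= 0) stop("library_size_mean must be > 0")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate one continuous feature block from a latent factor
#'
#' `block[i, k] = baseline_k + loading * u_i * [k informative] + N(0, noise_sd)`;
#' with `positive = TRUE` the result is exponentiated (log-normal-like
#' intensities, as for metabolite data).
#'
#' @param latent per-sample latent factor values.
#' @param n_features number of features (columns).
#' @param informative_idx indices of features that load on the latent factor.
#' @param loading coefficient on the latent factor.
#' @param noise_sd residual SD, > 0.
#' @param positive exponentiate so all entries are positive.
#' @param baseline per-feature baseline (recycled); default 0.
#' @param seed integer seed.
#' @return samples x features numeric matrix.
#' @export
generate_continuous_block <- function(latent, n_features, informative_idx,
                                      loading, noise_sd, positive = FALSE,
                                      baseline = 0, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(informative_idx) &&
      (min(informative_idx) < 1 || max(informative_idx) > n_features)) {
    stop("informative_idx out of range")
  }
  n <- length(latent)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  baseline <- rep_len(baseline, n_features)
  load_vec <- numeric(n_features)
  load_vec[informative_idx] <- loading
  signal <- outer(latent, load_vec)
  x <- sweep(signal, 2, baseline, "+") +
    matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  if (positive) x <- exp(x)
  x
}

#' Generate compositional OTU counts from a latent factor
#'
#' Logistic-normal/multinomial model: per sample, log-abundances are
#' `baseline + gamma * u + N(0, log_noise_sd)`, soft-maxed to a composition,
#' and counts drawn from a multinomial with a log-normal library size. Column
#' sums equal the drawn library sizes.
#'
#' @param latent per-sample latent factor values.
#' @param baselines per-taxon baseline log-abundances (length >= 2).
#' @param loadings per-taxon coefficients on the latent factor (nonzero only
#'   for informative taxa).
#' @param library_size_mean,library_size_cv log-normal library-size model.
#' @param log_noise_sd SD of per-entry log-abundance noise, default 0.5.
#' @param seed integer seed.
#' @param sample_ids optional sample names.
#' @return a [count_table] (taxa x samples).
#' @export
generate_otu_counts <- function(latent, baselines, loadings,
                                library_size_mean = 35000,
                                library_size_cv = 0.1,
                                log_noise_sd = 0.5,
                                seed = 1L, sample_ids = NULL) {
  m <- length(baselines)
  if (m < 2) stop("need at least 2 taxa")
  if (any(!is.finite(baselines))) stop("baselines must be finite")
  if (length(loadings) != m) stop("loadings must match baselines")
  n <- length(latent)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # log-normal library sizes with the requested mean and CV
  sdlog <- sqrt(log(1 + library_size_cv^2))
  meanlog <- log(library_size_mean) - sdlog^2 / 2
  libs <- pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
  counts <- matrix(0L, m, n)
  for (i in seq_len(n)) {
    eta <- baselines + loadings * latent[i] +
      stats::rnorm(m, sd = log_noise_sd)
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    counts[, i] <- stats::rmultinom(1, size = libs[i], prob = p)[, 1]
  }
  count_table(counts, taxa_ids = paste0("otu_", seq_len(m)),
              sample_ids = sample_ids)
}

#' Generate a synthetic two-group multi-omics study
#'
#' Draws a per-sample latent factor `u_i = mu_g + N(0, 1)` (group means
#' `-group_effect/2` and `+group_effect/2`), then builds three aligned blocks
#' from it: a continuous gene block, a positive metabolite block and a
#' compositional OTU [count_table]. A cyclic timepoint covariate shifts all
#' baselines (a nuisance effect orthogonal to group), and per-sample
#' phenotypes (fasting glucose mg/dL, fasting insulin mU/L, bodyweight g)
#' carry a group shift so index formulas and phenotype correlations are
#' exercisable.
#'
#' @param config a [synth_config].
#' @return a `multi_omics_study`: list with `sample_ids`, `metadata` (data
#'   frame: sample_id, group, genotype, timepoint), `gene_block`,
#'   `metabolite_block` (samples x features), `otu_block` (a [count_table]),
#'   `phenotypes` (data frame), and `true_model` (planted informative indices
#'   and latent values — for recovery tests only, never read by analysis
#'   stages).
#' @examples
#' study <- generate_study(synth_config(seed = 7))
#' dim(study$gene_block)
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- sum(config$n_per_group)
  group <- factor(rep(c("control", "treated"), config$n_per_group),
                  levels = c("control", "treated"))
  sample_ids <- paste0("s", seq_len(n))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  timepoint <- factor(rep_len(seq_len(config$time_levels), n))

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  mu <- c(-1, 1) * config$group_effect / 2
  latent <- mu[as.integer(group)] + stats::rnorm(n)
  time_base <- config$time_shift * (as.integer(timepoint) - 1)

  sub_seeds <- sample.int(.Machine$integer.max, 4)
  gene_idx <- seq_len(config$n_informative)
  met_idx <- seq_len(config$n_informative)
  taxa_idx <- seq_len(config$n_informative_taxa)

  genes <- generate_continuous_block(
    latent, config$n_genes, gene_idx, config$loading, config$noise_sd,
    positive = FALSE, baseline = 0, seed = sub_seeds[1]
  ) + time_base
  colnames(genes) <- paste0("gene_", seq_len(config$n_genes))
  rownames(genes) <- sample_ids

  mets <- generate_continuous_block(
    latent, config$n_metabolites, met_idx, config$loading, config$noise_sd,
    positive = TRUE, baseline = 0, seed = sub_seeds[2]
  ) * exp(time_base)
  colnames(mets) <- paste0("metabolite_", seq_len(config$n_metabolites))
  rownames(mets) <- sample_ids

  baselines <- stats::rnorm(config$n_taxa, mean = 0, sd = 1)
  loadings <- numeric(config$n_taxa)
  loadings[taxa_idx] <- config$taxa_loading *
    rep_len(c(1, -1), config$n_informative_taxa) # both directions of response
  otus <- generate_otu_counts(
    latent + time_base, baselines, loadings,
    library_size_mean = config$library_size_mean,
    library_size_cv = config$library_size_cv,
    seed = sub_seeds[3], sample_ids = sample_ids
  )

  set.seed(sub_seeds[4])
  glucose <- 180 - 60 * (as.integer(group) - 1) + stats::rnorm(n, sd = 15)
  insulin <- 12 - 4 * (as.integer(group) - 1) + stats::rnorm(n, sd = 1.5)
  bodyweight <- 45 - 5 * (as.integer(group) - 1) + stats::rnorm(n, sd = 2)
  phenotypes <- data.frame(
    sample_id = sample_ids,
    glucose = pmax(glucose, 40),
    insulin = pmax(insulin, 1),
    bodyweight = pmax(bodyweight, 20)
  )

  structure(
    list(
      sample_ids = sample_ids,
      metadata = data.frame(
        sample_id = sample_ids, group = group,
        genotype = factor(rep("db/db", n)), timepoint = timepoint
      ),
      gene_block = genes,
      metabolite_block = mets,
      otu_block = otus,
      phenotypes = phenotypes,
      true_model = list(
        latent = latent,
        informative_genes = gene_idx,
        informative_metabolites = met_idx,
        informative_taxa = taxa_idx
      )
    ),
    class = "multi_omics_study"
  )
}

#' @export
print.multi_omics_study <- function(x, ...) {
  cat("multi_omics_study:", length(x$sample_ids), "samples;",
      ncol(x$gene_block), "genes,", ncol(x$metabolite_block), "metabolites,",
      nrow(x$otu_block$counts), "taxa\n")
  print(table(x$metadata$group))
  invisible(x)
}

#' Write a synthetic study to a directory of TSV files
#'
#' Writes `gene_block.tsv`, `metabolite_block.tsv` (features x samples),
#' `otu_counts.tsv` (taxa x samples), `metadata.tsv` and `truth.json` in the
#' package's TSV dialect (tab-delimited, header row of sample ids, first
#' column the feature id).
#'
#' @param study a `multi_omics_study`.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "multi_omics_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gene_block = file.path(dir, "gene_block.tsv"),
    metabolite_block = file.path(dir, "metabolite_block.tsv"),
    otu_counts = file.path(dir, "otu_counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(t(study$gene_block), paths["gene_block"])
  write_matrix_tsv(t(study$metabolite_block), paths["metabolite_block"])
  write_matrix_tsv(study$otu_block$counts, paths["otu_counts"])
  meta <- merge(study$metadata, study$phenotypes, by = "sample_id", sort = FALSE)
  utils::write.table(meta, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(study$true_model, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
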