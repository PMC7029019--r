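#' Write a feature-by-sample matrix as TSV
#'
#' Package TSV dialect: tab-delimited, UTF-8, header row of sample ids,
#' first column the feature id (column name `feature_id`).
#'
#' @param x features x samples matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a matrix TSV
#'
#' Reads the dialect written by [write_matrix_tsv()]. `orientation`
#' declares what the file's rows are; the returned matrix is always
#' samples x features (count tables additionally get wrapped by the caller).
#'
#' @param path TSV file.
#' @param orientation `"features_in_rows"` (default; the file has taxa/genes
#'   in rows and samples in columns, and is transposed on read) or
#'   `"samples_in_rows"`.
#' @param integer_counts reject missing/non-integer values (for count
#'   tables).
#' @return samples x features numeric matrix with ids preserved.
#' @export
read_matrix_tsv <- function(path, orientation = c("features_in_rows",
                                                  "samples_in_rows"),
                            integer_counts = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- ids
  if (integer_counts) {
    if (any(is.na(m))) stop("missing values not allowed in count table ", path)
    if (any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
      stop("count table ", path, " must contain non-negative integers")
    }
  } else if (any(is.na(m))) {
    stop("missing values in ", path, " (imputation is not supported)")
  }
  if (orientation == "features_in_rows") m <- t(m)
  m
}

#' Read sample metadata
#'
#' TSV with a `sample_id` column; `group`, `genotype` and `timepoint` are
#' typed as factors, all other columns left as read (phenotypes numeric).
#' When `align_to` sample ids are given, the metadata is subset and ordered
#' to them, erroring on ids that are missing.
#'
#' @param path TSV file.
#' @param align_to optional character vector of sample ids (block order).
#' @return data frame with rownames = sample ids.
#' @export
read_metadata <- function(path, align_to = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  for (col in intersect(c("group", "genotype", "timepoint"), names(df))) {
    df[[col]] <- as.factor(df[[col]])
  }
  rownames(df) <- df$sample_id
  if (!is.null(align_to)) {
    missing <- setdiff(align_to, df$sample_id)
    if (length(missing)) {
      stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
    }
    df <- df[align_to, , drop = FALSE]
    df <- droplevels(df)
  }
  df
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults mirror the full study profile
#' (200 rdCV repetitions, 1000 permutations, keepX 10 per block, one
#' component, tenfold keepX tuning, rarefaction depth 28257); scale
#' `rdcv_repetitions`/`n_permutations` down for quick runs.
#'
#' @param synth a [synth_config()] to simulate from, or NULL when `paths`
#'   point at input files.
#' @param paths named list (`gene_block`, `metabolite_block`, `otu_counts`,
#'   `metadata`) of TSV inputs; ignored when `synth` is given.
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived by stable hashing of
#'   stage names so adding a stage does not shift the others.
#' @param rdcv_repetitions,rdcv_outer_folds,rdcv_inner_folds,rdcv_max_components
#'   rdCV settings (200, 7, 6, 3).
#' @param n_permutations rdCV permutation count, default 1000.
#' @param perm_repetitions rdCV repetitions per permutation, default 1.
#' @param keepX per-block selection size, default 10.
#' @param n_components integration components, default 1.
#' @param tune_folds keepX tuning folds, default 10 (`tune_grid = NULL`
#'   skips tuning and uses `keepX` directly).
#' @param tune_grid optional named list of candidate keepX values per block.
#' @param rarefaction_depth default 28257.
#' @param css_quantile,css_scale CSS settings (0.5, 1000).
#' @param clr_pseudocount default 1.
#' @param otu_transform OTU block transform entering the integration:
#'   `"clr"` (default) or `"css"` relative abundances.
#' @param metabolite_log log-transform metabolite intensities before
#'   autoscaling (default TRUE — intensities are log-normal-like, and
#'   correlation-based integration assumes roughly linear relations).
#' @param ancom_alpha,ancom_threshold ANCOM settings (0.05, 0.7).
#' @param permanova_permutations default 999.
#' @param coexpr_beta soft-threshold power or `"auto"`, default "auto".
#' @param coexpr_cut_height,coexpr_min_module_size module detection (0.25,
#'   the minimum size scaled to the gene count: default 5 for small panels).
#' @param edge_weight_min network edge export threshold, default 0.4.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), paths = NULL,
                            out_dir = tempfile("ifomics_run_"), seed = 1L,
                            rdcv_repetitions = 200, rdcv_outer_folds = 7,
                            rdcv_inner_folds = 6, rdcv_max_components = 3,
                            n_permutations = 1000, perm_repetitions = 1,
                            keepX = 10, n_components = 1,
                            tune_folds = 10, tune_grid = NULL,
                            rarefaction_depth = 28257,
                            css_quantile = 0.5, css_scale = 1000,
                            clr_pseudocount = 1,
                            otu_transform = c("clr", "css"),
                            metabolite_log = TRUE,
                            ancom_alpha = 0.05, ancom_threshold = 0.7,
                            permanova_permutations = 999,
                            coexpr_beta = "auto", coexpr_cut_height = 0.25,
                            coexpr_min_module_size = 5,
                            edge_weight_min = 0.4) {
  otu_transform <- match.arg(otu_transform)
  if (is.null(synth) && is.null(paths)) stop("give either synth or paths")
  if (!is.null(paths)) {
    need <- c("gene_block", "metabolite_block", "otu_counts", "metadata")
    if (!all(need %in% names(paths))) {
      stop("paths must name: ", paste(need, collapse = ", "))
    }
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing)) stop("missing input file(s): ",
                           paste(unlist(paths[need][missing]), collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# derive a reproducible sub-2^28 stage seed from the global seed + stage name
.derive_seed <- function(global_seed, stage) {
  hex <- substr(.string_md5(paste0(global_seed, ":", stage)), 1, 7)
  strtoi(hex, 16L) # < 2^28, safely below .Machine$integer.max
}

.string_md5 <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end analysis
#'
#' Stage order follows the study design: per-block preprocessing (counts to
#' CSS and CLR, continuous blocks autoscaled), per-block rdCV PLS-DA with a
#' permutation gate, multi-block sparse integration (optional keepX tuning,
#' component correlations, circos links, clustered-image-map orders), the
#' microbiome suite (observed richness on rarefied counts, Bray-Curtis on
#' CSS, PCoA, PERMANOVA, partial CAP conditioning on timepoint, ANCOM,
#' CLR-phenotype correlations) and the co-expression suite on the gene
#' block. All artifacts are written under `config$out_dir` together with a
#' JSON run manifest (config snapshot, per-stage seeds, checksums,
#' warnings).
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest` (invisibly also written as `manifest.json`),
#'   with a `results` attribute carrying the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
  }
  stage_seeds <- list()
  seed_for <- function(stage) {
    s <- .derive_seed(config$seed, stage)
    stage_seeds[[stage]] <<- s
    s
  }
  results <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      partial <- list(config = .config_snapshot(config), seeds = stage_seeds,
                      failed_stage = name, error = conditionMessage(e))
      jsonlite::write_json(partial, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[ifomics] stage=%s seed=%s elapsed=%.2fs", name,
                    if (name %in% names(stage_seeds))
                      stage_seeds[[name]] else "none",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # --- input ---------------------------------------------------------------
  study <- run_stage("input", function() {
    if (!is.null(config$synth)) {
      cfg <- config$synth
      cfg$seed <- seed_for("input")
      generate_study(cfg)
    } else {
      genes <- read_matrix_tsv(config$paths$gene_block)
      mets <- read_matrix_tsv(config$paths$metabolite_block)
      otus <- read_matrix_tsv(config$paths$otu_counts, integer_counts = TRUE)
      meta <- read_metadata(config$paths$metadata, align_to = rownames(genes))
      if (nlevels(droplevels(meta$group)) < 2) {
        stop("group column has fewer than 2 levels")
      }
      pheno_cols <- names(meta)[vapply(meta, is.numeric, logical(1))]
      list(
        sample_ids = rownames(genes),
        metadata = meta,
        gene_block = genes,
        metabolite_block = mets[rownames(genes), , drop = FALSE],
        otu_block = count_table(t(otus[rownames(genes), , drop = FALSE])),
        phenotypes = meta[, c("sample_id", pheno_cols), drop = FALSE],
        true_model = NULL
      )
    }
  })
  labels <- study$metadata$group

  # --- preprocessing -------------------------------------------------------
  prep <- run_stage("preprocess", function() {
    css <- css_normalize(study$otu_block, quantile = config$css_quantile,
                         scale = config$css_scale)
    clr <- clr_transform(study$otu_block, pseudocount = config$clr_pseudocount)
    otu_for_integration <- if (config$otu_transform == "clr") {
      t(clr$values)
    } else {
      t(sweep(study$otu_block$counts, 2, study$otu_block$library_size, "/"))
    }
    mets <- study$metabolite_block
    if (config$metabolite_log) {
      if (any(mets <= 0)) stop("metabolite intensities must be positive for log transform")
      mets <- log(mets)
    }
    list(css = css, clr = clr,
         blocks = list(genes = study$gene_block,
                       otus = otu_for_integration,
                       metabolites = mets))
  })

  # --- per-block rdCV + permutation gate -----------------------------------
  rdcv <- run_stage("rdcv", function() {
    out <- list()
    for (b in names(prep$blocks)) {
      cfg <- rdcv_config(outer_folds = config$rdcv_outer_folds,
                         inner_folds = config$rdcv_inner_folds,
                         repetitions = config$rdcv_repetitions,
                         max_components = config$rdcv_max_components,
                         seed = seed_for(paste0("rdcv_", b)))
      res <- rdcv_run(prep$blocks[[b]], labels, cfg)
      perm <- permutation_test(prep$blocks[[b]], labels, cfg,
                               n_permutations = config$n_permutations,
                               perm_repetitions = config$perm_repetitions,
                               seed = seed_for(paste0("perm_", b)))
      out[[b]] <- list(rdcv = res, permutation = perm)
      write_matrix_tsv(t(res$probabilities),
                       file.path(config$out_dir,
                                 paste0("rdcv_probabilities_", b, ".tsv")))
    }
    out
  })

  # --- integration ---------------------------------------------------------
  integration <- run_stage("integration", function() {
    bs <- block_set(prep$blocks, labels)
    keepx <- rep_len(config$keepX, length(prep$blocks))
    names(keepx) <- names(prep$blocks)
    tuning <- NULL
    if (!is.null(config$tune_grid)) {
      tuning <- tune_keepx(bs, grid = config$tune_grid,
                           folds = config$tune_folds,
                           n_components = config$n_components,
                           seed = seed_for("tune_keepx"))
      keepx <- tuning$keepX
    }
    model <- diablo_fit(bs, keepX = keepx, n_components = config$n_components)
    links <- circos_links(model)
    sel_mat <- do.call(cbind, lapply(model$block_names, function(b) {
      model$blocks_scaled[[b]][, model$selected[[b]][[1]], drop = FALSE]
    }))
    cim <- if (nrow(sel_mat) >= 2 && ncol(sel_mat) >= 2) cim_order(sel_mat) else NULL
    for (b in model$block_names) {
      utils::write.table(
        data.frame(feature = rownames(model$weights[[b]]),
                   weight = model$weights[[b]][, 1]),
        file.path(config$out_dir, paste0("diablo_weights_", b, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(links, file.path(config$out_dir, "circos_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cim)) {
      utils::write.table(
        data.frame(row_order = cim$row_order),
        file.path(config$out_dir, "cim_row_order.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(col_order = cim$col_order),
        file.path(config$out_dir, "cim_col_order.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(model = model, tuning = tuning,
         component_correlations = component_correlations(model),
         links = links, cim = cim)
  })

  # --- microbiome suite ----------------------------------------------------
  microbiome <- run_stage("microbiome", function() {
    depth <- config$rarefaction_depth
    rare <- withCallingHandlers(
      tryCatch(rarefy_counts(study$otu_block, depth,
                             seed = seed_for("rarefaction")),
               error = function(e) {
                 note("rarefaction skipped: ", conditionMessage(e))
                 NULL
               }),
      warning = function(w) {
        note("rarefaction: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    richness <- if (!is.null(rare)) observed_richness(rare) else
      observed_richness(study$otu_block)
    bc <- bray_curtis(t(prep$css$values))
    ord <- pcoa_ordination(bc)
    perma <- permanova(bc, labels,
                       n_permutations = config$permanova_permutations,
                       seed = seed_for("permanova"))
    cap <- cap_partial(bc, constraints = data.frame(group = labels),
                       condition = data.frame(
                         timepoint = study$metadata$timepoint),
                       n_permutations = config$permanova_permutations,
                       seed = seed_for("cap"))
    ancom <- ancom_w(study$otu_block, labels, alpha = config$ancom_alpha,
                     threshold_fraction = config$ancom_threshold)
    pheno <- study$phenotypes[, setdiff(names(study$phenotypes), "sample_id"),
                              drop = FALSE]
    clr_cor <- clr_phenotype_correlations(prep$clr, pheno)
    utils::write.table(
      data.frame(sample_id = names(richness), observed_otus = richness),
      file.path(config$out_dir, "observed_richness.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(taxon = names(ancom$W), W = ancom$W,
                 detected = ancom$detected),
      file.path(config$out_dir, "ancom.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clr_cor,
                       file.path(config$out_dir, "clr_phenotype_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(richness = richness, bray_curtis = bc, pcoa = ord,
         permanova = perma, cap = cap, ancom = ancom, clr_cor = clr_cor)
  })

  # --- co-expression suite -------------------------------------------------
  coexpr <- run_stage("coexpr", function() {
    expr <- study$gene_block
    beta <- config$coexpr_beta
    pick <- NULL
    if (identical(beta, "auto")) {
      pick <- withCallingHandlers(
        pick_soft_threshold(expr),
        warning = function(w) {
          note("soft-threshold: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      beta <- pick$beta
    }
    adj <- signed_adjacency(expr, beta = beta)
    tom <- tom_similarity(adj)
    mods <- withCallingHandlers(
      detect_modules(tom, min_module_size = config$coexpr_min_module_size,
                     cut_height = config$coexpr_cut_height),
      warning = function(w) {
        note("module detection: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    hubs <- NULL
    trait_cor <- NULL
    if (any(mods$labels > 0)) {
      eg <- module_eigengenes(expr, mods)
      trait_cor <- module_trait_correlation(eg$eigengenes, labels)
      hubs <- select_hub_genes(expr, mods, labels)
      utils::write.table(hubs$table,
                         file.path(config$out_dir, "hub_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    edges <- export_network_edges(tom, weight_min = config$edge_weight_min,
                                  file = file.path(config$out_dir,
                                                   "network_edges.tsv"))
    utils::write.table(
      data.frame(gene = names(mods$labels), module = mods$labels),
      file.path(config$out_dir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(beta = beta, soft_threshold = pick, modules = mods,
         trait_correlation = trait_cor, hubs = hubs, edges = edges)
  })

  results <- list(study = study, preprocess = prep, rdcv = rdcv,
                  integration = integration, microbiome = microbiome,
                  coexpr = coexpr)

  artifacts <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  checksums <- tools::md5sum(artifacts)
  names(checksums) <- basename(artifacts)
  manifest <- structure(
    list(
      config = .config_snapshot(config),
      seeds = stage_seeds,
      version = as.character(utils::packageVersion("ifomics")),
      checksums = as.list(checksums),
      warnings = warnings_log,
      stages = c("input", "preprocess", "rdcv", "integration", "microbiome",
                 "coexpr")
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$synth <- if (!is.null(snap$synth)) unclass(snap$synth) else NULL
  snap
}

#' Write a human-readable run report
#'
#' Markdown summary of a completed [run_pipeline()] run: per-block rdCV
#' accuracy and permutation p, selected features per block, cross-block link
#' counts, PERMANOVA/CAP statistics, ANCOM detections and hub genes. All
#' numbers are re-read from the in-memory stage results carried by the
#' manifest, so regeneration is idempotent.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param file output path, default `report.md` in the run directory.
#' @return the report lines, invisibly.
#' @export
write_report <- function(manifest, file = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  res <- attr(manifest, "results")
  if (is.null(res)) stop("manifest carries no in-memory results")
  if (is.null(file)) file <- file.path(manifest$config$out_dir, "report.md")
  ln <- c("# ifomics run report", "",
          paste0("Global seed: ", manifest$config$seed), "")
  ln <- c(ln, "## Per-block predictive models (rdCV PLS-DA)", "")
  for (b in names(res$rdcv)) {
    r <- res$rdcv[[b]]
    ln <- c(ln, sprintf(
      "- %s: accuracy %.4f (%d repetitions), permutation p (empirical) %.4g, consensus %d component(s)",
      b, r$rdcv$accuracy, r$rdcv$config$repetitions,
      r$permutation$p_empirical, r$rdcv$consensus_components))
  }
  ln <- c(ln, "", "## Integration", "")
  model <- res$integration$model
  for (b in model$block_names) {
    ln <- c(ln, sprintf("- %s selected (component 1): %s", b,
                        paste(model$selected[[b]][[1]], collapse = ", ")))
  }
  cc <- res$integration$component_correlations
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  ln <- c(ln, sprintf("- cross-block component correlations: %s",
                      paste(sprintf("%s-%s r=%.3f", rownames(cc)[pairs[, 1]],
                                    colnames(cc)[pairs[, 2]], cc[pairs]),
                            collapse = "; ")),
          sprintf("- circos links at |r| >= %.2f: %d",
                  attr(res$integration$links, "threshold"),
                  nrow(res$integration$links)))
  ln <- c(ln, "", "## Microbiome", "",
          sprintf("- PERMANOVA: pseudo-F %.3f, R2 %.3f, p %.4g",
                  res$microbiome$permanova$pseudo_F,
                  res$microbiome$permanova$R2,
                  res$microbiome$permanova$p_value),
          sprintf("- partial CAP: group %.1f%% of total variance (p %.4g), conditioned (time) %.1f%%",
                  100 * res$microbiome$cap$variance_explained[["constrained"]],
                  res$microbiome$cap$p_value, 100 * res$microbiome$cap$conditioned),
          sprintf("- ANCOM: %d taxa detected (W >= %.1f)",
                  sum(res$microbiome$ancom$detected),
                  res$microbiome$ancom$threshold))
  ln <- c(ln, "", "## Co-expression", "")
  mods <- res$coexpr$modules
  ln <- c(ln, sprintf("- beta = %s; %d module(s); %d unassigned gene(s)",
                      format(res$coexpr$beta),
                      length(setdiff(unique(mods$labels), 0L)),
                      sum(mods$labels == 0)))
  if (!is.null(res$coexpr$hubs)) {
    ln <- c(ln, sprintf("- hub genes: %s",
                        if (length(res$coexpr$hubs$hubs))
                          paste(res$coexpr$hubs$hubs, collapse = ", ")
                        else "none"))
  } else {
    ln <- c(ln, "- hub genes: skipped (no assigned modules)")
  }
  ln <- c(ln, sprintf("- network edges above %.2f: %d",
                      manifest$config$edge_weight_min, nrow(res$coexpr$edges)))
  if (length(manifest$warnings)) {
    ln <- c(ln, "", "## Warnings", "", paste0("- ", manifest$warnings))
  }
  writeLines(ln, file)
  invisible(ln)
}
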