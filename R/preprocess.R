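#' Cumulative sum scaling (CSS) normalization
#'
#' Normalizes each sample of a count table by the sum of its counts up to a
#' quantile of its positive count distribution, a library-size correction that
#' is robust to a few dominant taxa. For sample j with counts `x[, j]`, the
#' scaling factor is `s_j = sum(x[x <= q_j])` over positive counts, where
#' `q_j` is the `quantile` of the sample's positive counts; normalized values
#' are `x / s_j * scale`.
#'
#' @param table a [count_table].
#' @param quantile fraction in (0, 1]; quantile of the positive counts up to
#'   which counts are summed. Default 0.5 (the median).
#' @param scale positive constant all normalized values are multiplied by.
#' @return a `normalized_matrix`: list with `values` (taxa x samples),
#'   `method = "css"`, `scaling_factor` per sample and the parameters used.
#' @details With `quantile = 1` the scaling factor is the library size and the
#'   result equals relative abundance times `scale`. Quantiles are computed
#'   with `type = 7` (the R default); the factor sums all counts less than or
#'   equal to the quantile value.
#' @export
css_normalize <- function(table, quantile = 0.5, scale = 1000) {
  stopifnot(inherits(table, "count_table"))
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  if (scale <= 0) stop("scale must be positive")
  if (any(table$library_size == 0)) {
    stop("samples with zero library size: ",
         paste(table$sample_ids[table$library_size == 0], collapse = ", "))
  }
  x <- table$counts
  s <- vapply(seq_len(ncol(x)), function(j) {
    xi <- x[, j]
    pos <- xi[xi > 0]
    qj <- stats::quantile(pos, probs = quantile, names = FALSE)
    sum(xi[xi <= qj])
  }, numeric(1))
  names(s) <- table$sample_ids
  zero <- s == 0
  if (any(zero)) {
    stop("CSS scaling factor is zero for sample(s): ",
         paste(table$sample_ids[zero], collapse = ", "))
  }
  values <- sweep(x, 2, s, "/") * scale
  normalized_matrix(values, "css", scaling_factor = s,
                    parameters = list(quantile = quantile, scale = scale))
}

normalized_matrix <- function(values, method, scaling_factor = NULL,
                              parameters = list()) {
  structure(
    list(values = values, method = method,
         scaling_factor = scaling_factor, parameters = parameters),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$method, "): ", nrow(x$values), " x ",
      ncol(x$values), "\n", sep = "")
  invisible(x)
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample without replacement to exactly `depth` total counts
#' (multivariate hypergeometric draw). Samples whose library size is below
#' `depth` are dropped with a warning rather than failing the run.
#'
#' @param table a [count_table].
#' @param depth integer target depth, e.g. 28257.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [count_table] whose columns all sum to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  keep <- table$library_size >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(table$sample_ids[!keep], collapse = ", "))
  }
  x <- table$counts[, keep, drop = FALSE]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # vegan::rrarefy works on samples-in-rows community matrices; silence its
  # "observed counts" heuristic, which misfires on tables whose minimum
  # positive count exceeds 1
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(x), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  count_table(out, taxa_ids = table$taxa_ids,
              sample_ids = table$sample_ids[keep])
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, `y_i = log(x_i + pseudocount) - mean(log(x + pseudocount))`,
#' mapping compositions to unconstrained space; each sample's transformed
#' values sum to zero.
#'
#' @param table a [count_table] (or non-negative taxa x samples matrix).
#' @param pseudocount positive offset added before taking logs. Default 1.
#' @return a `normalized_matrix` with `method = "clr"` (taxa x samples).
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (any(x < 0)) stop("counts must be non-negative")
  lx <- log(x + pseudocount)
  values <- sweep(lx, 2, colMeans(lx), "-")
  normalized_matrix(values, "clr", parameters = list(pseudocount = pseudocount))
}

#' Autoscale a samples-by-features matrix
#'
#' Feature-wise centering and unit-variance scaling (mean 0, sd 1, sample sd
#' with n - 1 denominator). Constant features are dropped with a warning by
#' default; the centering/scaling parameters are stored so held-out samples
#' can be projected with [apply_autoscale()].
#'
#' @param x samples x features numeric matrix.
#' @param on_constant `"drop"` (default) or `"error"`.
#' @return a `normalized_matrix` with `method = "autoscale"`, and `center`,
#'   `scale` vectors plus `kept` feature names in `parameters`.
#' @export
autoscale <- function(x, on_constant = c("drop", "error")) {
  on_constant <- match.arg(on_constant)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscale needs at least 2 samples")
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  constant <- sds < .Machine$double.eps^0.5
  if (any(constant)) {
    if (on_constant == "error") {
      stop("zero-variance feature(s): ", paste(colnames(x)[constant], collapse = ", "))
    }
    warning("dropping ", sum(constant), " zero-variance feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  ctr <- colMeans(x)
  values <- sweep(sweep(x, 2, ctr, "-"), 2, sds, "/")
  normalized_matrix(values, "autoscale",
                    parameters = list(center = ctr, scale = sds,
                                      kept = colnames(x)))
}

#' Apply stored autoscaling parameters to new samples
#'
#' @param normalized a `normalized_matrix` returned by [autoscale()].
#' @param x_new samples x features matrix carrying (at least) the features the
#'   scaling was trained on.
#' @return scaled samples x features matrix over the kept features.
#' @export
apply_autoscale <- function(normalized, x_new) {
  stopifnot(inherits(normalized, "normalized_matrix"),
            normalized$method == "autoscale")
  p <- normalized$parameters
  x_new <- as.matrix(x_new)[, p$kept, drop = FALSE]
  sweep(sweep(x_new, 2, p$center, "-"), 2, p$scale, "/")
}

#' Expression filter on an abundance threshold
#'
#' Keeps a gene when its value exceeds `threshold` (strictly) in at least
#' `min_samples` samples; the FPKM > 1 in at least 10 samples rule by default.
#'
#' @param x genes x samples (or samples x genes, see `genes_in_rows`) matrix.
#' @param threshold strict lower bound, default 1.
#' @param min_samples minimum number of samples exceeding it, default 10.
#' @param genes_in_rows logical; default TRUE (genes in rows).
#' @return list with `matrix` (filtered) and `kept` (gene ids).
#' @export
filter_by_expression <- function(x, threshold = 1, min_samples = 10,
                                 genes_in_rows = TRUE) {
  x <- as.matrix(x)
  if (!genes_in_rows) x <- t(x)
  if (threshold < 0) stop("threshold must be >= 0")
  if (min_samples > ncol(x)) stop("min_samples exceeds sample count")
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  n_above <- rowSums(x > threshold)
  keep <- n_above >= min_samples
  out <- x[keep, , drop = FALSE]
  if (!genes_in_rows) out <- t(out)
  list(matrix = out, kept = rownames(x)[keep])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Homeostasis-model insulin-resistance index
#'
#' `HOMA-IR = (fasting insulin (mU/L) x fasting glucose (mg/dL) x 0.05551) / 22.5`;
#' the 0.05551 factor converts glucose from mg/dL to mmol/L.
#'
#' @param fasting_insulin mU/L, non-negative.
#' @param fasting_glucose mg/dL, non-negative.
#' @return the index (unitless). Vectorized.
#' @examples
#' homa_ir(10, 180) # 4.4408
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(fasting_insulin < 0) || any(fasting_glucose < 0)) {
    stop("insulin and glucose must be non-negative")
  }
  (fasting_insulin * fasting_glucose * 0.05551) / 22.5
}

#' Relative expression fold change (2^-ddCT)
#'
#' Comparative-CT quantification for qRT-PCR:
#' `2^-((ct_target_treated - ct_ref_treated) - (ct_target_control - ct_ref_control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values; finite. Vectorized.
#' @return fold change relative to the control condition.
#' @export
ddct_ratio <- function(ct_target_treated, ct_ref_treated,
                       ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("CT values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
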