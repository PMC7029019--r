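#' Observed richness per sample
#'
#' Number of taxa with a nonzero count in each sample (observed OTUs).
#'
#' @param table a [count_table].
#' @return named integer vector, one entry per sample.
#' @export
observed_richness <- function(table) {
  stopifnot(inherits(table, "count_table"))
  out <- colSums(table$counts > 0)
  names(out) <- table$sample_ids
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = 1 - 2 sum_k min(x_ik, x_jk) / (sum_k x_ik + sum_k x_jk)` over a
#' samples x taxa abundance matrix; entries lie in \[0, 1\]. Note Bray-Curtis
#' is a dissimilarity, not a metric: the triangle inequality can fail.
#'
#' @param abundance samples x taxa non-negative matrix (counts or normalized
#'   abundances), or a [count_table] (transposed internally).
#' @return a `distance_matrix`: list with `sample_ids` and symmetric matrix
#'   `d` with zero diagonal.
#' @export
bray_curtis <- function(abundance) {
  if (inherits(abundance, "count_table")) abundance <- .samples_by_taxa(abundance)
  if (inherits(abundance, "normalized_matrix")) abundance <- t(abundance$values)
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  zero <- rowSums(abundance) == 0
  if (any(zero)) {
    ids <- rownames(abundance)
    if (is.null(ids)) ids <- as.character(which(zero))
    stop("all-zero sample(s): ", paste(ids[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(abundance, method = "bray"))
  distance_matrix(d, rownames(abundance))
}

#' Construct a distance matrix object
#'
#' @param d square symmetric matrix, zero diagonal, non-negative entries.
#' @param sample_ids optional ids; default rownames or `sample_i`.
#' @return a `distance_matrix`.
#' @export
distance_matrix <- function(d, sample_ids = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(d)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(d)))
  }
  dimnames(d) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = sample_ids, d = d), class = "distance_matrix")
}

#' Principal coordinate analysis (PCoA)
#'
#' Eigendecomposition of the Gower-centered `-D^2/2` matrix. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' negative eigenvalues — which arise for non-Euclidean dissimilarities such
#' as Bray-Curtis — are reported but excluded from the coordinates, with no
#' Cailliez/Lingoes correction applied.
#'
#' @param dist a `distance_matrix`.
#' @return an `ordination`: `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (over positive
#'   eigenvalues) and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  n <- nrow(dist$d)
  res <- withCallingHandlers(
    stats::cmdscale(dist$d, k = n - 1, eig = TRUE),
    warning = function(w) {
      # cmdscale warns when fewer than k eigenvalues are positive; the
      # positive-axis truncation below is exactly the intended behaviour
      if (grepl("eigenvalues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- res$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- res$points[, seq_len(sum(pos)), drop = FALSE]
  rownames(coords) <- dist$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig,
      proportion_explained = eig[pos] / sum(eig[pos]),
      negative_eigenvalues = eig[eig < 0]
    ),
    class = "ordination"
  )
}

# Anderson's pseudo-F from squared distances and a grouping
.permanova_f <- function(d2, groups) {
  n <- length(groups)
  a <- nlevels(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssa <- sst - ssw
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  list(f = f, r2 = ssa / sst)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Pseudo-F from among/within sums of squared distances (Anderson's
#' formulation); significance by permutation of whole-sample group labels,
#' with the +1 correction `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param dist a `distance_matrix`.
#' @param groups factor (or coercible) of group labels, >= 2 levels.
#' @param n_permutations number of random label permutations, default 999.
#' @param seed integer seed for the permutation draw.
#' @param permutations optional integer matrix (one permutation of
#'   `seq_along(groups)` per row) overriding the random draw — used for
#'   exhaustive enumeration on small designs.
#' @return a `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = 1L,
                      permutations = NULL) {
  stopifnot(inherits(dist, "distance_matrix"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("every group needs at least one sample")
  if (length(groups) != nrow(dist$d)) stop("groups must match samples")
  d2 <- dist$d^2
  obs <- .permanova_f(d2, groups)
  if (is.null(permutations)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    permutations <- t(replicate(n_permutations, sample.int(length(groups))))
  }
  n_perm <- nrow(permutations)
  f_perm <- apply(permutations, 1, function(idx) {
    .permanova_f(d2, groups[idx])$f
  })
  p <- (1 + sum(f_perm >= obs$f - 1e-12)) / (1 + n_perm)
  structure(
    list(pseudo_F = obs$f, R2 = obs$r2, p_value = p,
         n_permutations = n_perm, seed = seed),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

# dummy-encode factors with first-level reference, no intercept column
.encode_factors <- function(df) {
  df <- as.data.frame(df)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Partial constrained analysis of principal coordinates (CAP / db-RDA)
#'
#' Distance-based redundancy analysis with conditioning: the distance matrix
#' is embedded by [pcoa_ordination()] (positive axes), nuisance (condition)
#' columns are regressed out, and the residual coordinates are projected onto
#' the constraint space. Variance fractions are inertias over total inertia,
#' so conditioned + constrained + residual = 1. Term significance is assessed
#' by Freedman-Lane-style permutation of the reduced-model residual
#' coordinates (raw-label permutation available via `permute_raw`).
#'
#' @param dist a `distance_matrix`.
#' @param constraints data frame of design factors of interest.
#' @param condition optional data frame of nuisance factors to partial out.
#' @param n_permutations default 999.
#' @param seed integer seed.
#' @param permute_raw permute original coordinates instead of reduced-model
#'   residuals.
#' @return a `cap_result`: `variance_explained` (fraction of total inertia
#'   per constraint term, plus the `constrained` total), `conditioned`,
#'   `residual`, overall `pseudo_F` and permutation `p_value`,
#'   `n_permutations`, `seed`.
#' @export
cap_partial <- function(dist, constraints, condition = NULL,
                        n_permutations = 999, seed = 1L, permute_raw = FALSE) {
  stopifnot(inherits(dist, "distance_matrix"))
  ord <- pcoa_ordination(dist)
  y <- ord$coordinates
  n <- nrow(y)
  constraints <- as.data.frame(constraints)
  zc <- .encode_factors(constraints)
  zn <- if (!is.null(condition)) .encode_factors(as.data.frame(condition)) else NULL
  n_cols <- ncol(zc) + if (is.null(zn)) 0 else ncol(zn)
  if (n < n_cols + 2) stop("too few samples for the requested design")

  total <- sum(scale(y, scale = FALSE)^2)
  # partial out condition (always including an intercept)
  x0 <- cbind(intercept = rep(1, n), zn)
  q0 <- qr(x0)
  y_res <- qr.resid(q0, y)
  conditioned <- total - sum(y_res^2)
  # residualize constraints on the condition too
  z_res <- qr.resid(q0, zc)
  if (max(abs(z_res)) < 1e-10) {
    # constraints fully absorbed by the condition: nothing left to explain
    warning("constraints are collinear with the condition; constrained variance is 0")
    per_term <- numeric(length(attr(stats::terms(~ ., data = constraints),
                                    "term.labels")))
    names(per_term) <- attr(stats::terms(~ ., data = constraints), "term.labels")
    y_res <- qr.resid(q0, y)
    return(structure(
      list(variance_explained = c(per_term, constrained = 0),
           conditioned = conditioned / total,
           residual = sum(y_res^2) / total,
           pseudo_F = 0, p_value = 1,
           n_permutations = n_permutations, seed = seed),
      class = "cap_result"))
  }
  qz <- qr(z_res)
  if (qz$rank < ncol(z_res)) {
    stop("constraint matrix is rank-deficient after conditioning: rank ",
         qz$rank, " < ", ncol(z_res), " columns")
  }
  fit <- qr.fitted(qz, y_res)
  constrained <- sum(fit^2)
  residual <- sum(y_res^2) - constrained
  df_resid <- n - qr(cbind(x0, zc))$rank

  # per-term decomposition: marginal fit of each term given the others
  terms <- colnames(zc)
  term_of <- attr(stats::model.matrix(~ ., data = constraints), "assign")[-1]
  term_names <- attr(stats::terms(~ ., data = constraints), "term.labels")
  per_term <- vapply(seq_along(term_names), function(k) {
    others <- z_res[, term_of != k, drop = FALSE]
    q_oth <- qr(cbind(x0, others))
    y_r <- qr.resid(q_oth, y)
    z_k <- qr.resid(q_oth, zc[, term_of == k, drop = FALSE])
    sum(qr.fitted(qr(z_k), y_r)^2)
  }, numeric(1))
  names(per_term) <- term_names

  stat_one <- function(y_in) {
    y_r <- qr.resid(q0, y_in)
    sum(qr.fitted(qz, y_r)^2)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # Freedman-Lane: permute reduced-model residuals, add back fitted condition
  fitted0 <- qr.fitted(q0, y)
  f_obs <- (constrained / qz$rank) / (residual / df_resid)
  f_perm <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n)
    y_p <- if (permute_raw) y[idx, , drop = FALSE] else fitted0 + y_res[idx, , drop = FALSE]
    c_p <- stat_one(y_p)
    r_p <- sum(qr.resid(q0, y_p)^2) - c_p
    (c_p / qz$rank) / (r_p / df_resid)
  }, numeric(1))
  p_overall <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)

  structure(
    list(
      variance_explained = c(per_term / total, constrained = constrained / total),
      conditioned = conditioned / total,
      residual = residual / total,
      pseudo_F = f_obs,
      p_value = p_overall,
      n_permutations = n_permutations,
      seed = seed
    ),
    class = "cap_result"
  )
}

#' @export
print.cap_result <- function(x, ...) {
  cat("Partial CAP (db-RDA)\n")
  ve <- x$variance_explained
  for (nm in names(ve)) {
    cat(sprintf("  %s: %.1f%% of total variance\n", nm, 100 * ve[[nm]]))
  }
  cat(sprintf("  conditioned: %.1f%%, residual: %.1f%%\n",
              100 * x$conditioned, 100 * x$residual))
  cat(sprintf("  pseudo-F = %.3f, permutation p = %.4g\n", x$pseudo_F, x$p_value))
  invisible(x)
}

#' ANCOM differential abundance (W statistic)
#'
#' Analysis of composition of microbiomes: for every ordered pair of taxa
#' (i, j != i) the additive log-ratio `log((x_i + pc) / (x_j + pc))` is tested
#' for a location difference across groups (Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for more). Within each focal taxon i its m - 1 p-values are
#' BH-adjusted at level `alpha`; `W_i` is the number of rejections, and taxon
#' i is flagged as differentially abundant when
#' `W_i >= threshold_fraction * (m - 1)`.
#'
#' @param table a [count_table] with at least 3 taxa.
#' @param groups factor of group labels (>= 2 levels).
#' @param alpha within-taxon BH level, default 0.05.
#' @param pseudocount added before the log-ratio, default 1.
#' @param threshold_fraction detection cutoff on W / (m - 1), default 0.7.
#' @return an `ancom_result`: `W` per taxon, `detected` logical flags,
#'   `threshold` (count scale), and the per-pair p-value matrix.
#' @export
ancom_w <- function(table, groups, alpha = 0.05, pseudocount = 1,
                    threshold_fraction = 0.7) {
  stopifnot(inherits(table, "count_table"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  m <- nrow(table$counts)
  if (m < 3) stop("ANCOM needs at least 3 taxa")
  lx <- log(table$counts + pseudocount) # taxa x samples
  two_groups <- nlevels(groups) == 2
  g1 <- groups == levels(groups)[1]
  pmat <- matrix(NA_real_, m, m, dimnames = list(table$taxa_ids, table$taxa_ids))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      lr <- lx[i, ] - lx[j, ]
      p <- if (two_groups) {
        if (stats::var(lr) == 0) 1 else
          stats::wilcox.test(lr[g1], lr[!g1], exact = FALSE)$p.value
      } else {
        if (stats::var(lr) == 0) 1 else
          stats::kruskal.test(lr, groups)$p.value
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  w <- vapply(seq_len(m), function(i) {
    q <- stats::p.adjust(pmat[i, -i], method = "BH")
    sum(q < alpha)
  }, numeric(1))
  names(w) <- table$taxa_ids
  threshold <- threshold_fraction * (m - 1)
  structure(
    list(W = w, detected = w >= threshold, threshold = threshold,
         alpha = alpha, pseudocount = pseudocount,
         threshold_fraction = threshold_fraction, p_values = pmat),
    class = "ancom_result"
  )
}

#' @export
print.ancom_result <- function(x, ...) {
  cat("ANCOM: ", sum(x$detected), " taxa detected (W >= ",
      format(x$threshold), " of ", length(x$W) - 1, ")\n", sep = "")
  invisible(x)
}

#' CLR-phenotype Pearson correlations with BH-FDR
#'
#' Pearson correlation of every CLR-transformed taxon with every phenotype,
#' two-sided p from the t distribution, BH adjustment across all
#' (taxon, phenotype) pairs.
#'
#' @param clr a `normalized_matrix` from [clr_transform()] (taxa x samples)
#'   or a plain taxa x samples matrix.
#' @param phenotypes data frame or matrix of numeric phenotypes, samples in
#'   rows aligned with the CLR columns.
#' @return data frame with `taxon`, `phenotype`, `r`, `p`, `q`.
#' @export
clr_phenotype_correlations <- function(clr, phenotypes) {
  values <- if (inherits(clr, "normalized_matrix")) clr$values else as.matrix(clr)
  ph <- as.matrix(as.data.frame(phenotypes)[
    , vapply(as.data.frame(phenotypes), is.numeric, logical(1)), drop = FALSE])
  n <- ncol(values)
  if (nrow(ph) != n) stop("phenotypes must align with samples")
  if (n < 3) stop("need at least 3 samples")
  if (any(apply(ph, 2, stats::sd) == 0)) stop("zero-variance phenotype")
  r <- stats::cor(t(values), ph)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    taxon = rep(rownames(values), times = ncol(ph)),
    phenotype = rep(colnames(ph), each = nrow(values)),
    r = as.vector(r),
    p = as.vector(p)
  )
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
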