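#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(i, j)) / 2)^beta` so anti-correlated genes get adjacency
#' near 0 (the signed network convention); `signed = FALSE` gives the
#' unsigned `|cor|^beta` variant. Zero-variance genes are dropped with a
#' warning.
#'
#' @param expr samples x genes matrix (>= 3 samples).
#' @param beta soft-threshold power, >= 1.
#' @param signed default TRUE.
#' @return symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta = 6, signed = TRUE) {
  expr <- as.matrix(expr)
  if (beta < 1) stop("beta must be >= 1")
  if (nrow(expr) < 3) stop("need at least 3 samples")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s): ",
            paste(colnames(expr)[sds == 0], collapse = ", "))
    expr <- expr[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(expr)
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  a
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power the connectivity distribution is binned and the
#' R-squared of the log10(frequency) on log10(mean connectivity) regression
#' is computed (the scale-free topology criterion). The chosen beta is the
#' smallest power reaching `r2_target` (default 0.8), or the argmax R-squared
#' when none does.
#'
#' @param expr samples x genes matrix.
#' @param powers candidate powers, default `c(1:10, 12, 14, 16, 18, 20)`.
#' @param signed signed adjacency (default TRUE).
#' @param r2_target default 0.8.
#' @param n_bins connectivity histogram bins, default 10.
#' @return list with `beta` and `fit_table` (power, r_squared,
#'   mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                signed = TRUE, r2_target = 0.8, n_bins = 10) {
  if (!length(powers)) stop("candidate power set is empty")
  expr <- as.matrix(expr)
  if (ncol(expr) < 20) warning("fewer than 20 genes: scale-free fit unreliable")
  fit <- lapply(powers, function(bt) {
    a <- signed_adjacency(expr, beta = bt, signed = signed)
    k <- colSums(a) - 1
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    r2 <- if (sum(ok) >= 3) {
      summary(stats::lm(log10(freq[ok]) ~ log10(kmean[ok])))$r.squared
    } else NA_real_
    c(r_squared = r2, mean_connectivity = mean(k))
  })
  tab <- data.frame(power = powers, do.call(rbind, fit))
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= r2_target)
  beta <- if (length(hit)) tab$power[hit[1]] else
    tab$power[which.max(tab$r_squared)]
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over u distinct from i and j, and connectivity
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Values lie in \[0, 1\] for
#' adjacencies in \[0, 1\].
#'
#' @param adjacency symmetric matrix in \[0, 1\].
#' @return symmetric TOM with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0 # (A0^2)_ij = sum_u a_iu a_uj, u != i and u != j on off-diagonal
  k <- colSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static branch cut: clusters at `cut_height` smaller than
#' `min_module_size` are left unassigned (label 0); remaining modules are
#' labeled 1, 2, ... by decreasing size.
#'
#' @param tom topological overlap (or any similarity in \[0, 1\]).
#' @param min_module_size default 30.
#' @param cut_height dissimilarity cut, default 0.25.
#' @return a `module_set`: `labels` (named integer vector, 0 = unassigned),
#'   `dendrogram` (hclust), `cut_height`, `min_module_size`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.25) {
  tom <- as.matrix(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(tom)))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  } else {
    warning("no cluster reaches min_module_size; all genes unassigned")
  }
  names(labels) <- genes
  structure(
    list(labels = labels, dendrogram = h, cut_height = cut_height,
         min_module_size = min_module_size),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$labels)
  cat("module_set:", sum(names(tab) != "0"), "module(s);",
      if ("0" %in% names(tab)) tab[["0"]] else 0, "unassigned of",
      length(x$labels), "genes\n")
  invisible(x)
}

#' Module eigengenes and kME
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression (unit-norm sample vector), sign-oriented so the
#' mean correlation with the module's genes is non-negative.
#' `kME(gene, module) = cor(expression, eigengene)`.
#'
#' @param expr samples x genes matrix.
#' @param modules a `module_set` (or named label vector).
#' @return list with `eigengenes` (samples x modules, columns `ME1`, ...),
#'   `kme` (genes x modules) and `module_labels`.
#' @export
module_eigengenes <- function(expr, modules) {
  expr <- as.matrix(expr)
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  labels <- labels[colnames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  me <- matrix(0, nrow(expr), length(mods))
  colnames(me) <- paste0("ME", mods)
  rownames(me) <- rownames(expr)
  for (i in seq_along(mods)) {
    sub <- expr[, labels == mods[i], drop = FALSE]
    if (ncol(sub) < 2) stop("module ", mods[i], " has fewer than 2 genes")
    sub_s <- scale(sub)
    sv <- tryCatch(svd(sub_s, nu = 1, nv = 0),
                   error = function(e) {
                     warning("singular module matrix for module ", mods[i])
                     svd(sub_s + 1e-10, nu = 1, nv = 0)
                   })
    v <- sv$u[, 1]
    if (mean(stats::cor(sub, v)) < 0) v <- -v
    me[, i] <- v
  }
  kme <- stats::cor(expr, me)
  list(eigengenes = me, kme = kme, module_labels = labels)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a numeric (or 0/1
#' coded) trait, with two-sided t-based p-values.
#'
#' @param eigengenes samples x modules matrix (from [module_eigengenes()]).
#' @param trait numeric vector or two-level factor (coded 0/1).
#' @return data frame with `module`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else as.matrix(eigengenes)
  trait <- .code_trait(trait)
  if (stats::sd(trait) == 0) stop("constant trait")
  n <- nrow(me)
  r <- drop(stats::cor(me, trait))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  data.frame(module = colnames(me), r = r, p = p, row.names = NULL)
}

.code_trait <- function(trait) {
  if (is.numeric(trait)) return(trait)
  f <- droplevels(as.factor(trait))
  if (nlevels(f) != 2) stop("non-numeric traits must have exactly 2 levels")
  as.numeric(f) - 1
}

#' Select hub genes
#'
#' Hub genes satisfy all three criteria simultaneously: correlation with
#' their own module eigengene `kME > kme_min`, absolute trait correlation
#' `|r| > trait_min`, and BH-adjusted trait-correlation `q < fdr_max`
#' (adjustment across all assigned genes).
#'
#' @param expr samples x genes matrix.
#' @param modules a `module_set`.
#' @param trait numeric or two-level trait.
#' @param kme_min default 0.8.
#' @param trait_min default 0.85.
#' @param fdr_max default 0.01.
#' @param module restrict to one module label (optional).
#' @return a `hub_result`: `hubs` (gene ids), `table` (per-gene module, kME,
#'   trait r, p, q, hub flag), thresholds used.
#' @export
select_hub_genes <- function(expr, modules, trait, kme_min = 0.8,
                             trait_min = 0.85, fdr_max = 0.01, module = NULL) {
  expr <- as.matrix(expr)
  eg <- module_eigengenes(expr, modules)
  labels <- eg$module_labels
  trait_num <- .code_trait(trait)
  assigned <- names(labels)[labels > 0]
  if (!is.null(module)) assigned <- names(labels)[labels == module]
  n <- nrow(expr)
  r_trait <- drop(stats::cor(expr[, assigned, drop = FALSE], trait_num))
  tt <- r_trait * sqrt((n - 2) / pmax(1 - r_trait^2, .Machine$double.eps))
  p_trait <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  q_trait <- stats::p.adjust(p_trait, method = "BH")
  kme_own <- vapply(assigned, function(g) {
    eg$kme[g, paste0("ME", labels[g])]
  }, numeric(1))
  hub <- kme_own > kme_min & abs(r_trait) > trait_min & q_trait < fdr_max
  tab <- data.frame(
    gene = assigned, module = labels[assigned], kme = kme_own,
    trait_r = r_trait, trait_p = p_trait, trait_q = q_trait, hub = hub,
    row.names = NULL
  )
  structure(
    list(hubs = assigned[hub], table = tab,
         thresholds = c(kme_min = kme_min, trait_min = trait_min,
                        fdr_max = fdr_max)),
    class = "hub_result"
  )
}

#' @export
print.hub_result <- function(x, ...) {
  cat("hub_result:", length(x$hubs), "hub gene(s) of", nrow(x$table),
      "assigned genes\n")
  invisible(x)
}

#' Export network edges above a weight threshold
#'
#' Undirected edges (i < j) of a symmetric weight matrix (TOM or adjacency)
#' with weight strictly above `weight_min`.
#'
#' @param weights symmetric matrix.
#' @param weight_min default 0.4.
#' @param file optional TSV path to write (`gene_a`, `gene_b`, `weight`).
#' @return the edge data frame (invisibly when `file` is given).
#' @export
export_network_edges <- function(weights, weight_min = 0.4, file = NULL) {
  w <- as.matrix(weights)
  if (max(abs(w - t(w))) > 1e-12) stop("weight matrix must be symmetric")
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(w)))
  hit <- which(upper.tri(w) & w > weight_min, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = ids[hit[, 1]], gene_b = ids[hit[, 2]],
    weight = w[hit]
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    utils::write.table(edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(edges))
  }
  edges
}
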