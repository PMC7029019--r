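#' Assemble an aligned multi-block set
#'
#' @param blocks named list of samples x features matrices sharing one sample
#'   order (checked via rownames when present).
#' @param labels class labels aligned with the rows.
#' @param autoscale_blocks autoscale each block (default TRUE); the standard
#'   preparation for integration.
#' @return a `block_set`: `blocks` (scaled), `labels`, `scalers`.
#' @export
block_set <- function(blocks, labels, autoscale_blocks = TRUE) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("blocks must be a named list")
  }
  if (anyDuplicated(names(blocks))) stop("block names must be unique")
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  blocks <- lapply(blocks, as.matrix)
  for (b in names(blocks)) {
    if (nrow(blocks[[b]]) != n) stop("block '", b, "' does not match labels")
    if (ncol(blocks[[b]]) < 1) stop("block '", b, "' is empty")
    if (is.null(colnames(blocks[[b]]))) {
      colnames(blocks[[b]]) <- paste0(b, "_", seq_len(ncol(blocks[[b]])))
    }
  }
  rn <- lapply(blocks, rownames)
  rn <- rn[!vapply(rn, is.null, logical(1))]
  if (length(rn) > 1 && !all(vapply(rn, identical, logical(1), rn[[1]]))) {
    stop("blocks disagree on sample ordering")
  }
  scalers <- NULL
  if (autoscale_blocks) {
    scalers <- lapply(blocks, autoscale)
    blocks <- lapply(scalers, function(s) s$values)
  }
  structure(list(blocks = blocks, labels = labels, scalers = scalers),
            class = "block_set")
}

# keep the k largest-|value| entries of v, zero the rest; ties by index order
.hard_threshold <- function(v, k) {
  if (k >= length(v)) return(v)
  ord <- order(abs(v), decreasing = TRUE) # stable: ties -> smaller index first
  v[ord[-seq_len(k)]] <- 0
  v
}

# design-weighted sum of score covariances (the sGCCA objective)
.sgcca_objective <- function(scores, t_y, design, y_weight) {
  nb <- length(scores)
  n1 <- length(t_y) - 1
  obj <- 0
  if (nb > 1) {
    for (a in seq_len(nb - 1)) for (b in seq((a + 1), nb)) {
      obj <- obj + design[a, b] * sum(scores[[a]] * scores[[b]]) / n1
    }
  }
  for (a in seq_len(nb)) {
    obj <- obj + y_weight[a] * sum(scores[[a]] * t_y) / n1
  }
  obj
}

#' Fit a multi-block sparse discriminant model (sGCCA)
#'
#' Sparse generalized canonical correlation with a discriminant response:
#' finds, per component, one weight vector per block maximizing the
#' design-weighted sum of covariances between block scores and the response
#' score, with exactly `keepX` nonzero weights per block. Block updates are
#' block-coordinate ascent: each block's weight is the design-weighted sum of
#' covariances with the other blocks' and the response's scores,
#' hard-thresholded to the `keepX` largest |values| and renormalized — so the
#' objective is non-decreasing over inner iterations (asserted). Weights are
#' initialized from each block's dominant singular vector, making fits
#' deterministic without a seed. After convergence each block is deflated by
#' its own component; the response block keeps full weight 1 to every X
#' block and is not deflated against them.
#'
#' @param blocks a [block_set] (or named list of matrices plus `labels`).
#' @param labels class labels (ignored when `blocks` is a `block_set`).
#' @param design symmetric block x block matrix with entries in \[0, 1\] and
#'   zero diagonal; default the full design (all off-diagonal 1).
#' @param keepX named list/vector of nonzero-weight counts per block
#'   (recycled); default all features.
#' @param n_components number of components, default 1.
#' @param max_iter,tol convergence controls (100, 1e-6 on max weight change).
#' @return a `diablo_model`: per block `weights` (features x A, exactly keepX
#'   nonzeros per column), `scores`, `loadings`; `selected` feature ids per
#'   block per component; `design`; `objective` trace per component;
#'   `convergence` diagnostics; the response indicator scores `y_scores`.
#' @export
diablo_fit <- function(blocks, labels = NULL, design = NULL, keepX = NULL,
                       n_components = 1, max_iter = 100, tol = 1e-6) {
  if (!inherits(blocks, "block_set")) blocks <- block_set(blocks, labels)
  xb <- blocks$blocks
  nb <- length(xb)
  bn <- names(xb)
  labels <- blocks$labels
  n <- length(labels)

  if (is.null(design)) {
    design <- matrix(1, nb, nb) - diag(nb)
  }
  design <- as.matrix(design)
  if (!isTRUE(all.equal(design, t(design))) || any(design < 0 | design > 1) ||
      any(diag(design) != 0)) {
    stop("design must be symmetric with entries in [0,1] and zero diagonal")
  }
  dimnames(design) <- list(bn, bn)
  y_weight <- rep(1, nb) # implicit full connection of every block to the response

  p <- vapply(xb, ncol, integer(1))
  if (is.null(keepX)) keepX <- p
  keepX <- rep_len(unlist(keepX), nb)
  names(keepX) <- bn
  if (any(keepX < 1 | keepX > p)) stop("keepX out of range for a block")

  y <- stats::model.matrix(~ labels - 1)
  ys <- sweep(y, 2, colMeans(y), "-")

  weights <- lapply(p, function(pk) matrix(0, pk, n_components))
  scores <- lapply(seq_len(nb), function(i) matrix(0, n, n_components))
  loadings <- lapply(p, function(pk) matrix(0, pk, n_components))
  y_scores <- matrix(0, n, n_components)
  objective <- vector("list", n_components)
  convergence <- data.frame(component = seq_len(n_components),
                            iterations = NA_integer_, converged = NA)
  xd <- xb
  yd <- ys

  for (comp in seq_len(n_components)) {
    w <- lapply(seq_len(nb), function(i) {
      sv <- svd(xd[[i]], nu = 0, nv = 1)$v[, 1]
      sv / sqrt(sum(sv^2))
    })
    t_list <- lapply(seq_len(nb), function(i) drop(xd[[i]] %*% w[[i]]))
    a_y <- svd(yd, nu = 0, nv = 1)$v[, 1]
    t_y <- drop(yd %*% a_y)
    obj_trace <- .sgcca_objective(t_list, t_y, design, y_weight)
    converged <- FALSE
    iters <- max_iter
    for (it in seq_len(max_iter)) {
      max_delta <- 0
      for (b in seq_len(nb)) {
        target <- y_weight[b] * t_y
        for (b2 in seq_len(nb)) {
          if (b2 != b && design[b, b2] > 0) {
            target <- target + design[b, b2] * t_list[[b2]]
          }
        }
        z <- drop(crossprod(xd[[b]], target))
        z <- .hard_threshold(z, keepX[b])
        nz <- sqrt(sum(z^2))
        if (nz < 1e-12) z[which.max(abs(z))] <- 1 else z <- z / nz
        max_delta <- max(max_delta, max(abs(z - w[[b]])))
        w[[b]] <- z
        t_list[[b]] <- drop(xd[[b]] %*% z)
      }
      # response-block update (unit-norm weight on the indicator matrix)
      target_y <- Reduce(`+`, Map(`*`, t_list, as.list(y_weight)))
      a_new <- drop(crossprod(yd, target_y))
      a_new <- a_new / sqrt(sum(a_new^2))
      t_y <- drop(yd %*% a_new)
      obj_trace <- c(obj_trace, .sgcca_objective(t_list, t_y, design, y_weight))
      if (max_delta < tol) { converged <- TRUE; iters <- it; break }
    }
    if (!converged) {
      warning("component ", comp, " did not converge in ", max_iter,
              " iterations (last max weight change ", format(max_delta), ")")
    }
    for (b in seq_len(nb)) {
      weights[[b]][, comp] <- w[[b]]
      scores[[b]][, comp] <- t_list[[b]]
      tt <- sum(t_list[[b]]^2)
      loadings[[b]][, comp] <- drop(crossprod(xd[[b]], t_list[[b]])) / tt
      xd[[b]] <- xd[[b]] - tcrossprod(t_list[[b]], loadings[[b]][, comp])
    }
    y_scores[, comp] <- t_y
    # deflate the response by its own score only
    yd <- yd - tcrossprod(t_y, drop(crossprod(yd, t_y)) / sum(t_y^2))
    objective[[comp]] <- obj_trace
    convergence$iterations[comp] <- iters
    convergence$converged[comp] <- converged
  }

  names(weights) <- names(scores) <- names(loadings) <- bn
  for (b in bn) {
    rownames(weights[[b]]) <- colnames(blocks$blocks[[b]])
    rownames(loadings[[b]]) <- colnames(blocks$blocks[[b]])
  }
  selected <- lapply(bn, function(b) {
    lapply(seq_len(n_components), function(a) {
      rownames(weights[[b]])[weights[[b]][, a] != 0]
    })
  })
  names(selected) <- bn
  structure(
    list(
      weights = weights, scores = scores, loadings = loadings,
      y_scores = y_scores, selected = selected, design = design,
      keepX = keepX, n_components = n_components,
      labels = labels, class_levels = levels(labels),
      block_names = bn, feature_ids = lapply(blocks$blocks, colnames),
      blocks_scaled = blocks$blocks, scalers = blocks$scalers,
      objective = objective, convergence = convergence
    ),
    class = "diablo_model"
  )
}

#' @export
print.diablo_model <- function(x, ...) {
  cat("Multi-block sparse discriminant model:", length(x$block_names),
      "blocks,", x$n_components, "component(s)\n")
  for (b in x$block_names) {
    cat("  ", b, ": keepX = ", x$keepX[b], ", selected (comp 1): ",
        paste(utils::head(x$selected[[b]][[1]], 5), collapse = ", "),
        if (length(x$selected[[b]][[1]]) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Predict class membership from a multi-block model
#'
#' Per block, the predicted indicator is computed from that block's
#' regression form; the final class is the majority vote across blocks, ties
#' broken by the block-averaged predicted indicators.
#'
#' @param model a `diablo_model`.
#' @param new_blocks named list of samples x features matrices on the
#'   original (unscaled) scale when the model was fit from a [block_set]
#'   with autoscaling, otherwise on the training scale.
#' @return list with `class`, `per_block` (factor per block) and `y_hat`
#'   (averaged predicted indicator).
#' @export
diablo_predict <- function(model, new_blocks) {
  missing <- setdiff(model$block_names, names(new_blocks))
  if (length(missing)) stop("missing block(s): ", paste(missing, collapse = ", "))
  k <- length(model$class_levels)
  y <- stats::model.matrix(~ model$labels - 1)
  y_means <- colMeans(y)
  per_block <- list()
  y_hat_sum <- NULL
  for (b in model$block_names) {
    xb <- as.matrix(new_blocks[[b]])
    if (!is.null(model$scalers)) xb <- apply_autoscale(model$scalers[[b]], xb)
    xb <- xb[, model$feature_ids[[b]], drop = FALSE]
    W <- model$weights[[b]]; P <- model$loadings[[b]]
    rot <- W %*% solve(crossprod(P, W))
    scores <- xb %*% rot
    # regress the centered indicator on this block's training scores
    Tb <- model$scores[[b]]
    ys <- sweep(y, 2, y_means, "-")
    Q <- solve(crossprod(Tb), crossprod(Tb, ys))
    y_hat <- sweep(scores %*% Q, 2, y_means, "+")
    colnames(y_hat) <- model$class_levels
    per_block[[b]] <- factor(model$class_levels[apply(y_hat, 1, which.max)],
                             levels = model$class_levels)
    y_hat_sum <- if (is.null(y_hat_sum)) y_hat else y_hat_sum + y_hat
  }
  y_hat_avg <- y_hat_sum / length(model$block_names)
  votes <- vapply(per_block, as.integer, integer(nrow(y_hat_avg)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  final <- vapply(seq_len(nrow(votes)), function(i) {
    tab <- tabulate(votes[i, ], nbins = k)
    top <- which(tab == max(tab))
    if (length(top) == 1) top else top[which.max(y_hat_avg[i, top])]
  }, integer(1))
  list(
    class = factor(model$class_levels[final], levels = model$class_levels),
    per_block = per_block,
    y_hat = y_hat_avg
  )
}

#' Tune keepX by cross-validated misclassification
#'
#' Coordinate-wise search over per-block candidate grids, blocks visited in
#' input order: for each candidate value of one block (others held at their
#' current best) the misclassification rate is estimated by k-fold
#' cross-validation (tenfold by default); the argmin wins, ties resolved
#' toward the smallest keepX.
#'
#' @param blocks a [block_set].
#' @param design block design matrix (default full).
#' @param grid named list of candidate keepX vectors per block.
#' @param folds cross-validation folds, default 10.
#' @param n_components components fit during tuning, default 1.
#' @param seed integer seed for the fold draw.
#' @return list with `keepX` (named vector), `errors` (per block: named
#'   vector of CV error per candidate).
#' @export
tune_keepx <- function(blocks, design = NULL, grid, folds = 10,
                       n_components = 1, seed = 1L) {
  stopifnot(inherits(blocks, "block_set"))
  bn <- names(blocks$blocks)
  if (is.null(names(grid))) names(grid) <- bn[seq_along(grid)]
  if (!all(bn %in% names(grid))) stop("grid must cover every block")
  if (any(vapply(grid, length, integer(1)) == 0)) stop("empty grid")
  labels <- blocks$labels
  n <- length(labels)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fold <- .make_folds(labels, min(folds, n), stratified = TRUE)

  cv_error <- function(keepx) {
    errs <- vapply(unique(fold), function(f) {
      tr <- fold != f
      tr_blocks <- structure(list(
        blocks = lapply(blocks$blocks, function(m) m[tr, , drop = FALSE]),
        labels = droplevels(labels[tr]), scalers = NULL
      ), class = "block_set")
      fit <- diablo_fit(tr_blocks, design = design, keepX = keepx,
                        n_components = n_components)
      te_blocks <- lapply(blocks$blocks, function(m) m[!tr, , drop = FALSE])
      pred <- diablo_predict(fit, te_blocks)$class
      mean(pred != labels[!tr])
    }, numeric(1))
    mean(errs)
  }

  current <- vapply(grid[bn], min, numeric(1)) # start from the sparsest point
  errors <- list()
  for (b in bn) {
    cand <- sort(unique(grid[[b]]))
    errs <- vapply(cand, function(k) {
      kx <- current; kx[b] <- k
      cv_error(kx)
    }, numeric(1))
    names(errs) <- cand
    errors[[b]] <- errs
    current[b] <- cand[which.min(errs)] # first minimum: ties -> smallest keepX
  }
  list(keepX = current, errors = errors, folds = min(folds, n), seed = seed)
}

#' Pearson correlations between first-component block scores
#'
#' @param model a `diablo_model`.
#' @param component which component, default 1.
#' @return symmetric block x block correlation matrix with unit diagonal.
#' @export
component_correlations <- function(model, component = 1) {
  stopifnot(inherits(model, "diablo_model"))
  s <- vapply(model$scores, function(m) m[, component], numeric(length(model$labels)))
  r <- stats::cor(s)
  dimnames(r) <- list(model$block_names, model$block_names)
  r
}

#' Cross-block feature links for a circos display
#'
#' Pearson correlation between every cross-block pair of selected features on
#' the autoscaled data; edges kept where `|r| >= r_threshold`, with their
#' sign (positive links are the "brown", negative the "gray" ribbons of a
#' circos plot).
#'
#' @param model a `diablo_model`.
#' @param r_threshold in (0, 1\], default 0.7.
#' @param component which component's selection, default 1.
#' @return a data frame (`feature_a`, `block_a`, `feature_b`, `block_b`,
#'   `r`, `sign`) with attribute `threshold`.
#' @export
circos_links <- function(model, r_threshold = 0.7, component = 1) {
  stopifnot(inherits(model, "diablo_model"))
  if (r_threshold <= 0 || r_threshold > 1) stop("r_threshold must be in (0, 1]")
  bn <- model$block_names
  sel <- lapply(bn, function(b) model$selected[[b]][[component]])
  names(sel) <- bn
  edges <- list()
  for (a in seq_along(bn)[-length(bn)]) {
    for (b in seq((a + 1), length(bn))) {
      xa <- model$blocks_scaled[[bn[a]]][, sel[[bn[a]]], drop = FALSE]
      xb <- model$blocks_scaled[[bn[b]]][, sel[[bn[b]]], drop = FALSE]
      if (!ncol(xa) || !ncol(xb)) next
      r <- stats::cor(xa, xb)
      hit <- which(abs(r) >= r_threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        edges[[length(edges) + 1]] <- data.frame(
          feature_a = rownames(r)[hit[, 1]], block_a = bn[a],
          feature_b = colnames(r)[hit[, 2]], block_b = bn[b],
          r = r[hit], sign = ifelse(r[hit] > 0, "positive", "negative")
        )
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(feature_a = character(), block_a = character(),
               feature_b = character(), block_b = character(),
               r = numeric(), sign = character())
  rownames(out) <- NULL
  attr(out, "threshold") <- r_threshold
  out
}

#' Clustered-image-map row/column orders
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of the
#' samples x selected-features matrix; leaf orders are made deterministic by
#' hclust's convention (ties resolved by merge order, smaller index first).
#'
#' @param selected_matrix samples x features numeric matrix.
#' @return list with `row_order`, `col_order` (integer permutations) and the
#'   two `hclust` objects.
#' @export
cim_order <- function(selected_matrix) {
  m <- as.matrix(selected_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  hr <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = "complete")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
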