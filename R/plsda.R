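#' Fit a PLS-DA model (NIPALS PLS2 on an indicator response)
#'
#' Partial least squares discriminant analysis: the class labels are one-hot
#' coded into an indicator matrix Y, X and Y are centered (X also unit-
#' variance scaled) using the training data only, and components are
#' extracted by NIPALS. Per component the weight vector w maximizes the
#' covariance of the X-score `t = Xw` with the Y structure; X and Y are then
#' deflated by regression on t. The first-component weight equals the
#' dominant left singular vector of `X' Y` (both centered).
#'
#' @param x samples x features numeric matrix.
#' @param labels factor (or coercible) of class labels, >= 2 classes with
#'   >= 1 sample each.
#' @param n_components number of latent components; truncated with a warning
#'   if it exceeds the data rank.
#' @param scale_x scale features to unit variance (default TRUE). Constant
#'   features get scale 1 so they contribute nothing after centering.
#' @return a `pls_model`: weights `W` (features x A), scores `T` (samples x
#'   A), X-loadings `P`, Y-loadings `Q`, centering/scaling parameters,
#'   `class_levels`, `y_means`, `n_components`.
#' @export
plsda_fit <- function(x, labels, n_components = 2, scale_x = TRUE) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(p))
  feature_ids <- colnames(x)

  x_center <- colMeans(x)
  x_scale <- if (scale_x) apply(x, 2, stats::sd) else rep(1, p)
  x_scale[x_scale < .Machine$double.eps^0.5] <- 1
  xs <- sweep(sweep(x, 2, x_center, "-"), 2, x_scale, "/")

  y <- stats::model.matrix(~ labels - 1)
  colnames(y) <- levels(labels)
  y_means <- colMeans(y)
  ys <- sweep(y, 2, y_means, "-")

  max_rank <- min(n - 1, p)
  a_req <- n_components
  n_components <- min(n_components, max_rank)
  if (n_components < 1) stop("n_components must be >= 1")

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(y), n_components)
  a_used <- 0
  for (a in seq_len(n_components)) {
    z <- crossprod(xs, ys) # p x classes
    # power iteration for the dominant left singular vector of z
    w <- z[, which.max(colSums(z^2))]
    nz <- sqrt(sum(w^2))
    if (nz < 1e-12) break # X exhausted
    w <- w / nz
    for (it in 1:200) {
      w_new <- z %*% crossprod(z, w)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    w <- drop(w)
    tvec <- drop(xs %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(xs, tvec)) / tt
    qvec <- drop(crossprod(ys, tvec)) / tt
    xs <- xs - tcrossprod(tvec, pvec)
    ys <- ys - tcrossprod(tvec, qvec)
    W[, a] <- w; Tm[, a] <- tvec; P[, a] <- pvec; Q[, a] <- qvec
    a_used <- a
  }
  if (a_used < a_req) {
    warning("n_components truncated to ", a_used, " (rank limit)")
  }
  keep <- seq_len(max(a_used, 1))
  W <- W[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  rownames(W) <- rownames(P) <- feature_ids
  rownames(Q) <- levels(labels)
  rownames(Tm) <- rownames(x)
  structure(
    list(
      W = W, T = Tm, P = P, Q = Q,
      x_center = x_center, x_scale = x_scale,
      y_means = y_means, labels = labels, class_levels = levels(labels),
      feature_ids = feature_ids, n_components = a_used
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS-DA model:", length(x$feature_ids), "features,",
      x$n_components, "component(s), classes:",
      paste(x$class_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes from a PLS-DA model
#'
#' Applies the stored centering/scaling, computes the predicted indicator
#' matrix from the regression form `B = W (P'W)^-1 Q'`, and assigns each
#' sample to the class with the largest predicted indicator ("max dist"
#' rule; `rule = "centroid"` assigns to the nearest class centroid in score
#' space). Ties break deterministically toward the first class in class
#' order. The returned `probabilities` are the predicted indicators
#' normalized by softmax; for repeated-CV class probabilities use the
#' assignment frequencies from [rdcv_run()].
#'
#' @param model a `pls_model`.
#' @param x_new samples x features matrix over the model's features.
#' @param rule `"max_dist"` (default) or `"centroid"`.
#' @return list with `class` (factor), `y_hat` (predicted indicators) and
#'   `probabilities` (rows sum to 1).
#' @export
plsda_predict <- function(model, x_new, rule = c("max_dist", "centroid")) {
  rule <- match.arg(rule)
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != length(model$feature_ids)) {
    if (!is.null(colnames(x_new)) &&
        all(model$feature_ids %in% colnames(x_new))) {
      x_new <- x_new[, model$feature_ids, drop = FALSE]
    } else {
      stop("x_new does not carry the model's feature set")
    }
  }
  xs <- sweep(sweep(x_new, 2, model$x_center, "-"), 2, model$x_scale, "/")
  rot <- model$W %*% solve(crossprod(model$P, model$W))
  scores <- xs %*% rot
  y_hat <- scores %*% t(model$Q)
  y_hat <- sweep(y_hat, 2, model$y_means, "+")
  colnames(y_hat) <- model$class_levels
  if (rule == "max_dist") {
    idx <- apply(y_hat, 1, which.max) # which.max: first maximum wins
  } else {
    centroids <- do.call(rbind, lapply(model$class_levels, function(lev) {
      colMeans(model$T[model$labels == lev, , drop = FALSE])
    }))
    d2 <- outer(rowSums(scores^2), rowSums(centroids^2), "+") -
      2 * scores %*% t(centroids)
    idx <- apply(d2, 1, which.min)
  }
  ex <- exp(y_hat - apply(y_hat, 1, max))
  probs <- ex / rowSums(ex)
  list(
    class = factor(model$class_levels[idx], levels = model$class_levels),
    y_hat = y_hat,
    probabilities = probs
  )
}

#' rdCV configuration
#'
#' @param outer_folds outer ("testing") fold count, default 7.
#' @param inner_folds inner ("tuning") fold count, default 6.
#' @param repetitions number of outer-loop repetitions, default 200 (the
#'   full study configuration; scale down for quick runs).
#' @param max_components largest component count tuned over, default 3.
#' @param stratified stratify folds by class, default TRUE.
#' @param balanced use balanced misclassification as the inner fitness
#'   (default TRUE; protects unequal group sizes). FALSE = plain error rate.
#' @param seed integer seed.
#' @return an `rdcv_config` list.
#' @export
rdcv_config <- function(outer_folds = 7, inner_folds = 6, repetitions = 200,
                        max_components = 3, stratified = TRUE,
                        balanced = TRUE, seed = 1L) {
  cfg <- list(outer_folds = as.integer(outer_folds),
              inner_folds = as.integer(inner_folds),
              repetitions = as.integer(repetitions),
              max_components = as.integer(max_components),
              stratified = isTRUE(stratified), balanced = isTRUE(balanced),
              seed = as.integer(seed))
  if (cfg$repetitions < 1) stop("repetitions must be >= 1")
  if (cfg$outer_folds < 2 || cfg$inner_folds < 2) stop("folds must be >= 2")
  class(cfg) <- "rdcv_config"
  cfg
}

# stratified fold assignment; relaxes to plain folds when a class is too small
.make_folds <- function(labels, k, stratified) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  fold
}

.misclass <- function(truth, predicted, balanced) {
  if (balanced) {
    per_class <- vapply(levels(truth), function(lev) {
      idx <- truth == lev
      if (!any(idx)) return(NA_real_)
      mean(predicted[idx] != truth[idx])
    }, numeric(1))
    mean(per_class, na.rm = TRUE)
  } else {
    mean(predicted != truth)
  }
}

#' Repeated double cross-validation for PLS-DA
#'
#' The outer loop estimates prediction performance on held-out folds; for
#' each outer fold an inner cross-validation over the outer-training samples
#' tunes the component count (1..`max_components`) to the minimum (balanced)
#' misclassification, ties resolved toward fewer components. The whole
#' procedure is repeated `repetitions` times with fresh random splits; class
#' probabilities are the per-sample frequencies of class assignment across
#' repetitions, and accuracy is the fraction of samples whose
#' repetition-averaged assignment matches the truth (correctly predicted
#' samples / total samples).
#'
#' @param x samples x features matrix.
#' @param labels class labels (two or more classes).
#' @param config an [rdcv_config()].
#' @return an `rdcv_result`: `probabilities` (samples x classes, assignment
#'   frequencies), `assignments` (samples x repetitions factor codes),
#'   `predicted` (consensus class per sample), `misclassified` (sample ids),
#'   `accuracy`, `accuracy_majority` (identical consensus rule, retained for
#'   symmetry with per-repetition accuracies), `per_repetition_accuracy`,
#'   `selected_components` (per outer model) and `consensus_components`.
#' @export
rdcv_run <- function(x, labels, config = rdcv_config()) {
  stopifnot(inherits(config, "rdcv_config"))
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  n <- nrow(x)
  if (length(labels) != n) stop("labels must match rows of x")
  if (min(table(labels)) < 2) stop("every class needs at least 2 samples")
  if (min(table(labels)) < config$outer_folds && config$stratified) {
    warning("smallest class below outer_folds; folds will be uneven")
  }
  sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  k_levels <- nlevels(labels)
  assignments <- matrix(NA_integer_, n, config$repetitions)
  sel_comp <- integer(0)
  rep_acc <- numeric(config$repetitions)

  for (r in seq_len(config$repetitions)) {
    outer_fold <- .make_folds(labels, config$outer_folds, config$stratified)
    for (f in unique(outer_fold)) {
      test_idx <- which(outer_fold == f)
      train_idx <- which(outer_fold != f)
      y_tr <- droplevels(labels[train_idx])
      if (nlevels(y_tr) < k_levels) {
        stop("class absent from an outer-training set; reduce outer_folds")
      }
      max_a <- min(config$max_components, length(train_idx) -
                     ceiling(length(train_idx) / config$inner_folds) - 1,
                   ncol(x))
      max_a <- max(max_a, 1)
      best_a <- 1
      if (max_a > 1) {
        inner_fold <- .make_folds(labels[train_idx], config$inner_folds,
                                  config$stratified)
        err <- matrix(NA_real_, config$inner_folds, max_a)
        for (g in unique(inner_fold)) {
          val_idx <- train_idx[inner_fold == g]
          fit_idx <- train_idx[inner_fold != g]
          if (nlevels(droplevels(labels[fit_idx])) < k_levels) next
          fit <- plsda_fit(x[fit_idx, , drop = FALSE], labels[fit_idx],
                           n_components = max_a)
          for (a in seq_len(min(max_a, fit$n_components))) {
            sub <- .truncate_components(fit, a)
            pred <- plsda_predict(sub, x[val_idx, , drop = FALSE])$class
            err[g, a] <- .misclass(labels[val_idx], pred, config$balanced)
          }
        }
        mean_err <- colMeans(err, na.rm = TRUE)
        mean_err[is.nan(mean_err)] <- Inf
        best_a <- which.min(mean_err) # first minimum: ties -> fewer components
      }
      model <- plsda_fit(x[train_idx, , drop = FALSE], labels[train_idx],
                         n_components = best_a)
      pred <- plsda_predict(model, x[test_idx, , drop = FALSE])$class
      assignments[test_idx, r] <- as.integer(pred)
      sel_comp <- c(sel_comp, model$n_components)
    }
    rep_acc[r] <- mean(labels == levels(labels)[assignments[, r]])
  }

  probs <- t(apply(assignments, 1, function(row) {
    tabulate(row, nbins = k_levels) / length(row)
  }))
  colnames(probs) <- levels(labels)
  rownames(probs) <- sample_ids
  predicted <- factor(levels(labels)[apply(probs, 1, which.max)],
                      levels = levels(labels))
  correct <- predicted == labels
  consensus <- as.integer(names(which.max(table(sel_comp))))
  structure(
    list(
      probabilities = probs, assignments = assignments,
      predicted = predicted, truth = labels, sample_ids = sample_ids,
      misclassified = sample_ids[!correct],
      accuracy = mean(correct),
      per_repetition_accuracy = rep_acc,
      selected_components = sel_comp,
      consensus_components = consensus,
      config = config
    ),
    class = "rdcv_result"
  )
}

# view of a fitted pls_model truncated to its first a components
.truncate_components <- function(model, a) {
  keep <- seq_len(a)
  model$W <- model$W[, keep, drop = FALSE]
  model$T <- model$T[, keep, drop = FALSE]
  model$P <- model$P[, keep, drop = FALSE]
  model$Q <- model$Q[, keep, drop = FALSE]
  model$n_components <- a
  model
}

#' @export
print.rdcv_result <- function(x, ...) {
  cat(sprintf("rdCV PLS-DA: accuracy %.4f (%d/%d correct), %d repetitions, consensus %d component(s)\n",
              x$accuracy, sum(x$predicted == x$truth), length(x$truth),
              x$config$repetitions, x$consensus_components))
  if (length(x$misclassified)) {
    cat("misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Accuracy of an rdCV result
#'
#' Correctly predicted samples / total samples, using the
#' repetition-averaged class assignment.
#'
#' @param result an `rdcv_result`.
#' @return fraction in \[0, 1\].
#' @export
predictive_accuracy <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  mean(result$predicted == result$truth)
}

#' Permutation test for rdCV PLS-DA accuracy
#'
#' Compares the observed rdCV accuracy against accuracies of models refit on
#' label-shuffled data. Each permutation uses a reduced-cost rdCV
#' (`perm_repetitions`, default 1) for tractability. Reports the empirical
#' `p = (1 + #(perm >= obs)) / (1 + n_permutations)` and a parametric
#' one-sided t comparison of the observed accuracy with the permuted
#' distribution.
#'
#' @param x samples x features matrix.
#' @param labels class labels.
#' @param config an [rdcv_config()] for the observed model.
#' @param n_permutations default 1000.
#' @param perm_repetitions rdCV repetitions per permutation, default 1.
#' @param seed integer seed (controls both the observed run via `config` and
#'   the permutations).
#' @return a `permutation_result`: `observed`, `permuted` (vector),
#'   `p_empirical`, `p_parametric`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(x, labels, config = rdcv_config(),
                             n_permutations = 1000, perm_repetitions = 1,
                             seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  labels <- droplevels(as.factor(labels))
  observed <- rdcv_run(x, labels, config)$accuracy
  perm_cfg <- config
  perm_cfg$repetitions <- as.integer(perm_repetitions)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_permutations)
  perm_orders <- replicate(n_permutations, sample.int(length(labels)),
                           simplify = FALSE)
  permuted <- vapply(seq_len(n_permutations), function(i) {
    perm_cfg$seed <- perm_seeds[i]
    rdcv_run(x, labels[perm_orders[[i]]], perm_cfg)$accuracy
  }, numeric(1))
  p_emp <- (1 + sum(permuted >= observed - 1e-12)) / (1 + n_permutations)
  t_stat <- (observed - mean(permuted)) / stats::sd(permuted)
  p_par <- stats::pt(t_stat, df = n_permutations - 1, lower.tail = FALSE)
  structure(
    list(observed = observed, permuted = permuted,
         p_empirical = p_emp, p_parametric = p_par,
         n_permutations = n_permutations, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed accuracy %.4f vs %d permutations\n",
              x$observed, x$n_permutations))
  cat(sprintf("  empirical p = %.4g, parametric (t) p = %.4g\n",
              x$p_empirical, x$p_parametric))
  invisible(x)
}
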