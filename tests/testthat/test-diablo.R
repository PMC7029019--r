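make_blocks <- function(seed, n1 = 10, n2 = 11) {
  study <- generate_study(synth_config(seed = seed,
                                       n_per_group = c(n1, n2)))
  list(
    bs = block_set(list(genes = study$gene_block,
                        otus = t(clr_transform(study$otu_block)$values),
                        metabolites = log(study$metabolite_block)),
                   study$metadata$group),
    study = study
  )
}

test_that("single-block full-keepX fit reduces to PLS-DA", {
  set.seed(201)
  for (i in 1:5) {
    x <- matrix(rnorm(21 * 8), 21, 8)
    lab <- two_group_labels(10, 11)
    pls <- plsda_fit(x, lab, 1)
    dia <- diablo_fit(block_set(list(g = x), lab), keepX = 8,
                      design = matrix(0, 1, 1), n_components = 1)
    w_d <- dia$weights$g[, 1]
    w_p <- pls$W[, 1]
    if (sum(w_d * w_p) < 0) w_d <- -w_d
    expect_lt(max(abs(w_d - w_p)), 1e-8)
  }
})

test_that("fits enforce exact per-block sparsity and unit-norm weights", {
  mb <- make_blocks(202)
  fit <- diablo_fit(mb$bs, keepX = c(10, 10, 10), n_components = 2)
  for (b in fit$block_names) {
    expect_equal(unname(colSums(fit$weights[[b]] != 0)), c(10, 10))
    expect_equal(unname(colSums(fit$weights[[b]]^2)), c(1, 1),
                 tolerance = 1e-10)
    # deflation: successive scores of one block are orthogonal
    expect_lt(abs(sum(fit$scores[[b]][, 1] * fit$scores[[b]][, 2])), 1e-8)
  }
})

test_that("the design-weighted covariance objective never decreases", {
  set.seed(203)
  for (i in 1:10) {
    n <- 18
    lab <- two_group_labels(9, 9)
    blocks <- list(a = matrix(rnorm(n * 12), n, 12),
                   b = matrix(rnorm(n * 9), n, 9))
    fit <- diablo_fit(block_set(blocks, lab), keepX = c(5, 4))
    for (tr in fit$objective) {
      expect_true(all(diff(tr) >= -1e-9 * max(1, abs(tr[1]))))
    }
  }
})

test_that("planted cross-block structure is recovered", {
  overlaps <- matrix(NA_real_, 5, 3)
  cors <- numeric(5)
  for (i in 1:5) {
    mb <- make_blocks(210 + i)
    fit <- diablo_fit(mb$bs, keepX = c(10, 10, 10))
    truth <- list(
      genes = paste0("gene_", mb$study$true_model$informative_genes),
      otus = paste0("otu_", mb$study$true_model$informative_taxa),
      metabolites = paste0("metabolite_",
                           mb$study$true_model$informative_metabolites)
    )
    overlaps[i, ] <- vapply(fit$block_names, function(b) {
      length(intersect(fit$selected[[b]][[1]], truth[[b]]))
    }, numeric(1))
    cc <- component_correlations(fit)
    cors[i] <- min(abs(cc[upper.tri(cc)]))
  }
  expect_gte(mean(overlaps[, 1]), 8) # genes: 10 planted
  expect_gte(mean(overlaps[, 3]), 8) # metabolites: 10 planted
  expect_gte(mean(cors), 0.8)
})

test_that("keepX tuning returns grid argmins and honours trivial grids", {
  mb <- make_blocks(220)
  one <- tune_keepx(mb$bs, grid = list(genes = 7, otus = 7, metabolites = 7),
                    folds = 5, seed = 1)
  expect_equal(unname(one$keepX), c(7, 7, 7))
  tuned <- tune_keepx(mb$bs,
                      grid = list(genes = c(5, 10), otus = c(5, 10),
                                  metabolites = c(5, 10)),
                      folds = 5, seed = 2)
  for (b in names(tuned$errors)) {
    errs <- tuned$errors[[b]]
    expect_equal(unname(tuned$keepX[b]),
                 as.numeric(names(errs)[which.min(errs)]))
  }
  expect_error(tune_keepx(mb$bs, grid = list(genes = numeric(0), otus = 5,
                                             metabolites = 5)),
               "empty grid")
})

test_that("prediction votes are consistent with per-block outputs", {
  mb <- make_blocks(221)
  fit <- diablo_fit(mb$bs, keepX = c(10, 10, 10))
  pred <- diablo_predict(fit, list(genes = mb$study$gene_block,
                                   otus = t(clr_transform(mb$study$otu_block)$values),
                                   metabolites = log(mb$study$metabolite_block)))
  # brute-force recount of the majority vote with indicator tie-break
  k <- length(fit$class_levels)
  manual <- vapply(seq_along(pred$class), function(i) {
    votes <- tabulate(vapply(pred$per_block, function(pb) as.integer(pb[i]),
                             integer(1)), nbins = k)
    top <- which(votes == max(votes))
    if (length(top) == 1) top else top[which.max(pred$y_hat[i, top])]
  }, integer(1))
  expect_equal(as.integer(pred$class), manual)
  # separable training data: all blocks agree and accuracy is 1
  expect_true(all(vapply(pred$per_block, function(pb)
    mean(pb == mb$study$metadata$group) > 0.9, logical(1))))
  expect_equal(as.character(pred$class),
               as.character(mb$study$metadata$group))
  expect_error(diablo_predict(fit, list(genes = mb$study$gene_block)),
               "missing block")
})

test_that("component correlations match direct recomputation", {
  mb <- make_blocks(222)
  # duplicated block correlates perfectly with itself
  dup <- block_set(list(a = mb$study$gene_block, b = mb$study$gene_block),
                   mb$study$metadata$group)
  fit_dup <- diablo_fit(dup, keepX = c(10, 10))
  expect_equal(component_correlations(fit_dup)["a", "b"], 1,
               tolerance = 1e-8)
  fit <- diablo_fit(mb$bs, keepX = c(10, 10, 10))
  cc <- component_correlations(fit)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  manual <- cor(fit$scores$genes[, 1], fit$scores$otus[, 1])
  expect_equal(cc["genes", "otus"], manual, tolerance = 1e-12)
})

test_that("independent blocks sit inside a permutation-derived null envelope", {
  # fitted |r| on noise blocks is an extreme-value statistic, so it is judged
  # against the null obtained by refitting after permuting one block's rows
  set.seed(224)
  lab <- two_group_labels(10, 10)
  inside <- 0L
  for (i in 1:5) {
    blocks <- list(a = matrix(rnorm(20 * 15), 20, 15),
                   b = matrix(rnorm(20 * 15), 20, 15))
    obs <- abs(component_correlations(
      diablo_fit(block_set(blocks, sample(lab)), keepX = c(3, 3)))["a", "b"])
    env <- replicate(15, {
      perm <- blocks
      perm$b <- perm$b[sample.int(20), , drop = FALSE]
      abs(component_correlations(
        diablo_fit(block_set(perm, sample(lab)), keepX = c(3, 3)))["a", "b"])
    })
    if (obs <= max(env) + 1e-12) inside <- inside + 1L
    # and the null regime stays clearly below perfect correlation
    expect_lt(obs, 0.95)
  }
  expect_gte(inside, 4)
})

test_that("circos links respect thresholds, signs and monotonicity", {
  mb <- make_blocks(225)
  fit <- diablo_fit(mb$bs, keepX = c(10, 10, 10))
  links_07 <- circos_links(fit, r_threshold = 0.7)
  links_09 <- circos_links(fit, r_threshold = 0.9)
  expect_lte(nrow(links_09), nrow(links_07))
  expect_true(all(abs(links_07$r) >= 0.7))
  expect_true(all(links_07$sign == ifelse(links_07$r > 0, "positive",
                                          "negative")))
  # no intra-block edges
  expect_true(all(links_07$block_a != links_07$block_b))
  # threshold 1: only exactly collinear pairs survive
  dup <- block_set(list(a = mb$study$gene_block, b = mb$study$gene_block),
                   mb$study$metadata$group, autoscale_blocks = TRUE)
  fit_dup <- diablo_fit(dup, keepX = c(5, 5))
  l1 <- circos_links(fit_dup, r_threshold = 1)
  expect_true(all(abs(l1$r) >= 1 - 1e-12))
  expect_error(circos_links(fit, r_threshold = 0), "r_threshold")
  # features sharing a latent loading link positively at 0.7
  hits <- 0L
  for (i in 1:10) {
    mbs <- make_blocks(230 + i)
    f <- diablo_fit(mbs$bs, keepX = c(10, 10, 10))
    l <- circos_links(f, r_threshold = 0.7)
    pair <- l[l$feature_a == "gene_1" & l$feature_b == "metabolite_1", ]
    if (nrow(pair) == 1 && pair$sign == "positive") hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("clustered-image-map orders match complete-linkage clustering", {
  # merge heights against a brute-force complete-linkage recomputation
  set.seed(226)
  m <- matrix(rnorm(20), 5, 4)
  ord <- cim_order(m)
  brute_complete <- function(d) {
    d <- as.matrix(d)
    active <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(NA, NA); best_h <- Inf
      for (i in seq_along(active)[-length(active)]) {
        for (j in seq((i + 1), length(active))) {
          h <- max(d[active[[i]], active[[j]]])
          if (h < best_h) { best_h <- h; best <- c(i, j) }
        }
      }
      heights <- c(heights, best_h)
      merged <- c(active[[best[1]]], active[[best[2]]])
      active <- active[-best]
      active[[length(active) + 1]] <- merged
    }
    heights
  }
  expect_equal(ord$row_hclust$height, brute_complete(dist(m)),
               tolerance = 1e-12)
  expect_equal(ord$col_hclust$height, brute_complete(dist(t(m))),
               tolerance = 1e-12)

  # identical rows merge first and sit adjacently
  m2 <- rbind(a = c(0, 0, 0), b = c(5, 5, 5), c = c(0, 0, 0), d = c(9, 1, 2))
  o2 <- cim_order(m2)
  pos <- match(c(1, 3), o2$row_order)
  expect_equal(abs(diff(pos)), 1)

  # block-diagonal structure separates into contiguous groups
  m3 <- rbind(matrix(rnorm(12, 0, 0.1), 4, 3), matrix(rnorm(12, 10, 0.1), 4, 3))
  o3 <- cim_order(m3)
  first_group <- o3$row_order[1:4]
  expect_true(all(first_group %in% 1:4) || all(first_group %in% 5:8))
  expect_error(cim_order(m3[1, , drop = FALSE]), "at least 2")
})
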