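# expression with two planted modules of mutually correlated genes
planted_two_modules <- function(n = 30, size1 = 10, size2 = 10, noise = 8,
                                within_r = 0.9, seed = 1) {
  set.seed(seed)
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  sd_noise <- sqrt(1 / within_r - 1) # cor between two genes sharing a latent
  g1 <- sapply(seq_len(size1), function(i) lat1 + rnorm(n, sd = sd_noise))
  g2 <- sapply(seq_len(size2), function(i) lat2 + rnorm(n, sd = sd_noise))
  bg <- matrix(rnorm(n * noise), n, noise)
  expr <- cbind(g1, g2, bg)
  colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  list(expr = expr,
       truth = rep(c(1, 2, 0), c(size1, size2, noise)))
}

test_that("signed adjacency follows ((1 + r)/2)^beta", {
  t_vec <- seq(0, 1, length.out = 7)
  expr <- cbind(up = t_vec, up2 = 2 * t_vec + 1, down = -t_vec)
  set.seed(301)
  # build a pair with exact correlation 0.5
  a <- rnorm(50); b <- 0.5 * scale(a) + sqrt(1 - 0.25) * scale(resid(lm(rnorm(50) ~ a)))
  expect_equal(cor(a, b)[1], 0.5, tolerance = 1e-10)
  m <- cbind(g1 = a, g2 = drop(b))
  adj <- signed_adjacency(m, beta = 6)
  expect_equal(adj["g1", "g2"], 0.75^6, tolerance = 1e-10)

  adj2 <- signed_adjacency(expr[, 1:3], beta = 4)
  expect_equal(adj2["up", "up2"], 1, tolerance = 1e-12)   # r = +1
  expect_equal(adj2["up", "down"], 0, tolerance = 1e-12)  # r = -1
  expect_true(all(adj2 >= 0 & adj2 <= 1))

  const <- cbind(expr[, 1:3], flat = rep(2, 7))
  expect_warning(adj3 <- signed_adjacency(const, beta = 2), "zero-variance")
  expect_equal(ncol(adj3), 3)
  expect_error(signed_adjacency(m, beta = 0.5), "beta")
})

test_that("soft-threshold selection behaves on trivial and structured input", {
  pm <- planted_two_modules(seed = 2)
  one <- pick_soft_threshold(pm$expr, powers = 6)
  expect_equal(one$beta, 6)
  # mean connectivity is non-increasing in the power
  tab <- pick_soft_threshold(pm$expr, powers = c(2, 4, 6, 8))$fit_table
  expect_true(all(diff(tab$mean_connectivity) <= 1e-12))
  expect_warning(pick_soft_threshold(pm$expr[, 1:10], powers = c(2, 4)),
                 "20 genes")
})

test_that("soft threshold reaches a scale-free fit on hub-structured expression", {
  # hubness continuum: a few genes load strongly on a shared factor, most
  # weakly, giving the heavy-tailed connectivity profile of scale-free nets
  set.seed(1)
  n <- 50; p <- 150
  u <- runif(p)^2.5
  lat <- rnorm(n)
  expr <- sapply(seq_len(p), function(i) {
    sqrt(u[i]) * lat + sqrt(1 - u[i]) * rnorm(n)
  })
  colnames(expr) <- paste0("g", seq_len(p))
  pick <- pick_soft_threshold(expr)
  best <- pick$fit_table[pick$fit_table$power == pick$beta, ]
  expect_gte(best$r_squared, 0.8)
})

test_that("TOM matches a brute-force triple loop and stays in [0, 1]", {
  # 6-gene toy adjacency
  set.seed(304)
  r <- matrix(runif(36), 6, 6)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:6), paste0("g", 1:6))
  tom <- tom_similarity(a)
  brute <- matrix(0, 6, 6, dimnames = dimnames(a))
  for (i in 1:6) for (j in 1:6) {
    if (i == j) { brute[i, j] <- 1; next }
    l <- 0
    for (u in 1:6) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    brute[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(tom, brute, tolerance = 1e-12)

  # maximal overlap: identical neighbourhoods with a_ij = 1
  a2 <- matrix(1, 4, 4)
  expect_equal(unname(tom_similarity(a2)[1, 2]), 1)

  # bounds over random adjacencies
  for (k in 1:100) {
    r <- matrix(runif(64), 8, 8)
    ar <- (r + t(r)) / 2
    diag(ar) <- 1
    tr <- tom_similarity(ar)
    expect_true(all(tr >= -1e-12 & tr <= 1 + 1e-12))
  }
})

test_that("planted modules are recovered with high adjusted Rand index", {
  pm <- planted_two_modules(seed = 5)
  adj <- signed_adjacency(pm$expr, beta = 6)
  tom <- tom_similarity(adj)
  mods <- detect_modules(tom, min_module_size = 5, cut_height = 0.6)
  ari <- adjusted_rand(mods$labels[pm$truth > 0], pm$truth[pm$truth > 0])
  expect_gte(ari, 0.9)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(mods$labels[pm$truth > 0],
                                                pm$truth[pm$truth > 0]),
                 tolerance = 1e-12)
  }
  # labels ordered by decreasing module size
  sizes <- table(mods$labels[mods$labels > 0])
  expect_true(all(diff(as.vector(sizes)) <= 0))

  # permuting gene order leaves memberships invariant up to relabeling
  perm <- sample(ncol(pm$expr))
  tom_p <- tom_similarity(signed_adjacency(pm$expr[, perm], beta = 6))
  mods_p <- detect_modules(tom_p, min_module_size = 5, cut_height = 0.6)
  expect_equal(adjusted_rand(mods$labels[colnames(tom_p)], mods_p$labels), 1)

  # oversized minimum leaves everything unassigned
  expect_warning(all0 <- detect_modules(tom, min_module_size = 1000), "unassigned")
  expect_true(all(all0$labels == 0))
})

test_that("module eigengenes maximize explained variance and orient positively", {
  pm <- planted_two_modules(seed = 6)
  mods <- detect_modules(tom_similarity(signed_adjacency(pm$expr, beta = 6)),
                         min_module_size = 5, cut_height = 0.6)
  eg <- module_eigengenes(pm$expr, mods)
  expect_equal(unname(colSums(eg$eigengenes^2)), rep(1, ncol(eg$eigengenes)),
               tolerance = 1e-10)
  expect_true(all(abs(eg$kme) <= 1 + 1e-12))
  for (m in colnames(eg$eigengenes)) {
    lab <- as.integer(sub("ME", "", m))
    members <- names(mods$labels)[mods$labels == lab]
    # sign orientation: mean correlation with member genes is non-negative
    expect_gte(mean(eg$kme[members, m]), 0)
    # variance share equals the leading eigenvalue share (oracle)
    sub <- scale(pm$expr[, members])
    ev <- eigen(crossprod(sub), symmetric = TRUE)$values
    share_eig <- ev[1] / sum(ev)
    share_me <- sum((sub %*% t(sub) %*% eg$eigengenes[, m])^2 /
                      sum((t(sub) %*% eg$eigengenes[, m])^2))
    proj <- drop(crossprod(sub, eg$eigengenes[, m]))
    expect_equal(sum(proj^2) / sum(ev), share_eig, tolerance = 1e-8)
  }

  # module of identical genes: eigengene is the standardized profile, kME = 1
  prof <- rnorm(12)
  same <- cbind(g1 = prof, g2 = prof, g3 = prof)
  labs <- c(g1 = 1L, g2 = 1L, g3 = 1L)
  eg2 <- module_eigengenes(same, labs)
  expect_equal(unname(abs(cor(eg2$eigengenes[, "ME1"], prof))), 1,
               tolerance = 1e-10)
  expect_equal(unname(eg2$kme[, "ME1"]), rep(1, 3), tolerance = 1e-10)
})

test_that("module-trait correlations match the closed form and find planted modules", {
  pm <- planted_two_modules(seed = 7)
  # trait built from the first latent: module 1 should win
  hits <- 0L
  for (i in 1:20) {
    pmi <- planted_two_modules(seed = 100 + i)
    mods <- detect_modules(tom_similarity(signed_adjacency(pmi$expr, beta = 6)),
                           min_module_size = 5, cut_height = 0.6)
    if (max(mods$labels) < 2) next
    eg <- module_eigengenes(pmi$expr, mods)
    trait <- rowMeans(pmi$expr[, pmi$truth == 1])
    mt <- module_trait_correlation(eg, trait)
    # identify which detected module corresponds to planted module 1
    truth_mod <- names(which.max(table(
      mods$labels[pmi$truth == 1][mods$labels[pmi$truth == 1] > 0])))
    if (mt$module[which.max(abs(mt$r))] == paste0("ME", truth_mod)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18)

  # closed-form oracle on a 5-sample toy
  me <- cbind(ME1 = c(0.1, -0.2, 0.4, 0.3, -0.6))
  trait <- c(1, 0, 1, 1, 0)
  mt <- module_trait_correlation(me, trait)
  r_manual <- sum((me - mean(me)) * (trait - mean(trait))) /
    sqrt(sum((me - mean(me))^2) * sum((trait - mean(trait))^2))
  expect_equal(mt$r, r_manual, tolerance = 1e-12)
  # eigengene equal to the trait
  mt2 <- module_trait_correlation(cbind(ME1 = trait), trait)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(me, rep(2, 5)), "constant")
})

test_that("hub genes satisfy all three criteria conjunctively", {
  set.seed(308)
  n <- 30
  trait <- rep(c(0, 1), each = 15)
  lat <- trait * 2 + rnorm(n, sd = 0.3)
  hubs_true <- sapply(1:6, function(i) lat + rnorm(n, sd = 0.2))
  weak <- sapply(1:6, function(i) lat + rnorm(n, sd = 2))
  noise <- matrix(rnorm(n * 8), n, 8)
  expr <- cbind(hubs_true, weak, noise)
  colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  mods <- detect_modules(tom_similarity(signed_adjacency(expr, beta = 6)),
                         min_module_size = 4, cut_height = 0.7)
  res <- select_hub_genes(expr, mods, trait)
  # brute-force refilter of the emitted statistics table
  manual <- with(res$table, gene[kme > 0.8 & abs(trait_r) > 0.85 &
                                   trait_q < 0.01])
  expect_setequal(res$hubs, manual)
  expect_true(all(res$table$hub == (res$table$kme > 0.8 &
                                      abs(res$table$trait_r) > 0.85 &
                                      res$table$trait_q < 0.01)))
  expect_equal(unname(res$thresholds),
               c(0.8, 0.85, 0.01))

  # a gene identical to the trait inside a module is always a hub
  expr2 <- cbind(expr[, 1:6], mirror = trait + rnorm(n, sd = 1e-6))
  labs <- setNames(rep(1L, 7), colnames(expr2))
  res2 <- select_hub_genes(expr2, structure(list(labels = labs),
                                            class = "module_set"), trait)
  expect_true("mirror" %in% res2$hubs)
})

test_that("network edge export applies a strict threshold and is monotone", {
  set.seed(309)
  r <- matrix(runif(49), 7, 7)
  w <- (r + t(r)) / 2
  diag(w) <- 1
  dimnames(w) <- list(paste0("g", 1:7), paste0("g", 1:7))
  e04 <- export_network_edges(w, 0.4)
  e06 <- export_network_edges(w, 0.6)
  expect_lte(nrow(e06), nrow(e04))
  expect_true(all(e04$weight > 0.4))
  expect_equal(nrow(export_network_edges(w, 1)), 0) # off-diagonal weights <= 1
  # every qualifying pair appears exactly once (i < j)
  n_expected <- sum(w[upper.tri(w)] > 0.4)
  expect_equal(nrow(e04), n_expected)
  f <- tempfile(fileext = ".tsv")
  export_network_edges(w, 0.4, file = f)
  expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")),
               n_expected)
  unlink(f)
})
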