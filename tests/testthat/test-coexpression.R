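# Network construction: variable selection, soft threshold, scale-free fit,
# topological overlap, module detection, eigengenes, enrichment, KO ANOVA.

test_that("top-variable selection ranks by variance with stable ties", {
  expr <- cbind(a = c(0, 4, 0, 4), b = c(0, 3, 0, 3), c = c(0, 2, 0, 2),
                d = c(0, 1, 0, 1))
  expect_equal(select_top_variable(expr, 0.5), c("a", "b"))
  expect_equal(sort(select_top_variable(expr, 1)), c("a", "b", "c", "d"))
  # the study-scale arithmetic: top 25% of 39,558 reporters is 9,889
  big <- matrix(rnorm(4 * 39558), nrow = 4)
  colnames(big) <- sprintf("r%05d", seq_len(ncol(big)))
  expect_length(select_top_variable(big, 0.25), 9889)
  expect_error(select_top_variable(expr, 0), "positive")
})

test_that("soft-threshold adjacency follows the power law", {
  r <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0, -0.3, 0, 1), 3, 3)
  a <- adjacency(r, 6)
  expect_equal(a[1, 2], 0.5^6)
  expect_equal(a[1, 2], 0.015625)
  expect_equal(a[1, 3], 0.3^6, tolerance = 1e-12)
  expect_equal(diag(a), rep(0, 3))
  expect_equal(adjacency(r, 1)[1, 3], 0.3, tolerance = 1e-12)
  # signed variant zeroes negative correlations
  expect_equal(adjacency(r, 6, signed = TRUE)[1, 3], 0)
  # monotone decreasing in beta for |r| < 1
  expect_lt(adjacency(r, 7)[1, 2], adjacency(r, 6)[1, 2])
  expect_error(adjacency(r, 0.5), "beta")
})

test_that("scale-free R2 is exact on power laws and 0 on degenerate input", {
  # construct connectivities whose histogram is exactly p(k) ~ k^-1.5:
  # k = 4^i with counts 8^(6-i), one distinct k per log bin, so
  # log p(k) is exactly linear in log k
  ks <- 4^(1:6)
  counts <- 8^(6:1)
  k <- rep(ks, counts)
  r2 <- scale_free_r2(k, n_bins = 6)
  expect_equal(as.numeric(r2), 1, tolerance = 1e-9)

  flat <- scale_free_r2(rep(3, 100))
  expect_equal(as.numeric(flat), 0)
  expect_equal(attr(flat, "flag"), "degenerate_connectivity")

  # random lognormal connectivities match a direct regression oracle
  set.seed(31)
  k2 <- exp(rnorm(2000, 1, 0.7))
  got <- as.numeric(scale_free_r2(k2, 10))
  lk <- log10(k2)
  br <- seq(min(lk), max(lk), length.out = 11)
  bin <- cut(lk, br, include.lowest = TRUE)
  f <- tapply(lk, bin, length); m <- tapply(lk, bin, mean)
  keep <- !is.na(f)
  fit <- lm(log10(f[keep] / 2000) ~ m[keep])
  expect_equal(got, summary(fit)$r.squared, tolerance = 1e-12)

  # invariant to rescaling all connectivities
  expect_equal(as.numeric(scale_free_r2(7 * k2, 10)), got, tolerance = 1e-9)
})

test_that("pick_beta selects the smallest qualifying power", {
  set.seed(32)
  # block-structured correlations: R2 rises with beta
  f <- matrix(rnorm(100 * 4), 100, 4)
  load <- matrix(0, 4, 120)
  for (b in 1:4) load[b, (b - 1) * 30 + 1:30] <- 1
  expr <- f %*% load + matrix(rnorm(100 * 120, 0, 0.6), 100, 120)
  r <- cor(expr)
  cfg <- network_config(r2_min = 0.3)
  b <- pick_beta(r, cfg)
  r2 <- attr(b, "r2")
  qualifying <- as.integer(names(r2))[r2 > cfg$r2_min]
  expect_equal(as.integer(b), min(qualifying))
  expect_gt(r2[[as.character(as.integer(b))]], 0.3)

  # threshold 0: smallest candidate wins
  cfg0 <- network_config(r2_min = 0)
  expect_equal(as.integer(pick_beta(r, cfg0)), 1L)

  # unreachable threshold: argmax with a warning flag
  cfg99 <- network_config(r2_min = 0.999999)
  expect_warning(b2 <- pick_beta(r, cfg99), "argmax")
  expect_equal(as.integer(b2), as.integer(names(which.max(attr(b2, "r2")))))
})

test_that("topological overlap matches a triple-loop oracle", {
  set.seed(33)
  a <- matrix(runif(36), 6, 6); a <- (a + t(a)) / 2; diag(a) <- 0
  expect_equal(tom(a), oracle_tom(a), tolerance = 1e-12)
  # all-zero adjacency: zero off-diagonal
  z <- matrix(0, 4, 4)
  expect_equal(tom(z), diag(4))
  # complete graph with unit weights: overlap 1 everywhere
  o <- matrix(1, 5, 5); diag(o) <- 0
  expect_equal(tom(o), matrix(1, 5, 5))
  # range and symmetry on random input
  w <- tom(a)
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_equal(w, t(w), tolerance = 1e-12)
  expect_error(tom(a + 2), "\\[0, 1\\]")
})

test_that("module detection recovers planted blocks and greys out noise", {
  set.seed(34)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- cbind(outer(f1, rep(1, 30)) + matrix(rnorm(n * 30, 0, 0.4), n),
                outer(f2, rep(1, 30)) + matrix(rnorm(n * 30, 0, 0.4), n))
  colnames(expr) <- sprintf("g%02d", 1:60)
  w <- tom(adjacency(cor(expr), 6))
  part <- cluster_modules(w, network_config(min_module_size = 10))
  truth <- rep(1:2, each = 30)
  non_grey <- part$module != "grey"
  expect_gte(sum(non_grey), 55)
  expect_gt(oracle_ari(part$module[non_grey], truth[non_grey]), 0.95)
  expect_equal(sort(unique(part$module[non_grey])), c("blue", "turquoise"))

  # degenerate: fewer genes than the minimum module size
  expect_warning(small <- cluster_modules(w[1:5, 1:5],
                                          network_config(min_module_size = 20)),
                 "grey")
  expect_true(all(small$module == "grey"))
})

test_that("module eigengenes track the planted factor with stable sign", {
  set.seed(35)
  f <- rnorm(120)
  expr <- outer(f, rep(1, 25)) + matrix(rnorm(120 * 25, 0, 0.5), 120)
  colnames(expr) <- sprintf("m%02d", 1:25)
  part <- tibble::tibble(gene = colnames(expr), module = "turquoise")
  class(part) <- c("module_partition", class(part))
  eg <- module_eigengene(expr, part)
  expect_gt(abs(cor(eg$turquoise, f)), 0.9)
  eg2 <- module_eigengene(-expr, part)
  expect_equal(cor(eg$turquoise, eg2$turquoise), -1, tolerance = 1e-9)
})

test_that("module enrichment matches the hypergeometric oracle", {
  uni <- sprintf("u%03d", 1:100)
  set_ <- uni[1:10]; mod <- uni[6:25]   # overlap 5
  out <- set_enrichment(set_, mod, uni)
  expect_equal(out$overlap, 5L)
  expect_equal(out$fold, (5 / 20) / (10 / 100))
  expect_equal(out$p, oracle_hyper_tail(5, 10, 90, 20), tolerance = 1e-12)
  # set == module: fold = universe / set
  self <- set_enrichment(set_, set_, uni)
  expect_equal(self$fold, 10)
  dis <- set_enrichment(uni[1:10], uni[11:30], uni)
  expect_equal(dis$fold, 0)
  expect_gte(dis$p, 0.5)
  expect_error(set_enrichment(c(set_, "zzz"), mod, uni), "subsets")
})

test_that("KO ANOVA signature has the right power and calibration", {
  set.seed(36)
  n_genes <- 2000
  wt <- matrix(rnorm(3 * n_genes), 3)
  ko <- matrix(rnorm(3 * n_genes), 3)
  shift <- sample(n_genes, 50)
  ko[, shift] <- ko[, shift] + 5
  colnames(wt) <- colnames(ko) <- sprintf("k%04d", seq_len(n_genes))
  sig <- ko_signature(ko, wt)
  expect_gte(sum(sig$in_signature[shift]), 45)

  # identical groups: empty signature
  same <- ko_signature(wt, wt)
  expect_equal(sum(same$in_signature), 0)

  # null calibration: false-positive rate within 2 SE of alpha
  null_sig <- ko_signature(matrix(rnorm(3 * n_genes), 3),
                           matrix(rnorm(3 * n_genes), 3))
  fp <- mean(null_sig$in_signature)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(fp - 0.05), 2.5 * se)
  expect_error(ko_signature(ko[1, , drop = FALSE], wt), ">= 2")
})
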