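# Catalog construction rules: cis window, collapsing, sharing, binning,
# hotspot nulls, signature PC and trait correlations.

test_that("cis classification honours the 20 Mb inclusive window", {
  rec <- tibble::tibble(
    chr = c(3, 3, 3, 3, 5, 3),
    peak_Mb = c(50, 50, 50, 50, 50, 50),
    gene_chr = c(3, 3, 3, 3, 3, NA),
    gene_Mb = c(55, 85, 70, 70.0001, 50, NA))
  out <- classify_cis(rec)
  expect_equal(out$cis, c("cis", "trans", "cis", "trans", "trans", "unknown"))
})

test_that("catalog collapsing keeps one max-LOD record per reporter/chr/tissue", {
  rec <- tibble::tibble(
    reporter = c("a", "a", "a", "b"),
    chr = c(1, 1, 2, 1),
    tissue = "adipose",
    lod = c(6, 8, 5.5, 7))
  out <- collapse_catalog(rec)
  expect_equal(nrow(out), 3)
  expect_equal(out$lod[out$reporter == "a" & out$chr == 1], 8)
  expect_equal(nrow(collapse_catalog(rec[0, ])), 0)
})

test_that("tissue sharing uses union (or A-conditioned) denominators", {
  mk <- function(reporters, cis) tibble::tibble(
    reporter = reporters, chr = 1, tissue = "x", lod = 6, cis = cis)
  a <- mk(c("x", "y", "z"), "trans")
  b <- mk(c("y", "z", "w"), "trans")
  out <- tissue_sharing(a, b)
  expect_equal(out$fraction_pct[out$class == "trans"], 50)  # 2 of 4
  expect_equal(tissue_sharing(a, a)$fraction_pct[2], 100)
  dis <- tissue_sharing(a, mk(c("q", "r"), "trans"))
  expect_equal(dis$fraction_pct[dis$class == "trans"], 0)
  cond <- tissue_sharing(a, b, denominator = "a")
  expect_equal(cond$fraction_pct[cond$class == "trans"], 100 * 2 / 3,
               tolerance = 1e-12)
})

test_that("binning is half-open and counts unique reporters", {
  cat <- tibble::tibble(reporter = c("a", "a", "b", "c"),
                        chr = c(1, 1, 1, 1),
                        peak_cM = c(30.0, 31, 39.999, 40))
  b <- bin_counts(cat, 10, "cM")
  expect_equal(b$count[b$bin_start == 30], 2)  # a counted once, b once
  expect_equal(b$count[b$bin_start == 40], 1)  # boundary goes right
})

test_that("uniform catalogs rarely exceed modest bin maxima", {
  set.seed(6)
  mx <- replicate(30, {
    cat <- tibble::tibble(reporter = sprintf("g%04d", 1:1000),
                          chr = sample(1:10, 1000, TRUE),
                          peak_cM = runif(1000, 0, 100))
    max(bin_counts(cat, 10, "cM")$count)
  })
  expect_gte(mean(mx < 30), 0.99)
})

test_that("hotspot test matches an exact Poisson summation oracle", {
  chroms <- tibble::tibble(chr = 1:2, length = 50)
  cat <- tibble::tibble(reporter = sprintf("g%d", 1:50),
                        chr = rep(1:2, each = 25),
                        peak_cM = rep(seq(0, 48, length.out = 25), 2))
  perm <- list(cat)
  hs <- hotspot_test(cat, perm, chroms, 10, "cM")
  lambda <- 50 / 10
  for (i in seq_len(nrow(hs))) {
    k <- hs$count[i]
    oracle <- sum(exp(-lambda) * lambda^(k:200) / factorial(k:200))
    expect_equal(hs$p_poisson[i], oracle, tolerance = 1e-12)
  }
  # zero observed count in a bin is p = 1 by convention; absent bins are
  # simply not listed
  expect_true(all(hs$p_poisson <= 1))
  expect_error(hotspot_test(cat, perm, tibble::tibble(chr = 1, length = 0),
                            10, "cM"), "zero")
})

test_that("a planted hotspot dwarfs Poisson and permutation nulls", {
  cross <- small_cross$cross
  sim <- small_cross$sim
  pr <- genotype_probabilities(cross, step = 5)
  Y <- apply(sim$expr, 2, adjust_for_gender, gender = cross$gender)
  ms <- hk_scan_matrix(Y, pr)
  catalog <- build_catalog(peak_table(ms, 5), sim$genes, cross$map,
                           threshold = 5)
  perm <- permute_scan_matrix(Y, pr, n_perm = 3, seed = 2, peaks = TRUE)
  perm_cats <- lapply(perm$peak_tables, build_catalog, genes = sim$genes,
                      map = cross$map, threshold = 5)
  chroms <- tibble::tibble(chr = small_cross$cfg$chromosomes$chr,
                           length = small_cross$cfg$chromosomes$length_cM)
  hs <- hotspot_test(catalog, perm_cats, chroms, 10, "cM")
  top <- glance(hs)
  expect_equal(top$top_chr, 2)                     # the planted chromosome
  expect_lt(top$p_poisson, 1e-10)
  expect_gt(top$top_count, top$perm_max)
  expect_equal(top$p_empirical, 1 / (3 + 1))
})

test_that("signature PC1 recovers planted structure with a stable sign", {
  set.seed(7)
  f <- rnorm(100)
  expr <- outer(f, rep(1, 20)) + matrix(rnorm(2000, 0, 0.3), 100, 20)
  colnames(expr) <- sprintf("s%02d", 1:20)
  sc <- signature_pc1(expr, colnames(expr))
  expect_gt(abs(cor(sc, f)), 0.95)
  # sign flip of the input flips the score only
  sc2 <- signature_pc1(-expr, colnames(expr))
  expect_equal(abs(cor(sc, sc2)), 1, tolerance = 1e-9)
  # identical genes: |cor| with the common profile is 1
  same <- outer(f, rep(1, 3)); colnames(same) <- c("a", "b", "c")
  expect_equal(abs(cor(signature_pc1(same, colnames(same)), f)), 1,
               tolerance = 1e-9)
  expect_error(signature_pc1(expr, "s01"), "at least 2")
})

test_that("trait correlations with the PC behave under null and identity", {
  set.seed(8)
  score <- rnorm(360)
  traits <- tibble::tibble(id = as.character(1:360), self = score,
                           indep = rnorm(360),
                           tiny = c(1, 2, rep(NA, 358)))
  out <- correlate_pc_traits(score, traits)
  expect_equal(out$r[out$trait == "self"], 1, tolerance = 1e-12)
  expect_lt(abs(out$r[out$trait == "indep"]), 0.15)
  expect_true(is.na(out$r[out$trait == "tiny"]))
  expect_equal(out$flag[out$trait == "tiny"], "insufficient_pairs")
  # p-value matches the t approximation
  r <- out$r[out$trait == "indep"]
  tstat <- r * sqrt(358 / (1 - r^2))
  expect_equal(out$p[out$trait == "indep"], 2 * pt(-abs(tstat), 358),
               tolerance = 1e-9)
})

test_that("replication rules behave on self and noise cohorts", {
  cross <- small_cross$cross
  sim <- small_cross$sim
  pr <- genotype_probabilities(cross, step = 5)
  Y <- apply(sim$expr, 2, adjust_for_gender, gender = cross$gender)
  ms <- hk_scan_matrix(Y, pr)
  hot_genes <- sim$genes$gene[sim$genes$type == "hotspot"]

  self_a <- replication_analysis(hot_genes, ms, chr = 2, rule = "lod_anywhere")
  expect_equal(self_a$fraction_pct, 100)
  self_b <- replication_analysis(hot_genes, ms, chr = 2,
                                 rule = "peak_in_interval",
                                 interval = c(30, 50))
  expect_equal(self_b$fraction_pct, 100)

  # pure-noise cohort: anywhere-rule fraction stays modest
  set.seed(9)
  noise <- matrix(rnorm(200 * length(hot_genes)), 200)
  colnames(noise) <- hot_genes
  ms_noise <- hk_scan_matrix(noise, pr)
  noise_a <- replication_analysis(hot_genes, ms_noise, chr = 2,
                                  rule = "lod_anywhere")
  expect_lt(noise_a$fraction_pct, 25)
  # tighter rule is never easier
  noise_b <- replication_analysis(hot_genes, ms_noise, chr = 2,
                                  rule = "peak_in_interval",
                                  interval = c(30, 50))
  expect_lte(noise_b$fraction_pct, noise_a$fraction_pct)

  # absent reporters tallied separately
  part <- replication_analysis(c(hot_genes, "missing_gene"), ms, chr = 2)
  expect_equal(part$n_missing, 1)
  expect_equal(part$n_tested, length(hot_genes))
})

test_that("peak Mb interpolation is linear between flanking markers", {
  map <- tibble::tibble(chr = 1, pos_cM = c(0, 10, 20),
                        pos_Mb = c(0, 30, 40))
  expect_equal(interpolate_mb(map, 1, 5), 15)
  expect_equal(interpolate_mb(map, 1, 15), 35)
  expect_equal(interpolate_mb(map, 1, 25), 40)  # clamped beyond terminal
})
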