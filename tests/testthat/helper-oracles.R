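# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration, normal equations, triple loops) and stay
# independent of the package's own code paths.

# A small cross used by several files; built once.
small_cross <- local({
  cfg <- sim_config(
    n_f2 = 200,
    chromosomes = tibble::tibble(chr = 1:5, length_cM = 80, mb_per_cM = 2),
    marker_spacing = 10, missing_rate = 0.02,
    hotspot = list(chr = 2, pos_cM = 40, n_genes = 30, effect = 1,
                   sign_mix = 0.5),
    n_cis_genes = 10, n_null_genes = 40, seed = 101L)
  cross <- simulate_f2(cfg)
  sim <- simulate_expression(cross, cfg)
  list(cfg = cfg, cross = cross, sim = sim)
})

# Brute-force F2 HMM posterior by exhaustive path enumeration over a short
# chain of loci. obs: genotype codes (NA = missing) per locus; rf: vector of
# recombination fractions between adjacent loci; returns loci x 3 posterior.
oracle_genoprob <- function(obs, rf, error = 0) {
  L <- length(obs)
  prior <- c(0.25, 0.5, 0.25)
  trans <- function(r) matrix(c(
    (1 - r)^2,   2 * r * (1 - r), r^2,
    r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
    r^2,         2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
  emit <- function(g, o) {
    if (is.na(o)) 1 else if (g == o) 1 - error else error / 2
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  w <- apply(paths, 1, function(g) {
    p <- prior[g[1]] * emit(g[1], obs[1])
    if (L > 1) for (t in 2:L) {
      p <- p * trans(rf[t - 1])[g[t - 1], g[t]] * emit(g[t], obs[t])
    }
    p
  })
  post <- matrix(0, L, 3)
  for (t in seq_len(L)) for (s in 1:3) {
    post[t, s] <- sum(w[paths[, t] == s])
  }
  post / rowSums(post)
}

# Construct a degenerate genotype-probability object from hard genotype
# codes (individuals x loci), for regression-oracle comparisons.
hard_probs <- function(geno, chr = 1, pos = seq(0, by = 10,
                                                length.out = ncol(geno))) {
  n <- nrow(geno); L <- ncol(geno)
  prob <- array(0, c(n, L, 3), dimnames = list(NULL, NULL, c("AA", "AB", "BB")))
  for (t in seq_len(L)) prob[cbind(seq_len(n), t, geno[, t])] <- 1
  grid <- tibble::tibble(chr = chr, pos_cM = pos,
                         marker = sprintf("m%d", seq_len(L)), pseudo = FALSE)
  structure(list(prob = prob, grid = grid, step = 10, error = 0),
            class = "f2_genoprob")
}

# Three-parameter least squares by explicit normal equations, LOD from raw
# residual sums of squares.
oracle_hk_lod <- function(y, geno_codes) {
  la <- c(1, 0, -1)[geno_codes]
  ld <- as.numeric(geno_codes == 2)
  X <- cbind(1, la, ld)
  b <- solve(t(X) %*% X, t(X) %*% y)
  rss1 <- sum((y - X %*% b)^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Note hk components use L_A = P(AA) - P(BB); with codes 1/2/3 hard calls,
# L_A = +1 for AA, -1 for BB.

# Triple-loop topological overlap.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    w[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# Upper-tail hypergeometric by direct summation.
oracle_hyper_tail <- function(q, m, n, k) {
  sum(vapply(q:min(m, k), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1)))
}

# Upper normal tail via the complementary error function series
# (continued-fraction for large x, Taylor for small), independent of pnorm.
oracle_normal_tail <- function(z) {
  erfc_cf <- function(x) {
    # Lentz continued fraction for erfc(x), x > 0
    f <- x; c_ <- x; d <- 0
    for (i in 1:200) {
      an <- i / 2
      d <- 1 / (x + an * d)
      c_ <- x + an / c_
      f <- f * c_ * d
    }
    exp(-x^2) / sqrt(pi) / f
  }
  erf_series <- function(x) {
    s <- 0
    for (n in 0:60) s <- s + (-1)^n * x^(2 * n + 1) /
        (factorial(n) * (2 * n + 1))
    2 / sqrt(pi) * s
  }
  x <- z / sqrt(2)
  if (x > 1.5) erfc_cf(x) / 2 else (1 - erf_series(x)) / 2
}

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
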