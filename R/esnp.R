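# Matched-resampling test of whether an eSNP set is enriched for small GWAS
# p-values: random SNP sets drawn from the eligible universe, matched to the
# eSNP set's MAF-decile x distance-bin profile; Z = (observed - null mean) /
# null SD with a one-sided upper normal-tail p.

#' Filter a SNP table to the eligible universe
#'
#' Keeps SNPs within 1 Mb of a gene (distance at most 1,000,000 bp) with
#' minor allele frequency strictly greater than 0.04. SNPs with missing MAF
#' are excluded and tallied in the `excluded_missing_maf` attribute.
#'
#' @param snps Tibble with at least `maf` and `dist_gene` (bp) columns.
#' @param max_dist Maximum distance to a gene in bp.
#' @param min_maf MAF lower bound (strict).
#' @return The eligible subset, with exclusion tallies as attributes.
#' @export
eligible_universe <- function(snps, max_dist = 1e6, min_maf = 0.04) {
  miss <- is.na(snps$maf)
  keep <- !miss & snps$maf > min_maf & snps$dist_gene <= max_dist
  structure(snps[keep, ],
            excluded_missing_maf = sum(miss),
            excluded_filters = sum(!keep) - sum(miss))
}

#' Fraction of SNPs below an association threshold
#'
#' @param p Association p-values of the SNP set.
#' @param threshold Significance threshold (default 0.05; strict).
#' @return Fraction in `[0, 1]`.
#' @export
observed_fraction <- function(p, threshold = 0.05) {
  if (length(p) == 0) abort("empty SNP set.")
  mean(p < threshold)
}

# Stratum labels for matching: MAF deciles x distance quartile bins, with
# break points taken from the universe.
matching_strata <- function(universe, maf_bins = 10, dist_bins = 4) {
  maf_breaks <- unique(quantile(universe$maf, seq(0, 1, length.out = maf_bins + 1)))
  dist_breaks <- unique(quantile(universe$dist_gene,
                                 seq(0, 1, length.out = dist_bins + 1)))
  list(
    maf = function(x) cut(x, maf_breaks, include.lowest = TRUE, labels = FALSE),
    dist = function(x) cut(x, dist_breaks, include.lowest = TRUE, labels = FALSE))
}

#' Matched null resampling of SNP-set fractions
#'
#' Draws `n_resamples` random SNP sets from the universe, each matched to
#' the eSNP set's MAF-decile x distance-bin profile (sampling without
#' replacement within a resample, independent across resamples), and records
#' the fraction of each set with association p below the threshold. The
#' per-stratum hit count of a without-replacement draw is hypergeometric, so
#' the stratum counts are drawn directly from that law, which is
#' distribution-identical to materialising every index draw. Strata of the
#' universe too small to supply their quota borrow from the nearest stratum
#' with a warning.
#'
#' @param universe Eligible SNP tibble ([eligible_universe()]).
#' @param esnp_set Tibble of the eSNP set (subset of the universe columns;
#'   needs `maf` and `dist_gene` for the profile).
#' @param n_resamples Number of resamples.
#' @param seed Integer seed.
#' @param threshold Association threshold.
#' @param maf_bins,dist_bins Matching resolution.
#' @return Numeric vector of null fractions, length `n_resamples`.
#' @export
sample_null_fractions <- function(universe, esnp_set, n_resamples = 2000,
                                  seed = 1L, threshold = 0.05,
                                  maf_bins = 10, dist_bins = 4) {
  if (nrow(universe) < nrow(esnp_set))
    abort("universe smaller than the eSNP set.")
  set.seed(seed)
  strat <- matching_strata(universe, maf_bins, dist_bins)
  u_key <- paste(strat$maf(universe$maf), strat$dist(universe$dist_gene))
  s_key <- paste(strat$maf(esnp_set$maf), strat$dist(esnp_set$dist_gene))
  quota <- table(s_key)
  hit <- universe$p < threshold
  pool_n <- tapply(rep(1L, length(u_key)), u_key, sum)
  pool_hits <- tapply(hit, u_key, sum)
  m <- nrow(esnp_set)

  # pre-resolve strata that cannot supply their quota: merge into the
  # nearest stratum (by MAF then distance bin) that can
  for (k in names(quota)) {
    avail <- if (k %in% names(pool_n)) pool_n[[k]] else 0L
    if (avail < quota[[k]]) {
      warn(paste0("stratum '", k, "' too small; borrowing from neighbours."))
      parts <- as.integer(strsplit(k, " ")[[1]])
      cand <- names(pool_n)[order(vapply(strsplit(names(pool_n), " "),
        function(v) abs(as.integer(v[1]) - parts[1]) * 10 +
          abs(as.integer(v[2]) - parts[2]), numeric(1)))]
      for (nb in cand) {
        if (nb == k) next
        pool_n[nb] <- pool_n[[nb]] + avail
        pool_hits[nb] <- pool_hits[[nb]] + (if (avail > 0) pool_hits[[k]] else 0)
        quota_nb <- if (nb %in% names(quota)) quota[[nb]] else 0
        quota[nb] <- quota_nb + quota[[k]]
        quota <- quota[names(quota) != k]
        pool_n <- pool_n[names(pool_n) != k]
        pool_hits <- pool_hits[names(pool_hits) != k]
        break
      }
    }
  }
  quota <- quota[quota > 0]
  counts <- numeric(n_resamples)
  for (k in names(quota)) {
    counts <- counts + stats::rhyper(n_resamples, pool_hits[[k]],
                                     pool_n[[k]] - pool_hits[[k]],
                                     quota[[k]])
  }
  counts / m
}

#' Z statistic and normal-tail p for eSNP enrichment
#'
#' `Z = (observed - null mean) / null SD`; `p = 1 - Phi(Z)` (one-sided upper
#' tail); the 95% CI is the 2.5/97.5 percentile range of the null fractions.
#'
#' @param observed Observed fraction of the eSNP set below the threshold.
#' @param null_fractions Vector from [sample_null_fractions()].
#' @return Tibble: observed, null_mean, null_sd, ci_low, ci_high, z, p.
#' @export
z_and_p <- function(observed, null_fractions) {
  m <- mean(null_fractions); s <- sd(null_fractions)
  if (!is.finite(s) || s <= 0) abort("degenerate null: SD is zero.")
  z <- (observed - m) / s
  ci <- unname(quantile(null_fractions, c(0.025, 0.975)))
  tibble(observed = observed, null_mean = m, null_sd = s,
         ci_low = ci[1], ci_high = ci[2], z = z,
         p = pnorm(z, lower.tail = FALSE))
}

#' Full matched-resampling eSNP enrichment test
#'
#' Filters to the eligible universe, computes the observed fraction of the
#' eSNP set with GWAS p below the threshold, builds the matched null, and
#' reports the Z statistic with its one-sided normal-tail p.
#'
#' @param snps Full SNP table.
#' @param esnp_ids Ids of the eSNP set (matched on the `snp` column).
#' @param threshold Association threshold.
#' @param n_resamples Number of matched resamples (the production default is
#'   100,000; tests use far fewer).
#' @param seed Integer seed.
#' @return Object of class `esnp_result`: one-row tibble from [z_and_p()]
#'   plus `n_set`, `n_universe`, `n_resamples`, `seed`.
#' @export
esnp_enrichment <- function(snps, esnp_ids, threshold = 0.05,
                            n_resamples = 100000, seed = 1L) {
  uni <- eligible_universe(snps)
  set <- uni[uni$snp %in% esnp_ids, ]
  if (nrow(set) == 0) abort("no eligible eSNPs.")
  obs <- observed_fraction(set$p, threshold)
  nulls <- sample_null_fractions(uni, set, n_resamples, seed, threshold)
  res <- z_and_p(obs, nulls)
  res$n_set <- nrow(set); res$n_universe <- nrow(uni)
  res$n_resamples <- n_resamples; res$seed <- seed
  structure(res, class = c("esnp_result", class(res)),
            null_fractions = nulls)
}
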