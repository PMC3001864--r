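# Permutation-based FDR for clinical-trait QTL (trait-wise nulls) and eQTL
# (null pooled across probes from a small number of permuted scans).

#' Trait-wise permutation FDR for clinical-trait QTL
#'
#' Converts the observed peak LOD of each trait to an empirical p-value
#' against its own permutation null, `p = (1 + #\{null >= obs\}) / (n_perm + 1)`,
#' converts the permuted genome-wide maxima to p-values the same way, and
#' estimates `FDR(t) = mean over permutations of #\{p_perm <= t\} /
#' max(1, #\{p_obs <= t\})`, monotonised so that FDR never increases as the
#' threshold tightens.
#'
#' @param obs_lod Named vector of observed genome-wide peak LODs, one per
#'   trait.
#' @param nulls Named list of [permute_and_scan()] results (or numeric
#'   max-LOD vectors), one per trait, same names as `obs_lod`.
#' @return Object of class `fdr_table`: tibble with `trait`, `lod`,
#'   `p_obs`, `fdr`, sorted by decreasing LOD; attribute `provenance`.
#' @export
trait_fdr <- function(obs_lod, nulls) {
  if (!setequal(names(obs_lod), names(nulls)))
    abort("`obs_lod` and `nulls` must cover the same traits.")
  nulls <- lapply(nulls, function(x) if (is.list(x)) x$max_lod else x)
  nperm <- length(nulls[[1]])
  traits <- names(obs_lod)
  p_obs <- vapply(traits, function(tr) {
    (1 + sum(nulls[[tr]] >= obs_lod[[tr]])) / (nperm + 1)
  }, numeric(1))
  # permuted maxima converted to p within their own trait's null
  p_perm <- matrix(NA_real_, length(traits), nperm,
                   dimnames = list(traits, NULL))
  for (tr in traits) {
    nl <- nulls[[tr]]
    p_perm[tr, ] <- vapply(nl, function(v) (1 + sum(nl >= v)) / (nperm + 1),
                           numeric(1))
  }
  ord <- order(p_obs)
  thresholds <- p_obs[ord]
  fdr <- vapply(thresholds, function(t) {
    mean(colSums(p_perm <= t)) / max(1, sum(p_obs <= t))
  }, numeric(1))
  fdr <- pmin(fdr, 1)
  # q-value style monotonisation over increasing p thresholds
  fdr <- rev(cummin(rev(fdr)))
  res <- tibble(trait = traits[ord], lod = unname(obs_lod[ord]),
                p_obs = unname(thresholds), fdr = fdr)
  structure(res, class = c("fdr_table", class(res)),
            provenance = list(kind = "trait-wise", n_perm = nperm))
}

#' Pooled permutation FDR for eQTL
#'
#' Pools permuted peak LODs across all probes as the null distribution and
#' estimates, at each observed LOD threshold `lambda`,
#' `FDR(lambda) = (average permuted count >= lambda) / (observed count >=
#' lambda)`, monotonised to be non-increasing in `lambda` and capped at 1.
#'
#' @param obs_lod Numeric vector of observed peak LODs across probes (one
#'   entry per collapsed eQTL candidate).
#' @param perm_lod Matrix probes x permutations (or list of vectors) of
#'   permuted peak LODs.
#' @return Object of class `fdr_table`: tibble with `lod`, `fdr`.
#' @export
eqtl_fdr <- function(obs_lod, perm_lod) {
  if (is.list(perm_lod)) perm_lod <- do.call(cbind, perm_lod)
  nperm <- ncol(perm_lod)
  lambdas <- sort(unique(obs_lod), decreasing = TRUE)
  fdr <- vapply(lambdas, function(l) {
    n_obs <- sum(obs_lod >= l)
    if (n_obs == 0) return(1)
    min(1, (sum(perm_lod >= l) / nperm) / n_obs)
  }, numeric(1))
  fdr <- cummax(fdr)  # non-increasing in lod = non-decreasing going down
  res <- tibble(lod = lambdas, fdr = fdr)
  structure(res, class = c("fdr_table", class(res)),
            provenance = list(kind = "pooled-eqtl", n_perm = nperm))
}

#' Look up the estimated FDR at a LOD threshold
#'
#' @param table An `fdr_table`.
#' @param lod LOD threshold(s).
#' @return Estimated FDR at each threshold (FDR of the closest attained
#'   threshold at or below the requested LOD; 1 if none attained).
#' @export
fdr_at_lod <- function(table, lod) {
  tab <- as_tibble(table)
  tab <- tab[order(tab$lod), ]
  vapply(lod, function(l) {
    i <- which(tab$lod >= l)
    if (length(i) == 0) 1 else max(tab$fdr[i][which.min(tab$lod[i])], 0)
  }, numeric(1))
}
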