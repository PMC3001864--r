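# Hotspot-signature summaries: cross-cohort replication of signature eQTL,
# the first principal component of the signature expression submatrix, and
# its correlation with clinical traits.

#' Cross-cohort replication of signature eQTL
#'
#' For each signature reporter present in the replication cohort, checks
#' whether its LOD curve on the stated chromosome satisfies the replication
#' rule: rule `"lod_anywhere"` requires LOD at or above `lod` anywhere on
#' the chromosome; rule `"peak_in_interval"` additionally requires the
#' chromosome-wide maximum-LOD position to fall inside `interval` (cM).
#'
#' @param reporters Character vector of signature reporter ids.
#' @param scan An [hk_scan_matrix()] result for the replication cohort
#'   (columns covering the reporters; absent reporters are tallied
#'   separately, not counted as failures).
#' @param chr Chromosome on which replication is assessed.
#' @param rule `"lod_anywhere"` or `"peak_in_interval"`.
#' @param lod LOD threshold (default 2 for `"lod_anywhere"`, 3 is the
#'   conventional stricter choice for `"peak_in_interval"`).
#' @param interval Length-2 cM interval for `"peak_in_interval"`.
#' @return Tibble: rule, n_tested, n_replicated, n_missing, fraction_pct.
#' @export
replication_analysis <- function(reporters, scan, chr,
                                 rule = c("lod_anywhere", "peak_in_interval"),
                                 lod = if (match.arg(rule) == "lod_anywhere") 2 else 3,
                                 interval = NULL) {
  rule <- match.arg(rule)
  present <- intersect(reporters, colnames(scan$lod))
  missing <- setdiff(reporters, present)
  idx <- which(scan$grid$chr == chr)
  if (length(idx) == 0) abort("no grid loci on the requested chromosome.")
  sub <- scan$lod[idx, present, drop = FALSE]
  if (rule == "lod_anywhere") {
    rep_ok <- apply(sub, 2, max) >= lod
  } else {
    if (is.null(interval) || length(interval) != 2)
      abort("`interval` (length-2 cM range) required for peak_in_interval.")
    pk <- max.col(t(sub), ties.method = "first")
    pk_pos <- scan$grid$pos_cM[idx][pk]
    pk_lod <- sub[cbind(pk, seq_len(ncol(sub)))]
    rep_ok <- pk_lod >= lod & pk_pos >= interval[1] & pk_pos <= interval[2]
  }
  n_tested <- length(present)
  tibble(rule = rule, lod_threshold = lod,
         n_tested = n_tested, n_replicated = sum(rep_ok),
         n_missing = length(missing),
         fraction_pct = if (n_tested == 0) NA_real_ else
           100 * sum(rep_ok) / n_tested)
}

#' First principal component of a signature expression submatrix
#'
#' Standardises each signature gene across individuals, takes the first
#' principal component, and orients the sign so the sum of gene loadings is
#' positive.
#'
#' @param expr Individuals x genes expression matrix.
#' @param reporters At least two signature gene ids (columns of `expr`).
#' @return Numeric per-individual score vector (PC1 scores).
#' @export
signature_pc1 <- function(expr, reporters) {
  reporters <- intersect(reporters, colnames(expr))
  if (length(reporters) < 2) abort("need at least 2 signature genes.")
  sub <- scale(expr[, reporters, drop = FALSE])
  pc <- prcomp(sub, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (sum(pc$rotation[, 1]) < 0) score <- -score
  unname(score)
}

#' Correlate a per-individual score with clinical traits
#'
#' Pearson correlation with a two-sided t-approximation p-value per numeric
#' trait column, pairwise-complete.
#'
#' @param score Per-individual score (e.g. [signature_pc1()]).
#' @param traits Tibble of traits; non-numeric columns (ids, gender) are
#'   ignored.
#' @return Tibble: trait, n, r, p (NA with a flag when fewer than 3
#'   complete pairs).
#' @export
correlate_pc_traits <- function(score, traits) {
  num <- names(traits)[vapply(traits, is.numeric, logical(1))]
  out <- lapply(num, function(tr) {
    y <- traits[[tr]]
    ok <- complete.cases(score, y)
    if (sum(ok) < 3)
      return(tibble(trait = tr, n = sum(ok), r = NA_real_, p = NA_real_,
                    flag = "insufficient_pairs"))
    ct <- cor.test(score[ok], y[ok], method = "pearson")
    tibble(trait = tr, n = sum(ok), r = unname(ct$estimate),
           p = ct$p.value, flag = NA_character_)
  })
  bind_rows(out)
}
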