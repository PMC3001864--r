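# Weighted gene co-expression network analysis: soft-threshold power
# selection by scale-free topology fit, topological overlap, average-linkage
# module detection with a fixed-height branch cut, module eigengenes, and
# gene-set / knockout-signature enrichment.

MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Network construction configuration
#'
#' @param top_fraction Fraction of most variable genes retained.
#' @param beta_range Candidate integer soft-threshold powers.
#' @param r2_min Minimum scale-free fitting index R^2.
#' @param n_bins Connectivity-histogram bins for the fit.
#' @param min_module_size Smallest non-grey module.
#' @param cut_height Absolute dissimilarity height for the branch cut
#'   (on the 1 - TOM scale; background gene joins saturate at 1, so the
#'   cut sits just below).
#' @param rank_by `"variance"` or `"mad"` for [select_top_variable()].
#' @param signed Use signed correlations (negative correlations get zero
#'   weight) instead of absolute values.
#' @return A `network_config` list.
#' @export
network_config <- function(top_fraction = 0.25, beta_range = 1:20,
                           r2_min = 0.8, n_bins = 10, min_module_size = 20,
                           cut_height = 0.99,
                           rank_by = c("variance", "mad"), signed = FALSE) {
  rank_by <- match.arg(rank_by)
  if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` not in (0,1].")
  if (any(beta_range < 1)) abort("`beta_range` powers must be >= 1.")
  if (min_module_size < 2) abort("`min_module_size` must be >= 2.")
  if (cut_height <= 0 || cut_height > 1) abort("`cut_height` not in (0,1].")
  structure(list(top_fraction = top_fraction, beta_range = as.integer(beta_range),
                 r2_min = r2_min, n_bins = n_bins,
                 min_module_size = min_module_size,
                 cut_height = cut_height, rank_by = rank_by,
                 signed = signed),
            class = "network_config")
}

#' Select the most variable genes
#'
#' Ranks genes by variance (or MAD) across individuals and keeps
#' `floor(fraction * n_genes)`, ties broken by gene id.
#'
#' @param expr Individuals x genes matrix.
#' @param fraction Fraction to keep.
#' @param rank_by `"variance"` or `"mad"`.
#' @return Character vector of selected gene ids.
#' @export
select_top_variable <- function(expr, fraction = 0.25,
                                rank_by = c("variance", "mad")) {
  rank_by <- match.arg(rank_by)
  if (fraction <= 0) abort("`fraction` must be positive.")
  if (ncol(expr) < 1) abort("need at least one gene.")
  v <- if (rank_by == "variance") apply(expr, 2, var) else
    apply(expr, 2, stats::mad)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(expr)))
  ord <- order(-v, ids)
  k <- min(floor(fraction * ncol(expr)), ncol(expr))
  ids[ord][seq_len(max(k, 1))]
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned: `a_ij = |r_ij|^beta`; signed (`signed = TRUE`):
#' `a_ij = r_ij^beta` truncated at zero for negative correlations (odd
#' powers) -- the absolute-value network is the default. Diagonal set to 0.
#'
#' @param correlations Symmetric correlation matrix in `[-1, 1]`.
#' @param beta Soft-threshold power (>= 1).
#' @param signed Use the signed variant.
#' @return Weighted adjacency matrix with zero diagonal.
#' @export
adjacency <- function(correlations, beta, signed = FALSE) {
  if (beta < 1) abort("`beta` must be >= 1.")
  a <- if (signed) pmax(correlations, 0)^beta else abs(correlations)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fitting index
#'
#' Bins connectivities into equal-width bins on the log scale, computes the
#' frequency p(k) per bin, and reports the R^2 of the least-squares line of
#' log p(k) on the mean log k per occupied bin. Degenerate inputs (all k
#' equal, or fewer than 3 occupied bins) return 0 with a flag.
#'
#' @param k Connectivity vector (row sums of the adjacency).
#' @param n_bins Number of histogram bins.
#' @return Numeric R^2 with attribute `flag`.
#' @export
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2)
    return(structure(0, flag = "degenerate_connectivity"))
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  bin <- cut(lk, breaks, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  centers <- tapply(lk, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(structure(0, flag = "too_few_bins"))
  x <- centers[keep]
  y <- log10(freq[keep] / length(lk))
  if (sd(y) < 1e-12) return(structure(0, flag = "flat_pk"))
  structure(unname(cor(x, y)^2), flag = NULL)
}

#' Pick the soft-threshold power
#'
#' Returns the smallest candidate power whose network has a scale-free
#' fitting index above the configured minimum; if none qualifies, the
#' argmax-R^2 power with a warning flag.
#'
#' @param correlations Gene-gene correlation matrix.
#' @param config A [network_config()].
#' @return Integer beta with attributes `r2` (per-candidate R^2 vector) and
#'   `flag`.
#' @export
pick_beta <- function(correlations, config = network_config()) {
  r2 <- vapply(config$beta_range, function(b) {
    a <- adjacency(correlations, b, signed = config$signed)
    as.numeric(scale_free_r2(rowSums(a), config$n_bins))
  }, numeric(1))
  names(r2) <- config$beta_range
  ok <- which(r2 > config$r2_min)
  if (length(ok) > 0) {
    structure(config$beta_range[ok[1]], r2 = r2, flag = NULL)
  } else {
    warn("no candidate power reaches the scale-free R^2 minimum; using argmax.")
    structure(config$beta_range[which.max(r2)], r2 = r2,
              flag = "below_threshold")
  }
}

#' Topological overlap matrix
#'
#' `omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with unit diagonal. Captures shared-neighbour structure on top
#' of the direct connection.
#'
#' @param a Adjacency matrix with entries in `[0, 1]` and zero diagonal.
#' @return Topological overlap matrix (symmetric, entries in `[0, 1]`).
#' @export
tom <- function(a) {
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0, 1].")
  k <- rowSums(a)
  shared <- a %*% a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  w <- num / den
  diag(w) <- 1
  w
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the topological-overlap
#' dissimilarity `1 - omega`, followed by a fixed-height branch cut at the
#' configured absolute height; branches of at least the minimum size become
#' colour-labelled modules (descending size order from a fixed palette),
#' all other genes are grey.
#'
#' @param w Topological overlap matrix (gene names as dimnames).
#' @param config A [network_config()].
#' @return Object of class `module_partition`: tibble (gene, module) with
#'   attributes `sizes`, `heights`, `cut_height`.
#' @export
cluster_modules <- function(w, config = network_config()) {
  genes <- rownames(w)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(w)))
  if (nrow(w) < config$min_module_size) {
    warn("fewer genes than the minimum module size; all grey.")
    res <- tibble(gene = genes, module = "grey")
    return(structure(res, class = c("module_partition", class(res)),
                     sizes = integer(0), heights = numeric(0),
                     cut_height = NA_real_))
  }
  hc <- hclust(as.dist(1 - w), method = "average")
  cut_h <- config$cut_height
  cl <- cutree(hc, h = cut_h)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= config$min_module_size]
  labels <- rep("grey", length(cl))
  for (i in seq_along(big)) {
    col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else
      sprintf("module%02d", i)
    labels[cl == as.integer(big[i])] <- col
  }
  res <- tibble(gene = genes, module = labels)
  mod_sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  structure(res, class = c("module_partition", class(res)),
            sizes = mod_sizes, heights = hc$height, cut_height = cut_h)
}

#' Module eigengenes
#'
#' First principal component of each module's standardised expression
#' submatrix, sign-oriented so the mean correlation with the module's genes
#' is positive, returned standardised.
#'
#' @param expr Individuals x genes matrix.
#' @param partition A [cluster_modules()] result.
#' @return Tibble individuals x modules (column per non-grey module), plus a
#'   `flags` attribute naming degenerate modules.
#' @export
module_eigengene <- function(expr, partition) {
  mods <- setdiff(unique(partition$module), "grey")
  flags <- character(0)
  out <- tibble(.rows = nrow(expr))
  for (m in mods) {
    genes <- intersect(partition$gene[partition$module == m], colnames(expr))
    if (length(genes) < 2) { flags <- c(flags, m); next }
    sub <- scale(expr[, genes, drop = FALSE])
    if (any(!is.finite(sub))) { flags <- c(flags, m); next }
    pc <- prcomp(sub, center = FALSE)
    e <- pc$x[, 1]
    if (mean(cor(e, sub)) < 0) e <- -e
    out[[m]] <- as.numeric(scale(e))
  }
  structure(out, flags = flags)
}

#' Gene-set enrichment of a module (hypergeometric)
#'
#' Fold = (|set intersect module| / |module|) / (|set| / |universe|), with an
#' upper-tail hypergeometric p-value.
#'
#' @param set,module_genes,universe Character vectors of gene ids; `set` and
#'   `module_genes` must be subsets of `universe`.
#' @return Tibble: overlap, fold, p.
#' @export
set_enrichment <- function(set, module_genes, universe) {
  set <- unique(set); module_genes <- unique(module_genes)
  universe <- unique(universe)
  if (!all(set %in% universe) || !all(module_genes %in% universe))
    abort("`set` and `module_genes` must be subsets of `universe`.")
  if (length(set) == 0 || length(module_genes) == 0)
    return(tibble(overlap = 0L, fold = NA_real_, p = 1))
  ov <- length(intersect(set, module_genes))
  fold <- (ov / length(module_genes)) / (length(set) / length(universe))
  p <- phyper(ov - 1, length(set), length(universe) - length(set),
              length(module_genes), lower.tail = FALSE)
  tibble(overlap = as.integer(ov), fold = fold, p = p)
}

#' Knockout differential-expression signature
#'
#' Per-gene one-way ANOVA comparing knockout and wild-type groups; the
#' signature is the set of genes with p below `alpha`.
#'
#' @param ko,wt Samples x genes expression matrices (same genes).
#' @param alpha Signature p-value threshold.
#' @return Tibble: gene, F, p, in_signature.
#' @export
ko_signature <- function(ko, wt, alpha = 0.05) {
  if (nrow(ko) < 2 || nrow(wt) < 2) abort("need >= 2 samples per group.")
  if (ncol(ko) != ncol(wt)) abort("gene sets differ between groups.")
  n1 <- nrow(ko); n2 <- nrow(wt); n <- n1 + n2
  m1 <- colMeans(ko); m2 <- colMeans(wt)
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums(sweep(ko, 2, m1)^2) + colSums(sweep(wt, 2, m2)^2)
  Fstat <- (ssb / 1) / (ssw / (n - 2))
  p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
  # both groups constant and equal: 0/0 -> no evidence
  p[ssb < 1e-24 & ssw < 1e-24] <- 1
  genes <- colnames(ko)
  if (is.null(genes)) genes <- as.character(seq_along(p))
  tibble(gene = genes, F = Fstat, p = p, in_signature = p < alpha)
}
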