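# Single-QTL Haley-Knott genome scans with additive + dominance components.
# At each grid locus the trait is regressed on the expected genotype
# components L_A = P(AA) - P(BB) and L_D = P(AB); LOD = (n/2) log10(RSS0/RSS1)
# against the intercept-only model.

LOD_CAP <- 300

#' Pre-adjust a trait for gender
#'
#' Returns the residuals of a least-squares fit of the trait on an intercept
#' and the gender indicator; downstream scans use these residuals as the
#' dependent variable.
#'
#' @param y Numeric trait vector (may contain `NA`).
#' @param gender Two-level factor or binary vector, no missing values.
#' @return Residual vector (mean zero) with `NA` preserved at missing `y`.
#' @export
adjust_for_gender <- function(y, gender) {
  if (anyNA(gender)) abort("`gender` must not contain missing values.")
  g <- as.integer(factor(gender))
  if (length(unique(g[!is.na(y)])) < 2) {
    warn("only one gender level present; returning centred trait.")
    return(y - mean(y, na.rm = TRUE))
  }
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  fit <- lm.fit(cbind(1, g[ok]), y[ok])
  out[ok] <- fit$residuals
  out
}

# Design components at every grid locus: list of n x 2 pieces is wasteful;
# return two matrices n x L.
hk_components <- function(probs) {
  n <- dim(probs$prob)[1]
  list(LA = matrix(probs$prob[, , "AA"] - probs$prob[, , "BB"], nrow = n),
       LD = matrix(probs$prob[, , "AB"], nrow = n))
}

#' Haley-Knott single-QTL genome scan
#'
#' Regresses a trait on `[1, L_A, L_D]` at every grid locus and reports the
#' LOD score `(n/2) log10(RSS0/RSS1)` against the intercept-only model.
#' Individuals with missing trait values are dropped. A perfect fit is
#' capped at LOD 300 and flagged; a rank-deficient design drops the
#' dominance column and is flagged.
#'
#' @param y Numeric trait vector aligned to the individuals of `probs`.
#' @param probs An [genotype_probabilities()] result.
#' @param min_n Minimum number of non-missing observations.
#' @return Object of class `lod_scan`: tibble of the grid with a `lod`
#'   column, plus attributes `peak` (tibble), `coef_peak`, `n`, `flags`.
#' @export
hk_scan <- function(y, probs, min_n = 10) {
  if (length(y) != dim(probs$prob)[1])
    abort("`y` length does not match the individuals in `probs`.")
  ok <- !is.na(y)
  if (sum(ok) < min_n) abort("fewer than `min_n` non-missing observations.")
  comp <- hk_components(probs)
  yv <- y[ok]
  n <- length(yv)
  rss0 <- sum((yv - mean(yv))^2)
  L <- nrow(probs$grid)
  lod <- numeric(L)
  if (rss0 <= 0) {
    # constant trait carries no linkage information
    res <- probs$grid
    res$lod <- lod
    return(structure(res, class = c("lod_scan", class(res)),
                     peak = tibble(chr = res$chr[1], pos_cM = res$pos_cM[1],
                                   lod = 0),
                     coef_peak = c(mu = mean(yv), add = 0, dom = 0), n = n,
                     flags = "constant_trait"))
  }
  flags <- character(0)
  coefs <- matrix(NA_real_, L, 3,
                  dimnames = list(NULL, c("mu", "add", "dom")))
  for (t in seq_len(L)) {
    X <- cbind(1, comp$LA[ok, t], comp$LD[ok, t])
    fit <- lm.fit(X, yv)
    if (fit$rank < 3) {
      fit <- lm.fit(X[, 1:2, drop = FALSE], yv)
      flags <- union(flags, "rank_deficient")
      coefs[t, 1:2] <- fit$coefficients
    } else {
      coefs[t, ] <- fit$coefficients
    }
    rss1 <- sum(fit$residuals^2)
    if (rss1 <= 0 || !is.finite(rss1)) {
      lod[t] <- LOD_CAP
      flags <- union(flags, "lod_capped")
    } else {
      lod[t] <- (n / 2) * log10(rss0 / rss1)
      if (lod[t] > LOD_CAP) {
        lod[t] <- LOD_CAP
        flags <- union(flags, "lod_capped")
      }
    }
  }
  lod <- pmax(lod, 0)
  res <- probs$grid
  res$lod <- lod
  pk <- which.max(lod)
  structure(res,
            class = c("lod_scan", class(res)),
            peak = tibble(chr = res$chr[pk], pos_cM = res$pos_cM[pk],
                          lod = lod[pk]),
            coef_peak = coefs[pk, ], n = n, flags = flags)
}

#' Haley-Knott scan of many traits at once
#'
#' Vectorised over traits: one least-squares solve per locus with all trait
#' columns as right-hand sides. Traits must be complete (no `NA`); use
#' [hk_scan()] for traits with missingness.
#'
#' @param Y Numeric matrix, individuals x traits.
#' @param probs An [genotype_probabilities()] result.
#' @return Object of class `lod_scan_matrix`: list with `lod` (loci x traits
#'   matrix), `grid`, `n`.
#' @export
hk_scan_matrix <- function(Y, probs) {
  if (anyNA(Y)) abort("`Y` must be complete; scan traits with NA one at a time.")
  comp <- hk_components(probs)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  yty <- rss0
  L <- nrow(probs$grid)
  lod <- matrix(0, L, ncol(Y), dimnames = list(NULL, colnames(Y)))
  for (t in seq_len(L)) {
    X <- cbind(1, comp$LA[, t], comp$LD[, t])
    qx <- qr(X)
    # RSS1 = ||y||^2 - ||Q'y||^2 on centred y (intercept included in X)
    qty <- qr.qty(qx, Yc)[seq_len(qx$rank), , drop = FALSE]
    rss1 <- pmax(yty - colSums(qty^2), 0)
    l <- ifelse(rss0 <= 0, 0,
                ifelse(rss1 <= 0, LOD_CAP, (n / 2) * log10(rss0 / rss1)))
    lod[t, ] <- pmin(pmax(l, 0), LOD_CAP)
  }
  structure(list(lod = lod, grid = probs$grid, n = n),
            class = "lod_scan_matrix")
}

#' Per-trait, per-chromosome peak table of a matrix scan
#'
#' @param scan An [hk_scan_matrix()] result.
#' @param threshold Keep peaks with LOD at or above this value.
#' @return Tibble: trait, chr, pos_cM, lod.
#' @export
peak_table <- function(scan, threshold = 0) {
  grid <- scan$grid
  out <- list()
  for (ch in unique(grid$chr)) {
    idx <- which(grid$chr == ch)
    sub <- scan$lod[idx, , drop = FALSE]
    pk <- max.col(t(sub), ties.method = "first")
    lods <- sub[cbind(pk, seq_len(ncol(sub)))]
    out[[as.character(ch)]] <- tibble(
      trait = colnames(scan$lod), chr = ch,
      pos_cM = grid$pos_cM[idx][pk], lod = lods)
  }
  res <- bind_rows(out)
  res[res$lod >= threshold, ]
}

#' Permutation null of the genome-wide maximum LOD
#'
#' Permutes individual labels of the trait against the genotypes (whole
#' genotype rows preserved, the standard QTL permutation), rescans, and
#' records the genome-wide maximum LOD per permutation.
#'
#' @param y Trait vector (or residuals from [adjust_for_gender()]).
#' @param probs Genotype probabilities.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `perm_null`: list with `max_lod`, `n_perm`,
#'   `seed`.
#' @export
permute_and_scan <- function(y, probs, n_perm, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  set.seed(seed)
  n <- length(y)
  mx <- vapply(seq_len(n_perm), function(i) {
    yp <- y[sample.int(n)]
    max(hk_scan(yp, probs)$lod)
  }, numeric(1))
  structure(list(max_lod = mx, n_perm = n_perm, seed = seed),
            class = "perm_null")
}

#' Permutation scans for a trait matrix
#'
#' One shared individual-label permutation per round applied to all columns,
#' then a matrix scan; returns per-trait genome-wide maxima and, optionally,
#' per-trait per-chromosome peaks for building permuted eQTL catalogs.
#'
#' @inheritParams hk_scan_matrix
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param peaks If `TRUE`, also keep the per-chromosome peak table of every
#'   permutation.
#' @return List with `max_lod` (traits x n_perm matrix) and optionally
#'   `peak_tables` (list of tibbles).
#' @export
permute_scan_matrix <- function(Y, probs, n_perm, seed = 1L, peaks = FALSE) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  set.seed(seed)
  n <- nrow(Y)
  mx <- matrix(NA_real_, ncol(Y), n_perm,
               dimnames = list(colnames(Y), NULL))
  pts <- if (peaks) vector("list", n_perm) else NULL
  for (i in seq_len(n_perm)) {
    sc <- hk_scan_matrix(Y[sample.int(n), , drop = FALSE], probs)
    mx[, i] <- apply(sc$lod, 2, max)
    if (peaks) pts[[i]] <- peak_table(sc)
  }
  list(max_lod = mx, peak_tables = pts, n_perm = n_perm, seed = seed)
}
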