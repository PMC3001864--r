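# Likelihood-based causality model selection (LCMS). Given a locus L with
# per-individual genotype posteriors, a transcript R and a clinical trait C
# that share the locus, three generative models are compared by AIC:
#   M1 causal:      P(L) P(R|L) P(C|R)   -- L acts on C through R
#   M2 reactive:    P(L) P(C|L) P(R|C)   -- R lies downstream of C
#   M3 independent: P(L) P(R|L) P(C|L)   -- L acts on R and C independently
# R and C are normal about per-genotype means at L; genotype uncertainty is
# handled by a mixture likelihood over the 3-class posterior. P(L) is common
# to all three models and drops out of AIC differences.

#' Find cQTL:eQTL genomic overlaps
#'
#' Collects trait-transcript pairs whose QTL peaks (LOD at or above
#' `peak_lod`) have intersecting support regions on the same chromosome,
#' where the support region is the maximal contiguous run of loci with LOD
#' above `overlap_lod` containing the peak. The test marker L is the
#' genotyped marker nearest the midpoint of the two peak positions (ties go
#' to the lower cM).
#'
#' @param trait_scans Named list of [hk_scan()] results (clinical traits).
#' @param expr_scans An [hk_scan_matrix()] result (transcripts), or a named
#'   list of `lod_scan` objects.
#' @param map Genotyped-marker map (`marker`, `chr`, `pos_cM`).
#' @param peak_lod Minimum peak LOD for both members (default 2).
#' @param overlap_lod Support-region threshold (LOD strictly above; default 1).
#' @return Tibble: trait, reporter, chr, trait_peak_cM, expr_peak_cM,
#'   marker, marker_cM.
#' @export
find_overlaps <- function(trait_scans, expr_scans, map,
                          peak_lod = 2, overlap_lod = 1) {
  trait_peaks <- purrr::imap_dfr(trait_scans, function(s, nm)
    scan_supports(as_tibble(s)[c("chr", "pos_cM", "lod")], nm,
                  peak_lod, overlap_lod))
  if (inherits(expr_scans, "lod_scan_matrix")) {
    expr_peaks <- purrr::map_dfr(colnames(expr_scans$lod), function(g) {
      d <- expr_scans$grid[c("chr", "pos_cM")]
      d$lod <- expr_scans$lod[, g]
      scan_supports(d, g, peak_lod, overlap_lod)
    })
  } else {
    expr_peaks <- purrr::imap_dfr(expr_scans, function(s, nm)
      scan_supports(as_tibble(s)[c("chr", "pos_cM", "lod")], nm,
                    peak_lod, overlap_lod))
  }
  if (nrow(trait_peaks) == 0 || nrow(expr_peaks) == 0)
    return(tibble(trait = character(), reporter = character(), chr = numeric(),
                  trait_peak_cM = numeric(), expr_peak_cM = numeric(),
                  marker = character(), marker_cM = numeric()))
  pairs <- inner_join(trait_peaks, expr_peaks, by = "chr",
                      suffix = c("_t", "_e"), relationship = "many-to-many")
  pairs <- pairs[pairs$lo_t <= pairs$hi_e & pairs$lo_e <= pairs$hi_t, ]
  if (nrow(pairs) == 0)
    return(tibble(trait = character(), reporter = character(), chr = numeric(),
                  trait_peak_cM = numeric(), expr_peak_cM = numeric(),
                  marker = character(), marker_cM = numeric()))
  mid <- (pairs$peak_t + pairs$peak_e) / 2
  mk <- character(nrow(pairs)); mk_cm <- numeric(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sub <- map[map$chr == pairs$chr[i], ]
    if (nrow(sub) == 0) {
      warn(paste0("no genotyped marker on chr ", pairs$chr[i],
                  "; overlap dropped."))
      next
    }
    d <- abs(sub$pos_cM - mid[i])
    # tie -> lower cM
    cand <- which(d == min(d))
    j <- cand[which.min(sub$pos_cM[cand])]
    mk[i] <- sub$marker[j]; mk_cm[i] <- sub$pos_cM[j]; keep[i] <- TRUE
  }
  tibble(trait = pairs$id_t[keep], reporter = pairs$id_e[keep],
         chr = pairs$chr[keep], trait_peak_cM = pairs$peak_t[keep],
         expr_peak_cM = pairs$peak_e[keep],
         marker = mk[keep], marker_cM = mk_cm[keep])
}

# Per-chromosome peak + LOD>overlap support run containing the peak.
scan_supports <- function(d, id, peak_lod, overlap_lod) {
  out <- list()
  for (ch in unique(d$chr)) {
    s <- d[d$chr == ch, ]
    s <- s[order(s$pos_cM), ]
    pk <- which.max(s$lod)
    if (s$lod[pk] < peak_lod) next
    above <- s$lod > overlap_lod
    lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- pk; while (hi < nrow(s) && above[hi + 1]) hi <- hi + 1
    out[[as.character(ch)]] <- tibble(
      id = id, chr = ch, peak = s$pos_cM[pk], peak_lod = s$lod[pk],
      lo = s$pos_cM[lo], hi = s$pos_cM[hi])
  }
  bind_rows(out)
}

# EM fit of a 3-genotype-mean normal with common variance, observations
# weighted by per-individual genotype posteriors W (n x 3).
# Returns maximised log-likelihood sum_i log sum_g W_ig N(y_i; mu_g, sigma).
fit_genotype_mixture <- function(W, y, tol = 1e-8, max_iter = 500) {
  n <- length(y)
  mu <- colSums(W * y) / pmax(colSums(W), 1e-12)
  s2 <- max(var(y) * (n - 1) / n, 1e-12)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(g) dnorm(y, mu[g], sqrt(s2)), numeric(n))
    num <- W * dens
    rs <- rowSums(num)
    if (any(rs <= 0) || !all(is.finite(rs)))
      return(list(logLik = NA_real_, degenerate = TRUE))
    ll <- sum(log(rs))
    gam <- num / rs
    cs <- colSums(gam)
    mu <- ifelse(cs > 1e-12, colSums(gam * y) / cs, mu)
    s2 <- sum(gam * (outer(y, mu, `-`))^2) / n
    if (s2 < 1e-12)
      return(list(logLik = ll, mu = mu, sigma2 = s2, degenerate = TRUE))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(logLik = ll, mu = mu, sigma2 = s2, degenerate = FALSE)
}

# EM fit of the joint independent-residual model: emission is the product
# N(r; muR_g, sR) N(c; muC_g, sC) within each genotype class.
fit_joint_mixture <- function(W, r, c_, tol = 1e-8, max_iter = 500) {
  n <- length(r)
  muR <- colSums(W * r) / pmax(colSums(W), 1e-12)
  muC <- colSums(W * c_) / pmax(colSums(W), 1e-12)
  sR <- max(var(r) * (n - 1) / n, 1e-12)
  sC <- max(var(c_) * (n - 1) / n, 1e-12)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(g)
      dnorm(r, muR[g], sqrt(sR)) * dnorm(c_, muC[g], sqrt(sC)), numeric(n))
    num <- W * dens
    rs <- rowSums(num)
    if (any(rs <= 0) || !all(is.finite(rs)))
      return(list(logLik = NA_real_, degenerate = TRUE))
    ll <- sum(log(rs))
    gam <- num / rs
    cs <- colSums(gam)
    muR <- ifelse(cs > 1e-12, colSums(gam * r) / cs, muR)
    muC <- ifelse(cs > 1e-12, colSums(gam * c_) / cs, muC)
    sR <- sum(gam * (outer(r, muR, `-`))^2) / n
    sC <- sum(gam * (outer(c_, muC, `-`))^2) / n
    if (sR < 1e-12 || sC < 1e-12)
      return(list(logLik = ll, degenerate = TRUE))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(logLik = ll, muR = muR, muC = muC, sigma2R = sR, sigma2C = sC,
       degenerate = FALSE)
}

# Maximised Gaussian simple-linear-regression log-likelihood of y on x.
fit_regression_loglik <- function(x, y) {
  n <- length(y)
  fit <- lm.fit(cbind(1, x), y)
  s2 <- sum(fit$residuals^2) / n
  if (s2 < 1e-12) return(list(logLik = NA_real_, degenerate = TRUE))
  list(logLik = -n / 2 * (log(2 * pi * s2) + 1), degenerate = FALSE)
}

#' Likelihood-based causality model selection for one triplet
#'
#' Fits the causal (M1), reactive (M2) and independent (M3) models for a
#' locus-transcript-trait triplet and calls the model with the smallest AIC.
#' Genotype uncertainty at L enters through a mixture likelihood over the
#' 3-class posterior (pass hard 0/1 rows for hard-call mode). Parameter
#' counts are 7, 7 and 8; with `m3_correlation = TRUE` the independent
#' model gains a residual-correlation parameter (k = 9) for sensitivity
#' analysis. Ties (AIC difference below 1e-9) and degenerate fits yield
#' `"no_call"`.
#'
#' @param W Genotype posterior matrix at L (individuals x 3), rows summing
#'   to 1.
#' @param R Transcript abundance vector.
#' @param C Clinical trait vector.
#' @param min_n Minimum number of complete triplets.
#' @param m3_correlation Add a bivariate-normal residual correlation to M3.
#' @return Object of class `lcms_call`: list with `aic` (named length-3),
#'   `logLik`, `k`, `verdict`, `reason`.
#' @export
lcms <- function(W, R, C, min_n = 30, m3_correlation = FALSE) {
  ok <- complete.cases(W, R, C)
  W <- W[ok, , drop = FALSE]; R <- R[ok]; C <- C[ok]
  n <- length(R)
  if (n < min_n) abort("fewer complete triplets than `min_n`.")
  no_call <- function(reason) {
    structure(list(aic = c(M1 = NA_real_, M2 = NA_real_, M3 = NA_real_),
                   logLik = NULL, k = c(M1 = 7, M2 = 7, M3 = 8),
                   verdict = "no_call", reason = reason, n = n),
              class = "lcms_call")
  }
  if (sd(R) < 1e-12 || sd(C) < 1e-12) return(no_call("constant_input"))

  mRL <- fit_genotype_mixture(W, R)
  mCL <- fit_genotype_mixture(W, C)
  rCR <- fit_regression_loglik(R, C)
  rRC <- fit_regression_loglik(C, R)
  m3 <- if (m3_correlation) fit_joint_mixture_cor(W, R, C) else
    fit_joint_mixture(W, R, C)
  fits <- list(mRL, mCL, rCR, rRC, m3)
  if (any(vapply(fits, function(f) isTRUE(f$degenerate) || is.na(f$logLik),
                 logical(1))))
    return(no_call("degenerate_fit"))

  ll <- c(M1 = mRL$logLik + rCR$logLik,
          M2 = mCL$logLik + rRC$logLik,
          M3 = m3$logLik)
  k <- c(M1 = 7, M2 = 7, M3 = if (m3_correlation) 9 else 8)
  aic <- 2 * k - 2 * ll
  o <- order(aic)
  verdict <- if (aic[o[2]] - aic[o[1]] < 1e-9) "no_call" else
    c(M1 = "causal", M2 = "reactive", M3 = "independent")[names(aic)[o[1]]]
  structure(list(aic = aic, logLik = ll, k = k, verdict = unname(verdict),
                 reason = NA_character_, n = n),
            class = "lcms_call")
}

# M3 variant with correlated bivariate-normal residuals (k = 9).
fit_joint_mixture_cor <- function(W, r, c_, tol = 1e-8, max_iter = 500) {
  n <- length(r)
  muR <- colSums(W * r) / pmax(colSums(W), 1e-12)
  muC <- colSums(W * c_) / pmax(colSums(W), 1e-12)
  sR <- max(var(r) * (n - 1) / n, 1e-12)
  sC <- max(var(c_) * (n - 1) / n, 1e-12)
  rho <- 0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    det <- sR * sC * (1 - rho^2)
    if (det < 1e-24) return(list(logLik = ll_old, degenerate = TRUE))
    dens <- vapply(1:3, function(g) {
      zr <- (r - muR[g]); zc <- (c_ - muC[g])
      q <- (zr^2 / sR - 2 * rho * zr * zc / sqrt(sR * sC) + zc^2 / sC) /
        (1 - rho^2)
      exp(-q / 2) / (2 * pi * sqrt(det))
    }, numeric(n))
    num <- W * dens
    rs <- rowSums(num)
    if (any(rs <= 0) || !all(is.finite(rs)))
      return(list(logLik = NA_real_, degenerate = TRUE))
    ll <- sum(log(rs))
    gam <- num / rs
    cs <- colSums(gam)
    muR <- ifelse(cs > 1e-12, colSums(gam * r) / cs, muR)
    muC <- ifelse(cs > 1e-12, colSums(gam * c_) / cs, muC)
    zr <- outer(r, muR, `-`); zc <- outer(c_, muC, `-`)
    sR <- sum(gam * zr^2) / n
    sC <- sum(gam * zc^2) / n
    cov <- sum(gam * zr * zc) / n
    rho <- max(min(cov / sqrt(sR * sC), 0.999), -0.999)
    if (sR < 1e-12 || sC < 1e-12)
      return(list(logLik = ll, degenerate = TRUE))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(logLik = ll, degenerate = FALSE)
}

#' Run LCMS over a table of cQTL:eQTL overlaps
#'
#' @param overlaps Result of [find_overlaps()].
#' @param probs Genotype probabilities (markers in the grid).
#' @param expr Expression matrix (individuals x reporters).
#' @param traits Trait tibble (columns named as in `overlaps$trait`).
#' @param ... Passed to [lcms()].
#' @return Tibble: trait, reporter, chr, marker, AIC1-3, verdict.
#' @export
lcms_table <- function(overlaps, probs, expr, traits, ...) {
  purrr::pmap_dfr(overlaps, function(trait, reporter, chr, marker, ...) {
    idx <- which(probs$grid$marker == marker)[1]
    W <- probs$prob[, idx, ]
    call <- lcms(W, expr[, reporter], traits[[trait]])
    tibble(trait = trait, reporter = reporter, chr = chr, marker = marker,
           aic_causal = call$aic[["M1"]], aic_reactive = call$aic[["M2"]],
           aic_independent = call$aic[["M3"]], verdict = call$verdict)
  })
}

#' @export
print.lcms_call <- function(x, ...) {
  cat("LCMS call:", x$verdict, "(n =", x$n, ")\n")
  if (!all(is.na(x$aic))) {
    cat(sprintf("  AIC  causal %.2f  reactive %.2f  independent %.2f\n",
                x$aic[["M1"]], x$aic[["M2"]], x$aic[["M3"]]))
  }
  invisible(x)
}

#' Causal-gene enrichment of a signature
#'
#' Fold enrichment = (causal-in-signature / signature size) /
#' (causal-on-array / array size), with a one-sided Fisher exact p-value on
#' the corresponding 2x2 table.
#'
#' @param n_sig_causal Reporters testing causal within the signature.
#' @param n_sig Signature size.
#' @param n_causal Reporters testing causal on the whole array.
#' @param n_array Array size.
#' @return Tibble: fold, p, flag.
#' @export
causal_enrichment <- function(n_sig_causal, n_sig, n_causal, n_array) {
  if (n_sig_causal > n_sig || n_causal > n_array || n_sig_causal > n_causal ||
      n_sig > n_array)
    abort("counts must be nested: signature within array, causal subsets within each.")
  if (n_causal == 0)
    return(tibble(fold = NA_real_, p = 1, flag = "no_causal_genes"))
  fold <- (n_sig_causal / n_sig) / (n_causal / n_array)
  tab <- matrix(c(n_sig_causal, n_sig - n_sig_causal,
                  n_causal - n_sig_causal,
                  n_array - n_sig - n_causal + n_sig_causal), 2, 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble(fold = fold, p = p, flag = NA_character_)
}

#' Coverage of causal reporters by a signature
#'
#' @param n_in_signature Causal reporters inside the signature.
#' @param n_total Causal reporters in total.
#' @return Percent coverage (`NA` for a zero denominator).
#' @export
coverage_fraction <- function(n_in_signature, n_total) {
  if (n_total == 0) return(NA_real_)
  if (n_in_signature < 0 || n_in_signature > n_total)
    abort("`n_in_signature` must lie in [0, n_total].")
  100 * n_in_signature / n_total
}
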