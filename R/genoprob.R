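# Genetic map estimation and conditional genotype probabilities for an F2
# intercross: Haldane map function, EM estimation of adjacent-marker
# recombination fractions, and a 3-state forward-backward algorithm on a
# cM grid with pseudomarkers.

#' Haldane map function and its inverse
#'
#' Converts genetic distance in cM to a recombination fraction assuming no
#' crossover interference: r = 0.5 (1 - exp(-2 d / 100)).
#'
#' @param d Genetic distance in cM (non-negative).
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return `haldane()`: recombination fraction; `haldane_inverse()`:
#'   distance in cM.
#' @examples
#' haldane(10)            # ~ 0.0906
#' haldane_inverse(0.25)  # ~ 34.66 cM
#' @export
haldane <- function(d) {
  if (any(d < 0)) abort("genetic distance must be non-negative.")
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane
#' @export
haldane_inverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("r must be in [0, 0.5).")
  -50 * log(1 - 2 * r)
}

#' Estimate a genetic map from F2 genotypes
#'
#' Estimates the recombination fraction between each adjacent marker pair by
#' EM over the F2 two-meiosis transition model (the double-heterozygote cell,
#' which mixes zero and two recombinant meioses, is resolved in expectation),
#' converts to cM via the inverse Haldane function, and accumulates positions
#' along each chromosome. Physical marker order is trusted; markers are not
#' reordered. Monomorphic markers are dropped with a warning.
#'
#' @param cross An `f2_cross` (or any list with `geno` matrix and `map`
#'   tibble with `marker` and `chr`).
#' @return A tibble (`marker`, `chr`, `pos_cM`, `pos_Mb` if available, `r_prev`
#'   the recombination fraction to the previous marker).
#' @export
estimate_map <- function(cross) {
  geno <- cross$geno
  map <- cross$map
  out <- list()
  for (ch in unique(map$chr)) {
    mk <- map$marker[map$chr == ch]
    keep <- vapply(mk, function(m) {
      tab <- table(geno[, m])
      length(tab) > 1
    }, logical(1))
    if (any(!keep))
      warn(paste0("monomorphic markers skipped on chr ", ch, ": ",
                  paste(mk[!keep], collapse = ", ")))
    mk <- mk[keep]
    r <- rep(NA_real_, length(mk))
    if (length(mk) > 1) {
      for (j in 2:length(mk)) {
        r[j] <- est_rf_em(geno[, mk[j - 1]], geno[, mk[j]])
      }
    }
    pos <- cumsum(c(0, haldane_inverse(pmin(r[-1], 0.4999))))
    res <- tibble(marker = mk, chr = ch, pos_cM = pos, r_prev = r)
    if ("pos_Mb" %in% names(map))
      res$pos_Mb <- map$pos_Mb[match(mk, map$marker)]
    out[[as.character(ch)]] <- res
  }
  bind_rows(out)
}

# EM estimate of the recombination fraction between two F2 markers.
# Genotypes coded 1/2/3; each individual contributes two meioses. The
# expected number of recombinant meioses is known for every cell of the 3x3
# joint table except (AB, AB), where it is 2 r^2 / ((1-r)^2 + r^2).
est_rf_em <- function(g1, g2, tol = 1e-10, max_iter = 200) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) return(NA_real_)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i], g2[i]] <- tab[g1[i], g2[i]] + 1
  # recombinant meioses per cell (AB/AB handled inside the loop)
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  r <- 0.25
  for (it in seq_len(max_iter)) {
    e_hh <- 2 * r^2 / ((1 - r)^2 + r^2)
    rec[2, 2] <- e_hh
    r_new <- sum(tab * rec) / (2 * n)
    r_new <- min(max(r_new, 1e-12), 0.5 - 1e-12)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  r
}

# F2 transition matrix between genotype states (AA, AB, BB) for two
# independent meioses with recombination fraction r.
f2_transition <- function(r) {
  matrix(c((1 - r)^2,      2 * r * (1 - r),      r^2,
           r * (1 - r),    (1 - r)^2 + r^2,      r * (1 - r),
           r^2,            2 * r * (1 - r),      (1 - r)^2),
         3, 3, byrow = TRUE)
}

#' Conditional genotype probabilities on a cM grid
#'
#' Computes P(AA), P(AB), P(BB) at every marker and at pseudomarkers spaced
#' every `step` cM, conditional on all marker data on the chromosome, by a
#' 3-state forward-backward algorithm. The prior is the F2 segregation
#' (1/4, 1/2, 1/4); transitions come from two independent meioses under the
#' Haldane map; emissions allow a genotyping error rate `error` (probability
#' 1 - error for the observed class, error/2 for each other class; missing
#' genotypes are uninformative).
#'
#' @param cross An `f2_cross`.
#' @param map Optional map tibble (`marker`, `chr`, `pos_cM`); defaults to
#'   the cross's own map.
#' @param step Grid step in cM.
#' @param error Genotyping error rate in `[0, 0.5)`.
#' @return An object of class `f2_genoprob`: list with `prob` (array
#'   individuals x loci x 3), `grid` (tibble: chr, pos_cM, marker, pseudo),
#'   `step`, `error`.
#' @export
genotype_probabilities <- function(cross, map = cross$map, step = 2,
                                   error = 0.001) {
  if (error < 0 || error >= 0.5) abort("`error` must be in [0, 0.5).")
  geno <- cross$geno
  n <- nrow(geno)
  prior <- c(0.25, 0.5, 0.25)
  grids <- list(); probs <- list()
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, ]
    sub <- sub[order(sub$pos_cM), ]
    grid_pos <- sort(unique(c(sub$pos_cM,
                              seq(min(sub$pos_cM), max(sub$pos_cM), by = step))))
    is_marker <- grid_pos %in% sub$pos_cM
    mk_at <- rep(NA_character_, length(grid_pos))
    mk_at[is_marker] <- sub$marker[match(grid_pos[is_marker], sub$pos_cM)]
    L <- length(grid_pos)

    # emission matrices per locus: n x 3
    emis <- vector("list", L)
    for (t in seq_len(L)) {
      if (is.na(mk_at[t]) || !mk_at[t] %in% colnames(geno)) {
        emis[[t]] <- matrix(1, n, 3)
      } else {
        g <- geno[, mk_at[t]]
        e <- matrix(error / 2, n, 3)
        obs <- !is.na(g)
        e[cbind(which(obs), g[obs])] <- 1 - error
        e[!obs, ] <- 1
        emis[[t]] <- e
      }
    }
    rs <- haldane(diff(grid_pos))
    trans <- lapply(rs, f2_transition)

    fwd <- vector("list", L)
    f <- sweep(emis[[1]], 2, prior, `*`)
    f <- f / rowSums(f)
    fwd[[1]] <- f
    if (L > 1) for (t in 2:L) {
      f <- (fwd[[t - 1]] %*% trans[[t - 1]]) * emis[[t]]
      f <- f / rowSums(f)
      fwd[[t]] <- f
    }
    bwd <- matrix(1, n, 3)
    post <- array(0, c(n, L, 3))
    post[, L, ] <- fwd[[L]] * bwd
    if (L > 1) for (t in (L - 1):1) {
      bwd <- (bwd * emis[[t + 1]]) %*% t(trans[[t]])
      bwd <- bwd / rowSums(bwd)
      post[, t, ] <- fwd[[t]] * bwd
    }
    post <- post / array(rep(apply(post, c(1, 2), sum), 3), dim(post))
    grids[[as.character(ch)]] <- tibble(chr = ch, pos_cM = grid_pos,
                                        marker = mk_at, pseudo = !is_marker)
    probs[[as.character(ch)]] <- post
  }
  grid <- bind_rows(grids)
  prob <- array(0, c(n, nrow(grid), 3),
                dimnames = list(rownames(geno), NULL, c("AA", "AB", "BB")))
  at <- 0
  for (p in probs) {
    prob[, at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  structure(list(prob = prob, grid = grid, step = step, error = error),
            class = "f2_genoprob")
}

#' @export
print.f2_genoprob <- function(x, ...) {
  cat("F2 genotype probabilities:", dim(x$prob)[1], "individuals,",
      nrow(x$grid), "grid loci (step", x$step, "cM, error rate",
      x$error, ")\n")
  invisible(x)
}
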