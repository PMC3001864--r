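# Built-in simulation harness for calibrating the LCMS verdict rates under
# each generative model at a biallelic F2 locus.

#' Simulate one locus-transcript-trait triplet under a named model
#'
#' The locus genotype segregates 1:2:1; the downstream structure follows the
#' requested model: `"causal"` L -> R -> C, `"reactive"` L -> C -> R,
#' `"independent"` L -> R and L -> C with independent noises. Additive
#' genotype effects, unit residual SDs.
#'
#' @param model `"causal"`, `"reactive"` or `"independent"`.
#' @param n Number of individuals.
#' @param effect Additive genotype effect (residual-SD units).
#' @param link Linking coefficient between R and C (or genotype and the
#'   second variable for `"independent"`).
#' @param noise_sd Noise SD of the downstream variable.
#' @return List with `W` (hard genotype indicator matrix n x 3), `R`, `C`,
#'   `g` (genotype codes).
#' @export
simulate_lcms_triplet <- function(model = c("causal", "reactive", "independent"),
                                  n = 300, effect = 1, link = 1,
                                  noise_sd = 1) {
  model <- match.arg(model)
  g <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  W <- matrix(0, n, 3); W[cbind(seq_len(n), g + 2L)] <- 1
  if (model == "causal") {
    R <- effect * g + rnorm(n)
    C <- link * R + rnorm(n, 0, noise_sd)
  } else if (model == "reactive") {
    C <- effect * g + rnorm(n)
    R <- link * C + rnorm(n, 0, noise_sd)
  } else {
    R <- effect * g + rnorm(n)
    C <- link * g + rnorm(n, 0, noise_sd)
  }
  list(W = W, R = R, C = C, g = g)
}

#' LCMS calibration table under the three generative models
#'
#' Simulates `n_rep` triplets under each model and tabulates the verdict
#' rates, giving the operating characteristics of the AIC-based call at the
#' chosen sample size and effect sizes.
#'
#' @param n_rep Replicates per model.
#' @param n Individuals per replicate.
#' @param effect,link,noise_sd Passed to [simulate_lcms_triplet()].
#' @param seed Integer seed.
#' @return Tibble: model, verdict, count, rate.
#' @export
lcms_calibration <- function(n_rep = 500, n = 300, effect = 1, link = 1,
                             noise_sd = 1, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (model in c("causal", "reactive", "independent")) {
    verdicts <- vapply(seq_len(n_rep), function(i) {
      tr <- simulate_lcms_triplet(model, n, effect, link, noise_sd)
      lcms(tr$W, tr$R, tr$C)$verdict
    }, character(1))
    tab <- table(factor(verdicts,
                        levels = c("causal", "reactive", "independent",
                                   "no_call")))
    out[[model]] <- tibble(model = model, verdict = names(tab),
                           count = as.integer(tab),
                           rate = as.integer(tab) / n_rep)
  }
  bind_rows(out)
}
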