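# Synthetic F2 intercross generator. Emulates the statistical structure of a
# two-strain mouse intercross: 1:2:1 segregation under a Haldane map, a
# chromosome-localised trans-eQTL hotspot, cis eQTL, gender effects, clinical
# traits that are causal / reactive / independent with respect to the hotspot
# transcripts, and a GWAS SNP universe with an enriched eSNP subset.

#' Simulation configuration for a synthetic F2 cross
#'
#' Bundles every parameter of the synthetic-cross generators. Defaults mirror
#' a mouse F2 study: 360 individuals, 19 autosomes, a trans-eQTL hotspot on
#' chromosome 8 around 35 cM driving 200 transcripts.
#'
#' @param n_f2 Number of F2 individuals.
#' @param chromosomes Tibble with columns `chr`, `length_cM`, `mb_per_cM`
#'   (linear cM-to-Mb scale per chromosome). Default: 19 autosomes with
#'   lengths declining from 100 to 55 cM and 2 Mb/cM.
#' @param marker_spacing Marker spacing in cM.
#' @param missing_rate Genotype missingness rate (missing completely at
#'   random).
#' @param hotspot List with `chr`, `pos_cM`, `n_genes`, `effect` (additive
#'   allele effect in residual-SD units), `sign_mix` (fraction of hotspot
#'   genes with a negative effect).
#' @param n_cis_genes,cis_effect Count and additive effect of cis-regulated
#'   genes (each gets a QTL at its own genomic location).
#' @param n_null_genes Count of genes with no genetic effect.
#' @param gender_effect_sd SD of per-gene gender effects (0 disables them).
#' @param residual_sd Residual SD of expression noise.
#' @param trait_specs List of trait specifications, each a list with `name`,
#'   `architecture` (`"causal"`, `"reactive"` or `"independent"`), `coef`
#'   (linking coefficient) and `noise_sd`.
#' @param snp_spec List with `n_snps`, `esnp_fraction`, `enriched_fraction`
#'   (fraction pi of eSNPs with association p below 0.05), `maf_range`.
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_f2 = 360,
                       chromosomes = default_chromosomes(),
                       marker_spacing = 10,
                       missing_rate = 0.02,
                       hotspot = list(chr = 8, pos_cM = 35, n_genes = 200,
                                      effect = 1, sign_mix = 0.5),
                       n_cis_genes = 100,
                       cis_effect = 1,
                       n_null_genes = 700,
                       gender_effect_sd = 0.3,
                       residual_sd = 1,
                       trait_specs = default_trait_specs(),
                       snp_spec = list(n_snps = 50000, esnp_fraction = 0.1,
                                       enriched_fraction = 0.10,
                                       maf_range = c(0.01, 0.5)),
                       seed = 1L) {
  if (n_f2 <= 0) abort("`n_f2` must be positive.")
  if (nrow(chromosomes) == 0) abort("`chromosomes` must be non-empty.")
  if (marker_spacing <= 0) abort("`marker_spacing` must be positive.")
  if (missing_rate < 0 || missing_rate > 1) abort("`missing_rate` not in [0,1].")
  if (!is.null(hotspot)) {
    if (hotspot$n_genes < 0) abort("hotspot gene count must be >= 0.")
    if (hotspot$sign_mix < 0 || hotspot$sign_mix > 1)
      abort("`sign_mix` must be in [0,1].")
    if (!hotspot$chr %in% chromosomes$chr)
      abort("hotspot chromosome not in the chromosome list.")
  }
  structure(
    list(n_f2 = as.integer(n_f2), chromosomes = chromosomes,
         marker_spacing = marker_spacing, missing_rate = missing_rate,
         hotspot = hotspot, n_cis_genes = n_cis_genes,
         cis_effect = cis_effect, n_null_genes = n_null_genes,
         gender_effect_sd = gender_effect_sd, residual_sd = residual_sd,
         trait_specs = trait_specs, snp_spec = snp_spec,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_chromosomes <- function() {
  tibble(chr = 1:19,
         length_cM = round(seq(100, 55, length.out = 19)),
         mb_per_cM = 2)
}

#' @rdname sim_config
#' @export
default_trait_specs <- function() {
  list(
    list(name = "fat_mass",   architecture = "causal",      coef = 1, noise_sd = 1),
    list(name = "glucose",    architecture = "reactive",    coef = 1, noise_sd = 1),
    list(name = "bone_density", architecture = "independent", coef = 1, noise_sd = 1))
}

#' Simulate F2 intercross genotypes
#'
#' Draws two independent gametes per individual under a Haldane model
#' (Poisson crossover count with mean equal to chromosome length in Morgans,
#' crossover positions uniform, no interference) and forms genotypes as the
#' union of gamete alleles. Missingness is applied completely at random at
#' the configured rate; the complete genotypes are retained in the object for
#' downstream simulation truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `f2_cross`: a list with `geno` (individuals x
#'   markers integer matrix, 1 = AA, 2 = AB, 3 = BB, `NA` missing), `geno_true`
#'   (same without missingness), `map` (tibble: marker, chr, pos_cM, pos_Mb),
#'   `gender` (balanced factor), `ids`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrs <- config$chromosomes
  n <- config$n_f2

  map <- purrr::pmap_dfr(chrs, function(chr, length_cM, mb_per_cM) {
    pos <- seq(0, length_cM, by = config$marker_spacing)
    tibble(marker = sprintf("c%dm%03d", chr, seq_along(pos)),
           chr = chr, pos_cM = pos, pos_Mb = pos * mb_per_cM)
  })

  geno <- matrix(NA_integer_, nrow = n, ncol = nrow(map))
  colnames(geno) <- map$marker
  col0 <- 0L
  for (ci in seq_len(nrow(chrs))) {
    len <- chrs$length_cM[ci]
    pos <- map$pos_cM[map$chr == chrs$chr[ci]]
    g1 <- simulate_gametes(n, len, pos)
    g2 <- simulate_gametes(n, len, pos)
    geno[, col0 + seq_along(pos)] <- g1 + g2 + 1L
    col0 <- col0 + length(pos)
  }
  geno_true <- geno
  if (config$missing_rate > 0) {
    drop <- runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }
  ids <- sprintf("F2_%04d", seq_len(n))
  rownames(geno) <- rownames(geno_true) <- ids
  gender <- factor(sample(rep(c("F", "M"), length.out = n)),
                   levels = c("F", "M"))
  structure(list(geno = geno, geno_true = geno_true, map = map,
                 gender = gender, ids = ids, config = config),
            class = "f2_cross")
}

# One chromosome of gametes for n individuals: matrix n x length(pos) of
# allele counts (0/1). Haldane: Poisson(#crossovers) with mean L/100 Morgans.
simulate_gametes <- function(n, length_cM, pos) {
  start <- sample(0:1, n, replace = TRUE)
  ncx <- rpois(n, length_cM / 100)
  out <- matrix(start, nrow = n, ncol = length(pos))
  has <- which(ncx > 0)
  for (i in has) {
    xo <- sort(runif(ncx[i], 0, length_cM))
    # allele flips once per crossover to the left of the marker
    flips <- findInterval(pos, xo)
    out[i, ] <- (start[i] + flips) %% 2L
  }
  out
}

#' Simulate expression traits on a synthetic cross
#'
#' Hotspot genes receive an additive effect of the hotspot locus genotype
#' (genes themselves located in trans, on other chromosomes), cis genes an
#' additive effect at their own location, null genes noise only; all genes
#' get a per-gene gender effect and Gaussian residual noise.
#'
#' @param cross An [simulate_f2()] result.
#' @param config The same [sim_config()].
#' @return List with `expr` (individuals x genes matrix), `genes` (tibble:
#'   gene, type, chr, pos_Mb, qtl_chr, qtl_cM, effect) serving as the truth
#'   table.
#' @export
simulate_expression <- function(cross, config = cross$config) {
  stopifnot(inherits(cross, "f2_cross"))
  set.seed(config$seed + 1L)
  n <- nrow(cross$geno)
  hs <- config$hotspot
  n_hot <- if (is.null(hs)) 0L else hs$n_genes
  n_genes <- n_hot + config$n_cis_genes + config$n_null_genes
  map <- cross$map

  gender_num <- as.integer(cross$gender == "M") - 0.5

  genes <- tibble(
    gene = sprintf("g%05d", seq_len(n_genes)),
    type = rep(c("hotspot", "cis", "null"),
               c(n_hot, config$n_cis_genes, config$n_null_genes)))

  expr <- matrix(rnorm(n * n_genes, 0, config$residual_sd), n, n_genes)
  gender_eff <- rnorm(n_genes, 0, config$gender_effect_sd)
  expr <- expr + outer(gender_num, gender_eff)

  qtl_chr <- rep(NA_real_, n_genes); qtl_cM <- rep(NA_real_, n_genes)
  g_chr <- rep(NA_real_, n_genes); g_Mb <- rep(NA_real_, n_genes)
  eff <- rep(0, n_genes)

  if (n_hot > 0) {
    hot_marker <- nearest_marker(map, hs$chr, hs$pos_cM)
    x <- 2L - cross$geno_true[, hot_marker]     # AA = +1, AB = 0, BB = -1
    sgn <- ifelse(runif(n_hot) < hs$sign_mix, -1, 1)
    a <- hs$effect * sgn * config$residual_sd
    idx <- seq_len(n_hot)
    expr[, idx] <- expr[, idx] + outer(x, a)
    eff[idx] <- a
    qtl_chr[idx] <- hs$chr
    qtl_cM[idx] <- map$pos_cM[map$marker == hot_marker]
    # genes located in trans: any chromosome other than the hotspot's
    other <- config$chromosomes$chr[config$chromosomes$chr != hs$chr]
    g_chr[idx] <- sample(other, n_hot, replace = TRUE)
    g_Mb[idx] <- runif(n_hot) *
      chr_length_Mb(config, g_chr[idx])
  }

  if (config$n_cis_genes > 0) {
    idx <- n_hot + seq_len(config$n_cis_genes)
    mk <- sample(nrow(map), config$n_cis_genes, replace = TRUE)
    x <- 2L - cross$geno_true[, mk, drop = FALSE]
    a <- config$cis_effect * config$residual_sd
    expr[, idx] <- expr[, idx] + x * a
    eff[idx] <- a
    qtl_chr[idx] <- g_chr[idx] <- map$chr[mk]
    qtl_cM[idx] <- map$pos_cM[mk]
    g_Mb[idx] <- map$pos_Mb[mk]
  }

  if (config$n_null_genes > 0) {
    idx <- n_hot + config$n_cis_genes + seq_len(config$n_null_genes)
    g_chr[idx] <- sample(config$chromosomes$chr, config$n_null_genes,
                         replace = TRUE)
    g_Mb[idx] <- runif(config$n_null_genes) * chr_length_Mb(config, g_chr[idx])
  }

  colnames(expr) <- genes$gene
  rownames(expr) <- cross$ids
  genes$chr <- g_chr; genes$pos_Mb <- g_Mb
  genes$qtl_chr <- qtl_chr; genes$qtl_cM <- qtl_cM
  genes$effect <- eff; genes$gender_effect <- gender_eff
  list(expr = expr, genes = genes)
}

chr_length_Mb <- function(config, chr) {
  m <- match(chr, config$chromosomes$chr)
  config$chromosomes$length_cM[m] * config$chromosomes$mb_per_cM[m]
}

nearest_marker <- function(map, chr, pos_cM) {
  sub <- map[map$chr == chr, ]
  sub$marker[which.min(abs(sub$pos_cM - pos_cM))]
}

#' Simulate clinical traits with known causal architecture
#'
#' Three architectures relative to the hotspot locus L and its transcripts R:
#' `causal` (L -> R -> C): the trait is a linear function of the hotspot
#' signature score (mean of standardised hotspot-gene expression) plus noise;
#' `reactive` (L -> C -> R): the trait is generated from the locus genotype
#' and a fresh block of linked genes is generated from the trait (appended to
#' the expression matrix); `independent` (L -> R, L -> C): the trait is
#' generated from the locus genotype with noise independent of the
#' transcripts.
#'
#' @param sim Result of [simulate_expression()].
#' @param cross The [simulate_f2()] cross.
#' @param config The [sim_config()].
#' @param n_linked Number of reactive-linked genes appended per reactive
#'   trait.
#' @return List with `traits` (tibble: id, gender, one column per trait),
#'   `expr` (expression matrix, extended if reactive traits are present),
#'   `genes` (gene truth table, extended likewise), `trait_truth`.
#' @export
simulate_traits <- function(sim, cross, config = cross$config, n_linked = 20) {
  set.seed(config$seed + 2L)
  hs <- config$hotspot
  if (is.null(hs) || hs$n_genes == 0)
    abort("trait simulation requires a hotspot in the config.")
  map <- cross$map
  hot_marker <- nearest_marker(map, hs$chr, hs$pos_cM)
  x <- 2L - cross$geno_true[, hot_marker]
  hot_idx <- which(sim$genes$type == "hotspot")
  # orient each gene by its true effect sign so the score tracks the locus
  sgn <- sign(sim$genes$effect[hot_idx])
  score <- rowMeans(scale(sim$expr[, hot_idx, drop = FALSE]) *
                      rep(sgn, each = nrow(sim$expr)))
  n <- length(x)
  traits <- tibble(id = cross$ids, gender = cross$gender)
  truth <- list()
  expr <- sim$expr; genes <- sim$genes

  for (spec in config$trait_specs) {
    arch <- spec$architecture
    if (!arch %in% c("causal", "reactive", "independent"))
      abort(paste0("unknown trait architecture: ", arch))
    y <- switch(arch,
      causal = spec$coef * as.numeric(scale(score)) +
        rnorm(n, 0, spec$noise_sd),
      reactive = ,
      independent = spec$coef * x + rnorm(n, 0, spec$noise_sd))
    linked <- character(0)
    if (arch == "reactive" && n_linked > 0) {
      new <- matrix(rnorm(n * n_linked, 0, config$residual_sd), n, n_linked)
      new <- new + outer(as.numeric(scale(y)), rep(spec$coef, n_linked))
      cn <- sprintf("%s_r%03d", spec$name, seq_len(n_linked))
      colnames(new) <- cn
      expr <- cbind(expr, new)
      other <- config$chromosomes$chr[config$chromosomes$chr != hs$chr]
      gch <- sample(other, n_linked, replace = TRUE)
      genes <- bind_rows(genes, tibble(
        gene = cn, type = "reactive_linked", chr = gch,
        pos_Mb = runif(n_linked) * chr_length_Mb(config, gch),
        qtl_chr = hs$chr, qtl_cM = map$pos_cM[map$marker == hot_marker],
        effect = spec$coef, gender_effect = 0))
      linked <- cn
    }
    traits[[spec$name]] <- y
    truth[[spec$name]] <- tibble(
      trait = spec$name, architecture = arch, coef = spec$coef,
      noise_sd = spec$noise_sd, locus_chr = hs$chr,
      locus_marker = hot_marker,
      linked_genes = list(if (arch == "causal") genes$gene[hot_idx] else linked))
  }
  list(traits = traits, expr = expr, genes = genes,
       trait_truth = bind_rows(truth), score = score)
}

#' Simulate a GWAS SNP study with an enriched eSNP subset
#'
#' Non-eSNPs draw association p-values uniformly on (0,1); a fraction pi of
#' eSNPs draws p below 0.05 (uniform within), the rest uniform above. MAF
#' and distance-to-gene are drawn from configured ranges so that
#' eligibility filtering and matched resampling are exercisable.
#'
#' @param config A [sim_config()].
#' @return List with `snps` (tibble: snp, chr, bp, maf, p, dist_gene, esnp)
#'   and `esnp_ids`.
#' @export
simulate_snp_study <- function(config) {
  spec <- config$snp_spec
  if (spec$n_snps <= 0) abort("`n_snps` must be positive.")
  if (spec$enriched_fraction < 0.05)
    warn("enriched fraction below 0.05 is indistinguishable from null.")
  set.seed(config$seed + 3L)
  m <- spec$n_snps
  esnp <- runif(m) < spec$esnp_fraction
  p <- runif(m)
  hit <- esnp & (runif(m) < spec$enriched_fraction)
  p[hit] <- runif(sum(hit), 0, 0.05)
  p[esnp & !hit] <- runif(sum(esnp & !hit), 0.05, 1)
  snps <- tibble(
    snp = sprintf("rs%07d", seq_len(m)),
    chr = sample(1:22, m, replace = TRUE),
    bp = sample.int(2e8, m, replace = TRUE),
    maf = runif(m, spec$maf_range[1], spec$maf_range[2]),
    p = p,
    dist_gene = pmin(rexp(m, 1 / 3e5), 5e6),
    esnp = esnp)
  list(snps = snps, esnp_ids = snps$snp[esnp])
}
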