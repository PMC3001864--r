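# broom-style tidiers for the fitted-object classes.

#' Tidy a LOD scan into a long tibble
#'
#' @param x A `lod_scan`.
#' @param ... Unused.
#' @return Tibble: chr, pos_cM, marker, pseudo, lod.
#' @method tidy lod_scan
#' @export
tidy.lod_scan <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a LOD scan
#'
#' @param x A `lod_scan`.
#' @param ... Unused.
#' @return Tibble: peak chr, pos, LOD, n, flags.
#' @method glance lod_scan
#' @export
glance.lod_scan <- function(x, ...) {
  pk <- attr(x, "peak")
  tibble(chr = pk$chr, pos_cM = pk$pos_cM, lod = pk$lod,
         n = attr(x, "n"),
         flags = paste(attr(x, "flags"), collapse = ";"))
}

#' Tidy a matrix scan into a long tibble
#'
#' @param x A `lod_scan_matrix`.
#' @param ... Unused.
#' @return Tibble: trait, chr, pos_cM, lod.
#' @method tidy lod_scan_matrix
#' @export
tidy.lod_scan_matrix <- function(x, ...) {
  grid <- x$grid
  out <- as_tibble(x$lod)
  out$chr <- grid$chr
  out$pos_cM <- grid$pos_cM
  tidyr::pivot_longer(out, cols = -c("chr", "pos_cM"),
                      names_to = "trait", values_to = "lod")
}

#' Tidy an LCMS call
#'
#' @param x An `lcms_call`.
#' @param ... Unused.
#' @return Tibble: model, k, logLik, AIC.
#' @method tidy lcms_call
#' @export
tidy.lcms_call <- function(x, ...) {
  tibble(model = c("causal", "reactive", "independent"),
         k = unname(x$k),
         logLik = if (is.null(x$logLik)) NA_real_ else unname(x$logLik),
         aic = unname(x$aic))
}

#' One-row summary of an LCMS call
#'
#' @param x An `lcms_call`.
#' @param ... Unused.
#' @return Tibble: verdict, best AIC, margin to runner-up, n.
#' @method glance lcms_call
#' @export
glance.lcms_call <- function(x, ...) {
  margin <- if (all(is.na(x$aic))) NA_real_ else
    diff(sort(x$aic))[1]
  tibble(verdict = x$verdict,
         aic_best = if (all(is.na(x$aic))) NA_real_ else min(x$aic),
         aic_margin = margin, n = x$n, reason = x$reason)
}

#' @method tidy fdr_table
#' @export
tidy.fdr_table <- function(x, ...) as_tibble(x)

#' @method glance fdr_table
#' @export
glance.fdr_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  tibble(kind = prov$kind, n_perm = prov$n_perm,
         n_thresholds = nrow(x), min_fdr = min(x$fdr))
}

#' @method tidy hotspot_result
#' @export
tidy.hotspot_result <- function(x, ...) as_tibble(x)

#' @method glance hotspot_result
#' @export
glance.hotspot_result <- function(x, ...) {
  tibble(top_chr = x$chr[1], top_bin_start = x$bin_start[1],
         top_count = x$count[1], expected = x$expected[1],
         p_poisson = x$p_poisson[1], p_empirical = x$p_empirical[1],
         perm_max = max(attr(x, "perm_max")), n_bins = attr(x, "n_bins"))
}

#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) as_tibble(x)

#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  sizes <- attr(x, "sizes")
  tibble(n_modules = length(sizes),
         largest = if (length(sizes)) max(sizes) else NA_integer_,
         smallest = if (length(sizes)) min(sizes) else NA_integer_,
         n_grey = sum(x$module == "grey"),
         cut_height = attr(x, "cut_height"))
}
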