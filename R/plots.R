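# ggplot2 displays for the main result types.

#' Plot a LOD curve across the genome
#'
#' @param object A `lod_scan`.
#' @param ... Unused.
#' @return A ggplot: LOD against position, faceted by chromosome.
#' @method autoplot lod_scan
#' @export
autoplot.lod_scan <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0, "pt"))
}

#' Plot per-bin eQTL counts with the permutation ceiling
#'
#' @param object A `hotspot_result`.
#' @param ... Unused.
#' @return A ggplot: bin counts by chromosome with a dashed line at the
#'   largest permutation maximum.
#' @method autoplot hotspot_result
#' @export
autoplot.hotspot_result <- function(object, ...) {
  d <- as_tibble(object)
  pm <- max(attr(object, "perm_max"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::geom_hline(yintercept = pm, linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "bin start", y = "unique reporters per bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0, "pt"))
}

#' Plot module sizes of a network partition
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes, grey shown last.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  d <- count(as_tibble(object), .data$module, name = "size")
  d <- arrange(d, .data$module == "grey", dplyr::desc(.data$size))
  d$module <- factor(d$module, levels = d$module)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$module, y = .data$size,
                                  fill = .data$module)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scale-free fit profile across candidate powers
#'
#' @param correlations Gene-gene correlation matrix.
#' @param config A [network_config()].
#' @return A ggplot of scale-free R^2 against the candidate power, with the
#'   acceptance threshold marked.
#' @export
plot_scale_free_fit <- function(correlations, config = network_config()) {
  b <- pick_beta(correlations, config)
  d <- tibble(beta = config$beta_range, r2 = unname(attr(b, "r2")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = config$r2_min, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = as.integer(b), colour = "red") +
    ggplot2::labs(x = "soft-threshold power", y = "scale-free R²") +
    ggplot2::theme_minimal()
}
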