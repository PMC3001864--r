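# eQTL catalog construction: cis/trans classification (+/- 20 Mb window),
# collapsing to one record per (reporter, chromosome, tissue), cross-tissue
# sharing, genomic binning and trans-eQTL hotspot testing against Poisson
# and permutation nulls.

#' Classify eQTL records as cis or trans
#'
#' An eQTL is cis when its peak lies on the gene's own chromosome within
#' +/- `window` Mb of the gene's physical position (boundary inclusive);
#' otherwise trans. Records with unknown gene location are classified
#' `"unknown"` and should be excluded from cis/trans tallies.
#'
#' @param records Tibble with columns `chr` (QTL chromosome), `peak_Mb`,
#'   `gene_chr`, `gene_Mb`.
#' @param window Cis window half-width in Mb.
#' @return The tibble with a `cis` column (`"cis"`, `"trans"`, `"unknown"`).
#' @export
classify_cis <- function(records, window = 20) {
  records$cis <- dplyr::case_when(
    is.na(records$gene_chr) | is.na(records$gene_Mb) ~ "unknown",
    records$chr == records$gene_chr &
      abs(records$peak_Mb - records$gene_Mb) <= window ~ "cis",
    TRUE ~ "trans")
  records
}

#' Interpolate a peak's Mb position from the genetic map
#'
#' Linear interpolation between the flanking markers' Mb coordinates;
#' positions beyond the terminal markers are extrapolated from the nearest
#' pair.
#'
#' @param map Tibble with `chr`, `pos_cM`, `pos_Mb`.
#' @param chr,pos_cM Peak coordinates (vectorised).
#' @return Mb positions.
#' @export
interpolate_mb <- function(map, chr, pos_cM) {
  vapply(seq_along(chr), function(i) {
    sub <- map[map$chr == chr[i], ]
    sub <- sub[order(sub$pos_cM), ]
    if (nrow(sub) == 1) return(sub$pos_Mb[1])
    stats::approx(sub$pos_cM, sub$pos_Mb, xout = pos_cM[i], rule = 2)$y
  }, numeric(1))
}

#' Build a collapsed eQTL catalog from a peak table
#'
#' Applies the LOD threshold and keeps one record per (reporter, chromosome,
#' tissue) at the maximum LOD, with interpolated peak Mb and cis/trans
#' classification.
#'
#' @param peaks Tibble from [peak_table()] (columns `trait`, `chr`,
#'   `pos_cM`, `lod`), with `trait` holding reporter ids.
#' @param genes Gene location tibble (`gene`, `chr`, `pos_Mb`).
#' @param map Genetic map with Mb positions for interpolation.
#' @param tissue Tissue label for the catalog.
#' @param threshold Catalog LOD threshold.
#' @param window Cis window (Mb).
#' @return Tibble: reporter, tissue, chr, peak_cM, peak_Mb, lod, gene_chr,
#'   gene_Mb, cis.
#' @export
build_catalog <- function(peaks, genes, map, tissue = "tissue",
                          threshold = 5, window = 20) {
  cat <- peaks[peaks$lod >= threshold, ]
  cat <- cat %>%
    rename(reporter = "trait", peak_cM = "pos_cM") %>%
    mutate(tissue = tissue)
  cat <- collapse_catalog(cat)
  if (nrow(cat) == 0) {
    return(tibble(reporter = character(), tissue = character(),
                  chr = numeric(), peak_cM = numeric(), peak_Mb = numeric(),
                  lod = numeric(), gene_chr = numeric(), gene_Mb = numeric(),
                  cis = character()))
  }
  cat$peak_Mb <- interpolate_mb(map, cat$chr, cat$peak_cM)
  cat <- left_join(cat,
                   genes %>% select(reporter = "gene", gene_chr = "chr",
                                    gene_Mb = "pos_Mb"),
                   by = "reporter")
  classify_cis(cat, window = window)
}

#' Collapse an eQTL catalog to unique (reporter, chromosome, tissue) records
#'
#' Each reporter is counted once per chromosome and tissue, at its maximum
#' LOD on that chromosome.
#'
#' @param records Tibble with `reporter`, `chr`, `tissue`, `lod`.
#' @return One row per (reporter, chr, tissue) at maximum LOD.
#' @export
collapse_catalog <- function(records) {
  if (nrow(records) == 0) return(records)
  records %>%
    group_by(.data$reporter, .data$chr, .data$tissue) %>%
    slice_max(.data$lod, n = 1, with_ties = FALSE) %>%
    ungroup()
}

#' Cross-tissue eQTL sharing
#'
#' Fraction of shared (reporter, chromosome) keys between two collapsed
#' catalogs, split by cis/trans status. A key's class is taken from
#' whichever catalog carries it (cis wins on conflict).
#'
#' @param a,b Collapsed catalogs ([build_catalog()]).
#' @param denominator `"union"` (default) or `"a"` (fraction of catalog A's
#'   keys found in B).
#' @return Tibble: class, shared, denominator size, fraction (percent).
#' @export
tissue_sharing <- function(a, b, denominator = c("union", "a")) {
  denominator <- match.arg(denominator)
  key <- function(x) paste(x$reporter, x$chr, sep = "::")
  ka <- key(a); kb <- key(b)
  cls <- c(setNames(a$cis, ka), setNames(b$cis, kb))
  cls <- cls[!duplicated(names(cls)) | cls == "cis"]
  cls <- tapply(cls, names(cls), function(v) if ("cis" %in% v) "cis" else v[1])
  out <- lapply(c("cis", "trans"), function(cl) {
    keys <- names(cls)[cls == cl]
    A <- intersect(ka, keys); B <- intersect(kb, keys)
    den <- if (denominator == "union") length(union(A, B)) else length(A)
    shared <- length(intersect(A, B))
    frac <- if (den == 0) 0 else shared / den
    tibble(class = cl, shared = shared, denominator = den,
           fraction_pct = 100 * frac, flag_empty = den == 0)
  })
  bind_rows(out)
}

#' Per-bin unique-reporter eQTL counts
#'
#' Bins are half-open `[start, start + size)`, anchored at 0 on each
#' chromosome; a reporter is counted at most once per bin.
#'
#' @param catalog Collapsed catalog.
#' @param bin_size Bin size (10 cM or 10 Mb, say).
#' @param unit `"cM"` (uses `peak_cM`) or `"Mb"` (uses `peak_Mb`).
#' @return Tibble: chr, bin_start, count.
#' @export
bin_counts <- function(catalog, bin_size = 10, unit = c("cM", "Mb")) {
  unit <- match.arg(unit)
  pos <- if (unit == "cM") catalog$peak_cM else catalog$peak_Mb
  catalog %>%
    mutate(bin_start = floor(pos / bin_size) * bin_size) %>%
    distinct(.data$reporter, .data$chr, .data$bin_start) %>%
    count(.data$chr, .data$bin_start, name = "count")
}

#' Trans-eQTL hotspot test against Poisson and permutation nulls
#'
#' The expected count per bin is the catalog size divided by the number of
#' genome bins (all mapped chromosomes, full length). The Poisson upper-tail
#' p-value is computed in log space and floored at the smallest positive
#' double; the empirical p compares each bin's observed count with the
#' genome-wide maximum bin count of each permuted catalog.
#'
#' @param catalog Observed collapsed catalog.
#' @param perm_catalogs List of permuted catalogs (same construction).
#' @param chromosomes Tibble `chr`, `length` in the binning unit.
#' @param bin_size Bin size.
#' @param unit `"cM"` or `"Mb"`.
#' @return Object of class `hotspot_result`: tibble (chr, bin_start,
#'   count, expected, p_poisson, p_empirical) sorted by decreasing count;
#'   attributes `perm_max` and `n_bins`.
#' @export
hotspot_test <- function(catalog, perm_catalogs, chromosomes,
                         bin_size = 10, unit = c("cM", "Mb")) {
  unit <- match.arg(unit)
  n_bins <- sum(ceiling(chromosomes$length / bin_size))
  if (n_bins == 0) abort("zero genome bins.")
  obs <- bin_counts(catalog, bin_size, unit)
  expected <- nrow(catalog) / n_bins
  # log-space upper tail, floored at the smallest positive double
  logp <- ppois(obs$count - 1, expected, lower.tail = FALSE, log.p = TRUE)
  p_pois <- pmax(exp(logp), .Machine$double.xmin)
  p_pois[obs$count == 0] <- 1
  perm_max <- vapply(perm_catalogs, function(pc) {
    b <- bin_counts(pc, bin_size, unit)
    if (nrow(b) == 0) 0 else max(b$count)
  }, numeric(1))
  P <- length(perm_max)
  p_emp <- vapply(obs$count, function(k) (1 + sum(perm_max >= k)) / (P + 1),
                  numeric(1))
  res <- obs %>%
    mutate(expected = expected, p_poisson = p_pois, p_empirical = p_emp) %>%
    arrange(dplyr::desc(.data$count))
  structure(res, class = c("hotspot_result", class(res)),
            perm_max = perm_max, n_bins = n_bins)
}
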