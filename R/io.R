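# Readers and writers for the table dialects used across the pipeline.
# Canonical on-disk format is TSV (CSV accepted), UTF-8, "NA" missing token,
# 1-based bp coordinates, floating-point cM.

read_delim_auto <- function(path, ...) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("NA", ""), ...)
}

write_tsv_file <- function(x, path) readr::write_tsv(x, path, na = "NA")

GENO_CODES <- c(A = 1L, H = 2L, B = 3L, "0" = 1L, "1" = 2L, "2" = 3L)

#' Read an F2 genotype table
#'
#' Accepts codes `A/H/B/NA` or `0/1/2/-` (mapped to AA/AB/BB/missing).
#' Orientation is individuals-in-rows by default; `orientation =
#' "markers_in_rows"` transposes, and `"auto"` decides by matching the
#' header against the map's marker ids.
#'
#' @param path Delimited text file; first column holds row ids.
#' @param map Map tibble (`marker`, `chr`, `pos_cM`, optionally `pos_Mb`)
#'   used for validation and ordering.
#' @param orientation `"individuals_in_rows"`, `"markers_in_rows"` or
#'   `"auto"`.
#' @return An `f2_cross`-shaped list (`geno`, `map`, `ids`); `geno_true` is
#'   set equal to `geno` (observed data carries no hidden truth).
#' @export
read_genotypes <- function(path, map,
                           orientation = c("auto", "individuals_in_rows",
                                           "markers_in_rows")) {
  orientation <- match.arg(orientation)
  d <- read_delim_auto(path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    abort(paste0("duplicate row ids in ", path, ": ",
                 ids[duplicated(ids)][1]))
  m <- as.matrix(d[-1])
  if (orientation == "auto") {
    in_rows <- mean(ids %in% map$marker)
    in_cols <- mean(colnames(m) %in% map$marker)
    orientation <- if (in_rows > in_cols) "markers_in_rows" else
      "individuals_in_rows"
  }
  if (orientation == "markers_in_rows") {
    m <- t(m)
    tmp <- ids; ids <- rownames(m); markers <- tmp
    colnames(m) <- markers
  }
  bad <- !is.na(m) & !(m %in% c(names(GENO_CODES), "-"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("unknown genotype code '%s' at row %d, column %d of %s",
                  m[bad][1], w[1], w[2], path))
  }
  geno <- matrix(GENO_CODES[m], nrow(m), ncol(m),
                 dimnames = list(ids, colnames(m)))
  missing_markers <- setdiff(colnames(geno), map$marker)
  if (length(missing_markers) > 0)
    abort(paste0("markers absent from the map: ",
                 paste(head(missing_markers, 5), collapse = ", ")))
  ord <- map$marker[map$marker %in% colnames(geno)]
  geno <- geno[, ord, drop = FALSE]
  list(geno = geno, geno_true = geno,
       map = map[map$marker %in% ord, ], ids = ids)
}

#' Write an F2 genotype table
#'
#' @param cross An `f2_cross`.
#' @param path Output TSV (individuals in rows, `A/H/B` codes).
#' @export
write_genotypes <- function(cross, path) {
  codes <- c("A", "H", "B")[cross$geno]
  m <- matrix(codes, nrow(cross$geno), ncol(cross$geno))
  d <- as_tibble(m, .name_repair = ~colnames(cross$geno))
  d <- dplyr::bind_cols(tibble(id = rownames(cross$geno)), d)
  write_tsv_file(d, path)
}

#' Read / write a genetic map
#'
#' TSV with columns `marker`, `chr`, `pos_cM` and optionally `pos_Mb`.
#' @param path File path.
#' @return Tibble ordered by chromosome and position.
#' @export
read_map <- function(path) {
  d <- read_delim_auto(path)
  need <- c("marker", "chr", "pos_cM")
  if (!all(need %in% names(d)))
    abort(paste0("map file must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(d$marker)) abort("duplicate marker ids in map.")
  arrange(d, .data$chr, .data$pos_cM)
}

#' @rdname read_map
#' @param map Map tibble.
#' @export
write_map <- function(map, path) write_tsv_file(map, path)

#' Read an expression matrix
#'
#' Delimited table, individuals in rows (first column ids), genes in
#' columns; all cells numeric.
#'
#' @param path File path.
#' @return Numeric matrix individuals x genes.
#' @export
read_expression <- function(path) {
  d <- read_delim_auto(path)
  ids <- as.character(d[[1]])
  vals <- d[-1]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    col <- names(vals)[nonnum][1]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))) &
                   !is.na(vals[[col]]))[1]
    abort(sprintf("non-numeric cell in column '%s' (data row %s) of %s",
                  col, row, path))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param expr Individuals x genes matrix.
#' @export
write_expression <- function(expr, path) {
  d <- dplyr::bind_cols(tibble(id = rownames(expr)),
                        as_tibble(expr, .name_repair = "minimal"))
  write_tsv_file(d, path)
}

#' Read / write a clinical trait table
#'
#' TSV with `id`, `gender` and one numeric column per trait.
#' @param path File path.
#' @return Tibble.
#' @export
read_traits <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("id", "gender") %in% names(d)))
    abort("trait table must have `id` and `gender` columns.")
  d$gender <- factor(d$gender)
  d
}

#' @rdname read_traits
#' @param traits Trait tibble.
#' @export
write_traits <- function(traits, path) write_tsv_file(traits, path)

#' Read / write a GWAS SNP table
#'
#' TSV with `snp`, `chr`, `bp`, `maf`, `p`, `dist_gene`.
#' @param path File path.
#' @return Tibble.
#' @export
read_snps <- function(path) {
  d <- read_delim_auto(path)
  need <- c("snp", "maf", "p", "dist_gene")
  if (!all(need %in% names(d)))
    abort(paste0("SNP table must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(d$snp)) abort("duplicate SNP ids.")
  d
}

#' @rdname read_snps
#' @param snps SNP tibble.
#' @export
write_snps <- function(snps, path) write_tsv_file(snps, path)

#' Align individuals across tables
#'
#' Intersects individual ids across genotype, expression and trait inputs
#' and reports the overlap; errors when fewer than half of either table's
#' ids survive (a sign of misaligned inputs).
#'
#' @param ... Named character vectors of individual ids.
#' @param min_overlap Minimum tolerated overlap fraction per table.
#' @return List with `ids` (the intersection) and `report` tibble.
#' @export
align_individuals <- function(..., min_overlap = 0.5) {
  sets <- list(...)
  common <- Reduce(intersect, sets)
  report <- tibble(table = names(sets),
                   n = lengths(sets),
                   n_shared = length(common),
                   overlap = length(common) / lengths(sets))
  if (any(report$overlap < min_overlap))
    abort(paste0("id overlap below ", min_overlap,
                 " for table(s): ",
                 paste(report$table[report$overlap < min_overlap],
                       collapse = ", ")))
  list(ids = common, report = report)
}

#' Pipeline run configuration
#'
#' Thresholds and permutation counts for a full analysis run, serialisable
#' to YAML and read back losslessly.
#'
#' @param cis_window_Mb Cis window half-width.
#' @param eqtl_lod,cqtl_lod,suggestive_lod LOD thresholds.
#' @param hotspot_bin_cM,hotspot_bin_Mb Hotspot bin sizes.
#' @param replication_lod_anywhere,replication_lod_interval Replication rule
#'   thresholds.
#' @param n_perm_cqtl,n_perm_eqtl Permutation counts.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cis_window_Mb = 20, eqtl_lod = 5, cqtl_lod = 4.3,
                       suggestive_lod = 3.0, hotspot_bin_cM = 10,
                       hotspot_bin_Mb = 10, replication_lod_anywhere = 2,
                       replication_lod_interval = 3,
                       n_perm_cqtl = 1000, n_perm_eqtl = 5, seed = 1L) {
  cfg <- list(cis_window_Mb = cis_window_Mb, eqtl_lod = eqtl_lod,
              cqtl_lod = cqtl_lod, suggestive_lod = suggestive_lod,
              hotspot_bin_cM = hotspot_bin_cM, hotspot_bin_Mb = hotspot_bin_Mb,
              replication_lod_anywhere = replication_lod_anywhere,
              replication_lod_interval = replication_lod_interval,
              n_perm_cqtl = n_perm_cqtl, n_perm_eqtl = n_perm_eqtl,
              seed = as.integer(seed))
  if (any(vapply(cfg, function(v) v <= 0, logical(1))))
    abort("all run-config values must be positive.")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
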