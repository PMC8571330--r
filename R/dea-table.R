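#' Dataset metadata
#'
#' One row of metadata describing a differential-expression-analysis (DEA)
#' result table: which dataset it came from, which species and technology,
#' which experimental comparison it tests and on how many samples.
#' Comparisons with fewer than three biological replicates are rejected, the
#' usual inclusion floor for meta-analytic collections.
#'
#' @param dataset_id Unique dataset identifier (e.g. a GEO-style accession).
#' @param species `"human"` or `"mouse"`.
#' @param technology `"microarray"` or `"rnaseq"`.
#' @param comparison Comparison label string in the `A_vs_B` controlled
#'   vocabulary (see [parse_comparison_label()]).
#' @param n_samples Total samples in the comparison, at least 3.
#' @param platform Free-text platform name.
#' @param tissue Free-text tissue.
#' @param biotype_scope `"coding"`, `"noncoding"` or `"mixed"` — which gene
#'   biotypes the dataset profiles. Exclusively non-coding datasets are
#'   benchmarked in their own groups and excluded from cross-species
#'   integration.
#' @return A one-row tibble of class `dataset_meta`.
#' @examples
#' dataset_meta("GSE0001", "human", "rnaseq", "IPF_vs_Ctrl", 12)
#' @export
dataset_meta <- function(dataset_id, species, technology, comparison,
                         n_samples, platform = "unspecified",
                         tissue = "lung", biotype_scope = "coding") {
  species <- arg_match0(species, c("human", "mouse"))
  technology <- arg_match0(technology, c("microarray", "rnaseq"))
  biotype_scope <- arg_match0(biotype_scope, c("coding", "noncoding", "mixed"))
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L, nzchar(dataset_id))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 3L) {
    abort("`n_samples` must be an integer >= 3 (fewer than three biological replicates are excluded).")
  }
  parse_comparison_label(comparison)  # validates the controlled vocabulary
  out <- tibble(dataset_id = dataset_id, species = species,
                technology = technology, platform = platform, tissue = tissue,
                comparison = comparison, n_samples = n_samples,
                biotype_scope = biotype_scope)
  class(out) <- c("dataset_meta", class(out))
  out
}

#' Construct a DEA result table
#'
#' Couples per-feature differential expression statistics with dataset
#' metadata. Fold changes are stored as log2 values; p-values may be `NA`
#' (flagged missing) but when present must lie in \[0, 1\].
#'
#' @param stats A data frame with columns `feature_id`, `log2fc`,
#'   `p_nominal`, `p_adjusted`. Feature ids must be unique and non-empty;
#'   at least one row is required.
#' @param meta A [dataset_meta()] row.
#' @return A tibble of class `dea_table` carrying `meta` as an attribute
#'   (retrieve with [dea_meta()]).
#' @export
dea_table <- function(stats, meta) {
  if (!inherits(meta, "dataset_meta")) abort("`meta` must be built by `dataset_meta()`.")
  stats <- as_tibble(stats)
  required <- c("feature_id", "log2fc", "p_nominal", "p_adjusted")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols)) {
    abort(sprintf("`stats` lacks required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  stats <- stats[required]
  if (nrow(stats) == 0L) abort("A DEA table needs at least one row.")
  if (any(!nzchar(stats$feature_id) | is.na(stats$feature_id))) {
    abort("Feature ids must be non-empty.")
  }
  dup <- stats$feature_id[duplicated(stats$feature_id)]
  if (length(dup)) {
    abort(sprintf("Duplicated feature id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  for (col in c("p_nominal", "p_adjusted")) {
    v <- stats[[col]]
    if (!is.numeric(v)) abort(sprintf("`%s` must be numeric.", col))
    bad <- is.finite(v) & (v < 0 | v > 1)
    if (any(bad)) abort(sprintf("`%s` outside [0, 1] for: %s.", col,
                                paste(head(stats$feature_id[bad], 5L), collapse = ", ")))
  }
  structure(stats, meta = meta, class = c("dea_table", class(stats)))
}

#' Retrieve the metadata of a DEA table
#' @param table A [dea_table()].
#' @return The `dataset_meta` row.
#' @export
dea_meta <- function(table) {
  meta <- attr(table, "meta", exact = TRUE)
  if (is.null(meta)) abort("Not a `dea_table`: no metadata attached.")
  meta
}

#' @export
print.dea_table <- function(x, ...) {
  m <- dea_meta(x)
  cat(sprintf("<dea_table> %s | %s %s | %s | %d samples | %d features\n",
              m$dataset_id, m$species, m$technology, m$comparison,
              m$n_samples, nrow(x)))
  NextMethod()
}

# Stack a list of dea_tables into one long tibble keyed by dataset_id.
collection_stats <- function(tables) {
  list_rbind(map(tables, function(t) {
    mutate(as_tibble(t), dataset_id = dea_meta(t)$dataset_id, .before = 1L)
  }))
}

# Bind the metadata rows of a list of dea_tables; enforces id uniqueness.
collection_meta <- function(tables) {
  meta <- list_rbind(map(tables, function(t) as_tibble(dea_meta(t))))
  dup <- meta$dataset_id[duplicated(meta$dataset_id)]
  if (length(dup)) {
    abort(sprintf("Duplicated dataset id(s) in collection: %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  meta
}

default_col_map <- c(feature = "feature", log2fc = "log2fc",
                     pvalue = "pvalue", padj = "padj")

#' Read a tab-delimited DEA result table
#'
#' Reads a UTF-8, tab-delimited file with a header row and returns a
#' validated [dea_table()]. Column names are configurable through
#' `col_map`; rows whose statistics fail to parse as numbers are retained
#' with the offending value flagged missing (`NA`).
#'
#' @param path Path to the file.
#' @param meta A [dataset_meta()] row describing the dataset.
#' @param col_map Named character vector mapping the roles `feature`,
#'   `log2fc`, `pvalue`, `padj` to the column names present in the file.
#' @return A [dea_table()].
#' @export
read_dea_table <- function(path, meta, col_map = default_col_map) {
  col_map <- utils::modifyList(as.list(default_col_map), as.list(col_map))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, comment = "#")
  needed <- unlist(col_map[c("feature", "log2fc", "pvalue", "padj")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s) %s; file header was: %s.",
                  paste(missing_cols, collapse = ", "),
                  paste(names(raw), collapse = ", ")))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  stats <- tibble(
    feature_id = raw[[col_map$feature]],
    log2fc     = num(raw[[col_map$log2fc]]),
    p_nominal  = num(raw[[col_map$pvalue]]),
    p_adjusted = num(raw[[col_map$padj]])
  )
  dea_table(stats, meta)
}

#' Write a DEA table (tab-delimited) with a JSON metadata sidecar
#'
#' The statistics go to `path`; the dataset metadata is written next to it
#' as `<path>.meta.json` so a collection can be reconstructed with
#' [read_dea_table()] + [dataset_meta()].
#'
#' @param table A [dea_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dea_table <- function(table, path) {
  stats <- as_tibble(table)
  names(stats) <- c("feature", "log2fc", "pvalue", "padj")
  readr::write_tsv(stats, path, progress = FALSE)
  jsonlite::write_json(as.list(dea_meta(table)), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. Thin
#' validated front end over [stats::p.adjust()]; inputs outside \[0, 1\]
#' raise an error rather than being clipped, `NA`s propagate.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) abort("`pvals` must be numeric.")
  bad <- is.finite(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) {
    abort(sprintf("p-value(s) outside [0, 1]: %s.",
                  paste(head(format(pvals[bad]), 5L), collapse = ", ")))
  }
  p.adjust(pvals, method = "BH")
}
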