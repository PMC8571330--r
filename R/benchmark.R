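#' @title Dataset benchmarking with star accreditation
#' @description
#' Transcriptomic dataset collections are heterogeneous; before integrating
#' several datasets it helps to know which ones behave most like the rest of
#' their peer group. The accreditation system computes seven descriptive
#' metrics per dataset/comparison, pools them into per-group distributions
#' (groups share species and technology; exclusively non-coding datasets are
#' grouped separately), and awards one star per metric whose value falls
#' inside a group-level quantile band (the closed interquartile range by
#' default). Seven stars is the maximum; stars encode within-group
#' similarity, not biological quality.
#'
#' The seven starred metrics are: (1) number of detected genes, (2) number
#' of DE genes, (3) number of known pro-fibrotic genes among the DE genes,
#' (4) the triple of DE-gene counts with low (1.2 < FC < 2), intermediate
#' (2 <= FC < 5) and high (FC >= 5) absolute linear fold change — granted as
#' a single star only when all three bin counts sit inside their bands,
#' (5) the (up+1)/(down+1) regulation ratio, and the areas under the
#' empirical CDF of the (6) nominal and (7) adjusted p-values.
#' @name benchmarking
NULL

# The scalar metric columns a star can be attached to; fc_* are folded into
# a single conjunctive star at assignment time.
metric_cols <- c("n_detected", "n_de", "n_profibrotic_de",
                 "fc_low", "fc_mid", "fc_high",
                 "updown_ratio", "auc_p_nominal", "auc_p_adjusted")

star_metrics <- c("n_detected", "n_de", "n_profibrotic_de", "fc_bins",
                  "updown_ratio", "auc_p_nominal", "auc_p_adjusted")

# Exact area under the empirical CDF of p on [0, 1]: the ECDF is a step
# function, so the integral is sum_i (1 - p_i) / n = 1 - mean(p).
# Equals 0.5 for uniform p-values. NA when no finite p-value exists.
ecdf_auc <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) return(NA_real_)
  1 - mean(p)
}

#' Compute the seven benchmarking metrics for one DEA table
#'
#' @param table A [dea_table()].
#' @param panel Character vector of pro-fibrotic gene symbols for the
#'   table's species.
#' @param thresholds A [de_thresholds()] used for the DE call.
#' @return A one-row tibble with columns `dataset_id`, `comparison`, and the
#'   metrics `n_detected`, `n_de`, `n_profibrotic_de`, `fc_low`, `fc_mid`,
#'   `fc_high`, `updown_ratio`, `auc_p_nominal`, `auc_p_adjusted`.
#' @examples
#' tabs <- simulate_dea_collection(sim_config(n_datasets = 1, n_features = 200, seed = 1))
#' compute_metrics(tabs$tables[[1]], panel = c("COL1A1", "FN1"))
#' @export
compute_metrics <- function(table, panel = character(),
                            thresholds = de_thresholds()) {
  if (!inherits(table, "dea_table")) abort("`table` must be a `dea_table`.")
  m <- dea_meta(table)
  calls <- de_calls(table, thresholds)
  de <- calls != "non_de"
  # bin on the log2 scale so exact linear boundaries (2, 5) are not lost to
  # the 2^log2(x) round trip; every DE gene already has |FC| > min_abs_fc
  de_l <- abs(table$log2fc)[de & is.finite(table$log2fc)]
  tibble(
    dataset_id = m$dataset_id,
    comparison = m$comparison,
    n_detected = nrow(table),
    n_de = sum(de),
    n_profibrotic_de = length(intersect(panel, table$feature_id[de])),
    fc_low  = sum(de_l < 1),
    fc_mid  = sum(de_l >= 1 & de_l < log2(5)),
    fc_high = sum(de_l >= log2(5)),
    updown_ratio = (sum(calls == "up") + 1) / (sum(calls == "down") + 1),
    auc_p_nominal = ecdf_auc(table$p_nominal),
    auc_p_adjusted = ecdf_auc(table$p_adjusted)
  )
}

# Benchmarking groups: species x technology, with exclusively non-coding
# datasets kept apart ("noncoding" scope forms its own stratum).
group_key <- function(meta) {
  paste(meta$species, meta$technology,
        ifelse(meta$biotype_scope == "noncoding", "noncoding", "coding"),
        sep = "/")
}

#' Build per-group metric distributions
#'
#' Pools the metric values of all datasets sharing a benchmarking group and
#' records, per metric, the closed star band `[quantile(q_lo), quantile(q_hi)]`
#' (linear interpolation between order statistics). Groups smaller than
#' `min_group_size` yield no distribution — their members later receive an
#' `NA` star report.
#'
#' @param metrics Tibble of per-dataset metrics joined with their metadata
#'   (as produced inside [benchmark_collection()]), containing at least the
#'   metric columns plus `group`.
#' @param band Quantile pair `c(q_lo, q_hi)` with `0 <= q_lo < q_hi <= 1`;
#'   default the interquartile band `c(0.25, 0.75)`.
#' @param min_group_size Minimum group size for a distribution (default 3).
#' @return A tibble with one row per (group, metric): `group`, `metric`,
#'   `lo`, `hi`, `n_members`.
#' @export
build_group_distributions <- function(metrics, band = c(0.25, 0.75),
                                      min_group_size = 3L) {
  stopifnot(is.numeric(band), length(band) == 2L,
            band[1] >= 0, band[2] <= 1, band[1] < band[2])
  if (nrow(metrics) == 0L) abort("No metrics supplied.")
  if (!"group" %in% names(metrics)) abort("`metrics` must carry a `group` column.")
  # all-missing metrics (e.g. adjusted-p AUC absent everywhere) get an NA band
  q_safe <- function(x, q) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    unname(quantile(x, q, type = 7))
  }
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$group, .data$metric) |>
    summarise(
      n_members = dplyr::n(),
      lo = if (dplyr::n() >= min_group_size) q_safe(.data$value, band[1]) else NA_real_,
      hi = if (dplyr::n() >= min_group_size) q_safe(.data$value, band[2]) else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$n_members >= min_group_size) |>
    select("group", "metric", "lo", "hi", "n_members")
}

#' Assign accreditation stars to one dataset
#'
#' One star per metric whose value lies within the closed group interval
#' `[lo, hi]`. The fold-change bin triple earns its single star only when
#' all three bin counts lie within their respective intervals. A metric
#' flagged missing (`NA`) never earns a star.
#'
#' @param metrics One-row tibble from [compute_metrics()].
#' @param dist Distribution rows for the dataset's group, from
#'   [build_group_distributions()].
#' @return One-row tibble: `dataset_id`, `comparison`, one logical
#'   `star_<metric>` column per starred metric, and `total_stars` (0-7),
#'   or all-`NA` stars when `dist` is empty (group too small).
#' @export
assign_stars <- function(metrics, dist) {
  stopifnot(nrow(metrics) == 1L)
  base <- tibble(dataset_id = metrics$dataset_id, comparison = metrics$comparison)
  if (is.null(dist) || nrow(dist) == 0L) {
    for (m in star_metrics) base[[paste0("star_", m)]] <- NA
    base$total_stars <- NA_integer_
    return(base)
  }
  inside <- function(metric_name, value) {
    row <- dist[dist$metric == metric_name, ]
    if (nrow(row) != 1L || !is.finite(value)) return(FALSE)
    if (!is.finite(row$lo) || !is.finite(row$hi)) return(FALSE)
    value >= row$lo && value <= row$hi
  }
  stars <- c(
    n_detected = inside("n_detected", metrics$n_detected),
    n_de = inside("n_de", metrics$n_de),
    n_profibrotic_de = inside("n_profibrotic_de", metrics$n_profibrotic_de),
    fc_bins = inside("fc_low", metrics$fc_low) &&
      inside("fc_mid", metrics$fc_mid) && inside("fc_high", metrics$fc_high),
    updown_ratio = inside("updown_ratio", metrics$updown_ratio),
    auc_p_nominal = inside("auc_p_nominal", metrics$auc_p_nominal),
    auc_p_adjusted = inside("auc_p_adjusted", metrics$auc_p_adjusted)
  )
  for (m in star_metrics) base[[paste0("star_", m)]] <- unname(stars[[m]])
  base$total_stars <- sum(stars)
  base
}

#' Benchmark a collection of DEA tables end to end
#'
#' Runs [compute_metrics()] per table, groups datasets by species/technology
#' (non-coding-only datasets separately), builds per-group metric
#' distributions and assigns stars.
#'
#' @param tables List of [dea_table()] objects.
#' @param panels Named list mapping species (`human`, `mouse`) to character
#'   vectors of pro-fibrotic gene symbols; missing species get an empty panel.
#' @param thresholds A [de_thresholds()].
#' @param band,min_group_size Passed to [build_group_distributions()].
#' @param comparison Optional comparison label; when given, only tables with
#'   that exact comparison are benchmarked (mirroring single-comparison
#'   re-runs such as `IPF_vs_Ctrl` on lung).
#' @return An object of class `fk_benchmark`: a list with `reports` (star
#'   reports), `metrics` (per-dataset metric values plus group), and
#'   `distributions`. Use [tidy()] for the report table, [glance()] for a
#'   one-row summary, [autoplot()] for a star chart.
#' @examples
#' sim <- simulate_dea_collection(sim_config(n_datasets = 5, n_features = 300, seed = 7))
#' bench <- benchmark_collection(sim$tables)
#' tidy(bench)
#' @export
benchmark_collection <- function(tables, panels = list(),
                                 thresholds = de_thresholds(),
                                 band = c(0.25, 0.75), min_group_size = 3L,
                                 comparison = NULL) {
  if (!length(tables)) abort("Empty collection.")
  meta <- collection_meta(tables)
  if (!is.null(comparison)) {
    keep <- meta$comparison == comparison
    tables <- tables[keep]
    meta <- meta[keep, ]
    if (!nrow(meta)) abort(sprintf("No table matches comparison %s.", comparison))
  }
  metrics <- list_rbind(map(tables, function(t) {
    sp <- dea_meta(t)$species
    compute_metrics(t, panel = panels[[sp]] %||% character(), thresholds = thresholds)
  }))
  metrics$group <- group_key(meta)
  dist <- build_group_distributions(metrics, band = band,
                                    min_group_size = min_group_size)
  reports <- list_rbind(map(seq_len(nrow(metrics)), function(i) {
    g <- metrics$group[i]
    rep <- assign_stars(metrics[i, ], dist[dist$group == g, ])
    rep$group <- g
    rep
  }))
  structure(list(reports = reports, metrics = metrics, distributions = dist,
                 band = band, thresholds = as_de_thresholds(thresholds)),
            class = "fk_benchmark")
}

#' @export
print.fk_benchmark <- function(x, ...) {
  cat(sprintf("<benchmark> %d dataset(s), %d group distribution row(s)\n",
              nrow(x$reports), nrow(x$distributions)))
  print(select(x$reports, "dataset_id", "comparison", "group", "total_stars"))
  invisible(x)
}

#' @describeIn benchmark_collection Star report as a tibble.
#' @param x An `fk_benchmark` object.
#' @param ... Unused.
#' @method tidy fk_benchmark
#' @export
tidy.fk_benchmark <- function(x, ...) x$reports

#' @describeIn benchmark_collection One-row summary: datasets, groups,
#'   ungrouped (NA) reports, mean and max total stars.
#' @method glance fk_benchmark
#' @export
glance.fk_benchmark <- function(x, ...) {
  tibble(
    n_datasets = nrow(x$reports),
    n_groups = dplyr::n_distinct(x$distributions$group),
    n_ungrouped = sum(is.na(x$reports$total_stars)),
    mean_stars = mean(x$reports$total_stars, na.rm = TRUE),
    max_stars = if (all(is.na(x$reports$total_stars))) NA_integer_
                else max(x$reports$total_stars, na.rm = TRUE)
  )
}

#' @describeIn benchmark_collection Bar chart of total stars per
#'   dataset/comparison, faceted by benchmarking group.
#' @param object An `fk_benchmark` object.
#' @method autoplot fk_benchmark
#' @export
autoplot.fk_benchmark <- function(object, ...) {
  df <- object$reports |>
    filter(!is.na(.data$total_stars)) |>
    mutate(label = paste(.data$dataset_id, .data$comparison, sep = "\n"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$total_stars),
                                   y = .data$total_stars)) +
    ggplot2::geom_col(fill = "goldenrod") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 7), breaks = 0:7) +
    ggplot2::labs(x = NULL, y = "Accreditation stars") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
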