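#' @title Vote-counting consensus differential expression
#' @description
#' Integration across datasets is by vote counting, not by p-value or
#' effect-size pooling: a feature is consensus differentially expressed when
#' it is called DE in the same direction in at least `k` of the `n`
#' integrated datasets (default `k = ceiling(n / 2)`, i.e. at least half)
#' and is *never* called DE in the opposite direction in any of the rest.
#' The consensus fold change is the arithmetic mean of the log2 fold changes
#' over the supporting datasets only. Features absent from a table neither
#' support nor veto; `k` is always computed against the number of selected
#' datasets, so the requirement stays user-predictable.
#' @name consensus
NULL

#' Identify consensus differentially expressed features within one species
#'
#' @param tables List of [dea_table()] objects, all of the same species.
#' @param thresholds A [de_thresholds()]. Gene-level integration
#'   conventionally thresholds the nominal p-value (the default); carry the
#'   adjusted statistics in the evidence for reporting.
#' @param k Required number of same-direction DE calls; default
#'   `ceiling(n / 2)` ("at least half"). Must satisfy `1 <= k <= n`.
#' @return A tibble of class `fk_consensus` with columns `feature_id`,
#'   `direction` (`up`/`down`), `consensus_log2fc` (mean over supporting
#'   datasets), `n_support`, `n_selected`, `n_detected_in`, and a list
#'   column `evidence` holding the per-dataset statistics and calls.
#' @examples
#' sim <- simulate_dea_collection(sim_config(n_datasets = 4, n_features = 400, seed = 2))
#' head(consensus_features(sim$tables))
#' @export
consensus_features <- function(tables, thresholds = de_thresholds(), k = NULL) {
  if (!length(tables)) abort("Empty collection.")
  meta <- collection_meta(tables)
  if (dplyr::n_distinct(meta$species) > 1L) {
    abort("Mixed-species input: same-species consensus requires one species (see `cross_species_consensus()`).")
  }
  n <- length(tables)
  k <- if (is.null(k)) as.integer(ceiling(n / 2)) else as.integer(k)
  if (k < 1L || k > n) abort(sprintf("`k` must lie in [1, %d].", n))

  long <- collection_stats(tables)
  long$call <- unlist(map(tables, function(t) as.character(de_calls(t, thresholds))))

  votes <- long |>
    group_by(.data$feature_id) |>
    summarise(
      n_detected_in = dplyr::n(),
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      mean_up = mean(.data$log2fc[.data$call == "up"]),
      mean_down = mean(.data$log2fc[.data$call == "down"]),
      .groups = "drop"
    ) |>
    mutate(direction = case_when(
      .data$n_up >= k & .data$n_down == 0L ~ "up",
      .data$n_down >= k & .data$n_up == 0L ~ "down",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$direction)) |>
    mutate(
      consensus_log2fc = ifelse(.data$direction == "up", .data$mean_up, .data$mean_down),
      n_support = ifelse(.data$direction == "up", .data$n_up, .data$n_down)
    )

  evidence <- long |>
    select("feature_id", "dataset_id", "log2fc", "p_nominal", "p_adjusted", "call") |>
    semi_join(votes, by = "feature_id") |>
    tidyr::nest(evidence = !"feature_id")

  out <- votes |>
    select("feature_id", "direction", "consensus_log2fc", "n_support", "n_detected_in") |>
    mutate(n_selected = n, .after = "n_support") |>
    left_join(evidence, by = "feature_id") |>
    arrange(desc(abs(.data$consensus_log2fc)))

  structure(out, k = k, n_selected = n,
            thresholds = as_de_thresholds(thresholds),
            species = meta$species[[1L]],
            class = c("fk_consensus", class(out)))
}

#' @export
print.fk_consensus <- function(x, ...) {
  cat(sprintf("<consensus> %d feature(s) from %d dataset(s) (k = %d, species = %s)\n",
              nrow(x), attr(x, "n_selected"), attr(x, "k"), attr(x, "species")))
  NextMethod()
}

#' @describeIn consensus_features Flat evidence-free consensus table.
#' @param x An `fk_consensus` object.
#' @param ... Unused.
#' @method tidy fk_consensus
#' @export
tidy.fk_consensus <- function(x, ...) {
  as_tibble(x) |> select(!"evidence")
}

#' @describeIn consensus_features One-row summary of the consensus call set.
#' @method glance fk_consensus
#' @export
glance.fk_consensus <- function(x, ...) {
  tibble(n_consensus = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_selected = attr(x, "n_selected"),
         k = attr(x, "k"))
}

#' @describeIn consensus_features Consensus fold-change distribution by
#'   direction.
#' @param object An `fk_consensus` object.
#' @method autoplot fk_consensus
#' @export
autoplot.fk_consensus <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$consensus_log2fc, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = "consensus log2 fold change", y = "features") +
    ggplot2::theme_minimal()
}

#' Keep only one-to-one homology pairs
#'
#' Drops every pair whose human or mouse gene participates in more than one
#' pair, leaving a strict 1:1 human:mouse map.
#'
#' @param homology Data frame with columns `human_gene`, `mouse_gene`.
#' @return Tibble of the retained pairs.
#' @export
filter_one_to_one <- function(homology) {
  homology <- distinct(as_tibble(homology), .data$human_gene, .data$mouse_gene)
  # both members must be unique in the original map: a gene with any
  # additional homologue disqualifies all of its pairs
  filter(homology,
         !.data$human_gene %in% .data$human_gene[duplicated(.data$human_gene)],
         !.data$mouse_gene %in% .data$mouse_gene[duplicated(.data$mouse_gene)])
}

#' Cross-species consensus via one-to-one homology
#'
#' Runs the complete same-species consensus rule (including the
#' opposite-direction veto) independently in each species, then reports the
#' homologue pairs that are consensus in *both* species with the same
#' direction and have strict 1:1 human:mouse homology. Consensus fold
#' changes are reported per species. Exclusively non-coding datasets are
#' rejected.
#'
#' @param human_tables,mouse_tables Lists of [dea_table()] objects.
#' @param homology Data frame with columns `human_gene`, `mouse_gene`
#'   (filtered to 1:1 internally).
#' @param thresholds A [de_thresholds()].
#' @param k_human,k_mouse Optional per-species `k`; default at-least-half.
#' @return Tibble with `human_gene`, `mouse_gene`, `direction`,
#'   `human_log2fc`, `mouse_log2fc`, `human_support`, `mouse_support`.
#' @export
cross_species_consensus <- function(human_tables, mouse_tables, homology,
                                    thresholds = de_thresholds(),
                                    k_human = NULL, k_mouse = NULL) {
  if (!length(human_tables) || !length(mouse_tables)) {
    abort("Both species need at least one dataset.")
  }
  for (t in c(human_tables, mouse_tables)) {
    if (dea_meta(t)$biotype_scope == "noncoding") {
      abort(sprintf("Dataset %s profiles only non-coding genes and cannot enter cross-species integration.",
                    dea_meta(t)$dataset_id))
    }
  }
  pairs <- filter_one_to_one(homology)
  empty <- tibble(human_gene = character(), mouse_gene = character(),
                  direction = character(), human_log2fc = double(),
                  mouse_log2fc = double(), human_support = integer(),
                  mouse_support = integer())
  if (nrow(pairs) == 0L) {
    warn("Empty homology map after 1:1 filtering; no cross-species consensus possible.")
    return(empty)
  }
  hs <- tidy(consensus_features(human_tables, thresholds, k_human))
  ms <- tidy(consensus_features(mouse_tables, thresholds, k_mouse))
  pairs |>
    inner_join(rename(hs, human_gene = "feature_id"), by = "human_gene") |>
    inner_join(rename(ms, mouse_gene = "feature_id"), by = "mouse_gene",
               suffix = c("_human", "_mouse")) |>
    filter(.data$direction_human == .data$direction_mouse) |>
    mutate(direction = .data$direction_human,
           human_log2fc = .data$consensus_log2fc_human,
           mouse_log2fc = .data$consensus_log2fc_mouse,
           human_support = .data$n_support_human,
           mouse_support = .data$n_support_mouse) |>
    select(dplyr::all_of(names(empty)))
}

#' Pair consensus miRNAs with oppositely deregulated target genes
#'
#' Given consensus call sets for miRNAs and for mRNAs (the former built with
#' FDR-adjusted thresholds, `use_adjusted = TRUE`, per the miRNA
#' convention), returns every (miRNA, target) pair from the target map whose
#' two members are consensus DE in opposite directions — the anticorrelation
#' pattern expected of a repressive miRNA-target interaction.
#'
#' @param mirna_consensus,mrna_consensus `fk_consensus` tables (or any data
#'   frame with `feature_id` and `direction`).
#' @param targets Data frame with columns `mirna`, `target`.
#' @return Tibble: `mirna`, `mirna_direction`, `target`, `target_direction`,
#'   plus consensus fold changes when available.
#' @export
mirna_mrna_integration <- function(mirna_consensus, mrna_consensus, targets) {
  targets <- distinct(as_tibble(targets), .data$mirna, .data$target)
  if (any(targets$mirna == targets$target)) abort("Self-edges in target map.")
  mi <- as_tibble(mirna_consensus)
  mr <- as_tibble(mrna_consensus)
  grab <- function(df, id_col, prefix) {
    out <- tibble("{id_col}" := df$feature_id,
                  "{prefix}_direction" := as.character(df$direction))
    if ("consensus_log2fc" %in% names(df)) {
      out[[paste0(prefix, "_log2fc")]] <- df$consensus_log2fc
    }
    out
  }
  if (!nrow(mi) || !nrow(mr) || !nrow(targets)) {
    return(tibble(mirna = character(), mirna_direction = character(),
                  target = character(), target_direction = character()))
  }
  targets |>
    inner_join(grab(mi, "mirna", "mirna"), by = "mirna") |>
    inner_join(grab(mr, "target", "target"), by = "target") |>
    filter(.data$mirna_direction != .data$target_direction) |>
    arrange(.data$mirna, .data$target)
}
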