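#' @title Two-shell protein-protein interaction networks
#' @description
#' A condition-specific interaction view is built around one queried
#' protein from a STRING-style scored edge list (combined scores 0-1000).
#' The first shell holds at most nine high-confidence interactors of the
#' query (score strictly above 700 by default, ranked by score). The second
#' shell adds, for each first-shell protein, its two most confident
#' interactors that are neither the query nor already in the first shell.
#' All edges of the input table among the included nodes are retained, with
#' the score as edge weight. Nodes are then labelled with a consensus
#' direction of transcriptomic deregulation (`Unknown`, `NonDE`,
#' `Upregulated`, `Downregulated`) via the primary gene coding for each
#' reviewed (Swiss-Prot-like) protein.
#' @name ppi
NULL

#' Validate a scored interaction table
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`
#'   (integer 0-1000). Undirected: at most one record per unordered pair,
#'   no self-loops. Pair order is canonicalised.
#' @return A tibble of class `interaction_table`.
#' @export
interaction_table <- function(edges) {
  edges <- as_tibble(edges)
  required <- c("protein_a", "protein_b", "score")
  if (!all(required %in% names(edges))) {
    abort("`edges` needs columns protein_a, protein_b, score.")
  }
  edges <- edges[required]
  if (any(edges$protein_a == edges$protein_b)) abort("Self-loops are not allowed.")
  if (any(!is.finite(edges$score) | edges$score < 0 | edges$score > 1000)) {
    abort("Scores must lie within [0, 1000].")
  }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  if (anyDuplicated(paste(a, b, sep = "\r"))) {
    abort("Duplicate records for an unordered protein pair.")
  }
  structure(edges, class = c("interaction_table", class(edges)))
}

# Neighbours of `id` as a tibble (partner, score), best score first,
# ties broken by lexicographic partner id so ranking is total.
neighbours_of <- function(edges, id) {
  hit_a <- edges$protein_a == id
  hit_b <- edges$protein_b == id
  tibble(partner = c(edges$protein_b[hit_a], edges$protein_a[hit_b]),
         score = c(edges$score[hit_a], edges$score[hit_b])) |>
    arrange(desc(.data$score), .data$partner)
}

#' Build a query-centred two-shell interaction network
#'
#' @param query Protein id at the centre (shell 0). Must exist in
#'   `universe` (it need not have any edge).
#' @param interactions An [interaction_table()].
#' @param max_first_shell Maximum number of first-shell proteins (default 9).
#' @param per_node_second Second-shell interactors retained per first-shell
#'   protein (default 2).
#' @param min_score First-shell score floor; only interactors with score
#'   strictly greater than this enter shell 1 (default 700).
#' @param second_min_score Optional score floor for second-shell candidates;
#'   `NULL` (default) ranks them purely by confidence with no floor.
#' @param universe Optional character vector of known protein ids used to
#'   validate the query; defaults to the ids present in the edge list.
#' @return An object of class `shell_network`: list with `nodes`
#'   (`protein`, `shell`, `label`) and `edges` (`protein_a`, `protein_b`,
#'   `weight`). Labels start `NA`; see [annotate_network()].
#' @examples
#' it <- simulate_interactome(n_proteins = 30, seed = 5)
#' net <- build_two_shell_network("P01", it$interactions)
#' tidy(net)
#' @export
build_two_shell_network <- function(query, interactions, max_first_shell = 9L,
                                    per_node_second = 2L, min_score = 700,
                                    second_min_score = NULL, universe = NULL) {
  if (!inherits(interactions, "interaction_table")) {
    interactions <- interaction_table(interactions)
  }
  known <- universe %||% unique(c(interactions$protein_a, interactions$protein_b))
  if (!query %in% known) abort(sprintf("Unknown query protein %s.", query))

  shell1 <- neighbours_of(interactions, query) |>
    filter(.data$score > min_score) |>
    slice_head(n = max_first_shell) |>
    pull("partner")

  shell2 <- character()
  for (p in shell1) {
    cand <- neighbours_of(interactions, p) |>
      filter(!.data$partner %in% c(query, shell1))
    if (!is.null(second_min_score)) cand <- filter(cand, .data$score > second_min_score)
    shell2 <- c(shell2, head(cand$partner, per_node_second))
  }
  shell2 <- setdiff(unique(shell2), c(query, shell1))

  nodes <- tibble(
    protein = c(query, shell1, sort(shell2)),
    shell = c(0L, rep(1L, length(shell1)), rep(2L, length(shell2))),
    label = NA_character_
  )
  edges <- interactions |>
    filter(.data$protein_a %in% nodes$protein & .data$protein_b %in% nodes$protein) |>
    rename(weight = "score") |>
    as_tibble()
  structure(list(nodes = nodes, edges = edges, query = query),
            class = "shell_network")
}

#' @export
print.shell_network <- function(x, ...) {
  cat(sprintf("<shell_network> query %s | shell1: %d, shell2: %d | %d edge(s)\n",
              x$query, sum(x$nodes$shell == 1L), sum(x$nodes$shell == 2L),
              nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_two_shell_network Node table with shell and label.
#' @param x A `shell_network`.
#' @param ... Unused.
#' @method tidy shell_network
#' @export
tidy.shell_network <- function(x, ...) x$nodes

#' @describeIn build_two_shell_network One-row shell-size/label summary.
#' @method glance shell_network
#' @export
glance.shell_network <- function(x, ...) {
  tibble(query = x$query,
         n_shell1 = sum(x$nodes$shell == 1L),
         n_shell2 = sum(x$nodes$shell == 2L),
         n_edges = nrow(x$edges),
         n_labelled = sum(!is.na(x$nodes$label)))
}

#' Convert a shell network to an igraph object
#'
#' Nodes carry `shell` and `label` attributes, edges carry the interaction
#' score as `weight`; suitable for any layout/rendering backend or for
#' GraphML export via [igraph::write_graph()].
#'
#' @param net A `shell_network`.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "shell_network"))
  igraph::graph_from_data_frame(
    d = select(net$edges, "protein_a", "protein_b", "weight"),
    directed = FALSE,
    vertices = net$nodes
  )
}

#' @describeIn build_two_shell_network Shell-coloured network sketch.
#' @param object A `shell_network`.
#' @method autoplot shell_network
#' @export
autoplot.shell_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  seg <- object$edges |>
    left_join(select(nodes, "protein", "x", "y"), by = c(protein_a = "protein")) |>
    left_join(select(nodes, "protein", "x", "y"), by = c(protein_b = "protein"),
              suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey70", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = factor(.data$shell),
                                     colour = .data$label %||% "unlabelled"),
                        size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$protein),
                       vjust = -1.2, size = 3) +
    ggplot2::labs(shape = "shell", colour = "label") +
    ggplot2::theme_void()
}

#' Consensus deregulation label for one gene
#'
#' Summarises per-dataset DE statistics of a gene into a single label:
#' * `Unknown` when the protein is unreviewed (TrEMBL-like entries are not
#'   supported);
#' * `NonDE` when no dataset yields a DE call;
#' * with one DE dataset, or two agreeing DE datasets, the direction is kept
#'   as is;
#' * with two disagreeing DE datasets, the bigger dataset (larger
#'   `n_samples`; ties broken by larger `n_detected`, then by dataset id)
#'   wins;
#' * with three or more DE datasets, the most frequent direction wins, a
#'   tied count falling back to the biggest DE dataset's direction.
#'
#' @param gene_stats Data frame with one row per dataset in which the gene
#'   was detected: columns `dataset_id`, `log2fc`, `p_nominal`,
#'   `p_adjusted`, `n_samples`, optionally `n_detected`.
#' @param thresholds A [de_thresholds()].
#' @param reviewed Is the protein a reviewed (Swiss-Prot-like) entry?
#' @return One of `"Unknown"`, `"NonDE"`, `"Upregulated"`, `"Downregulated"`.
#' @export
consensus_label <- function(gene_stats, thresholds = de_thresholds(),
                            reviewed = TRUE) {
  if (!isTRUE(reviewed)) return("Unknown")
  gene_stats <- as_tibble(gene_stats)
  if (nrow(gene_stats) == 0L) return("NonDE")
  p <- if (as_de_thresholds(thresholds)$use_adjusted) gene_stats$p_adjusted else gene_stats$p_nominal
  gene_stats$call <- classify_de(gene_stats$log2fc, p, thresholds)
  de <- filter(gene_stats, .data$call != "non_de")
  if (nrow(de) == 0L) return("NonDE")
  as_label <- function(call) if (call == "up") "Upregulated" else "Downregulated"
  if (!"n_detected" %in% names(de)) de$n_detected <- NA_integer_
  biggest <- de |>
    arrange(desc(.data$n_samples), desc(.data$n_detected), .data$dataset_id) |>
    slice_head(n = 1L)
  if (nrow(de) == 1L) return(as_label(as.character(de$call[[1L]])))
  if (nrow(de) == 2L) {
    if (dplyr::n_distinct(de$call) == 1L) return(as_label(as.character(de$call[[1L]])))
    return(as_label(as.character(biggest$call[[1L]])))
  }
  n_up <- sum(de$call == "up")
  n_down <- sum(de$call == "down")
  if (n_up > n_down) return("Upregulated")
  if (n_down > n_up) return("Downregulated")
  as_label(as.character(biggest$call[[1L]]))
}

#' Validate a protein -> gene annotation table
#'
#' @param annotation Data frame with columns `protein_id`, `reviewed`
#'   (logical), `gene`, `is_primary` (logical; exactly one primary gene per
#'   reviewed protein — the gene featured as primary by the annotation
#'   source is the one used for labelling).
#' @return A validated tibble.
#' @export
protein_annotation <- function(annotation) {
  annotation <- as_tibble(annotation)
  required <- c("protein_id", "reviewed", "gene", "is_primary")
  if (!all(required %in% names(annotation))) {
    abort("`annotation` needs columns protein_id, reviewed, gene, is_primary.")
  }
  chk <- annotation |>
    filter(.data$reviewed) |>
    group_by(.data$protein_id) |>
    summarise(n_primary = sum(.data$is_primary), n_genes = dplyr::n(), .groups = "drop")
  if (any(chk$n_genes < 1L) || any(chk$n_primary != 1L)) {
    abort("Every reviewed protein needs >= 1 coding gene with exactly one marked primary.")
  }
  annotation
}

#' Annotate a shell network with consensus deregulation labels
#'
#' For each node, the primary gene of a reviewed protein is looked up in
#' the supplied DEA tables (pre-filtered by the caller to the experimental
#' parameters of interest) and [consensus_label()] applied to its
#' per-dataset statistics. Unreviewed proteins, and proteins absent from
#' the annotation, are labelled `Unknown` (the latter with a warning). The
#' per-node statistics used — including the adjusted p-values — are kept in
#' the returned object for inspection and export.
#'
#' @param net A `shell_network` from [build_two_shell_network()].
#' @param tables List of [dea_table()] objects.
#' @param annotation A [protein_annotation()] table.
#' @param thresholds A [de_thresholds()].
#' @return The network with `nodes$label` filled in and a `data_used`
#'   tibble (per node, per dataset statistics) attached.
#' @export
annotate_network <- function(net, tables, annotation,
                             thresholds = de_thresholds()) {
  stopifnot(inherits(net, "shell_network"))
  annotation <- protein_annotation(annotation)
  long <- collection_stats(tables)
  sizes <- collection_meta(tables) |> select("dataset_id", "n_samples")
  n_det <- long |> count(.data$dataset_id, name = "n_detected")
  long <- long |> left_join(sizes, by = "dataset_id") |>
    left_join(n_det, by = "dataset_id")

  data_used <- list()
  labels <- map_chr(net$nodes$protein, function(p) {
    ann <- filter(annotation, .data$protein_id == p)
    if (nrow(ann) == 0L) {
      warn(sprintf("Protein %s absent from annotation; labelled Unknown.", p))
      return("Unknown")
    }
    if (!any(ann$reviewed)) return("Unknown")
    gene <- ann$gene[ann$is_primary][[1L]]
    stats <- filter(long, .data$feature_id == gene)
    data_used[[p]] <<- mutate(stats, protein = p, .before = 1L)
    consensus_label(stats, thresholds, reviewed = TRUE)
  })
  net$nodes$label <- labels
  net$data_used <- list_rbind(data_used)
  net
}

#' Write a shell network as plain-text edge list + node attribute table
#'
#' @param net A (preferably annotated) `shell_network`.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`, plus `<prefix>_data_used.tsv` when annotation
#'   statistics are attached.
#' @return `prefix`, invisibly.
#' @export
write_shell_network <- function(net, prefix) {
  stopifnot(inherits(net, "shell_network"))
  readr::write_tsv(net$edges, paste0(prefix, "_edges.tsv"), progress = FALSE)
  readr::write_tsv(net$nodes, paste0(prefix, "_nodes.tsv"), progress = FALSE)
  if (!is.null(net$data_used) && nrow(net$data_used)) {
    readr::write_tsv(net$data_used, paste0(prefix, "_data_used.tsv"), progress = FALSE)
  }
  invisible(prefix)
}

#' Read a STRING-flavoured scored edge list
#'
#' Three tab-delimited columns: `protein_a`, `protein_b`, `combined_score`
#' (0-1000).
#'
#' @param path File path.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cci", progress = FALSE, comment = "#")
  names(raw)[1:3] <- c("protein_a", "protein_b", "score")
  interaction_table(raw)
}
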