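#' @title Co-expression subnetwork extraction
#' @description
#' Weighted gene co-expression network analysis (WGCNA) yields, per gene, a
#' module assignment, a module membership (MM: correlation of the gene's
#' profile with its module eigengene) and a gene significance (GS:
#' correlation with the phenotype trait), plus a topological overlap matrix
#' (TOM) over module genes. Fitting those models is upstream of this
#' package; here a precomputed `module_data` object is mined for the
#' visualisation subnetwork around a queried gene: module members whose MM
#' *and* GS lie strictly above the module's 60th percentile are kept as
#' nodes, edges connect candidate pairs with TOM strictly above the
#' module's 3rd quartile of off-diagonal TOM values, zero-degree non-query
#' nodes are dropped (the query is the only node allowed to have no edge),
#' and a maximum-TOM spanning forest is computed over what remains.
#' @name coexpr
NULL

#' Bundle precomputed co-expression module data
#'
#' @param genes Data frame with columns `gene`, `module`, `mm` (module
#'   membership in \[-1, 1\]), `gs` (gene significance in \[-1, 1\]).
#' @param tom Symmetric numeric matrix of topological overlap values in
#'   \[0, 1\] with row/column names covering every gene in `genes`; the
#'   diagonal is ignored.
#' @return An object of class `module_data`.
#' @export
module_data <- function(genes, tom) {
  genes <- as_tibble(genes)
  required <- c("gene", "module", "mm", "gs")
  if (!all(required %in% names(genes))) {
    abort("`genes` needs columns gene, module, mm, gs.")
  }
  if (anyDuplicated(genes$gene)) abort("Duplicated gene in module table.")
  if (any(abs(genes$mm) > 1 | abs(genes$gs) > 1, na.rm = TRUE)) {
    abort("`mm` and `gs` are correlations and must lie in [-1, 1].")
  }
  tom <- as.matrix(tom)
  if (is.null(rownames(tom)) || !identical(rownames(tom), colnames(tom))) {
    abort("`tom` needs identical row and column names.")
  }
  if (!all(genes$gene %in% rownames(tom))) {
    abort("Every gene in `genes` must appear in the TOM.")
  }
  off <- tom[row(tom) != col(tom)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) abort("Off-diagonal TOM values must lie in [0, 1].")
  if (max(abs(tom - t(tom))) > 1e-8) abort("`tom` must be symmetric.")
  structure(list(genes = genes[required], tom = tom), class = "module_data")
}

#' @export
print.module_data <- function(x, ...) {
  cat(sprintf("<module_data> %d gene(s) in %d module(s); TOM %d x %d\n",
              nrow(x$genes), dplyr::n_distinct(x$genes$module),
              nrow(x$tom), ncol(x$tom)))
  invisible(x)
}

# Strict quantile threshold filter for one module: genes with mm AND gs
# strictly above the module-local percentiles (linear-interpolation rule).
module_candidates <- function(data, module, mm_pct, gs_pct) {
  members <- filter(data$genes, .data$module == !!module)
  # percentile 0 means no filter: "above the 0th percentile" keeps everything
  cut_at <- function(x, pct) {
    if (pct <= 0) -Inf else unname(quantile(x, pct, na.rm = TRUE, type = 7))
  }
  mm_cut <- cut_at(members$mm, mm_pct)
  gs_cut <- cut_at(members$gs, gs_pct)
  members$gene[members$mm > mm_cut & members$gs > gs_cut]
}

#' Re-apply the node-selection filter at chosen strictness
#'
#' Pure re-application of the MM/GS percentile filter for the queried
#' gene's module, letting the strictness of node selection be tuned.
#' Monotone: raising either percentile never adds a gene.
#'
#' @param data A [module_data()].
#' @param query Gene whose module is filtered.
#' @param mm_pct,gs_pct Percentile cutoffs in `[0, 1)`.
#' @return Character vector of candidate genes (query not automatically
#'   included).
#' @export
tune_thresholds <- function(data, query, mm_pct = 0.60, gs_pct = 0.60) {
  stopifnot(inherits(data, "module_data"))
  if (mm_pct >= 1 || gs_pct >= 1 || mm_pct < 0 || gs_pct < 0) {
    abort("Percentiles must lie in [0, 1).")
  }
  module <- data$genes$module[data$genes$gene == query]
  if (length(module) != 1L) abort(sprintf("Gene %s is not assigned to any module.", query))
  sort(module_candidates(data, module, mm_pct, gs_pct))
}

#' Extract the visualisation subnetwork around a queried gene
#'
#' Applies the MM/GS percentile node filter and the TOM quantile edge
#' filter described in [coexpr], drops zero-degree non-query nodes, and
#' computes a maximum-TOM spanning forest (Kruskal on distance `1 - TOM`)
#' over the retained graph.
#'
#' @param query Gene at the centre; must belong to a module. It is always
#'   retained, even when isolated or below the percentile cutoffs.
#' @param data A [module_data()].
#' @param mm_pct,gs_pct Node-filter percentiles (default 0.60), strict `>`
#'   against the module-local quantile.
#' @param tom_q Edge-filter quantile over the module's off-diagonal TOM
#'   values (default 0.75, the 3rd quartile), strict `>`.
#' @return An object of class `coexpr_subnetwork`: list with `nodes`
#'   (`gene`, `is_query`, `mm`, `gs`), `edges` (`gene_a`, `gene_b`,
#'   `tom`), and `spanning_tree` (subset of `edges`).
#' @examples
#' md <- simulate_module_data(n_genes = 40, n_modules = 2, seed = 3)
#' sub <- extract_subnetwork(md$genes$gene[1], md)
#' glance(sub)
#' @export
extract_subnetwork <- function(query, data, mm_pct = 0.60, gs_pct = 0.60,
                               tom_q = 0.75) {
  stopifnot(inherits(data, "module_data"))
  module <- data$genes$module[data$genes$gene == query]
  if (length(module) != 1L) abort(sprintf("Gene %s is not assigned to any module.", query))
  members <- filter(data$genes, .data$module == !!module)

  candidates <- union(query, module_candidates(data, module, mm_pct, gs_pct))
  candidates <- sort(candidates)

  sub_tom <- data$tom[members$gene, members$gene, drop = FALSE]
  off <- sub_tom[row(sub_tom) != col(sub_tom)]
  # a single-gene module has no off-diagonal TOM: nothing can pass strictly
  tom_cut <- if (length(off)) unname(quantile(off, tom_q, na.rm = TRUE, type = 7)) else Inf

  cand_tom <- data$tom[candidates, candidates, drop = FALSE]
  idx <- which(upper.tri(cand_tom) & cand_tom > tom_cut, arr.ind = TRUE)
  edges <- tibble(gene_a = candidates[idx[, 1]],
                  gene_b = candidates[idx[, 2]],
                  tom = cand_tom[idx])

  keep <- union(query, unique(c(edges$gene_a, edges$gene_b)))
  nodes <- members |>
    filter(.data$gene %in% keep) |>
    mutate(is_query = .data$gene == query) |>
    select("gene", "is_query", "mm", "gs") |>
    arrange(desc(.data$is_query), .data$gene)

  spanning <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    mst <- igraph::mst(g, weights = 1 - edges$tom)
    el <- igraph::as_data_frame(mst, what = "edges")
    tibble(gene_a = pmin(el$from, el$to), gene_b = pmax(el$from, el$to),
           tom = el$tom) |> arrange(.data$gene_a, .data$gene_b)
  } else {
    edges
  }
  edges <- edges |>
    mutate(gene_a2 = pmin(.data$gene_a, .data$gene_b),
           gene_b = pmax(.data$gene_a, .data$gene_b),
           gene_a = .data$gene_a2) |>
    select("gene_a", "gene_b", "tom") |>
    arrange(.data$gene_a, .data$gene_b)

  structure(list(nodes = nodes, edges = edges, spanning_tree = spanning,
                 query = query, module = module,
                 thresholds = c(mm_pct = mm_pct, gs_pct = gs_pct, tom_q = tom_q)),
            class = "coexpr_subnetwork")
}

#' @export
print.coexpr_subnetwork <- function(x, ...) {
  cat(sprintf("<coexpr_subnetwork> query %s (module %s): %d node(s), %d edge(s), %d spanning edge(s)\n",
              x$query, x$module, nrow(x$nodes), nrow(x$edges),
              nrow(x$spanning_tree)))
  invisible(x)
}

#' @describeIn extract_subnetwork Node table.
#' @param x A `coexpr_subnetwork`.
#' @param ... Unused.
#' @method tidy coexpr_subnetwork
#' @export
tidy.coexpr_subnetwork <- function(x, ...) x$nodes

#' @describeIn extract_subnetwork One-row size summary.
#' @method glance coexpr_subnetwork
#' @export
glance.coexpr_subnetwork <- function(x, ...) {
  tibble(query = x$query, module = x$module, n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges), n_spanning = nrow(x$spanning_tree))
}

#' @describeIn extract_subnetwork TOM-weighted subnetwork sketch with the
#'   spanning forest emphasised and the query marked.
#' @param object A `coexpr_subnetwork`.
#' @method autoplot coexpr_subnetwork
#' @export
autoplot.coexpr_subnetwork <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes)
  lay <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  span_key <- paste(object$spanning_tree$gene_a, object$spanning_tree$gene_b)
  seg <- object$edges |>
    mutate(spanning = paste(.data$gene_a, .data$gene_b) %in% span_key) |>
    left_join(select(nodes, "gene", "x", "y"), by = c(gene_a = "gene")) |>
    left_join(select(nodes, "gene", "x", "y"), by = c(gene_b = "gene"),
              suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$tom,
                                       colour = .data$spanning)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey75")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$is_query,
                                     fill = .data$is_query),
                        shape = 21) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red", `FALSE` = "grey40")) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
                       vjust = -1.2, size = 3) +
    ggplot2::guides(size = "none", alpha = "none") +
    ggplot2::theme_void()
}

#' Read module data from plain-text files
#'
#' @param genes_path Tab-delimited gene attribute table (`gene`, `module`,
#'   `mm`, `gs`).
#' @param tom_path Tab-delimited square TOM matrix with header row and a
#'   first column of gene names.
#' @return A [module_data()].
#' @export
read_module_data <- function(genes_path, tom_path) {
  genes <- readr::read_tsv(genes_path, col_types = "ccdd", progress = FALSE,
                           comment = "#")
  tom_raw <- readr::read_tsv(tom_path, col_types = readr::cols(), progress = FALSE,
                             comment = "#")
  tom <- as.matrix(tom_raw[, -1])
  rownames(tom) <- tom_raw[[1]]
  module_data(genes, tom)
}

#' Write a co-expression subnetwork as plain-text tables
#'
#' @param sub A `coexpr_subnetwork`.
#' @param prefix Path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>_spanning.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_subnetwork <- function(sub, prefix) {
  stopifnot(inherits(sub, "coexpr_subnetwork"))
  readr::write_tsv(sub$nodes, paste0(prefix, "_nodes.tsv"), progress = FALSE)
  readr::write_tsv(sub$edges, paste0(prefix, "_edges.tsv"), progress = FALSE)
  readr::write_tsv(sub$spanning_tree, paste0(prefix, "_spanning.tsv"), progress = FALSE)
  invisible(prefix)
}
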