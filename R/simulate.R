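#' @title Synthetic data with controlled ground truth
#' @description
#' Every analysis in the package can be exercised without downloads through
#' seeded generators that emit the same tabular formats the readers accept.
#' The DEA-collection generator plants a configurable fraction of features
#' that are consistently deregulated across all datasets of a collection
#' (direction-consistent log2 effects, significance drawn from a
#' left-skewed Beta alternative), against a null of Uniform(0,1) p-values
#' and small symmetric log2 fold-change noise. All randomness flows from a
#' single seed; a fixed seed reproduces the outputs byte-identically.
#' @name synthetic
NULL

with_sim_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

#' Configuration for the DEA-collection generator
#'
#' Defaults describe a typical small integration exercise: four same-species
#' datasets of 2000 features each, 5% of features planted as shared DE with
#' a strong mean absolute log2 effect of 2 (sd 0.3) and alternative
#' p-values from Beta(0.1, 1), against Uniform(0, 1) null p-values and null
#' log2 fold changes from N(0, 0.2).
#'
#' @param n_datasets Number of datasets in the collection.
#' @param n_features Features per dataset.
#' @param frac_planted Fraction of features planted as shared DE, in \[0, 1\].
#' @param effect_mean,effect_sd Mean and sd of the planted absolute log2
#'   fold change (sign fixed per feature, shared across datasets).
#' @param null_log2fc_sd Sd of the null log2 fold-change noise.
#' @param alt_shape1,alt_shape2 Beta parameters of the alternative p-value
#'   model; the default Beta(0.1, 1) is heavily skewed toward zero.
#' @param species,technology,platform,tissue,comparison,biotype_scope
#'   Metadata shared by the collection (comparison in `A_vs_B` form).
#' @param n_samples_range Inclusive range from which each dataset's total
#'   sample count is drawn.
#' @param feature_prefix Prefix of generated feature ids.
#' @param dataset_prefix Prefix of generated dataset ids; vary it when
#'   combining several simulated collections.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 4L, n_features = 2000L,
                       frac_planted = 0.05, effect_mean = 2,
                       effect_sd = 0.3, null_log2fc_sd = 0.2,
                       alt_shape1 = 0.1, alt_shape2 = 1,
                       species = "human", technology = "microarray",
                       platform = "synthetic", tissue = "lung",
                       comparison = "IPF_vs_Ctrl",
                       biotype_scope = "coding",
                       n_samples_range = c(6L, 20L),
                       feature_prefix = "GENE", dataset_prefix = "SIM",
                       seed = 1L) {
  stopifnot(n_datasets >= 1L, n_features >= 1L,
            frac_planted >= 0, frac_planted <= 1,
            effect_sd >= 0, null_log2fc_sd >= 0,
            alt_shape1 > 0, alt_shape2 > 0,
            length(n_samples_range) == 2L,
            n_samples_range[1] >= 3L,
            n_samples_range[1] <= n_samples_range[2])
  parse_comparison_label(comparison)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic DEA-table collection with planted consensus signal
#'
#' @param config A [sim_config()].
#' @return List with `tables` (list of [dea_table()]) and `truth` (tibble:
#'   `feature_id`, `direction`, `planted_log2fc` per dataset as a list
#'   column).
#' @examples
#' sim <- simulate_dea_collection(sim_config(n_datasets = 2, n_features = 100, seed = 9))
#' sim$tables[[1]]
#' head(sim$truth)
#' @export
simulate_dea_collection <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must come from `sim_config()`.")
  c0 <- config
  with_sim_seed(c0$seed, {
    features <- sprintf("%s%04d", c0$feature_prefix, seq_len(c0$n_features))
    n_planted <- round(c0$frac_planted * c0$n_features)
    planted <- features[seq_len(n_planted)]
    direction <- if (n_planted) sample(c("up", "down"), n_planted, replace = TRUE) else character()
    sign <- ifelse(direction == "up", 1, -1)

    effects <- vector("list", c0$n_datasets)
    tables <- vector("list", c0$n_datasets)
    for (d in seq_len(c0$n_datasets)) {
      log2fc <- rnorm(c0$n_features, 0, c0$null_log2fc_sd)
      p <- runif(c0$n_features)
      if (n_planted) {
        eff <- sign * rnorm(n_planted, c0$effect_mean, c0$effect_sd)
        log2fc[seq_len(n_planted)] <- eff
        p[seq_len(n_planted)] <- rbeta(n_planted, c0$alt_shape1, c0$alt_shape2)
        effects[[d]] <- eff
      } else {
        effects[[d]] <- double()
      }
      meta <- dataset_meta(
        dataset_id = sprintf("%s%02d", c0$dataset_prefix, d), species = c0$species,
        technology = c0$technology, platform = c0$platform,
        tissue = c0$tissue, comparison = c0$comparison,
        n_samples = sample(seq(c0$n_samples_range[1], c0$n_samples_range[2]), 1L),
        biotype_scope = c0$biotype_scope
      )
      tables[[d]] <- dea_table(
        tibble(feature_id = features, log2fc = log2fc,
               p_nominal = p, p_adjusted = bh_adjust(p)),
        meta
      )
    }
    truth <- tibble(
      feature_id = planted, direction = direction,
      planted_log2fc = if (n_planted) map(seq_len(n_planted), function(i)
        map_dbl(effects, i)) else list()
    )
    list(tables = tables, truth = truth, config = c0)
  })
}

#' Generate a synthetic scored interactome with protein annotation
#'
#' Random undirected graph over `n_proteins` with integer combined scores
#' uniform on \[1, 1000\]; a configurable fraction of proteins is flagged
#' unreviewed, and a fraction of the reviewed ones receives a secondary
#' (non-primary) coding gene to exercise the 1:many annotation rule. A
#' high-confidence hub of given degree can be planted for shell-cap tests.
#'
#' @param n_proteins Number of proteins (ids `P01`, `P02`, ...).
#' @param edge_density Probability of each unordered pair being connected.
#' @param frac_unreviewed Fraction of proteins flagged unreviewed.
#' @param frac_multi_gene Fraction of reviewed proteins with a secondary gene.
#' @param hub_id Optional id of a planted hub protein (added to the universe).
#' @param hub_degree Number of partners wired to the hub.
#' @param hub_score_range Inclusive integer score range for hub edges
#'   (default above the 700 high-confidence floor).
#' @param seed Integer seed.
#' @return List with `interactions` (an [interaction_table()]) and
#'   `annotation` (a [protein_annotation()] tibble; protein `Pk` codes
#'   primary gene `Gk`).
#' @export
simulate_interactome <- function(n_proteins = 30L, edge_density = 0.15,
                                 frac_unreviewed = 0.2, frac_multi_gene = 0.1,
                                 hub_id = NULL, hub_degree = 0L,
                                 hub_score_range = c(701L, 1000L), seed = 1L) {
  stopifnot(edge_density > 0, edge_density <= 1)
  with_sim_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n_proteins))
    pairs <- t(utils::combn(ids, 2L))
    keep <- runif(nrow(pairs)) <= edge_density
    edges <- tibble(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L],
                    score = sample(1:1000, sum(keep), replace = TRUE))
    if (!is.null(hub_id)) {
      partners <- sample(setdiff(ids, hub_id), min(hub_degree, n_proteins))
      hub_edges <- tibble(
        protein_a = hub_id, protein_b = partners,
        score = sample(seq(hub_score_range[1], hub_score_range[2]),
                       length(partners), replace = TRUE)
      )
      hub_keys <- paste(pmin(hub_id, partners), pmax(hub_id, partners))
      edges <- edges |>
        filter(!paste(pmin(.data$protein_a, .data$protein_b),
                      pmax(.data$protein_a, .data$protein_b)) %in% hub_keys) |>
        bind_rows(hub_edges)
      ids <- union(ids, hub_id)
    }
    reviewed <- setNames(runif(length(ids)) >= frac_unreviewed, ids)
    annotation <- list_rbind(imap(reviewed, function(rev, p) {
      gene <- sub("^P", "G", p)
      rows <- tibble(protein_id = p, reviewed = rev, gene = gene, is_primary = TRUE)
      if (rev && runif(1) < frac_multi_gene) {
        rows <- bind_rows(rows, tibble(protein_id = p, reviewed = rev,
                                       gene = paste0(gene, "alt"),
                                       is_primary = FALSE))
      }
      rows
    }))
    list(interactions = interaction_table(edges),
         annotation = protein_annotation(annotation))
  })
}

#' Generate block-structured co-expression module data
#'
#' Genes are split evenly over modules; topological overlap is drawn
#' Uniform(0.4, 0.9) within a module and Uniform(0.01, 0.2) between
#' modules, so within-module similarity dominates by construction. Module
#' membership and gene significance are continuous draws with distinct
#' ranks.
#'
#' @param n_genes Total genes (ids `CG001`, ...).
#' @param n_modules Number of modules (labels `module1`, ...); at most
#'   `n_genes`.
#' @param seed Integer seed.
#' @return A [module_data()] object.
#' @export
simulate_module_data <- function(n_genes = 40L, n_modules = 2L, seed = 1L) {
  stopifnot(n_genes >= n_modules, n_modules >= 1L)
  with_sim_seed(seed, {
    genes <- sprintf("CG%03d", seq_len(n_genes))
    module <- sprintf("module%d", rep_len(seq_len(n_modules), n_genes))
    tab <- tibble(gene = genes, module = sort(module),
                  mm = runif(n_genes, 0.05, 0.99),
                  gs = runif(n_genes, 0.05, 0.99))
    tom <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    same <- outer(tab$module, tab$module, "==")
    ut <- upper.tri(tom)
    vals <- ifelse(same[ut], runif(sum(ut), 0.4, 0.9), runif(sum(ut), 0.01, 0.2))
    tom[ut] <- vals
    tom <- tom + t(tom)
    diag(tom) <- 1
    module_data(tab, tom)
  })
}

#' Generate a 1:1 human-mouse homology map over generated feature ids
#'
#' Pairs `"<human_prefix>000k"` with `"<mouse_prefix>000k"` index-wise, the
#' naming convention of [simulate_dea_collection()]. One-to-many pairs can
#' be planted to exercise the 1:1 filter.
#'
#' @param n_pairs Number of index-wise pairs.
#' @param human_prefix,mouse_prefix Feature-id prefixes.
#' @param n_one_to_many Number of extra conflicting pairs appended (human
#'   gene `i` additionally mapped to mouse gene `i + 1`).
#' @return Tibble with `human_gene`, `mouse_gene`.
#' @export
simulate_homology_map <- function(n_pairs, human_prefix = "HG",
                                  mouse_prefix = "mg", n_one_to_many = 0L) {
  base <- tibble(human_gene = sprintf("%s%04d", human_prefix, seq_len(n_pairs)),
                 mouse_gene = sprintf("%s%04d", mouse_prefix, seq_len(n_pairs)))
  if (n_one_to_many > 0L) {
    i <- seq_len(min(n_one_to_many, n_pairs - 1L))
    base <- bind_rows(base, tibble(
      human_gene = sprintf("%s%04d", human_prefix, i),
      mouse_gene = sprintf("%s%04d", mouse_prefix, i + 1L)
    ))
  }
  base
}

#' Generate a random miRNA -> target map
#'
#' @param mirnas Character vector of miRNA ids.
#' @param genes Character vector of candidate target gene ids.
#' @param targets_per_mirna Targets drawn (without replacement) per miRNA.
#' @param seed Integer seed.
#' @return Tibble with `mirna`, `target`.
#' @export
simulate_target_map <- function(mirnas, genes, targets_per_mirna = 5L, seed = 1L) {
  with_sim_seed(seed, {
    list_rbind(map(mirnas, function(m) {
      tibble(mirna = m,
             target = sample(genes, min(targets_per_mirna, length(genes))))
    }))
  })
}
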