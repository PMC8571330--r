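test_that("shell caps, the score floor and tie-breaking are honoured on adversarial input", {
  # 25-interactor hub, dense score grid 701..725
  edges <- tibble::tibble(protein_a = "HUB",
                          protein_b = sprintf("Q%02d", 1:25),
                          score = 701:725)
  net <- build_two_shell_network("HUB", edges)
  s1 <- net$nodes$protein[net$nodes$shell == 1]
  expect_length(s1, 9)
  expect_setequal(s1, sprintf("Q%02d", 17:25))  # the nine highest scores

  # nothing above the floor: the network is the lone query node
  weak <- tibble::tibble(protein_a = "HUB", protein_b = sprintf("Q%02d", 1:5),
                         score = rep(700, 5))  # exactly 700 is not > 700
  lone <- build_two_shell_network("HUB", weak)
  expect_equal(lone$nodes$protein, "HUB")
  expect_equal(nrow(lone$edges), 0L)

  # all scores tied: lexicographic protein id breaks the cut deterministically
  tied <- tibble::tibble(protein_a = "HUB", protein_b = sprintf("T%02d", 1:12),
                         score = rep(900, 12))
  st <- build_two_shell_network("HUB", tied)
  expect_equal(sort(st$nodes$protein[st$nodes$shell == 1]), sprintf("T%02d", 1:9))

  expect_error(build_two_shell_network("NOPE", edges), "Unknown query")
})

test_that("two-shell construction equals the enumeration oracle on random 12-protein toys", {
  for (seed in 1:6) {
    it <- simulate_interactome(n_proteins = 12, edge_density = 0.5, seed = seed)
    edges <- tibble::as_tibble(it$interactions)
    query <- "P01"
    # exercise both default and small caps so the cut actually bites
    for (cfg in list(c(9, 2, 700), c(3, 1, 400))) {
      net <- build_two_shell_network(query, it$interactions,
                                     max_first_shell = cfg[1],
                                     per_node_second = cfg[2],
                                     min_score = cfg[3])
      want <- oracle_two_shell(edges, query, cfg[1], cfg[2], cfg[3])
      expect_equal(net$nodes$protein[net$nodes$shell == 1], want$shell1)
      expect_equal(sort(net$nodes$protein[net$nodes$shell == 2]), want$shell2)
      # shells partition the node set; every retained edge joins included nodes
      expect_equal(anyDuplicated(net$nodes$protein), 0L)
      expect_lte(sum(net$nodes$shell == 2), 2 * cfg[2] * sum(net$nodes$shell == 1))
      expect_true(all(net$edges$protein_a %in% net$nodes$protein))
    }
  }
})

test_that("the consensus label decision tree reproduces the four published cases", {
  thr <- de_thresholds()
  stat <- function(id, lfc, p, n) {
    tibble::tibble(dataset_id = id, log2fc = lfc, p_nominal = p,
                   p_adjusted = p, n_samples = n)
  }
  # DE in a single dataset: direction kept as is
  expect_equal(consensus_label(stat("A", 1, 0.01, 10), thr), "Upregulated")
  # two datasets, inconsistent: the biggest dataset's direction wins
  two <- rbind(stat("A", 1, 0.01, 10), stat("B", -1, 0.01, 20))
  expect_equal(consensus_label(two, thr), "Downregulated")
  # three datasets: most frequent direction
  three <- rbind(stat("A", 1, 0.01, 5), stat("B", 1, 0.01, 6), stat("C", -1, 0.01, 50))
  expect_equal(consensus_label(three, thr), "Upregulated")
  # unreviewed (TrEMBL-like) protein: Unknown regardless of statistics
  expect_equal(consensus_label(three, thr, reviewed = FALSE), "Unknown")

  # boundary branches: no DE call; two consistent; tie at >2 DE datasets
  expect_equal(consensus_label(stat("A", 0.1, 0.9, 10), thr), "NonDE")
  expect_equal(consensus_label(rbind(stat("A", 1, 0.01, 5), stat("B", 2, 0.02, 9)), thr),
               "Upregulated")
  four_tied <- rbind(stat("A", 1, 0.01, 5), stat("B", 1, 0.01, 6),
                     stat("C", -1, 0.01, 50), stat("D", -1, 0.01, 7))
  expect_equal(consensus_label(four_tied, thr), "Downregulated")
  expect_equal(consensus_label(tibble::tibble()[0, ], thr), "NonDE")
})

test_that("network annotation labels every node via its primary gene", {
  edges <- tibble::tibble(
    protein_a = c("P1", "P1", "P1", "P2"),
    protein_b = c("P2", "P3", "P4", "P5"),
    score = c(900, 850, 800, 950)
  )
  annotation <- tibble::tibble(
    protein_id = c("P1", "P2", "P2", "P3", "P5"),
    reviewed = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    gene = c("GA", "GB", "GBalt", "GC", "GE"),
    is_primary = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  # GB is DE only in DS1 (up); GBalt (the non-primary gene) is strongly down
  # everywhere and must be ignored; GA is non-DE in both datasets.
  tables <- list(
    make_table(c("GA", "GB", "GBalt", "GE"), c(0.1, 1.5, -3, 2),
               c(0.8, 0.01, 0.001, 0.004), meta = make_meta("DS1", n_samples = 8)),
    make_table(c("GA", "GB", "GBalt"), c(0.05, 0.2, -3),
               c(0.9, 0.6, 0.001), meta = make_meta("DS2", n_samples = 12))
  )
  net <- build_two_shell_network("P1", edges)
  expect_warning(net <- annotate_network(net, tables, annotation), "P4")
  labels <- setNames(net$nodes$label, net$nodes$protein)
  expect_equal(unname(labels["P1"]), "NonDE")
  expect_equal(unname(labels["P2"]), "Upregulated")  # primary gene GB, not GBalt
  expect_equal(unname(labels["P3"]), "Unknown")      # unreviewed
  expect_equal(unname(labels["P4"]), "Unknown")      # absent from annotation
  expect_equal(unname(labels["P5"]), "Upregulated")
  expect_true(all(net$nodes$label %in% c("Unknown", "NonDE", "Upregulated", "Downregulated")))
  # the per-node statistics used are retained, adjusted p included
  expect_true(all(c("protein", "dataset_id", "p_adjusted") %in% names(net$data_used)))

  # independent per-node oracle re-running the decision tree
  sizes <- c(DS1 = 8, DS2 = 12)
  for (p in c("P1", "P2", "P5")) {
    gene <- annotation$gene[annotation$protein_id == p & annotation$is_primary][1]
    rows <- do.call(rbind, lapply(tables, function(t) {
      i <- match(gene, t$feature_id)
      if (is.na(i)) return(NULL)
      tibble::tibble(dataset_id = dea_meta(t)$dataset_id, log2fc = t$log2fc[i],
                     p_nominal = t$p_nominal[i], p_adjusted = t$p_adjusted[i],
                     n_samples = sizes[[dea_meta(t)$dataset_id]])
    }))
    expect_equal(unname(labels[p]), consensus_label(rows))
  }
})

test_that("shell networks convert to igraph and export as plain text", {
  it <- simulate_interactome(n_proteins = 15, edge_density = 0.4, seed = 4)
  universe <- unique(it$annotation$protein_id)
  net <- build_two_shell_network("P02", it$interactions, min_score = 300,
                                 universe = universe)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  prefix <- file.path(withr::local_tempdir(), "net")
  write_shell_network(net, prefix)
  expect_true(file.exists(paste0(prefix, "_edges.tsv")))
  nodes_back <- readr::read_tsv(paste0(prefix, "_nodes.tsv"), show_col_types = FALSE)
  expect_equal(nodes_back$protein, net$nodes$protein)

  # identical input yields identical output (total tie-breaking)
  net2 <- build_two_shell_network("P02", it$interactions, min_score = 300,
                                  universe = universe)
  expect_identical(net$nodes, net2$nodes)
})

test_that("interaction tables reject self-loops, duplicates and out-of-range scores", {
  expect_error(interaction_table(tibble::tibble(protein_a = "A", protein_b = "A", score = 10)),
               "Self-loops")
  expect_error(interaction_table(tibble::tibble(protein_a = c("A", "B"),
                                                protein_b = c("B", "A"),
                                                score = c(10, 20))),
               "Duplicate")
  expect_error(interaction_table(tibble::tibble(protein_a = "A", protein_b = "B", score = 1500)),
               "within")
})
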