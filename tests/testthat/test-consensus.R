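test_that("consensus calls match the brute-force oracle for every call pattern, n = 1..5", {
  for (n in 1:5) {
    pats <- all_patterns(n)
    features <- sprintf("F%03d", seq_len(nrow(pats)))
    tables <- lapply(seq_len(n), function(d) {
      table_from_calls(features, pats[, d], meta = make_meta(id = sprintf("DS%d", d)))
    })
    k <- ceiling(n / 2)
    got <- consensus_features(tables)
    expect_equal(attr(got, "k"), as.integer(k))
    want <- vapply(seq_len(nrow(pats)), function(i) oracle_consensus(pats[i, ], k),
                   character(1))
    got_dir <- setNames(rep(NA_character_, length(features)), features)
    got_dir[got$feature_id] <- got$direction
    expect_equal(unname(got_dir), want, info = sprintf("n = %d", n))
  }
})

test_that("consensus support counts, evidence and fold changes follow the supporting datasets", {
  # up in 2 of 4 (log2fc 1 and 2), non-DE in the rest: consensus mean is 1.5
  tables <- list(
    make_table(c("G1", "G2"), c(1, 1), c(0.01, 0.01), meta = make_meta("A")),
    make_table(c("G1", "G2"), c(2, -1), c(0.01, 0.01), meta = make_meta("B")),
    make_table(c("G1", "G2"), c(0, 0), c(0.9, 0.9), meta = make_meta("C")),
    make_table(c("G1", "G2"), c(0, 0), c(0.9, 0.9), meta = make_meta("D"))
  )
  cons <- consensus_features(tables)
  expect_equal(cons$feature_id, "G1")  # G2 is vetoed by the down call
  expect_equal(cons$consensus_log2fc, 1.5)
  expect_equal(cons$n_support, 2L)
  expect_equal(cons$n_selected, 4L)
  ev <- cons$evidence[[1]]
  expect_equal(nrow(ev), 4L)
  expect_true(all(c("dataset_id", "log2fc", "p_nominal", "p_adjusted", "call") %in% names(ev)))
  # no evidence entry opposes the consensus direction
  expect_false(any(ev$call == "down"))

  # single dataset: ceil(1/2) = 1 suffices
  one <- consensus_features(tables[1])
  expect_setequal(one$feature_id, c("G1", "G2"))
  expect_equal(one$n_support, c(1L, 1L))
})

test_that("features absent from some tables neither support nor veto; k stays on n", {
  tables <- list(
    table_from_calls(c("G1", "G2"), c("up", "up"), make_meta("A")),
    table_from_calls(c("G1", "G2"), c("up", "absent"), make_meta("B")),
    table_from_calls(c("G1", "G2"), c("non_de", "absent"), make_meta("C")),
    table_from_calls(c("G1", "G2"), c("non_de", "absent"), make_meta("D"))
  )
  cons <- consensus_features(tables)  # k = 2 on n = 4
  expect_equal(cons$feature_id, "G1")
  expect_equal(cons$n_detected_in[cons$feature_id == "G1"], 4L)
})

test_that("consensus is monotone in k, permutation-invariant, and never double-called", {
  sim <- simulate_dea_collection(sim_config(n_datasets = 5, n_features = 400,
                                            frac_planted = 0.1, effect_mean = 0.8,
                                            effect_sd = 0.6, seed = 13))
  sets <- lapply(1:5, function(k) consensus_features(sim$tables, k = k))
  for (k in 1:4) {
    expect_true(all(sets[[k + 1]]$feature_id %in% sets[[k]]$feature_id))
  }
  # no feature both up and down at any k (the veto forbids it)
  for (s in sets) expect_equal(anyDuplicated(s$feature_id), 0L)

  shuffled <- consensus_features(sim$tables[c(3, 1, 5, 2, 4)])
  base <- consensus_features(sim$tables)
  expect_equal(dplyr::arrange(tidy(shuffled), feature_id),
               dplyr::arrange(tidy(base), feature_id))
})

test_that("tightening thresholds only adds consensus features through veto removal", {
  set.seed(99)
  n <- 4
  feats <- sprintf("F%03d", 1:300)
  tables <- lapply(1:n, function(d) {
    make_table(feats, rnorm(300, 0, 1.2), runif(300),
               meta = make_meta(sprintf("DS%d", d)))
  })
  loose_thr <- de_thresholds(min_abs_fc = 1.2, max_p = 0.05)
  loose <- consensus_features(tables, loose_thr)
  for (thr in list(de_thresholds(min_abs_fc = 1.6, max_p = 0.05),
                   de_thresholds(min_abs_fc = 1.2, max_p = 0.02))) {
    tight <- consensus_features(tables, thr)
    # per-feature support never grows under tighter thresholds
    joined <- dplyr::inner_join(tidy(tight), tidy(loose), by = "feature_id",
                                suffix = c("_tight", "_loose"))
    expect_true(all(joined$n_support_tight <= joined$n_support_loose))
    # a feature gained under tightening must have been vetoed before:
    # it carried an opposite-direction DE call at the looser thresholds
    gained <- setdiff(tight$feature_id, loose$feature_id)
    for (f in gained) {
      dir <- tight$direction[tight$feature_id == f]
      opp <- if (dir == "up") "down" else "up"
      loose_calls <- vapply(tables, function(t) {
        as.character(de_calls(t, loose_thr))[match(f, t$feature_id)]
      }, character(1))
      expect_true(opp %in% loose_calls)
    }
  }
})

test_that("cross-species consensus demands 1:1 homology and matched direction", {
  h <- list(
    table_from_calls(c("HG1", "HG2", "HG3"), c("up", "up", "up"), make_meta("H1")),
    table_from_calls(c("HG1", "HG2", "HG3"), c("up", "up", "non_de"), make_meta("H2")),
    table_from_calls(c("HG1", "HG2", "HG3"), c("non_de", "up", "up"), make_meta("H3"))
  )
  m <- list(
    table_from_calls(c("mg1", "mg2", "mg3"), c("up", "down", "up"),
                     make_meta("M1", species = "mouse", comparison = "BleomD14_vs_Ctrl")),
    table_from_calls(c("mg1", "mg2", "mg3"), c("up", "down", "non_de"),
                     make_meta("M2", species = "mouse", comparison = "BleomD14_vs_Ctrl"))
  )
  hom <- tibble::tibble(human_gene = c("HG1", "HG2", "HG3", "HG3"),
                        mouse_gene = c("mg1", "mg2", "mg3", "mg3x"))
  out <- cross_species_consensus(h, m, hom)
  # HG1/mg1: both consensus up -> reported. HG2/mg2: direction mismatch.
  # HG3: 1:2 homology -> excluded regardless of calls.
  expect_equal(out$human_gene, "HG1")
  expect_equal(out$direction, "up")
  expect_named(out, c("human_gene", "mouse_gene", "direction", "human_log2fc",
                      "mouse_log2fc", "human_support", "mouse_support"))

  # empty homology map warns and returns nothing
  expect_warning(none <- cross_species_consensus(h, m, hom[0, ]), "Empty homology")
  expect_equal(nrow(none), 0L)

  # non-coding datasets are rejected
  nc <- table_from_calls("MIR1", "up",
                         make_meta("N1", biotype_scope = "noncoding"))
  expect_error(cross_species_consensus(c(h, list(nc)), m, hom), "non-coding")

  # mixed species in the same-species entry point errors
  expect_error(consensus_features(c(h, m)), "Mixed-species")
})

test_that("miRNA-mRNA integration returns exactly the anticorrelated target pairs", {
  mirna <- tibble::tibble(feature_id = c("miR-1", "miR-2", "miR-3"),
                          direction = c("up", "down", "up"),
                          consensus_log2fc = c(1, -1, 2))
  mrna <- tibble::tibble(feature_id = sprintf("G%d", 1:6),
                         direction = c("down", "down", "up", "up", "down", "up"),
                         consensus_log2fc = c(-1, -2, 1, 2, -0.5, 0.7))
  targets <- tibble::tibble(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3", "miR-9"),
    target = c("G1", "G3", "G4", "G5", "G9", "G1")
  )
  out <- mirna_mrna_integration(mirna, mrna, targets)
  # brute-force double loop over the same inputs
  want <- list()
  for (i in seq_len(nrow(targets))) {
    m_i <- match(targets$mirna[i], mirna$feature_id)
    g_i <- match(targets$target[i], mrna$feature_id)
    if (!is.na(m_i) && !is.na(g_i) && mirna$direction[m_i] != mrna$direction[g_i]) {
      want[[length(want) + 1]] <- c(targets$mirna[i], targets$target[i])
    }
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(out), nrow(want))
  expect_setequal(paste(out$mirna, out$target), paste(want[, 1], want[, 2]))
  # the same-direction pair miR-1 -> G3 must not appear
  expect_false(any(out$mirna == "miR-1" & out$target == "G3"))

  expect_equal(nrow(mirna_mrna_integration(mirna[0, ], mrna, targets)), 0L)
  expect_error(mirna_mrna_integration(mirna, mrna,
                                      tibble::tibble(mirna = "x", target = "x")),
               "Self-edges")
})

test_that("random target maps match a brute-force pairing oracle", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:50)
  mirnas <- sprintf("miR-%d", 1:10)
  mi <- tibble::tibble(feature_id = mirnas,
                       direction = sample(c("up", "down"), 10, replace = TRUE))
  mr <- tibble::tibble(feature_id = sample(genes, 30),
                       direction = sample(c("up", "down"), 30, replace = TRUE))
  tm <- simulate_target_map(mirnas, genes, targets_per_mirna = 8, seed = 6)
  out <- mirna_mrna_integration(mi, mr, tm)
  brute <- 0L
  for (i in seq_len(nrow(tm))) {
    a <- mi$direction[match(tm$mirna[i], mi$feature_id)]
    b <- mr$direction[match(tm$target[i], mr$feature_id)]
    if (!is.na(a) && !is.na(b) && a != b) brute <- brute + 1L
  }
  expect_equal(nrow(out), brute)
})
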