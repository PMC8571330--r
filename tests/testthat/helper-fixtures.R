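# Shared fixture builders. All fixtures are constructed in code; p_adjusted
# defaults to the nominal p so gene-level calls (nominal) and table
# invariants stay easy to reason about in hand-counted tests.

make_meta <- function(id = "DS1", species = "human", technology = "microarray",
                      comparison = "IPF_vs_Ctrl", n_samples = 10,
                      biotype_scope = "coding") {
  dataset_meta(id, species, technology, comparison, n_samples,
               biotype_scope = biotype_scope)
}

make_table <- function(features, log2fc, p, padj = p, meta = make_meta()) {
  dea_table(tibble::tibble(feature_id = features, log2fc = log2fc,
                           p_nominal = p, p_adjusted = padj), meta)
}

# One table per call pattern: `calls` is a character vector over features
# using "up", "down", "non_de" (or "absent" to omit the feature).
table_from_calls <- function(features, calls, meta = make_meta()) {
  keep <- calls != "absent"
  stopifnot(any(keep))
  lfc <- c(up = 1, down = -1, non_de = 0)[calls[keep]]
  p <- c(up = 0.001, down = 0.001, non_de = 0.9)[calls[keep]]
  make_table(features[keep], unname(lfc), unname(p), meta = meta)
}

# Independent order-statistic quantile oracle (linear interpolation between
# order statistics): h = (n-1)q + 1, x_(floor(h)) + frac(h) * diff.
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent Benjamini-Hochberg step-up oracle: p * n / rank, cumulative
# minimum from the largest p downwards, clipped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Independent brute-force vote-counting oracle over per-dataset call
# patterns: counts the calls directly, never touching the implementation.
oracle_consensus <- function(pattern, k) {
  n_up <- sum(pattern == "up")
  n_down <- sum(pattern == "down")
  if (n_up >= k && n_down == 0L) return("up")
  if (n_down >= k && n_up == 0L) return("down")
  NA_character_
}

all_patterns <- function(n, states = c("up", "down", "non_de")) {
  as.matrix(expand.grid(rep(list(states), n), stringsAsFactors = FALSE))
}

# Independent enumeration oracle: ranks every candidate set from the raw
# edge tibble with plain base R, mirroring the published shell rules.
oracle_two_shell <- function(edges, query, max1 = 9, per2 = 2, floor1 = 700) {
  nb <- function(id) {
    hit <- edges$protein_a == id | edges$protein_b == id
    part <- ifelse(edges$protein_a[hit] == id, edges$protein_b[hit], edges$protein_a[hit])
    sc <- edges$score[hit]
    ord <- order(-sc, part)
    list(partner = part[ord], score = sc[ord])
  }
  q <- nb(query)
  keep <- q$score > floor1
  shell1 <- head(q$partner[keep], max1)
  shell2 <- character()
  for (p in shell1) {
    c2 <- nb(p)
    ok <- !(c2$partner %in% c(query, shell1))
    shell2 <- union(shell2, head(c2$partner[ok], per2))
  }
  list(shell1 = shell1, shell2 = sort(setdiff(shell2, c(query, shell1))))
}

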