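# Shared fixtures and independent oracles, built in code.

toy_records <- function(gene, sample_id, cds_change = "",
                        aa_change = "", histology = "ALL") {
  tibble::tibble(gene = gene, sample_id = sample_id,
                 cds_change = cds_change, aa_change = aa_change,
                 histology = histology, pubmed_id = "1")
}

write_toy_catalog <- function(rows, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  readr::write_tsv(rows, path)
  path
}

# Monte-Carlo oracle for the joint CDF of uniform order statistics.
# Independent of the recursion: uses the indicator characterization
# U_(j) <= r_j for all j  <=>  #(U_i <= r_j) >= j for all j,
# so no sorting and no shared code path with q_statistic().
mc_order_stat_cdf <- function(r, n_draws = 1e5) {
  r <- sort(r)
  n <- length(r)
  u <- matrix(runif(n_draws * n), nrow = n_draws)
  ok <- rep(TRUE, n_draws)
  for (j in seq_len(n)) {
    ok <- ok & rowSums(u <= r[j]) >= j
  }
  mean(ok)
}

# Brute-force confidence rule on an evidence row table.
brute_force_confident_pairs <- function(rows) {
  rows <- rows[rows$protein_a != rows$protein_b, ]
  a <- pmin(rows$protein_a, rows$protein_b)
  b <- pmax(rows$protein_a, rows$protein_b)
  key <- paste(a, b, sep = "|")
  keep <- vapply(unique(key), function(k) {
    sub <- rows[key == k, ]
    length(unique(sub$pubmed_id)) >= 2 ||
      length(unique(tolower(trimws(sub$method)))) >= 2
  }, TRUE)
  sort(unique(key)[keep])
}

# Brute-force joint-sample count for a gene pair.
brute_force_cooccurrence <- function(sample_sets, g1, g2) {
  samples_with <- function(g) {
    names(sample_sets)[vapply(sample_sets, function(s) g %in% s, TRUE)]
  }
  length(intersect(samples_with(g1), samples_with(g2)))
}

# Random evidence table over a fixed pair universe, with known per-pair
# publication/method counts.
random_evidence <- function(n_pairs = 50, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(sprintf("N%02d", 1:15), 2))
  pairs <- pairs[sample(nrow(pairs), n_pairs), , drop = FALSE]
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    n_pub <- sample(1:3, 1)
    n_meth <- sample(1:2, 1)
    tidyr::expand_grid(
      pubmed_id = as.character(sample.int(1e4, n_pub)),
      method = sample(c("two hybrid", "pull down", "coip"), n_meth)) |>
      dplyr::mutate(protein_a = pairs[i, 1], protein_b = pairs[i, 2],
                    .before = 1)
  })
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
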