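test_that("parse_catalog filters by histology and reports malformed rows", {
  rows <- toy_records(gene = c("FLT3", "NRAS", "TP53"),
                      sample_id = c("S1", "S2", "S3"),
                      cds_change = c("c.1A>T", "c.2C>G", "c.3G>A"),
                      histology = c("acute lymphoblastic leukaemia",
                                    "Lymphoblastic Leukaemia",
                                    "colon adenocarcinoma"))
  path <- write_toy_catalog(rows)

  filtered <- parse_catalog(path, disease_filter = "lymphoblastic")
  expect_equal(nrow(filtered), 2)
  expect_setequal(filtered$gene, c("FLT3", "NRAS"))

  all_rows <- parse_catalog(path)
  expect_equal(nrow(all_rows), 3)

  # malformed rows (no gene / no sample / no syntax) counted, not silent
  bad <- rows
  bad$cds_change[1] <- ""
  bad$sample_id[2] <- ""
  expect_message(out <- parse_catalog(write_toy_catalog(bad)),
                 "malformed")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_malformed"), 2)
})

test_that("parse_catalog fails loudly on missing columns and empty filters", {
  rows <- toy_records("FLT3", "S1", cds_change = "c.1A>T")
  path <- write_toy_catalog(dplyr::select(rows, -sample_id))
  expect_error(parse_catalog(path), "sample_id",
               class = "allnet_format_error")

  full <- write_toy_catalog(rows)
  expect_warning(empty <- parse_catalog(full, disease_filter = "myeloid"),
                 "no catalog records")
  expect_equal(nrow(empty), 0)
})

test_that("parse_catalog honors a custom column mapping", {
  rows <- toy_records("FLT3", "S1", cds_change = "c.1A>T")
  names(rows) <- c("Gene name", "ID_sample", "Mutation CDS", "Mutation AA",
                   "Histology", "Pubmed_PMID")
  path <- write_toy_catalog(rows)
  out <- parse_catalog(path, column_map = c(
    gene = "Gene name", sample_id = "ID_sample", cds_change = "Mutation CDS",
    aa_change = "Mutation AA", histology = "Histology",
    pubmed_id = "Pubmed_PMID"))
  expect_equal(out$gene, "FLT3")
  expect_error(parse_catalog(path, column_map = c(symbol = "Gene name")),
               "unknown column_map")
})

test_that("summarize_burden counts distinct syntaxes and samples", {
  rec <- toy_records("G", c("S1", "S2", "S1"),
                     cds_change = c("c.1A>T", "c.2C>G", "c.1A>T"))
  b <- summarize_burden(rec, total_samples = 10)
  expect_equal(b$n_distinct, 2)
  expect_equal(b$n_samples, 2)
  expect_equal(b$frequency, 0.2)

  single <- summarize_burden(toy_records("G", "S1", cds_change = "c.1A>T"),
                             total_samples = 1)
  expect_equal(single$n_distinct, 1)
  expect_equal(single$frequency, 1.0)

  expect_error(summarize_burden(rec, total_samples = 1),
               class = "allnet_consistency_error")
})

test_that("mutation identity prefers the coding change, protein as fallback", {
  rec <- toy_records("G", c("S1", "S2", "S3"),
                     cds_change = c("c.1A>T", "", ""),
                     aa_change = c("p.M1L", "p.A2S", "p.A2S"))
  b <- summarize_burden(rec, total_samples = 5)
  expect_equal(b$n_distinct, 2)  # c.1A>T and p.A2S
})

test_that("burden respects row duplication and pair-count identities", {
  set.seed(11)
  rec <- toy_records(gene = sample(LETTERS[1:5], 40, replace = TRUE),
                     sample_id = sample(sprintf("S%d", 1:12), 40,
                                        replace = TRUE),
                     cds_change = sprintf("c.%dA>T", sample(9, 40,
                                                            replace = TRUE)))
  b <- summarize_burden(rec, total_samples = 20)
  # sum of per-gene sample counts = number of distinct (gene, sample) pairs
  expect_equal(sum(b$n_samples),
               nrow(dplyr::distinct(rec, gene, sample_id)))
  # frequency invariant under duplication of identical rows
  b2 <- summarize_burden(dplyr::bind_rows(rec, rec), total_samples = 20)
  expect_equal(b$frequency, b2$frequency)
})

test_that("top_genes applies thresholds, deterministic order and truncation", {
  burdens <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E"),
    n_distinct = c(5, 2, 1, 3, 2),
    n_samples = c(9, 4, 8, 4, 1),
    frequency = c(0.9, 0.4, 0.8, 0.4, 0.1))
  out <- top_genes(burdens, min_distinct = 2, min_samples = 2, k = 3)
  expect_equal(out$gene, c("A", "B", "D"))  # tie B/D broken by symbol

  all_sorted <- top_genes(burdens, min_distinct = 0, min_samples = 0)
  expect_equal(nrow(all_sorted), 5)
  expect_equal(all_sorted$n_samples, sort(burdens$n_samples,
                                          decreasing = TRUE))

  # more-than-5%-of-samples rule at toy scale
  freqs <- tibble::tibble(gene = c("FLT3", "NRAS", "JAK2", "X"),
                          n_distinct = 2, n_samples = 2,
                          frequency = c(0.099, 0.0614, 0.0608, 0.04))
  kept <- top_genes(freqs, min_frequency = 0.05, key = "frequency")
  expect_equal(nrow(kept), 3)
  expect_equal(kept$gene[1], "FLT3")
})
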