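small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_genes = 30, n_seed_genes = 12, n_samples = 120, n_cell_lines = 24,
    planted_frequencies = c(G001 = 0.2, G002 = 0.15, G003 = 0.15,
                            G004 = 0.1, G005 = 0.1),
    planted_n_distinct = c(G001 = 12L),
    planted_hubs = data.frame(gene = "G001", degree = 5L),
    planted_seed_clique = c("G008", "G009"),
    planted_cooccurring_pairs = data.frame(gene_a = "G002", gene_b = "G003",
                                           n_joint = 8L),
    planted_exclusive_pairs = data.frame(gene_a = "G004", gene_b = "G005"),
    planted_candidates = data.frame(
      partner = c("P001", "P002"), n_seed_partners = c(3L, 2L),
      census_member = c(TRUE, FALSE), expression_fraction = c(16 / 24, 1)),
    n_background_seed_edges = 4, n_background_edges = 15,
    n_offtarget_records = 4)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

test_that("identical seeds give byte-identical datasets on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_config(seed = 9)), d1)
  write_dataset(generate_dataset(small_config(seed = 9)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_config(seed = 10)), d3)
  expect_false(identical(readLines(file.path(d1, "catalog.tsv")),
                         readLines(file.path(d3, "catalog.tsv"))))
})

test_that("planted per-gene sample counts are hit exactly", {
  cfg <- small_config(seed = 3)
  out <- generate_catalog(cfg)
  rec <- parse_catalog(out$catalog, disease_filter = "lymphoblastic")
  b <- summarize_burden(rec, total_samples = cfg$n_samples)
  expect_equal(b$n_samples[b$gene == "G001"], round(0.2 * 120))
  joined <- dplyr::inner_join(b, out$truth$burden, by = "gene")
  expect_equal(joined$n_samples.x, joined$n_samples.y)
  expect_equal(joined$frequency.x, joined$frequency.y)
})

test_that("zero corruption yields a fully consistent catalog", {
  cfg <- small_config(seed = 4, corruption_rate = 0)
  out <- generate_catalog(cfg)
  rec <- parse_catalog(out$catalog, disease_filter = "lymphoblastic")
  verdicts <- check_consistency(rec, out$cds)
  expect_true(all(verdicts$status == "consistent"))
  # with no corruption the distinct-mutation plan is also exact
  b <- summarize_burden(rec, total_samples = cfg$n_samples)
  joined <- dplyr::inner_join(b, out$truth$burden, by = "gene")
  expect_equal(joined$n_distinct, joined$n_distinct_planted)
})

test_that("corrupted records carry their planted failure status", {
  cfg <- small_config(seed = 5, corruption_rate = 0.25)
  out <- generate_catalog(cfg)
  truth <- out$truth$record_status
  expect_equal(sum(truth$status != "consistent"),
               round(0.25 * nrow(truth)))
  expect_setequal(unique(truth$status),
                  c("consistent", "ref_mismatch", "out_of_range",
                    "aa_mismatch", "unparsed"))
})

test_that("fully confident evidence passes the filter edge for edge", {
  cfg <- small_config(seed = 6, confident_edge_fraction = 1)
  out <- generate_network(cfg)
  net <- confidence_filter(aggregate_edges(out$evidence))
  expect_equal(nrow(net$edges), nrow(out$truth$edges))
})

test_that("the confident fraction of background edges is exact", {
  cfg <- small_config(seed = 7, confident_edge_fraction = 0.6)
  out <- generate_network(cfg)
  bg <- out$truth$edges[out$truth$edges$role == "background", ]
  expect_equal(sum(bg$confident), round(0.6 * nrow(bg)))
  planted <- out$truth$edges[out$truth$edges$role != "background", ]
  expect_true(all(planted$confident))
})

test_that("planted hubs and partner wiring are recovered from evidence", {
  cfg <- small_config(seed = 8)
  out <- generate_network(cfg)
  net <- confidence_filter(aggregate_edges(out$evidence))
  deg <- degree_table(induce_subnetwork(net, cfg$seed_genes))
  expect_equal(deg$gene[1], "G001")
  expect_equal(deg$degree[1], out$truth$seed_degrees$degree[1])

  sp <- shared_partners(net, cfg$seed_genes, min_partners = 2)
  expect_equal(sp$n_seed_partners[sp$partner == "P001"], 3L)
  expect_equal(sp$seed_neighbors[sp$partner == "P001"][[1]],
               out$truth$partner_map$P001)
})

test_that("candidate expression counts are planted exactly", {
  cfg <- small_config(seed = 9)
  out <- generate_expression(cfg)
  fr <- expression_fractions(out$expression)
  expect_equal(fr$expression_fraction[fr$gene == "P001"], 16 / 24)
  expect_equal(fr$expression_fraction[fr$gene == "P002"], 1)
  expect_equal(ncol(out$expression), cfg$n_cell_lines + 1)
})

test_that("infeasible plans are rejected before generation", {
  expect_error(small_config(planted_cooccurring_pairs = data.frame(
    gene_a = "G004", gene_b = "G005", n_joint = 50L)),
    class = "allnet_config_error")
  expect_error(small_config(corruption_rate = 1.5),
               class = "allnet_config_error")
  expect_error(small_config(planted_hubs = data.frame(gene = "G001",
                                                      degree = 40L)),
               class = "allnet_config_error")
  expect_error(small_config(planted_candidates = data.frame(
    partner = "G002", n_seed_partners = 2L, census_member = TRUE,
    expression_fraction = 0.7)),
    class = "allnet_config_error")
})

test_that("the census stand-in holds seeds plus census-flagged partners", {
  cfg <- small_config()
  cs <- census_set(cfg)
  expect_true(all(cfg$seed_genes %in% cs))
  expect_true("P001" %in% cs)
  expect_false("P002" %in% cs)
})
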