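toy_criteria <- function() {
  tibble::tibble(gene = c("A", "B", "C", "D"),
                 n_distinct = c(10, 7, 5, 2),
                 n_samples = c(30, 12, 20, 3),
                 degree = c(6, 5, 1, 0))
}

test_that("a gene ranked first everywhere gets final rank 1", {
  rk <- combine_rankings(toy_criteria())
  expect_equal(rk$gene[rk$final_rank == 1], "A")
  expect_equal(rk$q_score[1], min(rk$q_score))
  # rank ratios are ranks over the cohort size
  expect_equal(rk$ratio_n_distinct, rk$rank_n_distinct / nrow(rk))
})

test_that("genes with identical ratios get identical Q", {
  crit <- tibble::tibble(gene = c("A", "B"), c1 = c(5, 5), c2 = c(2, 2))
  rk <- combine_rankings(crit)
  expect_equal(rk$q_score[1], rk$q_score[2])
})

test_that("a single criterion degenerates to the rank ratio", {
  crit <- tibble::tibble(gene = c("A", "B", "C"), c1 = c(9, 5, 1))
  rk <- combine_rankings(crit)
  expect_equal(sort(rk$q_score), c(1 / 3, 2 / 3, 1))
})

test_that("ranking order is invariant under gene relabeling", {
  crit <- toy_criteria()
  relabeled <- crit
  relabeled$gene <- c("W", "X", "Y", "Z")  # same alphabetical order
  rk1 <- combine_rankings(crit)
  rk2 <- combine_rankings(relabeled)
  expect_equal(rk1$q_score, rk2$q_score)
  expect_equal(match(rk1$gene, crit$gene), match(rk2$gene, relabeled$gene))
})

test_that("genes missing a criterion take the worst rank and are flagged", {
  crit <- tibble::tibble(gene = c("A", "B", "C"),
                         c1 = c(9, 5, 1), c2 = c(4, NA, 2))
  rk <- combine_rankings(crit)
  b <- rk[rk$gene == "B", ]
  expect_equal(b$n_missing, 1L)
  expect_equal(b$rank_c2, 3)
  expect_equal(rk$n_missing[rk$gene == "A"], 0L)
})

test_that("list-of-vectors input matches the data-frame interface", {
  crit <- toy_criteria()
  as_list <- list(
    n_distinct = setNames(crit$n_distinct, crit$gene),
    n_samples = setNames(crit$n_samples, crit$gene),
    degree = setNames(crit$degree, crit$gene))
  expect_equal(tidy(combine_rankings(as_list)),
               tidy(combine_rankings(crit)))
})

test_that("glance and tidy summarize a ranking", {
  rk <- combine_rankings(toy_criteria())
  g <- glance(rk)
  expect_equal(g$n_genes, 4)
  expect_equal(g$n_criteria, 3)
  expect_equal(g$top_gene, "A")
  expect_false(inherits(tidy(rk), "allnet_ranking"))
})

partners_fixture <- tibble::tibble(
  partner = c("EXT1", "GOLGA2", "LOW"),
  n_seed_partners = c(3L, 1L, 2L),
  seed_neighbors = list(c("N1", "F7", "P5"), "N1", c("N1", "F7")))

test_that("candidates must meet all three criteria to pass", {
  census <- c("EXT1", "GOLGA2")
  expression <- tibble::tibble(gene = c("EXT1", "GOLGA2", "LOW"),
                               expression_fraction = c(16 / 24, 1.0, 1.0))
  out <- candidate_filter(partners_fixture, census, expression)
  expect_true(out$passes[out$partner == "EXT1"])
  expect_false(out$passes[out$partner == "GOLGA2"])  # one seed partner
  expect_false(out$passes[out$partner == "LOW"])     # not in census
  expect_equal(out$partner[1], "EXT1")               # passers sorted first
})

test_that("the 60% expression threshold is inclusive", {
  expression <- tibble::tibble(gene = c("EXT1", "LOW"),
                               expression_fraction = c(15 / 24, 14 / 24))
  out <- candidate_filter(
    dplyr::mutate(partners_fixture[c(1, 3), ], n_seed_partners = 2L),
    census = c("EXT1", "LOW"), expression)
  expect_true(out$passes[out$partner == "EXT1"])   # 0.625 >= 0.6
  expect_false(out$passes[out$partner == "LOW"])   # 0.583 < 0.6
})

test_that("partners missing from the expression table fail and are flagged", {
  expression <- tibble::tibble(gene = "EXT1", expression_fraction = 0.9)
  expect_message(
    out <- candidate_filter(partners_fixture, census = "LOW", expression),
    "absent from the expression table")
  low <- out[out$partner == "LOW", ]
  expect_true(low$missing_expression)
  expect_equal(low$expression_fraction, 0)
  expect_false(low$passes)
})

test_that("expression fractions come from binary line calls", {
  expr <- tibble::tibble(gene = c("A", "B"),
                         CL01 = c(1L, 0L), CL02 = c(1L, 0L),
                         CL03 = c(0L, 0L))
  f <- expression_fractions(expr)
  expect_equal(f$expression_fraction, c(2 / 3, 0))
  expect_error(candidate_filter(partners_fixture, "A",
                                c(A = 1.5)), class = "allnet_domain_error")
})

test_that("set_overlap reports counts and per-set fractions", {
  out <- set_overlap(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(out$n_common, 2)
  expect_equal(out$fraction_a, 0.5)
  expect_equal(out$fraction_b, 2 / 3)

  same <- set_overlap(letters[1:3], letters[1:3])
  expect_equal(unlist(same), c(n_common = 3, fraction_a = 1, fraction_b = 1))

  expect_equal(set_overlap(letters[1:3], letters[4:6])$n_common, 0)
  expect_warning(empty <- set_overlap(character(), letters[1:3]), "empty")
  expect_equal(empty$fraction_a, 0)
})

test_that("census coverage is a guarded percentage", {
  expect_equal(census_coverage(0, 572), 0)
  expect_equal(census_coverage(572, 572), 100)
  expect_equal(census_coverage(116, 572, digits = 2), 20.28)
  expect_error(census_coverage(1, 0), class = "allnet_domain_error")
  expect_error(census_coverage(10, 5))
})
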