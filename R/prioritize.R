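#' Rank values with average ties
#'
#' Rank 1 is the best value (the largest when `descending`). Tied values take
#' the average of the ranks they span, so the rank sum is always n(n+1)/2.
#'
#' @param values Named numeric vector (names are gene symbols).
#' @param descending Rank largest value first (default), as for mutation
#'   counts and degrees.
#' @return Named numeric vector of ranks.
#' @examples
#' rank_with_ties(c(a = 10, b = 8, c = 8, d = 4, e = 1))
#' @export
rank_with_ties <- function(values, descending = TRUE) {
  stopifnot(length(values) > 0)
  v <- if (descending) -as.numeric(values) else as.numeric(values)
  setNames(rank(v, ties.method = "average"), names(values))
}

#' Q statistic of uniform order statistics
#'
#' The probability that N independent uniform(0,1) order statistics fall at or
#' below the given rank ratios — the chance of observing ranks at least this
#' good under the null that each ranking is random. Computed by the recursion
#'
#' \deqn{Q = N! V_N, \quad V_0 = 1, \quad
#'   V_k = \sum_{i=1}^{k} (-1)^{i-1} \frac{V_{k-i}}{i!} r_{N-k+1}^i}
#'
#' over the ascending-sorted ratios \eqn{r_1 \le \dots \le r_N}. Input order
#' does not matter (sorting is internal). Smaller Q means the gene ranks
#' better across criteria than chance would allow.
#'
#' @param rank_ratios Numeric vector of rank ratios, each in (0, 1].
#' @return A probability in \[0, 1\] (clamped against floating-point drift).
#' @examples
#' q_statistic(0.3)              # N = 1: the ratio itself
#' q_statistic(c(0.5, 0.5))      # P(both uniforms <= 0.5) = 0.25
#' @export
q_statistic <- function(rank_ratios) {
  r <- as.numeric(rank_ratios)
  if (length(r) == 0) {
    abort("rank_ratios must be non-empty", class = "allnet_domain_error")
  }
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
    abort("rank ratios must lie in (0, 1]", class = "allnet_domain_error")
  }
  r <- sort(r)
  n <- length(r)
  v <- numeric(n + 1)
  v[1] <- 1
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[k + 1] <- sum((-1)^(i - 1) * v[k - i + 1] / factorial(i) *
                      r[n - k + 1]^i)
  }
  min(max(factorial(n) * v[n + 1], 0), 1)
}

#' Combine per-criterion rankings into Q scores
#'
#' Aggregates several gene rankings (e.g. number of distinct mutations,
#' number of mutated samples, network degree) by order statistics. Per
#' criterion, genes are ranked with average ties and ranks are divided by the
#' number of genes to give rank ratios; each gene's Q score is then the joint
#' order-statistic probability of its ratios ([q_statistic()]). Genes are
#' sorted by ascending Q (best first); ties are broken by mean rank ratio,
#' then symbol.
#'
#' A gene absent from one criterion receives the worst rank for it (rank = n)
#' so that all genes remain comparable; the `n_missing` column flags how many
#' criteria were imputed this way.
#'
#' @param criteria Data frame with a `gene` column and one numeric column per
#'   criterion, or a named list of named numeric vectors. `NA` means the gene
#'   is unranked under that criterion.
#' @param descending Logical, recycled over criteria: rank the largest value
#'   first (default `TRUE`).
#' @return A tibble of class `allnet_ranking` with columns `gene`,
#'   `rank_<criterion>`, `ratio_<criterion>`, `n_missing`, `q_score`,
#'   `final_rank`.
#' @export
combine_rankings <- function(criteria, descending = TRUE) {
  if (is.data.frame(criteria)) {
    stopifnot("gene" %in% names(criteria))
    genes <- as.character(criteria$gene)
    crit_names <- setdiff(names(criteria), "gene")
    tables <- lapply(crit_names, function(cn) {
      v <- setNames(criteria[[cn]], genes)
      v[!is.na(v)]
    })
    names(tables) <- crit_names
  } else {
    tables <- criteria
    crit_names <- names(tables)
    genes <- unique(unlist(lapply(tables, names)))
  }
  if (length(tables) < 1) abort("at least one criterion is required")
  descending <- rep_len(descending, length(tables))
  n <- length(genes)

  ranks <- matrix(NA_real_, n, length(tables),
                  dimnames = list(genes, crit_names))
  for (j in seq_along(tables)) {
    rk <- rank_with_ties(tables[[j]], descending = descending[j])
    ranks[names(rk), j] <- rk
  }
  n_missing <- rowSums(is.na(ranks))
  ranks[is.na(ranks)] <- n          # unranked genes get the worst rank
  ratios <- ranks / n
  q <- apply(ratios, 1, q_statistic)

  out <- tibble(gene = genes, n_missing = as.integer(n_missing),
                q_score = unname(q),
                mean_ratio = rowMeans(ratios))
  for (cn in crit_names) {
    out[[paste0("rank_", cn)]] <- unname(ranks[, cn])
    out[[paste0("ratio_", cn)]] <- unname(ratios[, cn])
  }
  out <- out %>%
    arrange(.data$q_score, .data$mean_ratio, .data$gene) %>%
    mutate(final_rank = row_number()) %>%
    select("gene", dplyr::starts_with("rank_"), dplyr::starts_with("ratio_"),
           "n_missing", "mean_ratio", "q_score", "final_rank")
  class(out) <- c("allnet_ranking", class(out))
  out
}

#' @describeIn tidy-allnet The ranking table itself, as a plain tibble.
#' @export
tidy.allnet_ranking <- function(x, ...) {
  class(x) <- setdiff(class(x), "allnet_ranking")
  x
}

#' @describeIn tidy-allnet One-row summary of a ranking: gene count, number
#'   of criteria, best gene and its Q score.
#' @export
glance.allnet_ranking <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_criteria = sum(startsWith(names(x), "rank_")),
         top_gene = x$gene[x$final_rank == 1][1],
         top_q = min(x$q_score))
}

#' Guilt-by-association candidate filter
#'
#' Scores shared partners of the disease gene set against the three candidate
#' criteria: interacting with at least `min_partners` disease gene products,
#' membership in the cancer gene census, and expression in at least
#' `min_expression` of the ALL cell line panel. A candidate passes only when
#' all three hold.
#'
#' @param partners Output of [shared_partners()].
#' @param census Character vector of cancer gene census symbols.
#' @param expression Tibble with columns `gene` and `expression_fraction`
#'   (fractions in \[0, 1\]), or a named numeric vector. Partners absent from
#'   the table are treated as unexpressed (fraction 0) and flagged.
#' @param min_partners Minimum disease-gene partners (default 2).
#' @param min_expression Minimum expression fraction, inclusive (default 0.6;
#'   with a 24-line panel this is 15+ lines).
#' @return Tibble `partner`, `n_seed_partners`, `census_member`,
#'   `expression_fraction`, `missing_expression`, `passes`; passing
#'   candidates first, sorted by descending `n_seed_partners`.
#' @export
candidate_filter <- function(partners, census, expression,
                             min_partners = 2, min_expression = 0.6) {
  if (!is.data.frame(expression)) {
    expression <- tibble(gene = names(expression),
                         expression_fraction = as.numeric(expression))
  }
  if (any(expression$expression_fraction < 0 |
            expression$expression_fraction > 1)) {
    abort("expression fractions must lie in [0, 1]",
          class = "allnet_domain_error")
  }
  scored <- partners %>%
    select("partner", "n_seed_partners") %>%
    left_join(select(expression, "gene", "expression_fraction"),
              by = c(partner = "gene")) %>%
    mutate(missing_expression = is.na(.data$expression_fraction),
           expression_fraction = coalesce(.data$expression_fraction, 0),
           census_member = .data$partner %in% census,
           passes = .data$n_seed_partners >= min_partners &
             .data$census_member &
             .data$expression_fraction >= min_expression) %>%
    arrange(desc(.data$passes), desc(.data$n_seed_partners), .data$partner)
  if (any(scored$missing_expression)) {
    inform(paste0(sum(scored$missing_expression),
                  " partner(s) absent from the expression table; ",
                  "treated as unexpressed"))
  }
  scored
}

#' Per-gene expression fractions from a binary expression table
#'
#' @param expression Tibble with a `gene` column and one 0/1 column per cell
#'   line.
#' @return Tibble `gene`, `expression_fraction`.
#' @export
expression_fractions <- function(expression) {
  lines <- setdiff(names(expression), "gene")
  tibble(gene = expression$gene,
         expression_fraction =
           rowMeans(as.matrix(expression[, lines, drop = FALSE])))
}

#' Overlap between two gene sets
#'
#' Venn-style overlap: the common count plus the fraction of each set it
#' represents (e.g. targets co-regulated by two regulators as a share of each
#' regulator's target set).
#'
#' @param set_a,set_b Character vectors.
#' @return One-row tibble `n_common`, `fraction_a`, `fraction_b`.
#' @export
set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) {
    warn("overlap with an empty set; fraction reported as 0")
  }
  n_common <- length(intersect(set_a, set_b))
  tibble(n_common = n_common,
         fraction_a = if (length(set_a) == 0) 0 else n_common / length(set_a),
         fraction_b = if (length(set_b) == 0) 0 else n_common / length(set_b))
}

#' Census coverage percentage
#'
#' The percentage of the cancer gene census mutated in the disease gene set.
#'
#' @param n_in_disease_set Number of census genes found mutated.
#' @param n_census Census size (572 in the COSMIC census snapshot used here).
#' @param digits Rounding precision of the reported percentage (default 0).
#' @return Percentage on the 0–100 scale.
#' @examples
#' census_coverage(116, 572)  # 20
#' @export
census_coverage <- function(n_in_disease_set, n_census, digits = 0) {
  if (n_census <= 0) {
    abort("n_census must be positive", class = "allnet_domain_error")
  }
  stopifnot(n_in_disease_set >= 0, n_in_disease_set <= n_census)
  round(100 * n_in_disease_set / n_census, digits = digits)
}
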