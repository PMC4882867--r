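#' Configuration for the synthetic ALL benchmark generator
#'
#' Describes a synthetic cohort with planted, exactly recoverable structure:
#' per-gene mutation frequencies and distinct-mutation counts, a network hub,
#' a seed-gene clique, co-occurring and mutually exclusive mutation pairs,
#' guilt-by-association candidate partners (and near-misses that each fail
#' exactly one filter criterion), and a known fraction of mutation records
#' with deliberately inconsistent syntax. The same configuration drives
#' [generate_catalog()], [generate_network()] and [generate_expression()];
#' identical seeds give byte-identical outputs.
#'
#' The defaults emulate the shape of the real study at desk scale: 40 disease
#' ("seed") genes among 120 proteins, 400 catalogued samples, a 24-cell-line
#' expression panel, the seven top mutation frequencies set to the published
#' top-seven values (9.9 % down to 5.32 %), one gene planted best in all
#' three ranking criteria, and one interacting gene pair mutated without any
#' co-occurrence (the NOTCH1/FLT3 exclusivity pattern).
#'
#' @param seed Integer RNG seed; the generator functions derive their own
#'   streams from it.
#' @param n_genes Total proteins in the universe (seed genes plus partners).
#' @param n_seed_genes Number of disease genes (named `G001`, `G002`, ...).
#' @param n_samples Number of catalogued tumor samples.
#' @param n_cell_lines Size of the expression panel.
#' @param planted_frequencies Named numeric: per-gene target fraction of
#'   samples mutated. Seed genes not listed get a fraction drawn uniformly
#'   from `background_frequency_range`.
#' @param planted_n_distinct Named integer: per-gene distinct mutation count
#'   (capped at the gene's sample count). Unlisted genes draw from 2–12.
#' @param planted_hubs Data frame `gene`, `degree`: seed genes wired to that
#'   many other seed genes.
#' @param planted_seed_clique Seed genes to interconnect completely.
#' @param planted_cooccurring_pairs Data frame `gene_a`, `gene_b`, `n_joint`:
#'   interacting seed-gene pairs mutated together in exactly `n_joint`
#'   samples.
#' @param planted_exclusive_pairs Data frame `gene_a`, `gene_b`: interacting
#'   seed-gene pairs that are each mutated but never co-mutated.
#' @param planted_candidates Data frame `partner`, `n_seed_partners`,
#'   `census_member`, `expression_fraction` describing partner proteins and
#'   which candidate criteria each meets.
#' @param n_background_seed_edges,n_background_edges Random confident-or-not
#'   edges among seed genes / among unplanted pairs.
#' @param confident_edge_fraction Fraction of background edges given enough
#'   evidence to pass the confidence filter (planted edges always pass).
#' @param corruption_rate Fraction of catalog records whose mutation syntax is
#'   deliberately corrupted, cycling over the failure classes `ref_mismatch`,
#'   `out_of_range`, `aa_mismatch`, `unparsed`.
#' @param background_frequency_range,cds_length_range,background_expression_rate,n_offtarget_records
#'   Background knobs: frequency range for unplanted seed genes; CDS length
#'   range (rounded to multiples of 3); Bernoulli rate for unplanted
#'   expression calls; number of non-ALL histology rows appended to exercise
#'   disease filtering.
#' @return A `synthetic_config` list, validated for feasibility.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_genes = 120,
    n_seed_genes = 40,
    n_samples = 400,
    n_cell_lines = 24,
    planted_frequencies = c(G001 = 0.099, G002 = 0.0614, G003 = 0.0608,
                            G004 = 0.0587, G005 = 0.0567, G006 = 0.0552,
                            G007 = 0.0532),
    planted_n_distinct = c(G001 = 30L),
    planted_hubs = data.frame(gene = "G001", degree = 8L),
    planted_seed_clique = c("G010", "G011", "G012"),
    planted_cooccurring_pairs = data.frame(gene_a = c("G002", "G004"),
                                           gene_b = c("G003", "G005"),
                                           n_joint = c(12L, 8L)),
    planted_exclusive_pairs = data.frame(gene_a = "G006", gene_b = "G007"),
    planted_candidates = data.frame(
      partner = c("P001", "P002", "P003", "P004", "P005", "P006"),
      n_seed_partners = c(4L, 3L, 2L, 2L, 2L, 1L),
      census_member = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
      expression_fraction = c(16, 18, 15, 16, 13, 16) / 24),
    n_background_seed_edges = 15,
    n_background_edges = 50,
    confident_edge_fraction = 0.8,
    corruption_rate = 0.2,
    background_frequency_range = c(0.005, 0.04),
    cds_length_range = c(99, 300),
    background_expression_rate = 0.5,
    n_offtarget_records = 12) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_seed_genes = n_seed_genes, n_samples = n_samples,
              n_cell_lines = n_cell_lines,
              planted_frequencies = planted_frequencies,
              planted_n_distinct = planted_n_distinct,
              planted_hubs = as_tibble(planted_hubs),
              planted_seed_clique = planted_seed_clique,
              planted_cooccurring_pairs = as_tibble(planted_cooccurring_pairs),
              planted_exclusive_pairs = as_tibble(planted_exclusive_pairs),
              planted_candidates = as_tibble(planted_candidates),
              n_background_seed_edges = n_background_seed_edges,
              n_background_edges = n_background_edges,
              confident_edge_fraction = confident_edge_fraction,
              corruption_rate = corruption_rate,
              background_frequency_range = background_frequency_range,
              cds_length_range = cds_length_range,
              background_expression_rate = background_expression_rate,
              n_offtarget_records = n_offtarget_records)
  cfg$seed_genes <- sprintf("G%03d", seq_len(n_seed_genes))
  cfg$partner_genes <- sprintf("P%03d", seq_len(n_genes - n_seed_genes))
  cfg$samples <- sprintf("S%04d", seq_len(n_samples))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "allnet_config_error")
  if (cfg$n_seed_genes >= cfg$n_genes) {
    fail("n_seed_genes must be smaller than n_genes")
  }
  fr <- c(cfg$planted_frequencies, cfg$confident_edge_fraction,
          cfg$corruption_rate, cfg$background_expression_rate,
          cfg$planted_candidates$expression_fraction)
  if (any(fr < 0 | fr > 1)) fail("all fractions must lie in [0, 1]")
  unknown <- setdiff(names(cfg$planted_frequencies), cfg$seed_genes)
  if (length(unknown) > 0) {
    fail(paste0("planted_frequencies name unknown seed gene(s): ",
                paste(unknown, collapse = ", ")))
  }
  if (any(cfg$planted_hubs$degree >= cfg$n_genes)) {
    fail("planted hub degrees must be smaller than n_genes")
  }
  if (any(cfg$planted_hubs$degree >= cfg$n_seed_genes)) {
    fail("planted hub degrees must be smaller than n_seed_genes")
  }
  pair_genes <- c(cfg$planted_cooccurring_pairs$gene_a,
                  cfg$planted_cooccurring_pairs$gene_b,
                  cfg$planted_exclusive_pairs$gene_a,
                  cfg$planted_exclusive_pairs$gene_b)
  if (!all(pair_genes %in% cfg$seed_genes)) {
    fail("co-occurrence/exclusivity pairs must be between seed genes")
  }
  if (!all(cfg$planted_candidates$partner %in% cfg$partner_genes)) {
    fail("planted candidate partners must come from the non-seed gene pool")
  }
  if (any(cfg$planted_candidates$n_seed_partners > cfg$n_seed_genes)) {
    fail("candidate seed-partner counts exceed the number of seed genes")
  }
  # joint counts must fit inside both marginals
  tgt <- target_sample_counts(cfg)
  co <- cfg$planted_cooccurring_pairs
  if (nrow(co) > 0) {
    bad <- co$n_joint > pmin(tgt[co$gene_a], tgt[co$gene_b])
    if (any(bad)) fail("planted joint sample counts exceed a marginal count")
  }
  invisible(cfg)
}

# planted fractions -> exact per-gene sample counts; unplanted seed genes get
# a deterministic mid-range fraction placeholder resolved at generation time
target_sample_counts <- function(cfg) {
  freq <- rep(mean(cfg$background_frequency_range), cfg$n_seed_genes)
  names(freq) <- cfg$seed_genes
  freq[names(cfg$planted_frequencies)] <- cfg$planted_frequencies
  round(freq * cfg$n_samples)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

constraint_partners <- function(pairs) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    out[[a]] <- c(out[[a]], b)
    out[[b]] <- c(out[[b]], a)
  }
  out
}

# The joint-sample plan covering every confident seed-seed edge: planted
# co-occurring pairs keep their configured counts, planted exclusive pairs
# get zero, and every other confident seed-seed edge gets exactly one shared
# sample — so the overlay's exclusive flags and heaviest edges recover the
# planted structure exactly, with no incidental ties.
joint_plan <- function(cfg, seed_edges) {
  co <- mutate(select(cfg$planted_cooccurring_pairs,
                      "gene_a", "gene_b", "n_joint"),
               canonical = paste(pmin(.data$gene_a, .data$gene_b),
                                 pmax(.data$gene_a, .data$gene_b)))
  ex <- mutate(select(cfg$planted_exclusive_pairs, "gene_a", "gene_b"),
               canonical = paste(pmin(.data$gene_a, .data$gene_b),
                                 pmax(.data$gene_a, .data$gene_b)),
               n_joint = 0L)
  other <- seed_edges %>%
    mutate(canonical = paste(.data$protein_a, .data$protein_b)) %>%
    filter(!.data$canonical %in% c(co$canonical, ex$canonical)) %>%
    mutate(gene_a = .data$protein_a, gene_b = .data$protein_b,
           n_joint = 1L) %>%
    select("gene_a", "gene_b", "n_joint", "canonical")
  bind_rows(co, ex, other)
}

# Assign mutated-sample sets honoring exact marginal counts and the exact
# joint counts of `joints` (0 for exclusive pairs). Joint samples are placed
# first; each constrained gene is then filled sequentially avoiding every
# sample already held by any constraint partner, which keeps all pairwise
# intersections exactly as planted.
plan_sample_sets <- function(cfg, target, joints) {
  sets <- lapply(setNames(seq_along(target), names(target)),
                 function(i) character())
  partners <- constraint_partners(joints)
  co <- filter(joints, .data$n_joint > 0)
  for (i in seq_len(nrow(co))) {
    a <- co$gene_a[i]; b <- co$gene_b[i]; j <- co$n_joint[i]
    forbidden <- unique(unlist(sets[unique(c(partners[[a]], partners[[b]]))]))
    pool <- setdiff(cfg$samples, c(sets[[a]], sets[[b]], forbidden))
    if (length(pool) < j) {
      abort("infeasible plan: not enough samples for planted joint mutations",
            class = "allnet_config_error")
    }
    joint <- sample(pool, j)
    sets[[a]] <- c(sets[[a]], joint)
    sets[[b]] <- c(sets[[b]], joint)
  }
  fill_order <- c(intersect(names(target), names(partners)),
                  setdiff(names(target), names(partners)))
  for (g in fill_order) {
    need <- target[[g]] - length(sets[[g]])
    if (need < 0) {
      abort("infeasible plan: joint samples exceed a gene's marginal count",
            class = "allnet_config_error")
    }
    forbidden <- unique(unlist(sets[partners[[g]]]))
    pool <- setdiff(cfg$samples, c(sets[[g]], forbidden))
    if (length(pool) < need) {
      abort("infeasible plan: sample pool exhausted under exclusivity",
            class = "allnet_config_error")
    }
    sets[[g]] <- sort(c(sets[[g]], sample(pool, need)))
  }
  sets
}

random_cds <- function(len_range) {
  len <- sample(seq(len_range[1], len_range[2]), 1)
  len <- max(3, (len %/% 3) * 3)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

other_bases <- function(base) setdiff(c("A", "C", "G", "T"), base)

predicted_protein_change <- function(cds, pos, alt) {
  codon_idx <- ceiling(pos / 3)
  start <- (codon_idx - 1) * 3 + 1
  ref_codon <- substr(cds, start, start + 2)
  alt_codon <- ref_codon
  substr(alt_codon, pos - start + 1, pos - start + 1) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa) paste0("p.", ref_aa, codon_idx, "=")
  else paste0("p.", ref_aa, codon_idx, alt_aa)
}

corruption_classes <- c("ref_mismatch", "out_of_range", "aa_mismatch",
                        "unparsed")

corrupt_record <- function(row, cds, class) {
  parsed <- parse_cds_change(row$cds_change)
  pos <- parsed$pos; ref <- parsed$ref; alt <- parsed$alt
  if (class == "ref_mismatch") {
    wrong <- setdiff(other_bases(ref), alt)[1]
    row$cds_change <- paste0("c.", pos, wrong, ">", alt)
  } else if (class == "out_of_range") {
    row$cds_change <- paste0("c.", nchar(cds) + 3, ref, ">", alt)
  } else if (class == "aa_mismatch") {
    pred <- predicted_protein_change(cds, pos, alt)
    ref_aa <- substr(pred, 3, 3)
    codon_idx <- ceiling(pos / 3)
    wrong_aa <- if (ref_aa == "W") "G" else "W"
    row$aa_change <- paste0("p.", ref_aa, codon_idx, wrong_aa)
  } else {                                  # unparsed: an indel-style string
    row$cds_change <- paste0("c.", pos, "_", pos + 1, "delinsAT")
  }
  row
}

#' Generate a synthetic somatic mutation catalog
#'
#' Emits a COSMIC-style catalog whose per-gene mutated-sample counts, joint
#' co-occurrence counts and exclusivity patterns match the configuration
#' exactly (samples are assigned without replacement), together with the
#' coding sequences the mutation syntaxes were derived from and a ground-truth
#' record of everything planted. A configured fraction of records is
#' corrupted with a known verification-failure class.
#'
#' @param config A [synthetic_config()].
#' @return A list: `catalog` (record tibble; disease records first, then any
#'   off-target histology rows), `cds` (named `DNAStringSet`), and `truth`
#'   (planted burden table, per-record status table, per-gene sample sets).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  net_plan <- plan_network_edges(config)
  conf_seed_edges <- filter(net_plan$edges, .data$confident,
                            .data$protein_a %in% config$seed_genes,
                            .data$protein_b %in% config$seed_genes)
  with_local_seed(config$seed, {
    target <- target_sample_counts(config)
    # resolve unplanted seed-gene frequencies randomly within the range
    unplanted <- setdiff(config$seed_genes, names(config$planted_frequencies))
    target[unplanted] <- round(runif(
      length(unplanted), config$background_frequency_range[1],
      config$background_frequency_range[2]) * config$n_samples)
    target <- pmax(target, 2)               # every seed gene is observable
    joints <- joint_plan(config, conf_seed_edges)
    # a gene's marginal count must hold all of its planted joint samples;
    # background genes are bumped, explicitly planted frequencies must fit
    joint_load <- tapply(c(joints$n_joint, joints$n_joint),
                         c(joints$gene_a, joints$gene_b), sum)
    for (g in names(joint_load)) {
      if (target[[g]] < joint_load[[g]]) {
        if (g %in% names(config$planted_frequencies)) {
          abort(paste0("infeasible plan: planted frequency of ", g,
                       " cannot hold its planted joint samples"),
                class = "allnet_config_error")
        }
        target[[g]] <- joint_load[[g]]
      }
    }
    sets <- plan_sample_sets(config, target, joints)

    cds <- vapply(config$seed_genes,
                  function(g) random_cds(config$cds_length_range), "")
    n_distinct_target <- vapply(config$seed_genes, function(g) {
      d <- if (g %in% names(config$planted_n_distinct)) {
        config$planted_n_distinct[[g]]
      } else {
        sample(2:12, 1)
      }
      as.integer(min(d, target[[g]], nchar(cds[[g]])))
    }, 1L)

    rows <- purrr::map(config$seed_genes, function(g) {
      s <- sets[[g]]
      d <- n_distinct_target[[g]]
      positions <- sample(nchar(cds[[g]]), d)
      refs <- vapply(positions, function(p) substr(cds[[g]], p, p), "")
      alts <- vapply(refs, function(r) sample(other_bases(r), 1), "")
      idx <- sample(c(seq_len(d),
                      sample.int(d, length(s) - d, replace = TRUE)))
      tibble(gene = g, sample_id = s,
             cds_change = paste0("c.", positions[idx], refs[idx], ">",
                                 alts[idx]),
             aa_change = vapply(idx, function(i) {
               predicted_protein_change(cds[[g]], positions[i], alts[i])
             }, ""),
             histology = "acute lymphoblastic leukaemia",
             pubmed_id = as.character(sample.int(10^6, length(s),
                                                 replace = TRUE)))
    })
    catalog <- bind_rows(rows)

    status <- rep("consistent", nrow(catalog))
    n_corrupt <- round(config$corruption_rate * nrow(catalog))
    if (n_corrupt > 0) {
      corrupt_idx <- sample(nrow(catalog), n_corrupt)
      classes <- rep_len(corruption_classes, n_corrupt)
      for (k in seq_len(n_corrupt)) {
        i <- corrupt_idx[k]
        catalog[i, ] <- corrupt_record(catalog[i, ],
                                       cds[[catalog$gene[i]]], classes[k])
        status[i] <- classes[k]
      }
    }
    record_status <- tibble(gene = catalog$gene,
                            sample_id = catalog$sample_id,
                            cds_change = catalog$cds_change,
                            status = status)

    if (config$n_offtarget_records > 0) {
      off <- tibble(
        gene = sample(config$partner_genes, config$n_offtarget_records,
                      replace = TRUE),
        sample_id = sprintf("X%03d", seq_len(config$n_offtarget_records)),
        cds_change = "c.1A>T", aa_change = "",
        histology = "adenocarcinoma",
        pubmed_id = as.character(sample.int(10^6,
                                            config$n_offtarget_records,
                                            replace = TRUE)))
      catalog <- bind_rows(catalog, off)
    }

    truth <- list(
      burden = tibble(gene = config$seed_genes,
                      n_samples = as.integer(target[config$seed_genes]),
                      n_distinct_planted =
                        as.integer(n_distinct_target[config$seed_genes]),
                      frequency = as.numeric(target[config$seed_genes]) /
                        config$n_samples),
      record_status = record_status,
      sample_sets = sets,
      total_samples = config$n_samples)
    list(catalog = catalog,
         cds = Biostrings::DNAStringSet(cds),
         truth = truth)
  })
}

# Deterministic edge plan shared by generate_network() (which emits the
# evidence rows for it) and generate_catalog() (which needs the confident
# seed-seed edge list to plan joint mutated samples). Draws only from the
# seed+1 stream, so both callers see the identical plan.
plan_network_edges <- function(config) {
  with_local_seed(config$seed + 1L, {
    add <- function(acc, a, b, role) {
      bind_rows(acc, mutate(canonical_pair(a, b), role = role))
    }
    edges <- tibble(protein_a = character(), protein_b = character(),
                    role = character())
    partner_map <- list()

    for (i in seq_len(nrow(config$planted_hubs))) {
      hub <- config$planted_hubs$gene[i]
      nb <- sample(setdiff(config$seed_genes, hub),
                   config$planted_hubs$degree[i])
      edges <- add(edges, rep(hub, length(nb)), nb, "hub")
    }
    cl <- config$planted_seed_clique
    if (length(cl) >= 2) {
      cmb <- utils::combn(sort(cl), 2)
      edges <- add(edges, cmb[1, ], cmb[2, ], "clique")
    }
    co <- config$planted_cooccurring_pairs
    edges <- add(edges, co$gene_a, co$gene_b, "cooccurring")
    ex <- config$planted_exclusive_pairs
    edges <- add(edges, ex$gene_a, ex$gene_b, "exclusive")
    for (i in seq_len(nrow(config$planted_candidates))) {
      p <- config$planted_candidates$partner[i]
      nb <- sample(config$seed_genes,
                   config$planted_candidates$n_seed_partners[i])
      partner_map[[p]] <- sort(nb)
      edges <- add(edges, rep(p, length(nb)), nb, "candidate")
    }
    edges <- distinct(edges, .data$protein_a, .data$protein_b,
                      .keep_all = TRUE)

    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    used <- pair_key(edges$protein_a, edges$protein_b)

    seed_pairs <- utils::combn(config$seed_genes, 2)
    free_seed <- which(!pair_key(seed_pairs[1, ], seed_pairs[2, ]) %in% used)
    pick <- sample(free_seed, min(config$n_background_seed_edges,
                                  length(free_seed)))
    bg_seed <- tibble(protein_a = seed_pairs[1, pick],
                      protein_b = seed_pairs[2, pick],
                      role = "background")
    used <- c(used, pair_key(bg_seed$protein_a, bg_seed$protein_b))

    # background edges never touch planted candidate partners, so that their
    # seed-partner counts stay exactly as planted
    free_nodes <- setdiff(c(config$seed_genes, config$partner_genes),
                          config$planted_candidates$partner)
    all_pairs <- utils::combn(sort(free_nodes), 2)
    keys <- pair_key(all_pairs[1, ], all_pairs[2, ])
    eligible <- which(!keys %in% used &
                        !(all_pairs[1, ] %in% config$seed_genes &
                            all_pairs[2, ] %in% config$seed_genes))
    pick <- sample(eligible, min(config$n_background_edges, length(eligible)))
    bg <- tibble(protein_a = all_pairs[1, pick],
                 protein_b = all_pairs[2, pick],
                 role = "background")
    edges <- bind_rows(edges, bg_seed, bg)

    n_bg <- sum(edges$role == "background")
    conf_bg <- rep(FALSE, n_bg)
    conf_bg[sample(n_bg, round(config$confident_edge_fraction * n_bg))] <- TRUE
    edges$confident <- TRUE
    edges$confident[edges$role == "background"] <- conf_bg
    list(edges = edges, partner_map = partner_map)
  })
}

#' Generate a synthetic evidence-annotated PPI edge list
#'
#' Plants a seed-gene hub of known degree, a seed clique, confident edges for
#' every co-occurring and exclusive pair, candidate partners wired to a known
#' number of seed genes, and uniform background edges over unplanted pairs.
#' Evidence lists are sized so that every planted edge, and exactly the
#' configured fraction of background edges, pass the two-publications-or-two-
#' methods confidence rule. Aborts if the realized network would not leave the
#' planted hub as the strict degree maximum of the seed-gene subnetwork.
#'
#' @param config A [synthetic_config()].
#' @return A list: `evidence` (tibble `protein_a`, `protein_b`, `pubmed_id`,
#'   `method`, one row per evidence item), and `truth` (planted edge roles,
#'   confident flags, expected seed-subnetwork degrees, candidate partner
#'   map).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  plan <- plan_network_edges(config)
  edges <- plan$edges
  partner_map <- plan$partner_map
  with_local_seed(config$seed + 3L, {
    methods_pool <- c("two hybrid", "anti tag coimmunoprecipitation",
                      "pull down", "x-ray crystallography")
    evidence <- purrr::map(seq_len(nrow(edges)), function(i) {
      e <- edges[i, ]
      if (e$confident) {
        pattern <- sample(c("pubs", "methods", "both"), 1)
        ev <- switch(pattern,
          pubs = tibble(pubmed_id = as.character(sample.int(10^6, 2)),
                        method = sample(methods_pool, 1)),
          methods = tibble(pubmed_id = as.character(sample.int(10^6, 1)),
                           method = sample(methods_pool, 2)),
          both = tibble(pubmed_id = as.character(sample.int(10^6, 2)),
                        method = sample(methods_pool, 2)))
      } else {
        ev <- tibble(pubmed_id = as.character(sample.int(10^6, 1)),
                     method = sample(methods_pool, 1))
      }
      flip <- runif(nrow(ev)) < 0.5        # random row orientation
      tibble(protein_a = if_else(flip, e$protein_b, e$protein_a),
             protein_b = if_else(flip, e$protein_a, e$protein_b),
             pubmed_id = ev$pubmed_id, method = ev$method)
    }) %>% bind_rows()

    conf_edges <- filter(edges, .data$confident)
    seed_sub <- filter(conf_edges, .data$protein_a %in% config$seed_genes,
                       .data$protein_b %in% config$seed_genes)
    deg <- table(factor(c(seed_sub$protein_a, seed_sub$protein_b),
                        levels = config$seed_genes))
    for (i in seq_len(nrow(config$planted_hubs))) {
      hub <- config$planted_hubs$gene[i]
      if (any(deg[names(deg) != hub] >= deg[[hub]])) {
        abort("infeasible plan: a non-hub seed gene reached the hub's degree",
              class = "allnet_config_error")
      }
    }

    truth <- list(
      edges = edges,
      seed_degrees = tibble(gene = names(deg), degree = as.integer(deg)) %>%
        arrange(desc(.data$degree), .data$gene),
      hub_genes = config$planted_hubs$gene,
      partner_map = partner_map,
      cooccurring_pairs = config$planted_cooccurring_pairs,
      exclusive_pairs = config$planted_exclusive_pairs)
    list(evidence = evidence, truth = truth)
  })
}

#' Generate a synthetic binary expression table
#'
#' Binary genes-by-cell-lines calls. Planted candidate partners are expressed
#' in exactly `round(expression_fraction * n_cell_lines)` lines; every other
#' gene's calls are Bernoulli draws at the background rate.
#'
#' @param config A [synthetic_config()].
#' @return A list: `expression` (tibble, `gene` plus one 0/1 column per cell
#'   line) and `truth` (per-candidate expressed-line counts).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed + 2L, {
    genes <- c(config$seed_genes, config$partner_genes)
    m <- matrix(as.integer(runif(length(genes) * config$n_cell_lines) <
                             config$background_expression_rate),
                nrow = length(genes),
                dimnames = list(genes,
                                sprintf("CL%02d",
                                        seq_len(config$n_cell_lines))))
    cand <- config$planted_candidates
    for (i in seq_len(nrow(cand))) {
      k <- round(cand$expression_fraction[i] * config$n_cell_lines)
      row <- integer(config$n_cell_lines)
      if (k > 0) row[sample(config$n_cell_lines, k)] <- 1L
      m[cand$partner[i], ] <- row
    }
    truth <- list(candidate_expressed_lines =
                    tibble(partner = cand$partner,
                           n_expressed = as.integer(
                             round(cand$expression_fraction *
                                     config$n_cell_lines))))
    list(expression = bind_cols(tibble(gene = genes), as_tibble(m)),
         truth = truth)
  })
}

#' Cancer-census stand-in for a synthetic configuration
#'
#' The census emulation: all seed (disease) genes plus the planted candidate
#' partners flagged as census members.
#'
#' @param config A [synthetic_config()].
#' @return Sorted character vector of census symbols.
#' @export
census_set <- function(config) {
  sort(unique(c(config$seed_genes,
                config$planted_candidates$partner[
                  config$planted_candidates$census_member])))
}

#' Generate a complete synthetic benchmark dataset
#'
#' Runs [generate_catalog()], [generate_network()] and
#' [generate_expression()] under one configuration and bundles their outputs
#' with the census stand-in and the merged ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `catalog`, `cds`, `evidence`, `expression`,
#'   `census`, `config` and `truth`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cat_out <- generate_catalog(config)
  net_out <- generate_network(config)
  exp_out <- generate_expression(config)
  cand <- config$planted_candidates
  truth <- c(cat_out$truth, net_out$truth, exp_out$truth)
  truth$best_gene <- config$planted_hubs$gene[1]
  truth$candidates <- mutate(
    cand,
    passes = .data$n_seed_partners >= 2 & .data$census_member &
      .data$expression_fraction >= 0.6)
  list(catalog = cat_out$catalog, cds = cat_out$cds,
       evidence = net_out$evidence, expression = exp_out$expression,
       census = census_set(config), config = config, truth = truth)
}

#' Write a synthetic dataset to a directory
#'
#' Emits exactly the dialects the pipeline consumes: `catalog.tsv`,
#' `cds.fasta`, `evidence.tsv`, `expression.tsv`, `census.txt`, and the
#' ground truth as `ground_truth.yaml`.
#'
#' @param data Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(data$catalog, file.path(dir, "catalog.tsv"))
  Biostrings::writeXStringSet(data$cds, file.path(dir, "cds.fasta"))
  readr::write_tsv(data$evidence, file.path(dir, "evidence.tsv"))
  readr::write_tsv(data$expression, file.path(dir, "expression.tsv"))
  writeLines(data$census, file.path(dir, "census.txt"))
  truth <- data$truth
  truth$record_status <- as.data.frame(truth$record_status)
  truth$burden <- as.data.frame(truth$burden)
  truth$edges <- as.data.frame(truth$edges)
  truth$seed_degrees <- as.data.frame(truth$seed_degrees)
  truth$cooccurring_pairs <- as.data.frame(truth$cooccurring_pairs)
  truth$exclusive_pairs <- as.data.frame(truth$exclusive_pairs)
  truth$candidate_expressed_lines <-
    as.data.frame(truth$candidate_expressed_lines)
  truth$candidates <- as.data.frame(truth$candidates)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
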