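#' Read and filter a COSMIC-style somatic mutation catalog
#'
#' Parses a tab-separated somatic mutation catalog into a tidy record table,
#' optionally restricted to one disease. Each row of the catalog describes a
#' single reported mutation: the gene symbol, the sample in which it was
#' observed, the coding-level (`c.`) and/or protein-level (`p.`) mutation
#' syntax, the sample histology and the PubMed id of the reporting study.
#'
#' Rows missing a gene symbol, missing a sample id, or carrying neither a
#' coding nor a protein change are malformed: they are dropped from the result
#' but counted (attribute `n_malformed`, plus a message) rather than silently
#' discarded. Histology filtering is a case-insensitive substring match, since
#' catalog histology strings are inconsistent in case.
#'
#' @param source Path to a TSV file with a header row (or a data frame already
#'   in memory).
#' @param disease_filter Optional string; keep only records whose histology
#'   contains it (case-insensitive). `NULL` keeps everything.
#' @param column_map Named character vector mapping the six canonical column
#'   names (`gene`, `sample_id`, `cds_change`, `aa_change`, `histology`,
#'   `pubmed_id`) to the names used in the file, for catalogs with other
#'   headers.
#' @return A tibble with the six canonical columns, one row per mutation
#'   record, with attribute `n_malformed`.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tsample_id\tcds_change\taa_change\thistology\tpubmed_id",
#'              "FLT3\tS1\tc.1A>T\t\tlymphoblastic leukaemia\t1"), path)
#' parse_catalog(path, disease_filter = "lymphoblastic")
#' @export
parse_catalog <- function(source, disease_filter = NULL, column_map = NULL) {
  canonical <- c("gene", "sample_id", "cds_change", "aa_change",
                 "histology", "pubmed_id")
  if (is.data.frame(source)) {
    raw <- as_tibble(source)
  } else {
    raw <- readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
  }
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad) > 0) {
      abort(paste0("unknown column_map keys: ", paste(bad, collapse = ", ")))
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- canonical[!map %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(map[missing_cols], collapse = ", ")),
          class = "allnet_format_error")
  }
  records <- raw[, unname(map)]
  names(records) <- canonical
  records <- mutate(records, across(all_of(canonical),
                                    ~ if_else(is.na(.x), "", as.character(.x))))

  ok <- records$gene != "" & records$sample_id != "" &
    (records$cds_change != "" | records$aa_change != "")
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    inform(paste0(n_malformed, " malformed catalog row(s) dropped ",
                  "(missing gene, sample id, or any mutation syntax)"))
  }
  records <- records[ok, ]

  if (!is.null(disease_filter)) {
    keep <- grepl(disease_filter, records$histology, ignore.case = TRUE,
                  fixed = FALSE)
    records <- records[keep, ]
    if (nrow(records) == 0) {
      warn(paste0("no catalog records match disease filter '",
                  disease_filter, "'"))
    }
  }
  attr(records, "n_malformed") <- n_malformed
  records
}

#' Per-gene mutation burden
#'
#' Summarizes a mutation record table into one row per gene: the number of
#' distinct mutation syntaxes, the number of distinct mutated samples, and the
#' mutation frequency (the fraction of all catalogued samples carrying a
#' mutation in the gene). Two records are the same mutation when their
#' identity key matches; the key is the coding change when present, else the
#' protein change.
#'
#' @param records Tibble of mutation records as returned by [parse_catalog()].
#' @param total_samples Total number of samples screened in the catalog; must
#'   be at least the number of distinct sample ids observed.
#' @return A tibble with columns `gene`, `n_distinct`, `n_samples`,
#'   `frequency`, sorted by descending `n_samples` then gene symbol.
#' @examples
#' rec <- tibble::tibble(gene = "G", sample_id = c("S1", "S2", "S1"),
#'                       cds_change = c("c.1A>T", "c.2C>G", "c.1A>T"),
#'                       aa_change = "", histology = "ALL", pubmed_id = "1")
#' summarize_burden(rec, total_samples = 10)
#' @export
summarize_burden <- function(records, total_samples) {
  stopifnot(is.numeric(total_samples), length(total_samples) == 1,
            total_samples >= 1)
  observed <- n_distinct(records$sample_id)
  if (total_samples < observed) {
    abort(paste0("total_samples (", total_samples, ") is smaller than the ",
                 observed, " distinct sample ids observed in the catalog"),
          class = "allnet_consistency_error")
  }
  records %>%
    mutate(mutation_key = if_else(.data$cds_change != "",
                                  .data$cds_change, .data$aa_change)) %>%
    group_by(.data$gene) %>%
    summarise(n_distinct = n_distinct(.data$mutation_key),
              n_samples = n_distinct(.data$sample_id),
              .groups = "drop") %>%
    mutate(frequency = .data$n_samples / total_samples) %>%
    arrange(desc(.data$n_samples), .data$gene)
}

#' Threshold and rank genes by mutation burden
#'
#' Applies joint thresholds on distinct-mutation and mutated-sample counts
#' (the catalog-scale analogue of "at least 2 distinct mutations in at least
#' 556 samples"), sorts the survivors by a chosen key and truncates to the top
#' `k`. Ties on the key are broken by gene symbol so output is deterministic.
#'
#' @param burdens Burden table from [summarize_burden()].
#' @param min_distinct,min_samples Minimum distinct mutations / mutated
#'   samples a gene must reach (inclusive).
#' @param min_frequency Keep only genes mutated in more than this fraction of
#'   samples (strict, e.g. `0.05` for the more-than-5-percent rule).
#' @param k Maximum number of genes returned; `Inf` returns all survivors.
#' @param key Sorting key: `"n_samples"`, `"n_distinct"` or `"frequency"`.
#' @return The filtered, sorted, truncated burden tibble.
#' @export
top_genes <- function(burdens, min_distinct = 1, min_samples = 1,
                      min_frequency = 0, k = Inf,
                      key = c("n_samples", "n_distinct", "frequency")) {
  key <- match.arg(key)
  stopifnot(k >= 1)
  out <- burdens %>%
    filter(.data$n_distinct >= min_distinct,
           .data$n_samples >= min_samples,
           min_frequency == 0 | .data$frequency > min_frequency) %>%
    arrange(desc(.data[[key]]), .data$gene)
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Write a burden table as TSV
#'
#' @param burdens Burden tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_burden <- function(burdens, path) {
  readr::write_tsv(burdens, path)
  invisible(path)
}
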