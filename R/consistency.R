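#' Parse a coding-substitution HGVS string
#'
#' Recognizes the single-nucleotide coding substitution subset
#' `c.<pos><ref>><alt>` (e.g. `c.4G>T`). Anything else — indels, duplications,
#' fusions, malformed strings — is reported as unparsed, never an error, so
#' that full catalogs stream through the checker.
#'
#' @param cds_change Character vector of coding-change strings.
#' @return A tibble with columns `cds_change`, `pos`, `ref`, `alt`, `parsed`.
#' @export
parse_cds_change <- function(cds_change) {
  m <- stringr::str_match(cds_change, "^c\\.([0-9]+)([ACGT])>([ACGT])$")
  tibble(cds_change = cds_change,
         pos = as.integer(m[, 2]),
         ref = m[, 3],
         alt = m[, 4],
         parsed = !is.na(m[, 1]))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(if_else(is.na(aa), "X", aa))
}

#' Verify mutation syntax against coding sequences
#'
#' For each record whose coding change parses as a single-nucleotide
#' substitution, checks that the stated reference base matches the coding
#' sequence (CDS) at that 1-based position, applies the substitution,
#' translates the affected codon under the standard genetic code, and compares
#' the predicted protein change with the record's stated one. Synonymous
#' substitutions predict `p.<AA><n>=`.
#'
#' Verdict statuses: `consistent` (reference base matches and, when a protein
#' change is stated, it equals the prediction), `ref_mismatch`, `aa_mismatch`,
#' `out_of_range` (position beyond the CDS), and `unparsed` (syntax outside
#' the single-substitution subset, or no CDS available for the gene).
#'
#' @param records Mutation record tibble (see [parse_catalog()]).
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of coding sequences, names matching `records$gene`; each CDS
#'   length must be a multiple of 3.
#' @return `records` with columns `status` and `predicted_aa_change` appended.
#' @examples
#' rec <- tibble::tibble(gene = "G", sample_id = "S1", cds_change = "c.4G>T",
#'                       aa_change = "p.A2S", histology = "", pubmed_id = "")
#' check_consistency(rec, c(G = "ATGGCTTAA"))
#' @export
check_consistency <- function(records, sequences) {
  seqs <- as.character(sequences)
  names(seqs) <- names(sequences)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("coding sequences must be named by gene symbol")
  }
  bad_len <- nchar(seqs) %% 3 != 0 | nchar(seqs) < 3
  if (any(bad_len)) {
    abort(paste0("CDS length not a positive multiple of 3 for: ",
                 paste(names(seqs)[bad_len], collapse = ", ")))
  }
  parsed <- parse_cds_change(records$cds_change)
  status <- character(nrow(records))
  predicted <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- verify_one(records$gene[i], parsed$pos[i], parsed$ref[i],
                    parsed$alt[i], parsed$parsed[i],
                    records$aa_change[i], seqs)
    status[i] <- v$status
    predicted[i] <- v$predicted
  }
  mutate(records, status = status, predicted_aa_change = predicted)
}

verify_one <- function(gene, pos, ref, alt, parsed, aa_change, seqs) {
  none <- list(status = "unparsed", predicted = "")
  if (!parsed || !gene %in% names(seqs)) return(none)
  cds <- seqs[[gene]]
  if (pos < 1 || pos > nchar(cds)) return(list(status = "out_of_range",
                                               predicted = ""))
  if (substr(cds, pos, pos) != ref) return(list(status = "ref_mismatch",
                                                predicted = ""))
  codon_idx <- ceiling(pos / 3)          # 1-based HGVS pos -> codon number
  codon_start <- (codon_idx - 1) * 3 + 1
  ref_codon <- substr(cds, codon_start, codon_start + 2)
  alt_codon <- ref_codon
  substr(alt_codon, pos - codon_start + 1, pos - codon_start + 1) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  predicted <- if (ref_aa == alt_aa) {
    paste0("p.", ref_aa, codon_idx, "=")
  } else {
    paste0("p.", ref_aa, codon_idx, alt_aa)
  }
  if (aa_change != "" && aa_change != predicted) {
    return(list(status = "aa_mismatch", predicted = predicted))
  }
  list(status = "consistent", predicted = predicted)
}

#' Locate a coding sequence on a clone by exact match
#'
#' Transfers CDS coordinates onto a clone sequence by leftmost exact substring
#' search, the deterministic stand-in for alignment-based coordinate transfer
#' when clone inserts contain the CDS verbatim.
#'
#' @param cds CDS sequence (character scalar or `DNAString`).
#' @param clone Clone sequence.
#' @return 0-based offset of the leftmost match, or `NA_integer_` when the
#'   CDS does not occur in the clone.
#' @examples
#' locate_on_clone("ATGGCT", "GGATGGCTTA")  # 2
#' @export
locate_on_clone <- function(cds, clone) {
  hit <- regexpr(as.character(cds), as.character(clone), fixed = TRUE)
  if (hit[1] == -1L) NA_integer_ else as.integer(hit[1] - 1L)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named `DNAStringSet`; names are truncated at the first whitespace.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
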