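# Two-stage novelty filter: exact substring removal against the reference
# proteome, then local-alignment similarity against known proteins.

collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Stage 1: remove peptides found verbatim in a reference proteome
#'
#' A peptide is removed iff its sequence occurs as a contiguous substring of
#' any reference protein. With `il_equivalent = TRUE` (default) isoleucine
#' and leucine are collapsed on both sides before matching, since the two
#' residues are isobaric and indistinguishable by mass spectrometry.
#'
#' @param peptides character vector of peptide backbone sequences.
#' @param reference database data.frame (needs `aa_sequence`).
#' @param il_equivalent logical; collapse I to L before matching.
#' @return list with character vectors `removed` and `retained` (an
#'   exhaustive, disjoint partition of the input, input order preserved).
#' @export
reference_substring_filter <- function(peptides, reference,
                                       il_equivalent = TRUE) {
  if (nrow(reference) == 0L) {
    stopf("reference proteome is empty", class = "sorfpipe_input_error")
  }
  check_protein(peptides)
  pep <- if (il_equivalent) collapse_il(peptides) else peptides
  ref <- if (il_equivalent) collapse_il(reference$aa_sequence)
         else reference$aa_sequence
  haystack <- paste(ref, collapse = "\n")  # \n never matches a residue
  hit <- vapply(pep, function(p) grepl(p, haystack, fixed = TRUE), logical(1),
                USE.NAMES = FALSE)
  list(removed = peptides[hit], retained = peptides[!hit])
}

#' Stage 2: maximum local-alignment similarity to a known proteome
#'
#' For each peptide, computes the best Smith-Waterman local alignment
#' (match +1, mismatch 0, gap -1) against every known protein and reports
#' `100 * identities / peptide length` for the best hit. Among co-optimal
#' alignments the identity-richest one is used; the denominator is the full
#' peptide length so that partial matches are penalised (the point of the
#' filter is to exclude isoforms and point mutations of known proteins).
#'
#' @param peptides character vector.
#' @param known database data.frame of known proteins (needs `accession`,
#'   `aa_sequence`).
#' @param il_equivalent logical; collapse I/L before aligning (default off,
#'   mirroring protein BLAST).
#' @return data.frame with columns `peptide`, `percent`, `best_hit`
#'   (`NA` when `known` is empty; ties broken to the lexicographically
#'   smallest accession).
#' @export
max_similarity_to_known <- function(peptides, known, il_equivalent = FALSE) {
  check_protein(peptides)
  if (nrow(known) == 0L) {
    return(data.frame(peptide = peptides, percent = 0,
                      best_hit = NA_character_, stringsAsFactors = FALSE))
  }
  ord <- order(known$accession)  # first max hit => lexicographically smallest
  known <- known[ord, , drop = FALSE]
  pep <- if (il_equivalent) collapse_il(peptides) else peptides
  seqs <- if (il_equivalent) collapse_il(known$aa_sequence)
          else known$aa_sequence
  res <- .sw_identity_many(pep, seqs)
  data.frame(
    peptide = peptides,
    percent = 100 * res[, 1L] / nchar(peptides),
    best_hit = known$accession[res[, 2L]],
    stringsAsFactors = FALSE
  )
}

#' Two-stage novelty filter
#'
#' Applies [reference_substring_filter()] then [max_similarity_to_known()].
#' A peptide is novel iff it is not a substring of any reference protein and
#' its maximum similarity to a known protein does not exceed `cutoff`
#' percent (strictly greater than `cutoff` is excluded; a peptide at exactly
#' the cutoff is retained).
#'
#' @param peptides character vector of peptide backbone sequences.
#' @param reference reference proteome database (stage 1).
#' @param known known-protein database (stage 2).
#' @param cutoff similarity cutoff in percent, in (0, 100].
#' @param il_reference,il_known I/L collapsing per stage; defaults ON for
#'   the substring stage (conservative novelty) and OFF for the alignment
#'   stage.
#' @return list with `novel_peptides` (character) and `verdicts`, a
#'   data.frame with one row per input peptide: `peptide`, `stage`
#'   (`refprot_hit`/`similar_known`/`novel`), `max_similarity`, `best_hit`.
#' @export
filter_novel <- function(peptides, reference, known, cutoff = 80,
                         il_reference = TRUE, il_known = FALSE) {
  stopifnot(cutoff > 0, cutoff <= 100)
  part <- reference_substring_filter(peptides, reference,
                                     il_equivalent = il_reference)
  verdicts <- data.frame(
    peptide = peptides, stage = NA_character_,
    max_similarity = NA_real_, best_hit = NA_character_,
    stringsAsFactors = FALSE
  )
  hit1 <- peptides %in% part$removed
  verdicts$stage[hit1] <- "refprot_hit"
  verdicts$max_similarity[hit1] <- 100
  surv <- which(!hit1)
  if (length(surv)) {
    sim <- max_similarity_to_known(peptides[surv], known)
    verdicts$max_similarity[surv] <- sim$percent
    verdicts$best_hit[surv] <- sim$best_hit
    verdicts$stage[surv] <- ifelse(sim$percent > cutoff,
                                   "similar_known", "novel")
  }
  list(novel_peptides = verdicts$peptide[verdicts$stage == "novel"],
       verdicts = verdicts)
}

#' Assign peptides to database entries and flag unique ones
#'
#' A peptide is assigned every database entry whose sequence contains it as
#' a contiguous substring and is `unique` when exactly one entry matches.
#' Peptides matching no entry are flagged `unassigned` — that signals an
#' identification table inconsistent with the database.
#'
#' @param peptides character vector.
#' @param database database data.frame, deduplicated by sequence (see
#'   [merge_databases()]).
#' @param il_equivalent logical; collapse I/L before matching.
#' @return data.frame with columns `peptide`, `accessions`
#'   (semicolon-joined), `n_accessions`, `unique`, `unassigned`.
#' @export
assign_peptides <- function(peptides, database, il_equivalent = TRUE) {
  check_protein(peptides)
  if (anyDuplicated(database$aa_sequence)) {
    stopf("database must be deduplicated by sequence before assignment",
          class = "sorfpipe_input_error")
  }
  seqs <- if (il_equivalent) collapse_il(database$aa_sequence)
          else database$aa_sequence
  pep <- if (il_equivalent) collapse_il(peptides) else peptides
  acc <- vapply(pep, function(p) {
    hits <- database$accession[grepl(p, seqs, fixed = TRUE)]
    paste(hits, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  n <- ifelse(acc == "", 0L, lengths(strsplit(acc, ";", fixed = TRUE)))
  data.frame(
    peptide = peptides, accessions = acc, n_accessions = as.integer(n),
    unique = n == 1L, unassigned = n == 0L, stringsAsFactors = FALSE
  )
}
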