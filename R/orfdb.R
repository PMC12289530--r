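# sORF enumeration by three-frame translation and database construction.

#' Translate a DNA string with the standard codon table
#'
#' Codons containing `N` yield `X`; stop codons yield `*` (the caller decides
#' how to truncate). With `init_met = TRUE` the first codon is rendered as
#' `M` regardless of identity, the convention for near-cognate initiation
#' (CTG, GTG and friends are decoded as methionine by the initiator tRNA).
#'
#' @param dna DNA string over `{A,C,G,T,N}`, length a multiple of 3.
#' @param init_met logical; force position 1 to methionine.
#' @return Protein string (possibly containing `*` and `X`).
#' @examples
#' translate_dna("ATGAAA")            # "MK"
#' translate_dna("CTGAAA", init_met = TRUE)  # "MK"
#' @export
translate_dna <- function(dna, init_met = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L, !is.na(dna))
  n <- nchar(dna)
  if (n %% 3L != 0L) {
    stopf("DNA length (%d) is not a multiple of 3", n,
          class = "sorfpipe_length_error")
  }
  if (n == 0L) return("")
  if (grepl("[^ACGTN]", dna)) {
    stopf("DNA contains characters outside {A,C,G,T,N}",
          class = "sorfpipe_input_error")
  }
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  if (init_met) aa[1L] <- "M"
  paste(aa, collapse = "")
}

# Codon strings of one frame of a transcript (drops the <3 nt remainder).
frame_codons <- function(sequence, frame) {
  n <- nchar(sequence)
  ncod <- (n - frame) %/% 3L
  if (ncod <= 0L) return(character(0))
  starts <- frame + seq(0L, ncod - 1L) * 3L + 1L
  substring(sequence, starts, starts + 2L)
}

#' Enumerate sORFs on a transcript by three-frame scanning
#'
#' Scans all three forward frames for ORFs that begin at a configured start
#' codon and end at the first in-frame stop. Coordinates are 0-based,
#' half-open, in transcript space; the stop codon lies inside
#' `[start, end)` but is excluded from the amino-acid sequence. ORFs whose
#' stop falls beyond the transcript end are discarded. With
#' `emit_all_starts = FALSE` only the most upstream qualifying start per
#' (frame, stop) pair is reported, which caps database redundancy.
#'
#' @param transcript one row of a validated transcript table (data.frame or
#'   list with `transcript_id` and `sequence`).
#' @param start_codons character vector of permitted initiation codons.
#' @param min_aa,max_aa bounds on the protein length (stop excluded).
#' @param emit_all_starts logical; emit every qualifying start, not just the
#'   most upstream one per stop.
#' @return data.frame with columns `sorf_id`, `transcript_id`, `start`,
#'   `end`, `frame`, `start_codon`, `aa_sequence`, sorted by (start, end).
#' @export
find_sorfs <- function(transcript,
                       start_codons = DEFAULT_START_CODONS,
                       min_aa = 7L, max_aa = 200L,
                       emit_all_starts = FALSE) {
  stopifnot(min_aa >= 1L, max_aa >= min_aa, length(start_codons) >= 1L)
  sequence <- transcript$sequence
  tid <- transcript$transcript_id
  empty <- data.frame(
    sorf_id = character(0), transcript_id = character(0),
    start = integer(0), end = integer(0), frame = integer(0),
    start_codon = character(0), aa_sequence = character(0),
    stringsAsFactors = FALSE
  )
  if (is.na(sequence) || nchar(sequence) < 6L) return(empty)

  out <- vector("list", 3L)
  for (frame in 0:2) {
    codons <- frame_codons(sequence, frame)
    if (length(codons) < 2L) next
    is_start <- codons %in% start_codons
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    if (!length(stop_idx) || !length(start_idx)) next
    # First in-frame stop strictly after each start; NA if none.
    nxt <- stop_idx[findInterval(start_idx, stop_idx) + 1L]
    keep <- !is.na(nxt)
    s <- start_idx[keep]
    t <- nxt[keep]
    aa_len <- t - s
    keep2 <- aa_len >= min_aa & aa_len <= max_aa
    s <- s[keep2]; t <- t[keep2]
    if (!length(s)) next
    if (!emit_all_starts) {
      first <- !duplicated(t)  # start_idx ascending => first hit is most upstream
      s <- s[first]; t <- t[first]
    }
    start_nt <- frame + (s - 1L) * 3L
    end_nt <- frame + t * 3L
    aa <- vapply(seq_along(s), function(i) {
      translate_dna(substr(sequence, start_nt[i] + 1L, end_nt[i] - 3L),
                    init_met = TRUE)
    }, character(1))
    out[[frame + 1L]] <- data.frame(
      sorf_id = sprintf("%s:%d-%d:%d", tid, start_nt, end_nt, frame),
      transcript_id = tid, start = start_nt, end = end_nt, frame = frame,
      start_codon = codons[s], aa_sequence = aa, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) return(empty)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a microprotein database from transcripts
#'
#' Runs [find_sorfs()] on every transcript and emits one database entry per
#' sORF. Accessions encode `transcript_id:start-end:frame` so entries remain
#' traceable to their genomic context.
#'
#' @param transcripts validated transcript table.
#' @inheritParams find_sorfs
#' @return data.frame with columns `accession`, `aa_sequence`, `source`,
#'   `transcript_id`, `start`, `end`, `frame`, `start_codon`.
#' @export
build_sorf_database <- function(transcripts,
                                start_codons = DEFAULT_START_CODONS,
                                min_aa = 7L, max_aa = 200L,
                                emit_all_starts = FALSE) {
  if (anyDuplicated(transcripts$transcript_id)) {
    stopf("duplicate transcript_id in input", class = "sorfpipe_input_error")
  }
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    find_sorfs(transcripts[i, ], start_codons = start_codons,
               min_aa = min_aa, max_aa = max_aa,
               emit_all_starts = emit_all_starts)
  })
  sorfs <- do.call(rbind, rows)
  if (is.null(sorfs) || nrow(sorfs) == 0L) {
    return(data.frame(accession = character(0), aa_sequence = character(0),
                      source = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0), frame = integer(0),
                      start_codon = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    accession = sorfs$sorf_id, aa_sequence = sorfs$aa_sequence,
    source = "rnaseq_3frame", transcript_id = sorfs$transcript_id,
    start = sorfs$start, end = sorfs$end, frame = sorfs$frame,
    start_codon = sorfs$start_codon, stringsAsFactors = FALSE
  )
}

#' Merge protein databases, optionally collapsing identical sequences
#'
#' With `dedup = TRUE` one entry is kept per distinct amino-acid sequence
#' (first-seen accession wins; all contributing sources are recorded in a
#' `sources` column). With `dedup = FALSE` the sets are simply concatenated.
#' Redundant databases inflate search space and false-positive risk, hence
#' deduplication is the default.
#'
#' @param sets list of database data.frames (columns `accession`,
#'   `aa_sequence`, `source` at minimum).
#' @param dedup logical.
#' @return A single database data.frame in deterministic (first-seen) order.
#' @export
merge_databases <- function(sets, dedup = TRUE) {
  cols <- c("accession", "aa_sequence", "source")
  sets <- lapply(sets, function(s) {
    miss <- setdiff(cols, names(s))
    if (length(miss)) stopf("database lacks columns: %s",
                            paste(miss, collapse = ", "),
                            class = "sorfpipe_input_error")
    s[, cols, drop = FALSE]
  })
  db <- do.call(rbind, sets)
  if (is.null(db) || nrow(db) == 0L) {
    return(data.frame(accession = character(0), aa_sequence = character(0),
                      source = character(0), sources = character(0),
                      stringsAsFactors = FALSE))
  }
  dup_acc <- db$accession[duplicated(db$accession)]
  if (length(dup_acc)) {
    clash <- vapply(unique(dup_acc), function(a) {
      length(unique(db$aa_sequence[db$accession == a])) > 1L
    }, logical(1))
    if (any(clash)) {
      stopf("accession collision with differing sequences: %s",
            paste(head(unique(dup_acc)[clash], 3L), collapse = ", "),
            class = "sorfpipe_integrity_error")
    }
  }
  if (!dedup) {
    db$sources <- db$source
    rownames(db) <- NULL
    return(db)
  }
  grp <- match(db$aa_sequence, unique(db$aa_sequence))
  sources <- vapply(split(db$source, grp), function(s) {
    paste(unique(s), collapse = ";")
  }, character(1))
  keep <- !duplicated(grp)
  out <- db[keep, , drop = FALSE]
  out$sources <- sources[as.character(grp[keep])]
  rownames(out) <- NULL
  out
}
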