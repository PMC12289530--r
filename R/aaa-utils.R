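# Shared constants and input checks.

STOP_CODONS <- c("TAA", "TAG", "TGA")

DEFAULT_START_CODONS <- c("ATG", "CTG", "GTG")

# Standard monoisotopic residue masses (Da), 20 proteinogenic residues.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
CARBAMIDOMETHYL_MASS <- 57.02146

AA_ALPHABET <- c(names(RESIDUE_MASS), "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "sorfpipe_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_protein <- function(x, what = "peptide") {
  if (!is.character(x) || any(is.na(x)) || any(nchar(x) == 0L)) {
    stopf("%s sequences must be non-empty strings", what,
          class = "sorfpipe_input_error")
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    stopf("%s contains non-standard residues: %s", what,
          paste(head(x[bad], 3L), collapse = ", "),
          class = "sorfpipe_input_error")
  }
  invisible(x)
}

#' Validate a transcript table
#'
#' Checks the invariants of the transcript container: uppercase DNA over
#' `{A,C,G,T,N}`, a biotype in `coding`/`noncoding`/`novel`, and for coding
#' transcripts a CDS interval (0-based, half-open) whose width is a positive
#' multiple of 3 of at least 6 nt and lies within the sequence.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype`, `sequence`, `cds_start`, `cds_end` (the last two `NA` unless
#'   `biotype == "coding"`).
#' @return The validated data.frame, invisibly.
#' @export
validate_transcripts <- function(transcripts) {
  req <- c("transcript_id", "biotype", "sequence", "cds_start", "cds_end")
  miss <- setdiff(req, names(transcripts))
  if (length(miss)) {
    stopf("transcript table lacks columns: %s", paste(miss, collapse = ", "),
          class = "sorfpipe_input_error")
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stopf("duplicate transcript_id", class = "sorfpipe_input_error")
  }
  if (any(!transcripts$biotype %in% c("coding", "noncoding", "novel"))) {
    stopf("biotype must be coding/noncoding/novel",
          class = "sorfpipe_input_error")
  }
  if (any(grepl("[^ACGTN]", transcripts$sequence)) ||
      any(nchar(transcripts$sequence) == 0L)) {
    stopf("sequences must be non-empty uppercase DNA over {A,C,G,T,N}",
          class = "sorfpipe_input_error")
  }
  coding <- transcripts$biotype == "coding"
  if (any(coding)) {
    cs <- transcripts$cds_start[coding]
    ce <- transcripts$cds_end[coding]
    len <- nchar(transcripts$sequence[coding])
    ok <- !is.na(cs) & !is.na(ce) & cs >= 0 & cs < ce & ce <= len &
      (ce - cs) %% 3 == 0 & (ce - cs) >= 6
    if (!all(ok)) {
      stopf("invalid CDS interval for: %s",
            paste(head(transcripts$transcript_id[coding][!ok], 3L),
                  collapse = ", "),
            class = "sorfpipe_input_error")
    }
  }
  if (any(!coding & !(is.na(transcripts$cds_start) & is.na(transcripts$cds_end)))) {
    stopf("CDS interval only allowed on coding transcripts",
          class = "sorfpipe_input_error")
  }
  invisible(transcripts)
}
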