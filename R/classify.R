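# Seven-category genomic-context classification of sORFs.

#' Admissible sORF categories
#' @export
SORF_CATEGORIES <- c("lncRNA", "uORF", "uoORF", "intORF", "dORF", "doORF",
                     "novel")

#' Classify one sORF by its genomic context
#'
#' Decision rules, applied in order against the host transcript:
#' a `novel`-biotype transcript gives `novel`; a noncoding transcript gives
#' `lncRNA`; on a coding transcript with CDS `[cs, ce)` the sORF interval
#' `[start, end)` is compared to the CDS — entirely upstream (`end <= cs`)
#' is `uORF`; spanning the CDS start is `uoORF`; entirely downstream
#' (`start >= ce`) is `dORF`; spanning the CDS end is `doORF`; contained in
#' the CDS in a shifted reading frame is `intORF`. An sORF contained in the
#' CDS *in frame* is a canonical-protein fragment, not a microprotein: it
#' raises a `sorfpipe_canonical_frame` error, because such sequences must
#' already have been removed by the novelty filter and meeting one here
#' indicates an upstream fault. An sORF abutting the CDS start
#' (`end == cs`) is uORF, not uoORF; mirrored at the 3' end. An sORF
#' overlapping the CDS start in a shifted frame is uoORF (upstream overlap
#' takes precedence over internal).
#'
#' @param sorf one row of a [find_sorfs()] table (list-like with `start`,
#'   `end`, `transcript_id`).
#' @param transcript the matching transcript row (`biotype`, `cds_start`,
#'   `cds_end`).
#' @return One of [SORF_CATEGORIES].
#' @export
classify_sorf <- function(sorf, transcript) {
  if (!identical(as.character(sorf$transcript_id),
                 as.character(transcript$transcript_id))) {
    stopf("sORF/transcript mismatch: %s vs %s", sorf$transcript_id,
          transcript$transcript_id, class = "sorfpipe_input_error")
  }
  bt <- transcript$biotype
  if (bt == "novel") return("novel")
  if (bt == "noncoding") return("lncRNA")
  cs <- transcript$cds_start
  ce <- transcript$cds_end
  s <- sorf$start
  e <- sorf$end
  if (e <= cs) return("uORF")
  if (s < cs && e > cs && e <= ce) return("uoORF")
  if (s >= ce) return("dORF")
  if (s >= cs && s < ce && e > ce) return("doORF")
  if (s >= cs && e <= ce) {
    if ((s - cs) %% 3L != 0L) return("intORF")
    stopf(paste0("sORF %s is an in-frame fragment of the canonical CDS; ",
                 "it should have been removed by the novelty filter"),
          sorf$sorf_id %||% sorf$transcript_id,
          class = "sorfpipe_canonical_frame")
  }
  # s < cs and e > ce: the sORF spans the whole CDS; the upstream overlap
  # rule takes precedence.
  "uoORF"
}

#' Classify a table of sORFs
#'
#' @param sorfs [find_sorfs()]-style table.
#' @param transcripts validated transcript table covering every
#'   `transcript_id` in `sorfs`.
#' @return `sorfs` with a `category` column appended.
#' @export
classify_sorfs <- function(sorfs, transcripts) {
  idx <- match(sorfs$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    stopf("sORFs reference unknown transcripts",
          class = "sorfpipe_input_error")
  }
  sorfs$category <- vapply(seq_len(nrow(sorfs)), function(i) {
    classify_sorf(sorfs[i, ], transcripts[idx[i], ])
  }, character(1))
  sorfs
}

#' Summary statistics of a classified sORF set
#'
#' @param sorfs classified sORF table (needs `category`, `start_codon`,
#'   `aa_sequence`).
#' @return list with `category_fractions`, `start_codon_fractions`,
#'   `length_median` (amino acids) and `length_fraction_100_200` (fraction
#'   of sORFs of 100-200 aa inclusive).
#' @export
summarize_sorfs <- function(sorfs) {
  if (is.null(sorfs) || nrow(sorfs) == 0L) {
    stopf("cannot summarise an empty sORF set",
          class = "sorfpipe_input_error")
  }
  n <- nrow(sorfs)
  lens <- nchar(sorfs$aa_sequence)
  cat_tab <- table(factor(sorfs$category, levels = SORF_CATEGORIES))
  cat_frac <- as.numeric(cat_tab) / n
  names(cat_frac) <- names(cat_tab)
  sc_tab <- table(sorfs$start_codon)
  sc_frac <- as.numeric(sc_tab) / n
  names(sc_frac) <- names(sc_tab)
  list(
    category_fractions = cat_frac[cat_frac > 0],
    start_codon_fractions = sc_frac,
    length_median = median(lens),
    length_fraction_100_200 = mean(lens >= 100 & lens <= 200)
  )
}
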