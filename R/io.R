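# File formats: FASTA (via Biostrings), annotation/peptide/design TSV, MGF.

#' Read transcripts from FASTA plus a TSV annotation
#'
#' The annotation carries `transcript_id`, `gene_id`, `biotype`,
#' `cds_start`, `cds_end` (empty/NA CDS for non-coding transcripts,
#' 0-based half-open otherwise); sequences come from the FASTA keyed by
#' `transcript_id`.
#'
#' @param fasta_path,annotation_path file paths.
#' @return validated transcript data.frame.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  miss <- setdiff(ann$transcript_id, ids)
  if (length(miss)) {
    stopf("annotation rows without FASTA sequence: %s",
          paste(head(miss, 3L), collapse = ", "),
          class = "sorfpipe_input_error")
  }
  ann$sequence <- as.character(seqs)[match(ann$transcript_id, ids)]
  ann$cds_start <- suppressWarnings(as.integer(ann$cds_start))
  ann$cds_end <- suppressWarnings(as.integer(ann$cds_end))
  validate_transcripts(ann)
  ann
}

#' Write transcripts to FASTA plus TSV annotation
#' @param transcripts validated transcript table.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  cols <- c("transcript_id", "gene_id", "biotype", "cds_start", "cds_end")
  write.table(transcripts[, intersect(cols, names(transcripts))],
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Write a protein database as FASTA
#'
#' Structured headers `acc|transcript_id|start-end|frame|start_codon|source`
#' for three-frame entries; plain `acc||||source` style otherwise.
#'
#' @param db database data.frame.
#' @param path output path.
#' @export
write_database_fasta <- function(db, path) {
  has <- function(col) col %in% names(db)
  hdr <- sprintf(
    "%s|%s|%s|%s|%s|%s",
    db$accession,
    if (has("transcript_id")) db$transcript_id else "",
    if (has("start")) sprintf("%d-%d", db$start, db$end) else "",
    if (has("frame")) db$frame else "",
    if (has("start_codon")) db$start_codon else "",
    db$source
  )
  seqs <- Biostrings::AAStringSet(setNames(db$aa_sequence, hdr))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' Headers written by [write_database_fasta()] are unpacked; plain FASTA
#' (external Ribo-seq or public databases) gets the whole header as
#' accession and the supplied `source` label.
#'
#' @param path FASTA path.
#' @param source default source label for plain headers.
#' @return database data.frame.
#' @export
read_database_fasta <- function(path, source = "public_external") {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  structured <- lengths(parts) == 6L
  db <- data.frame(
    accession = vapply(parts, `[`, "", 1L),
    aa_sequence = as.character(seqs),
    source = ifelse(structured, vapply(parts, `[`, "", 6L), source),
    stringsAsFactors = FALSE
  )
  db$accession[!structured] <- sub("\\s.*$", "", names(seqs)[!structured])
  rownames(db) <- NULL
  db
}

#' Read / write peptide tables
#'
#' TSV with columns `peptide`, optional `accessions` (semicolon-joined),
#' optional `qvalue`, and one numeric intensity column per sample.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_peptide_table
#' @param tab peptide table.
#' @export
write_peptide_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design TSV
#' @param path TSV with `sample_id`, `donor`, `condition`, `assay`,
#'   `replicate`.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) {
    stopf("duplicate sample_id in design", class = "sorfpipe_input_error")
  }
  d
}

#' Write spectra to an MGF peak list
#'
#' BEGIN IONS / END IONS dialect with TITLE, PEPMASS, CHARGE and mz
#' intensity pairs.
#'
#' @param spectra named list of `spectrum` objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s", nm),
      sprintf("PEPMASS=%.5f", mean(sp$peaks$mz)),
      sprintf("CHARGE=%d+", sp$precursor_charge),
      sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read an MGF peak list
#' @param path MGF path.
#' @return named list of `spectrum` objects (TITLE used as name and, when
#'   it looks like a peptide, as the spectrum's peptide).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stopf("malformed MGF: unbalanced BEGIN/END IONS",
          class = "sorfpipe_input_error")
  }
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    charge <- grep("^CHARGE=", block, value = TRUE)
    z <- if (length(charge)) as.integer(sub("^CHARGE=(\\d+).*", "\\1",
                                            charge[1])) else 2L
    pk <- block[grepl("^[0-9]", block)]
    mat <- do.call(rbind, strsplit(pk, "[ \t]+"))
    pep <- sub("\\..*$", "", title)
    if (!grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), pep)) {
      pep <- NA_character_
    }
    if (is.na(title)) title <- sprintf("spectrum_%d", k)
    out[[title]] <-
      spectrum(as.numeric(mat[, 1L]), as.numeric(mat[, 2L]),
               peptide = pep, precursor_charge = z)
  }
  out
}
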