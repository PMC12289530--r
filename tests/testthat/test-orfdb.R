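test_that("translate_dna follows the standard code and conventions", {
  expect_equal(translate_dna("ATGAAA"), "MK")
  expect_equal(translate_dna("CTGAAA", init_met = TRUE), "MK")
  expect_equal(translate_dna("CTGAAA", init_met = FALSE), "LK")
  expect_equal(translate_dna("ATGNNNTAA"), "MX*")
  expect_error(translate_dna("ATGA"), class = "sorfpipe_length_error")
  set.seed(41)
  for (k in 1:50) {
    dna <- paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(1:20, 1),
                        replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                 collapse = "")
    expect_identical(translate_dna(dna), oracle_translate(dna))
    expect_identical(translate_dna(dna, TRUE), oracle_translate(dna, TRUE))
  }
})

test_that("find_sorfs handles forced cases", {
  tx <- function(seq) data.frame(transcript_id = "t", sequence = seq,
                                 stringsAsFactors = FALSE)
  expect_equal(nrow(find_sorfs(tx("CCCCCCCCC"), min_aa = 1)), 0)
  one <- find_sorfs(tx("ATGAAATAA"), start_codons = "ATG", min_aa = 2)
  expect_equal(one$start, 0)
  expect_equal(one$end, 9)
  expect_equal(one$frame, 0)
  expect_equal(one$aa_sequence, "MK")
  # ORF without an in-frame stop is not emitted
  expect_equal(nrow(find_sorfs(tx("ATGAAAAAA"), min_aa = 1)), 0)
})

test_that("find_sorfs matches the exhaustive per-codon oracle", {
  set.seed(42)
  for (k in 1:30) {
    tr <- random_transcript_row(sprintf("t%02d", k), len = 300)
    for (eas in c(FALSE, TRUE)) {
      got <- find_sorfs(tr, min_aa = 3, max_aa = 60, emit_all_starts = eas)
      exp <- oracle_find_sorfs(tr$sequence, DEFAULT_START_CODONS,
                               min_aa = 3, max_aa = 60,
                               emit_all_starts = eas)
      expect_equal(got[, c("start", "end", "frame")], exp,
                   ignore_attr = TRUE)
    }
  }
})

test_that("every emitted sORF satisfies its invariants and round-trips", {
  set.seed(43)
  for (k in 1:20) {
    tr <- random_transcript_row(sprintf("r%02d", k), len = 400)
    so <- find_sorfs(tr, min_aa = 3, max_aa = 100)
    if (!nrow(so)) next
    expect_true(all((so$end - so$start) %% 3 == 0))
    expect_true(all(so$end <= nchar(tr$sequence)))
    expect_true(all(substr(tr$sequence, so$end - 2, so$end) %in%
                      c("TAA", "TAG", "TGA")))
    expect_equal(nchar(so$aa_sequence), (so$end - so$start) / 3 - 1)
    expect_equal(so$frame, so$start %% 3)
    for (i in seq_len(nrow(so))) {
      expect_identical(
        translate_dna(substr(tr$sequence, so$start[i] + 1, so$end[i] - 3),
                      init_met = TRUE),
        so$aa_sequence[i]
      )
    }
  }
})

test_that("start-codon and min_aa monotonicity hold", {
  set.seed(44)
  for (k in 1:10) {
    tr <- random_transcript_row(sprintf("m%02d", k), len = 350)
    small <- find_sorfs(tr, start_codons = "ATG", min_aa = 5, max_aa = 100,
                        emit_all_starts = TRUE)
    large <- find_sorfs(tr, start_codons = c("ATG", "CTG", "GTG"),
                        min_aa = 5, max_aa = 100, emit_all_starts = TRUE)
    expect_true(all(small$sorf_id %in% large$sorf_id))
    strict <- find_sorfs(tr, start_codons = "ATG", min_aa = 10,
                         max_aa = 100, emit_all_starts = TRUE)
    expect_true(all(strict$sorf_id %in% small$sorf_id))
  }
})

test_that("build_sorf_database emits one traceable entry per sORF", {
  tx <- data.frame(
    transcript_id = c("a", "b"), gene_id = NA, biotype = "noncoding",
    sequence = c("ATGAAAAAAAAAAAATAA", "CCCCCCCCCCCC"),
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  db <- build_sorf_database(tx, min_aa = 2)
  expect_equal(nrow(db), 1)
  expect_equal(db$accession, "a:0-18:0")
  expect_equal(db$source, "rnaseq_3frame")
  expect_equal(nrow(build_sorf_database(tx[0, ], min_aa = 2)), 0)
  expect_error(build_sorf_database(rbind(tx, tx[1, ])),
               class = "sorfpipe_input_error")
  # entry count equals the oracle's over a random set
  set.seed(45)
  txs <- do.call(rbind, lapply(1:20, function(i) {
    random_transcript_row(sprintf("s%02d", i), len = 250)
  }))
  db2 <- build_sorf_database(txs, min_aa = 3, max_aa = 60)
  n_oracle <- sum(vapply(txs$sequence, function(sq) {
    nrow(oracle_find_sorfs(sq, DEFAULT_START_CODONS, 3, 60))
  }, numeric(1)))
  expect_equal(nrow(db2), n_oracle)
})

test_that("merge_databases deduplicates by sequence and checks integrity", {
  mk <- function(acc, seqs, src = "public_external") {
    data.frame(accession = acc, aa_sequence = seqs, source = src,
               stringsAsFactors = FALSE)
  }
  a <- mk(c("a1", "a2", "a3"), c("MKLV", "MPQR", "MSHARED"))
  b <- mk(c("b1", "b2", "b3", "b4"),
          c("MSHARED", "MAAA", "MCCC", "MDDD"), src = "riboseq_external")
  expect_equal(nrow(merge_databases(list(a, b), dedup = TRUE)), 6)
  expect_equal(nrow(merge_databases(list(a, b), dedup = FALSE)), 7)
  m <- merge_databases(list(a, b), dedup = TRUE)
  expect_equal(m$sources[m$aa_sequence == "MSHARED"],
               "public_external;riboseq_external")
  expect_equal(m$accession[m$aa_sequence == "MSHARED"], "a3")
  clash <- mk("a1", "MOTHER")
  expect_error(merge_databases(list(a, clash)),
               class = "sorfpipe_integrity_error")
  # distinct-sequence count matches a set-union oracle
  set.seed(46)
  for (k in 1:5) {
    s1 <- mk(sprintf("x%d", 1:15), replicate(15, random_peptide(4, 8)))
    s2 <- mk(sprintf("y%d", 1:15), replicate(15, random_peptide(4, 8)))
    got <- nrow(merge_databases(list(s1, s2), dedup = TRUE))
    expect_equal(got, length(unique(c(s1$aa_sequence, s2$aa_sequence))))
  }
})

test_that("database FASTA output is byte-identical across reruns", {
  set.seed(47)
  txs <- do.call(rbind, lapply(1:5, function(i) {
    random_transcript_row(sprintf("d%02d", i), len = 200)
  }))
  db <- build_sorf_database(txs, min_aa = 3, max_aa = 60)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_database_fasta(db, f1)
  write_database_fasta(db, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_database_fasta(f1)
  expect_equal(back$aa_sequence, db$aa_sequence)
  expect_equal(back$accession, db$accession)
})
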