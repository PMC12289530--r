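test_that("simulate_transcriptome is seed-deterministic and seed-sensitive", {
  a <- simulate_transcriptome(seed = 101)
  b <- simulate_transcriptome(seed = 101)
  expect_identical(a, b)
  c <- simulate_transcriptome(seed = 102)
  expect_false(identical(a$transcripts$sequence, c$transcripts$sequence))
  # FASTA output is byte-identical for the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts(a$transcripts, f1, paste0(f1, ".tsv"))
  write_transcripts(b$transcripts, f2, paste0(f2, ".tsv"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("one planted sORF per requested context, all recoverable", {
  sim <- simulate_transcriptome(n_coding = 5, n_noncoding = 1,
                                n_novel = 1, seed = 103)
  expect_equal(nrow(sim$truth_sorfs), 7)
  expect_setequal(sim$truth_sorfs$category, SORF_CATEGORIES)
  # find_sorfs re-discovers each planted sORF at its exact coordinates
  for (i in seq_len(nrow(sim$truth_sorfs))) {
    tr <- sim$transcripts[sim$transcripts$transcript_id ==
                            sim$truth_sorfs$transcript_id[i], ]
    found <- find_sorfs(tr)
    expect_true(sim$truth_sorfs$sorf_id[i] %in% found$sorf_id)
  }
})

test_that("reference proteome matches a codon-table oracle and spikes variants", {
  sim <- simulate_transcriptome(n_coding = 5, n_noncoding = 0,
                                n_novel = 0, seed = 104)
  ref <- generate_reference_proteome(sim$transcripts)
  expect_equal(nrow(ref), 5)
  for (i in seq_len(nrow(ref))) {
    tr <- sim$transcripts[i, ]
    cds <- substr(tr$sequence, tr$cds_start + 1, tr$cds_end - 3)
    expect_identical(ref$aa_sequence[i],
                     sub("\\*.*$", "", oracle_translate(cds)))
  }
  src <- "MKVLAAGHTRWP"
  withv <- generate_reference_proteome(sim$transcripts,
                                       variant_sources = src, seed = 104)
  expect_equal(nrow(withv), 6)
  var <- withv$aa_sequence[6]
  expect_equal(nchar(var), nchar(src))
  d <- sum(strsplit(var, "")[[1]] != strsplit(src, "")[[1]])
  expect_equal(d, 1)
  # a 1-of-12 variant puts the source's similarity at 11/12 = 91.7%
  expect_equal(max_similarity_to_known(src, withv[6, ])$percent,
               100 * 11 / 12, tolerance = 1e-9)
})

test_that("tryptic digestion follows K/R-not-P with missed cleavages", {
  expect_equal(tryptic_digest("AAAAAAKGGGGGGR", max_missed = 0),
               c("AAAAAAK", "GGGGGGR"))
  expect_equal(tryptic_digest("AAAAAAKPGGGGGR", max_missed = 0),
               "AAAAAAKPGGGGGR")
  set.seed(105)
  for (k in 1:25) {
    prot <- random_protein(20, 60)
    expect_identical(tryptic_digest(prot), oracle_tryptic(prot))
    expect_identical(tryptic_digest(prot, max_missed = 0, min_len = 1,
                                    max_len = 1000),
                     oracle_tryptic(prot, 0, 1, 1000))
  }
})

test_that("simulate_intensities plants recoverable effects deterministically", {
  design <- make_design(conditions = c("unstim", "PMA_Iono"))
  pm <- data.frame(peptide = c("AAAAAAK", "CCCCCCK"),
                   protein_id = c("P1", "P2"), stringsAsFactors = FALSE)
  eff <- data.frame(protein_id = "P1", condition = "PMA_Iono", fc = 3)
  t1 <- simulate_intensities(design, pm, eff, seed = 106)
  t2 <- simulate_intensities(design, pm, eff, seed = 106)
  expect_identical(t1, t2)
  expect_false(identical(
    t1, simulate_intensities(design, pm, eff, seed = 107)))
  # null protein: expected log2 difference 0; planted: log2(3), both
  # estimated over replicated draws
  act <- design$sample_id[design$condition == "PMA_Iono"]
  uns <- design$sample_id[design$condition == "unstim"]
  diffs <- vapply(1:200, function(s) {
    tab <- simulate_intensities(design, pm, eff, seed = s)
    c(mean(log2(unlist(tab[1, act]))) - mean(log2(unlist(tab[1, uns]))),
      mean(log2(unlist(tab[2, act]))) - mean(log2(unlist(tab[2, uns]))))
  }, numeric(2))
  expect_lt(abs(mean(diffs[1, ]) - log2(3)), 0.2)
  expect_lt(abs(mean(diffs[2, ])), 0.2)
  # nascent proteins lose signal only under the CHX+OPP control
  dn <- make_design(conditions = "unstim",
                    assays = c("global", "nascent_OPP", "nascent_CHX_OPP"))
  tn <- simulate_intensities(dn, pm, nascent_set = "P1", chx_ratio = 4,
                             seed = 108)
  opp <- dn$sample_id[dn$assay == "nascent_OPP"]
  chx <- dn$sample_id[dn$assay == "nascent_CHX_OPP"]
  expect_equal(label_nascent(unlist(tn[1, opp]), unlist(tn[1, chx])),
               "nascent")
  expect_equal(label_nascent(unlist(tn[2, opp]), unlist(tn[2, chx])),
               "pre_existing")
})

test_that("simulate_spectra degrades monotonically from a perfect copy", {
  # zero degradation reproduces the theoretical spectrum exactly
  sp0 <- simulate_spectra("PEPTIDEK", dropout_p = 0, jitter_sd_da = 0,
                          n_noise_peaks = 0, seed = 109)[[1]]
  expect_equal(
    spectrum_similarity(sp0, theoretical_spectrum("PEPTIDEK"))$score, 1)
  # full dropout leaves noise only
  sp1 <- simulate_spectra("PEPTIDEK", dropout_p = 1, seed = 110)[[1]]
  expect_lt(
    spectrum_similarity(sp1, theoretical_spectrum("PEPTIDEK"))$score, 0.3)
})

test_that("simulate_dataset composes a coherent truth table", {
  ds <- simulate_dataset(seed = 111)
  expect_setequal(ds$truth$planted_sorfs$category, SORF_CATEGORIES)
  # planted novel peptides really survive the filter; expected-similar do not
  v <- filter_novel(c(ds$truth$planted_novel_peptides,
                      ds$truth$expected_similar_peptides),
                    ds$reference, ds$known)$verdicts
  expect_true(all(
    v$stage[v$peptide %in% ds$truth$planted_novel_peptides] == "novel"))
  expect_true(all(
    v$stage[v$peptide %in% ds$truth$expected_similar_peptides] != "novel"))
  # the peptide table covers canonical and microprotein peptides
  expect_true(any(grepl("^REF_", ds$peptide_table$protein_id)))
  expect_true(any(ds$peptide_table$protein_id %in%
                    ds$truth$planted_sorfs$sorf_id))
  expect_identical(ds$design$sample_id %in% names(ds$peptide_table),
                   rep(TRUE, nrow(ds$design)))
})
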