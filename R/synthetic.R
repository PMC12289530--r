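# Seeded synthetic-data generator: transcriptome with planted sORFs in all
# seven genomic contexts, reference/known proteomes, tryptic peptide tables
# with planted fold changes, and degraded experimental spectra. Every
# generator call seeds its own stream and restores the caller's RNG state.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                    paste0), c("A","C","G","T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_sense_codons <- function(n) {
  if (n <= 0L) return("")
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

# Planted ORF: start codon, aa_len - 1 sense codons, one stop codon.
rand_orf_nt <- function(aa_len, start_codon) {
  paste0(start_codon, rand_sense_codons(aa_len - 1L),
         sample(STOP_CODONS, 1L))
}

# Microprotein length model: log-normal with median 44 aa, most below
# 100 aa and a tail reaching toward 200, mirroring observed sORF length
# distributions.
rand_orf_aa_len <- function(n = 1L, min_aa = 10L, max_aa = 190L) {
  pmin(pmax(round(exp(rnorm(n, log(44), 0.45))), min_aa), max_aa)
}

rand_start_codon <- function(n = 1L) {
  # ~7.8% near-cognate initiation
  sample(c("ATG", "CTG", "GTG"), n, replace = TRUE,
         prob = c(0.922, 0.048, 0.030))
}

overwrite_substr <- function(x, start0, replacement) {
  # start0 is 0-based
  substr(x, start0 + 1L, start0 + nchar(replacement)) <- replacement
  x
}

# One transcript with a planted sORF in the requested context. Returns NULL
# when the random draw violates a constraint (caller retries).
plant_transcript <- function(tid, gid, context, start_codons, min_aa, max_aa) {
  orf_aa <- rand_orf_aa_len()
  sc <- rand_start_codon()
  biotype <- switch(context, lncRNA = "noncoding", novel = "novel", "coding")

  if (biotype != "coding") {
    orf_nt_len <- 3L * (orf_aa + 1L)
    pad5 <- sample(3:60, 1L)
    pad3 <- sample(20:80, 1L)
    s <- sample(0:pad5, 1L)
    seq <- paste0(rand_dna(pad5), rand_dna(orf_nt_len), rand_dna(pad3))
    seq <- overwrite_substr(seq, s, rand_orf_nt(orf_aa, sc))
    e <- s + orf_nt_len
    tr <- data.frame(transcript_id = tid, gene_id = gid, biotype = biotype,
                     sequence = seq, cds_start = NA_integer_,
                     cds_end = NA_integer_, stringsAsFactors = FALSE)
  } else {
    cds_aa <- sample(50:100, 1L)
    if (context %in% c("intORF", "uoORF")) {
      orf_aa <- min(orf_aa, cds_aa - 8L)
    }
    orf_nt_len <- 3L * (orf_aa + 1L)
    cds_nt <- 3L * (cds_aa + 1L)
    cds_seq <- paste0("ATG", rand_sense_codons(cds_aa - 1L),
                      sample(STOP_CODONS, 1L))
    if (context == "uORF") {
      utr5 <- orf_nt_len + sample(3:45, 1L)
      utr3 <- sample(30:90, 1L)
      s <- sample(0:(utr5 - orf_nt_len), 1L)
    } else if (context == "dORF") {
      utr5 <- sample(20:60, 1L)
      utr3 <- orf_nt_len + sample(3:45, 1L)
      s <- utr5 + cds_nt + sample(0:(utr3 - orf_nt_len), 1L)
    } else if (context == "uoORF") {
      ov <- sample(2:min(8L, orf_aa), 1L)
      sh <- sample(1:2, 1L)  # frame shift: the sORF stop must not sit in
                             # the CDS frame
      overlap <- 3L * ov + sh                   # nt inside the CDS
      u <- orf_nt_len - overlap                 # nt upstream of the CDS
      if (u < 1L) return(NULL)
      utr5 <- u + sample(5:40, 1L)
      utr3 <- sample(30:90, 1L)
      s <- utr5 - u
    } else if (context == "doORF") {
      ov <- sample(2:8, 1L)
      sh <- sample(1:2, 1L)  # frame shift keeps the upstream CDS start
                             # from absorbing the planted ORF
      utr5 <- sample(20:60, 1L)
      s <- utr5 + cds_nt - 3L * ov + sh
      utr3 <- (s + orf_nt_len - (utr5 + cds_nt)) + sample(5:40, 1L)
    } else if (context == "intORF") {
      room <- cds_nt - 6L - orf_nt_len
      if (room < 2L) return(NULL)
      utr5 <- sample(20:60, 1L)
      utr3 <- sample(30:90, 1L)
      q <- sample(0:((room - 2L) %/% 3L), 1L)
      s <- utr5 + 3L + 3L * q + sample(1:2, 1L)
    } else {
      stopf("unknown context '%s'", context, class = "sorfpipe_input_error")
    }
    cs <- utr5
    ce <- utr5 + cds_nt
    seq <- paste0(rand_dna(utr5), cds_seq, rand_dna(utr3))
    seq <- overwrite_substr(seq, s, rand_orf_nt(orf_aa, sc))
    e <- s + orf_nt_len
    # canonical protein must survive the overlap intact enough
    prot <- translate_dna(substr(seq, cs + 1L, ce - 3L))
    prot <- sub("\\*.*$", "", prot)
    if (context %in% c("uoORF", "intORF") && grepl("\\*", translate_dna(
      substr(seq, cs + 1L, ce - 3L)))) return(NULL)
    if (nchar(prot) < 20L) return(NULL)
    tr <- data.frame(transcript_id = tid, gene_id = gid, biotype = "coding",
                     sequence = seq, cds_start = cs, cds_end = ce,
                     stringsAsFactors = FALSE)
  }

  found <- find_sorfs(tr, start_codons = start_codons,
                      min_aa = min_aa, max_aa = max_aa)
  hit <- found[found$start == s & found$end == e, , drop = FALSE]
  if (nrow(hit) != 1L) return(NULL)  # displaced by an upstream start
  got <- tryCatch(classify_sorf(hit, tr), error = function(err) NA_character_)
  if (!identical(got, context)) return(NULL)
  hit$category <- context
  list(transcript = tr, sorf = hit)
}

#' Simulate a transcriptome with planted sORFs in all seven contexts
#'
#' Generates coding, lncRNA and novel transcripts, each carrying exactly one
#' planted sORF whose coordinates, start codon and genomic-context category
#' are recorded in a truth table. Coding transcripts carry a stop-free CDS;
#' the planted contexts cycle through `coding_contexts`. Construction is
#' rejection-sampled: a draw is discarded when a random upstream start would
#' displace the planted ORF or the overlap would truncate the canonical
#' protein, so every planted sORF is recoverable by [find_sorfs()] with the
#' same parameters.
#'
#' @param n_coding,n_noncoding,n_novel transcript counts per biotype.
#' @param coding_contexts contexts cycled over coding transcripts.
#' @param start_codons,min_aa,max_aa the ORF-calling parameters the
#'   downstream database build will use.
#' @param seed integer seed; fully determines the output.
#' @return list with `transcripts` (validated table) and `truth_sorfs`
#'   (planted sORF table with `category`).
#' @export
simulate_transcriptome <- function(n_coding = 5L, n_noncoding = 4L,
                                   n_novel = 2L,
                                   coding_contexts = c("uORF", "uoORF",
                                                       "intORF", "dORF",
                                                       "doORF"),
                                   start_codons = DEFAULT_START_CODONS,
                                   min_aa = 7L, max_aa = 200L, seed = 1L) {
  stopifnot(n_coding >= 0L, n_noncoding >= 0L, n_novel >= 0L)
  contexts <- c(
    if (n_coding > 0L)
      coding_contexts[(seq_len(n_coding) - 1L) %% length(coding_contexts) + 1L],
    rep("lncRNA", n_noncoding),
    rep("novel", n_novel)
  )
  with_seed(seed, {
    transcripts <- list()
    sorfs <- list()
    for (i in seq_along(contexts)) {
      tid <- sprintf("TX%03d", i)
      gid <- sprintf("G%03d", i)
      res <- NULL
      for (try in 1:500) {
        res <- plant_transcript(tid, gid, contexts[i], start_codons,
                                min_aa, max_aa)
        if (!is.null(res)) break
      }
      if (is.null(res)) {
        stopf("could not realise context '%s' after 500 draws", contexts[i],
              class = "sorfpipe_config_error")
      }
      transcripts[[i]] <- res$transcript
      sorfs[[i]] <- res$sorf
    }
    transcripts <- do.call(rbind, transcripts)
    truth <- do.call(rbind, sorfs)
    rownames(transcripts) <- rownames(truth) <- NULL
    validate_transcripts(transcripts)
    list(transcripts = transcripts, truth_sorfs = truth)
  })
}

#' Reference proteome stand-in from coding transcripts
#'
#' One canonical protein per coding CDS (translated, truncated at the first
#' stop). `variant_sources` sequences are additionally spiked as 1-residue
#' variants — stand-ins for isoforms/mutations in a curated database, there
#' to exercise the 80% similarity stage.
#'
#' @param transcripts validated transcript table.
#' @param variant_sources character vector of protein sequences to spike as
#'   near-duplicates.
#' @param seed integer seed (used for variant positions).
#' @return database data.frame (`accession`, `aa_sequence`, `source`).
#' @export
generate_reference_proteome <- function(transcripts,
                                        variant_sources = character(0),
                                        seed = 1L) {
  coding <- transcripts[transcripts$biotype == "coding", , drop = FALSE]
  prot <- vapply(seq_len(nrow(coding)), function(i) {
    p <- translate_dna(substr(coding$sequence[i], coding$cds_start[i] + 1L,
                              coding$cds_end[i] - 3L))
    sub("\\*.*$", "", p)
  }, character(1))
  keep <- nchar(prot) > 0L
  db <- data.frame(
    accession = sprintf("REF_%s", coding$transcript_id[keep]),
    aa_sequence = prot[keep], source = "public_external",
    stringsAsFactors = FALSE
  )
  if (length(variant_sources)) {
    vars <- with_seed(seed, vapply(variant_sources, function(sq) {
      pos <- sample(nchar(sq), 1L)
      old <- substr(sq, pos, pos)
      repl <- sample(setdiff(setdiff(AA_ALPHABET, "X"), old), 1L)
      substr(sq, pos, pos) <- repl
      sq
    }, character(1), USE.NAMES = FALSE))
    db <- rbind(db, data.frame(
      accession = sprintf("VAR_%03d", seq_along(vars)),
      aa_sequence = vars, source = "public_external",
      stringsAsFactors = FALSE
    ))
  }
  db
}

#' In silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and emits every
#' peptide with at most `max_missed` internal missed cleavage sites and a
#' length within `[min_len, max_len]`, in order of position then missed
#' cleavages.
#'
#' @param protein protein string.
#' @param max_missed maximum internal missed cleavages.
#' @param min_len,max_len peptide length bounds.
#' @return character vector of peptides (may contain duplicates when the
#'   protein repeats itself).
#' @export
tryptic_digest <- function(protein, max_missed = 2L, min_len = 7L,
                           max_len = 30L) {
  check_protein(protein, "protein")
  stopifnot(max_missed >= 0L)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment boundaries
  nf <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + max_missed)) {
      pep <- substr(protein, bounds[i] + 1L, bounds[j + 1L])
      if (nchar(pep) >= min_len && nchar(pep) <= max_len) {
        out <- c(out, pep)
      }
    }
  }
  out
}

#' Build a sample design table
#'
#' @param donors,conditions character vectors; one sample per
#'   donor x condition x assay.
#' @param assays assay labels (`global`, `nascent_OPP`,
#'   `nascent_CHX_OPP`).
#' @return design data.frame with `sample_id`, `donor`, `condition`,
#'   `assay`, `replicate`.
#' @export
make_design <- function(donors = c("D1", "D2", "D3"),
                        conditions = c("unstim", "PMA_Iono", "CD3_CD28"),
                        assays = "global") {
  g <- expand.grid(donor = donors, condition = conditions, assay = assays,
                   stringsAsFactors = FALSE)
  g$replicate <- match(g$donor, donors)
  g$sample_id <- sprintf("%s_%s_%s", g$assay, g$condition, g$donor)
  g[, c("sample_id", "donor", "condition", "assay", "replicate")]
}

#' Simulate a peptide intensity table
#'
#' Log2 intensity of every peptide of a protein in a sample is the protein
#' baseline, plus a fixed per-peptide ionisation offset, plus a per-donor
#' protein effect `Normal(0, donor_sd)`, plus the planted condition effect
#' (`log2` of the planted fold change), plus an assay effect (nascent-set
#' proteins lose `log2(chx_ratio)` under the CHX+OPP control), plus
#' measurement noise `Normal(0, sigma_log2)`. Values are returned on the
#' linear scale.
#'
#' @param design design table from [make_design()].
#' @param peptide_map data.frame with `peptide`, `protein_id`.
#' @param effects optional data.frame (`protein_id`, `condition`, `fc`)
#'   of planted linear fold changes relative to the baseline condition.
#' @param baseline_log2 mean log2 baseline (linear scale ~1e4; the pipeline
#'   is scale-invariant after the log transform).
#' @param sigma_log2 measurement noise SD on the log2 scale.
#' @param donor_sd SD of the per-donor protein effect.
#' @param peptide_sd SD of the fixed per-peptide offset.
#' @param nascent_set protein ids whose CHX+OPP signal is depressed.
#' @param chx_ratio linear OPP / CHX+OPP ratio for nascent proteins.
#' @param seed integer seed.
#' @return data.frame with `peptide`, `protein_id` and one intensity column
#'   per `design$sample_id`.
#' @export
simulate_intensities <- function(design, peptide_map, effects = NULL,
                                 baseline_log2 = log2(1e4),
                                 sigma_log2 = 0.3, donor_sd = 0.25,
                                 peptide_sd = 0.5,
                                 nascent_set = character(0),
                                 chx_ratio = 4, seed = 1L) {
  stopifnot(sigma_log2 > 0)
  prots <- unique(peptide_map$protein_id)
  with_seed(seed, {
    base <- setNames(baseline_log2 + rnorm(length(prots), 0, 1), prots)
    pep_off <- rnorm(nrow(peptide_map), 0, peptide_sd)
    donors <- unique(design$donor)
    don_eff <- matrix(rnorm(length(prots) * length(donors), 0, donor_sd),
                      nrow = length(prots),
                      dimnames = list(prots, donors))
    cond_eff <- matrix(0, nrow = length(prots),
                       ncol = length(unique(design$condition)),
                       dimnames = list(prots, unique(design$condition)))
    if (!is.null(effects) && nrow(effects)) {
      for (k in seq_len(nrow(effects))) {
        cond_eff[effects$protein_id[k], effects$condition[k]] <-
          log2(effects$fc[k])
      }
    }
    out <- data.frame(peptide = peptide_map$peptide,
                      protein_id = peptide_map$protein_id,
                      stringsAsFactors = FALSE)
    for (r in seq_len(nrow(design))) {
      sid <- design$sample_id[r]
      assay_eff <- ifelse(
        design$assay[r] == "nascent_CHX_OPP" &
          peptide_map$protein_id %in% nascent_set,
        -log2(chx_ratio), 0
      )
      l2 <- base[peptide_map$protein_id] + pep_off +
        don_eff[cbind(peptide_map$protein_id,
                      rep(design$donor[r], nrow(peptide_map)))] +
        cond_eff[cbind(peptide_map$protein_id,
                       rep(design$condition[r], nrow(peptide_map)))] +
        assay_eff +
        rnorm(nrow(peptide_map), 0, sigma_log2)
      out[[sid]] <- 2^l2
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate degraded experimental spectra
#'
#' Starts from the theoretical b/y spectrum of each peptide, drops each peak
#' with probability `dropout_p`, jitters retained m/z by
#' `Normal(0, jitter_sd_da)`, and adds `n_noise_peaks` uniform noise peaks
#' over the observed m/z range at uniform random intensity in (0, 1].
#'
#' @param peptides character vector.
#' @param dropout_p peak dropout probability in `[0, 1)` (1 is allowed and
#'   leaves only noise).
#' @param jitter_sd_da m/z jitter SD in Da.
#' @param n_noise_peaks noise peaks per spectrum.
#' @param fragment_charges passed to [theoretical_spectrum()].
#' @param seed integer seed.
#' @return named list of `spectrum` objects.
#' @export
simulate_spectra <- function(peptides, dropout_p = 0.2,
                             jitter_sd_da = 0.005, n_noise_peaks = 5L,
                             fragment_charges = 1L, seed = 1L) {
  stopifnot(dropout_p >= 0, dropout_p <= 1)
  with_seed(seed, {
    out <- lapply(peptides, function(p) {
      theo <- theoretical_spectrum(p, fragment_charges = fragment_charges)
      keep <- runif(nrow(theo$peaks)) >= dropout_p
      mz <- theo$peaks$mz[keep] + rnorm(sum(keep), 0, jitter_sd_da)
      int <- theo$peaks$intensity[keep]
      if (n_noise_peaks > 0L) {
        rng <- range(theo$peaks$mz)
        mz <- c(mz, runif(n_noise_peaks, rng[1], rng[2]))
        int <- c(int, runif(n_noise_peaks))
      }
      keep_pos <- mz > 0
      spectrum(mz[keep_pos], int[keep_pos], peptide = p,
               precursor_charge = max(fragment_charges) + 1L)
    })
    names(out) <- make.unique(peptides)
    out
  })
}

#' Simulate a complete pipeline input set with ground truth
#'
#' Composes the generators into one dataset: transcriptome with planted
#' sORFs in all seven contexts, reference proteome (stage-1 stand-in) and
#' known proteome (stage-2 stand-in; reference plus one spiked 1-residue
#' variant of a planted microprotein), a sample design, a peptide table
#' mixing canonical and microprotein peptides with planted activation fold
#' changes, degraded experimental spectra, and a truth table.
#'
#' @param seed integer master seed.
#' @param n_coding,n_noncoding,n_novel transcript counts.
#' @param conditions experimental conditions; the first is the baseline.
#' @param planted_fc linear fold change planted on up-regulated
#'   microproteins in both activation conditions.
#' @param n_up number of planted up-regulated microproteins (capped at the
#'   number of detected microproteins).
#' @param sigma_log2,donor_sd intensity noise parameters.
#' @param dropout_p,jitter_sd_da,n_noise_peaks spectral degradation.
#' @param spike_variant spike a near-duplicate of one microprotein into the
#'   known proteome.
#' @param nascent_assays include OPP / CHX+OPP nascent samples.
#' @return list with `transcripts`, `reference`, `known`, `design`,
#'   `peptide_table`, `spectra` and `truth` (planted sORFs, planted novel
#'   peptides, expected-similar peptides, planted effects, nascent set,
#'   classes, seed).
#' @export
simulate_dataset <- function(seed = 1L, n_coding = 5L, n_noncoding = 4L,
                             n_novel = 2L,
                             conditions = c("unstim", "PMA_Iono",
                                            "CD3_CD28"),
                             planted_fc = 3, n_up = 3L,
                             sigma_log2 = 0.3, donor_sd = 0.25,
                             dropout_p = 0.2, jitter_sd_da = 0.005,
                             n_noise_peaks = 5L, spike_variant = TRUE,
                             nascent_assays = TRUE) {
  tx <- simulate_transcriptome(n_coding = n_coding,
                               n_noncoding = n_noncoding,
                               n_novel = n_novel, seed = seed)
  micro <- tx$truth_sorfs

  # detected microproteins: those with at least one usable tryptic peptide
  micro_pep <- lapply(seq_len(nrow(micro)), function(i) {
    unique(tryptic_digest(micro$aa_sequence[i]))
  })
  detected <- which(lengths(micro_pep) > 0L)

  variant_sources <- character(0)
  variant_protein <- NA_character_
  if (spike_variant && length(detected)) {
    variant_protein <- micro$sorf_id[detected[1L]]
    variant_sources <- micro$aa_sequence[detected[1L]]
  }
  reference <- generate_reference_proteome(tx$transcripts, seed = seed + 1L)
  known <- generate_reference_proteome(tx$transcripts,
                                       variant_sources = variant_sources,
                                       seed = seed + 1L)

  # peptide selection: all canonical peptides capped at 4 per protein,
  # up to 2 peptides per detected microprotein
  canon_pep <- do.call(rbind, lapply(seq_len(nrow(reference)), function(i) {
    peps <- unique(tryptic_digest(reference$aa_sequence[i]))
    peps <- head(peps, 4L)
    if (!length(peps)) return(NULL)
    data.frame(peptide = peps, protein_id = reference$accession[i],
               stringsAsFactors = FALSE)
  }))
  micro_tab <- do.call(rbind, lapply(detected, function(i) {
    data.frame(peptide = head(micro_pep[[i]], 2L),
               protein_id = micro$sorf_id[i], stringsAsFactors = FALSE)
  }))
  peptide_map <- rbind(canon_pep, micro_tab)
  peptide_map <- peptide_map[!duplicated(peptide_map$peptide), , drop = FALSE]

  # planted novel peptides: microprotein peptides that genuinely pass the
  # novelty filter (rejection against the generated databases makes every
  # planted item realisable)
  micro_rows <- peptide_map$protein_id %in% micro$sorf_id
  verdicts <- filter_novel(peptide_map$peptide[micro_rows], reference,
                           known)$verdicts
  planted_novel <- verdicts$peptide[verdicts$stage == "novel"]
  expected_similar <- verdicts$peptide[verdicts$stage != "novel"]

  novel_prots <- unique(peptide_map$protein_id[
    micro_rows & peptide_map$peptide %in% planted_novel])

  # planted effects: first n_up detected microproteins with novel evidence
  up_prots <- head(novel_prots, n_up)
  act <- setdiff(conditions, conditions[1L])
  effects <- if (length(up_prots) && length(act)) {
    expand.grid(protein_id = up_prots, condition = act,
                stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(0), condition = character(0))
  }
  effects$fc <- rep(planted_fc, nrow(effects))

  assays <- if (nascent_assays) c("global", "nascent_OPP",
                                  "nascent_CHX_OPP") else "global"
  design <- make_design(conditions = conditions, assays = assays)
  nascent_set <- if (length(novel_prots)) {
    novel_prots[seq_along(novel_prots) %% 2L == 1L]
  } else character(0)

  peptide_table <- simulate_intensities(
    design, peptide_map, effects = effects, sigma_log2 = sigma_log2,
    donor_sd = donor_sd, nascent_set = nascent_set, seed = seed + 2L
  )

  spectra <- simulate_spectra(planted_novel, dropout_p = dropout_p,
                              jitter_sd_da = jitter_sd_da,
                              n_noise_peaks = n_noise_peaks,
                              seed = seed + 3L)

  classes <- c(setNames(rep("canonical", nrow(reference)),
                        reference$accession),
               setNames(rep("microprotein", nrow(micro)), micro$sorf_id))

  list(
    transcripts = tx$transcripts, reference = reference, known = known,
    design = design, peptide_table = peptide_table, spectra = spectra,
    truth = list(planted_sorfs = micro, planted_novel_peptides = planted_novel,
                 expected_similar_peptides = expected_similar,
                 planted_effects = effects, nascent_set = nascent_set,
                 variant_protein = variant_protein, classes = classes,
                 seed = seed)
  )
}
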