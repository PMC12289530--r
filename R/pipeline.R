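# End-to-end orchestration: config handling, stage composition, report.

#' Default pipeline configuration
#'
#' All thresholds of the workflow with their defaults: ORF calling
#' (start codons ATG/CTG/GTG, 7-200 aa), novelty (80 percent similarity
#' cutoff), spectral QC (0.02 Da tolerance; reporting thresholds
#' 0.5/0.7/0.75), differential expression (fold change 2 / 0.5 at BH
#' adjusted p < 0.05), candidate selection (similarity > 0.75, donor fold
#' change > 1.50 in at least 2 donors) and the nascent-labeling OPP/CHX
#' ratio (2).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    transcript_fasta = NULL, annotation = NULL,
    reference_fasta = NULL, known_fasta = NULL,
    external_dbs = character(0),
    peptide_table = NULL, design = NULL, mgf = NULL,
    out_dir = NULL,
    start_codons = DEFAULT_START_CODONS, min_aa = 7L, max_aa = 200L,
    emit_all_starts = FALSE,
    similarity_cutoff = 80,
    tolerance_da = 0.02, spectral_thresholds = c(0.5, 0.7, 0.75),
    baseline_condition = "unstim",
    dep_fc_up = 2, dep_fc_down = 0.5, dep_alpha = 0.05,
    cand_sim = 0.75, cand_fc = 1.50, cand_min_donors = 2L,
    nascent_min_ratio = 2,
    seed = 1L
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unset keys with
#' [default_config()] values and rejects unknown keys and out-of-range
#' thresholds.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return Complete, validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "),
          class = "sorfpipe_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$similarity_cutoff <= 0 || cfg$similarity_cutoff > 100 ||
      cfg$cand_sim < 0 || cfg$cand_sim > 1 ||
      cfg$dep_alpha <= 0 || cfg$dep_alpha >= 1 ||
      cfg$min_aa < 1 || cfg$max_aa < cfg$min_aa || cfg$tolerance_da <= 0) {
    stopf("config threshold out of documented range",
          class = "sorfpipe_config_error")
  }
  cfg
}

# Polynomial rolling hash (mod 2^31 - 1) over the canonical JSON rendering
# of the config; enough to tag a report with the settings that made it.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

stage_fail <- function(stage, err) {
  stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(err),
        class = "sorfpipe_stage_error")
}

#' Run the full microprotein discovery pipeline
#'
#' Stage order: build and merge the sORF database, two-stage novelty
#' filtering of peptides, peptide assignment with uniqueness flags,
#' genomic-context classification of evidenced sORFs, spectral similarity
#' QC, protein quantification, differential expression per activation
#' contrast, nascent labeling, and candidate selection. Canonical peptides
#' are assigned against the reference proteome and microprotein peptides
#' against the novel database, so canonical quantification is not destroyed
#' by redundant in-frame three-frame entries.
#'
#' @param config config list or YAML path (see [load_config()]).
#' @param data optional in-memory dataset (as from [simulate_dataset()]);
#'   when `NULL` all inputs are read from the configured paths.
#' @return The report: a nested list with per-stage counts, classification
#'   summary, similarity fractions, DEP counts, nascent labels and the
#'   candidate table. Written to `<out_dir>/report.json` (plus stage TSVs)
#'   when `out_dir` is set.
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  cfg <- load_config(config)
  if (is.null(data)) {
    data <- tryCatch(list(
      transcripts = read_transcripts(cfg$transcript_fasta, cfg$annotation),
      reference = read_database_fasta(cfg$reference_fasta),
      known = read_database_fasta(cfg$known_fasta),
      design = read_design(cfg$design),
      peptide_table = read_peptide_table(cfg$peptide_table),
      spectra = if (!is.null(cfg$mgf)) read_mgf(cfg$mgf) else NULL
    ), error = function(e) stage_fail("load_inputs", e))
  }
  report <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                 stages = list())

  # --- database construction -------------------------------------------
  db <- tryCatch({
    micro_db <- build_sorf_database(
      data$transcripts, start_codons = cfg$start_codons,
      min_aa = cfg$min_aa, max_aa = cfg$max_aa,
      emit_all_starts = cfg$emit_all_starts
    )
    ext <- lapply(cfg$external_dbs, read_database_fasta)
    n_raw <- nrow(micro_db) + sum(vapply(ext, nrow, 0L))
    merged <- merge_databases(c(list(micro_db), ext), dedup = TRUE)
    list(meta = micro_db, merged = merged, n_raw = n_raw)
  }, error = function(e) stage_fail("build_db", e))
  report$stages$build_db <- list(
    input = db$n_raw, removed = db$n_raw - nrow(db$merged),
    retained = nrow(db$merged)
  )

  # --- novelty filter ---------------------------------------------------
  peptides <- data$peptide_table$peptide
  nov <- tryCatch(
    filter_novel(peptides, data$reference, data$known,
                 cutoff = cfg$similarity_cutoff),
    error = function(e) stage_fail("novelty_filter", e)
  )
  report$stages$novelty_filter <- list(
    input = length(peptides),
    removed = sum(nov$verdicts$stage != "novel"),
    retained = length(nov$novel_peptides),
    refprot_hits = sum(nov$verdicts$stage == "refprot_hit"),
    similar_known = sum(nov$verdicts$stage == "similar_known")
  )

  # --- assignment -------------------------------------------------------
  assign <- tryCatch({
    canon_pep <- nov$verdicts$peptide[nov$verdicts$stage == "refprot_hit"]
    ref_dedup <- merge_databases(list(data$reference), dedup = TRUE)
    a_canon <- if (length(canon_pep)) {
      assign_peptides(canon_pep, ref_dedup)
    } else NULL
    a_micro <- if (length(nov$novel_peptides)) {
      assign_peptides(nov$novel_peptides, db$merged)
    } else NULL
    rbind(a_canon, a_micro)
  }, error = function(e) stage_fail("assign", e))
  report$stages$assign <- list(
    input = nrow(assign) %||% 0L,
    removed = sum(assign$unassigned),
    retained = sum(!assign$unassigned),
    unique_peptides = sum(assign$unique)
  )

  # --- classification ---------------------------------------------------
  cls <- tryCatch({
    novel_acc <- unique(unlist(strsplit(
      assign$accessions[assign$peptide %in% nov$novel_peptides &
                          !assign$unassigned], ";", fixed = TRUE)))
    sorfs <- db$meta[db$meta$accession %in% novel_acc, , drop = FALSE]
    names(sorfs)[names(sorfs) == "accession"] <- "sorf_id"
    if (nrow(sorfs)) classify_sorfs(sorfs, data$transcripts) else sorfs
  }, error = function(e) stage_fail("classify", e))
  report$stages$classify <- list(input = nrow(cls), removed = 0L,
                                 retained = nrow(cls))
  if (nrow(cls)) {
    report$classification <- summarize_sorfs(cls)
  }

  # --- spectral QC ------------------------------------------------------
  sim_by_protein <- numeric(0)
  if (!is.null(data$spectra) && length(data$spectra)) {
    qc <- tryCatch({
      scores <- vapply(data$spectra, function(sp) {
        if (is.na(sp$peptide)) return(NA_real_)
        theo <- theoretical_spectrum(sp$peptide)
        spectrum_similarity(sp, theo, tolerance_da = cfg$tolerance_da)$score
      }, numeric(1))
      scores <- scores[!is.na(scores)]
      peps <- vapply(data$spectra, `[[`, "", "peptide")
      prot_of <- setNames(assign$accessions, assign$peptide)
      by_prot <- tapply(scores, prot_of[names(scores)], max)
      list(scores = scores, by_prot = by_prot)
    }, error = function(e) stage_fail("spectra_qc", e))
    sim_by_protein <- qc$by_prot[!is.na(names(qc$by_prot))]
    report$stages$spectra_qc <- list(
      input = length(data$spectra),
      removed = length(data$spectra) - length(qc$scores),
      retained = length(qc$scores)
    )
    report$similarity_fractions <- as.list(
      similarity_fractions(qc$scores, cfg$spectral_thresholds)
    )
  }

  # --- quantification ---------------------------------------------------
  global <- data$design[data$design$assay == "global", , drop = FALSE]
  classes_vec <- {
    acc_all <- c(data$reference$accession, db$merged$accession)
    setNames(ifelse(acc_all %in% data$reference$accession,
                    "canonical", "microprotein"), acc_all)
  }
  quants <- tryCatch({
    tab <- data$peptide_table[data$peptide_table$peptide %in%
                                assign$peptide, , drop = FALSE]
    aggregate_proteins(tab, assign, classes_vec, global$sample_id)
  }, error = function(e) stage_fail("quantify", e))
  report$stages$quantify <- list(
    input = nrow(quants) + length(attr(quants, "dropped")),
    removed = length(attr(quants, "dropped")),
    retained = nrow(quants)
  )

  # --- differential expression -----------------------------------------
  base_cond <- cfg$baseline_condition
  act <- setdiff(unique(global$condition), base_cond)
  de <- tryCatch({
    res <- lapply(act, function(cond) {
      differential_expression(quants, global, c(cond, base_cond))
    })
    names(res) <- act
    res
  }, error = function(e) stage_fail("differential_expression", e))
  deps <- lapply(de, call_deps, fc_up = cfg$dep_fc_up,
                 fc_down = cfg$dep_fc_down, alpha = cfg$dep_alpha)
  report$dep_counts <- lapply(deps, function(d) {
    list(up = length(d$up), down = length(d$down))
  })
  n_tested <- if (length(de)) sum(!is.na(de[[1]]$p)) else 0L
  report$stages$differential_expression <- list(
    input = nrow(quants), removed = nrow(quants) - n_tested,
    retained = n_tested
  )

  # --- nascent labeling -------------------------------------------------
  opp_s <- data$design$sample_id[data$design$assay == "nascent_OPP"]
  chx_s <- data$design$sample_id[data$design$assay == "nascent_CHX_OPP"]
  nascent <- tryCatch({
    if (length(opp_s)) {
      full_tab <- data$peptide_table[data$peptide_table$peptide %in%
                                       assign$peptide, , drop = FALSE]
      nq <- aggregate_proteins(full_tab, assign, classes_vec,
                               c(opp_s, chx_s))
      labels <- vapply(quants$protein_id, function(p) {
        r <- nq[nq$protein_id == p, , drop = FALSE]
        if (!nrow(r)) return("pre_existing")
        label_nascent(unlist(r[1, opp_s]), unlist(r[1, chx_s]),
                      min_ratio = cfg$nascent_min_ratio)
      }, character(1))
      labels
    } else {
      setNames(rep("pre_existing", nrow(quants)), quants$protein_id)
    }
  }, error = function(e) stage_fail("nascent", e))
  micro_ids <- quants$protein_id[quants$protein_class == "microprotein"]
  report$nascent_counts <- list(
    nascent = sum(nascent[micro_ids] == "nascent"),
    pre_existing = sum(nascent[micro_ids] == "pre_existing")
  )

  # --- candidates -------------------------------------------------------
  cand <- tryCatch({
    micro_de <- lapply(de, function(r) {
      r[r$protein_class == "microprotein", , drop = FALSE]
    })
    if (length(micro_de) && any(vapply(micro_de, nrow, 0L) > 0)) {
      select_candidates(micro_de, sim_by_protein,
                        sim_threshold = cfg$cand_sim,
                        fc_threshold = cfg$cand_fc,
                        min_donors = cfg$cand_min_donors)
    } else {
      data.frame(protein_id = character(0))
    }
  }, error = function(e) stage_fail("candidates", e))
  report$stages$candidates <- list(
    input = nrow(cand),
    removed = sum(!(cand$passes %||% logical(0))),
    retained = sum(cand$passes %||% logical(0))
  )
  report$candidates <- cand

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_database_fasta(db$merged, file.path(cfg$out_dir, "database.fasta"))
    write.table(nov$verdicts, file.path(cfg$out_dir, "verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cls)) {
      write.table(cls[, c("sorf_id", "transcript_id", "start", "end",
                          "frame", "start_codon", "category")],
                  file.path(cfg$out_dir, "classified_sorfs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (cond in names(de)) {
      write.table(de[[cond]],
                  file.path(cfg$out_dir, sprintf("de_%s.tsv", cond)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(cand)) {
      write.table(cand, file.path(cfg$out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}

#' Validate a pipeline report against the bundled schema
#'
#' The schema (`inst/extdata/report_schema.json`) lists the required
#' top-level fields, required per-stage count fields and their types.
#'
#' @param report report list from [run_pipeline()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json", package = "sorfpipe")
  )
  miss <- setdiff(unlist(schema$required), names(report))
  if (length(miss)) {
    stopf("report lacks fields: %s", paste(miss, collapse = ", "),
          class = "sorfpipe_schema_error")
  }
  for (st in names(report$stages)) {
    smiss <- setdiff(unlist(schema$stage_required),
                     names(report$stages[[st]]))
    if (length(smiss)) {
      stopf("stage '%s' lacks counts: %s", st,
            paste(smiss, collapse = ", "), class = "sorfpipe_schema_error")
    }
    cnt <- report$stages[[st]]
    if (cnt$retained + cnt$removed != cnt$input &&
        !st %in% unlist(schema$nonconserving_stages)) {
      stopf("stage '%s' violates retained + removed = input", st,
            class = "sorfpipe_schema_error")
    }
  }
  invisible(TRUE)
}
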