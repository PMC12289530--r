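# Protein quantification, differential expression and candidate selection.

#' Aggregate unique-peptide intensities to protein level
#'
#' Only peptides flagged unique contribute. Per protein and sample the
#' intensity is the sum of its unique peptides' observed intensities
#' (missing values stay missing; they are absence, not zero). Proteins then
#' face the class-specific evidence rule: canonical proteins need at least
#' two unique peptides, microproteins one. Failing proteins are dropped and
#' listed in the `dropped` attribute.
#'
#' @param peptide_table data.frame with `peptide` and one numeric intensity
#'   column per sample (NA = not observed).
#' @param assignments output of [assign_peptides()] covering every peptide.
#' @param classes named character vector mapping accession to
#'   `"canonical"` or `"microprotein"`.
#' @param sample_ids character; which columns of `peptide_table` hold
#'   intensities.
#' @return data.frame with `protein_id`, `protein_class`,
#'   `n_unique_peptides` and one column per sample; attribute `dropped`
#'   names the proteins failing the evidence rule.
#' @export
aggregate_proteins <- function(peptide_table, assignments, classes,
                               sample_ids) {
  idx <- match(peptide_table$peptide, assignments$peptide)
  if (anyNA(idx)) {
    stopf("assignments do not cover all peptides",
          class = "sorfpipe_input_error")
  }
  a <- assignments[idx, ]
  uniq <- a$unique & !a$unassigned
  tab <- peptide_table[uniq, , drop = FALSE]
  prot <- a$accessions[uniq]
  prots <- unique(prot)
  rows <- lapply(prots, function(p) {
    sub <- tab[prot == p, sample_ids, drop = FALSE]
    ints <- vapply(sample_ids, function(s) {
      v <- sub[[s]]
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }, numeric(1))
    cls <- unname(classes[p])
    c(list(protein_id = p,
           protein_class = if (is.na(cls)) "microprotein" else cls,
           n_unique_peptides = nrow(sub)),
      as.list(ints))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0),
                      protein_class = character(0),
                      n_unique_peptides = integer(0))
    for (s in sample_ids) out[[s]] <- numeric(0)
    attr(out, "dropped") <- character(0)
    return(out)
  }
  min_pep <- ifelse(out$protein_class == "canonical", 2L, 1L)
  keep <- out$n_unique_peptides >= min_pep
  dropped <- out$protein_id[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Log2 fold change between two sample groups
#'
#' `log2(mean(observed intensities in a) / mean(observed in b))`; means are
#' taken over observed (non-missing) values only. A group with no observed
#' value yields `NA` (undefined fold change; the protein is skipped for the
#' contrast).
#'
#' @param intensities named numeric vector (sample -> intensity, NA
#'   allowed).
#' @param group_a,group_b character vectors of sample ids.
#' @return numeric scalar, possibly `NA`.
#' @export
log2_fold_change <- function(intensities, group_a, group_b) {
  a <- intensities[group_a]
  b <- intensities[group_b]
  if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
  log2(mean(a, na.rm = TRUE) / mean(b, na.rm = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort ascending, `q_i = p_i * m / i`, enforce
#' monotone non-decreasing from the largest rank down, cap at 1, return in
#' the original order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p values must be in [0, 1]", class = "sorfpipe_input_error")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

#' Differential expression between two conditions
#'
#' Per protein: a two-sided two-sample t test (equal variance by default)
#' on log2-transformed intensities, BH adjustment across all tested
#' proteins, the group-mean log2 fold change, and within-donor raw
#' fold changes `mean(condition_a) / mean(condition_b)`. Proteins observed
#' in fewer than 2 samples of either group are reported with fold change
#' only (`p = NA`). Groups that are both constant get `p = 1` when their
#' means are equal and `p = 0` otherwise.
#'
#' @param quants output of [aggregate_proteins()].
#' @param design data.frame with `sample_id`, `donor`, `condition`.
#' @param contrast character length 2: `c(condition_a, condition_b)` —
#'   fold changes are a over b.
#' @param var_equal logical; `FALSE` gives Welch's t test.
#' @return data.frame with `protein_id`, `protein_class`, `log2fc`, `p`,
#'   `adj_p` and one `fc_donor_<d>` column per donor.
#' @export
differential_expression <- function(quants, design, contrast,
                                    var_equal = TRUE) {
  stopifnot(length(contrast) == 2L)
  sa <- design$sample_id[design$condition == contrast[1L]]
  sb <- design$sample_id[design$condition == contrast[2L]]
  if (!length(sa) || !length(sb)) {
    stopf("contrast conditions absent from design",
          class = "sorfpipe_input_error")
  }
  donors <- sort(unique(design$donor))
  res <- lapply(seq_len(nrow(quants)), function(i) {
    ints <- unlist(quants[i, c(sa, sb), drop = FALSE])
    a <- ints[sa]; b <- ints[sb]
    l2fc <- log2_fold_change(ints, sa, sb)
    p <- NA_real_
    ao <- a[!is.na(a)]; bo <- b[!is.na(b)]
    if (length(ao) >= 2L && length(bo) >= 2L) {
      la <- log2(ao); lb <- log2(bo)
      if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
        p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
      } else {
        p <- t.test(la, lb, var.equal = var_equal)$p.value
      }
    }
    dfc <- vapply(donors, function(d) {
      ds <- design$sample_id[design$donor == d]
      log2_fold_change(ints, intersect(sa, ds), intersect(sb, ds))
    }, numeric(1))
    c(list(protein_id = quants$protein_id[i],
           protein_class = quants$protein_class[i],
           log2fc = l2fc, p = p),
      setNames(as.list(2^dfc), paste0("fc_donor_", donors)))
  })
  out <- do.call(rbind, lapply(res, as.data.frame, stringsAsFactors = FALSE))
  out$adj_p <- NA_real_
  tested <- !is.na(out$p)
  out$adj_p[tested] <- bh_adjust(out$p[tested])
  cols <- c("protein_id", "protein_class", "log2fc", "p", "adj_p")
  out[, c(cols, setdiff(names(out), cols)), drop = FALSE]
}

#' Call differentially expressed proteins
#'
#' Strict thresholds on the linear fold change `FC = 2^log2fc` and the
#' BH-adjusted p value: up-regulated iff `FC > fc_up` and `adj_p < alpha`;
#' down-regulated iff `FC < fc_down` and `adj_p < alpha`. A protein sitting
#' exactly on a threshold is not called.
#'
#' @param results output of [differential_expression()] for one contrast.
#' @param fc_up,fc_down,alpha thresholds.
#' @return list with character vectors `up` and `down`.
#' @export
call_deps <- function(results, fc_up = 2, fc_down = 0.5, alpha = 0.05) {
  fc <- 2^results$log2fc
  ok <- !is.na(fc) & !is.na(results$adj_p)
  list(up = results$protein_id[ok & fc > fc_up & results$adj_p < alpha],
       down = results$protein_id[ok & fc < fc_down & results$adj_p < alpha])
}

#' Label a protein nascent or pre-existing
#'
#' A protein is nascent iff it is detected in an OPP-enriched sample and its
#' mean OPP intensity exceeds `min_ratio` times its mean intensity under the
#' CHX + OPP control (cycloheximide blocks elongation, so residual signal
#' there is background). An absent CHX signal is treated as the detection
#' floor, so any OPP detection without CHX signal is nascent. A protein seen
#' only in the global assay is pre-existing.
#'
#' @param opp_intensities,chx_opp_intensities numeric vectors (NA = not
#'   observed) for the OPP and CHX+OPP conditions.
#' @param min_ratio required OPP / CHX+OPP enrichment.
#' @param detected_global logical; was the protein seen in the global assay
#'   (used only to verify the protein exists somewhere).
#' @return `"nascent"` or `"pre_existing"`.
#' @export
label_nascent <- function(opp_intensities, chx_opp_intensities,
                          min_ratio = 2, detected_global = TRUE) {
  opp <- opp_intensities[!is.na(opp_intensities)]
  chx <- chx_opp_intensities[!is.na(chx_opp_intensities)]
  if (!length(opp) && !length(chx) && !detected_global) {
    stopf("protein absent from all assays", class = "sorfpipe_input_error")
  }
  if (!length(opp)) return("pre_existing")
  if (!length(chx)) return("nascent")
  if (mean(opp) > min_ratio * mean(chx)) "nascent" else "pre_existing"
}

#' Select candidate microproteins
#'
#' A microprotein passes iff (i) its best spectral similarity is strictly
#' above `sim_threshold` and (ii) in at least one of the supplied activation
#' contrasts at least `min_donors` donors show a raw within-donor fold
#' change strictly above `fc_threshold`. Failure reasons are recorded per
#' protein.
#'
#' @param micro_results named list of [differential_expression()] outputs,
#'   one per activation contrast, restricted to microproteins.
#' @param similarity named numeric vector: protein -> best spectral
#'   similarity score.
#' @param sim_threshold,fc_threshold,min_donors selection thresholds.
#' @return data.frame with `protein_id`, `max_spectral_similarity`,
#'   `n_supporting_donors` (best contrast), `passes`, `reasons`.
#' @export
select_candidates <- function(micro_results, similarity,
                              sim_threshold = 0.75, fc_threshold = 1.50,
                              min_donors = 2L) {
  stopifnot(length(micro_results) >= 1L)
  prots <- unique(unlist(lapply(micro_results, `[[`, "protein_id")))
  rows <- lapply(prots, function(p) {
    sim <- if (p %in% names(similarity)) unname(similarity[[p]]) else NA_real_
    support <- vapply(micro_results, function(res) {
      r <- res[res$protein_id == p, , drop = FALSE]
      if (!nrow(r)) return(0L)
      fcs <- unlist(r[1, grepl("^fc_donor_", names(r)), drop = FALSE])
      sum(!is.na(fcs) & fcs > fc_threshold)
    }, integer(1))
    n_support <- max(support)
    reasons <- character(0)
    if (is.na(sim) || sim <= sim_threshold) {
      reasons <- c(reasons, sprintf("spectral similarity %s not above %.2f",
                                    ifelse(is.na(sim), "missing",
                                           format(sim, digits = 3)),
                                    sim_threshold))
    }
    if (n_support < min_donors) {
      reasons <- c(reasons,
                   sprintf("only %d donor(s) with fold change > %.2f",
                           n_support, fc_threshold))
    }
    data.frame(protein_id = p,
               max_spectral_similarity = if (is.na(sim)) NA_real_ else sim,
               n_supporting_donors = n_support,
               passes = length(reasons) == 0L,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
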