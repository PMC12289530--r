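# Theoretical b/y fragment spectra and spectral similarity scoring.

#' Construct a spectrum object
#'
#' @param mz,intensity numeric vectors of equal length; peaks are sorted by
#'   ascending m/z.
#' @param peptide optional backbone sequence the spectrum belongs to.
#' @param precursor_charge integer precursor charge state.
#' @return An object of class `spectrum`: a list with `peptide`,
#'   `precursor_charge` and a `peaks` data.frame (`mz`, `intensity`).
#' @export
spectrum <- function(mz, intensity = rep(1, length(mz)), peptide = NA,
                     precursor_charge = 2L) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  if (length(mz) && any(mz <= 0)) {
    stopf("m/z values must be positive", class = "sorfpipe_input_error")
  }
  ord <- order(mz)
  structure(
    list(peptide = peptide, precursor_charge = as.integer(precursor_charge),
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, charge %d, %d peaks\n",
              if (is.na(x$peptide)) "(no peptide)" else x$peptide,
              x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Theoretical b/y-ion fragment spectrum of a peptide
#'
#' Monoisotopic fragment masses from the standard residue-mass table:
#' `b_i` = sum of the first i residues + proton; `y_i` = sum of the last i
#' residues + water + proton. For charge z the m/z is
#' `(neutral fragment + z * proton) / z`. All peaks carry uniform intensity
#' 1 (a deliberate, deterministic stand-in for learned intensity
#' prediction). Carbamidomethylation of cysteine (+57.02146 Da) is applied
#' as a fixed modification by default, matching the standard alkylation
#' protocol.
#'
#' @param peptide backbone sequence, length >= 2, standard residues only.
#' @param fragment_charges integer vector of fragment charge states.
#' @param ion_series subset of `c("b", "y")`.
#' @param carbamidomethyl logical; fixed +57.02146 on C.
#' @return A `spectrum` object with `ion` and `charge` annotation columns.
#' @export
theoretical_spectrum <- function(peptide, fragment_charges = 1L,
                                 ion_series = c("b", "y"),
                                 carbamidomethyl = TRUE) {
  check_protein(peptide)
  stopifnot(nchar(peptide) >= 2L, all(ion_series %in% c("b", "y")),
            length(ion_series) >= 1L, all(fragment_charges >= 1L))
  aa <- strsplit(peptide, "")[[1]]
  if (any(aa == "X")) {
    stopf("cannot compute masses for unknown residue X",
          class = "sorfpipe_input_error")
  }
  res_mass <- RESIDUE_MASS[aa]
  if (carbamidomethyl) res_mass[aa == "C"] <- res_mass[aa == "C"] +
      CARBAMIDOMETHYL_MASS
  n <- length(aa)
  prefix <- cumsum(res_mass)          # b-ion neutral residue sums
  suffix <- rev(cumsum(rev(res_mass)))  # suffix sums
  frag <- list()
  for (z in fragment_charges) {
    if ("b" %in% ion_series) {
      neutral <- prefix[seq_len(n - 1L)]
      frag[[length(frag) + 1L]] <- data.frame(
        mz = (neutral + z * PROTON_MASS) / z,
        ion = sprintf("b%d^%d", seq_len(n - 1L), z), charge = z
      )
    }
    if ("y" %in% ion_series) {
      neutral <- suffix[n + 1L - seq_len(n - 1L)] + WATER_MASS
      frag[[length(frag) + 1L]] <- data.frame(
        mz = (neutral + z * PROTON_MASS) / z,
        ion = sprintf("y%d^%d", seq_len(n - 1L), z), charge = z
      )
    }
  }
  pk <- do.call(rbind, frag)
  ord <- order(pk$mz)
  sp <- spectrum(pk$mz[ord], rep(1, nrow(pk)), peptide = peptide,
                 precursor_charge = max(fragment_charges) + 1L)
  sp$peaks$ion <- pk$ion[ord]
  sp$peaks$charge <- pk$charge[ord]
  sp
}

#' Match experimental peaks to theoretical peaks
#'
#' Greedy nearest-neighbour matching within an absolute tolerance: candidate
#' pairs are ranked by ascending `|delta m/z|` (ties to the lower m/z) and
#' accepted greedily, so each theoretical and each experimental peak is used
#' at most once.
#'
#' @param experimental,theoretical `spectrum` objects.
#' @param tolerance_da absolute matching tolerance in Da.
#' @return data.frame with columns `exp_idx`, `theo_idx`, `delta_mz`
#'   (possibly zero rows).
#' @export
match_peaks <- function(experimental, theoretical, tolerance_da = 0.02) {
  em <- experimental$peaks$mz
  tm <- theoretical$peaks$mz
  none <- data.frame(exp_idx = integer(0), theo_idx = integer(0),
                     delta_mz = numeric(0))
  if (!length(em) || !length(tm)) return(none)
  d <- abs(outer(em, tm, "-"))
  cand <- which(d <= tolerance_da, arr.ind = TRUE)
  if (!nrow(cand)) return(none)
  dd <- d[cand]
  ord <- order(dd, em[cand[, 1L]], tm[cand[, 2L]])
  cand <- cand[ord, , drop = FALSE]
  used_e <- logical(length(em))
  used_t <- logical(length(tm))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_e[i] && !used_t[j]) {
      used_e[i] <- TRUE; used_t[j] <- TRUE; keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(exp_idx = cand[, 1L], theo_idx = cand[, 2L],
                    delta_mz = em[cand[, 1L]] - tm[cand[, 2L]])
  out[order(out$theo_idx), , drop = FALSE]
}

#' Spectral similarity between an experimental and a theoretical spectrum
#'
#' Normalised dot product (cosine) of square-root-transformed intensity
#' vectors laid out over the union of matched and unmatched peak slots:
#' matched slots contribute `sqrt(I_exp * I_theo)` to the cross term while
#' every peak, matched or not, contributes to its own norm. The score lies
#' in `[0, 1]`; 1 means every peak of either spectrum is matched with
#' proportional intensities, 0 means no peak matches within tolerance.
#'
#' @inheritParams match_peaks
#' @param transform intensity transform before the cosine; `"sqrt"`
#'   (default) or `"none"`.
#' @return list with `score`, `n_matched`, `n_theoretical`.
#' @export
spectrum_similarity <- function(experimental, theoretical,
                                tolerance_da = 0.02, transform = "sqrt") {
  nt <- nrow(theoretical$peaks)
  if (nt == 0L) {
    stopf("theoretical spectrum is empty", class = "sorfpipe_input_error")
  }
  ne <- nrow(experimental$peaks)
  if (ne == 0L) return(list(score = 0, n_matched = 0L, n_theoretical = nt))
  tr <- switch(transform, sqrt = sqrt, none = identity,
               stopf("unknown transform '%s'", transform,
                     class = "sorfpipe_input_error"))
  m <- match_peaks(experimental, theoretical, tolerance_da)
  ei <- tr(experimental$peaks$intensity)
  ti <- tr(theoretical$peaks$intensity)
  cross <- sum(ei[m$exp_idx] * ti[m$theo_idx])
  denom <- sqrt(sum(ei^2)) * sqrt(sum(ti^2))
  score <- if (denom == 0) 0 else cross / denom
  list(score = min(max(score, 0), 1), n_matched = nrow(m),
       n_theoretical = nt)
}

#' Fraction of similarity scores strictly above each threshold
#'
#' @param scores numeric vector of scores in `[0, 1]`.
#' @param thresholds numeric vector of thresholds.
#' @return Named numeric vector: `fraction(t) = |{s > t}| / n`.
#' @export
similarity_fractions <- function(scores, thresholds = c(0.5, 0.7, 0.75)) {
  if (!length(scores)) {
    stopf("empty score list", class = "sorfpipe_input_error")
  }
  stopifnot(all(scores >= 0 & scores <= 1))
  setNames(vapply(thresholds, function(t) mean(scores > t), numeric(1)),
           format(thresholds))
}
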