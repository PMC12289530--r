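# Independent brute-force oracles. Each one re-derives its answer from
# first principles (hand-typed codon table, exhaustive scans, naive DP) and
# shares no code with the implementation it checks.

ORACLE_CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(sapply(bases, function(b1) {
    sapply(bases, function(b2) paste0(b1, b2, bases))
  }))
  aas <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

oracle_translate <- function(dna, init_met = FALSE) {
  n <- nchar(dna)
  out <- character(n %/% 3)
  for (k in seq_len(n %/% 3)) {
    codon <- substr(dna, 3 * k - 2, 3 * k)
    out[k] <- if (grepl("N", codon)) "X" else ORACLE_CODON_TABLE[[codon]]
  }
  if (init_met && length(out)) out[1] <- "M"
  paste(out, collapse = "")
}

# Exhaustive per-codon scan over all three frames.
oracle_find_sorfs <- function(sequence, start_codons, min_aa, max_aa,
                              emit_all_starts = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(sequence)
  rows <- list()
  if (n >= 3) {
    for (s in 0:(n - 3)) {
      if (!(substr(sequence, s + 1, s + 3) %in% start_codons)) next
      e <- NA_integer_
      p <- s + 3
      while (p + 3 <= n) {
        if (substr(sequence, p + 1, p + 3) %in% stops) {
          e <- p + 3L
          break
        }
        p <- p + 3
      }
      if (is.na(e)) next
      aa_len <- (e - s) / 3 - 1
      if (aa_len < min_aa || aa_len > max_aa) next
      rows[[length(rows) + 1]] <- data.frame(start = s, end = e,
                                             frame = s %% 3)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0)))
  }
  out <- do.call(rbind, rows)
  if (!emit_all_starts) {
    out <- do.call(rbind, lapply(split(out, out$end), function(g) {
      g[which.min(g$start), ]
    }))
  }
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# Naive all-pairs substring scan.
oracle_substring_hits <- function(peptides, proteins, il = TRUE) {
  f <- function(x) if (il) chartr("I", "L", x) else x
  vapply(peptides, function(p) {
    any(vapply(proteins, function(q) grepl(f(p), f(q), fixed = TRUE),
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# Full-matrix Smith-Waterman (match +1 / mismatch 0 / gap -1) maximising
# (score, identities) lexicographically.
oracle_sw_identity <- function(pep, prot) {
  P <- strsplit(pep, "")[[1]]
  Q <- strsplit(prot, "")[[1]]
  m <- length(P); n <- length(Q)
  H <- matrix(0L, m + 1, n + 1)
  M <- matrix(0L, m + 1, n + 1)
  best_h <- 0L; best_m <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- if (P[i] == Q[j]) 1L else 0L
      h <- 0L; mm <- 0L
      ch <- H[i, j] + sc; cm <- M[i, j] + sc
      if (ch > h || (ch == h && cm > mm)) { h <- ch; mm <- cm }
      ch <- H[i, j + 1] - 1L; cm <- M[i, j + 1]
      if (ch > h || (ch == h && cm > mm)) { h <- ch; mm <- cm }
      ch <- H[i + 1, j] - 1L; cm <- M[i + 1, j]
      if (ch > h || (ch == h && cm > mm)) { h <- ch; mm <- cm }
      H[i + 1, j + 1] <- h; M[i + 1, j + 1] <- mm
      if (h > best_h || (h == best_h && mm > best_m)) {
        best_h <- h; best_m <- mm
      }
    }
  }
  c(score = best_h, identities = best_m)
}

oracle_max_similarity <- function(pep, proteins) {
  100 * max(vapply(proteins, function(q) {
    oracle_sw_identity(pep, q)[["identities"]]
  }, numeric(1))) / nchar(pep)
}

# Exhaustive peak assignment: maximum-cardinality matching within
# tolerance, minimal total |delta mz| among those. Feasible for <= 8
# theoretical peaks.
oracle_match_peaks <- function(exp_mz, theo_mz, tol) {
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  recurse <- function(j, used, pairs, cost) {
    if (j > length(theo_mz)) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    recurse(j + 1L, used, pairs, cost)  # leave theo peak j unmatched
    for (i in seq_along(exp_mz)) {
      d <- abs(exp_mz[i] - theo_mz[j])
      if (!used[i] && d <= tol) {
        used2 <- used; used2[i] <- TRUE
        recurse(j + 1L, used2,
                rbind(pairs, data.frame(exp_idx = i, theo_idx = j)), cost + d)
      }
    }
  }
  recurse(1L, logical(length(exp_mz)),
          data.frame(exp_idx = integer(0), theo_idx = integer(0)), 0)
  best$pairs[order(best$pairs$theo_idx), , drop = FALSE]
}

# Regex-based tryptic digestion (split on K/R not before P, then join
# adjacent fragments).
oracle_tryptic <- function(prot, max_missed = 2, min_len = 7,
                           max_len = 30) {
  frags <- strsplit(prot, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(frags)) {
    for (j in i:min(length(frags), i + max_missed)) {
      pep <- paste(frags[i:j], collapse = "")
      if (nchar(pep) >= min_len && nchar(pep) <= max_len) {
        out <- c(out, pep)
      }
    }
  }
  out
}

random_peptide <- function(min_len = 7, max_len = 15) {
  alpha <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  paste(sample(alpha, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

random_protein <- function(min_len = 40, max_len = 80) {
  random_peptide(min_len, max_len)
}

random_transcript_row <- function(tid, len = 300) {
  data.frame(
    transcript_id = tid, gene_id = NA_character_, biotype = "noncoding",
    sequence = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""),
    cds_start = NA_integer_, cds_end = NA_integer_, stringsAsFactors = FALSE
  )
}
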