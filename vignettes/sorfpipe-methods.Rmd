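---
title: "sorfpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sorfpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfpipe)
```

## The problem

Microproteins are translated from small open reading frames (sORFs) in
transcript regions conventionally annotated as noncoding: lncRNAs, 5'
and 3' UTRs, shifted reading frames inside canonical CDSs, and
unannotated transcripts. Because they are missing from reference protein
databases, a standard database search can never identify them; and
because a three-frame translated custom database is hugely redundant,
naive searches drown in false positives. `sorfpipe` implements the
downstream computational workflow: custom database construction, a
stringent novelty filter, genomic-context classification, spectral
confidence scoring, and rule-based quantification with candidate
selection — plus a seeded generator that fabricates every input with
known ground truth.

## sORF enumeration

Transcripts are scanned in their three forward frames (transcripts are
assumed oriented 5'→3'; there is no reverse-complement stage, since
genome-level work is out of scope). An sORF starts at a codon from the
configured start set and ends at the first in-frame stop; ORFs whose
stop lies beyond the transcript end are discarded as unverifiable.
Coordinates are 0-based half-open in transcript space, with the stop
codon inside `[start, end)` but excluded from the protein, so
`length(aa) = (end - start)/3 - 1`. Near-cognate starts (CTG, GTG) are
translated as methionine at position 1, matching initiator-tRNA
behaviour.

Parameters and defaults:

| parameter | default | why |
|---|---|---|
| `start_codons` | ATG, CTG, GTG | ATG plus the two most common near-cognate starts; observed alternative-start usage in microprotein surveys is ≈ 8% |
| `min_aa` | 7 | shortest peptide the search space can evidence (peptide length range 7–30) |
| `max_aa` | 200 | microproteins are reported up to ~200 aa (most < 100, median ~44) |
| `emit_all_starts` | `FALSE` | one ORF per (frame, stop) — the most upstream qualifying start — to cap database redundancy, a known false-positive risk of merged custom databases |

`build_sorf_database()` derives accessions as
`transcript_id:start-end:frame`, so every entry remains traceable;
`merge_databases()` collapses identical amino-acid sequences (first-seen
accession wins, contributing sources recorded) because redundant entries
multiply the effective search space without adding information.

## Novelty filtering

The filter runs in the order: substring stage, then similarity stage.

**Stage 1** removes any peptide occurring verbatim inside a reference
protein. Isoleucine/leucine are collapsed by default at this stage
(`il_reference = TRUE`): the residues are isobaric and no fragment
spectrum can distinguish them, so treating them as distinct would let
trivially explainable peptides masquerade as novel.

**Stage 2** computes, for each surviving peptide, the best
Smith–Waterman local alignment (match +1, mismatch 0, gap −1, linear
gaps) against every known protein, and reports
`100 × identities / peptide length`. Peptides strictly above the 80%
cutoff are excluded as likely isoforms or point mutants; exactly 80% is
retained (the contract is "similarity no more than 80%" for kept
peptides). Two deliberate choices:

* **Denominator = full peptide length**, not alignment length. A 7-of-7
  local match inside a 14-mer is 50%, not 100%: partial matches should
  not disqualify a peptide, while a near-complete match should. The
  setting is the point of the filter — excluding close variants — and
  alignment-length normalisation would make short perfect islands
  indistinguishable from near-identity.
* **Identity count from the identity-richest co-optimal alignment.**
  With this scoring scheme, co-optimal alignments can differ in match
  count (a gap and a mismatch can trade off), so "the identity count of
  the best alignment" is ill-defined without a tie-break. The DP
  maximises (score, identities) lexicographically, which is well-defined
  because appending the same alignment step preserves the lexicographic
  order. This is also why the scorer is implemented in-package (Rcpp)
  rather than delegated to a library aligner whose traceback picks an
  arbitrary co-optimal alignment. I/L are *not* collapsed at this stage
  by default (`il_known = FALSE`), mirroring protein BLAST.

Both stages partition their input exhaustively and disjointly, and
lowering the cutoff can only shrink the novel set (tested properties).

## Classification

Seven categories, decided in transcript coordinates against the host
transcript's own CDS `[cs, ce)`:

* biotype `novel` → **novel**; biotype `noncoding` → **lncRNA**;
* else `end ≤ cs` → **uORF**; `start < cs < end ≤ ce` → **uoORF**;
  `start ≥ ce` → **dORF**; `cs ≤ start < ce < end` → **doORF**;
  contained in the CDS with `(start − cs) mod 3 ≠ 0` → **intORF**.

Boundary conventions: an sORF abutting the CDS start (`end == cs`) is a
uORF, mirrored at the 3' end; an sORF contained in the CDS *in frame* is
a canonical-protein fragment and raises a classed error
(`sorfpipe_canonical_frame`) rather than a label — such sequences must
already have been removed by the novelty filter, so meeting one marks an
upstream fault. One geometry the rule list does not name — an sORF
spanning the entire CDS — is classified uoORF, extending the "upstream
overlap takes precedence" convention. When a peptide maps to sORFs on
several transcripts, precedence is coding > noncoding > novel, then
lowest transcript id.

## Spectral similarity

Theoretical spectra are uniform-intensity singly-charged b/y ladders
from the standard monoisotopic residue masses, with fixed
carbamidomethyl-C (+57.02146 Da) by default; this deliberately replaces
learned intensity prediction — the score then measures *peak-position*
agreement, which is what a deterministic, dependency-free QC needs.
Matching is greedy nearest-neighbour within an absolute tolerance
(default 0.02 Da, the usual high-resolution MS2 setting): candidate
pairs sorted by |Δm/z| (ties to lower m/z), each peak used at most once.
The score is the cosine of √-transformed intensity vectors laid over
matched and unmatched slots; unmatched peaks contribute to their own
norm but not to the cross term, so the score lives in [0, 1], equals 1
exactly for a perfect copy, and 0 when nothing matches. Reporting
thresholds 0.5 / 0.7 / 0.75 are the conventional confidence tiers; 0.75
is the *strict* lower bound for candidate selection.

## Quantification and selection

* Protein intensity = **sum** of its unique peptides' intensities, the
  common TMT convention; it also preserves additivity for the synthetic
  oracle. Missing values stay missing — absence of evidence, never zero.
* Evidence rule: canonical proteins need ≥ 2 unique peptides,
  microproteins ≥ 1 (microproteins are short; demanding two tryptic
  peptides would discard most of the class).
* In the pipeline, canonical peptides are assigned against the
  *reference proteome* and novel peptides against the *sORF database*.
  Assigning canonical peptides against the merged three-frame database
  would make essentially all of them non-unique (every canonical protein
  is shadowed by its own in-frame three-frame fragments) and silently
  destroy canonical quantification.
* Differential expression: equal-variance two-sided t test on log2
  intensities (Welch via `var_equal = FALSE`), BH adjustment across the
  contrast, fold change from group means of observed intensities. Groups
  need ≥ 2 observed samples; both-constant groups give p = 1 at equal
  means (0 otherwise). DEP thresholds are strict: FC > 2 (or < 0.5) and
  adj. p < 0.05; a protein exactly on a threshold is not called.
* Donor fold changes are computed within donor on raw mean intensities
  (condition a / condition b), read on the linear scale; candidate
  selection requires spectral similarity strictly > 0.75 *and* donor
  FC > 1.50 in ≥ 2 donors in at least one activation contrast, with
  every failed criterion recorded as a reason.
* Nascent labeling: a protein is nascent iff its mean OPP-enriched
  intensity exceeds `min_ratio` (default 2) times its mean under the
  CHX+OPP control (cycloheximide blocks elongation, so CHX signal is
  background); absent CHX signal counts as the detection floor, and a
  protein seen only in the global assay is pre-existing. The ratio is a
  config knob — no quantitative convention exists for this comparison.

## The synthetic world

`simulate_dataset()` states one fixed world; its defaults are the
conditions the pipeline is specified against, not tuning dials.

* **Transcriptome**: planted sORF lengths are log-normal with median 44
  aa (σ_log ≈ 0.45, clamped to 10–190), start codons ATG/CTG/GTG at
  92.2 / 4.8 / 3.0% — matching the reported length median and ~7.8%
  near-cognate fraction. Coding transcripts carry a stop-free random CDS
  (50–100 codons); one sORF is planted per transcript, cycling the five
  coding contexts plus lncRNA and novel. Construction is
  rejection-sampled: a draw is discarded when a random upstream start
  would displace the planted ORF under the most-upstream rule, or when
  an overlap would truncate the canonical protein below 20 aa. Overlap
  contexts (uoORF, doORF, intORF) force a frame shift — a planted ORF in
  the CDS frame would either park its stop codon inside the CDS (uoORF)
  or be absorbed into the CDS ORF (doORF).
* **Proteomes**: the reference (stage-1) set is the translated CDSs; the
  known (stage-2) set adds a spiked 1-residue variant of one planted
  microprotein, so the 80% stage always has real work to do (a 1-of-12
  variant puts its peptides at ≥ 91.7%).
* **Peptides**: in-silico tryptic digestion (cleave after K/R, not
  before P, ≤ 2 missed cleavages, 7–30 aa); up to 4 peptides per
  canonical protein and 2 per microprotein. Planted novel peptides are
  those that genuinely pass the novelty filter against the generated
  databases — rejection against the stated databases is what makes every
  planted item realisable.
* **Intensities**: log2 intensity = protein baseline (≈ log2 1e4, scale
  is irrelevant after the log) + fixed per-peptide ionisation offset
  (σ = 0.5) + per-donor protein effect (σ = 0.25) + planted condition
  effect (log2 FC) + measurement noise (σ_log2 = 0.3). Peptides of one
  protein share the protein-level effects. Planted activation effects
  default to FC 3 in both activation conditions.
* **Spectra**: theoretical b/y ladder degraded by peak dropout
  (p = 0.2), m/z jitter (σ = 0.005 Da, inside the 0.02 Da tolerance) and
  5 uniform noise peaks.
* Every generator call seeds its own stream and restores the caller's
  RNG state; the seed fully determines all outputs.

What the generator does **not** emulate: chromatography, isotope
envelopes, DIA interference, ratio compression from co-isolation,
between-plex normalisation, realistic codon usage or GC structure, and
shared peptides between paralogs. A green recovery test therefore
establishes that the *logic* of the pipeline is correct under its stated
noise model — not that the thresholds would perform identically on real
LC-MS data.

## Calibration notes on the acceptance simulations

Two choices in the acceptance suite deserve justification:

* **Type-I error of the DE test** is measured on an iid null
  (`donor_sd = 0`). With donor effects on, every donor appears in both
  groups, the groups are positively correlated, and the unpaired t test
  is *conservative* — a property of the paired design, not a
  miscalibration of the test. The iid null is the correct world for
  "same distribution in both groups, nominal α".
* **End-to-end recovery** (200 proteins, 10 planted at FC 3,
  σ_log2 = 0.3, 3 donors, 2 conditions) uses 2 technical replicates per
  donor × condition and 2 peptides per protein. A power calculation
  fixes this before running: with a single sample per donor × condition
  and one peptide, a null protein's donor log2-FC has σ ≈ 0.42, giving
  P(FC > 1.5) ≈ 0.084 per donor and ≈ 2% per protein for the
  2-of-3-donors rule — ~4 expected false candidates among 190 nulls per
  run, so *no* threshold-faithful pipeline could meet "zero nulls in
  ≥ 95% of runs" in that world. With technical duplicates (as stated for
  the nascent profiling design) and two summed peptides, the donor
  log2-FC σ drops to ≈ 0.21, the per-null pass rate to ≈ 2.5 × 10⁻⁵,
  and the requirement becomes attainable. The criterion presupposes this
  replication; the parameters were derived from the analysis, not fitted
  to a test outcome.

## Degenerate inputs and conventions

* Empty transcript/peptide/database inputs return empty results where
  the contract says so (empty sequence → no sORFs; empty known set →
  similarity 0) and classed errors where silence would hide a fault
  (empty reference proteome, empty score list, empty sORF summary).
* All thresholds are strict where the rules quote strict language
  ("above 0.75", "fold change > 2"): values exactly on a boundary fail.
* BH adjustment is the exact step-up (sort, `p·m/i`, monotone from the
  top, cap at 1, original order); ties need no special casing.
* Peak matching ties (equal |Δm/z|) resolve to the lower m/z pair;
  theoretical spectra use uniform intensity 1.0.
* Unknown config keys are rejected rather than ignored — a misspelled
  threshold must never silently fall back to a default.

## Known limitations

* The similarity stage scores the peptide, not the assembled
  microprotein; a microprotein whose every peptide clears 80% may still
  be globally similar to a known protein.
* Classification uses the host transcript's own annotation; multi-isoform
  genes with conflicting CDS annotations are resolved by the fixed
  precedence rule, not by evidence.
* The b/y calculator ignores neutral losses, isotopes and charge > 1 by
  default; scores are comparable within this pipeline, not against
  Prosit-style predictors.
* Quantification assumes intensities already normalised across samples;
  no plex/batch correction is applied.
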