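---
title: "Methods: immunopeptidome screening for cross-reactive TCR ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunopeptidome screening for cross-reactive TCR ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## Scope and model

`pepscreen` implements the computational funnel from HLA class I
immunopeptidome tables to nominated cross-reactive self-peptide candidates
for one autoreactive TCR. The package consumes the outputs of upstream tools
(de novo sequencing / genome matching produce the peptide table with
q-values and category labels; NetMHCpan produces the per-allele percent
ranks) and never re-implements them: its subject matter is everything that
happens *after* those tables exist.

### FDR filtering

Records are kept when `q_value <= threshold`. The comparison is inclusive:
a peptide with q = 0.0106 is, by construction, exactly the peptide that
survives a 1.06% threshold and the 10% screen but not the 1% screen.
"Category-specific" filtering is interpreted as the same per-record rule
with per-category reporting (`attr(, "category_counts")`); recomputing
q-values within categories is an upstream concern of the identification
pipeline, whose q-values we consume as given.

### Best-binder assignment

For each record the assigned allele is the argmin of percent rank over the
cell line's allele panel; the minimal rank is classified with inclusive
cutoffs (strong `<= 0.5`, weak `<= 2.0`, the NetMHCpan convention — the
boundary values 0.5 and 2.0 are binders). Ties are broken by allele-list
order, first wins; this is deterministic and documented rather than
meaningful. A record whose minimal rank exceeds the weak cutoff is a
non-binder and carries no assigned allele. Lengths 8–11 enter the binder
length table; other lengths are tallied separately.

Percentages in length tables are rounded **half up** to two decimals
(`round_half_up()`), because that is how such tables are conventionally
printed; base R's banker's rounding would flip some printed cells. Printed
summaries of 1/388-type cells can still disagree in the last digit between
truncation and rounding conventions; we round and do not chase truncated
sources.

### The recognition motif

The motif is estimated per peptide length (8 and 9) from the *stimulatory*
members of a ligand panel:

* position-probability matrix
  `p(i, a) = (n_{i,a} + c) / (n + 20 c)` with pseudocount `c = 1` by default
  (a count-based Laplace estimate; `c = 0` gives maximum likelihood and
  zero-probability cells);
* log-odds `log2(p(i, a) / b_a)` with uniform background `b_a = 1/20` by
  default (a peptidome-derived background may be supplied);
* **anchor positions** (nonamer P2/P7/P9, octamer P2/P8) with allowed
  residue sets that are *data-driven*: the residues observed among the
  panel's stimulatory peptides at that position, i.e. the empirical
  HLA-binding motif of the panel. A config can pin explicit sets instead.
* **contact positions** (nonamer P5/P8, octamer P5/P7) with the requirement
  that at least one of them carries a basic residue (R/K). Q is additionally
  admitted at P5 by default (`allow_q_p5`), because stimulatory mimotopes
  with Q5 exist; an `all`-positions mode is available as a config switch.

The octamer positions are not independently established biology: they scale
the nonamer scheme by C-terminal alignment (the C-terminal anchor stays
C-terminal, the contact pair shifts with it). This was an open design point;
the chosen defaults are fully config-overridable, and the tests verify the
behaviour of the *default reconstruction*, not any unpublished
parameterization.

A peptide passes when (length has a motif) ∧ (all anchors allowed) ∧
(contact rule) ∧ (summed log-odds ≥ threshold). The default threshold is 0
bits — better than background — and deliberately permissive: the anchor and
contact constraints do the discriminating, the score ranks. Screening sorts
passed candidates by descending score with lexicographic tie-break, which
makes the output order-invariant and reproducible bit-for-bit.

Information content per position is `log2(20) + Σ_a p log2 p` with
`0·log 0 = 0`, bounded in `[0, log2 20]`; a pseudocount strictly shrinks it
toward 0 for non-degenerate rows.

Non-stimulatory panel members do not enter the default matrix (positive-only
counts); a discriminative stimulatory-vs-non-stimulatory log-odds mode
exists behind `discriminative = TRUE` for exploration.

### Set analytics

`intersection_counts()` computes exclusive membership-pattern counts (each
unique peptide counted once under its full pattern), so pattern counts sum
to the union size. `overlap_fraction()` reports the shared count (symmetric)
and the percent of the first set (directional); the integer-rounded percent
is how such overlaps are quoted in running text, the two-decimal version is
also emitted.

### ERAP1 haplotyping

Diplotypes are called by translating phased nucleotide genotypes at the nine
defining coding SNPs into residue-state strings of the canonical ERAP1
isoform and looking those strings up in a key mapping them to Hap1–Hap10.
The key is an **editable JSON config**, not hard-coded: the authoritative
SNP-to-residue and string-to-haplotype definitions live in the haplotype
literature, and the file bundled here (`erap1_key_synthetic.json`) is a
clearly marked synthetic placeholder that exercises the machinery. All
round-trip guarantees (compose two key haplotypes → call them back, for all
pairs) hold for whatever key is loaded. Unphased heterozygous input is
refused with the list of consistent phasings rather than silently resolved;
statistical phasing is out of scope.

### Stimulation normalization

The assay literature says "normalized to" without a formula, so both
defensible readings are exposed as separate pure functions:
`net_stimulation()` subtracts the negative-control percentage and floors at
0 (for empty-vector-style backgrounds), and `relative_stimulation()` forms
the background-corrected ratio `100·(s − b)/(p − b)` (for
"relative to the positive-control peptide" figures); the ratio is
affine-invariant and may exceed 100. Replicates are aggregated as mean ±
SEM before normalization of means, with a per-replicate switch.

## The synthetic world

`generate_peptidome_suite()` emulates the statistical structure of four
B-cell-line immunopeptidomes; the defaults are the stated conditions of the
analysis it validates and are not tuned to test outcomes:

* depths 3200 / 2100 / 8600 / 8500 unique peptides (two high-yield and two
  moderate-yield lines, the configured defaults of the suite contract);
* length spectrum 0.03 / 0.95 / 0.015 / 0.005 over 8–11-mers
  (9-mer-dominant, as in HLA-C ligandomes);
* one shared allele across lines plus four line-specific alleles, with two
  lines sharing an HLA-A pair so their overlap is larger;
* shared-allele strata: 3% strong, 2% weak, 84% binder-of-another-allele,
  11% non-binder (within the reported 4.9–17.3% non-binder range); percent
  ranks are truncated log-normal draws within each stratum's band, memoized
  per peptide–allele pair so a peptide shared between lines keeps its ranks;
* q-values: 95% in (0, 0.01], 3% in (0.01, 0.1], 2% in (0.1, 0.5], so the
  1%-vs-10% FDR boundary is exercised;
* pairwise sharing by retention probabilities (0.08 baseline, 0.30 between
  the two high-yield lines);
* per line 10 planted motif-conforming stimulatory peptides (strong binders,
  q ≤ 0.01), plus exactly one planted motif-conforming octamer forced into
  the **non-binder stratum** with q in (1%, 10%] — the scenario of a true
  TCR ligand that binder-only screening at stringent FDR would miss;
* 25 planted duplicate records per line (weaker q copies), so deduplication
  has work to do; duplicate counts are part of the gold labels;
* a synthetic proteome embedding every emitted peptide at recorded
  coordinates.

Everything is a pure function of the seed (the caller's RNG state is saved
and restored), and gold labels record planted peptides, membership patterns,
duplicate counts and planting positions.

What the generator does **not** emulate: mass spectra, retention times, de
novo sequencing error structure, I/L ambiguity, NetMHCpan's actual
sequence-to-rank mapping (ranks are drawn from strata, so sequence and rank
are independent given the stratum, except for planted peptides), realistic
residue composition (background is uniform by default, with a config hook
for anchor-position bias), and shared q-values across lines. A green
planted-recovery test therefore establishes that the pipeline's *logic* is
faithful — filtering, assignment, motif rules and ranking do what they
claim — not that the motif would achieve any particular sensitivity on real
ligandomes.

## Numerical and degenerate-input choices

* Rounding of reported percentages: half up, two decimals (integer for the
  directional overlap percent). Floating-point guard of one ulp-scale
  epsilon before flooring.
* Empty inputs: empty peptide table → empty peptidome with warning; empty
  first set in `overlap_fraction()` → percent 0 with warning; zero total in
  `length_distribution()` → all-zero percents.
* `pseudocount = 0` is allowed and produces −Inf log-odds cells; matching
  against them simply yields −Inf scores (never NaN) and such peptides fail
  any finite threshold.
* Sequences are upper-cased on ingestion; I and L are kept distinct as
  deposited.
* Proteome coordinates are 0-based half-open everywhere.
* Duplicate records resolve to the minimum-q representative.

## Limitations

* The bundled ERAP1 key is a placeholder; calls from it are not
  biologically interpretable.
* The default octamer anchor/contact positions are a reconstruction by
  C-terminal alignment, not an independently validated motif.
* The screen reproduces a *rule family*, not any specific published
  candidate shortlist, which depends on the deposited data and unpublished
  parameter choices.
* Anchor allowed sets derived from a small panel are conservative: residues
  compatible with binding but absent from the panel are rejected at anchors.
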