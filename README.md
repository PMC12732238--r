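# pepscreen

Tools for analysing HLA class I immunopeptidomes and nominating candidate
self-peptides recognized by an autoreactive T-cell receptor (TCR).

## The problem

In HLA-associated autoimmune disease, a single TCR can be polyspecific:
besides its index autoantigen it may recognize other self-peptides presented
on the same HLA molecule. Finding those cross-reactive ligands starts from
mass-spectrometry immunopeptidomes — tables of peptides eluted from HLA class
I of candidate presenting cells — and proceeds through a standard
computational funnel:

1. **FDR filtering.** Peptide identifications carry a q-value; the table is
   filtered at a 10% (exploratory) or 1% (stringent) false discovery rate,
   keeping records with `q ≤ t`.
2. **Binder assignment.** Each peptide is assigned to the HLA allele of the
   cell with the lowest NetMHCpan percent rank ("best binder analysis") and
   classified as a strong binder (`%rank ≤ 0.5`), weak binder
   (`0.5 < %rank ≤ 2`) or non-binder.
3. **Motif screening.** A peptide recognition motif for the TCR of interest
   is estimated from a panel of known stimulatory ligands as a
   position-probability matrix `p(i, a) = (n_{i,a} + c) / (n + 20c)` with
   log-odds `log2(p(i, a) / b_a)` against a background `b`. A peptide is a
   candidate when every HLA anchor position (P2/P7/P9 for nonamers) carries a
   panel-observed residue, at least one TCR contact position (P5/P8 for
   nonamers) carries a basic residue (R/K; Q admitted at P5), and the summed
   log-odds score beats the threshold. Both predicted binders and — since
   prediction false negatives occur — non-binders can be screened.
4. **Set analytics, haplotypes, assay normalization.** Upset-style exclusive
   intersection counts and pairwise overlaps across peptidomes; ERAP1
   diplotype calls from phased genotypes at the nine defining coding SNPs via
   an editable residue-combination key; background-subtracted and
   positive-control-relative normalization of TCR-hybridoma reporter
   readouts.

A deterministic synthetic-data generator reproduces the statistical shape of
real B-cell-line immunopeptidomes (unequal depths, 9-mer-dominant lengths,
rank strata, q-values straddling the FDR boundaries, partial sharing, planted
motif-conforming peptides) so the whole pipeline is validated offline.

## Worked example

```r
library(pepscreen)

suite <- generate_peptidome_suite(simulation_config(seed = 42))
p <- filter_by_fdr(suite$peptidomes[["BCL3"]], 0.10)
p
#> Immunopeptidome 'BCL3': 8474 records, 8449 unique peptides
#>   alleles: HLA-C*06:02, HLA-A*01:01, HLA-A*03:01, HLA-B*07:02, HLA-B*57:01

c06 <- c0602_binder_set(p)          # best-binder C*06:02 strong+weak set
length(c06)
#> [1] 429
length_distribution(c06)
#> 8-mers: 11 (2.56%)
#> 9-mers: 403 (93.94%)
#> 10-mers: 12 (2.80%)
#> 11-mers: 3 (0.70%)

motif <- build_motif(default_ligand_panel())
cand <- screen_peptidome(motif, p, include_nonbinders = TRUE)
head(cand[, c("sequence", "score", "rank")], 3)
#>    sequence    score rank
#> 1 FKQYRQRKI 13.23115    1
#> 2 PAPEKIVRL 12.40892    2
#> 3 AKFQKEVKL 12.25231    3

match_peptide(motif, "VRSRRCLRL")   # index autoantigen: R at P5/P8 -> passes
#>    sequence ... anchor_ok contact_ok    score passed
#> 1 VRSRRCLRL ...      TRUE       TRUE 18.67015   TRUE
match_peptide(motif, "VRHDGGNVL")   # non-antigenic control: fails contacts
#>    sequence ... anchor_ok contact_ok     score passed
#> 1 VRHDGGNVL ...     FALSE      FALSE -1.054021  FALSE

key <- read_erap1_key()             # bundled key is a synthetic placeholder
call_erap1(compose_genotype("Hap2", "Hap10", key, sample = "BCL3"), key)
#>   sample  diplotype
#> 1   BCL3 Hap2/Hap10
```

The screen evaluated 8,262 unique 8-/9-mers and returned 18 candidates, all
11 peptides planted in this cell line among them; the scores are log-odds
bits against a uniform background. A command-line interface mirroring these
steps is available via `pepscreen_cli()` (launcher in `inst/cli/pepscreen`):
`pepscreen filter --fdr 0.01 --in peptides.tsv --out filtered.tsv`, and
analogous `assign`, `motif-build`, `screen`, `overlap`, `erap1`, `normalize`
and `simulate` subcommands.

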