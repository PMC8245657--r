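---
title: "Neoantigen profiling from tumor/normal allele counts: models and design"
author: "neoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen profiling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprofiler)
```

## The problem

A tumor accumulates somatic mutations its matched normal tissue does not
carry. A non-synonymous single-nucleotide variant (nsSNV) changes one
amino acid in a protein, and every 8–11mer peptide window containing that
residue is a candidate *neoantigen*: if such a peptide binds one of the
patient's HLA class I molecules tightly enough to be presented, CD8+
cytotoxic T lymphocytes can recognise the tumor as foreign. Profiling a
patient therefore chains four inferential steps — somatic variant calling
from paired tumor/normal sequencing, functional classification of the
variants, exhaustive mutant-peptide enumeration with HLA-binding and
RNA-expression filters, and cohort-level statistics — and `neoprofiler`
implements exactly this chain, together with a synthetic data generator
that makes every step testable without access to patient sequencing data.

## The somatic caller

The caller's sole evidence at a site is the 2×2 table of reference- and
alternate-supporting read counts in tumor and normal (base quality ≥ 15
and mapping-quality/duplicate filtering are assumed upstream of the
counts; the caller never sees reads). `fisherSomaticP()` computes the
exact two-sided p-value of that table: the sum, over all tables with the
same margins, of hypergeometric probabilities not exceeding the observed
table's probability. This is the same convention as `stats::fisher.test`,
and the test suite pins it twice over — against an independent
`choose()`-based enumeration of every table with margins ≤ 30, and
against `stats::fisher.test` on random tables.

A site becomes a somatic call iff **all** six conditions hold, with
boundary semantics read literally off the inequalities:

| filter | threshold | boundary |
|---|---|---|
| depth (tumor **and** normal) | ≥ 10 | inclusive |
| tumor variant reads | ≥ 4 | inclusive |
| tumor VAF | ≥ 0.10 | inclusive (a 10/100 site passes) |
| normal VAF | < 0.02 | exclusive (a 2/100 normal fails) |
| Fisher p | < 0.05 | exclusive |

The depth filter is applied to both samples: its source description does
not say which sample, and requiring both is the conservative reading.
Relaxing any single threshold can only grow the call set — a property the
suite checks — and the call order always follows the input order.

## Classification and the splice window

Each call receives exactly one of six classes. Insertion/deletion tokens
(`INS`/`DEL`) are INDELs outright. The transcript model is CDS-only (an
ATG-to-stop coding sequence with annotated exon-junction offsets), so
there are no intronic coordinates; the canonical donor/acceptor
dinucleotides are therefore represented by the two exonic bases on each
side of every junction, and any SNV in that 4-base window is classified
`splicing` before codon logic runs. All other SNVs are decided by
translating the mutated codon (`Biostrings::GENETIC_CODE`): a new stop is
`stopgain`, a lost terminal stop is `stoploss`, an unchanged residue is
`sSNV` (including stop→stop), anything else `nsSNV`. Classification is
total by construction, and the simulator samples its ground truth from a
catalog classified by this same function, so simulated truth and called
class can never disagree for recovered sites.

## Peptide enumeration and the neoantigen criteria

For an nsSNV at protein position $i$ in a protein of length $n$, the
enumeration emits, for each length $L \in \{8,9,10,11\}$, every window
fully inside the protein that contains $i$: starts
$\max(1, i-L+1) \dots \min(i, n-L+1)$, i.e.
$\min(i, n-L+1) - \max(1, i-L+1) + 1$ windows when positive. An interior
residue yields $8+9+10+11 = 38$ peptides; residue 1 yields 4. Windows are
never padded past the termini — only physical substrings are peptides —
and the wildtype counterpart is the same window with the substituted
residue reverted.

A peptide–allele pair is a *predicted binder* when its IC50 is strictly
below 500 nM (a pair at exactly 500 is out); a variant is *expressed*
when the RNA reads covering its mutated position are ≥ 1. "Covering" is
the default read-count mode because expression support at the position is
the conservative criterion; counting only mutant-supporting reads is
available as `mutant_supporting`. The **neoantigen load** counts, by
default, distinct mutant peptide sequences that pass the binding filter
for at least one patient allele and whose source variant is expressed.
The counting unit is configurable (`peptide_allele_pairs`, `variants`)
because "load" could defensibly count any of the three; distinct peptides
is the default as it matches the number-of-neoantigen-peptides reading.
Homozygous HLA alleles are deduplicated before pairing — identical
predictions add no information — which makes the load invariant to
writing a homozygous genotype once or twice.

Vaccine candidate selection applies the stricter experimental rule: one
restricting allele, read count ≥ 2, ranked by ascending IC50 with ties
broken lexicographically (the ranking rule is the package's own explicit,
deterministic choice), at most `topK` candidates, wildtype counterparts
attached.

## The binding model

External neural-network affinity predictors are deliberately out of
scope; the package consumes their output tables (tab-separated
allele/peptide/IC50, duplicate pairs resolved to the minimum IC50 with a
logged warning) and ships a deterministic stand-in for testing:
a fixed 20×11 position-weight matrix stored as a text asset, row-rotated
per allele by an arithmetic hash of the allele name. A peptide's score is
the anchor-weighted mean of its per-position weights (positions 2 and the
C-terminus carry 3× weight, mirroring class I anchor positions), mapped
monotonically onto IC50 = $50000\,e^{-6s}$ nM ∈ (0, 50000]. The rate
constant 6 was chosen so that a random coding peptide passes the 500 nM
cut for one allele with probability ≈ 1–2%, giving the enumeration →
binder → expressed attrition the same order of magnitude as real
profiling (roughly 2–3 binding peptides per nsSNV across six alleles,
about half of which survive the expression filter). No randomness occurs
at prediction time, so any (peptide, allele) pair has one IC50 on every
platform.

## The synthetic cohort generator

The generator's defaults describe the study conditions the package is
exercised under: 31 patients of whom 13 are TNBC; expected exonic burden
72 for non-TNBC patients with a ×2 TNBC multiplier (overall mean ≈ 102
exonic mutations, hence ≈ 64 nsSNVs per patient under the class mix);
class mix nsSNV 62.4%, sSNV 24%, INDEL 6%, splicing 5%, stop gain 2.5%,
stop loss 0.1%; tumor and normal depths Poisson with mean 100; VAF from
Beta(2, 5) truncated to [0.05, 1] so that the caller's 10% threshold is
genuinely exercised from both sides; per-base sequencing error $10^{-3}$
(a normal sample acquires alternate reads only through this error);
decoy sites — one germline heterozygous site (VAF ≈ 0.5 in both samples)
per true variant and half as many pure-noise sites — for specificity
testing; RNA covering reads zero-inflated negative binomial
($\pi_0 = 0.4$, $\mu = 10$, size 1), so the read-count filter has real
attrition and loads sit near half the binder counts; HLA genotypes drawn
two per locus from a 15-allele pool. A single integer seed fully
determines the cohort; two runs serialize byte-identically.

What the generator does **not** emulate: read-level artefacts (mapping
error, strand bias, FFPE damage), genomic coordinates and real gene
structure, tumor purity and subclonality, germline variation beyond
decoy sites, linkage between mutations, and real HLA-binding motifs.
Passing tests therefore demonstrate that the pipeline's logic is correct
and calibrated under its stated model — not that any particular clinical
cohort's numbers would be reproduced.

## Cohort and assay statistics

`fpkm()` implements fragments per kilobase per million mapped reads
exactly; `pearsonCor()` wraps the Pearson correlation with its two-sided
t-transform p-value; `groupCompare()` reports the equal-variance
two-sample Student's t-test plus group medians and ranges. The
subtype-comparison default is deliberately the *unpaired* test: the TNBC
(n = 13) and non-TNBC (n = 18) groups cannot be paired, so the "paired
t-test" wording attached to such comparisons is not executable as
printed; a paired mode exists for genuinely paired designs and the
report logs the choice. ELISpot positivity requires a response *strictly*
more than 50% above control (a +50% tie is negative; zero-control
responses are positive with an unbounded fold, flagged). Cytotoxicity is
$(\text{control} - \text{sample})/\text{control} \times 100$, reported
unclipped — the formula has no floor, and a sample brighter than control
legitimately yields a negative percentage. p-values are reported without
multiple-testing adjustment, matching the analysis style the pipeline
reproduces; the immune panel defaults to CD8A, CD4, TCRB, GZMA, GZMB,
PRF1 and is configurable.

## Numerical and degenerate-input choices

* Fisher two-sided tail uses the standard `(1 + 10^{-7})` relative
  tolerance when comparing table probabilities, avoiding
  floating-point ties; values are capped at 1.
* Zero-variance vectors make a Pearson correlation undefined:
  `pearsonCor()` refuses them, while `cohortReport()` records an `NA` row
  so one degenerate pair cannot abort a pipeline run.
* Constant-versus-constant group comparisons are flagged `degenerate`
  with t = 0, p = 1 when equal.
* An `ic50ThresholdNm` of 0 would contradict the parameter's stated
  invariant (> 0); the constructor enforces positivity, and a
  near-zero threshold yields zero load everywhere, which the tests
  exercise.
* Tabular outputs fix float formatting to 6 significant digits, making
  reruns byte-identical across platforms.
* Truncated-Beta VAFs are drawn by inverse-CDF restriction
  (`qbeta(runif(lo, 1))`), not rejection, so draw counts are
  deterministic given the seed.

## Problem sizes used in the tests

The suite verifies the Fisher implementation exhaustively for all 2×2
tables with margins ≤ 30 against an independent enumeration oracle
(tolerance $10^{-9}$), the window enumeration for all protein lengths
≤ 30 at every position and length 8–11 against a brute-force scan,
caller sensitivity/specificity on ten default-depth patients, load
monotonicity on twenty patients across IC50 ∈ {500, 250, 50} and read
count ∈ {1, 2, 5}, TNBC-excess recovery and burden–load correlation on
100 replicates of the default 31-patient cohort, and the null behaviour
of immune-gene correlations on 200 independent-expression replicates.
These sizes are the package's chosen verification scale: large enough to
pin the distributional properties, small enough that the whole suite
runs in a few minutes on one CPU.

## Known limitations

* Coordinates are transcript-CDS-based; lifting real genomic VCFs onto
  transcript models (and strand-aware allele flipping) is out of scope.
* Only single-base substitutions generate neoepitopes here; INDEL and
  fusion neoantigens, HLA class II presentation, proteasomal processing
  and TAP transport scores are intentionally not modelled.
* The toy binding model ranks peptides reproducibly but has no
  immunological meaning; real profiling must substitute predictor output
  tables via `readAffinityTable()`.
* Multi-allelic sites, tumor purity correction and subclonal structure
  are not represented.
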