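---
title: "Methods: anatomy of a gene-family survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomy of a gene-family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famsurvey implements the canonical pipeline for a genome-wide survey of a
plant gene family, using the rice fatty acid desaturases as the model
family. This vignette explains each stage's model and assumptions, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Identification

Candidates are collected by three routes and unioned by locus:

1. **Domain evidence.** Either a precomputed tabular hit file from an
   external profile search (protein id, domain, E-value), or the internal
   fallback: a protein carrying at least two distinct histidine-box
   patterns counts as domain evidence. Desaturases coordinate a diiron
   center through two (soluble stearoyl-ACP enzymes) or three (membrane
   enzymes) His-rich boxes, so box multiplicity is a reasonable proxy
   when no profile-search output is at hand. The mode used is recorded in
   the result.
2. **Homology.** Smith–Waterman local alignment of each proteome entry
   against a small query set (typically the Arabidopsis subfamily
   representatives), scored with the Karlin–Altschul formula
   E = K·m·n·e^(−λS). We use the gapped BLOSUM62 constants λ = 0.267 and
   K = 0.041 with EMBOSS-needle gap penalties (open 10, extend 0.5) and
   keep entries at E ≤ 10⁻¹⁰. This keeps the screen self-contained and
   deterministic instead of shelling out to a BLAST binary; a hit-table
   import path exists for parity runs against external searches.
3. **Keyword.** Case-insensitive substring search of the functional
   annotation descriptions.

Redundancy removal keeps one representative transcript per locus: the
longest protein, ties broken by the lowest ".N" splice suffix. The
longest-CDS rule is our choice — surveys rarely state theirs — and it is
deliberately deterministic. A manual-include list lets curators retain
members that fail every screen (the classic case: a C-terminally
truncated paralog whose missing third box removes its domain signature);
such genes carry a `manual_include` flag and come out with an incomplete
H-box scan.

Names follow `Os<SUBFAMILY>-<k>`, numbered positionally by (chromosome,
start) within each subfamily, singletons unnumbered. Published naming is
not always strictly positional, so an override map applied last can
reproduce any historical naming exactly.

## Protein features

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da). The isoelectric point is found by bisection on the net
charge (tolerance 1e-4 pH) using the EMBOSS pKa set (N-term 8.6, C-term
3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1), recorded in the
output; published pI values computed with unknown pKa tables can differ
by a few tenths of a pH unit, which is why cross-source comparisons of pI
deserve a looser tolerance than molecular weight.

H-box patterns use a small grammar: uppercase literals, `X` as a
wildcard, and `"(Y)"` immediately after a residue as a two-way
alternative (so `DAA(S)DEKRHE` matches both DAADEKRHE and DASDEKRHE).
The packaged table carries the boxes of all six subfamilies; the membrane
Δ12 subfamily additionally ships the generic third-box core `HVXHH`,
since the literature quotes both the subfamily-specific and the generic
form. Scanning reports every occurrence (overlaps included) via a
zero-width lookahead regex; a brute-force position-by-position matcher
serves as the oracle in the test suite, and the completeness flag (every
box present at least once) is the truncation detector.

## Gene structure

Intron counts refer to the coding sequence: introns are counted between
consecutive CDS intervals, and the phase of intron i is the cumulative
CDS length 5′ of it modulo 3 (the number of bases of the interrupted
codon already emitted — the convention used by gene-structure display
tools). Introns lying wholly within UTRs are reported separately and
excluded from the headline count. A CDS length not divisible by 3 is
flagged, not fatal, so annotated truncations survive the pipeline.

## Alignment statistics

The dynamic programming is Biostrings' Gotoh affine-gap implementation;
this module defines the statistics the duplication rules are phrased in:

* **identity** — identical columns / full alignment length;
* **similarity** — positive-substitution columns within the
  non-terminal-gap span / span length;
* **coverage** — fraction of the longer sequence inside that span.

The published tandem criterion speaks of "homology at protein level" and
the segmental criterion of "similarity of aligned regions"; whether
"homology" means identity or similarity is not stated, so identity is the
default for the tandem rule and positive-substitution similarity for the
segmental rule, both configurable and logged. The coverage denominator is
the longer sequence, as the segmental criterion requires.

## Phylogeny

Multiple alignment is delegated to `mafft` (deterministic at default
settings); a pre-aligned FASTA can bypass it entirely. We preferred the
field-standard aligner over an internal progressive implementation: MSA
quality dominates everything downstream, and a bespoke aligner would be
the least validated component in the package. Distances use the Poisson
correction d = −ln(1 − p) with p the differing fraction over
complete-deletion columns (columns containing no gap in any row);
saturated pairs (p = 1) are capped at d = 10 with a warning rather than
propagating infinities.

Neighbor joining is implemented in the package so its determinism is
under our control: exact Q-criterion ties are broken by the
lexicographically smallest label pair (reference NJ implementations leave
tie order unspecified), making results invariant under input taxon
order; negative branch lengths are clamped to zero for display. An
independent NJ implementation (ape) is the cross-check in the test suite.
Bootstrap resampling draws complete-deletion columns with replacement
(the mask is applied before resampling), recomputes the tree per
replicate, and reports bipartition percentages; because resampling
indexes columns only, supports are taxon-order invariant at a fixed
seed. Subfamilies are assigned by minimum average distance to anchor
groups, with ties within 1e-9 left unassigned and warned about rather
than silently broken.

## Duplication classification

Tandem: same chromosome, fewer than 5 intervening annotated genes
(counted on genome-wide gene ordinals, any strand — the published
criterion does not define "genes" more precisely, so every annotated
locus counts), and identity > 0.5. Clusters are single-linkage closures,
so a chain a–b–c with a–c below threshold is still one cluster of three.
Segmental: coverage > 0.75 and similarity > 0.75, both strict, tested
over all pairs except those inside one tandem cluster — the two
mechanisms are reported disjointly per pair, while one gene may still
carry both labels via different partners. No synteny evidence is
required: the published criterion is purely pairwise, and adding
collinearity chains would change the operating characteristics of the
classifier.

## Promoters

The promoter is the 2000 bp immediately 5′ of the first CDS base
(strand-aware; truncated with a warning at contig edges). Positions are
reported relative to the ATG with −1 the base just upstream of the A.
Scanning is IUPAC-expanded on both strands, with complementary-strand
hits reported at template coordinates. The packaged element table uses
the standard PlantCARE consensus vocabulary; published surveys do not
print their motif sequences, so these defaults are implementation
provided and deliberately user-replaceable. Note that the MeJA pair
CGTCA/TGACG are reverse complements of each other, so a single planted
instance legitimately produces one hit of each name on opposite strands.

## Expression

Tissue group classification evaluates, in order: IV (maximum tissue mean
below τ_low), I (at least 80% of tissues at or above τ_high), III (all
high tissues in exactly one developmental category), else II. The
thresholds are not stated in the survey literature; the defaults are the
70th/30th percentiles of all tissue means, a rule that behaves sensibly
on transcriptome-scale matrices, and both thresholds are recorded in
every call for audit. For the synthetic panel (20 genes, not a
transcriptome) the generator instead emits its own scale-true thresholds
(τ_high = 8, τ_low = 4 on its log2 scale) in the truth record, and tests
use those.

Stress differential expression uses a Welch two-sample t-test on log2
signals with raw P < 0.05 and no multiple-testing correction — a
deliberate mirror of how such surveys call "significantly regulated";
the test suite verifies the empirical size (±0.03 of α at n = 3, 200
seeded replicates) and power (≥ 0.95 against a −2 log2 fold change at
sd 0.2). Hormone responses are strict fold-change calls on
control-normalized relative quantities (up iff RQ > 2, down iff
RQ < 0.5), with an early-response flag at the 3 h time point. 2^−ΔΔCt
quantification averages replicate Ct per (gene, sample), normalizes to
the reference gene and a calibrator sample, and propagates the replicate
SD to an RQ range.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates
the statistical structure the classifiers assume:

* a multi-chromosome genome (default: 6 chromosomes × 40 background
  genes) carrying a 20-member family in six subfamilies (9/4/4/1/1/1 —
  the shape of the desaturase family), all descended from one root
  protein so the family alignment stays colinear;
* one 3-gene tandem array (2 intervening genes, chain identity 0.6) and
  one 2-gene array, plus two segmental pairs planted at coverage and
  similarity 0.85 — a configuration with 5 tandem and 4 segmental genes,
  i.e. 45% of the family in duplication events. Planted identities,
  coverages and similarities are *verified with the package's own
  aligner* before emission and resampled until within ±0.03 of target; an
  unsatisfiable specification errors out after bounded retries;
* histidine boxes planted once per pattern at recorded offsets, with
  background residues rejection-repaired (using an independent regex
  matcher, not the scanner under test) until no pattern matches anywhere
  else — so false-positive tests are exact, not probabilistic;
* 2 kb promoters whose background is likewise repaired until the only
  element hits lie wholly within planted windows; implied hits (e.g. the
  CGTCA/TGACG pairing, or a shorter motif inside a longer planted one)
  are part of the recorded truth;
* mutations use BLOSUM62-non-positive substitutions, so the planted
  similarity equals the retained-position fraction by construction;
* expression archetypes on a 10/6/2 log2 scale with Gaussian replicate
  noise (default sd 0.3, 3 replicates), and Ct tables in which the
  expected 2^−ΔΔCt equals the planted fold change exactly at zero noise.

What it does **not** emulate: indel evolution (family divergence is
substitution-only, so real alignment uncertainty is understated), codon
usage and GC structure, microarray probe effects and normalization
artifacts, genome repeats, and annotation errors. Passing tests
therefore demonstrate that the classifiers implement their rules
correctly and recover structure under the stated noise model — not that
the rules themselves are robust to every pathology of real genomes.

## Numerical and reproducibility choices

* Every stochastic operation takes a mandatory integer seed; the same
  seed reproduces simulations byte for byte, and pipeline reruns with
  identical inputs and seed serialize identically.
* Degenerate inputs are explicit: empty CDS errors; p = 1 distances cap
  at 10; zero-variance equal-mean t-tests return "no call"; RQ ≤ 0 and
  Ct ≤ 0 are data errors; promoters at contig edges truncate with a
  warning.
* Problem sizes in the test suite are chosen for a laptop-scale run: the
  default synthetic fixture (260 genes, ~180 kb genome), a smaller
  7-gene family for pipeline tests, 100-replicate bootstraps, 200
  replicate calibration simulations, and enumeration oracles on
  sequences up to length 6.

## Known limitations

* The homology screen's E-values use fixed Karlin–Altschul constants; a
  full BLAST reproduction (composition-based statistics, edge-effect
  corrections) is out of scope, which is why an external hit-table
  import is provided.
* Segmental calls are pairwise only; no synteny blocks or Ks dating.
* The percentile defaults for expression-group thresholds are only
  meaningful when the input matrix spans a transcriptome's dynamic
  range; for small curated panels, pass explicit thresholds.
* `progressive_align()` requires the `mafft` executable on the PATH;
  pre-aligned input bypasses the requirement.
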