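---
title: "Tag counting with UMIs and error-correcting indexes: models and design choices"
author: "umicount authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag counting with UMIs and error-correcting indexes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umicount)
```

## The measurement model

Multiplexed digital gene expression (DGE) libraries attach two tags to
every first-strand cDNA at reverse transcription: a fixed 8-nt
*multiplex index* identifying the sample (cell), and a random 10-nt
*unique molecular identifier* (UMI). After pooling, PCR amplification
and sequencing, each fragment yields a read1 (the cDNA sequence) and an
index read that is sequenced at 20 nt, of which the first 18 nt are
informative: 8 nt of index followed by 10 nt of UMI.

Because the UMI is attached *before* amplification, all reads that map
to the same gene locus and carry the same UMI are copies of one
original molecule and are collapsed to a single count ("UMI
unification"). Reads mapped to different genes are never merged, even
with identical UMIs. The column sums of the resulting count matrix
estimate the number of captured cDNA molecules rather than the number
of sequenced fragments, removing PCR duplication bias. The per-sample
*UMI-unified rate*, `(mapped reads − UMI counts) / mapped reads`, is
reported as a proxy for duplication depth; with single cells it is
typically far above 90%, and the central invariant of the method —
verified exhaustively by the test suite — is that replicating every
molecule's reads any number of times leaves the count matrix unchanged.

## Index design and decoding

The package constructs index sets by a deterministic greedy
lexicographic scan (`design_indexes()`): all `4^L` words are visited in
lexicographic order and a word is retained when its Hamming distance to
every previously retained word is at least `min_distance`. The scan is
implemented by sphere elimination, which is mathematically equivalent
and linear in the number of retained words. With the defaults (`L = 8`,
`min_distance = 3`) the scan exhausts at 1024 sequences, far more than
the ~100 typically needed, and the distance-3 property guarantees
correction of any single substitution: decoding (`assign_index()`)
assigns an observed index to the unique stored index within Hamming
distance `max_correct = 1`. Ties or distances beyond the budget leave
the read unassigned — mis-assignment between single cells is considered
strictly worse than losing a read. `N` bases count as mismatches to all
four bases. The greedy construction is our own design choice: any set
with the distance property works, and externally designed tables are
accepted through `read_index_table()`.

Some runs demultiplex on a 6-nt prefix of the index field. The field
widths are fixed (8 + 10 = 18), so this is exposed as
`effective_index_len`, which truncates both the observation and the
stored set; the correction guarantee then depends on the pairwise
distance of the *truncated* set, which `demultiplex()` checks is at
least collision-free.

## Read processing

Index reads are trimmed to their first 18 nt (`trim_index_read()`),
split into index and UMI (`split_index_umi()`; the index-first layout
reflects the RT-oligo structure and is the default, with a flag for the
alternative), and the UMI is embedded into the read1 name as
`<id>_UMI:<seq>` (`embed_umi_in_name()`). The separator survives
alignment because SAM QNAMEs cannot contain whitespace; only the first
whitespace-delimited token of the original header is kept for the same
reason.

Read1 cleaning follows the common trailing-quality / sliding-window /
minimum-length recipe with defaults `TRAILING:20 SLIDINGWINDOW:4:15
MINLEN:30` (`quality_trim()`). The window rule truncates at the start
of the first 4-base window whose mean quality falls below 15; the two
rules are iterated to a fixpoint so the operation is idempotent.
Adapter removal (`trim_adapter()`) clips at a full adapter occurrence
or at a terminal match of at least 7 nt between the read 3' end and an
adapter prefix. This is a deliberate simplification of palindromic
adapter clipping — single-end DGE data only need read-through removal —
and the minimum overlap of 7 mirrors the conventional setting.

Reads whose UMI contains `N` are kept through demultiplexing but
flagged; they are discarded at unification, where an ambiguous UMI
cannot be grouped.

## Counting

`parse_alignments()` consumes SAM/BAM against a transcript reference
plus a transcript-to-gene map. Alignments of one read to several
transcripts of the same gene collapse to one assignment. Reads hitting
more than one gene follow `multimap_policy`; the default `discard` is
conservative, since probabilistic multi-mapping resolution is out of
scope. Because BAM conversion may reorder records, the `first` policy
is defined deterministically as the smallest (transcript id, position)
alignment rather than file order. The unification key is gene × UMI
only — alignment position is recorded but deliberately not part of the
key, and no Hamming-1 UMI merging is performed: unification is by exact
UMI identity, a fidelity choice that trades a small, quantifiable
inflation under UMI sequencing errors (measured by the simulator tests)
for freedom from over-merging.

`unify_umis()` picks one representative read per (gene, UMI) group
using a seeded RNG; the counts are provably independent of the seed and
the tests assert it. `toy_align()` is a test-scale exact k-mer aligner
(first 31-mer, leftmost occurrence, soft-clipped remainder) that makes
the whole pipeline executable without an external aligner; it is
plumbing, not a contribution, and any aligner producing SAM against the
transcript reference can be substituted.

## Saturation

`saturation_curve()` draws uniform without-replacement subsamples of
the mapped, gene-assigned reads — matching the notion of randomly
extracting reads from a fixed sequenced dataset, rather than binomial
thinning — and recomputes detected genes and the UMI-unified rate per
depth and replicate. Both statistics are non-decreasing in expectation,
and the full-depth row reproduces the unsubsampled statistics exactly.
The default depth grid is log-spaced because the statistics change
fastest at low depth.

## Quality screening and spike-ins

`qc_screen()` is an explicit, simplified re-implementation of
correlation-based outlier screening in the style of SinQC, using
exactly four configured quantities (defaults: MAX FPR 0.05, TPM cutoff
1, Spearman p < 0.001, Pearson p < 0.001). The original program's
internal algorithm is not public in the sources we work from, so the
rule here is our own and is stated in full in the function
documentation: a sample fails only when both best-partner correlation
tests (on `log2(TPM+1)` over genes expressed in either sample) are
non-significant *and* the sample is a technical outlier (lowest
best-partner correlation, or lower-tail detected genes / mapping rate),
with the number of failures capped at `floor(max_fpr * n)`. Under an
exchangeable null the empirical false-positive rate is below the
configured budget (0 flagged in 200 simulated null datasets in the
acceptance suite), and a planted uncorrelated sample is caught
essentially always. This screen is approximate by construction and
should not be expected to reproduce SinQC's exact pass/fail decisions.

All QC statistics use the `log2(x + 1)` pseudocount convention, stated
explicitly because R² values are only reproducible once the transform
is fixed. `replicate_concordance()` is OLS R² in that space;
`spikein_linearity()` regresses `log2(UMI + 1)` on `log2(nominal
concentration)` per sample, retaining drop-out spikes as pseudocount
points (with an excluded-fit variant reported alongside), so that slope
1 indicates proportional recovery and library-size scaling moves only
the intercept.

## Count-matrix statistics

**TMM factors** (`tmm_factors()`) implement the trimmed mean of
M-values: double trim (30% each side on M, 5% each side on A),
inverse-asymptotic-variance weights, factors recentred to geometric
mean 1. The implementation agrees with the reference implementation in
edgeR to floating-point precision on random matrices (a standing test).

**Exact NB test** (`nb_exact_test()`) conditions a gene's two group
sums on their total under a negative binomial model with a *common,
user-supplied* dispersion (default `phi = 0.1`). Conditioning makes the
null distribution parameter-free — a negative hypergeometric with
shape `n_A/phi`, `n_B/phi`, degenerating to a binomial at `phi = 0` —
and the two-sided p-value sums all outcomes no more probable than the
one observed (minimum-likelihood rule, tie mass included, with a 1e-10
relative tie tolerance). Tagwise/trended dispersion estimation is
intentionally not reimplemented; the fixed common dispersion is the
documented simplification, and the test is verified against exhaustive
enumeration of the conditional distribution for all splits with sums
up to 30. Before testing, counts are brought to equal effective library
sizes by moment matching (each sample scaled by the ratio of the
geometric-mean effective size to its own, group sums rounded); this is
simpler than quantile-to-quantile adjustment and empirically controls
type-I error within the acceptance window.

**iDEGES-style normalisation** (`ideges_normalize()`) iterates (default
3 times): test with current factors → mark putative DEGs at inner
FDR < 0.1, or the top 5% by p-value if fewer (`floorPDEG`) → recompute
TMM on the remaining genes, rescaling the subset factors to the full
library sizes. Iteration 0 is exactly plain TMM. The value of the loop
is visible under asymmetric differential expression: with 20% one-sided
4-fold DEGs, symmetric trimming of plain TMM is contaminated (the upper
trim fills with DEGs, so the lower trim cuts only null genes, biasing
the factor), while exclusion-then-TMM removes the asymmetry; the
acceptance suite shows the iterated factors beat plain TMM in well over
80% of runs.

**DEG calling** (`call_degs()`) applies the final test, BH adjustment
(`bh_fdr()`, a thin wrapper over the standard step-up implementation),
and calls DEGs at q < 0.01 by default. The m-value is the log2 fold
change of the second group over the first on normalised means with a
0.5 pseudocount; ranking is by (q, p, |m| descending) with gene-id
tie-breaks for determinism. All-zero genes are excluded and reported
`NA`.

**Hoeffding's D** (`hoeffding_d()`) uses the classical rank formula
with midranks and tie-weighted bivariate ranks, on the ×30 scale that
puts the population maximum at 1 (range −0.5 to 1), so values are
directly comparable to published D statistics such as 0.014 or 0.285
for weak and moderate dependence. The implementation is checked against
a definition-level double-loop oracle to 1e-12. The p-value is obtained
by a permutation test (default 10,000 shuffles of `y`); we chose not to
implement the table-interpolated asymptotic approximation used by some
packages, because the permutation reference is exact in distribution,
needs no tables, and is cheap at the sample sizes (tens of cells) this
statistic is used for here.

## qPCR utilities

Copy numbers of double-stranded plasmid standards use `mass / (bp ×
615 Da/bp / N_A)` with the SI-exact Avogadro constant; 615 Da/bp is the
convention adopted here (not 650). Standard curves are least squares of
Cp on `log10(concentration)` with inversion for quantification. Missing
quantification values are imputed per transcript (per row) as one tenth
of the row's minimum observed value; the helper operates on any numeric
vector, since "transcript level" may be a copy number or a Cp-derived
quantity.

## The simulator: what it emulates, and what it does not

`simulate_cells()` generates the full input side of the pipeline with
known truth: a log-normal gene abundance profile shared across cells
(sdlog 1), Poisson molecule counts per cell–gene around 10,000
molecules per cell, binomial capture at 50%, uniform random UMIs,
geometric PCR duplication (`reads = 1 + Geom(p_dup)`, default `p_dup =
0.3`, i.e. ~3.3 reads per molecule — a one-parameter heavy-tailed
stand-in for amplification, which real protocols do not specify), a
2-fold spike-in ladder that bypasses the expression model, uniform
fragment starts (fragmentation follows amplification, so duplicates of
one molecule need not share a start; a positional-bias knob is a
non-goal), constant Q37 base qualities, and independent per-base
substitution errors (defaults 1e-3 per region). Everything is a
deterministic function of one seed.

What passing tests on these data show: the combinatorial and accounting
core of the pipeline — demultiplexing, error correction, UMI
unification, conservation, saturation behaviour — is exact, and the
statistical modules behave correctly under their own model assumptions.
What they do not show: robustness to realistic base-quality profiles,
position-dependent error rates, chimeric reads, 3' coverage bias,
ambient contamination, or dispersion misspecification — real data
properties the generator deliberately omits.

## Problem sizes and numerical choices

The standing test suite runs the end-to-end identity at 10 cells × 200
genes × ~5,000 captured molecules per cell (~180,000 reads, and a
5-fold duplicated rerun of the same library), the exact-test
enumeration for all sums ≤ 30, type-I error on 10,000 null genes, the
normalisation comparison over 50 replicate simulations, and the QC
false-positive budget over 200 null datasets of 20 samples — sizes
chosen so the full suite completes in minutes on one core while keeping
Monte-Carlo standard errors well inside the asserted tolerances.
Tolerances are stated per test: exact identities at `identical()` or
1e-12, enumeration agreement at 1e-10, Monte-Carlo comparisons at 3–4
standard errors.

Degenerate inputs are handled explicitly: empty FASTQ input returns a
zero report; all-zero samples are an error for TMM; all-zero genes are
`NA` in DE results; depth-0 subsamples have zero detected genes and an
undefined unified rate (`NA`); decoding ties are unassigned rather than
guessed.

## Known limitations

* The QC screen is a documented approximation, not the original
  screening program.
* The exact test's common dispersion is fixed, not estimated; q-values
  shift accordingly if the true dispersion differs materially.
* No UMI-sequence error correction: UMI substitution errors inflate
  counts by design (quantified by the simulator tests at ~1e-3 error
  rates).
* Transcript-level (isoform) re-estimation of multi-mapping reads is
  out of scope; the `discard` default loses genuinely multi-gene reads.
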