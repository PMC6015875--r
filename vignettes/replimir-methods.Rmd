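---
title: "Methods: seed-site scanning, exact rank tests and synthetic ground truth in replimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-site scanning, exact rank tests and synthetic ground truth in replimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replimir)
```

## The problem

Human T cells lose the costimulatory receptor CD28 as they accumulate
population doublings (PDs), and miRNAs binding the CD28 3'UTR are one
proposed mechanism. Studying this computationally requires a short chain
of well-defined steps: find and classify candidate miRNA seed-match
sites on the CD28 3'UTR; design reporter constructs in which those
sites are destroyed; test a mature-miRNA count matrix from clones at
low versus high PD for differential expression; and analyse the qPCR
and dual-luciferase experiments that validate individual miRNAs.
`replimir` implements that chain, together with a synthetic-data
generator that produces every input with known ground truth, so each
stage can be verified without access to the original data.

## Seed-match model

A mature miRNA recognises its target principally through Watson–Crick
pairing of its seed, nucleotides 2–7 (extended to 2–8) counted from the
5' end. On the mRNA, read 5'→3', a perfect seed match is the reverse
complement of the seed, and the four canonical site classes are:

| class   | definition                                            | length |
|---------|-------------------------------------------------------|--------|
| 8mer    | match to miRNA positions 2–8, followed by an A        | 8      |
| 7mer-m8 | match to miRNA positions 2–8                          | 7      |
| 7mer-A1 | match to miRNA positions 2–7, followed by an A        | 7      |
| 6mer    | match to miRNA positions 2–7                          | 6      |

The A opposite miRNA position 1 is recognised as adenine on the mRNA
regardless of what the miRNA's first nucleotide is; this is why the
7mer-A1 and 8mer definitions append a literal A rather than a
complement.

`scan_sites()` locates every occurrence of the 6mer core and reports
each core locus exactly once, at the strongest class its flanking bases
support (8mer ⊃ 7mer-m8 ⊃ 6mer; 7mer-A1 ⊃ 6mer). Reporting loci rather
than all overlapping match variants is what makes per-miRNA site counts
meaningful — a single 8mer would otherwise also count as a 7mer-m8, a
7mer-A1 and a 6mer. Only these four classes are considered: no context
or conservation scoring, no thermodynamic model, no 3'-compensatory or
centred sites.

Alphabet conventions follow the input file types: miRNAs are stored as
RNA (T normalised to U on input), UTRs as DNA (U normalised to T), and
matching happens in DNA space. `N` never matches any class. Coordinates
are 1-based inclusive in transcript numbering: a region constructed
with `offset = 870` reports a site found at local position 3 as
transcript position 872, matching the "nt 870–2279" style used for
cloned UTR fragments. Scanning operates on whatever regions are
supplied — full UTR or cloned fragments is the caller's choice, since
site content can differ between the two (an uncloned gap contributes
nothing to a fragment scan).

```{r}
mirx <- mature_mirna("miR-X", "UAGGCAACUGA")
seed_match_strings(mirx)
scan_sites(mirx, utr_region("demo", "AAGTTGCCTAAA", offset = 870))
```

## Reporter mutagenesis design

`design_mutant()` reproduces the construct-design strategy of mutating
seed positions 2, 4 and 6 at every detected site. Within the 7mer-m8
match frame (frame base 1 pairs miRNA position 8), seed position *p*
pairs frame position 9 − *p*, so positions 2/4/6 map to frame positions
7/5/3, always inside the 6mer core. Each base is replaced through a
fixed transversion map (A→C, C→A, G→T, T→G), which destroys
Watson–Crick pairing at that position whatever the original base; the
original study does not state its replacement bases, so a deterministic
choice was made here for reproducibility.

Because the map is deterministic, a substitution can occasionally spell
a new seed core for another panel member. The design therefore runs in
passes: mutate all detected sites, re-scan, and mutate any newly
created sites the same way, erroring only if the sequence is not
site-free after ten passes (in practice a second pass is rare and a
third essentially never occurs). The returned substitution table
collapses multiply-touched positions to original → final base, and the
post-condition — zero panel sites on re-scan — is enforced, never
silently skipped.

## Small RNA-seq differential expression

The pipeline starts from a mature-miRNA count matrix (read mapping is
out of scope). The stages mirror a standard small RNA-seq workflow:

1. **Detection filter on raw counts** — keep miRNAs with a read count
   strictly greater than `min_count = 10` in at least `min_samples = 3`
   samples. The filter is applied to counts, not CPM, because the
   threshold is a read count.
2. **CPM normalisation** — each sample scaled to one million mapped
   reads, using the column total of the supplied matrix.
3. **Exact Mann–Whitney U test** per miRNA between the low-PD
   (≤ 40 doublings) and high-PD (> 40) groups, on CPM values.

The test statistic U is computed from mid-ranks. For pooled sample
sizes up to 14 the two-sided p-value is exact: all
$\binom{n_x+n_y}{n_x}$ assignments of the observed values to groups are
enumerated (ties handled simply by enumerating over the observed
multiset), and p is the fraction of assignments whose deviation
$|U - n_x n_y/2|$ reaches the observed one. Beyond that, a normal
approximation with tie correction and continuity correction is used.
With 6 + 6 samples, enumeration gives 924 assignments and a smallest
achievable two-sided p of 2/924 ≈ 0.0022; the test is conservative at
any nominal α because of this discreteness, which the null-simulation
property test confirms.

Fold changes are reported as direction-agnostic magnitudes
(max of the two mean ratios, with a pseudo-mean of 0.5 CPM replacing a
zero group mean), and candidate selection requires significance, a fold
change above `fc_min = 1.5`, and a group mean CPM above
`expr_min_cpm`. The expression threshold deliberately has **no
default**: "highly expressed" is a study-specific judgement, so the
caller must state it (the worked examples use 100 CPM).

Two further choices are worth making explicit. The test is unpaired
even though clones are measured at both PD levels, matching the
original analysis; a paired alternative (`wilcoxon_signed_rank()`) is
available. And no multiple-testing correction is applied to the DE
p-values — raw exact p-values are reported, as in the analysis being
reproduced; users wanting FDR control can apply `p.adjust` to the
output.

PCA is computed on log2(CPM + 1), centred per miRNA and unscaled, with
axis signs fixed by making each axis's largest-magnitude loading
positive so results are reproducible across platforms. Sample
clustering uses 1 − Pearson correlation with average linkage; distance
and linkage are common heatmap defaults (the original software is
named but not its settings). The agglomeration is written out in the
package rather than delegated to `hclust` because the merge order is
pinned deterministically — equal-distance merges break ties by the
smallest original item index and each merge lists its lower-index
subtree first — which `hclust` does not guarantee; heights agree with
`hclust` exactly and are cross-checked in the tests.

## Validation statistics

* **qPCR**: relative expression by the single-reference
  $2^{-\Delta C_t}$ method, $\Delta C_t = C_t^{target} -
  C_t^{reference}$ (reference RNU44).
* **Spearman correlation** on mid-ranks; exact permutation p (all n!
  permutations) for n ≤ 8, t approximation beyond.
* **Wilcoxon signed-rank**: zero differences dropped (the convention
  adopted here; the source analysis is silent), W the sum of signed
  mid-ranks, exact p over all $2^m$ sign assignments for m ≤ 20.
* **Friedman test** on within-block mid-ranks,
  $\chi^2_F = \frac{12}{nk(k+1)} \sum_j R_j^2 - 3n(k+1)$; exact p by
  enumerating all $(k!)^n$ within-block permutations when that count is
  ≤ 10^6, chi-square on k − 1 df beyond.
* **Post hoc versus baseline**: the original analysis pairs Friedman
  with Dunnett's test, an unusual combination since Dunnett assumes
  normal theory. `posthoc_vs_baseline()` instead compares each
  treatment to the baseline with the exact signed-rank test and
  multiplies p by the number of comparisons (Bonferroni bound, capped
  at 1) — a conservative rank-based surrogate, documented as such. A
  treatment identical to its baseline returns p = 1 rather than an
  error, since it carries no evidence. Note the resolution limit: with
  6 blocks the smallest exact signed-rank p is 2/64, so with three
  comparisons no adjusted p can fall below 0.094.
* **Dual-luciferase**: per well the ratio is Renilla/Firefly (Renilla
  carries the UTR; Firefly is the transfection control); duplicate
  wells are averaged within an experiment before any cross-experiment
  statistic, and each condition is divided by the same experiment's
  control average, anchoring the control at exactly 1. The WT-vs-mutant
  readout divides the normalised WT ratio by the matched mutant ratio
  (values < 1 mean repression through the mutated sites); wild-type
  over mutant is used, following the figure-legend wording of the
  source analysis.

## The synthetic-data generator

Every generator is a pure function of its `sim_config()`, including
the seed, so identical configs give byte-identical data. Defaults
encode the emulated study design:

* **Counts** (`gen_counts`): 6 clones × (low, high PD) = 12 libraries;
  300 miRNAs with baseline mean CPM log-uniform on [5, 5000]; 10
  planted DE miRNAs with |log2FC| = 1.5 split symmetrically around the
  baseline, direction random; negative-binomial counts with dispersion
  0.1 (clone-to-clone overdispersion; no variance estimates exist to
  calibrate against, so the value is a knob); library sizes uniform on
  [0.8, 1.2] million. Low-PD doubling numbers are drawn from 20–40 and
  high-PD from 41–70, consistent with the ≤ 40 / > 40 grouping.
* **UTRs** (`gen_utr`): planted sites are realised exactly — guard
  flanks prevent accidental upgrade of a 6mer to a 7mer — and the
  background is rejection-sampled until a full panel scan finds only
  the planted sites. Rejection (rather than post-hoc masking of chance
  hits) guarantees the truth list is complete, at the cost of
  occasional resampling.
* **qPCR** (`gen_ct`): $C_t^{target} = C_t^{ref} - \log_2 e +
  \mathcal{N}(0, sd)$ for planted expression $e$, so $2^{-\Delta C_t}$
  recovers the truth in expectation; default reference Ct 25, noise sd
  0.25 cycles.
* **Luciferase** (`gen_luciferase`): per-experiment lognormal baseline
  RL/FF ratio around 2; mimic conditions multiply wild-type construct
  ratios by the planted repression factor (default 0.7), mutants are
  untouched; two duplicate wells, three experiments, multiplicative
  lognormal well noise with CV 5%.

What the generator does *not* emulate: read-level artifacts (adapter
content, mapping multi-hits), within-clone correlation between the low
and high libraries of one clone, donor effects, batch structure, or
compositional coupling beyond the CPM constraint. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean overdispersed-count model, not robustness to every failure mode
of real small RNA-seq data.

## Numerical choices and degenerate inputs

Enumeration-based p-values compare deviations with a 10⁻⁹ absolute
guard so floating-point noise cannot flip a "greater or equal" at the
boundary. CPM columns are checked to sum to 10⁶ within 10⁻⁹ relative
tolerance. Degenerate inputs fail loudly and by name: zero-total
samples in CPM, constant vectors in Spearman, all-zero differences in
the signed-rank test, zero-variance items under correlation distance,
all-constant matrices in PCA, a missing control condition in
luciferase normalisation.

## Problem sizes in the test suite

The property suite runs at desk scale: 1,000 random miRNA/UTR pairs
against a brute-force substring oracle, 500 planted-site UTRs through
the mutagenesis post-condition, a 10,000-miRNA null simulation for the
type-I error bound, 500 planted miRNAs for log2FC recovery, and 20
simulation seeds for the PCA separation property. These sizes give
stable pass/fail behaviour for the properties concerned while keeping
the default test run fast enough to be part of routine development.

## Known limitations

* Site counts depend on which UTR regions are scanned; the package
  takes regions as given and does not fetch or reconcile transcript
  annotations.
* The exact Mann–Whitney enumeration grows combinatorially; beyond a
  pooled n of 14 the normal approximation is used, which is standard
  but no longer exact.
* The Dunnett surrogate is conservative; with few blocks its adjusted
  p-values have a hard floor (see above).
* The scanner implements seed complementarity only; it will report
  seed matches that a context-aware predictor would down-weight.
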