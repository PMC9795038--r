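---
title: "Allele-resolved quantification for RNAi plus engineered replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved quantification for RNAi plus engineered replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnairescue)
```

## The problem

Mutation-agnostic RNAi gene therapy pairs two payloads in one vector: an
RNAi hairpin that silences every endogenous transcript of a disease gene
(wild-type and mutant alike), and a replacement cDNA that must escape that
same hairpin. Escape is engineered by recoding the RNAi-binding site with
synonymous substitutions: the replacement protein is unchanged, but the
guide no longer finds an exact target. After treatment, endogenous and
exogenous transcripts are sequence-identical everywhere *except* that site,
so the recoded site doubles as the only available allele barcode. The
motivating system is *Tmc1*-related dominant hearing loss (the *Beethoven*
mouse), where single outer hair cells are sequenced after treatment and the
questions are: what fraction of *Tmc1* transcripts come from the
replacement, how strongly was the endogenous allele knocked down, and how
much total overexpression did the vector cause.

This vignette records the package's model of each stage, the parameters
that matter, and the design decisions taken where the underlying procedure
left choices open.

## Construct design

A target site is an interval of a coding sequence (0-based, half-open
coordinates throughout the package; the CLI wrapper documents the same
convention). `recode_site()` recodes every codon that lies *entirely*
inside the site: for each such codon it picks the synonymous codon with the
most nucleotide mismatches to the original, breaking ties by
lexicographically smallest codon so results are deterministic. Codons are
independent, so this per-codon greedy choice attains the global synonymous
maximum — a fact the test suite checks against exhaustive enumeration over
all synonymous codon assignments. Two protective rules: codons that only
partially overlap the site are never edited (protein safety outranks
divergence), and stop codons are preserved verbatim and flagged.

`infer_matching_frame()` answers the inverse question — given an
original/engineered pair, in which frame and strand are they synonymous? It
searches all 3 frame offsets x 2 orientations and declares synonymy only
when the peptides over fully covered codons are identical *and* every
differing base falls inside a fully covered codon; without the second
condition an edge difference outside the covered codons could masquerade as
synonymous. For the shipped site pair
(`GACGATCATGTACAGGACCGG` / `CACTATCATATATAGTACTGG`) the unique solution is
the reverse-complement strand in frame 0: both encode `PVLYMIV`, with all
six differences at wobble positions. The sites as printed are therefore
antisense to the coding frame — the package resolves this computationally
rather than assuming an orientation. Interestingly the recoding engine
can place seven synonymous substitutions in this site (per-codon maxima
1+1+2+1+0+1+1); the published design uses six of the seven, and since the
selection rule for which wobble edits to take is not recorded, the package
exposes both a "maximize" mode (`recode_site`) and a "verify a provided
pair" mode (`recoded_site_pair`) rather than guessing.

`verify_resistance()` operationalizes "escapes RNAi suppression" as
thresholds: at least `min_total_mismatches` substitutions overall and at
least `min_seed_mismatches` inside a declared seed interval (the guide's
seed region, positions 1–7 of the site as matched by the guide complement,
is where mismatches disrupt silencing most). These are design heuristics,
not predictions; hairpin thermodynamics and off-target scoring are out of
scope.

## Allele quantification

A fragment is assigned to an allele iff any of its reads contains the
full-length site — or its reverse complement — as an exact substring.
Exactness is deliberate: with 21-nt sites at Hamming distance 6, a
sequencing error inside the site removes the read from *both* tallies
(symmetric loss, no bias) rather than flipping its assignment, which would
require six coordinated errors. Mates sharing a read id are collapsed to
one fragment; a fragment matching both alleles is contradictory and counts
for neither (warned). Reads carrying `N` in the window never match.

Group allele fractions are *pooled*: cells with no site-spanning reads are
excluded and percentages are computed from summed counts, not from a mean
of per-cell percentages — matching the stated procedure of estimating "the
percentage ... in all cells containing reads at the binding site". Per-cell
expression is depth-normalized as counts per million; the underlying study
says only that counts were adjusted for per-cell depth, and CPM is the
simplest defensible reading (full-length single-cell chemistry, no UMIs).
The group fractions are then applied to every cell of the group
(`allocate_allele_expression`), with the exogenous share computed as the
remainder so the two components sum to the cell's expression exactly.

Knockdown efficiency is
`100 x (1 - mean(treated endogenous CPM) / mean(control total CPM))`,
treating untreated controls as fully endogenous. A published single figure
of 85% "among treated animals" is not exactly reconstructible from the
published per-group fractions (76.4%/96.5%) and fold changes
(83.6%/248%): applying this estimator group-wise to those figures gives
roughly 55% and 88%, and the weighting behind the single 85% is not
recorded. The package therefore reports the estimator per group *and*
pooled across treated cells, and documents the estimator itself rather
than inverting the printed number.

## QC filters and statistics

`filter_cells()` applies the gene filter first — genes detected in at
least `min_cells_per_gene` (default 3) cells — and only those surviving
genes count toward each cell's genes-expressed tally (default threshold
3000), matching the "such genes" word order of the source protocol. The
mitochondrial fraction (default ceiling 7%) is a read-level quantity and is
computed on the unfiltered table; mitochondrial genes are recognized by a
configurable id pattern (default `^mt-`, the mouse convention). The order
matters: the test suite includes a table where a cell survives a naive
all-genes tally but is correctly dropped under gene-first filtering. A
single pass is performed; re-filtering an already-filtered stable table is
a no-op.

`ddct_knockdown()` aggregates Ct triplicates by arithmetic mean (the
conventional reading of "assessed in triplicate"; no outlier rejection),
then `ddCt = dCt_test - dCt_control`, relative expression `2^-ddCt`, and
knockdown `100 x (1 - 2^-ddCt)` — computed from the means, with the
per-replicate spread reported alongside.

The group-comparison battery mirrors the field's standard decision tree:
Welch's t for two groups; for three or more, Bartlett's test at alpha =
0.05 (the source says only "significantly different"; 0.05 is the
conventional reading and is configurable) gates between classic one-way
ANOVA with Tukey's HSD and Welch's ANOVA with a Dunnett-T3-style post hoc.
For the latter the package computes pairwise Welch t statistics with
Welch–Satterthwaite degrees of freedom and applies a Sidak family
adjustment — a conservative approximation of Dunnett T3's
studentized-maximum-modulus reference distribution, recorded as `sidak`
in the output so no result misrepresents its adjustment. Groups
with zero variance make Bartlett undefined; these route to the Welch path
with a warning. `kruskal_dunn()` uses the tie-corrected Kruskal–Wallis H
(via `stats::kruskal.test`) and implements Dunn's z from its closed form,
with Benjamini–Hochberg adjustment across all pairs of one endpoint as the
family.

## Synthetic data: what it emulates and what it does not

The generators mirror the structure of the motivating experiment and are
pure functions of their arguments including the seed.

* `simulate_site_reads()` — per cell, each site-spanning read is a random
  flank + the allele's site (allele ~ Bernoulli(exogenous fraction),
  orientation ~ Bernoulli(0.5)) + a random flank, followed by uniform
  per-base substitution error. Defaults: 100-nt reads, 0.5% error.
* `simulate_expression_table()` — per-cell total expression in CPM is
  negative binomial with group mean `control_mean_cpm x fold_change`
  (variance `mu + mu^2 x dispersion`; overdispersion is evident in
  published per-cell spreads, though the distribution itself is the
  package's choice), split into endogenous/exogenous components by the
  group's true fraction. Depth is lognormal (median 5e5 reads,
  sdlog 0.3); filler genes and `mt-` pseudo-genes are emitted so the QC
  filters are exercisable and row sums approximate the drawn depth.
* `simulate_allele_expression()` — draws the two allele components as
  independent negative binomials; used for knockdown-recovery experiments
  where the treated endogenous mean is set directly to
  `control mean x residual`.
* `simulate_qpcr()` — the test sample's target Ct is shifted by
  `-log2(residual expression)` plus Gaussian per-replicate noise.

The shipped presets (`study_presets()`, stored as data in
`inst/extdata/study_groups.json`) mirror the four experimental groups of
the motivating study — wild-type and *Bth/+* untreated controls (fully
endogenous, fold change 1) and two treated groups with exogenous fractions
0.764 and 0.965 and fold changes 1.836 and 3.48 — at 12 cells per group,
control mean 300 CPM, and an implied knockdown residual of 0.15.

What the simulation does **not** model: transcriptome-wide structure,
splicing, UMIs, ambient RNA, chimeric reads, quality-score-correlated
errors, indels, or cell-type mixtures. Passing recovery tests therefore
demonstrates estimator correctness under the stated generative model, not
robustness to artifacts of real libraries; the real-data pathway is
validated structurally (formats, QC behavior, exact-match semantics), and
its exactness guarantees — an error-free read set is recovered ledger-exact
— are as strong as on real data because the counter has no tunable model.

## Numerical choices and problem sizes

Recovery experiments use 25 simulation replicates at the study's scale
(12 cells x 200 site reads for allele fractions; 12 cells per group for
knockdown; 50 cells per group, dispersion 0.15, for fold-change recovery),
which puts Monte-Carlo error comfortably inside the documented tolerances
(pooled fractions to within 1 percentage point, knockdown to 3, fold-change
increases to 5% relative). Zero dispersion is the deterministic
`round(mu)` limit. Degenerate statistical inputs have defined behavior:
two constant groups compare with p = 1 (equal means) or 0; all-identical
observations give H = 0, p = 1. Seeds must be supplied explicitly; derived
sub-seeds (per group, per replicate) are simple offsets so runs are
reproducible file-for-file, and report timestamps are isolated in a single
provenance field so everything else is byte-reproducible.

## Known limitations

* The exact-match counter requires reads to span the full 21-nt site; site
  coverage, not gene coverage, limits the cells usable for fractions.
* Allele allocation applies one pooled fraction to every cell of a group;
  a per-cell mode exists implicitly (run `pooled_allele_fraction` on one
  cell) but is not the default, by design.
* The Dunnett-T3 stand-in is conservative relative to the
  studentized-maximum-modulus distribution.
* The knockdown estimator compares group means of different animals'
  cells; it is a population-level, not per-cell, quantity, and inherits
  the ambiguity discussed above when reduced to a single figure.
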