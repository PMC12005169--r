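---
title: "Detecting and dating whole-genome duplications with wgdkit"
author: "wgdkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating whole-genome duplications with wgdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdkit)
```

## The problem

A whole-genome duplication (WGD) doubles every chromosome. Over time most
duplicated genes return to single copy (fractionation), but the event
leaves durable signatures: an excess of gene pairs at a common synonymous
divergence, duplicated collinear blocks, a 2:1 syntenic depth against an
unduplicated relative, and characteristic biases in which gene families
stay duplicated. wgdkit implements the standard analysis chain that reads
these signatures from coding sequences and gene order, together with a
clade simulator that plants a known WGD so every stage can be tested
against ground truth.

The motivating scenario, which the simulator's defaults emulate, is a
recent duplication shared by two sister species: paralog pairs created by
the WGD cluster at Ks ≈ 0.18, the two species' orthologs diverge at
Ks ≈ 0.08 (younger than the WGD, so the event predates their split), and
two much older duplication signals (Ks ≈ 0.92 and ≈ 2.03, the Brassicaceae
α-WGD and eudicot γ-triplication) persist in the background of the paralog
distribution.

## Ka/Ks: the molecular clock behind everything

`ng86()` implements Nei–Gojobori (1986) counting. Each codon position
contributes a fractional synonymous site count — the fraction of its three
possible single-nucleotide changes that preserve the amino acid (changes
creating a stop count as nonsynonymous, which keeps S + N equal to exactly
three times the compared columns). Codons differing at several positions
are resolved by averaging synonymous/nonsynonymous step counts over all
minimal substitution pathways, dropping pathways through stop codons; if
every pathway is blocked, the column is dropped from the comparison. The
proportions ps = Sd/S and pn = Nd/N are corrected for multiple hits with
Jukes–Cantor, d = −(3/4)·log(1 − 4p/3), which is undefined at p ≥ 3/4; such
pairs are flagged `saturated` rather than given a value.

We chose NG86 over ML codon models because it is closed-form: every number
it produces can be recomputed by explicit enumeration, which is how the
test suite checks it (an independent pathway-enumeration oracle over a
fixed codon alphabet). The estimator is a config point with one
implemented member; peak positions can shift by a few percent between
estimators, which matters when comparing absolute peak values across
studies.

Pairs are aligned by `align_codon_pair()`: a global protein alignment
(BLOSUM62, affine gaps 10/0.5) back-translated to codons, so gaps always
land on codon boundaries. Gap and ambiguous-base columns are excluded
pairwise.

## Ks peaks: log-normal mixtures selected by BIC

`ks_mixture()` fits Gaussian mixtures to log(Ks) by EM — equivalently
log-normal mixtures in Ks space — for each candidate component count K,
and selects K by minimum BIC with ties broken toward fewer components.
Initialization is quantile-based plus 10 random restarts; convergence is
declared at a log-likelihood increment below 1e−8 with a 500-iteration
cap, and the per-iteration log-likelihood trace is retained so tests can
assert EM monotonicity. Fitting in log space reflects the roughly
multiplicative noise of divergence estimates; raw-Ks Gaussian fitting is a
defensible alternative but mixes component scales.

A component's reported "peak" is its Ks-space median exp(μ_log), not the
log-normal mode exp(μ − σ²). Peak positions quoted in the WGD literature
behave like central tendencies, and the median is invariant to σ; the
choice is documented here and trivially switchable downstream since
`coef()` exposes all component parameters.

The default Ks filter range is [0.005, 3]: the lower bound removes the
zero-inflation of allelic/recent duplicates, the upper bound removes
near-saturated estimates while still admitting a γ-scale peak near 2. One
caveat found while validating the fitter: when a sample is drawn *exactly*
from a mixture whose oldest component sits near 2, truncating at 3 clips
that component's upper tail and BIC compensates with an extra component.
For recovery experiments on synthetic draws we therefore pass a filter
range that admits the whole sample; for real paralog data the default
range is the right tool because values beyond 3 are saturation noise, not
log-normal tail.

`estimate_wgd_age()` converts a peak to an age by linear calibration
against a WGD of known age — by default the Brassicaceae α-WGD at Ks 0.85
and 35 My, giving age = 35 × peak/0.85 (so a 0.18 peak dates to ≈ 7.4 My)
and an implied synonymous rate of 0.85/(2 × 35 Myr) ≈ 1.2e−8 per site per
year. `test_shared_wgd()` encodes the placement logic: a WGD is shared by
two species exactly when their ortholog-divergence peak is younger
(smaller Ks) than the WGD peak, with a dead band (default ±0.02) in which
the verdict is "ambiguous" rather than forced.

## Duplicate classification by collinearity

`chain_anchors()` chains similarity hits into collinear blocks per
scaffold pair by dynamic programming over gene-order ranks (strand is
ignored for ordering, as in gene-order collinearity tools): +10 per
anchor, −1 per skipped rank on either side, consecutive anchors at most
`max_gap = 25` ranks apart, both orientations, greedy extraction of
non-overlapping chains by descending score with ties broken toward the
smaller starting rank (for determinism). Blocks need `min_block = 5`
anchors by default — the right scale for duplicate calling; a 30-gene
minimum span is conventional for plotting-scale macro-synteny and is
available through the same knob.

`classify_duplicates()` applies the precedence wgd > tandem > proximal >
dispersed: block anchors are WGD pairs; remaining same-scaffold pairs
within 1 rank are tandem, within 10 proximal; the rest dispersed. The gaps
follow the conventions of the widely used duplicate-classification
pipelines and are configurable. `syntenic_depth_ratio()` counts, for each
reference gene, the blocks covering its rank: a once-duplicated genome
shows modal depth 2 against an unduplicated reference (the 2:1 quota) and
1 between two unduplicated genomes.

## Telomere window scan

`scan_telomere_windows()` counts occurrences of three tandem copies of the
plant telomere unit TTTAGGG (a 21-bp query) and its reverse complement in
non-overlapping windows (1 Mb by default; the pipeline uses 10 kb on
simulated chromosomes, which are far shorter than real ones). Overlapping
matches are all counted — a perfect array of k units contains exactly
k − 2 overlapping 21-mers — and a window is retained at ≥ 20 copies. The
threshold is applied to the summed forward + reverse count by default,
with a flag for separate thresholds, since the orientation of a telomere
array depends on which end it caps. Matches spanning a window boundary are
credited to the window containing the match start; N bases never match.
`classify_contig_telomeres()` calls a contig telomere-to-telomere
(`both_ends`) when its first and last windows are both retained.

## Fractionation and retention

`fractionation_profile()` follows homoeolog retention along an
unduplicated reference: per reference scaffold the two target scaffolds
with the most syntenic copies are the homoeologs (ties by name, for
determinism), and each window of 100 consecutive reference genes (25 in
the desk-scale pipeline, matching simulated scaffold sizes) yields a
retention percentage per homoeolog. Windows are non-overlapping;
`fractionation_bias_test()` then applies a two-sided exact sign test to
the per-window retention differences. The original assessments of
fractionation bias in this setting were visual; the sign test makes the
call reproducible, and is deliberately nonparametric because neighbouring
genes' retention is correlated within a window but window differences are
exchangeable under the no-bias null.

`classify_retention()` reproduces the pangene copy-number logic over two
outgroups and two WGD ingroups: rows single-copy in both outgroups with
ingroup counts in {1, 2} partition into retained-in-both (2,2),
single-in-both (1,1), and retained-in-one (2,1)/(1,2); everything else is
`filtered_out`. Pangenes absent (0 copies) from an ingroup are filtered
rather than treated as single-copy — absence in a pangene table is more
often an assembly/annotation artifact than a biological loss, and
excluding them keeps the four retention classes interpretable.
`go_enrichment()` is a classic one-sided Fisher (hypergeometric) test per
GO term with raw p-values; hierarchy-aware weighting (as in topGO's
weight01) is intentionally out of scope, so enrichment output is
schema-compatible with such analyses but p-values are not comparable to
hierarchy-weighted ones. The input gene→GO map is used as given; no
ontology-graph propagation is performed.

## The clade simulator

`simulate_clade()` generates a four-species clade —
(((ingroupA, ingroupB), outgroup1), outgroup2) — with the WGD on the
ingroup stem. Defaults: 200 ancestral genes of 300 codons on 4
chromosomes, splits at 40, 25 and 3.3 My, WGD at 7.4 My, synonymous rate
0.012/site/My, so expected WGD-pair Ks is 2 × 0.012 × 7.4 ≈ 0.178 and
ortholog Ks ≈ 0.079 — the shared-recent-WGD signature. Nonsynonymous rate
defaults to 0.2 × the synonymous rate (typical purifying selection). Gene
loss removes one homoeolog per pair with probability 0.2 per ingroup
species, split between subgenomes by `loss_bias` (0.5 = unbiased); tandem
duplicates arise with probability 0.05 per gene; 30 telomere units are
planted at each chromosome end.

Sequence evolution applies Poisson substitution events per site — third
positions at the synonymous branch length, first/second positions at the
nonsynonymous one — with uniform stop-avoiding replacement, so multiple
hits occur and the Jukes–Cantor-corrected estimator is consistent.
Ancestral CDS are restricted by default to codons whose third position is
four-fold degenerate (Ala/Gly/Val/Pro/Thr families), which makes the
synonymous-site bookkeeping exact and the analytic expectations
closed-form; a flag admits arbitrary sense codons, at the cost of a small
(amino-acid-context dependent) bias between nominal branch lengths and
NG86 expectations. With nonsynonymous changes enabled, an amino-acid
substitution can alter a third position's degeneracy, so realized Ks is
exactly 2rT only at ka = 0; at the default ka/ks = 0.2 the deviation is
well under the Monte-Carlo tolerances used in tests.

What the simulator does *not* model: indels, codon-usage bias,
pseudogenes (losses are whole-gene deletions — what a pangene analysis
can actually see), transposable elements, and the ancient α/γ background
peaks (multi-modal Ks samples for peak-recovery experiments are drawn
directly from specified log-normal mixtures via `simulate()` on a
`ks_mixture` object). Passing the recovery tests therefore demonstrates
correctness of the estimators under the model's assumptions, not
robustness to alignment error, annotation noise, or rate variation in
real genomes.

A single RNG stream is seeded once per run from `SimConfig$seed`; the same
seed gives byte-identical FASTA/GFF3/truth outputs, and the truth log
(WGD pairs, ortholog pairs, tandem pairs, losses, planted telomeres) is
complete, so conservation identities (e.g. emitted ingroup genes =
2 × n_genes − losses + tandems) are checked exactly.

## The end-to-end pipeline

`run_wgd_pipeline()` chains the stages on a simulated clade: synthetic
k-mer-seeded similarity hits (a deterministic stand-in for an all-vs-all
protein search, valid only for the simulator's indel-free genes) →
blocks → duplicate classes → NG86 Ks for WGD-classified pairs → mixture
peaks → calibrated age → cross-species ortholog Ks → shared-WGD verdict →
telomere scan → syntenic depth vs an outgroup (with the
outgroup-vs-outgroup comparison as the built-in no-WGD negative control) →
fractionation bias → pangene retention classes. The report is a plain
list, serialized to JSON and validated against a shipped field schema.

Problem sizes are deliberately desk-scale: 200 genes × 300 codons keeps a
full run in the low minutes while leaving every statistical check
well-powered (≈ 160 WGD pairs for the paralog fit, ≈ 8 fractionation
windows, ≈ 80 loss events). Real-data use replaces the simulated inputs
with `load_gene_models()` (FASTA + GFF3, longest-mRNA CDS, 0-based
half-open internally with conversion at the format boundary) and
`read_hit_table()` (12-column BLAST tabular; e-value ≤ 1e−10 and top-5
non-self subjects per query by default — the usual pre-filter scale for
duplicate classification, stated explicitly because published pipelines
rarely do).

This package exposes its functionality as an R API rather than a shell
tool: the functions above, `run_wgd_pipeline()`, and the repository's
`scripts/acceptance.R` are the intended entry points.

## Numerical choices, in one place

* EM: tol ΔlogL < 1e−8, max 500 iterations, 10 restarts, σ_log floored at
  1e−4, BIC ties → smaller K.
* NG86: stops count as nonsynonymous in site counting; stop-crossing
  pathways excluded; all-blocked columns dropped; saturation at p ≥ 3/4.
* Chaining: reward 10, gap penalty 1/rank, max_gap 25, min_block 5,
  score ties → smaller starting rank.
* Classification gaps: tandem ≤ 1, proximal ≤ 10.
* Telomere: 21-bp query, overlapping counts, ≥ 20 copies joint threshold,
  window-start boundary rule.
* Retention filter: outgroups exactly 1, ingroups in {1, 2}; zeros
  filtered out.
* Calibration: age = calib_age × peak/calib_peak; defaults 35 My at
  Ks 0.85. Note 35 × 0.18/0.85 = 7.41: one-decimal reporting (7.4) is
  stable, further decimals depend on unrounded peak estimates.
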