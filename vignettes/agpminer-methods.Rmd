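---
title: "Methods: HRGP mining and expression profiling in agpminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRGP mining and expression profiling in agpminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agpminer)
```

This vignette documents the models and procedures behind `agpminer`,
the parameters that matter, the numerical choices at the edges, and
what the synthetic-data generators do and do not emulate. The package's
interface is its exported R functions; analyses are scripted directly
against them.

## The mining model

Hydroxyproline-rich glycoproteins are defined compositionally. The
pipeline therefore works residue-by-residue on predicted protein
sequences, combining them with external predictor outputs supplied as
tables (`read_prediction_table()`, `read_domain_table()`). Hydroxyproline
can enter either as the residue letter `O` in the FASTA or as `P` plus a
per-position probability; both are reconciled by `hyp_positions()`, with
pre-marked `O` treated as probability 1. All coordinates everywhere are
1-based inclusive, matching how peptide spans are conventionally printed
(a mature span 27–42 of a protein whose signal ends at 26 and whose
omega site is 43).

### Filtering funnel

A protein is called secreted when at least two of the three secretion
predictors vote yes (three voters admit no tie); the signal end is the
median cleavage site among the agreeing predictors — the median is robust
to one discordant prediction and deterministic. Secreted proteins with
at least `min_hyp = 3` probable hydroxyprolines continue. The
hydroxylation probability threshold is exposed (`hyp_threshold`,
default 0.5) because published pipelines do not agree on a universal
cutoff; where no external hydroxylation model is available,
`predict_hyp_rule()` offers a transparent stand-in (a proline is called
hydroxylated when ≥ 60% of its ±5-residue window is P/A/S/T) — a
documented heuristic for testing, not a reimplementation of any trained
model.

### AG glycomodule scanning

An AG glycomodule is a dipeptide from {PA, PS, PT, AP, SP, TP} plus the
tentative {VP, PV, GP, PG}, with the proline hydroxylated. The scanner
defaults to the 10-motif alphabet; MAAB coverage (below) uses the
conservative 6-motif core so that the tentative motifs do not inflate
coverage. A hydroxyproline inside a run of three or more contiguous P/O
residues is an extensin-style site, not an AG site, so such motifs are
removed before clustering (`AOOO` yields nothing). Overlapping motifs
are all counted (`AOA` holds both AO and OA).

Clustering chains motifs whose **gap** — residues strictly between one
motif's end and the next motif's start — is at most `max_gap`; chains
with at least `min_motifs` motifs are reported once, as maximal chains,
not as all sub-chains. The relaxed rule is (3, 10), the strict rule
(4, 4); every strict pass is therefore a relaxed pass. Whether "apart"
should be read as gap or as start-to-start distance is genuinely open;
the gap reading keeps adjacent motifs at distance 0 and is the
convention pinned here (the scanner's brute-force oracle in the test
suite enumerates every contiguous motif subsequence, so the convention
is exercised explicitly).

### MAAB classification

Bias fractions are computed over the full sequence (signal included):
P/A/S/T for AGPs, P/S/K/Y for extensins, P/V/K/C for PRPs, with O
counting as P. Computing bias on the full rather than the mature
sequence avoids coupling the classification to cleavage-site accuracy;
signals are short relative to the sequences being classified. The
thresholds are `bias_min = 0.45` and `coverage_min = 0.15` of residues
under family motifs (AG dipeptides; SP₃₋₅; PPVX[KT] and KKPCPP), with
union coverage counting overlapped residues once, and extensin calls
additionally requiring ≥ 2 SP₃₋₅ motifs.

Only classes 1, 4 and 24 have fixed published semantics usable here:
biased + AGP-covered + GPI → 1; the same without GPI → 4; biased but
under-covered → 24. The remaining numbers of the 24-class scheme are a
**reconstruction** (EXT → 2, PRP → 3, two-family hybrids → 9/10/11,
three-family → 12) shipped as a data table (`maab_class_table()`) that
callers can replace wholesale; nothing downstream depends on the
numbers of classes other than 1/4/24. Sequences lacking a C-terminus
are never called GPI-anchored and carry a `partial` flag, since GPI
prediction on truncated sequences is unreliable.

### Architecture and families

The mature peptide runs from `nsp_end + 1` to `omega − 1`; the omega
residue itself is excluded because the printed spans of processed AG
peptides end one residue before the omega site, and it is returned
separately (`omega_residue`) for users preferring the inclusive
convention. Topology alternates extracellular/intracellular across TM
segments, starting extracellular for secreted proteins. Families are
assigned with priority FLA > KLA > AG peptide > classical AGP: the
priority resolves hypothetical multi-domain chimeras deterministically
(a fasciclin+kinase chimera would be unprecedented; FLA was chosen and
is documented). A KLA whose AG spans all fall intracellular keeps its
label but carries an `intracellular-AG-span` warning — hydroxylation
models are trained on secreted sequence, so such spans deserve great
caution. Kinase accessions default to PF07714 and PF00069 and are a
parameter.

## Alignment-free phylogeny

AG peptides are too short and divergent for trustworthy alignment, so
their tree is built from 3-mer counts. `O` is mapped to `P` before
counting (hydroxylation is a prediction, not sequence) and windows
containing `X` are skipped. The distance is the fractional common k-mer
count `F = Σ_w min(c_a(w), c_b(w)) / (min(L_a, L_b) − k + 1)`
transformed as `d = −ln(0.1 + 0.9F)`, pinned explicitly (with a raw
`1 − F` option) so results do not depend on any package's default.
Neighbor joining is the standard Saitou–Nei agglomeration and exactly
recovers additive matrices; `nj_tree()` accepts arbitrary matrices so
alignment-derived distances can be substituted.

Bootstrap for alignment-free data has no sites to resample; the
replicate unit here is the **k-mer word type** (columns of the count
table), resampled with replacement — the standard surrogate, documented
as a dialect choice. A replicate can leave a sequence with no sampled
words; such a sequence shares nothing (`F = 0`) in that replicate.
Support is the number of replicates (of `B = 100`) containing each
original internal bipartition; edges with support ≤ 50 are contracted
into multichotomies (`collapse_low_support()`, idempotent by
construction).

## Expression statistics

Per replicate, `ΔCt = Ct_gene − mean(Ct of the two reference genes)`
within the same sample and replicate; `log2FC = −(ΔCt − mean control
ΔCt) · log2(E)` with amplification efficiency `E = 2` by default (the
parameter is exposed for efficiency-corrected analyses). The control
sample's mean log2FC is zero per gene by construction, regardless of
noise. Each non-control sample is compared with the control by a
two-sided t-test — Student's for the wounding time course, Welch's for
the heterogeneous tissue panel, selectable by flag — and p-values are
BH-adjusted **jointly across all genes and comparisons** of a dataset.
A change is highlighted when it is significant (adjusted p < 0.05) and
strictly larger than 2 log2-fold; the boundary value 2.0 is not
flagged.

Association profiling runs on per-gene mean log2FC across samples
(replicate-level profiles are available via the returned `rel_expr`
data; sample means were chosen as the primary convention and the open
question is noted here). Pearson correlation feeds complete-linkage
clustering on `1 − r`; mutual information is estimated on an
equal-frequency binned contingency table with `⌈√n⌉` bins per margin
and bias-corrected by the delete-one jackknife,
`BCMI = n·MI − (n−1)·mean(MI₍₋ᵢ₎)`. The bin assignment is computed once
on the full data and the jackknife deletes observations from the
counts; re-binning every leave-one-out subset makes the estimator's
jackknife variance explode at small n (bin boundaries jump
discontinuously), drowning real dependence — with 16 samples the
re-binned variant's noise-pair BCMI spread exceeds the strongest
planted signals, while the fixed-assignment jackknife is stable. Exact
numerical agreement with kernel-based BCMI implementations is not
claimed; the estimator is fully specified instead. The top 5% of the
`C(G,2)` pairs (ties by id pair, `floor` of the fraction: 7 pairs for
18 genes) flags the strongest dependencies, including nonlinear ones
invisible to Pearson correlation.

## What the generators emulate

`make_proteome()` plants, per category, sequences that satisfy their
defining thresholds *by construction* and verifies them post-generation
against the package's own classifiers (a violation is an error, never a
silent mislabel): classical AGPs (~105 aa, PAST > 45%, ≥ 12 AG motifs,
with/without omega), AG peptides (< 90 aa, 6 motifs with gaps ≤ 2,
omega), FLAs (planted fasciclin hit flanked by AG spans), KLAs
(extracellular AG span, TM, intracellular kinase hit), extensin-like
sequences (SPPPP repeats: extensin bias and coverage, no AG motifs),
biased-but-motif-poor sequences (hydroxyprolines confined to PPPP runs
→ class 24), and non-secreted background with PAST capped at 0.30 —
clearly below the 0.45 bias threshold. Prediction bundles carry the
exact planted annotations ("perfect knowledge"): passing tests shows
the pipeline's logic is correct *given* correct predictions, not that
external predictors are accurate on real transcriptomes. Domain hits
are planted as annotations; the underlying residues are not
HMM-realistic sequence.

`make_wounding_ct()` emulates a 7-point wounding time course (0 min
control to 48 h, 3 replicates): two sharply induced genes with planted
peaks of 6.5 and 3.3 log2-fold at 6 h (modest change at 30 min, sharp
rise by 3 h, steady decline after the peak), a late riser (+2 at 48 h),
a late decliner (−1.5 at 48 h), two stable genes and two flat reference
genes. Ct noise is additive Gaussian with σ = 0.2 cycles — a typical
replicate SD for SYBR assays — applied independently per replicate, so
log2FC recovery is unbiased and exact at σ = 0.

`make_tissue_ct()` emulates a 16-sample tissue/organ panel (rosette
leaf as control) with 18 target genes spread τ = 2 log2 units across
samples. Correlated pairs share a latent sample effect with analytic
weights (`x = z`, `y = ρz + √(1−ρ²)e`; planted ρ = 0.93 and −0.8). The
nonlinear pair is exactly quadratic: one gene follows a **fixed**
per-tissue design profile and its partner the standardized square of
it. Tissues are fixed biological conditions, so a fixed design is the
natural model; the design vector was chosen once with zero third moment
(Pearson r of the pair ≈ 0) and with the magnitudes of its two parabola
arms occupying distinct rank quartiles, so the dependence survives
equal-frequency binning rather than being halved by the ±z fold of a
symmetric parabola. At n = 16 a random-latent quadratic pair is
frequently invisible to any small-sample MI estimate; the fixed design
makes the planted phenomenon (high BCMI, |r| < 0.5) reproducible, which
is what the generator is for.

## Problem sizes and determinism

Every stochastic component takes a seed, and fixed seeds give
byte-identical generator output. The test suite exercises the scanner
against a brute-force enumerator on 1000 random sequences, neighbor
joining on 100 random additive matrices (n ≤ 8), bootstrap with B = 100,
and 200 simulation replicates for the expression-recovery and BCMI
properties — sizes at which the Monte Carlo error of the checked means
(≈ 0.01–0.02) is far below the asserted tolerances (±0.05).

## Known limitations

The MAAB class numbers outside {1, 4, 24} are a reconstruction, not the
published tree. The hydroxylation stand-in is a window heuristic; real
mining should supply model-based probabilities. The k-mer distance and
bootstrap dialect are pinned reconstructions of common alignment-free
practice. BCMI values are estimator-specific; ranks, not magnitudes,
should be interpreted. The generators do not simulate predictor error,
HMM-realistic domain sequence, or read-level RNA-seq.
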