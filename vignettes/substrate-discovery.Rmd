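---
title: "Discovering dipeptidyl peptidase substrates from TAILS N-terminomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering dipeptidyl peptidase substrates from TAILS N-terminomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppsubs)
```

## The model

Dipeptidyl peptidases (DPPIV / S9b family) are exopeptidases: they remove one
dipeptide at a time from the free N-terminus of a substrate, cleaving
C-terminal to the second residue. Throughout this package the residues around
the scissile bond follow protease nomenclature: P2 is the first residue of
the mature protein, P1 the second (the bond after it is cleaved), and P1′ the
third, which becomes the first residue of the product. All coordinates are
1-based inclusive indices on the annotated protein sequence, with the
initiator Met at position 1.

A TAILS (terminal amine isotopic labeling of substrates) experiment enriches
protein N-termini, so each quantified peptide is anchored at a position in
its protein. Comparing a protease-proficient wild-type against two
loss-of-function mutant genotypes (a gene deletion and a catalytically dead
point mutant), a genuine substrate leaves a two-part signature in the plane
spanned by the two mutant-vs-wild-type log2 fold changes:

* the intact N-terminal peptide (the **substrate**) accumulates in the
  mutants, where it is no longer consumed;
* the peptide starting exactly two residues later (the **product**) is
  enriched in wild-type, where it is produced.

The pipeline operationalizes this signature in four stages: expected mature
N-terminus annotation, reporter-matrix processing, quadrant classification,
and substrate–product pairing.

### Expected mature N-terminus

Two co-translational rules determine where a protein's observable N-terminus
is expected, in strict precedence order:

1. **Signal peptide**: if an annotation is present, the mature N-terminus is
   `signal_peptide_end + 1`.
2. **Initiator-Met excision**: if residue 1 is Met and residue 2 is small
   (Gly, Ala, Ser, Thr, Cys, Pro or Val), Met1 is removed and the mature
   N-terminus is residue 2.

Otherwise the mature start is residue 1. Exactly one rule fires per protein;
an `X` or any non-excision residue at position 2 leaves the start unchanged.
Fragments not beginning with Met are tolerated (the excision rule simply
never fires). A peptide starting at the mature N-terminus classifies as
`nterm_substrate`; one starting `2k` residues downstream (k ≤ `max_cycles`,
default 15, covering long sequential processing runs) as `nterm_product`;
everything else — including odd offsets — as `internal`. Odd-offset
downstream peptides do occur in real data (processing may start from an
alternative frame we cannot verify); the package deliberately classifies
them `internal` rather than guessing, and the `offset` column makes them
easy to inspect.

### Digestion

In-silico digestion is Arg-C-like by default: cleavage after Arg, at most
one missed cleavage, peptide lengths 7–40 (a detectability window; the upper
bound is a package choice, exposed in `digest_params()`). Optional proline
blocking (no cleavage before Pro) is off by default because the digestion
specificity the pipeline mirrors names no proline rule. Semi-specific
enumeration — peptides with exactly one protease-generated terminus, the
other created by in-vivo processing — is what makes neo-N-termini visible;
the enumerator is validated against an exhaustive brute-force oracle over
all substrings in the test suite.

### Reporter-matrix processing

Channel intensities are log2-transformed (zero means non-detection and
becomes missing), median-centered per channel (the observed median of every
channel is exactly zero afterwards; the operation is idempotent), and
missing cells are imputed with **MinProb**: per channel, draws from a
Gaussian centered at the `q = 0.01` quantile of the observed values with
sd `0.3 ×` the observed sd. This models detection-limited (left-censored)
missingness. Imputation is seeded, never touches observed cells, and draws
in a canonical row order so results do not depend on row arrangement. Fold
changes are means over replicate channels (mutant minus wild-type), computed
on the imputed matrix by default; a flag (`fc_mode = "observed"`) restricts
to observed values for sensitivity analyses.

**Detected-only handling.** A peptide observed in at least one channel of
one side of a comparison and in none of the other side is informative beyond
its imputed fold change: the imputation floor sits at the low quantile of the
whole channel, so for low-abundance peptides the imputed fold change is
compressed toward zero no matter how clean the on/off pattern is. Following
common practice for "exclusively detected" proteins, such rows have their
log2 fold change recorded as a documented finite cap (`absent_fc`, default
±10) before classification and pairing. The cap keeps all fold changes
finite, is disable-able (`absent_fc = NULL`), and only ever strengthens an
already-directional observation.

### Quadrant classification and pairing

With threshold `fc_threshold = 2` (log2 units) a peptide is a
`substrate_candidate` when it exceeds the threshold upward in **both**
comparisons and starts at the mature N-terminus, and a `product_candidate`
when it exceeds downward in both and starts at an even dipeptide offset.
Requiring both comparisons is the package's reading of "red" peptides in the
underlying figure methodology; a config flag (`fc_gate = "either"`) gives the
laxer reading. Peptides starting beyond residue `max_start = 50` are
position-filtered: N-terminal biology is confined to the front of the
protein, and deep internal peptides serve only as normalization ballast.
Position-filtered peptides are also barred from pair membership — on
synthetic data, deep missed-cleavage peptide pairs two residues apart
occasionally acquire a spurious detected-only cap under stochastic dropout
and would otherwise form false pairs.

Pairs `(s, p)` require: start offset in `allowed_offsets` (default {2}, one
dipeptide step), at least one member beyond the threshold in both
comparisons, opposite movement (substrate up, product down; relaxable), and
a Manhattan distance `|Δfc_del| + |Δfc_cat| ≥ manhattan_min = 4`. The
Manhattan criterion is read as a **minimum** separation: substrate and
product move in opposite directions, so genuine pairs are far apart in
fold-change space; the opposite (≤) reading is available via
`manhattan_cmp = "le"` because the source wording is ambiguous. Matching is
one-to-one and greedy by descending distance with deterministic tie-breaks
(smaller offset, then lexicographic keys); an exhaustive maximum-weight
option exists behind `matching = "exhaustive"`. Candidates are reported as
pairs plus unpaired substrate/product singletons (detection bias and
substrate/product stability routinely break one side of a pair); singleton
products infer their substrate start as `start − 2`. For singletons the
both-comparisons gate applies, matching the pair-member gate. P2/P1/P1′ are
read from the proteome at the inferred substrate start; candidates whose P
positions fall outside the protein are flagged (`p_ok = FALSE`), never
dropped.

## IP-MS differential enrichment

Protein groups flagged as decoys, contaminants or site-only identifications
are removed. Missing log2 LFQ intensities are imputed per sample from
`Normal(mean − 1.8·sd, 0.3·sd)` (Gaussian downshift, simulating
low-abundance signals). The test statistic is the variance-offset
(SAM-style) moderated t, `d = (mean_bait − mean_control) / (se + S0)`, where
`se` is the pooled two-sample standard error; `S0` de-emphasizes
small-variance, small-effect proteins, and `s0 = 0` recovers the classical
t statistic exactly (cross-checked against an independent textbook
computation in the tests).

Significance is calibrated by permutation: all distinct relabelings of the
sample-group assignment are enumerated (or `n_permutations = 250` sampled
without replacement when more exist), **excluding the observed assignment
and its group-swap mirror** — both reproduce the observed statistics exactly
and carry no information about the null. For each candidate threshold `t`
(the observed `|d|` values) the estimated FDR is

```
FDR(t) = ((1 + B(t)) / (P + 1)) / max(1, m(t))
```

with `B(t)` the total permutation exceedances, `P` the relabelings used and
`m(t)` the observed exceedances; the add-one correction is the standard
finite-permutation adjustment and, at small designs (3 vs 3 has only 18
usable relabelings), prevents a single extreme null protein from ever being
callable at FDR 0.05. The estimator was chosen for exactly this calibration
property, verified by global-null simulation in the test suite; a median
variant (`estimator = "median"`) is selectable since the reference
procedure's internals are not fully specified. The cutoff is the smallest
`t` with `FDR(t) ≤ fdr_target`; two presets mirror the two analyses the
pipeline reproduces: strict (`FDR 0.05, S0 = 2`) and permissive
(`FDR 0.1, S0 = 1.22`). Volcano y-axis p-values are classical two-tailed
Student t (S0-free) and are reported alongside — never conflated with — the
permutation significance call.

## Time-course summaries

In-vitro digestion series are summarized as per-timepoint replicate means.
The qualitative detected/not-detected call is made quantitative by a simple,
configurable rule: product formation requires the final-timepoint mean to be
at least `fold_over_baseline = 5` times the baseline mean (floored at
`floor_frac = 1e-3` of the series maximum so a zero baseline cannot create
an infinite ratio) and a non-decreasing profile in at least half the steps.
The call is ratio-based, hence invariant to rescaling all intensities.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults that describe the study conditions end to end:

| Parameter | Default | Meaning |
|---|---|---|
| `n_proteins`, `length_range` | 1000, 150–400 aa | proteome size |
| `signal_fraction`, `signal_end_range` | 0.15, 15–25 | signal peptides (end positions where secreted-protein neo-N-termini cluster) |
| `n_substrates` | 50 | planted true substrates |
| `p1_weights` | P 1.0, A 0.8, S 0.3, T 0.3, G 0.2 | relative cleavage efficiency by P1 residue |
| `conversion` | wt 0.9, both mutants 0.02 | fraction of substrate molecules cleaved per genotype (both mutants are loss-of-function and share the default) |
| `abundance_mean/sd` | 20, 2 (log2) | log-normal protein abundance |
| `noise_sd` | 0.3 (log2) | multiplicative reporter noise |
| `mnar_quantile`, `mnar_slope` | 0.10, 1.0 | logistic dropout: 50% missing at the 10th intensity percentile, one log2 unit per logit — yields ~15% missingness, typical of reporter data |

Substrate proteins are constructed so their signature is observable: a
defined mature N-terminus (signal-peptide end or a position-2 residue from
the excision set), a P1 residue drawn from the specificity weights, and a
cleavage site planted so the N-terminal tryptic peptide is 14–28 residues
(no earlier site intervening). Each protein contributes its N-terminal
peptide (substrates also the 2-shifted product, with molecules split by the
genotype's conversion fraction) plus up to `n_background = 3` fully specific
internal peptides; full semi-specific enumeration of a realistic proteome
would produce millions of background rows without adding information to the
recovery tests. Structural zeros (a species absent under full conversion)
are written as intensity 0 and become missing at the log2 step; stochastic
dropout is written as `NA` — both non-detection paths are exercised.
Residue background frequencies are uniform; real proteomes are not, which
matters for motif statistics but not for the fold-change geometry being
tested. In the noiseless limit the observed substrate log2 fold change
equals `log2((1 − conversion_mut)/(1 − conversion_wt))` exactly, which the
tests assert to 1e-9.

The IP-MS generator plants log2 shifts on the bait side of a 3 + 3 design
(base N(25, 3), per-sample noise sd 0.3) and appends a configured fraction
of flagged rows to exercise filtering. It generates complete tables by
default (`missing_fraction = 0`); the downshift imputation path is exercised
by its own tests and engages automatically whenever tables contain `NA`.

**What passing tests do and do not show.** Recovery results on synthetic
data demonstrate that the pipeline's geometry, normalization and calibration
behave as designed under the stated noise model. Real TAILS data add
features the generator does not emulate — non-uniform residue composition,
correlated co-isolation noise, acetylated N-termini, isoform ambiguity,
protein-level degradation differences — so synthetic sensitivity should be
read as an upper bound, not a field estimate.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: truth recovery uses the full default
  conditions (1000 proteins / 50 substrates, one noisy and one noiseless
  run); FDR calibration uses 400 seeded global-null runs of 500 proteins
  (3 vs 3) — enough to estimate a ≤5% per-run false-call rate with margin —
  plus five planted-signal runs; oracle comparisons use 1000 random draws
  (statistic) and 100 random proteins of length ≤ 30 (digestion).
* All randomness is seeded; generators are bit-reproducible, imputation
  draws follow canonical row order, and pairing tie-breaks are
  deterministic (distance, then offset, then lexicographic keys).
* Degenerate inputs fail loudly with classed errors: signal-peptide
  annotations outside `1 ≤ end < length`, spans too short for the requested
  cleavage cycles or for P-position annotation, channels with fewer than
  three observed values at imputation, all-missing channels at centering,
  zero variance in both groups with `s0 = 0`, mismatched peptide sets
  between enzyme series.
* Fewer distinct relabelings than requested permutations triggers a classed
  warning and uses all of them.
* N-terminally acetylated peptides are included by default
  (`exclude_nterm_acetyl = FALSE`): acetylation blocks the free N-terminus a
  dipeptidyl peptidase needs, but upstream annotation of the modification is
  noisy enough that silent exclusion would be worse than an explicit flag.

## Known limitations

* The pairing geometry assumes exactly two mutant comparisons; other designs
  need a generalization of the quadrant logic.
* The detected-only cap is a reporting convention, not an estimate; fold
  changes of ±`absent_fc` should be read as "off-scale", and downstream
  meta-analyses should treat them categorically.
* With very small group sizes the permutation pool is coarse (18 usable
  relabelings at 3 vs 3); the add-one estimator keeps single-protein false
  calls impossible at FDR 0.05, but the FDR resolution is limited to
  multiples of `1/(P + 1)`.
* No protein inference, PSM-level scoring or spectrum processing: the
  pipeline consumes search-engine peptide tables and protein-group exports.
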