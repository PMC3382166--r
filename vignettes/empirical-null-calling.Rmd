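---
title: "Empirical-null change calling for multi-experiment isobaric-tag studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical-null change calling for multi-experiment isobaric-tag studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqnull)
```

## The problem and the design

In an 8-plex iTRAQ experiment, up to eight samples are labelled with
isobaric reagents and quantified together in one LC-MS/MS run; each
protein or phosphopeptide receives a fold-change ratio against a chosen
denominator channel. The design this package supports profiles six
oncogene-expressing cell lines (constitutively active tyrosine kinases:
BCR/ABL, TEL/PDGFRβ, NPM/ALK, KIT D816V, FLT3-ITD, FIP1L/PDGFRα) against a
vector control, with the control labelled in *two* channels of every run.
The second control channel is the **internal technical replicate**: its
control-vs-control ratios should all be 1 up to technical noise, so they
form an empirical null sample drawn from exactly the measurement process of
that run — same labelling, same chromatography, same instrument drift.

Three biological replicate experiments are run. The analysis questions are:
which features change in which oncogene conditions; whether those changes
are transcriptional, translocational or post-translational (by comparison
with matched mRNA and cytosolic layers); and what structure the per-oncogene
change sets share (clustering, multi-set Venn regions, common targets).

## The model

All inference is done on log ratios. Write $r_{ice}$ for the
median-normalized ratio of feature $i$ in condition $c$ of experiment $e$,
and let $N_e = \{\log r^{\text{int}}_{1e}, \dots\}$ be the internal
replicate's log ratios in experiment $e$.

**Normalization.** Each condition column is divided by its own median, so
the column median is exactly 1. This assumes most features are unchanged —
true here, where a few percent of the proteome responds to any one
oncogene. Normalization is idempotent and rank-preserving; p-values and
error factors, being scale-free within a feature, are left untouched.

**Significance interval.** The per-experiment interval
$[L_e, U_e]$ is the equal-tail central range holding 95% of $N_e$:
empirical type-7 (linearly interpolated) quantiles of the log ratios at
0.025 and 0.975, exponentiated back. Working on the log scale is the only
choice that makes a halving and a doubling equally extreme; the interval is
re-fitted for every run, so a noisy run demands a larger fold-change.
No parametric form is assumed, and no multiple-testing correction is
applied at this stage — the consensus rule across experiments supplies the
specificity.

**Confidence score.** The signed confidence of a ratio $r$ is the
proportion of the internal-replicate null that $r$ is outside of: with $G$
the continuous empirical CDF of $N_e$ (the inverse of the same type-7
quantile function used for the interval),
$$ \mathrm{conf}(r) \;=\; \mathrm{sign}\!\left(G(\log r) - \tfrac12\right)
   \cdot \left| 2\,G(\log r) - 1 \right|, $$
capped at $\pm 0.99$ and printed to two decimals. Using the *interpolated*
CDF rather than the step ECDF makes the score exactly consistent with the
interval: a ratio is strictly outside the 95% interval if and only if its
confidence magnitude exceeds 0.95 (so every "up" call carries a confidence
in $[0.95, 0.99]$). A step ECDF would violate that equivalence at finite
null sizes.

**Per-experiment change rule.** In protein mode a feature is called in
condition $c$ of experiment $e$ when $r_{ice}$ is *strictly* outside
$[L_e, U_e]$ **and** its spectrum-level p-value is present and $\le 0.05$.
In phospho mode the interval condition alone decides: entity p-values are
computed where at least two spectra exist but never used for calling,
because most phosphoentities are seen in too few spectra for the test to be
meaningful. Boundary ties are not outside (conservative), and an absent
p-value blocks a protein-mode call — the rule demands an explicit p.

**Consensus rule.** A feature × oncogene pair is called when one direction
is reached in strictly more than half of the experiments in which a ratio
is recorded (1 of 2 is not a majority; 1 of 1 is), and *no* experiment
calls the feature's internal replicate as changing — the internal veto.
Records with calls in both directions keep the majority direction but are
flagged `direction_conflict`; records quantified in a single experiment are
callable but identifiable by `n_quantified`. The reported ratio is the
geometric mean over quantified experiments (log-symmetric, so 0.5 and 2
average to 1) and the reported confidence the arithmetic mean of the signed
scores, which is large in magnitude only when experiments agree. An
alternative `any` rule (one calling experiment suffices) is available via
`run_config(consensus_rule = "any")`; the default is the majority rule.

**Phosphoentities.** Spectra identified with confidence strictly > 20 are
collapsed by (peptide sequence, set of modified residues) — positions are
peptide-relative, and modification order is irrelevant. The entity ratio is
the error-factor-weighted mean of spectrum log ratios with weights
$1/(\log_{10}\mathrm{EF})^2$; since $\log_{10}\mathrm{EF}$ is proportional
to the ratio's standard error, this is standard inverse-variance weighting.
When any EF in a group is absent the group falls back to equal weights, and
an EF of exactly 1 (zero estimated error) takes all the weight. This
weighting is our precision-weighting analogue of the proprietary scheme
used by the original search software, not a reproduction of it. The
stoichiometry of phosphorylation on a site is the phosphopeptide fold
divided by the parent protein fold; within 0.5 log2 units of 1 (a √2-fold
band, configurable) the site's occupancy is classified unchanged.

**Downstream layers.** A called feature is `mrna-concordant` when its mRNA
fold crosses 2-fold in the direction of the protein call, `discordant` when
it crosses the other way, and `post-translational` when it does not cross —
the 2-fold threshold is the one stated with the transcription-factor
analysis; the cytosolic threshold (1.5-fold) has no stated value and is a
configurable default chosen inside the usual band of biological relevance
for ratio data. Features absent from a layer are categorized
`not-assessed`, never dropped. Transcription-factor stratification counts,
per annotated factor and per direction, the fraction of called features
whose mRNA crossed concordantly; the TF annotation is an input table — no
motif scanning is performed. Oncogene dendrograms use Euclidean distance
and complete linkage on the log2 consensus-ratio matrix (the defaults of
the R heat-map idiom), clustering all quantified features by default with a
flag to restrict to called ones; missing entries are imputed to 0 ("no
change"), which leaves Euclidean distances untouched. Venn summaries report
exact counts for all $2^k - 1$ membership regions (up to six sets);
rendering is a plotting concern left to the caller.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `coverage` | 0.95 | proportion | central null coverage of the significance interval |
| `pvalue_threshold` | 0.05 | probability | per-experiment p cut-off (protein mode only) |
| `consensus_rule` | majority | — | strictly-more-than-half, or `any` |
| `id_confidence_threshold` | 20 | score | spectra kept when strictly above |
| `mrna_fold_threshold` | 2.0 | fold | mRNA concordance crossing |
| `cytosol_fold_threshold` | 1.5 | fold | cytosolic crossing (unstated upstream; free default) |
| `stoichiometry_log2_threshold` | 0.5 | log2 fold | unchanged-occupancy band |

## What the synthetic generator emulates — and what it does not

`generate_study()` produces the structure the caller assumes: per
experiment, each feature's log2 ratio is its true log2 fold (0 for null
features and for the internal replicate) plus Gaussian noise, realized as
the mean of $k$ spectrum-level log ratios with the mean's standard
deviation fixed at `log2_null_sd`. Ratio histograms are therefore
approximately log-normal and centred at 1 before any explicit
normalization. $k$ follows a shifted geometric distribution; each ratio
carries a p-value (one-sample t of the $k$ spectrum log ratios against 0)
and an error factor ($10^{t_{0.975,k-1}\,\mathrm{SE}_{\log_{10}}}$), both
absent at $k = 1$ where they are not estimable. Spiked features receive a
fold drawn log-uniformly from `spike_fold_range`, up or down with equal
probability, in a random nonempty subset of oncogenes; the mRNA layer
mirrors a spiked feature's fold with probability `mrna_coupling` and stays
null otherwise, and the cytosolic layer is always null — the structure in
which nuclear changes are post-translational rather than transcriptional or
translocational. Ground truth is returned for recovery testing.

Defaults are chosen once as realistic study conditions: `log2_null_sd =
0.15` (a typical 8-plex technical spread; the source study does not state
its null spread, so this is a free parameter, not an estimate of it), 3600
features, three experiments, `spectra_per_feature = 10`. The spectra depth
is a design-time choice backed by a power analysis: with the mean ratio's
sd fixed at 0.15, the per-experiment power to call a 2-fold spike in
protein mode is limited by the t-test's degrees of freedom at small $k$
(and is zero at $k = 1$, where the p-value is absent); a mean depth of 10
spectra per protein — ordinary for a 2D-fractionated iTRAQ study — gives
per-experiment power ≈ 0.84 and 2-of-3 consensus power ≈ 0.93.

The generator does *not* simulate raw spectra, isotope-purity effects,
channel cross-talk, ratio compression, missingness (every feature is
quantified in every experiment), or correlated noise across conditions of
one run. Passing recovery tests on this generator therefore demonstrates
the calling logic, not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

Quantiles are type 7 throughout; the confidence CDF is its exact inverse,
with duplicate null values handled by mid-probability averaging. A null
sample of fewer than 20 ratios is an error, never a silent fallback.
Nonpositive ratios are rejected at every boundary (normalization, IO,
classification) with the offending row named. Multiple internal-replicate
columns in one experiment are pooled into a single null sample. Seeds
derive per-experiment substreams by fixed offsets, so adding a fourth
experiment leaves the first three bit-identical.

## Known limitations

The internal veto bounds achievable sensitivity: a null internal column has
by construction about $1 - \text{coverage}$ of its ratios outside the
interval per experiment, so across $m$ experiments roughly
$1 - \text{coverage}^m$ of *all* features (14% at 95% coverage and $m = 3$
in phospho mode, where no p-value conjunction shrinks it; a few percent
less in protein mode) are vetoed regardless of their true state. Consensus
recovery of true changes can therefore not exceed the veto's survival rate
however strong the effect or deep the spectra; the test suite measures this
trade-off on spiked studies. This is a property of the published rule
("not changing in any internal replicate"), reproduced deliberately.
Confidence scores saturate at ±0.99 and cannot rank very extreme ratios
against each other; the interval bounds, not the scores, carry the calling
decision. The suite's property checks run at 2,000–3,600 features and
three experiments — the study's own scale, chosen so the empirical quantile
machinery is exercised at realistic null sizes.
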