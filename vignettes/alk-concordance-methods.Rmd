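---
title: "Methods: FISH pattern classification and IHC/FISH concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FISH pattern classification and IHC/FISH concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkconcord)
```

## The problem

ALK rearrangement is a targetable driver in non-small cell lung carcinoma
(NSCLC), routinely tested by two orthogonal assays: immunohistochemistry
(IHC, protein expression with the D5F3 antibody) and fluorescence in situ
hybridization (FISH, a split at the *ALK* locus). Most cases agree; the rare
discordant cases — FISH-positive/IHC-negative ("positive discordant") and
FISH-negative/IHC-positive ("negative discordant") — are clinically
consequential because they decide eligibility for tyrosine-kinase
inhibitors. `alkconcord` implements the analytical machinery for studying
such discordance: per-nucleus signal classification for two probe designs,
sample-level pattern calling, concordance classification with NGS evidence,
and the exact contingency statistics that compare pattern heterogeneity
between concordant and discordant groups.

## Signal model

A nucleus observed with the tri-color ALK/EML4 fusion probe shows a
multiset of fluorescent signal tokens over three channels: `O` (3' *ALK*
arm, orange), `G` (5' *ALK* arm, green), `B` (*EML4*, blue). Co-localized
channels form a single token (`O+G`, `O+B`, ...). Any token carrying both
`O` and `G` marks an intact *ALK* locus; the count of such tokens is the
nucleus's copy number. What remains after removing intact fusion tokens is
the *residue*, matched by exact multiset equality against a signature
table:

```{r}
signature_table()
```

Exact-multiset matching (multiplicities matter: `OB` is interstitial
deletion, `OB/GB` is inversion) reflects the fact that each listed variant
is a complete signal configuration of one rearranged locus. A non-empty
residue not in the table is `UNCLASSIFIED` and surfaced with its raw
configuration — this includes nuclei with two independent splits, for
which no published classification convention exists. 3'-deletion residues
(green retained, orange lost) are in the table but hard-wired to never
count toward positivity: the 3' probe arm covers the tyrosine-kinase
domain, so a sample dominated by such signals is guideline-negative even
though its *ALK* locus is clearly altered; the sample-level `atypical_flag`
surfaces these cases for orthogonal (NGS) testing.

The dual-color break-apart probe lacks the blue channel. Its per-nucleus
rule is: isolated `O` and isolated `G` at least two signal diameters apart,
and/or isolated `O` without isolated `G`, is positive; an isolated pair
below the distance criterion is the equivocal *short break* (negative for
scoring, flagged for tri-color retesting). The distance flag is measured
upstream at the microscope; this package consumes it as data
(`split_ok`). Consistency between the two encodings is a package
invariant: every tri-color translocation/inversion/5'-deletion
configuration, re-encoded by erasing the blue channel, scores positive or
short-break, never negative.

## Sample-level calling

* **Positivity**: a sample is positive when >= 15% of enumerated nuclei
  (inclusive cut-off) carry a positivity-counting rearrangement; 100
  nuclei are enumerated when available, at least 50 are required, below
  which the sample is `INSUFFICIENT` and excluded from every cohort
  denominator. The 15% threshold is a fraction of *enumerated* nuclei.
* **Pattern set**: the predominant variant is the configuration with the
  highest share of *rearranged* nuclei. Each minority variant survives as
  a secondary/tertiary pattern only if it reaches >= 4% of rearranged
  nuclei and cannot be derived from the predominant configuration by
  whole-token loss. Derivable variants are folded into the predominant's
  class: slicing a nucleus during sectioning can remove whole signals but
  cannot split a co-localized token into its channels, so e.g. `OB` at a
  low percentage in an `OB/GB`-predominant sample is a sectioning
  artifact, not evidence of interstitial deletion. This whole-token
  sub-multiset reading is the only one consistent with the observed
  combination vocabulary (interstitial deletion + inversion occurs only
  with interstitial deletion predominant; inversion + translocation and
  translocation + inversion both occur). Percentage ties for the
  predominant are broken toward the residue with more tokens, then
  lexicographically, and recorded — a tie has never been observed in real
  scoring data. At most three classes are reported (no observed sample
  carries more); overflow is recorded, never silently dropped.
* **Composite positives**: a positive sample where no single variant
  reaches 15% of enumerated nuclei is annotated as composite — positivity
  reached by several sub-threshold variants. This distinction is strongly
  enriched among discordant cases.
* **CNG category**: per-nucleus copy number (intact fusion count) is
  binned `<=3 / 4-6 / 7-9 / 10+`; the sample category is the *highest*
  bin whose nucleus fraction reaches a reporting threshold `theta`
  (default 0.10, configurable). The reduction from the per-nucleus
  distribution to one sample category is not fully specified in published
  scoring practice; the highest-class-above-threshold rule is this
  package's choice, chosen because it reproduces the reference per-group
  category tables and is monotone in the threshold (exercised in the test
  suite at several `theta` values).

```{r}
res <- summarize_fish_sample(classify_nuclei(
  realize_pattern_sample("interstitial_deletion+inversion",
                         sample_id = "demo")))
res
```

## Concordance and assay integration

IHC scoring: strong diffuse granular cytoplasmic staining (2+, 3+) is
positive; no staining, weak (1+) staining and the stippled pattern are
negative; the focal "dot-like" pattern counts as positive only in the
reevaluation stage. `apply_reevaluation()` moves dot-like repeat-positive
cases from positive discordant to positive concordant, conserving the
total. Sensitivity of FISH is positive concordant over positive concordant
plus negative discordant; specificity is negative concordant over negative
concordant plus positive discordant (the standard form with IHC as
reference; the raw quotient is returned, unrounded). NGS integration is
limited to what concordance analysis needs: the QC gate (>= 80 ng DNA,
RNA > 10 ng/uL, DV200 > 30%, library > 3 ng/uL, tumor content > 20%, with
the first violated criterion reported) and fusion calling at >= 5 unique
supporting reads. Variant tiering, TMB and MSI are out of scope.

## Contingency statistics

The association between concordance group and pattern-set size (a 2x3
table) is tested by Fisher's exact test with full enumeration of all
margin-consistent tables, two-sided under the minimum-likelihood
criterion (every table no more probable than the observed one
contributes). Probabilities accumulate in log space from `lchoose`;
enumeration is limited to 2xK tables with K <= 4 and a bounded candidate
count, and a table too large for enumeration is a capability error rather
than a silent approximation. An independent brute-force enumerator (exact
`choose()` ratios, recursive) lives in the test suite and must agree to
1e-9 on fuzzed tables; `stats::fisher.test` provides a third opinion.

Effect size is Cramer's V, `sqrt(chi2 / (n * min(r-1, c-1)))` with the
uncorrected Pearson statistic. Its 95% interval inverts the noncentral
chi-square distribution at the observed statistic: `lambda_hi` solves
`P(X_{df,lambda} <= chi2_obs) = 0.025`, `lambda_lo` the symmetric 0.975
equation (clamped at zero). Two mappings from noncentrality to the V
scale coexist in practice; this package defaults to the *adjusted* form
`sqrt((lambda + df) / (n * min(r-1, c-1)))`, which is the convention that
reproduces the published-style interval on the reference table, and
exposes `adjust = FALSE` for the bare `sqrt(lambda / ...)` form whose
lower bound is exactly zero at independence. Tables with a zero row or
column receive add-one Laplace smoothing before testing, and the result
records that smoothing fired.

```{r}
association_test(rbind(discordant = c(12, 14, 3),
                       concordant = c(137, 30, 1)))
```

## The synthetic cohort generator

No per-nucleus data are deposited for real cohorts, so the generator is a
first-class module: it emulates the statistical structure the analysis
assumes, giving every pipeline stage a ground truth.

* Four case archetypes (positive/negative x concordant/discordant). The
  FISH-positive archetypes draw a pattern combination per sample from the
  reference combination frequencies (`pattern_reference()`); combinations
  are rendered with representative residues and mixture weights 1.0 /
  0.7-0.3 / 0.5-0.3-0.2 for one/two/three classes.
* The per-sample rearranged fraction is Beta-distributed: means 0.45
  (positive concordant), 0.30 (positive discordant) and 0.03 with a much
  tighter concentration for the FISH-negative archetypes — a negative case
  is by definition one whose true split fraction sits well below the
  clinical cut-off, showing only background-level signals.
* Each rearranged nucleus is rendered as intact fusion tokens plus its
  variant's residue; with probability `p_artifact` (default 0.10) a
  sectioning event deletes one whole token uniformly at random — whole
  tokens only, never a single channel of a co-localized pair, matching
  the derivability rule so artifact folding is exercised by construction.
  A nucleus sectioned down to zero tokens becomes unenumerable and is
  dropped, exactly as at the microscope.
* CNG categories are drawn from the reference per-group frequencies; in an
  elevated sample 20% of nuclei carry the representative elevated copy
  number (2 / 5 / 8 / 11 intact copies for the four bins), so category
  recovery at the default reporting threshold is exact by construction.
* One global seed expands to per-case streams by a counter-based
  arithmetic split, so cohorts are byte-stable under case-count changes.

Deterministic counterpart: `realize_pattern_sample()` builds a 100-nucleus
sample realizing a prescribed ordered combination with fixed variant
counts (40 / 30+10 / 20+10+6 nuclei above the cut-off, 10+8 / 12+9 /
12+9+5 for composite positives, plus a derivable 6-nucleus sectioning
fragment wherever the predominant configuration can shed a token). These
counts keep every variant on the intended side of the 15% and 4% rules
with wide margins; `simulate_pattern_cohort()` expands the full reference
distribution (29 discordant + 168 concordant samples) through the
classifier and derivation, and is what `scripts/acceptance.R` runs.

What the generator does **not** model: spatial heterogeneity
(multi-component tumors with different sub-clones), inter-observer
enumeration variability, partial-channel signal degradation, and
continuous copy-number distributions within a sample. Passing recovery
tests therefore demonstrates the internal consistency of the
classification/derivation rules under the stated noise model, not
robustness to every failure mode of clinical material.

## Numerical and testing choices

* Percentages are kept as raw doubles; golden comparisons against printed
  (rounded or truncated) reference values use +-0.1 percentage-point
  tolerances.
* Fisher p-values are compared at 5% relative tolerance against the
  two-significant-figure reference value; implementation-vs-oracle
  agreement is 1e-9.
* Parameter-recovery tests run 100 samples (50 per positive archetype,
  100 nuclei each) at `p_artifact` up to 0.25 under fixed seeds and
  require >= 95% exact pattern-class-set recovery; measured rearranged
  fractions must track the generative truth within twice the mean
  binomial standard error.
* Degenerate inputs are explicit: empty nuclei are unenumerable errors,
  samples under 50 nuclei are `INSUFFICIENT` (excluded, listed), empty
  pattern sets are excluded from the contingency table with a message,
  zero-margin tables are smoothed before testing, and zero denominators
  in sensitivity/specificity return `NA` with a named marker.

## Known limitations

* The break-apart distance criterion consumes an upstream `split_ok`
  flag; no image or distance computation is performed.
* The exact test covers 2xK tables (K <= 4) only — the study's design —
  with no Monte Carlo fallback.
* The CNG sample-category reduction and the >3-pattern cap are package
  conventions where published practice is under-specified (see above);
  both are configurable or surfaced rather than hidden.
* NGS CNV amplification calling is anchored to a single documented
  threshold (14 copies at 20% tumor purity) and does not extrapolate a
  purity-scaling formula; other purities require explicit thresholds.
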