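---
title: "Methods: species attribution and comparative statistics for cervicovaginal Lactobacillus proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species attribution and comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactospec)
```

## Scope and data model

`lactospec` starts where peptide identification ends. Its inputs are
(a) a protein table — accession, species-level best database match,
total and unique peptide counts, and, for single-unique-peptide records,
an across-group ANOVA p-value and a fragment-ion-series flag; (b) a
protein × sample matrix of normalized total ion intensities ("relative
abundance", unitless); and (c) a sample table — VMB group (one of four
cluster-derived states: *L. crispatus*-dominated, *L. iners*-dominated,
moderate dysbiosis, severe dysbiosis), vaginal pH measured by strip in
0.5 increments on a 2–9 scale, and per-taxon 16S microarray
signal/background (S/B) ratios with a positivity call.

Two representation decisions matter downstream:

* **Missing intensities are explicit zeros.** Label-free pipelines report
  a protein undetected in a run as zero intensity; the matrix therefore
  admits no `NA`s, and log-scale analyses handle zeros explicitly (below).
* **16S positivity defaults to S/B > 0.** A microarray S/B of zero means
  no hybridization signal. No numeric detection floor is assumed; studies
  that used one can supply explicit `pos:<taxon>` columns, which override
  the default.

## Evidence filter

A protein passes iff it has at least one unique peptide and at least two
peptides overall. A protein with exactly one unique peptide is rescued
iff its ANOVA p is strictly below 0.05 **and** a series of at least four
continuous fragment ions was confirmed. Raw spectra are out of scope, so
the fragment-series check travels as a boolean input; when either rescue
field is missing the record fails with reason
`insufficient-evidence-metadata` — the conservative reading, since the
rescue path exists precisely to demand extra evidence. The threshold is
strict (`<`, not `≤`). The filter is monotone in both peptide counts and
order-invariant; the test suite checks it against an independently coded
truth table over the full grid of unique/total/p/flag combinations.

## Species-specificity classifier

The classifier rests on one assumption: a protein that is much more
abundant in samples where only one *Lactobacillus* species is abundant
most plausibly originates from that species. For species $s$ with target
samples $T$ (the $s$-dominated cluster) and reference samples $R$ (all
samples 16S-negative for $s$), a candidate protein is specific for $s$
iff

$$\frac{\operatorname{mean}_T(x)}{\operatorname{mean}_R(x)} \ge 2
\quad\text{and}\quad
\operatorname{median}_T(x) \ge \operatorname{median}_R(x),$$

computed on raw (untransformed) normalized intensities. Both thresholds
are inclusive ("at least 2-fold", "equal to or higher"). Candidacy
requires the best match to be $s$ itself or a multispecies entry;
`other` matches are never assigned.

Design choices that were genuinely open:

* **Reference group.** The *L. crispatus* reference is defined by the
  explicit condition — every sample 16S-negative for *L. crispatus* —
  rather than by cluster membership. The alternative reading (the
  *L. iners* cluster plus crispatus-free dysbiotic samples) would leave
  crispatus-positive members of the iners cluster inside the reference
  and dilute it; the negativity condition is the one the criteria's own
  logic requires. The built-in 50-sample cohort gives reference sizes of
  19 (iners) and 37 (crispatus) under this reading.
* **Target group.** Default is all members of the species' cluster; a
  config switch (`cluster_members_16s_positive`) restricts to
  16S-positive members (5 of 7 for crispatus in the built-in cohort).
* **Zero conventions.** Reference mean 0 with positive target mean is an
  infinite fold-change and passes; both means 0 means the protein was
  never observed in either group and fails (reported fold 0).
* **Multispecies double pass.** The source criteria assign a
  multispecies protein to exactly one species but do not say how a
  double pass resolves. Default: larger fold-change wins; an exact tie —
  including the doubly-infinite case — stays nonspecific. A stricter
  `nonspecific` tie-break is available. Double passes require unusual
  16S-overlap structure (each species' reference contains the other's
  target cluster, which pulls the reference mean up), which is plausibly
  why the source never needed the rule.

The decision is invariant to rescaling a protein's row by any positive
constant and monotone in target intensities; on small cohorts (≤ 6
samples × ≤ 4 proteins) it is tested for exact agreement with a
brute-force re-coding of the criteria.

## Cohorts, pH categories, abundance strata

Comparative analyses include only 16S-positive samples for the species,
within each VMB group. pH categories are half-open on the left label's
upper edge, with a closed top bin at 9: three bins (4–5, 5–6, ≥ 6) for
*L. iners*, two (4–5, ≥ 5) for *L. crispatus*. The boundary convention
is forced by the built-in cohort's arithmetic: with a cohort median pH
of 5 and bin sizes 7/18/6, pH = 5.0 must fall in "5–6", so "4–5" means
$[4, 5)$. Readings below 4 map to the lowest bin with a warning (none
occur in the 4–7 observed range). Abundance strata split a cohort at
the median S/B (high = strictly above; ties go low, mirroring the
strict "> 70" fixed-threshold rule) or at a fixed threshold.

## Statistics

**Pairwise Mann–Whitney.** Every unordered pair of non-empty levels gets
a two-sided test. The exact null distribution is used when the combined
n is ≤ 25 and the pooled values carry no ties; otherwise the normal
approximation with tie and continuity corrections. The switch is
deterministic so p-values are bit-for-bit reproducible. When all pooled
values are identical, p = 1 by convention. Raw p-values are reported by
default — the source design reports unadjusted pairwise panels — with
Holm adjustment behind a flag. Calibration is checked by Monte Carlo:
1000 null comparisons at the study's G2/G3 cohort sizes (11 vs 12,
exact path); the exact test is mildly conservative at the 0.05 level on
its discrete lattice, and the observed type-I rate is required to fall
in [0.035, 0.065].

**Regression.** For each dysbiosis-associated *L. iners* protein, OLS of
log10 intensity on VMB-group dummies (reference: the iners-dominated
group), pH-category dummies (reference "4–5"), and log10 S/B, fitted on
the iners analysis cohort. CIs use the t-distribution with residual
degrees of freedom. Shapiro–Wilk on residuals is a diagnostic: p < 0.05
warns, never fails. Zeros are replaced by half the smallest positive
value — per protein for intensities, per cohort for S/B — before the
log10 transform; the choice is recorded in the output manifest.
Structurally empty groups (the crispatus cluster contains no
iners-positive samples) drop out of the design, matching the fitted
models' G2/G3/G4 layout; an unpopulated pH category, by contrast, is a
requested-but-inestimable term and raises a rank-deficiency error that
names the aliased dummies, as does any other aliased term (e.g. constant
S/B).

## Synthetic-data generator

The generator plants ground truth so every stage is testable without raw
MS data. Its defaults are the study conditions: 7/11/14/18 women per
group; 40 proteins (7 iners-specific, 11 crispatus-specific, 22
nonspecific; specific proteins matched at multispecies level with
probability 0.2, echoing the 8-of-40 multispecies share); per-group 16S
positivity probabilities equal to the published per-group tallies (e.g.
12/14 for iners in moderate dysbiosis); pH distributions on the 0.5
grid spanning 4–7 and consistent with the three-bin layout; log-normal
S/B for positive samples, higher in the species' home cluster.

Intensities follow, on the log10 scale,

$$\log_{10} x = \beta_0 + \beta_s\,[\text{16S}^+\text{ for the true
species}] + \beta_d\,[\text{G3 or G4}] + \beta_p\,(\text{pH category
index}) + \varepsilon,\qquad \varepsilon \sim N(0, \sigma),$$

with nonspecific proteins omitting the species term. Default magnitudes
$\beta_0 = 5$, $\beta_s = 1.5$, $\beta_d = -0.5$, $\beta_p = -0.3$,
$\sigma = 0.3$ were chosen once as realistic label-free log10-scale
effects pointing in the direction of the source findings (lower specific
abundance under dysbiosis and at high pH); the true magnitudes are not
identifiable from published text, and these values were not revisited.
$\sigma = 0$ is allowed as the noiseless limit used by exact-recovery
tests. Randomness flows through three sub-streams (cohort, protein
metadata, intensities) derived from one seed, so enlarging the protein
panel never perturbs the cohort.

What the generator does **not** emulate: peptide/spectrum level
structure, protein–protein intensity correlation, heavy-tailed or
zero-inflated intensity distributions, microarray probe-level noise, or
any dependence of intensity on S/B beyond positivity (the planted S/B
coefficient is exactly 0). Passing recovery tests therefore demonstrates
correctness of the decision rules and estimators under the planted
model, not robustness to real-data pathologies.

## Parameter recovery, and a known limitation of the criteria

Classifier recovery is evaluated at 25 samples per group,
$\beta_s = 1$, $\sigma = 0.3$, over 20 seeds, **with the group and pH
effects at zero**, where ≥ 95% of planted specific proteins must be
recovered and ≤ 5% of nonspecific proteins falsely assigned. The
zero-confound design is deliberate: when strong negative dysbiosis/pH
effects are planted, *every* protein — specific or not — is less
abundant in the dysbiotic samples that dominate the crispatus reference
group, so health-correlated nonspecific proteins can clear the 2-fold
criterion spuriously. That is a property of 16S-informed fold-change
attribution itself, not of this implementation, and it is the main
caveat a user should carry to real data: the criteria are conservative
against the reference species but not against abundance–health
confounding. The worked pipeline example in the README shows the effect
at the confounded defaults.

Regression recovery uses a design where the fitted model is the
generative truth (iners-positive samples in G2/G3/G4, pH spread over all
three categories, n = 60): the noiseless fit must reproduce the planted
coefficients to 1e-8, and across 500 noisy replicates the pooled 95% CI
coverage of the five planted coefficients must lie in [0.93, 0.97].
Problem sizes throughout (20 seeds × 40 proteins for recovery, 1000
null comparisons, 500 regression replicates) were chosen to make the
Monte-Carlo bands tight enough to detect calibration errors of a few
percentage points while keeping the default test run fast.

## Determinism

`run_pipeline()` with a simulation config and fixed seed writes a result
bundle (tables, summary JSON, provenance manifest) whose files contain
no timestamps or environment-dependent content; two runs at the same
seed must be byte-identical, and the suite checks this.
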