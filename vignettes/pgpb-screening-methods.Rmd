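---
title: "Methods: a statistical flow sheet for PGPB screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a statistical flow sheet for PGPB screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpbscreen)
```

## The problem

Selecting plant-growth-promoting bacteria (PGPB) from a rhizosphere
isolation campaign means reducing hundreds of isolates — here four
culture-defined functional groups (mesophilic bacteria, spore-formers,
pseudomonads, actinobacteria) screened for phosphate solubilization,
siderophore production, ammonium production and nitrification — to a short
list worth validating in pots and, eventually, in the field. The difficulty
is statistical, not microbiological: the traits are a mix of qualitative
(halo/no halo) and quantitative (µM, µg/mL) variables, replicate quality is
uneven, and no a-priori cut-off ("select everything above 5 µg/mL IAA") is
defensible across assays with very different scales. This package implements
a flow sheet whose cut-offs come from the statistical distribution of the
screened population itself.

The pipeline has three stages, plus a calibrated data generator used for
testing and power exploration.

## Stage 1 — qualitative screen

Each qualitative assay is run in replicate and collapsed by `encode_binary()`
to a single code: **1 only when every replicate is positive**, 0 otherwise
(including a single positive among negatives). The unanimity reading is the
only one consistent with treating a lone positive replicate as noise; it
makes the code monotone — turning a replicate positive can never lose a 1 —
and conservative, since an irreproducible trait cannot support selection. An
assay never performed contributes 0 for the same reason.

`pattern_groups()` clusters isolates by *exact* binary pattern: the screen's
"homogeneous groups" are isolates answering identically on all four tests,
not clusters at some distance threshold. Labels are assigned in descending
lexicographic pattern order so they are reproducible; any letter scheme for
such groups is arbitrary, so reproducibility is the only property worth
engineering.

`run_pca()` is a diagnostic, never a selection input. Binary variables are
standardized (correlation-matrix PCA): on mixed positivity rates the
covariance-matrix alternative would let high-variance traits (positivity
near 50%) dominate regardless of structure. Loadings are reported as
trait–component correlations, the form in which screening studies usually
print them. Two numerical conventions make the output deterministic: each
component's sign is flipped so its largest-magnitude loading is positive,
and zero-variance traits (all isolates identical) are dropped with a warning
rather than propagating `NaN` through the standardization; if fewer than two
informative traits remain, PCA errors.

## Stage 2 — replicate QC, quartile coding, selection

### Replicate QC

Quantitative assays are replicated (triplicates in the standard design).
`qc_filter()` gates each replicate set on the coefficient of variation
(sample SD / mean, in percent): at or below 10% the set passes untouched.
Above 10%, Dixon's Q test (the standard small-*n* outlier test in analytical
chemistry, tabulated here for *n* = 3–10) asks whether the most extreme
replicate is "the one different from the other two":

$$Q = \frac{|x_{suspect} - x_{nearest}|}{x_{max} - x_{min}}$$

At α = 0.05 and *n* = 3 the critical value is 0.970. A significant suspect
is removed — never more than one per set; an unresolved high-CV set is kept
and flagged rather than discarded, because the flow sheet reduces isolates
by evidence, not by measurement misfortune. Both CV and Q are
scale-invariant, so the decision does not depend on assay units. A
significance-free variant (`unconditional = TRUE`) removes the suspect
whenever the CV gate fires, for users who read the removal rule as
unconditional; the test-gated version is the default because removing a
replicate that an outlier test cannot distinguish from its peers is hard to
justify. Sets whose mean is zero (assay negative throughout) bypass QC: the
CV is undefined there and the value codes 0 regardless.

### Quartile coding

For each functional group and parameter, the population cut-offs are the
median and quartiles over the **pooled raw replicates of all isolates**
(after QC), estimated by linear interpolation of order statistics
(`stats::quantile` type 7, the common spreadsheet/statistics default — the
estimator choice never moves any worked-example code). The isolate-level
value is the **mean of its QC-kept replicates**, and `assign_code()` maps it
to an ordinal scale:

| code | meaning |
|------|---------------------------------------------|
| 0 | assay absent, or no detectable activity (value ≤ 0) |
| 1 | 0 < value < median |
| 2 | median ≤ value < Q3 |
| 3 | value ≥ Q3 |

Boundaries are closed upward: a value exactly at the median codes 2 and a
value exactly at Q3 codes 3. The upper-boundary policy is forced by the
worked example shipped with the package, where one pseudomonad's IAA value
equals its group Q3 exactly yet is coded 3. Codes are monotone in the value
and invariant under any joint rescaling of values and cut-offs, so unit
changes cannot reorder isolates.

The worked-example cut-off table contains one row (pseudomonad
P-mineralization) violating q1 ≤ median ≤ q3 — plainly a typo in the source
tables. `quartile_summary()` rejects such rows unless `validate = FALSE` is
passed explicitly; the invalid row is likewise excluded from the generator's
default calibration. A handful of printed codes in the same tables are
mutually inconsistent with the printed values (codes for assays marked "not
assessed", one code off by one level at what is evidently a rounding
boundary of the underlying unrounded value); the package reproduces the
reproducible cells and documents the rest rather than special-casing them.

### Selection rules

**First round** (`first_round()`): per group × parameter, the candidates are
the code-3 isolates; when several compete, their replicate values go through
one-way ANOVA and Tukey HSD (Tukey–Kramer for unequal replicate counts after
QC), and only candidates carrying the **top homogeneous-group letter** stay.
A lone candidate is kept without a test. The comparison runs over the
candidate set by default (`compare = "group"` widens it to all assayed
isolates of the group, for users who prefer population-wide letters); if any
candidate has fewer than two replicates the comparison is not testable and
all candidates are kept, logged as such.

**Second round** (`second_round()`): isolates not yet selected join if at
least `min_traits = 2` parameters have **any** detectable level (code ≥ 1).
The code ≥ 1 reading — rather than code ≥ 3 — is forced by the worked
example, where an isolate with codes (0, 1, 2) is selected by this rule.
The rule is monotone: adding a measurement can only add isolates.

**Viability** (`viability_filter()`): isolates that lose viability in cold
storage are excluded last, by input flag. The flow sheet treats viability as
an observed property, not a computed one; no survival-kinetics model is
implied.

Compact letter displays use the insert-and-absorb algorithm over levels
ordered by descending mean (ties broken by label): every significant pair is
split, columns absorbed, letters assigned so that `a` always belongs to the
highest mean. The display satisfies the defining property — two levels share
a letter **iff** their Tukey comparison is non-significant — which the test
suite checks against a brute-force pairwise studentized-range oracle on
hundreds of random designs.

## Stage 3 — growth-chamber validation

`validate_growth()` takes pot-level biomass dry matter (g/pot) and plant
height (cm) per treatment (isolate or uninoculated control), computes
treatment means, percent change versus control,

$$\Delta\% = 100 \cdot \frac{\bar{x}_{treatment} - \bar{x}_{control}}{\bar{x}_{control}},$$

and Tukey letters per response at α = 0.01. Biomass and height are analysed
as independent responses (they are reported as separate panels in this kind
of experiment; no multivariate correction is applied), and percent change is
computed from treatment means rather than per-pot ratios, matching how such
increases are reported. The control must be present with at least two pots,
as must every treatment.

## The synthetic-data generator

`generate_dataset()` produces datasets with the statistical structure the
pipeline assumes, so every stage is testable without external data.

* **Qualitative traits**: each isolate carries a latent positive/negative
  state per trait, drawn at the per-group positivity probabilities of
  `default_positivity()`; replicates agree with the latent state except for
  a 2% flip rate, which exercises the unanimity rule. Default probabilities
  follow the published per-group screening rates for this system; where
  only a range is printed for a pair of groups, a value inside the range was
  fixed once (e.g. P-solubilization 0.41 mesophilic / 0.54 spore-formers
  within a printed 41–54% band) and not revisited.
* **Quantitative traits** are zero-inflated lognormal. The zero inflation is
  forced by the data this emulates: a first quartile of exactly 0 in one
  published group × parameter row implies a point mass of assay-negative
  isolates; the lognormal positive part is the standard model for strictly
  positive assay concentrations. `calibrate_lognormal()` inverts the
  quantile function in closed form — `log_location = ln(median)`,
  `log_scale = ln(q3/median)/z_{0.75}` — so the positive part's median and
  upper quartile equal the published calibration pair exactly. Calibration
  uses (median, q3) only: q1 is redundant under the symmetric-in-log model,
  and the one inconsistent printed q1 row is thereby avoided. IAA is assayed
  for every isolate; P-mineralization and nitrification only for isolates
  latently positive to the matching qualitative screen, mirroring how the
  quantitative workload was reduced in the screening design.
* **Replicate noise** is multiplicative lognormal at a 5% CV (keeping values
  positive); the default zero mass among performed assays is 0.10. Gross
  outliers hit 5% of replicate sets by multiplying one replicate by
  U(5, 10). The lower bound matters: with replicates at 5% CV, Dixon's
  *n* = 3 critical value 0.970 is only exceeded for multipliers above
  ~4.3 (Q ≈ (k − 1.05)/(k − 0.95)), so a milder "outlier" would never
  trigger the removal path the injection exists to exercise.
* **Elite strains** (`n_elites_per_group > 0`) are planted for the
  end-to-end recovery property: one designated isolate per group ×
  calibrated parameter takes a positive value 1.3× the cohort maximum for
  that parameter. Planting at a margin above the maximum — rather than at a
  fixed quantile — is deliberate: the first-round rule keeps only the top
  Tukey homogeneous group, so recovery is guaranteed only for isolates that
  actually top their parameter. The margin (30% against 5% replicate noise)
  makes the elite's lead decisive.
* **Growth data**: control pots at 2.0 g/pot biomass and 25 cm height
  (plausible for young pot-grown durum wheat at tillering), pot-level
  lognormal noise at 10% CV, three pots per treatment, and multiplicative
  treatment effects of 1.5 (biomass) and 1.25 (height) for elite strains —
  the effect sizes the validation stage is expected to resolve. No published
  dispersion exists for these measurements; the 10% pot CV is a generator
  choice.
* **Determinism**: a single integer seed drives hierarchical per-isolate
  substreams, so the same seed gives byte-identical data and enlarging a
  cohort never perturbs previously generated isolates. The caller's RNG
  state is saved and restored.

### What passing on synthetic data does and does not show

The generator draws traits independently within an isolate (no genetic
correlation between, say, P-solubilization and siderophore production), uses
a single lognormal family for all positive parts, flattens technical and
biological replication into one exchangeable replicate list, and has no
batch, plate or storage-time effects. Tests passing on these data show the
*rules* are implemented correctly and are well-behaved under the assumed
structure; they do not show that real rhizosphere data satisfy that
structure — in particular, correlated traits would change how many isolates
the second-round breadth rule admits, and heavier-tailed replicate error
would make the 10% CV gate fire more often than the calibrated 5% suggests.

## Degenerate inputs and numerical choices

* CV undefined for fewer than 2 values or non-positive mean → error;
  all-zero replicate sets bypass QC.
* Quartiles require ≥ 4 pooled values; Dixon's table covers *n* = 3–10 and
  larger sets are refused rather than silently approximated.
* ANOVA/Tukey require ≥ 2 groups with ≥ 2 values each; with zero residual
  variance, equal means give F = 0, p = 1, and unequal means give exact
  separation.
* Letter assignment breaks mean ties by label order, making every output
  deterministic.
* All randomness flows from explicit integer seeds below 2³¹.

## Problem sizes used by the test suite

The suite runs the worked example exactly; oracle comparisons on 200 random
3–5-group designs (letters), 2⁵ exhaustive outcome vectors (binary coding),
20 generator seeds at 15 isolates per group (elite recovery), 300 null
growth-chamber simulations (familywise error), and one 10,000-isolate cohort
(quantile recovery, where the sample median must sit within three
order-statistic standard errors of the calibrated 18.86 µg/mL). These sizes
give each stochastic check comfortable resolution while keeping the full
suite under a minute on one core.

## Known limitations

* The screen's published PCA loadings and growth-chamber panel means are not
  reproducible targets: the underlying raw matrices were never published, so
  the package checks its PCA against an independent eigendecomposition and
  its validation statistics against simulations with known effects instead.
* Dixon's test is limited to one removal per replicate set by construction;
  replicate sets with two gross outliers of three are unrecoverable and stay
  flagged.
* `second_round()`'s breadth rule counts detectable parameters, not effect
  sizes; with strongly correlated traits it will admit more isolates than
  trait-independence suggests.
* The viability flag is an input; the package does not model storage
  survival.
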