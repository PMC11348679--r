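---
title: "The PMD myelination score: model, analytics, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PMD myelination score: model, analytics, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdscore)
library(dplyr)
```

## The scoring model

Pelizaeus-Merzbacher disease (PMD) is an X-linked hypomyelinating
leukodystrophy caused by *PLP1* variants, with clinical severity ranging from
neonatal-onset connatal disease to mild spastic paraplegia. Because the myelin
deficit is visible on conventional MRI, a semiquantitative visual score of
white-matter signal can stratify patients and track change without
quantitative imaging.

The score grades *best myelination* — the most mature signal present in a
structure, so partial myelination is distinguished from absent myelination —
in a fixed set of anatomic items relative to cortex (pontine items relative to
surrounding brainstem white matter):

* **T2-weighted items (8):** central region, centrum semiovale, posterior
  limb of the internal capsule (PLIC), optic radiation, primary visual
  region, middle cerebellar peduncle (MCP), frontal (not central) white
  matter — each 0 = hyperintense, 1 = isointense, 2 = hypointense relative to
  cortex — plus the medial lemniscus, scored binary (0 = abnormally
  hyperintense relative to surrounding brainstem, 1 = normal
  iso-/hypointense).
* **T1-weighted items (6):** the five supratentorial pyramidal/visual-tract
  items plus MCP, each 0 = hypointense, 1 = isointense, 2 = hyperintense.

Higher always means more mature myelin. The sub-scores are plain sums: T2 in
0–15, T1 in 0–12, and the combined score in 0–27. Items once evaluated but
discarded for insufficient inter-rater concordance (ALIC, pontine pyramidal
tract, a simplified genu scoring, peridentate white matter) remain in the
registry flagged non-scoring, so historical tables read cleanly without ever
contributing to a sum.

Deliberate properties of this design: no age normalisation (a stable deficit
keeps a stable score, and infants with less myelin than a term neonate remain
representable), and strict refusal to emit a total from incomplete gradings
unless the caller opts into a flagged partial sum — silent imputation would
corrupt comparisons against the cut-offs below.

## Classification

Two independent routes map a scan to a severity group:

* **Rule-based** (`classify_rules()`): three sufficient-condition signatures
  evaluated most-specific-first — MILD (normal lemniscus, frontal at least
  T2-isointense, primary visual at least T1-isointense), then
  CLASSIC_OR_MILDER (T2-hypointense MCP, at least isointense centrum
  semiovale and PLIC on T2, T1-hyperintense central region, centrum
  semiovale, optic radiation and MCP), then SEVERE (no T2 item at 1 or
  above, PLIC not T1-hyperintense, optic radiation and centrum semiovale
  below T1-isointense). A scan matching none returns INDETERMINATE rather
  than a forced guess: the signatures are observed implications, not a
  partition. The ambiguous scope of the "without" clauses in the severe
  signature is resolved as independent conditions on optic radiation and
  centrum semiovale (both below T1-isointense).
* **Threshold-based** (`classify_threshold()`): combined first-MRI score
  against half-integer ROC cut-offs, by default 6.5 (severe vs classic) and
  14.5 (classic vs milder). Half-integer cut-offs mean integer scores never
  tie; comparisons are strict. The thresholds are intended for first MRIs —
  classic-type scores rise past 14.5 on follow-up.

## Inter-rater concordance

Ordinal grades from multiple raters are compared with linear weights,
`w[r,s] = 1 - |r-s|/(k-1)`. Observed agreement is the mean over subjects of
the weighted proportion of agreeing rater pairs. The default chance term is
**uniform over categories**, `P_e = sum(w)/k^2`, which makes the statistic
robust to kappa paradoxes — in severity-restricted samples most subjects sit
in one or two categories, and prevalence-based chance terms then punish
genuinely high agreement. A marginal-based (Fleiss-type) weighted kappa is
available as a labelled alternative for comparison, and a test demonstrates
the paradox: on a range-restricted table the marginal statistic collapses
while the uniform one does not. Subjects rated by different numbers of raters
are rejected (the design is balanced). No permutation p-value is computed.

Statistics are interpreted on the Cicchetti scale (poor < 0.40, fair
0.40–0.59, good 0.60–0.74, excellent 0.75–1.00) and items are retained when
the statistic reaches 0.60 (inclusive floor — the lower edge of "good"
retains, matching the retention of peridentate white matter at 0.62 and the
discarding of ALIC at 0.5 and simplified genu at 0.56 during score
development).

## Development analytics

* **Unifactoriality** (`pca_unifactorial()`): PCA on the inter-item
  correlation matrix with the Kaiser criterion (exactly the first eigenvalue
  above 1). Correlation-matrix PCA was chosen — the source analysis does not
  state its scaling — because the eigenvalue-1 rule is only meaningful on
  standardised variables. A valid myelination score should be essentially
  one age-driven factor; on simulated controls the first component carries
  well over 80% of the variance.
* **ROC** (`roc_analysis()`): AUC by pair counting with ties worth 1/2
  (identical to the Mann–Whitney statistic), cut-off at the midpoint between
  adjacent observed scores maximising Youden's J — the origin of the
  half-integer clinical cut-offs. The default direction treats the positive
  (more affected) class as scoring *lower*, since hypomyelination lowers the
  score. No confidence intervals are produced.
* **Group comparisons** (`compare_groups()`): pairwise two-sided Wilcoxon
  rank-sum tests with Holm adjustment; the exact null distribution is used
  when the combined sample size is at most 20 with no ties, the normal
  approximation with continuity correction otherwise.

## Volumetry surrogates

Atrophy is tracked separately from myelination — combining them into one
score would blur the severe/classic boundary, because severe patients are
imaged younger and have *less* atrophy. The surrogates are the bicaudate
ratio (BCR, minimum intercaudate distance over inner-table width; unitless,
scale-invariant), the anterior–posterior pons diameter (mm), and a visual
thin-corpus-callosum flag. Raw values are turned into z-scores against an
age-binned norms table, with mean and SD linearly interpolated between bin
midpoints so the z-score is exact at midpoints and continuous across
boundaries; ages outside the table's coverage are errors, not extrapolations.
Abnormality flags are strict: BCR flagged above +2 SD, pons below −2 SD
(a z-score within numerical tolerance of the boundary is not flagged). The
packaged norms table (`synthetic_volumetry_norms()`) is **synthetic** — a
smooth, plausibly shaped stand-in provided only so the pipeline runs and can
be tested; clinical use requires user-supplied reference norms.

## The synthetic cohort generator

No patient data ships with the package; every pipeline stage is exercised on
simulated cohorts that encode the score's documented behaviour.

**Controls** mature deterministically through per-item milestone ages — grade
1 then grade 2 — shifted by a bounded per-subject offset (uniform ±0.5
months), so grades are non-decreasing in age within a subject. The published
full-score windows (T1 items complete between 3.5 and 4.6 months, T2 items
between 8.7 and 10.8 months) do not say whether the spread is across items or
subjects; we interpret them as the spread of per-item grade-2 milestones
across items (3.5–4.1 and 8.7–10.3 months) plus the subject jitter, which
places every subject's full-score attainment inside the printed windows by
construction. Random scan ages are log-uniform over 2 weeks–20 years,
mimicking infant-heavy, age-adapted sampling.

**Patients** draw first-MRI grades from per-subtype, per-item grade
distributions calibrated once to the qualitative subtype signatures: connatal
and transitional scans have no sustained T2-isointense myelin (with a rare
transient isointense PLIC or optic radiation on very early scans), classic
scans have at least T2-isointense and T1-hyperintense PLIC, and the mild
group (intermediate, PLP0, SPG2, female) has a normal lemniscus and T1 sums
of uniformly 11 or 12, with PLP0 carrying the lowest T2 scores. Rejection
sampling enforces each subtype's admissible combined-score span at first MRI
(connatal 0–6, transitional 1–5, classic 7–14, PLP0 14–19, intermediate
17–22, SPG2 and female 18–24). Cohorts with at least two patients of a
subtype are additionally *range-anchored*: one patient is conditioned to each
end of the span, so a simulated cohort covers its documented score range by
construction rather than by seed luck. This is what reproduces the published
boundary structure deterministically — severe scores reach 6 while classic
starts at 7 (Youden cut-off 6.5 with AUC 100%), and classic meets PLP0 at 14,
keeping classic-versus-mild discrimination good but imperfect. The
transitional span ends at 5 rather than 6 because a transitional score of 6
would require the transient early isointensity, which is only available below
0.6 years while transitional first MRIs extend to 1.6 years; the severe-group
maximum of 6 is carried by the connatal profile, exactly the configuration of
the published worked example (T2 = 1 from a transient isointense item plus
T1 = 5 at 0.19 years).

**Follow-up dynamics** per subtype: `gain` steps immature items one grade
towards a ceiling with per-interval probability `1 - exp(-rate * dt)`
(classic, intermediate, female), `early_loss`/`late_loss` lower every
positive three-level grade by one at the first scan past the onset age
(connatal, transitional, PLP0 early; SPG2 late), `stable` copies the
baseline. Gains never lower a grade and losses never raise one, so simulated
trajectories are monotone in the profile's direction.

**Raters** report the true grade with probability `1 - epsilon` and an
adjacent grade otherwise (clamped at scale ends); **volumetry** simulates
control BCR z-scores centred at zero and patient z-scores drifting upward
with age, reconstructing raw millimetre measurements through the norms table
so the analysis side recovers the simulated z-scores exactly.

Everything is seeded: an identical specification and seed yields a
bit-identical cohort.

### What passing tests do and do not show

The generator encodes the *constraints* the score was reported to satisfy; it
does not model scanner/protocol heterogeneity, reader drift, partial-volume
ambiguity, or the correlation structure of real item errors. Recovery results
on synthetic cohorts (severe-vs-classic AUC 100% with cut-off 6.5, mild-group
T1 sums of 11–12, controls complete by 10.8 months) therefore demonstrate
internal consistency of the pipeline, not clinical validity. In particular,
the published patients-versus-controls AUC of 89.2% and classic-versus-mild
AUC of 96% arise from the original clinical cohort, which is not publicly
available; the synthetic cohorts cover these only qualitatively (overlap is
built into the classic and PLP0 profiles, so classic-versus-mild AUC is below
100%).

## Numerical choices and problem sizes

* Youden cut-off candidates are midpoints between consecutive *observed*
  scores; at ties in J the lowest such threshold is reported.
* Wilcoxon tests switch from exact to corrected-normal at combined n > 20 or
  in the presence of ties.
* Validation is strict about scales: grades must be integers within the
  item's scale, the lemniscus is T2-only and binary, one age per scan,
  duplicate (scan, modality, item) rows are errors naming the row.
* Test and acceptance problem sizes (200 simulated controls on a daily age
  grid around the maturation window, cohorts of 18–28 patients, 25–40
  property-test replicates) were chosen to exercise every code path in
  seconds while keeping Monte-Carlo checks comfortably away from their
  thresholds.

## Known limitations

* The agreement statistic follows the documented uniform-chance contract;
  the exact internals of the originally cited implementation are not
  reproducible from the publication.
* The packaged volumetry norms are synthetic; z-scores against them are not
  clinically interpretable.
* The correlation type behind the published BCR-z/age association is not
  stated; Pearson is used.
* Rule-based classification deliberately abstains (INDETERMINATE) on scans
  outside the three signatures; users wanting a forced choice should use the
  threshold route.
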