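---
title: "Immunomonitoring methods: expansion calling, responder scoring, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunomonitoring methods: expansion calling, responder scoring, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtcr)
```

## The problem

Pooled mutant-KRAS (mKRAS) peptide vaccines in resected pancreatic cancer
are monitored with two complementary readouts: serial IFN-γ ELISPOT of
peripheral blood (how strongly does the patient's T-cell compartment react
to each of the six vaccine antigens G12V, G12A, G12R, G12C, G12D, G13D),
and bulk TCRβ sequencing of short-term peptide-stimulated cultures (which
individual T-cell clonotypes carry that reactivity). `vaxtcr` implements
the full computational cascade for both readouts, plus high-similarity
CDR3 matching against external tumor repertoires and exploratory
survival stratification, and ships a seeded synthetic-data generator so
every stage can be validated against known ground truth without access to
patient-level data.

## Clonotype identity and repertoire model

A clonotype is the pair (TRBV gene/allele label, CDR3β amino-acid
sequence). Equality is exact on both components: the same CDR3 under a
different TRBV is a different clonotype. V labels are normalized only for
case and whitespace; allele-level labels (e.g. `TCRBV28.01.01`) are kept
at allele resolution because collapsing to gene level would merge
clonotypes the sequencing pipeline distinguishes. The CDR3 column of AIRR
inputs is `junction_aa`; the package treats that string as the clonotype
label without attempting junction-to-CDR3 trimming, so identity is
whatever convention the input uses — consistent inputs give consistent
identities. Records whose CDR3 contains characters outside the 20-letter
amino-acid alphabet (stop `*`, frameshift `X`) and, by default,
non-productive rearrangements are excluded before aggregation; counts of
identical clonotypes are summed and frequencies are counts over total
reads.

Two input dialects are supported: AIRR-C Rearrangement TSV (columns
`v_call`, `junction_aa`, `duplicate_count`, `productive`) and an
Adaptive-immunoSEQ-style export (synonym table shipped in
`inst/extdata/adaptive_column_map.yaml`, frame type `In` mapping to
productive). AIRR allows both `duplicate_count` and `consensus_count`;
the default count field is `duplicate_count` and it is overridable,
because vendor pipelines report template/read counts without
standardizing on either name. Whether "templates" or "reads" is the
better count unit for these assays is left to the caller; both columns
are accepted, neither is asserted as canonical.

## Repertoire clonality

Per culture we report the clonality index

$$ 1 - \frac{-\sum_i p_i \ln p_i}{\ln n} $$

with \(p_i\) the clonotype frequencies and \(n\) the number of unique
clonotypes: 0 for a perfectly even repertoire, approaching 1 at maximal
clonality. A terminology caution: this quantity circulates in the trial
literature under the name "Shannon equitability", although equitability
conventionally denotes the evenness \(H/\ln n\) itself; the implemented
statistic is its complement. It is undefined for \(n < 2\) (the
denominator is \(\ln 1 = 0\)) and the package raises an error rather than
returning a sentinel. On exactly uniform counts the function returns 0
directly instead of evaluating the sum, so the analytic endpoint is not
blurred by floating-point accumulation.

## Expansion calling

For each peptide-stimulation culture, every clonotype observed in that
culture is tested against a reference culture from the same subject.
Clonotypes seen only in the reference are not tested — they cannot be
"expanded". Three statistics are combined:

* **Read-count ratio** ("odds ratio" in the trial's usage): the
  clonotype's absolute read count in the expansion condition divided by
  its count in the reference. This is *not* a contingency-table odds
  ratio. A clonotype absent from the reference has ratio \(+\infty\),
  which passes any threshold; no pseudocount is added, matching the
  printed definition.
* **One-sided Fisher exact test** on the 2×2 table of (clonotype reads,
  other reads) × (condition, reference), in the enrichment direction,
  computed as the exact hypergeometric upper tail.
* **Benjamini–Yekutieli FDR adjustment** across the family of all
  clonotypes tested in that culture. The BY correction (valid under
  arbitrary dependence) is used because clonotype counts within one
  multinomial sample are dependent. Each (subject × condition) culture is
  one multiple-testing family: each expansion culture is a separate
  experiment with its own library.

A clonotype is called expanded when `q_by <= q_max` (default 0.05,
matching the global two-sided 0.05 significance convention — exposed in
the configuration because no separate FDR cutoff is conventional), the
read-count ratio is `>= or_min` (default 5) and its frequency in the
expansion culture is `>= freq_min` (default 0.1%). All boundaries are
inclusive, following the `>=` convention of the defining rule; figure
legends elsewhere quote `>5` or even `>10`, a discrepancy we document
rather than resolve — both are reachable through `expansion_config()`.
The frequency cutoff can be disabled (`apply_freq_cutoff = FALSE`) for
the mapping mode that keeps every OR-passing TCR.

The reference culture is the vehicle-only (DMSO/IL-2) control by default,
with the irrelevant-peptide control selectable; reports record which was
used. The frequency cutoff is evaluated before baseline filtering, since
it is a property of the expansion culture itself.

**Baseline filtering.** Clonotypes already present (count ≥ 1) in the
subject's unstimulated pre-vaccine repertoire are unlikely to be
vaccine-induced and are flagged and removed from the antigen-specific
catalogue. **Cross-reactive** clonotypes meet the expansion criteria for
two or more mKRAS peptides; **public** clonotypes are expanded (exact
TRBV+CDR3 identity) in two or more subjects. The near-identical variant —
same TRBV, CDR3 within one amino acid, different subjects — is reported
separately by `hs_public_pairs()`.

## High-similarity CDR3 matching

`hs_matches()` finds all clonotypes within `max_dist` (default 2)
amino-acid differences of an external CDR3 list, e.g. tumor repertoires
from an external cohort. The default metric is optimal string alignment
(OSA: Levenshtein plus adjacent transpositions), the default of the
standard R string-distance tooling this analysis style relies on; plain
Levenshtein is available, and whether indels and substitutions should be
weighted differently is deliberately not asserted. Matching against
external lists ignores the V gene (external CDR3 calls often lack
reliable V annotation), in contrast to `hs_public_pairs()` which requires
V identity — two deliberately different rules. A length-difference
pre-filter skips pairs whose length gap already exceeds `max_dist`; the
test suite verifies it never changes the result. The distance kernel is
compiled (C++), with a pure-R dynamic program kept in the test suite as
the independent oracle.

## ELISPOT responder scoring

Spot-forming units (SFU per million cells) arrive in long format:
subject, week, stimulation, replicate. Replicates (triplicates by
design) are averaged. The per-antigen response at each timepoint is the
fold change over the irrelevant-control-peptide well,
\((\mathrm{SFU}_{ag} + c)/(\mathrm{SFU}_{ctrl} + c)\) with a pseudocount
\(c = 1\) SFU by default (how empty control wells were handled upstream
is not standardized; the pseudocount is configurable). Folds are then
normalized to the week-0 fold so the baseline is exactly 1, and the
subject's T-cell response endpoint is the maximum fold change within the
17-week evaluation window (inclusive; `window_weeks = Inf` gives the
any-time secondary-endpoint variant). Responses are pooled two ways:
the arithmetic mean across the six antigens, and the single antigen
matching the patient's tumor KRAS mutation. Antigens excluded from a
subject's panel are omitted from the pooled mean with a warning, never
imputed.

**The 2.77·SD rule.** A subject is an immune responder when the
pre-to-post change in response exceeds 2.77 times the standard deviation
of the baseline values across patients. The constant is
\(z_{0.975}\sqrt{2} = 2.7718\ldots \approx 2.77\): the two-sided 5%
critical value for the difference of two equally variable measurements.
Whether the rule is applied to raw SFU differences or control-normalized
values is ambiguous in practice; both are implemented (`scale = "sfu"`,
the default, and `scale = "fold"`) and neither is asserted as the
original arithmetic. The comparison is strict (`>`): a change of exactly
2.77 SD is not a response. `responder_call()` reports both the one-sided
`responder` flag (positive change beyond the threshold) and the
two-sided `significant_change` flag (\(|\Delta|\) beyond the threshold) —
the latter is the event the multiplier is calibrated for.

Two calibration caveats are worth stating plainly. First, the rule
assumes a single pre/post comparison; selecting the maximal post-vaccine
timepoint inflates the null exceedance above 5%, so the package's
calibration checks use a two-timepoint design. Second, the cross-patient
baseline SD is a valid noise proxy only when patients share a common
baseline level; with real between-patient heterogeneity the rule is
conservative. Both behaviors are inherited from the rule itself, not
introduced by the implementation.

Per-antigen positivity applies the same rule antigen by antigen (each
antigen's own cross-patient baseline SD) and counts, per subject, how
many of the six antigens show a significant increase.

Out-of-range multiplex (Luminex) concentrations arrive as sentinel
strings: `OOR<` is replaced by the lower limit of the assay's standard
curve and `OOR>` by the upper limit (`clamp_oor()`).

## Outcome stratification

Subjects are split at a quantile of their immune-response score (default
the 25th percentile — the lowest-quartile design). The percentile uses
the type-7 linear-interpolation convention, and scores equal to the
threshold fall in the low group; the original convention is unknowable
from printed results, so ours is fixed and documented. Kaplan–Meier
curves, medians (earliest event time where the estimate reaches 0.5,
`NA` when never reached) and the two-group log-rank test are provided
through the `survival` package behind this module's interface; the test
suite checks them against hand product-limit computation and a direct
observed-minus-expected implementation. Cox hazard-ratio estimation is
deliberately not wrapped: it is a standard model fit users should run
directly (`survival::coxph`).

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates, per subject, a heavy-tailed background
repertoire (symmetric Dirichlet with concentration 0.1 — heavy-tailed
enough to exercise the statistics, with no claim to match fitted
real-repertoire laws) observed through multinomial read sampling at depth
10⁵ under ten conditions. Defaults mirror the study scale: 12 subjects,
2×10⁴ clonotypes, 10 truly reactive clones per antigen spiked at fold 20
with post-spike frequency at or above 0.2% (comfortably above both the
5-fold and 0.1% cutoffs, as the wet-lab cultures are designed to be), 20%
of spiked clones cross-reactive with the extra antigen biased toward
G12C/G12A/G12V, two public clonotypes planted in subject pairs with a
shared antigen, 10% of spiked clones also planted at baseline (and
therefore filtered by design), and five specific clones planted in each
tumor sample. Spiking multiplies frequencies and renormalizes, so every
emitted repertoire is a proper distribution; a configuration whose spike
mass reaches 1 is rejected. CDR3 strings are random length-10–18
sequences in a fixed `CASS…F` frame so the similarity module sees
realistic structure. Everything is a pure function of the seed.

The ELISPOT generator draws negative-binomial well counts (mean 50 SFU,
size 10) and gives responders an additive shift of 6 cross-patient
baseline SDs of the pooled response, ramping at week 4, holding a plateau
over weeks 8–16 (the boosting period keeps responses elevated) and
decaying afterwards. All subjects share a common baseline mean — the
homogeneity the 2.77·SD rule assumes — so the null calibration check is a
test of the rule under its own model. Because the effect is calibrated on
the pooled scale, tumor-matched (single-antigen) detection is noisier and
its sensitivity is expectedly below the pooled mode's.

What passing these tests shows: the statistics, thresholds and
bookkeeping are implemented correctly and recover planted truth under
the stated noise model. What it does not show: performance on real
repertoires with V(D)J-structured sharing, PCR/template noise,
batch effects, or HLA-dependent antigen response structure — none of
which the generator models.

## Numerical and design choices

* Fisher p-values come from the exact hypergeometric tail (`phyper`);
  the acceptance suite verifies agreement with exhaustive enumeration to
  below 10⁻¹² on all 1.76 million 2×2 tables with depths up to 50.
* BY adjustment is `p.adjust(method = "BY")`, checked against the direct
  step-up formula.
* All report numerics are serialized at 12 significant digits and all
  character ordering uses locale-independent radix sorting, so repeated
  runs are byte-identical and regression-testable; each pipeline run
  writes a manifest (config echo, config hash, output checksums) that
  fully determines the report bytes.
* Problem sizes in the validation suite — 10 cohort seeds, 2000-subject
  null calibration, 10⁴ distance pairs, depth-50 enumeration — were
  chosen as the smallest sizes at which the checked properties are
  sharply distinguishable from failure modes.
* Thresholds are inclusive (`>=`) for expansion calling and strict (`>`)
  for the responder rule, each following its defining convention.
* Degenerate inputs fail loudly: empty repertoires after filtering,
  single-clonotype clonality, zero baseline SD, all-identical
  stratification scores (warning, all high), missing baseline weeks.

## Known limitations

* Single-chain (β) analysis only; no paired αβ reconstruction.
* The expansion test conditions on observed library sizes; very shallow
  references make the read-count ratio unstable (it is reported as
  \(+\infty\) when the reference count is 0 rather than regularized).
* The responder rule's max-over-weeks selection and cross-patient SD
  proxy inherit the calibration caveats above.
* The generator's truth labels are planted at effect sizes where recovery
  should be near-perfect; it is a correctness harness, not a power
  benchmark.
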