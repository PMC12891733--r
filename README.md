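# vaxtcr

Immunomonitoring analysis for mutant-KRAS (mKRAS) peptide vaccine trials.

Phase-I neoantigen vaccine studies in resected pancreatic cancer monitor
vaccine-induced immunity with two readouts: serial IFN-γ ELISPOT of
peripheral blood against the six mKRAS antigens (G12V, G12A, G12R, G12C,
G12D, G13D), and bulk TCRβ sequencing of short-term peptide-stimulated
PBMC cultures to identify the individual clonotypes carrying that
reactivity. `vaxtcr` implements the complete computational cascade for
both, for trial statisticians and computational immunologists who need
the published analysis rules as tested, reusable code:

* **Repertoire IO** — AIRR-C Rearrangement TSV and Adaptive-immunoSEQ-style
  exports, aggregated to clonotypes defined as (TRBV label, CDR3β amino
  acids).
* **Expansion calling** — for every clonotype in a peptide culture vs. a
  vehicle-only or irrelevant-peptide control: one-sided Fisher exact test
  (exact hypergeometric tail), Benjamini–Yekutieli FDR per culture,
  read-count ratio OR = n_cond / n_ref, frequency cutoff. Default call:
  q ≤ 0.05, OR ≥ 5, frequency ≥ 0.1%. Clonotypes present in the
  unstimulated pre-vaccine baseline are filtered out; cross-reactive
  (≥ 2 antigens) and public (≥ 2 subjects, exact identity) clonotypes are
  classified, with tumor-repertoire overlap summaries. Repertoire
  clonality is reported as 1 − H/ln(n).
* **High-similarity TCRs** — CDR3 matching within ≤ 2 amino-acid
  differences (optimal string alignment distance, compiled) against
  external tumor CDR3 lists, plus near-identical public pairs (same TRBV,
  CDR3 within 1 aa, different subjects).
* **ELISPOT responder scoring** — control-normalized, baseline-folded
  responses; maximum fold change within a 17-week window; pooled-average
  and tumor-matched modes; responder if the pre-to-post change exceeds
  2.77 × the cross-patient baseline SD (2.77 = z₀.₉₇₅·√2, the two-sided
  5% critical multiplier for a difference of two equally variable
  measurements); per-antigen positivity counts; Luminex `OOR<`/`OOR>`
  clamping.
* **Outcomes** — lowest-quartile stratification of response scores,
  Kaplan–Meier medians and the two-group log-rank test.
* **Synthetic data** — a fully seeded generator for repertoires (spiked
  expansions, cross-reactive/public/baseline/tumor-planted truth),
  ELISPOT panels with known responders, and survival data, so the whole
  pipeline is testable end to end without patient-level data.

See `vignettes/immunomonitoring-methods.Rmd` for the methods account:
model assumptions, parameter defaults and why, numerical conventions, and
what the synthetic validation does and does not demonstrate.

## Worked example

Simulate a small cohort, call expansions for one subject, and score
ELISPOT responders:

```r
library(vaxtcr)

cfg <- sim_config(n_subjects = 4, n_clonotypes = 2000, depth = 50000, seed = 7)
cohort <- simulate_cohort(cfg)

res <- subject_expansion(cohort$repertoires$S01)
head(res$specific)
#>   subject_id        v_gene           cdr3_aa  antigens n_antigens cross_reactive
#> 1        S01 TCRBV12.01.01     CASSANAPAPCGF      G12D          1          FALSE
#> 2        S01 TCRBV28.01.01 CASSARVKIYNKYCYNF      G13D          1          FALSE
#> 3        S01 TCRBV25.01.01    CASSAVLQPWHVQF G12D,G12R          2           TRUE
#> 4        S01 TCRBV25.01.01   CASSDVYNIQCMGNF      G13D          1          FALSE
```

`res$specific` is subject S01's antigen-specific TCR catalogue after
baseline filtering: 54 clonotypes here, 9 of them cross-reactive
(expanded to ≥ 2 mKRAS peptides); 9 additional expanded clonotypes were
removed because they pre-existed in the unstimulated baseline. Overlap
with the subject's tumor repertoire:

```r
ov <- tumor_overlap(res$specific, cohort$repertoires$S01$tumor_tissue)
sprintf("tumor overlap: %d of %d specific TCRs (%.1f%%)", ov$n_overlap,
        nrow(res$specific), 100 * ov$fraction)
#> "tumor overlap: 5 of 54 specific TCRs (9.3%)"
```

ELISPOT responder calls on a simulated 12-subject panel (11 true
responders by default):

```r
es <- simulate_elispot(n_subjects = 12, seed = 7)
calls <- elispot_responders(es$sfu)
calls[1:2, c("subject_id", "delta", "threshold", "responder", "max_fold")]
#>   subject_id    delta threshold responder max_fold
#> 1      E0001 29.27778  8.888443      TRUE 1.540513
#> 2      E0002 28.66667  8.888443      TRUE 1.559047
sum(calls$responder)
#> [1] 11
```

`delta` is each subject's pre-to-post change in the pooled mean SFU
across the six antigens at their peak post-vaccine week; `threshold` is
2.77 × the cross-patient baseline SD; 11 of 12 subjects exceed it.

A thin command-line front end over the same functions is in
`inst/cli/vaxtcr.R` (`simulate`, `expand`, `elispot`, `all` subcommands).

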