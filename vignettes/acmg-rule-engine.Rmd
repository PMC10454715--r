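---
title: "An ACMG/AMP rule engine with VUS subclassification and P_POT triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ACMG/AMP rule engine with VUS subclassification and P_POT triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgrules)
```

## The model

The engine operates on one annotated variant per individual at a time and
in five stages:

1. **Decision-MAF pre-filter.** A single minor-allele frequency is
   integrated across dbNSFP, VEP and gnomAD and variants at or above 3 %
   are marked `filtered` and excluded from all further stages. The
   integration formula of the upstream pipeline is not public; we take the
   **maximum** over the available sources, which is the conservative
   choice for a frequency *filter* (a variant common in any one source is
   removed). This is an assumption of this implementation.
2. **Criterion assignment** (`assign_criteria()`). Engine-owned criteria —
   PP3/BP4, PM2, BP1, PVS1 — are computed from the record and *override*
   any upstream call for the same code; all other criteria (PS1, PM1, PP4,
   BS1, …) are accepted verbatim from the input, because they require
   case- or literature-level knowledge the engine does not model. BP6
   arriving at an off-scale level (VeryStrong/Moderate) is re-assigned
   Supporting; PP5 is capped at Supporting by symmetry (see below).
3. **Combination** (`acmg_verdict()`): the 2015 ACMG/AMP combining rules
   over the tally of met criteria at their *effective* strengths, so a
   PVS1 carried at Moderate counts as PM evidence. Conflicting
   pathogenic-side and benign-side rules collapse to VUS.
4. **Subclassification** (`vus_subclass()`): exact lookup of the full
   count tuple in the 36-pattern Hot/Middle/Cold table shipped as
   `inst/extdata/vus_subclass_table.tsv`.
5. **Sample-level P_POT** (`apply_ppot()`), then optional
   **segregation substitution** (`resolve_segregation()`).

## Tunable parameters

All numeric constants live in one configuration object,
`acmg_thresholds()`, loadable from JSON via `read_thresholds()`:

| key | default | meaning |
|---|---|---|
| `revel_path` / `revel_benign` | 0.644 / 0.29 | REVEL cutoffs (published calibration of computational predictors); comparisons inclusive |
| `cadd_path` / `cadd_benign` | 25.3 / 22.7 | CADD-phred cutoffs |
| `rank_cutoff_path` / `rank_cutoff_benign` | 0.644 / 0.29 | applied to the 15 dbNSFP rank scores (DANN … VEST3) |
| `n_rank_required` / `n_rank_total` | 8 / 15 | rank-score majority |
| `ada_cutoff` / `rf_cutoff` | 0.708 / 0.515 | dbscSNV AdaBoost / random-forest splice cutoffs |
| `bp1_benign_fraction_pct` | 33.1 | BP1 fires when the benign share of non-VUS missense variants *exceeds* this percentage |
| `bp1_missense_z` | 2.99 | BP1 missense-Z sub-rule threshold (opt-in per gene) |
| `decision_maf_pct` | 3.0 | pre-filter; *strictly below* passes |

The defaults are the published values and are not meant to be tuned; the
configuration exists so that a laboratory recalibration is a data change,
not a code change.

## Design decisions in the genuinely open spots

* **PP3/BP4 evaluability.** For combined missense+splice consequences the
  missense rule applies "if applicable". We define applicable as: at
  least two of the three missense conditions are *evaluable*, where a
  condition is evaluable iff its inputs are present (any rank score
  present makes the majority condition evaluable). An evaluable condition
  with missing data counts as *unmet*, never as absent. This makes the
  fallback deterministic under missing data.
* **Splice-cutoff equality.** The printed pathogenic rule uses `>=` and
  the benign rule `<=` on the same cutoffs, so exact equality satisfies
  both. We assign *neither* criterion and record a conflict rationale —
  contradictory computational evidence should not enter the checklist.
* **BP1 missense-Z sub-rule.** As printed ("missense Z < 2.99") the rule
  would fire for nearly every gene in the genome. It is therefore
  disabled by default and enabled per gene (`gene_info(bp1_z_rule =
  TRUE)`); the benign-fraction sub-rule (> 33.1 %) is the default route.
  Rationale percentages are rounded half away from zero to one decimal
  (196/529 = 37.051… prints as 37.1).
* **PM2 auto-trigger.** When no upstream PM2 call is supplied, PM2
  triggers if every present population field shows absence (no frequency
  entries, allele count 0) or, for recessive genes, a gnomAD homozygote
  count below 2 — and coverage is not known-bad. An explicit upstream
  trigger is always preferred; the exact upstream frequency logic is out
  of scope.
* **PP5 cap.** The engine caps upstream PP5 at Supporting, by symmetry
  with the automatic BP6 re-assignment; assertion criteria should not
  outweigh primary evidence without review.
* **PVS1 tree.** The engine consumes pre-computed booleans/fractions
  (`lof_annotation`) rather than transcript structure. The 10 %
  protein-removal cutoff is applied as strict `<` for the Moderate
  outcome (`NP6`); canonical-splice variants with a possible in-frame
  rescue run the preserved-protein logic one notch down; start loss caps
  at Moderate. Branches beyond the published worked example follow the
  public specification structure and are named by path codes so every
  outcome is auditable.
* **Subclass fallback.** The printed table enumerates 36 patterns and no
  rule for combinations outside it; an additive point scheme cannot
  reproduce the table (a `BS PP PS` row is Hot while `PP PP` is Cold). We
  therefore reduce unprinted patterns deterministically — drop benign
  units (BP, then BS), then the weakest pathogenic unit — until a printed
  row matches, defaulting to Middle; every fallback is flagged in the
  explanation.
* **P_POT semantics.** P_POT participates only in subclassification,
  never in the ACMG class: counting it there would let the proxy itself
  produce LP (1 PM + 2 PP + a Moderate P_POT would read as 2 PM + 2 PP),
  which is precisely what its downgrade rule exists to prevent. Eligible
  partners for the in-trans condition are judged on P_POT-free verdicts
  in a single pass, so two Middle VUS in one recessive gene each qualify
  the other, order-independently, and the "same gene" restriction is
  applied. For eight of the ten Middle rows the augmented pattern is a
  printed Hot row; for `BS PVS` and `BS PS` the augmented counts exceed
  the VUS combinations altogether and the variant is promoted to Hot
  directly, labelled "Hot (potential)".
* **De novo substitution.** Confirmed de novo maps to PS2 when parentage
  is confirmed, PM6 otherwise, selected by a flag on
  `segregation_result()` per standard usage.

## The synthetic generator

`generate_annotations(seed, n, profile)` emulates the *shape* of
annotated panel data: predictor scores uniform over their ranges with
25 %-ish missingness, boundary records placed exactly at each cutoff,
loss-of-function blocks covering every PVS1 branch, inheritance drawn
over AD/AR/XL and zygosity consistent with it. It does **not** emulate
the correlation structure of real predictors (REVEL and CADD are strongly
correlated in practice), realistic allele-frequency spectra, or gene-level
constraint; a green property test therefore establishes rule-logic
correctness (exclusivity, monotonicity, determinism), not calibration of
the thresholds — the thresholds are inputs, taken as given.

## Numerical and degenerate-input choices

* All score comparisons are inclusive (`>=` / `<=`), as printed.
* A BP1 denominator of zero makes the benign-fraction sub-rule not
  evaluable (not met).
* Records missing every population field pass the MAF filter at 0 and
  auto-trigger PM2 (absence of evidence of frequency is treated as
  absence, as upstream annotators do).
* Reports are byte-deterministic for identical inputs; no timestamps.
* The subclass table loader asserts, at every load, that no pattern is
  duplicated and that each of the 36 rows is genuinely VUS under the
  combining rules.

## Known limitations

* Criteria requiring case-level judgement (PP4, PS3, PM1, PS1, …) are
  pass-through; the engine never invents them (automation of functional
  or phenotype evidence is explicitly out of scope).
* HGVS strings are carried, not parsed; there is no genome-coordinate or
  transcript-sequence handling, and no VCF reader.
* The PVS1 branches not pinned by a worked example follow the public
  specification structure; laboratories with their own transcript
  curation should review the path codes.
* PP1 strength is fixed at Supporting regardless of the number of
  meioses.
* The heterozygous-in-a-dominant-gene P_POT condition is as permissive
  as printed; panels with many dominant genes will promote many Middle
  VUS, which is the stated intent of the reporting policy, not a bug.
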