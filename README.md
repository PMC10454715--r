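# acmgrules

An ACMG/AMP germline variant classification rule engine for R, with VUS
subclassification and diagnostic-reportability triage.

## The problem

Clinical laboratories classify germline sequence variants (SNVs and small
indels) into the five ACMG/AMP tiers — Pathogenic (P), Likely pathogenic
(LP), Uncertain significance (VUS), Likely benign (LB), Benign (B) — by
combining named evidence criteria (PVS1, PS1–PS4, PM1–PM6, PP1–PP5, BA1,
BS1–BS4, BP1–BP7), each carried at a strength (pathogenic side:
VeryStrong > Strong > Moderate > Supporting; benign side:
StandAlone > Strong > Supporting). Two practical problems remain after the
combining rules are applied:

1. **Most variants land in VUS**, which is too coarse for reporting
   decisions. Following ACGS practice, this package subclassifies every
   VUS into **Hot**, **Middle** or **Cold** by exact lookup of its
   strength multiset in an auditable 36-pattern table (16 Hot, 10 Middle,
   10 Cold) — e.g. `PM PM` is Middle, `PP PM PM` is Hot, a lone `PP` is
   Cold.
2. **Some Middle VUS are one segregation test away from LP.** The engine
   attaches a *pathogenicity potential* criterion (`P_POT`) to a Middle
   VUS when family testing could realistically upgrade it: another
   P/LP/Hot/Middle variant in the same recessive gene (potential in-trans
   PM3), homozygosity in a recessive gene, heterozygosity in a dominant
   gene (potential de novo PS2/PM6), or hemizygosity in an X-linked gene.
   `P_POT` is Moderate, downgraded to Supporting for the `1 PM + 2 PP`
   and `2 PM` combinations; it promotes the subclass to Hot (reportable)
   but never changes the ACMG class itself. Once segregation results
   arrive, `P_POT` is replaced by the observed criterion (PS2/PM6, PM3,
   PP1 — or BS4/BP2/BS2 when refuted) and the variant is reclassified.

Only P, LP and Hot VUS are reportable; Middle and Cold VUS are not.

The engine also computes the criteria that benefit from hard thresholds:

* **PP3/BP4** (computational evidence): for missense variants, at least
  2 of 3 of REVEL ≥ 0.644 / CADD ≥ 25.3 / ≥ 8 of 15 dbNSFP rank scores
  ≥ 0.644 (benign mirror: ≤ 0.29 / ≤ 22.7 / ≤ 0.29); for splice-region,
  synonymous-splice and intronic (±5) variants, dbscSNV AdaBoost ≥ 0.708
  AND RF ≥ 0.515 (benign: both ≤).
* **PVS1**: a graded loss-of-function decision tree over a structured
  annotation block (NMD prediction, exon relevance, fraction of protein
  removed, …) yielding VeryStrong…Supporting with a path code per branch
  (e.g. a frameshift escaping NMD that removes < 10 % of the protein is
  Moderate via `NP6`).
* **PM2** is always re-assigned Moderate when triggered; **BP6**
  triggered at off-scale levels is re-assigned Supporting pending
  geneticist confirmation; **BP1** fires for missense variants in genes
  where > 33.1 % of non-VUS missense variants are benign.
* A **decision MAF** pre-filter removes variants at ≥ 3 % frequency
  (maximum over dbNSFP/VEP/gnomAD) before any criterion is assigned.

## Worked example

The package ships the four curated worked examples as both R objects
(`builtin_cases()`) and plain-text data
(`inst/extdata/example_variants.jsonl` + `example_genes.tsv`). The
dominant-gene missense case:

```r
library(acmgrules)
cases <- builtin_cases()
print(run_fixture(cases$CELSR1))
```

```
PP3 Supporting: 13/15 predictors are damaging, REVEL score: 0.723 and CADD score: 29.1 (3/3 pathogenic conditions)
PM2 Moderate: Absent from controls (or at extremely low frequency if recessive) in Exome Sequencing Project, 1000 Genomes Project, or Exome Aggregation Consortium (re-assigned from Supporting)
BP1 Supporting: 33 out of 33 non-VUS missense variants in gene CELSR1 are benign = 100.0%, which is more than threshold of 33.1%
P_POT Moderate: possible de novo variant
Final: VUS Hot
subclass: Hot (potential)
Reportable: yes
```

Reading: the evidence `BP PP PM` is a Middle VUS pattern; because the
variant is heterozygous in a dominant gene, `P_POT` (Moderate — the
counts are 1 PM + 1 PP, not a downgrade combination) is attached and the
augmented pattern `BP PP PM PM` is a printed Hot row, so the variant
enters the report. If trio analysis later confirms the de novo
occurrence with parentage, `resolve_segregation()` swaps `P_POT` for PS2
(Strong) and 1 PS + 1 PM reclassifies the variant as Likely pathogenic.

## Command line

```sh
Rscript -e 'quit(status = acmgrules::acmg_cli())' classify \
  --in inst/extdata/example_variants.jsonl \
  --genes inst/extdata/example_genes.tsv \
  --out report.json
```

Subcommands: `classify`, `explain` (per-variant criterion trace),
`validate-table` (audit the 36-row subclass table), `confirm` (apply
geneticist strength confirmations and re-emit), `fixtures` (seeded
synthetic record generator).

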