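# svcohort

Population screening of structural variants (SVs) from dual-caller
resequencing call sets.

## The problem

Short-read SV callers disagree with one another and with themselves: raw
per-individual call sets carry large numbers of false positives and jittered
breakpoints. A standard remedy in cohort resequencing studies — here modelled
on a pig cohort split into a case group (WXP, wrinkled-skin Xiang pigs,
n = 7), a breed-matched control group (XP, n = 7) and a European outgroup
(EUP, n = 21) — is to keep only calls that (i) are supported by at least 3
read pairs, (ii) are reported independently by *two* callers for the same
individual, then (iii) merge calls across individuals into a non-redundant
cohort set, and (iv) keep SVs seen in at least 2 individuals, dropping
chromosome Y. `svcohort` implements that pipeline end to end, together with
the downstream population analyses: gene-model annotation, group-specific SV
screening, genotype-matrix PCA, exact carrier-frequency tests, gene-set
enrichment and a three-criterion candidate screen.

## The method in brief

* **Merge rule.** Two calls are mergeable iff they share chromosome and type
  and overlap by strictly more than 25 bp,
  `min(end_a, end_b) − max(start_a, start_b) > 25`; zero-width insertions
  are matched by breakpoint distance ≤ 25 bp. Cross-individual merging is
  single-linkage transitive clustering under this relation; each cluster is
  represented by its highest-support member (never a coordinate average) and
  carries the set of individuals it was seen in.
* **Coordinates.** 1-based positions with `length = end − start` for
  DEL/DUP/INV and `start == end` for insertions (insert length stored).
* **Group-specific SVs.** Carriers in exactly one group (and, after the
  cohort filter, at least two of them).
* **Carrier-frequency test.** Fisher's exact test on the
  groups × {carrier, non-carrier} table (exact conditional test for 3
  groups).
* **Enrichment.** One-tailed hypergeometric over-representation
  `P(X ≥ k)` for a query of `n` genes against a term of `K` genes in a
  background of `N`.
* **Candidate screen.** A group-specific SV × gene pair is a candidate if
  the gene sits in a significantly enriched skin/aging-tagged term or in a
  curated aging-gene list.

Because the original raw resequencing data are not consumed, the package
ships a synthetic-cohort simulator (`sim_config()`, `simulate_*()`) that
plants shared and group-specific SVs in a generated gene model and emulates
two noisy callers (breakpoint jitter, false negatives, independent false
positives, read-pair support), with a ground-truth table for validating
every stage.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
default-scale cohort (seed 42) and narrate what they find:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_consensus_merge.R
Rscript analysis/03_annotate.R
Rscript analysis/04_group_comparison.R
Rscript analysis/05_enrichment_screen.R
```

Output of a full run (abridged):

```
callerA: 9246 calls across 35 samples (36.6% false positives)
raw calls: 9246 (callerA) + 9312 (callerB)
consensus calls after support and both-caller rules: 5528
cohort filters: 393 in, 7 removed on Y, 4 removed below 2 carriers, 382 kept
non-redundant cohort SVs: 382 (DEL 317, DUP 31, INS 30, INV 4)
  intron                 179 ( 46.86%)
  intergenic             141 ( 36.91%)
WXP-specific SVs: 37 (DEL 30, DUP 3, INS 4, INV 0)
PCA: PC1 6.8%, PC2 5.9% of variance; group means on PC1: EUP 1.72, WXP -2.84, XP -2.32
SVs with significant carrier-frequency differences (p < 0.05): 73 of 382
3 of 33 terms enriched at p < 0.05; top term: TERM_SKIN_03 (p = 9.18e-07)
candidate (SV, gene) pairs: 22 across 20 genes
validation: 100.0% of 382 eligible planted SVs merged once; 94.9% of 39
planted WXP-specific SVs recovered; 0 false specifics
```

Reading: of ~18.5k raw caller records, the support and both-caller rules keep
5.5k per-individual consensus calls, which collapse into 382 cohort SVs —
essentially the 390 planted ones minus Y-chromosome and rarely-detected
records, with the independent false positives almost entirely suppressed.
The WXP-specific screen recovers the planted group structure, PC1 separates
European from Chinese groups, and the candidate screen returns the planted
skin/aging genes.

The same pipeline is available as one call, `run_pipeline(config, out_dir)`,
driven by a YAML or list config (see `?run_pipeline`), writing all artifact
tables plus a reproducible run manifest.

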