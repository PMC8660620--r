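---
title: "Consensus SV calling and population screening: methods and design"
author: "svcohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV calling and population screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design decisions behind
`svcohort`: what each stage computes, which knobs matter, what the
synthetic-cohort simulator does and does not emulate, and where the genuinely
open choices were resolved.

## The pipeline model

The package analyses cohort resequencing call sets in which each individual
has been processed by **two independent SV callers**. The statistical logic
is a cascade of noise filters followed by population comparisons:

1. **Support filter.** A caller record must be backed by at least
   `min_support = 3` supporting read pairs. Records without a support value
   are treated as support 0 and fail closed.
2. **Dual-caller consensus (per individual).** A call survives only if the
   other caller reports a matching call for the same individual. Matching
   uses the merge rule below, greedily one-to-one by best overlap, so one
   record can never spawn two consensus calls. The consensus record takes
   the coordinates of the higher-support member — an observed breakpoint
   pair, not an average — and the pair's maximum support.
3. **Cross-individual merging.** All consensus calls are clustered by
   single-linkage under the merge rule; each cluster becomes one
   non-redundant cohort SV with a carrier list. Single linkage was chosen
   because it collapses every chain of mutually-overlapping calls into one
   record and is invariant to input order; the representative is again the
   highest-support member (ties: leftmost, then shortest).
4. **Cohort filters.** SVs carried by fewer than `min_individuals = 2`
   individuals are dropped, as is everything on chromosome Y (removing the
   influence of sex on detection).

### The merge rule

Two records merge iff they have the same type, lie on the same chromosome,
and overlap by **strictly more than** `min_overlap = 25` bp:

$$\min(e_a, e_b) - \max(s_a, s_b) > 25.$$

The threshold is an absolute overlap, not a reciprocal fraction, and the
inequality is strict: a 25 bp overlap does not merge. Insertions are
zero-width (`start == end`), so overlap is undefined for them; they are
matched by breakpoint distance $|s_a - s_b| \le$ `ins_window`, with the
window defaulting to the same 25 bp. This is a package decision — breakpoint
distance is the only meaningful proximity measure for points, and reusing
the overlap threshold keeps a single tunable.

### Coordinate conventions

Positions are 1-based. For DEL/DUP/INV the recorded length equals
`end − start` exactly — the convention was adopted because every row of the
curated candidate table shipped in `inst/extdata/` satisfies it — and the
affected bases are taken to be `start+1 … end`. Insertions carry
`start == end` with the inserted-sequence length stored separately. Interval
arithmetic throughout (overlap, CDS containment, feature classification)
follows this `end − start` convention; a consequence is that a span variant
touching a single base of a feature does not count as overlapping it.
Coordinates are used as given; no left-alignment or normalization is
attempted before comparison.

## Annotation

Location classes are assigned per SV with precedence
`exon_intron > exon > utr > intron > upstream_downstream > intergenic`:
boundary-spanning events outrank purely exonic ones, coding overlap outranks
UTR-only overlap, and a gene-flank hit (within `flank` bp of the gene span)
outranks nothing but intergenic. The flank defaults to 5,000 bp, the common
annotator default, consistent with the curated candidate table whose largest
gene-associated distance is 4,352 bp. Exon and intron ordinals are
strand-aware (exon 1 is 5'-most) and reported in the conventional
`EXON=i/n,INTRON=j/m,STRAND=s` grammar; when several features are touched,
the 5'-most ordinal is printed. When an SV overlaps several genes, all genes
are reported and the highest-precedence class wins; across multiple
transcripts of one gene the most severe classification is kept.

Impact prediction is deliberately simplified to the two classes used in
typical cohort reports plus a none class. Rules fire in severity order:

| rule | consequence | impact |
|---|---|---|
| DEL/DUP over a stop codon | `stop_lost` | high |
| DEL/INS/DUP contained in CDS, affected length not divisible by 3 | `frameshift` | high |
| boundary-spanning or within 8 bp of a splice site | `splice_region` | modifier |
| UTR-only overlap | `utr_change` | modifier |
| within the gene flank | `regulatory_region` | modifier |
| purely intronic | `intron_variant` | modifier |
| intergenic | `intergenic_variant` | none |

The 8 bp splice window is a conventional annotator choice (configurable);
the regulatory class is a coarse stand-in for promoter and
transcription-factor-binding-site losses, which cannot be called without
motif data. Location summaries report percentages rounded **half-up** to two
decimals, because that is the convention that reproduces published summary
percentages computed from their integer counts.

## Population comparisons

The genotype model is presence/absence: entry 1 iff the individual is in
the SV's carrier set. Diploid genotypes are never called, so "allele
frequency" means carrier frequency throughout. PCA mean-centres the columns
without scaling (binary columns already share a scale) and decomposes by
SVD; the sign of each component is fixed by forcing its largest-magnitude
loading positive, with magnitude ties broken by column name so the
convention is invariant to column permutation. A zero-variance matrix yields
zero coordinates with a warning rather than an error.

Carrier-frequency differences are tested with Fisher's exact test on the
groups × {carrier, non-carrier} table; with three groups this is the exact
conditional test over all tables with the observed margins. Significance is
reported at raw p < 0.05 by default — matching the unadjusted reporting
style common in cohort SV studies — with Benjamini–Hochberg adjustment
available behind a flag.

Gene-set enrichment is the one-tailed hypergeometric over-representation
test, $P(X \ge k)$, with each term intersected with the background before
testing and no correction by default. The candidate screen then combines
three evidence streams: group-specificity (criterion 1, by construction),
membership in a significantly enriched term whose name matches a
configurable tag pattern (criterion 2; tags travel in the gene-set file, so
no biology is hard-coded), or membership in a curated aging-gene list
(criterion 3). Criteria 2 and 3 combine as OR — they are alternative
evidence streams feeding one candidate table. The literature-review step
that a human would apply on top of the mechanical screen is out of scope.

## The synthetic cohort

The simulator generates the study conditions the pipeline is validated
under: 35 individuals in groups WXP (7), XP (7) and EUP (21); a genome of 5
autosomes of 8 Mb plus 4 Mb X and Y (Y gene-free, present to exercise the
chromosome filter); 120 single-transcript genes with 5 exons, 100/150 bp
UTRs and in-frame CDS, spaced more than two flanks apart so flank
annotations are unambiguous; 300 cohort-shared SVs (carriers drawn across
groups, at least two groups each) and 90 group-specific SVs (40 WXP, 25 XP,
25 EUP; at least 2 carriers each); per-SV carrier frequency uniform on
[0.15, 0.9]; lengths log-uniform on [50, 2000] bp; type mix DEL 0.86 /
DUP 0.07 / INS 0.06 / INV 0.01, approximating a deletion-dominated cohort
call set; location stratification intron 0.45 / intergenic 0.38 /
flank 0.11 / exon 0.03 / exon-intron 0.02 / UTR 0.01, approximating
published group-specific location profiles. Caller noise defaults: Gaussian
breakpoint jitter (sd 10 bp, independent per breakpoint, lengths recomputed),
5% false negatives, 2 false positives per Mb per sample (independent across
callers — precisely the error mode the both-callers rule is designed to
suppress, making its benefit measurable), and support drawn as
1 + Poisson(9). Same-type planted SVs never overlap (200 bp guard band), so
ground truth stays unambiguous under the merge rule. These scales keep a
full replicate near ten seconds while leaving every stage statistically
non-trivial; the genome is deliberately small, and published full-scale
totals (tens of thousands of SVs from ~1 Tb of reads) are not reproduced at
this scale.

What the simulator does **not** emulate: read-level data (no FASTQ/BAM, no
alignment artefacts), sequence content (no repeat-driven caller bias,
no breakpoint homology), correlated caller errors, diploid genotypes, and
population genetics (no LD, drift or shared ancestry between groups —
carriers are drawn independently per SV). Passing recovery tests therefore
demonstrate the correctness of the consensus/merge/screen logic under
realistic noise geometry, not the field performance of any particular
caller.

## Numerical and degenerate-input choices

* Candidate overlap pairs are found with `IRanges::findOverlaps` per
  (chromosome, type); cluster components use an in-package union-find. The
  test suite checks the clustering against a brute-force $O(n^2)$ oracle.
* Consensus matching is greedy by descending overlap (ascending breakpoint
  distance for insertions), ties broken leftmost-then-shortest, giving a
  deterministic one-to-one matching.
* `merge_cohort` canonically re-sorts its input, so results are invariant
  to row order; IDs `sv_%05d` are assigned in (chromosome, start) order
  with natural chromosome ordering (autosomes numerically, then X, then Y).
* Empty inputs: empty call sets yield empty consensus/merged tables;
  an empty annotation input yields an empty summary; writing an empty
  cohort table is refused as a likely upstream error.
* In the null-calibration test of enrichment, terms of size 80–100 against a
  200-gene background are used: the hypergeometric test is discrete and
  conservative, and its attainable rejection rate at level 0.05 approaches
  the nominal level only for large terms (~0.048 there, versus ~0.01 for
  20-gene terms). The test asserts the empirical rate matches the nominal
  level to within a point and never exceeds it.

## Open choices resolved

* Whether dual-caller pairs are formed before cross-individual merging or
  simultaneously is not dictated by the pipeline's description; stages are
  ordered consensus-first, which the methods ordering suggests and which
  keeps per-individual evidence requirements explicit.
* "Two or more individuals" counts carriers across the whole cohort, not
  within any one group.
* Group-specific screening requires at least one carrier in the target
  group and zero elsewhere; no additional within-group minimum is imposed
  beyond the global two-individual filter.
* The per-group carrier counts feeding the Venn partition label each SV by
  the full set of groups with at least one carrier, sorted alphabetically.

## Known limitations

Translocations are out of scope (the two-caller design assumed here does
not call them reliably). Breakpoints are taken as reported — no re-alignment
or left-normalization — so callers with systematically shifted breakpoints
would need a larger `ins_window`/`min_overlap`. The impact annotator is
transcript-structural only: it knows nothing of codons beyond frame
arithmetic, and its regulatory class is positional, not motif-based. The
enrichment test treats genes as exchangeable units and ignores gene length
bias, which a field analysis of real SV data would want to correct for.
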