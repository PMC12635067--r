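---
title: "Methods: somatic SV concordance and transposon analysis in amplified single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic SV concordance and transposon analysis in amplified single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicSV)
```

## The problem

Whole-genome amplification (multiple displacement amplification, MDA) makes
single-cell long-read sequencing possible, but at a price: branched and
chimeric molecules that surface as spurious inversions, duplications and
low-support calls; strongly uneven coverage with long zero-coverage runs;
allelic dropout that preferentially erases one allele of heterozygous
variants; and a C>T-dominated substitution error spectrum. Any claim about
*somatic* structural variants (SVs) in single cells therefore rests on a
chain of call-level filters, a careful single-cell versus bulk comparison
restricted to regions callable in both, and null models for the genomic
placement of the surviving variants.

mosaicSV implements that chain as composable functions plus an end-to-end
pipeline, and ships a synthetic-data generator that plants ground truth with
exactly the failure modes above, so every stage can be validated against a
known answer.

## Filtering model

A call survives when its locus is covered by at least 5 reads, at least 3
reads support the variant, and the caller's FILTER field is `PASS`. SVs must
additionally be at least 50 bp long (the conventional SV floor; the boundary
is configurable and inclusive by default) and must not be inversions,
duplications or breakends — in MDA material those classes are dominated by
amplification chimeras and are excluded wholesale rather than adjudicated.
A high-confidence tier adds genotype quality GQ ≥ 20. Rules are applied in a
fixed order (type, filter, length, support, depth) with first-failing-rule
attribution, so filter reports are deterministic and always satisfy
`input = retained + sum(rejections)`. Calls with missing depth or support
fields are rejected under an explicit `missing_field` rule, never silently
kept.

## Concordance model

Single-cell calls are first merged across cells by greedy positional
clustering under the standard SV match geometry: same type, breakpoints
within 500 bp, size ratio (min/max) ≥ 0.7 — the defaults of widespread SV
benchmarking practice, since no tighter geometry is dictated by the
biology. Sorting before clustering makes the result independent of input
order; ties break on smallest breakpoint distance, then smallest size
difference, then leftmost position; the cluster representative is the
highest-support member.

Each merged variant is then matched one-to-one against the bulk callset.
Matched variants are *shared*; unmatched merged variants are
*single-cell-only*; bulk calls unmatched by any cell but lying inside at
least one cell's callable region (depth ≥ 5) are *bulk-only*. Bulk calls
outside every cell's callable region are excluded and counted — comparing
them would conflate absence of the variant with absence of data.

From the sharing records the package computes per-type recall of
single-cell variants in bulk, DEL/INS ratios per category and their
cohort-to-cohort fold, the heterozygous fraction of bulk-only variants
(the allelic-dropout signature: dropout hits one allele of a heterozygote,
so bulk-only variants should be enriched for 0/1 genotypes), a mosaic flag
(bulk VAF ≤ 0.35, low enough to separate subclonal events from germline
heterozygotes at VAF ≈ 0.5), and the joint histogram of bulk VAF against
single-cell occurrence. The occurrence denominator is the number of cells
*callable* at the locus, not all cells: with patchy amplification coverage
most loci are adequately covered in only a subset of cells, and dividing by
all cells would systematically understate occurrence.

## Transposon analysis

Variant sequences are assumed to be annotated by a RepeatMasker-style
masker; the package parses the `.out` format (both for reference
annotations and for per-variant sequence hits) and works from merged hit
intervals.

* A variant **contains** a family when ≥ 1 bp of it is masked by that
  family; the **dominant** family has the largest merged covered fraction
  (ties break lexicographically and are flagged).
* An insertion's **Alu subfamily group** (AluY / AluS / AluJ, by name
  prefix) is assigned only when a single Alu element covers more than 80%
  of the insertion — fragmented or composite insertions are `none`.
* A masked element is **full-length** when it reaches 90% of its family
  consensus length (Alu ≈ 300 bp, L1 ≈ 6,000 bp). With read-length-limited
  data, L1 recoveries are expected to fail this test while Alu copies pass.
* A deletion is **NAHR-consistent** when its two breakpoints fall on two
  *distinct* reference elements of the same family — the signature of
  non-allelic homologous recombination between repeat copies, which
  deletes the intervening sequence. Elements are expanded by a 50 bp
  breakpoint window to absorb caller imprecision. Matching is at family
  granularity (`SINE/Alu`, `LINE/L1`), not subfamily: recombination
  between, say, an AluSc and an AluSg copy is exactly the event of
  interest. A single element spanning the whole deletion never counts.

One design point deserves emphasis: the NAHR *verdict* is decided over all
candidate element pairs at the two breakpoints, not by first committing to
one element per breakpoint. When a breakpoint sits in a window overlapping
elements of several families, committing early can miss a valid
same-family pair that uses the runner-up element; deciding over pairs makes
the classifier provably equivalent to brute-force pair enumeration, which
the test suite asserts on randomized instances. The
largest-interior-overlap / smallest-divergence / leftmost rule is used only
to pick the representative pair that is reported.

Insertion-site preference is measured as the fraction of family-X
insertions whose insertion point lies inside a reference element of family
X, compared with the genomic fraction covered by that family (defaults:
11% SINE/Alu, 17% LINE/L1). The fold of observed over genomic fraction is
the enrichment; no strand or orientation requirement is imposed (none is
established for these events).

## Permutation statistics

The test statistic is the fraction of query intervals overlapping a feature
set (TE elements of one family, or exons). The null is built by re-placing
the intervals uniformly over the mappable (non-gap) genome with lengths
preserved, intra-set overlaps permitted and feature intervals not excluded
— the defaults of the standard genome-shuffling tool. The primary p-value
is the normal approximation on the permutation null
(`z = (obs − mean)/SD`), one-sided *greater* for TE association and *less*
for exon depletion; significance is `p ≤ 0.05`, with no multiple-testing
correction (raw p-values are reported and flagged, which is the convention
this analysis family uses; correcting across families/cells is left to the
caller).

The add-one-corrected empirical permutation p-value is always reported
alongside. This matters: on this discrete, right-skewed statistic the
normal approximation runs mildly hot at desk problem sizes — with 50
intervals and 1,000 permutations we measure a type-I error of ≈ 0.09–0.10
at α = 0.05 across independent seed sets, while the empirical p is
calibrated (≈ 0.04). The package keeps the normal z as the primary measure
for fidelity to the Z-test formulation, asserts *calibration* on the
empirical p in its test suite, and recommends the empirical p whenever the
interval set is small. Degenerate nulls (SD = 0, e.g. an empty feature set)
yield p of exactly 0 or 1 with an explicit flag rather than a NaN.

The permutation loop avoids per-iteration object construction: features are
reduced once, placements are drawn vectorised, and overlap is tested with a
sorted-boundary search. 10,000 permutations (the conventional production
setting, and the package default in `stats_config()`) complete in seconds;
the orchestrated pipeline defaults to 1,000 to keep full runs fast, and the
calibration experiments in the tests use 1,000 permutations × 200
repetitions.

## The synthetic generator

`sim_config()` describes one six-cell experiment on a 10 Mbp single-contig
genome. The defaults are the study conditions the analysis assumes:

* **TE annotation** — non-overlapping elements covering 11% (SINE/Alu,
  ~300 bp each, subfamilies drawn from AluY/AluS/AluJ groups) and 17%
  (LINE/L1, 500–6,000 bp) of the mappable genome, the human genome-wide
  densities.
* **Events** — 200 germline SVs with a DEL:INS composition of 0.75 (the
  genome-wide bulk ratio) and ⅔ heterozygous; 20 mosaic NAHR deletions
  whose breakpoints are placed *inside* two distinct same-family elements;
  200 mosaic TE insertions carrying a consensus-derived sequence with 2%
  substitution noise (so masker-style hits are unambiguous), landing inside
  a same-family reference element with probability
  `clamp(bias × density, 0, 1)` and uniformly *outside* same-family
  elements otherwise — the exclusion keeps the realized landing fraction
  exactly `bias × density`, so the planted bias is recoverable by a
  binomial check. The default bias of 3.26 is the mean fold-enrichment
  reported for brain single-cell TE insertions.
* **Rendering** — bulk coverage ≈ 50×; per-cell coverage as alternating
  geometric runs (mean 20 kb) with ≈ 50% covered at a mean of 4× —
  a zero-inflated model chosen to reproduce patchy amplification breadth,
  not the amplification mechanism itself. The expected bulk VAF of a
  mosaic event is carriers/(2 × n_cells), perturbed by binomial sampling
  at the local depth; truth variants drawn to zero bulk support are lost
  and counted. In a cell, a carried variant at a covered locus always
  yields at least one supporting read (the allele is present in the
  amplified template), heterozygous events are additionally lost with the
  dropout probability (default 0.2), and single-cell breakpoints are
  jittered by ±10 bp. Chimera artifacts (default expectation 10 per cell)
  are emitted directly as INV/DUP or low-support DEL/INS call records —
  the package operates at callset level by design, so artifacts are
  modelled where the filters see them, not at read level. Noise SNVs are
  C>T-biased (default 49.8%).

What the generator does *not* emulate: read-level chimera structure (and
hence split-alignment-based filtering), reference-genome sequence context,
segmental duplications and satellite repeats, caller-specific genotyping
errors, and truly single-cell somatic events absent from bulk (single-cell-
only calls arise here from artifacts and filtering, not from planted
biology). Passing tests therefore demonstrate that the analysis recovers
planted structure under the assumed noise model — not that real brains
behave like the model.

## Numerical and determinism choices

All internal coordinates are 0-based half-open; the 1-based conventions of
VCF and RepeatMasker `.out` are applied only at file boundaries, and both
conversions are involutions asserted by tests. Every stochastic function
takes an explicit seed and restores the caller's RNG state; the pipeline
fans a single global seed out to per-stage seeds at fixed offsets, so any
stage can be reproduced in isolation and identical configurations produce
byte-identical run directories. Writers emit fixed column order and sorted
row order for the same reason. Tie-breaks (merging, matching, NAHR
representative election, dominant family) are all total orders, stated in
the function documentation.

Problem sizes in the shipped tests — a 10 Mbp genome for parameter
recovery, 2 Mbp for pipeline exercises, 200 × 1,000 permutations for
calibration — were chosen as the smallest sizes at which the binomial and
calibration bands are meaningfully tight; all complete in about a minute
and a half on one core.

## Known limitations

* BND records are parsed and counted but excluded with INV/DUP by default;
  no breakend-graph reasoning is attempted.
* Genotypes are taken from the input callsets; there is no cross-sample
  re-genotyping, so a variant genotyped inconsistently across cells merges
  on geometry alone.
* The mosaic VAF threshold (0.35) is a pragmatic cut, not a mixture-model
  estimate; it is exposed in configuration.
* Population-variant removal is list-based matching against a supplied SV
  list, not a population-index query.
* With very dense TE annotations the NAHR background rate (random
  deletions hitting same-family pairs by chance) grows; the test suite
  measures it on the default fixture rather than assuming it negligible.
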