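---
title: "Auditing a genome assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a genome assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtforge)
```

numtforge audits a finished long-read genome assembly along four axes:
nuclear mitochondrial DNA (NUMT) content, read-depth copy number, scaffold
integrity, and structural-variant (SV) reliability. This vignette explains
the underlying models, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the places where we made a design
call that another implementation might make differently.

## Coordinates

Internally everything is 0-based half-open; conversion to and from 1-based
inclusive formats (blast6, BUSCO tables, VCF) happens only in the parsers
and writers. A single internal convention eliminates off-by-one drift in
interval arithmetic, and the parser tests assert the converters are inverse
on their domains.

## NUMT discovery

A mitochondrial genome is circular, so an insertion into the nucleus can
cover the (arbitrary) origin of the reference unit. Searching with a
*doubled* query — the unit concatenated with itself — lets a single local
alignment represent any contiguous insertion up to one full unit long.
`wrap_to_unit()` maps doubled-query coordinates back to `[0, L)`, splitting
origin-crossing intervals into a suffix + prefix pair; total length is
conserved by construction.

The doubling also creates a systematic artefact: every alignment that fits
entirely inside one unit appears twice, offset by `L`. `compress_unique()`
removes it as a side effect of its main job — reducing a redundant hit table
to disjoint genomic intervals. Hits are ranked (bitscore desc, subject
length desc, then subject id/start asc for determinism) and each is trimmed
on the genomic side against everything already accepted; the query interval
is trimmed proportionally. A duplicate occupies exactly the genomic bases of
its twin, so it vanishes. The result provably equals a per-base
"best-scoring hit wins" rule, and a brute-force per-base oracle checks that
equivalence over hundreds of random instances in the test suite.

Parameters:

* `max_evalue = 1e-4` — the homology-search significance cutoff (strictly
  less than).
* `min_frag = 25` bp — trimming residue below this is discarded. The
  smallest real NUMT fragment we target is 34 bp, so 25 bp keeps every
  fragment of scientific interest while suppressing 1–2 bp slivers.
* `merge_gap = 8000` bp — fragments on one scaffold whose genomic gap is at
  most this merge into blocks, transitively, regardless of strand or
  mitochondrial order. The merge is deliberately strand- and
  mt-order-agnostic: a decayed insertion is often shredded into re-arranged
  pieces that still represent one insertion event. Blocks never span
  scaffolds because genomic distance is undefined across them. Both the
  block span and the summed member length are reported, since "block size"
  is ambiguous between the two.

Spanning-read support (`count_spanning_reads()`) counts reads whose
alignment covers a fragment plus a flank on both sides, at flanks of 0,
100, 1000 and 5000 bp. Flanks are truncated at scaffold boundaries: a
fragment 50 bp from a scaffold end can still collect 5 kb-flank support
from a read reaching the end. The alternative — declaring such flanks
unsatisfiable — would systematically zero out support for telomere-adjacent
fragments, which is the wrong default for an audit whose question is "is
this insertion real?". Counts are non-increasing in the flank, a property
the tests assert.

`classify_mt_reads()` supports mitochondrial assembly hygiene: a read is
`pure_complete` when ≥ 99% of its length maps to the mtDNA *and* it covers
≥ 99% of the unit — the selection rule that avoids seeding a mitochondrial
assembly with NUMT-contaminated reads.

## Read-depth copy number

The single-copy baseline `X_SC` is the mode of the pooled integer per-base
depth histogram over BUSCO single-copy Complete genes, excluding assembly
gaps and any excluded sequences (for male samples, the X chromosome is the
canonical exclusion: its haploid depth would drag the baseline down; the
implementation generalises this to an arbitrary exclude-list, empty by
default). Copy number of a region is `N_reg = X_reg / X_SC` with `X_reg`
the mean non-gap depth — exactly linear in depth, so scaling every depth by
a constant leaves all estimates unchanged (tested).

Numerical choices:

* The mode is computed at integer resolution (depths are read counts), and
  a tied mode breaks toward the **lower** depth — the conservative
  direction for copy-number calls (it inflates rather than hides putative
  duplications).
* The modal estimator needs a few hundred kilobases of pooled gene
  territory to stabilise. For an exactly-integer Poisson rate λ the
  distribution has a *dual* mode at λ−1 and λ (P(λ−1) = P(λ)), so with the
  low tie-break the fitted baseline may land one read below the rate; the
  bias is bounded by λ/(λ−1) (3.4% at λ = 30) and real sequencing depth,
  which is overdispersed, does not sit on this knife edge. The null
  calibration in our tests therefore uses a non-integer rate (30.2), where
  the mode is unique; the copy-number recovery tests keep λ = 30 and
  tolerate either mode within their 5% band.
* Region uncertainty is genuinely under-determined by a modal baseline, so
  two views are reported side by side rather than collapsed: a
  coefficient-of-variation scaling `se = (sd_cn / mean_cn) × N_reg` from
  the per-gene BUSCO copy-number dispersion, and the BUSCO-mean 95% CI
  half-width `1.96 × sd_cn / √n` as the baseline's own calibration.

Gene-family totals (`gene_family_cn()`) weight each genomic hit's `N_reg`
by the fraction of the family query that hit covers, then sum — so two
full-length assembled copies at 97.5x over a 34x baseline give
2 × 97.5 / 34 ≈ 5.74 total copies. Overlapping hits are collapsed first
(merged span, maximum member coverage) so no genomic base is counted twice.
A single full-coverage hit reduces exactly to `region_cn()`. The
depth-ratio cross-check (`short_read_ratio_cn()`) divides summed per-copy
mean depth by the genome-wide mean — the estimator of choice when only
short-read data and a gene annotation are available. `filter_reads_by_length()`
plus `depth_from_reads()` support re-running any of this on reads ≥ 5 kb or
≥ 10 kb, damping repeat-induced depth fluctuation.

Gene coverage binning (`bin_gene_coverage()`) follows the reporting
convention of assembly-vs-assembly audits: in assembly mode values round to
the nearest integer (with exact 0 as Missing and (0, 0.5) as Partial); in
long-read mode to the nearest 0.5 (anything in (0, 0.5) is 0.5n), capped at
2.5n+. Bin midpoints round half **up** — a fixed, documented tie rule; with
continuous depth data exact midpoints are measure-zero, so the choice is
about determinism, not results.

## Scaffold tidying

Depth-bin thresholds default to `round(c(0.23, 0.71, 1.94) * X_SC)` — the
multipliers that reproduce the 8x/25x/68x cutoffs used in practice for a
35x single-copy genome — and are fully overridable; the formula is a
convenience back-derivation, not a claim about how those cutoffs were
originally chosen. Classification precedence is fixed:

1. median non-gap coverage < 3 → low-coverage filter;
2. ≥ 80% low+haploid bases and ≥ 95% self-mapped → haplotig;
3. ≥ 80% low bases → low-coverage artefact;
4. < 20% diploid and ≥ 50% high bases → probable collapsed repeat;
5. diploid strictly the largest bin and > 50% self-mapped → repeat
   annotation;
6. keep.

Rules 1–3 are removals, 4–5 annotations on retained scaffolds. "Dominant
diploid coverage" is operationalised as *strictly largest of the four
bins* — the simplest total definition; a threshold-based notion (e.g.
≥ 50% diploid) would leave inputs unclassified. Removal iterates to a
fixpoint (default cap 10 rounds) with self-mapping recomputed against
survivors each round, because a haplotig can lose its self-map support when
its partner is itself removed. Every rating carries the rule id and the
round number, so a curator can replay the decision path.

## SV consensus

No published criterion pins down what "intersection of two platforms'
calls" means numerically, so the matcher exposes the standard SV-merging
parameters and defaults them to common practice: reciprocal overlap ≥ 0.5
for deletions/inversions/duplications, breakpoint distance ≤ 1000 bp plus
size ratio ≥ 0.5 for insertions. Matching is greedy-best (largest
reciprocal overlap, or smallest distance, ties by position), injective in
both directions, and type-strict; the consensus count is symmetric in the
two inputs. Length filtering is strict (`> 100` bp) and always drops
breakends, which carry no length. The same matcher yields cross-sample
Venn counts; gene/exon annotation counts ≥ 1 bp interval intersections, so
an insertion breakpoint inside an intron hits the gene but no exon.

`relative_mapping()` centres each sample's percent-mapped across the
references on the sample's own mean — removing per-sample mapping-rate
level so references can be compared; rows sum to zero by construction.
`annotation_qc()` marks reciprocal best hits as predicted orthologues and
reports predicted/reference protein length ratios.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is built
around: a 16.7 kb circular mitochondrial unit; eight planted NUMTs with
lengths log-uniform on 34–6580 bp (the span of real fragment catalogues),
alternating strands, at least one origin-spanning; inter-NUMT gaps drawn so
some pairs fall under and some over the 8 kb merge distance; a two-copy
tandem gene array whose underlying individual carries six copies (depth
multiplier 3, the amylase situation); planted copy-number regions at 2, 3
and 6; two half-depth haplotig scaffolds; per-base depth Poisson(30 × CN);
10 kb reads at 30x placed uniformly; and ~66 planted SVs per run with
per-platform breakpoint jitter (sd 20 bp) and independent dropout. Scaffold
length (120 kb by default, 150 kb in the wider acceptance runs) is sized so
worst-case feature placement always fits — the generator errors rather than
silently truncating. Every generator is a pure function of (config, seed);
identical seeds give byte-identical files.

What it deliberately does **not** emulate: base-calling error and alignment
noise (hits are emitted at truth coordinates; an aligner's fuzziness is out
of scope), depth autocorrelation and GC/mappability waves (depth is
independent Poisson per base), read sequences (alignment intervals
suffice), and repeat-induced mismapping. Passing the recovery tests
therefore demonstrates that the *algorithms* are correct on their stated
inputs — exact compression, merging, wrapping, estimation — not that any
upstream aligner or caller is well-behaved on hard genomes. The
spanning-read closed form (binomial with
`p = (read_len − width + 1)/(scaffold_len − read_len + 1)`) and the
two-platform consensus expectation `(1 − fn_rate)²` give the tests
independent analytical oracles.

Problem sizes in the shipped tests — 3–4 scaffolds of 120–150 kb, ~350
tiled single-copy genes, 66 planted SVs, 200 random compression
instances — were chosen as the smallest scales at which the statistical
checks have clear expectations (e.g. ≥ 200 kb pooled gene bases for a
stable depth mode, binomial intervals that are informative but not
razor-thin).

## Known limitations

* The greedy compression's exact tie-breaking between equal-scoring hits is
  our own fixed convention; other unique-hit reducers may split ties
  differently (the per-base winner, and hence the fragment set, is
  identical whenever scores differ).
* Copy-number uncertainty inherits the ambiguity of a modal baseline; both
  reported dispersion views assume BUSCO-gene copy-number scatter transfers
  multiplicatively to arbitrary regions.
* The SV matcher handles two call sets; multi-set merging graphs (three or
  more platforms/samples jointly) are out of scope, as are SV calling and
  genotyping themselves.
* Depth ingestion is text-based (bedGraph / per-base TSV); pileup from BAM
  is expected to happen upstream, keeping the algorithmic core free of
  alignment-tool dependencies.
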