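---
title: "Methods and design of the drsage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the drsage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

drsage packages the downstream computations of a long-read (nanopore
direct RNA sequencing, DRS) aging transcriptome study: interval-set
derivation from a genome annotation, full-length read filtering, splice
junction fidelity, isoform novelty classification, poly(A) tail
analytics, and replicate-consensus calling of A-to-I (inosine) and
pseudouridine sites. This vignette explains each method, the tunable
parameters, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Coordinates and containers

All internal coordinates are 0-based half-open (`start` inclusive,
`end` exclusive), the BED convention, which makes interval lengths
`end - start` and set arithmetic unambiguous. File readers convert at
the boundary: GFF3 and SAF are 1-based inclusive, STAR SJ.out.tab
intron coordinates likewise. Interval tables are plain data frames;
union/complement/overlap operations are delegated to IRanges behind
that surface. The annotation database (`annotation_db`) groups
transcripts under genes with exon and CDS tables, chromosome sizes from
the FASTA, and the genome itself for sequence-dependent steps.

## Stringent introns and intergenic regions

A *stringent intron* is any inter-exon region of any transcript minus
every annotated exon of every gene — all biotypes, both strands. The
strand-blind, all-biotype subtraction is deliberate: the point of the
set is to measure reads in sequence that is *never* exonic, so even an
exon of an antisense gene disqualifies a region. *Stringent intergenic*
regions are the complement of transcript spans minus exons. Chromosome
termini (before the first and after the last transcript) are excluded
by default (`include_termini = FALSE`) because regions "between"
transcripts is the natural reading for a survey of intergenic
transcription; the flag restores them. By construction the exon union,
stringent introns, and terminus-inclusive intergenic set tile each
chromosome exactly once, and the tests assert this per base.

The median gene span (max transcript end − min transcript start per
gene) uses the midpoint rule for even counts with half-away-from-zero
rounding, so the reference value is an integer (1956 nt for the worm
annotation this pipeline was designed around).

## Full-length reads and feature assignment

A DRS read is *full-length* when it is a primary alignment, its
strand-aware 5′-most aligned position (block start on `+`, block end on
`-`) lies within `tss_window` of an annotated transcript 5′ end on the
same chromosome and strand, and its poly(A) caller QC tag is PASS. The
default `tss_window` of 10 nt reflects the jitter of nanopore 5′ ends
around true starts at typical alignment accuracy; it is a parameter
because protocols differ. The filter reports per-stage removal counts
that sum to the input (asserted in tests).

Reads are assigned to features when at least `frac_overlap` of their
aligned bases fall in the feature (0.5 for the intron/intergenic
survey, 0.8 for gene-level counting, mirroring common featureCounts
settings); intervals sharing a `feature_id` act as one meta-feature, so
a spliced read accumulates overlap across the exon union. Ambiguous
equal-overlap ties stay unassigned rather than being double-counted,
keeping category percentages additive to 100%.

The metagene profile rescales per-gene span coverage onto `n_bins`
equal bins 5′→3′ (strand-aware) and normalises each covered gene by the
mean of its own bin values, so each gene contributes bins summing to
`n_bins` and highly expressed genes do not dominate. Genes with zero
coverage are excluded. Gene span, not spliced transcript, is used: the
profile is meant to reveal 5′/3′ coverage bias from truncation, and
intron gaps affect all positions of a gene equally under the per-gene
normalisation.

## Splice junction fidelity

Observed junctions (collapsed, with unique-read support) are annotated
iff their intron coordinates exactly match the annotation-derived
junction database. Strand is ignored in matching by default because
collapsed tables carry undefined strands (STAR code 0); a flag enforces
it. The fidelity statistic is the percentage of junction-spanning
unique reads on unannotated junctions. For an unannotated junction the
mismatch label names the end that deviates: sharing an annotated donor
but not an acceptor means the 3′ end moved (`three_prime_only`), and
vice versa; `both` means neither end is annotated. Junctions whose
donor and acceptor each exist in the annotation but whose pairing is
new (exon skipping) get the fourth label `novel_combination`, keeping
the labels a partition.

Group comparisons of percentages use a probit transform (inverse
standard-normal CDF of the proportion) followed by a two-sided pooled
(Student) *t*-test; Welch is available via `var_equal = FALSE`. The
pooled test is the default because the upstream analyses this package
mirrors report a plain "t-test, two-sided". Proportions of exactly 0
or 1 are clamped to `1/(2n)` (or `1 - 1/(2n)`) with `n` the group's
read total when known, else `1e-6`, with a warning — the transform is
otherwise infinite.

## Isoform classification

Isoform identity is the exact ordered intron chain; terminal exon ends
are free. This matches collapse-style isoform calling, where terminal
ends are noisy but junctions are corrected. A call set is filtered to
isoforms with ≥ 20 reads summed over all samples *and* ≥ 10% of the
summed reads of their gene (both inclusive; unassigned isoforms pass
the fraction rule vacuously). Filtering is idempotent: removing
isoforms only raises the survivors' within-gene shares.

Productivity is a simplified ORF rule: build the spliced sequence, use
the assigned gene's annotated start codon when it maps into the
isoform (the 5′-most mappable one across the gene's transcripts), else
the first AUG, and call the isoform productive when an in-frame stop
codon completes before the transcript end. No NMD heuristics (e.g. the
50-nt rule) are applied — a premature stop is still "productive" here,
a recorded divergence from the upstream tool's richer labels.

The 3′UTR runs from the base after the stop codon to the isoform 3′
end; its genomic end coordinate is compared against the same gene's
annotated 3′UTR ends with an inclusive 10 nt window (an 11 nt offset is
novel, 10 nt is known). Gene scoping is a design choice — comparing
against all genes' ends would let a neighbouring gene mask a genuinely
novel end; a flag widens the scope. A fusion candidate is a
splice-novel isoform with at least one intron strictly longer than the
median gene span (1956 nt by default) whose exons overlap annotated
exons of two or more genes by ≥ 1 nt. The four-way report applies the
priority fusion > novel > novel-3′UTR > known, making the categories
exclusive.

## Poly(A) tails

Only PASS-tagged tail estimates are used; lengths are real-valued nt as
emitted by the caller. Group distributions pool reads (not per-sample
medians) — with three replicates per group, per-sample medians would be
too coarse for the per-isoform deltas. Abundance bins use type-7
quantiles of normalized isoform expression with boundary values going
to the lower bin; when the two cut points coincide the spread is
degenerate and everything at the cut is binned medium with a warning.
Per-isoform |Δmedian| classes (<10, 10–20 closed, >20 nt) require at
least 5 PASS reads per group per isoform — the smallest count for which
a median is at all stable; this threshold is a package default, exposed
as a parameter. The KS comparison is the classical two-sample statistic
with the asymptotic p-value.

## Modification-site consensus and consequences

An A-to-I site passes in an age group iff all of `n_required` (= 3)
replicates call it with edited fraction ≥ 0.05 *and* confidence ≥ 0.99;
a pseudouridine site needs probability ≥ 0.90 in all three replicates
(the pseudouridine caller emits no per-site fraction, so only the
probability is thresholded). All thresholds are inclusive, and the
passing set is monotone under tightening (tested). Feature assignment
uses the fixed priority CDS > 3′UTR > 5′UTR > noncoding exon > intron
among same-strand transcripts containing the position; this priority is
a design choice where several transcripts disagree. Sites contained
only by opposite-strand genes are labelled `antisense_intragenic` and
excluded from feature counts — the upstream analyses are silent on
antisense sites, and mixing them into sense-feature counts would be
misleading.

Recoding consequences substitute G at the edited position of the codon
(inosine is read as guanosine) in the representative CDS — the longest
CDS among containing transcripts — and compare translations under the
standard genetic code. Note that an A→G edit can never *create* a stop
codon (no stop differs from a sense codon by G→A at the edited
position), but it can destroy one (UGA→UGG) or retain one (UAA→UGA);
the class labels cover all five outcomes. The amino-acid property
classes used for "chemistry-changing" substitutions are the common
four-way scheme: nonpolar {A,V,L,I,P,M,F,W,G}, polar-uncharged
{S,T,C,Y,N,Q}, positive {K,R,H}, negative {D,E}.

Δediting between groups is measured in percentage points of the edited
fraction (`100 · (mean_old − mean_young)`), classified at a strict ±10
point threshold; a relative-change mode is available by flag since
"percent change" is ambiguous in prose. Repeat enrichment compares the
fraction of sites overlapping the repeat track to the repeat-covered
fraction of the genome with a one-sample two-sided normal-approximation
proportion test (exact binomial by flag) — a pragmatic choice where no
specific test is mandated. Tissue context is a per-gene z-score across
tissues, averaged over a gene set per tissue; zero-variance genes are
excluded with a warning.

## The synthetic-data generator

The generator is first-class, tested code: it emits every input the
pipeline ingests, in the exact file dialects, with a truth manifest
that covers every record. A single seed drives one root stream;
per-stage substreams are derived deterministically so identical
configurations are byte-identical.

The default configuration is a desk-scale worm-like study: 2
chromosomes × 200 kb, 60 non-overlapping genes (a third on the minus
strand; 20 with a second transcript sharing all introns but extending
the 3′ terminal exon by 120 nt, giving shared introns, shared TSSs and
two annotated 3′UTR ends per such gene; 6 noncoding), 20,000 reads at a
50% truncation rate, three young and three old samples, and ~20,000
poly(A) records. Gene spans are planted so the median is exactly
1956 nt — the reference median the fusion-intron rule quotes — which
lets the 1956 vs 1957 nt boundary be exercised at the real value. CDSs
are built from sense codons only (guaranteed AUG, planted stop, no
internal stop), with specific codons placed at known positions so every
realisable recoding class (synonymous, missense with and without a
property change, stop-lost, stop-retained) appears at a known site.

Planted structure and rationale:

- *Reads*: full-length reads start within ±5 nt of a TSS (inside the
  10 nt filter window) and are 95% PASS; truncated reads start ≥ 50 nt
  downstream (outside the window) — the 3′-biased coverage this creates
  is what the metagene profile is designed to detect. A few percent are
  flagged secondary/supplementary, and five reads sit on an unknown
  chromosome to exercise that counter.
- *Junctions*: per-sample tables are constructed, not sampled, so the
  unannotated read share is exactly the configured fraction
  (young 4.4/5.0/5.6%, old 7.4/8.0/8.6% — old higher, mirroring an
  age-related fidelity decline, with within-group spread so the probit
  t-test is well-defined). Shifted junctions avoid all annotated
  donor/acceptor coordinates so mismatch-end labels are unambiguous.
- *Isoforms*: read totals straddle both filters (19 vs 20 reads; a
  20/200 = 10% share kept vs a 21/221 = 9.5% share dropped), 3′ ends
  straddle the UTR window (+10 known vs ±11 and larger novel), and
  bridging introns straddle the fusion rule (exactly 1956 nt = novel vs
  2500 nt = fusion).
- *Tails*: per-isoform medians decrease with abundance rank (40 nt for
  the most abundant to 95 nt for the least), planting the
  abundance–tail anticorrelation. Old-group reads are the young
  multiset shifted by an exact per-isoform delta (3 nt baseline;
  planted 10, 12, 15, 20, 25, 30 and −15 nt covering every |Δ| class
  and both boundaries), so sample medians differ by exactly the planted
  shift and the truth manifest is exact rather than stochastic. The
  paired construction is a deliberate trade of distributional realism
  for exactness; the KS comparison still sees a genuine shift.
- *Edit sites*: fraction triples at exactly 0.05 and at 0.049,
  confidences at 0.99 and 0.989, probabilities at 0.90 and 0.89, sites
  missing from one replicate, and sites passing in only one age group;
  Δediting plants include an exact +10-point boundary (stable under the
  strict rule). The repeat track covers ~30% of the genome and each
  site's actual overlap is recorded as truth.

What the generator does **not** emulate: base-call or alignment errors
(blocks are exact transcript footprints), sequencing depth gradients,
biological covariance between stages (isoform counts, tails and edit
sites are planted independently), antisense transcription, overlapping
genes, trans-splicing, and the callers' score distributions (fractions
and confidences are planted values, not model outputs). Passing tests
therefore demonstrate that the *computations* are correct on inputs of
the right shape and scale — not that the upstream callers are accurate
on real signal, nor that real data would show these effect sizes.

## Numerical conventions and degenerate inputs

- Median: midpoint rule; gene-span median additionally rounds half away
  from zero to print an integer.
- Quantiles: type 7 (linear interpolation), ties to the lower bin.
- Zero junction-spanning reads, empty call tables, zero sites, or a
  gene set absent from the expression matrix are explicit errors, not
  silent zeros.
- Probit clamping as above; identical groups short-circuit to
  `t = 0, p = 1` (the pooled formula is 0/0 there).
- The boundary semantics are: filters inclusive (≥ 20 reads, ≥ 10%,
  ≥ 0.05, ≥ 0.99, ≥ 0.90, ≤ 10 nt UTR window), classifications strict
  (> 1956 nt intron, > 10 point Δediting), and the 10–20 nt tail class
  closed at both ends.

## Problem sizes

The shipped configuration (60 genes, 20,000 reads, 10,000 junction
reads per sample, ~20,000 tail records, 38 planted sites, 100-seed
interval-oracle sweeps, 10,000 random site-group consensus checks) was
chosen so the entire test suite and the end-to-end pipeline each finish
in about a minute on one CPU while still exercising every rule and
boundary; the generator scales by configuration if larger cohorts are
wanted.

## Known limitations

- Productivity ignores NMD and selects start codons greedily; unusual
  5′ leaders can mislabel isoforms.
- Junction matching is exact-coordinate; small alignment wobble must be
  corrected upstream (as collapse/correct tools do).
- The enrichment test treats sites as independent; clustered editing
  would inflate significance.
- `attribute_mismatch_end` labels relative to the annotation only; it
  cannot distinguish novel donors from acceptors on unstranded
  junctions beyond coordinate identity.
- Single-nucleotide site positions are assumed; multi-nucleotide or
  ambiguous calls are out of scope.
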