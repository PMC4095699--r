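---
title: "Methods: ploidy-adaptive copy-number calling, recurrence, and the mutation spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy-adaptive copy-number calling, recurrence, and the mutation spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impcna)
```

# The model

`impcna` analyses tumour genomes represented as allele-specific segmented
copy-number profiles: per segment a chromosome interval, an inferred
integer total copy number $t$ and an integer minor-allele copy number $m$
with $m \le t - m$. Profiles of this kind are the output of
allele-specific SNP-array segmentation pipelines; the package deliberately
takes them as given — raw-intensity normalisation and the pattern-based
ploidy/allelic-content inference that produces them are out of scope.
Copy numbers must be integers: the upstream inference reports integers,
and silently rounding fractional input would hide subclonality or noise
the model cannot represent, so fractional values are rejected.

## Ploidy and alteration states

Because the same absolute copy number means different things on different
backgrounds, alteration cutoffs are **ploidy-adaptive**:

| ploidy class     | LOSS       | NEUTRAL | GAIN                  | AMP       |
|------------------|-----------|---------|------------------------|-----------|
| near-diploid     | $t \le 1$ | 2       | $3 \le t < 6$          | $t \ge 6$ |
| near-tetraploid  | $t \le 2$ | 3–5     | $6 \le t < 8$          | $t \ge 8$ |

The full ploidy inference is replaced here by a deliberately simple
classifier: near-tetraploid iff the length-weighted (bp) mean total copy
number is $\ge 3.0$. The tie at exactly 3.0 is resolved toward
near-tetraploid — a documented convention, since the boundary case is
genuinely ambiguous and the upstream method resolves it internally from
information we do not model. A ploidy class already declared on a profile
(for example, carried in from upstream software) always wins over
inference. The X chromosome is treated like an autosome against the same
cutoffs (the analysed cohorts are breast carcinomas); an `exclude_x` flag
is available because hemizygous X in other settings would bias LOSS
frequencies.

States are projected from segments onto the probes of a `snp_map`; the
map is the unit in which all run-length rules are counted. Probes not
covered by any segment become NEUTRAL with a warning rather than an
error, so sparse real SEG files remain usable; an error would be wrong
because segment gaps are routine at centromeres.

LOH is called where $m = 0$ and $t \ge 1$, which covers both hemizygous
deletion ($t=1$) and copy-neutral LOH ($t=2, m=0$). $t = 0$ is a
homozygous deletion and is flagged separately — calling it LOH would
conflate absence of one allele with absence of the locus.

Breakpoints are within-chromosome changes between adjacent segments in
total copy number *or* allelic composition (the $(t, m)$ pair);
chromosome boundaries never count. Two adjacent segments with identical
$(t, m)$ (a split introduced by a file writer) contribute nothing, which
makes the count equal to (maximal constant runs) − (chromosomes present),
the identity the property tests exploit.

## Recurrent minimal regions

A region is recurrent for an event state when at least `min_snps = 25`
consecutive probes each exceed a cohort frequency of `min_freq = 0.20`
**strictly**. Both constants are the field's published convention for
amplification recurrence on high-density arrays; a separate
40%-frequency preset is conventionally used for "most frequent" gains
and losses, and both knobs are plain arguments. Key reading choices:

- "same copy number status" means the same discrete state after
  cutoff-based calling, not the same integer copy number — the rule is
  applied downstream of calling, so two samples at $t=6$ and $t=9$ on a
  near-diploid background both carry AMP;
- the run must be maximal: extending one probe in either direction
  breaks a constraint. Reported frequency is the minimum over the run
  (the conservative summary — every probe in the region is at or above
  it);
- region *carriers* are the samples altered across the **whole** run.
  This is the strict reading; a sample altered over half the region is
  not a carrier. It makes carriers directly usable as input to
  `minimal_common_region()`, whose job is to intersect one interval per
  carrier.

Group contrasts (`compare_group_frequencies`) use a frequency-difference
rule, $|f_A - f_B| >$ `min_diff` over a qualifying run, because the
underlying comparison between histology groups is reported without a
significance test; inventing one by default would misrepresent the
method. An optional per-region two-sided Fisher exact test with
Benjamini–Hochberg correction can be switched on.

## Genomic subsets

Probe-level state vectors are encoded LOSS $-1$, NEUTRAL $0$, GAIN $+1$,
AMP $+2$ and clustered with Ward's minimum-variance method on Euclidean
distances (`hclust(method = "ward.D2")`, the variant that operates on
unsquared Euclidean distances as Ward's criterion requires). The
upstream software's exact input encoding is unpublished; this ordinal
encoding is a documented choice, configurable per call, and no further
scaling is applied because the states already share one scale. `k = 2`
is the default cut (two named archetypes) but the full tree is returned
and a height-based cut is supported, because in practice a minority of
samples fall outside both named clusters.

## The somatic SNV pipeline

The filter is the five-criterion false-positive screen:
Fisher exact $P < 0.05$, coverage $\ge 10\times$, base quality
$\ge 20$, VAF $\ge 20\%$, high-quality alt reads $\ge 4$. Boundary
semantics are exactly as printed: the count/fraction thresholds are
inclusive, the $P$ threshold exclusive. Zero coverage fails the coverage
and VAF criteria with named flags instead of raising a division error,
because a screening filter that crashes on an empty site is useless in
batch mode.

The Fisher test is authored here rather than delegated: a one-sided
exact hypergeometric tail for tumour-enriched alternate reads (the
somatic-calling convention; the direction is not stated alongside the
threshold, so the convention is adopted and a two-sided variant is
available by flag). The observed table's own mass is included in the
tail. One subtlety found while deriving test oracles: a perfectly
balanced table such as (5,5)/(5,5) has one-sided $p \approx 0.672$, not
1 — $p = 1$ arises only when the tumour has zero alt reads. The unit and
acceptance suites pin the implementation to an independent
`choose()`-based enumeration over all margins up to total 60.

Prioritisation (drop known variants; keep missense only at
PolyPhen-2 $> 0.5$ **and** GERP $> 3$, deciding on whichever score is
present when only one is) is exposed as an *advisory* flag rather than a
hard drop in reporting tools: the validated mutation tables this
pipeline reproduces retain several low-score missense variants, so a
hard drop would be unfaithful to actual practice.

Effect classification runs the raw codon pair through the standard
genetic code (`Biostrings::GENETIC_CODE`); substitution classification
is positional (exactly one differing base; A↔G / C↔T transitions,
everything else a transversion; `ins`/`del` descriptors are indels).
Deleteriousness is PolyPhen-2 $> 0.5$ **or** GERP $> 4$: the OR is
forced by the data model, in which each variant record carries exactly
one of the two scores; records with neither score stay in the
denominator (they are variants, just unscorable) and out of the
numerator. GERP bands are $<3$ benign, 3–5 possibly damaging
(inclusive), $>5$ probably damaging — note a GERP of 4.05 is therefore
*deleterious* yet only *possibly damaging*; the two rules serve
different purposes and are kept separate.

Summary percentages are rounded half away from zero to whole percent
(22/36 → 61%), matching how such tables are printed; banker's rounding
would give 62% for 5/8-type fractions and silently disagree. Per-gene
cohort percentages use denominator 50 — the full sequenced series — by
default even though per-assay denominators differ (45/39/43/51 across
sequencing technologies); the parameter is exposed for per-assay use.
RNA-level support counts `yes` over evaluable records, where evaluable
means determined (`yes` + `no_coverage`, excluding `nd`): a variant with
RNA-seq coverage but no variant reads is evidence of non-expression, not
missing data.

The packaged mutation table (`inst/extdata/impc_mutations.tsv`, 36
variants in 23 genes) is transcribed with its printed annotation columns
retained as `effect_printed` / `type_printed`; analysis columns are
*recomputed* from the nucleotide descriptors at read time, and a test
asserts the recomputation agrees with the printed columns row by row.
The file is checksummed (md5) and the reader refuses a tampered copy.

## Expression integration

The copy-number/expression gate is an exact Pearson correlation with the
two-sided $p$ from the $t$ transform on $n-2$ degrees of freedom,
significant iff $r > 0.4$ and $p \le 0.05$. The gate is deliberately
one-directional: dosage effects raise expression with copy number, and a
strong negative correlation is biologically a different finding. Zero
variance in either vector gives an indeterminate, non-significant result.

The underexpression rule is a two-sided Welch test ($P \le 0.05$)
combined with linear-scale fold change $\ge 1.5$, fold change oriented
reference-over-case so that the threshold means "at least 1.5-fold lower
in cases". Sidedness is not stated where the rule is printed; two-sided
is the conservative choice and does not change the conjunctive flag's
semantics. qPCR relative expression is plain ΔCt,
$2^{-(Ct_\text{target} - Ct_\text{ref})}$, assuming 100% efficiency —
the reported quantity is "relative value / TBP" with no calibrator
sample, so ΔΔCt would require data that does not exist.

# The synthetic cohort: a stated world

The generator exists so that every downstream stage has a ground truth.
It emulates, qualitatively, the two-archetype cohort structure:

- **Sawtooth/8/16**: whole-arm 8p loss, 8q gain, 16p loss, 16q gain;
- **Firestorm/Amplifier**: 17p loss plus focal amplicons at the
  recurrently amplified loci 8q22 (2 Mb), 17q22–q23.3 (5.2 Mb) and
  20q13.2 (1.9 Mb), at copy number 8 (near-diploid) / 10
  (near-tetraploid).

Defaults that define this world, chosen once:

- *Event probability 0.9 per event.* No quantitative per-event rates are
  published for the archetypes; 0.9 reproduces the intended qualitative
  contrast (near-deterministic archetype signatures with occasional
  misses) and is the value the clustering-recovery acceptance criterion
  presupposes ("event probabilities ≥ 0.9, disjoint territories").
- *Ploidy mix 50/50* near-diploid/near-tetraploid, reflecting that both
  backgrounds occur prominently in the cohorts being emulated.
- *Reduced genome*: 22 autosomes + X with 1,000 evenly spaced probes per
  chromosome over approximate GRCh37 lengths, so a full cohort
  simulates, calls and clusters in seconds. Real-density maps can be
  supplied as `snp_map` objects.
- *Segment-wise events with boundaries snapped to probe positions*, no
  probe-level noise: planted run boundaries are then exactly recoverable,
  which is what makes the planted-region recovery tests sharp
  (recovered iff carrier fraction $> 0.20$ and length $\ge 25$ probes).
- *Somatic VAF* $\sim$ Beta with mean 0.4 and concentration 30
  (shape 12, 18). Mean 0.4 reflects heterozygous somatic variants at
  the >70% tumour cellularity the emulated cohorts guarantee; the
  spread keeps most sites above the 20% VAF filter while still
  generating borderline cases. Tumour purity is modelled *only* through
  this VAF distribution — copy-number profiles are not contaminated with
  normal signal, since the emulated profiles are already
  purity-corrected upstream.
- *Depths* Poisson with mean 100 in tumour and normal; germline sites
  are heterozygous in both, somatic sites reach the normal only via a
  0.1% error rate.

What the generator does **not** emulate — and therefore what a green
test does not establish: probe-level intensity noise, wavy artefacts,
segmentation error, subclonal (non-integer) copy states, overlapping or
nested events, normal-cell contamination of profiles, and linkage
between copy-number archetype and mutation burden. Tests green against
this world certify the *rules* (calling, run-length scanning,
clustering, filtering) and their boundary behaviour, not robustness to
array noise.

# Numerical and interface choices

- **Coordinates.** All coordinates — on disk and in memory — are 1-based
  inclusive. An internal 0-based half-open convention was considered and
  rejected: the R/Bioconductor ecosystem (IRanges and everything above
  it) is 1-based inclusive, and a private convention would add a
  conversion layer with no observable benefit. File dialects are
  unchanged.
- **Determinism.** Every generator takes an explicit integer seed and
  identical seeds give bit-identical outputs; the CLI logs effective
  parameters and seeds so a logged run is reproducible byte for byte.
- **Ward tie-breaking.** `hclust` is deterministic for a given input
  order; on tie-free inputs the partition is order-invariant (tested).
- **Degenerate inputs.** Empty profiles, zero-coverage sites,
  zero-variance vectors, all-`nd` RNA status, and disjoint carrier
  intervals all return typed indeterminate results or precise errors —
  never silent NaNs.
- **Percent rounding** is half-away-from-zero (see above), applied only
  at the reporting boundary; internal fractions stay exact.

# Known limitations

- The ploidy classifier is a one-statistic stand-in; genomes whose
  length-weighted mean copy number sits near 3 from a mix of high-level
  gains on a diploid background can be misclassified, shifting their
  cutoffs.
- Recurrence scanning is run-length based and does not model
  significance (no GISTIC-style background); arm-level versus focal
  classification is purely length-based.
- The Fisher filter assumes independent reads; duplicated or strand
  -biased evidence is not modelled (high-quality alt-read count is the
  only proxy).
- The CLI's `simulate` writes a fixed two-archetype design; bespoke
  mixes are an API-level feature.
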