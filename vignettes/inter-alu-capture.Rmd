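---
title: "Predicting inter-Alu PCR capture and post-processing paired variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting inter-Alu PCR capture and post-processing paired variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(interAlu)
  library(GenomicRanges)
})
```

## The method

Alu elements are ~300 bp primate-specific SINE retrotransposons present in
over a million copies in the human genome, with a mean spacing between
adjacent copies of roughly 2.4 kb. Inter-Alu PCR exploits this density:
primers matching the Alu consensus sequence anneal inside many copies at
once, and a PCR product forms wherever two binding sites face each other
within a product-size window. Sequencing those products yields a
genome-wide, Alu-anchored subset of the genome at a fraction of the cost of
whole-genome sequencing.

The orientation of each primer relative to the element decides which side
of the Alu its 3' extension leaves from:

* a **T-type** (tail-type) primer equals a window of the consensus in sense
  orientation; its extension runs through and beyond the poly-A tail;
* an **H-type** (head-type) primer is the reverse complement of a consensus
  window; its extension runs out of the element's 5' head.

A candidate amplicon is any pair of sites on one chromosome where the left
site extends rightward and the right site extends leftward, with an outer
span (including both primer footprints) inside a length window. Mixing H-
and T-type primers allows head-to-head, tail-to-tail and head-to-tail
products, which is what gives the assay its amplicon diversity. The union
of all candidate spans is the *capturable footprint* — the genome subset
the assay can in principle sequence.

Downstream, the package post-processes per-site variant calls from a paired
control/tumor comparison with a rule set driven by the **non-reference read
frequency** `f = nonref_depth / total_depth`:

* `f < 0.10` — homozygous reference; `0.10 <= f < 0.85` — heterozygous;
  `f >= 0.85` — homozygous non-reference; sites with total depth `< 10` are
  not analyzed further;
* **somatic SNV** — tumor heterozygous, control homozygous (reference *or*
  non-reference: the rule is read literally as "homozygous");
* **LOH** — control heterozygous, tumor homozygous;
* **novel** somatic SNVs — somatic minus LOH positions minus a known-SNP
  list;
* **hotspots** — fixed 5-Mb windows whose somatic SNV count strictly
  exceeds the mean plus twice the sample standard deviation of per-window
  counts.

## Primer naming and derivation

Convention names encode everything needed to derive the oligo from a
subfamily consensus: `AluY278T18` is the AluY tail-type primer of length 18
whose first paired consensus position is 278.

```{r primer}
reg <- syntheticConsensusRegistry()
aluPrimer("AluY278T18", registry = reg)
aluPrimer("AluY66H21", registry = reg)
```

The consensus registry is normally supplied by the user as a FASTA of
subfamily consensus sequences (`readConsensusFasta()`); published consensus
sequences are not redistributable here, so the packaged registry is a
synthetic Alu-like stand-in, built in code, that carries the published
primer windows at their stated offsets. Primer derivation is therefore
validated empirically: the derived `AluY278T18` and `AluY66H21` oligos
equal the published primer sequences. Legacy primers without a consensus
offset (e.g. `R12A/267`) are supported as explicit sequences with a
declared type and are never derived.

## A small end-to-end run

The simulator plants non-overlapping consensus copies on uniform random
background sequence; with divergence 0 the annotation is an exact truth
set.

```{r endtoend}
sim <- simulateGenome(seed = 11, chromLength = 100000, nAlus = 37,
                      divergence = 0)
primers <- lapply(c("AluY278T18", "AluY66H21", "AluSq263T16"),
                  aluPrimer, registry = reg)
sites <- findPrimerSiteSet(sim$genome, primers, maxMismatches = 0)
amps <- enumerateAmplicons(sites, minLen = 200, maxLen = 6000)
mergedFootprint(amps)$totalBp
meanGapLength(interAluGaps(mergeAluElements(sim$alus)))
```

Annotation-only mode (`predictSitesFromAnnotation()`) places convention
primers inside annotated elements by consensus offset, without any genome
sequence; on a zero-divergence simulation it agrees exactly with the
sequence scan, which the test suite asserts.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| amplicon length window | 200–6000 bp | fragments < 200 bp are removed during library construction; observed products reach ~6 kb |
| mismatch tolerance `k` | 0 (0 or 1 typical) | capture accounting is reported both for exact matches and one mismatch per primer |
| depth threshold | 10× | bases under 10× are excluded from all capture statistics and genotype calls |
| genotype boundaries | 0.10 / 0.85 | published non-reference-frequency thresholds, inclusive on the upper class |
| genic baseline | 40% | genome-wide gene content used for the enrichment excess |
| candidate-gene baseline | 26% | fraction of all genes on the candidate list |
| density window | 10 kb | per-chromosome coverage-density tracks |
| hotspot window | 5 Mb | somatic SNV hotspot rule |

The two baselines are configurable because they depend on gene-set
versions. Percentages are reported to one decimal, matching the style of
the published capture table.

## Numerical and design choices

* **Coordinates.** All in-memory intervals are `GRanges` (1-based closed);
  BED and BedGraph output is converted to 0-based half-open by
  `rtracklayer`, RepeatMasker `.out` input (1-based inclusive, `C` = minus
  strand) on read. VCF-style positions are 1-based.
* **Mismatch model.** Hamming distance only — substitutions, no indels or
  bulges; `N` bases in the genome count as mismatches so assembly gaps
  never produce phantom sites. All overlapping sites are reported; there is
  no greedy suppression, because the enumeration describes what is *in
  principle* capturable, not PCR competition kinetics.
* **Merging before gaps.** Overlapping or nested repeat annotations are
  merged (keeping the subfamily and strand of the longest constituent)
  before inter-Alu gaps are formed, so gaps are unique and non-negative.
  Gap length is the open space between element boundaries, not a
  midpoint-to-midpoint distance.
* **Amplicon span.** Outer coordinates, including both primer footprints —
  what a sequencer would read. Amplicons lying inside a single element are
  still enumerated; inter-Alu vs intra-Alu accounting happens in the
  capture statistics.
* **Annotation-mode family matching.** A convention primer is placed only
  in elements annotated with its own subfamily. Divergent copies of other
  subfamilies can bind a consensus primer in reality, but at unknowable
  mismatch cost without sequence, so the sequence scan is the authority
  whenever sequence is available.
* **Genotype boundaries.** Exactly the printed inequalities: `f = 0.10` is
  heterozygous, `f = 0.85` homozygous non-reference; total depth of zero is
  `UNCLASSIFIED`, not an error.
* **Hotspot statistic.** Sample (n−1) standard deviation over per-window
  counts; when a covered-region set is supplied the mean/sd are computed
  over covered windows only, since windows that are empty by design deflate
  the mean. The published figure legend also quotes an absolute "count
  > 4" phrasing that is inconsistent with its own mean + 2·sd = 5.3; the
  package implements the mean + 2·sd rule and offers `minCount` as an
  explicit absolute override rather than silently resolving the conflict.
* **Somatic definition.** "Control homozygous" includes homozygous
  non-reference, read literally; with the default simulation 10% of
  somatic sites have a hom-alt control.

## What the simulator does and does not emulate

`simulateGenome()` reproduces the *density and orientation structure* that
the capture prediction depends on: one ~300 bp element per ~2.7 kb
(matching human Alu density, hence a mean inter-Alu gap near 2.4 kb), a
subfamily mix dominated by AluS-aged copies (60% AluSq, 25% AluJo, 15%
AluY), uniform strands, and independent per-base substitution at a 10%
default divergence (real copies are ~15–20% divergent from each other,
i.e. roughly 8–10% from consensus). `simulatePairedCalls()` reproduces the
paired comparison's statistical structure: true allele fractions in
{0, 0.5, 1}, Poisson total depth (mean 67.4, the published average), and
binomial non-reference depths, with 274 somatic and 357 LOH sites and ~30%
of sites on the known-SNP list by default.

Not emulated: 5'-truncated and nested elements beyond an optional
truncation check, CpG-biased substitution, indel divergence, mappability
and GC biases in depth, allele-specific mapping artifacts, or tumor purity
below 100% (somatic sites are drawn at fraction 0.5). Passing tests
therefore demonstrate the correctness of the rules and the enumeration,
not the wet-lab performance of any primer set on real tissue.

## Problem sizes

The shipped checks run the site search against a brute-force Hamming
oracle on 10-kb simulated genomes at `k` of 0–2, the amplicon enumeration
against a quadratic all-pairs oracle on 30 sites, truth recovery on ~3,000
noise-free paired sites, heterozygote sensitivity on 10,000 binomial sites
at depth 30, and the end-to-end zero-divergence truth equality on a 100-kb
genome with 37 planted copies. Genome-scale totals (1.10 Gb of inter-Alu
gaps under 6 kb, ~14 Mb exact-match footprint) require the GRCh37
RepeatMasker annotation, which the user must supply locally
(`options(interAlu.rmsk = ...)`); the same code path then runs unchanged.

## Known limitations

* PCR competition, primer thermodynamics and amplification efficiency are
  out of scope; every convergent pair in the window counts equally.
* The packaged consensus registry is synthetic; genome-scale site search
  on real sequence should use a published consensus FASTA.
* LOH here is the read-frequency rule only; copy-number-based LOH calling
  is the territory of dedicated tools whose outputs this package consumes.
* Structural variants, indel calling and read mapping are upstream of this
  package and are consumed via standard formats.
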