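---
title: "Quantifying promoter NDR dynamics from MNase-seq with NDRquant"
author: "NDRquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter NDR dynamics from MNase-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NDRquant)
```

## The problem

In compact fungal genomes such as fission yeast, most promoters carry a
nucleosome-depleted region (NDR) immediately upstream of the transcription
start site (TSS), flanked by phased nucleosome arrays. Chromatin remodellers
(notably the RSC complex) keep these NDRs open; when remodelling is impaired
the NDR shrinks and the -1 nucleosome slides toward the TSS. MNase-seq —
sequencing of nuclease-protected mononucleosomal fragments — maps these
changes genome-wide. NDRquant implements the full quantification chain from
aligned fragments to per-gene NDR statistics and between-condition
comparisons, together with a synthetic-data generator that plants a known
truth so every stage can be validated.

## The processing model

For each sample the pipeline applies, in order:

1. **Clonal-read removal** (`removeClonalReads()`). PCR duplicates appear as
   towers of identical fragments at one (chromosome, start, strand)
   position. With `lambda = total fragments / genome length` as the
   genome-wide Poisson rate, the filter finds the smallest count $c$ with
   $P(X \ge c \mid \lambda) < p_{\mathrm{cutoff}}$ (default $10^{-10}$) and
   trims deeper stacks down to $c$ retained fragments. Trimming, rather than
   zeroing, preserves genuine signal under an amplification spike. The rate,
   threshold and removal count are exposed for audit.
2. **Half-fragment shifting** (`estimateFragmentSize()`,
   `shiftFragments()`). MNase leaves fragments whose sequenced ends sit half
   a fragment from the nucleosome dyad. The fragment size is the median
   interval length (paired/full-fragment data) or the mode of the
   plus/minus strand cross-correlation over 50–300 bp lags (single-end
   5'-end data). Each record becomes its adjusted centre: 5' ends move
   `floor(size/2)` bp 3'-ward; full fragments are replaced by their
   midpoint.
3. **Occupancy counting** (`computeOccupancy()`). Occupancy at base $b$ is
   the number of adjusted centres whose `extend`-bp window covers $b$
   (default: one estimated fragment size, i.e. a nucleosome footprint).
   Windows clip at chromosome ends.
4. **Quantile normalisation** (`quantileNormalize()`). All samples are
   forced onto the common distribution given by the across-sample mean of
   sorted value vectors; within-sample ranks are preserved and tied values
   receive the mean of the tied reference values. This makes an absolute
   occupancy threshold comparable across conditions — after joint
   normalisation the genome-wide mean and standard deviation, and hence the
   NDR threshold below, are numerically identical for all samples (a fact
   the test suite asserts).

On the normalised tracks the package computes:

- **NDR lengths at TSSs** (`genomeOccupancyThreshold()`, `ndrLengths()`).
  The threshold is `mean - sd` of genome-wide per-bp occupancy (population
  sd, floored at 0). A gene's NDR is the longest maximal run of bases
  strictly below the threshold, within ±1000 bp of the TSS, whose
  TSS-proximal border lies strictly closer than 65 bp to the TSS (runs
  containing the TSS qualify with distance 0; "closer than" is read as a
  strict inequality). Length ties break toward the run with the more
  upstream distal border. Genes without a qualifying run get length 0.
- **Shrinkage ranking** (`deltaNdr()`, `topShrinkageFraction()`). Per-gene
  `delta = length_mutant - length_wildtype`; genes with no NDR in either
  condition are flagged and excluded. The top fraction (default 10%) with
  the most negative delta is selected, ties at the cut broken by gene id.
  The ranking universe defaults to genes with a wild-type NDR; whether the
  field's "10% of coding genes" means all genes or detected genes is not
  settled, so both universes are supported via the `universe` argument.
- **Meta-gene profiles and the -1 shift** (`metageneProfile()`,
  `locateMinus1()`, `minus1Shift()`). Profiles average occupancy at signed
  TSS offsets (strand-aware, negative = upstream). The -1 nucleosome is the
  maximum of the 73-bp-smoothed profile in the upstream search range
  (default -300..-20 bp), ties toward the TSS; estimates at a search-range
  boundary are flagged rather than trusted. The shift between conditions is
  the difference of the two located offsets, positive toward the TSS. An
  alternative per-gene estimator (`minus1PerGene()`, averaging per-gene
  called -1 midpoints) is provided because an "average -1 midpoint" can be
  read either way; the profile maximum is the default and is markedly more
  stable at moderate depth.
- **Per-bp differential signal** (`differentialSignal()`). At every base
  the rounded (half-to-even) occupancies are compared by an upper-tail
  Poisson test with the smaller value plus a pseudocount of 1 as the rate;
  equal values give p = 1 exactly. The pseudocount keeps p defined at
  zero-coverage bases; rounding is needed because normalised tracks are
  non-integer. Dynamic regions are maximal runs with p below `1e-10`,
  scored by the -log10 of their minimum p. Which track serves as the
  Poisson rate is not canonical in the field's tooling; the symmetric
  min-as-rate convention is used and pinned by tests (it makes
  `differentialSignal(a, b)` and `differentialSignal(b, a)` identical up to
  sign).
- **Overlap enrichment and group comparisons** (`overlapFisher()`,
  `welchTTest()`). Gene-set overlap uses the one-sided hypergeometric tail
  (Fisher's exact enrichment test), computed in log space via `phyper`; no
  normal approximation anywhere. Replicate ChIP means are compared with
  Welch's unequal-variance t-test.
- **Single-locus qPCR ratios** (`percentIp()`,
  `modifiedOverUnmodified()`, `scanningEnrichment()`,
  `relativeExpression()`, `replicateSummary()`). All are simple
  scale-invariant ratios of post-standard-curve quantities;
  Ct-to-quantity conversion is out of scope because amplification
  efficiencies are instrument-specific.

`runComparison()` drives the whole wild-type-versus-mutant analysis from a
validated YAML configuration (schema version 1; unknown keys are errors) and
writes TSV tables, bedGraph tracks, gene sets and a manifest with parameters
and input checksums. One top-level seed derives all stage seeds, and reruns
are byte-identical.

## What the simulator emulates

`simulationConfig()` and friends generate a gene-dense genome in which each
gene contributes a TSS-anchored NDR whose proximal border abuts the TSS, an
upstream array (default 3 nucleosomes) and a downstream array (default 6),
phased at `footprint + linker` spacing. Defaults are chosen to resemble
fission yeast chromatin:

| parameter | default | why |
|---|---|---|
| `nucleosomeFootprint` | 147 bp | canonical nucleosomal DNA |
| `linkerLength` | 7 bp | the ~154-bp repeat length of fission yeast |
| `ndrLengthMean`, `ndrLengthSd` | 150, 25 bp | typical promoter NDRs; draws truncated at ±3 sd |
| `fuzzinessSd` | 20 bp | positional spread of fragment midpoints around the dyad |
| `fragmentLengthMean`, `fragmentLengthSd` | 147, 10 bp | mononucleosomal gel cut |
| `depth` | 30 | fragments per nucleosome; each nucleosome emits exactly `round(depth)` |
| `clonalFraction` | 0 | duplicates resampled uniformly from emitted fragments when > 0 |
| `nucleosomesUpstream/Downstream` | 3 / 6 | ~1.4-kb gene bodies |
| `intergenicGap` | 10 bp | see below |

Design choices worth spelling out:

- **Truth NDRs are occupancy-free gaps.** No fragment is sampled inside a
  truth NDR. The generative model behind real NDRs is unknown; this is the
  simplest model under which the NDR length statistic is identifiable, so
  recovery errors measure the estimator, not a modelling mismatch.
- **Exact per-nucleosome depth.** `depth` fragments per nucleosome are
  emitted deterministically, with all positional noise carried by
  `fuzzinessSd`. This separates the two noise sources so parameter-recovery
  benchmarks run at a controlled signal-to-noise ratio.
- **Geometry and the occupancy threshold.** Because the NDR threshold is
  `mean - sd` of the whole genome, the fraction of unoccupied genome
  controls where the threshold cuts the occupancy ramp at NDR borders. The
  default geometry (arrays covering ~85% of the genome, `intergenicGap` of
  10 bp) places the threshold near half the array plateau, which makes the
  threshold crossing an approximately unbiased estimator of the planted
  border. A sparser genome would bias all NDR calls short; this is a
  property of the mean-minus-sd rule itself that users should keep in mind
  with real data too.
- **Shrinkage is a rigid slide of the upstream flank.** `plantShrinkage()`
  moves the -1 nucleosome *and* the nucleosomes behind it toward the TSS by
  `delta`, keeping array spacing; the proximal border and the downstream
  (+1) side stay fixed. Moving the -1 nucleosome alone would tear a
  second, spurious NDR open behind it.
- **Strand conventions.** For minus-strand genes "upstream" means larger
  coordinates; all TSS-relative arithmetic is signed (negative = upstream)
  and the simulator alternates strands so both code paths are always
  exercised.
- **Single-end mode.** Libraries may be degraded to 5'-end point records
  (`singleEnd = TRUE`), exercising the cross-correlation size estimator and
  the point-record shifting path, since real archives contain both
  single-end and paired-end runs.

What the simulator does **not** emulate: sequence-dependent MNase bias,
GC/mappability artefacts, non-Normal insert-size distributions,
transcription-coupled remodelling within gene bodies, and NDRs away from
annotated TSSs. Passing recovery tests therefore demonstrates the
correctness and calibration of the estimators under the stated noise model,
not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

- Internal coordinates are the toolkit's native 1-based, closed `GRanges`
  convention; BED (0-based half-open), GFF3/SAM (1-based) converters sit at
  the file boundary only, so no off-by-one can drift through the middle of
  the pipeline.
- bedGraph/wig values are written with 17 significant digits; reading back
  reproduces every base-pair value bit-exactly (asserted in tests).
- Peak calling smooths with a 73-bp moving average (half a footprint, odd)
  and selects summits greedily by height with a 147-bp minimum distance;
  equal-height summits resolve toward the smaller coordinate, and plateau
  summits report the plateau middle. Flat tracks yield no calls.
- The Poisson differential test rounds normalised occupancies half-to-even
  before testing and returns p = 1 exactly where the rounded values are
  equal. Under null simulations (two independent draws from one truth) the
  fraction of bases with p < 0.05 is about 2%, i.e. the test is
  conservative at the base level.
- Degenerate inputs are first-class: zero genes, zero depth, empty BED
  files, flat tracks, all-tied rankings and monotone profiles all have
  defined, tested behaviour (empty results, length-0 NDRs or flagged
  estimates — never NA propagation or crashes).

## Validation scale and known limitations

The packaged validation (`scripts/acceptance.R`, mirrored by the acceptance
test file) simulates 200-gene genomes (~0.3 Mb) for NDR recovery, shrinkage
selection, null calibration and determinism, and a 5000-gene genome (~8 Mb,
the scale of the fission-yeast coding genome) with a 500-gene perturbed
subset for the -1 shift — sizes chosen so the full validation completes in
about a minute on one core while keeping estimator noise representative.

Two limitations are worth stating plainly:

- **Border precision of the NDR statistic.** With 30 fragments per
  nucleosome and 20-bp midpoint fuzziness, each NDR border estimate is a
  threshold crossing built from ~30 noisy fragment positions; its standard
  deviation is ~4.6 bp, so per-gene NDR lengths carry ~6 bp of noise and
  about 10% of genes land more than 10 bp from truth. This is an
  information limit of the per-gene statistic at that depth, not an
  implementation artefact: even averaging the fragment midpoints directly
  (the minimum-variance border estimator, which is *not* the thresholded-run
  definition) would only reach ~5 bp. Between-condition deltas subtract two
  such estimates and planted 100-bp shrinkages are recovered essentially
  perfectly; single-gene absolute lengths at moderate depth should be read
  with ±10 bp in mind.
- **The mean-minus-sd threshold is global.** It inherits sensitivity to the
  fraction of the genome that is signal-free (see the geometry note above).
  Comparisons across conditions are protected by joint quantile
  normalisation, which equalises the thresholds exactly.
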