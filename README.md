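# NDRquant

Nucleosome occupancy and promoter NDR dynamics from MNase-seq, for
chromatin biologists working in compact, gene-dense genomes (the defaults
are tuned to fission yeast).

Promoters of most yeast genes carry a nucleosome-depleted region (NDR)
immediately upstream of the transcription start site (TSS), held open by
chromatin remodellers. When remodelling fails, the NDR shrinks and the -1
nucleosome slides toward the TSS. NDRquant turns aligned MNase-seq
fragments into quantile-normalised per-base-pair occupancy tracks and
quantifies exactly that biology:

- **Occupancy tracks**: clonal (PCR-duplicate) read removal by a Poisson
  cutoff on per-position read stacks; shifting of each read 3'-ward by half
  the estimated fragment size; per-bp counting of adjusted reads; quantile
  normalisation across samples.
- **NDR statistic**: for each gene, the length of the longest run of bases
  below `mean - sd` of genome-wide occupancy whose TSS-proximal border lies
  closer than 65 bp to the TSS.
- **Comparisons**: per-gene NDR deltas between conditions, selection of the
  10% of genes with the strongest shrinkage, TSS-aligned meta-gene profiles
  with -1 nucleosome localisation and shift estimation, a per-bp Poisson
  differential signal with dynamic-region calling, one-sided Fisher's exact
  gene-set overlap enrichment, Welch's t-test, and the single-locus
  ChIP-qPCR ratio normalisations (percent IP, modified/unmodified,
  mononucleosomal/total scanning, act1-normalised relative expression).
- **Synthetic truth**: a simulator of phased nucleosome arrays around
  TSS-anchored NDRs with planted, recoverable perturbations, so the whole
  pipeline can be validated end to end.

The statistic at the core: with per-bp occupancy $o(b)$ and threshold
$t = \mu_o - \sigma_o$ (genome-wide), a gene's NDR is

$$\mathrm{NDR} = \arg\max_{R} |R|,\quad R \text{ a maximal run with }
o(b) < t\ \forall b \in R,\ d(R_{\mathrm{prox}}, \mathrm{TSS}) < 65\,
\mathrm{bp},$$

and between conditions the per-bp differential signal is the upper Poisson
tail $P(X \ge \max(a,b) \mid \lambda = \min(a,b) + 1)$ on rounded
normalised occupancies.

## Worked example

Simulate a wild type and a "remodeller mutant" in which a random 10% of
promoter NDRs lose 100 bp, then recover the perturbed genes from the
fragment data alone:

```r
library(NDRquant)

cfg   <- simulationConfig(nGenes = 100, depth = 30, fuzzinessSd = 20, seed = 7)
ann   <- generateAnnotation(cfg)
truth <- generateTruthMap(ann, cfg)

set.seed(8)
tl      <- truthNdr(truth)
planted <- sort(sample(tl$gene_id[tl$length > 110], 10))
mutantTruth <- plantShrinkage(truth, planted, 100)

wt  <- simulateFragments(truth,       cfg, sampleId = "wt",  seed = 71)
mut <- simulateFragments(mutantTruth, cfg, sampleId = "mut", seed = 72)
wt
#> FragmentSet 'wt': 27000 fragments

size <- estimateFragmentSize(wt)          # 147
tracks <- quantileNormalize(list(
  computeOccupancy(shiftFragments(wt,  size), ann, extend = size),
  computeOccupancy(shiftFragments(mut, size), ann, extend = size)))

thr <- genomeOccupancyThreshold(tracks[[1]])
round(thr, 2)
#> [1] 14.88

deltas <- deltaNdr(ndrLengths(tracks[[1]], ann, threshold = thr),
                   ndrLengths(tracks[[2]], ann, threshold = thr))
head(deltas, 3)
#>   gene_id length_a length_b delta excluded
#> 1   g0001      122        0  -122    FALSE
#> 2   g0002      128      129     1    FALSE
#> 3   g0003      151       47  -104    FALSE

sel <- topShrinkageFraction(deltas, fraction = 0.10)
setequal(sel, planted)
#> [1] TRUE

overlapFisher(sel, planted, geneIds(ann))$p.value
#> [1] 5.776904e-14
```

`length_a`/`length_b` are wild-type and mutant NDR lengths in bp;
`delta` is mutant minus wild type, so the planted -100 bp shrinkage shows
up directly (g0001 above loses its whole detectable NDR). The top-10%
selection recovers the planted set exactly, and the Fisher overlap p-value
quantifies how unlikely that agreement is by chance.

The -1 nucleosome shift uses meta-gene profiles of a gene subset. Planting
the 13 bp shift typical of remodeller mutants on the same 10 genes:

```r
shiftTruth <- plantShrinkage(truth, planted, 13)
mut2 <- simulateFragments(shiftTruth, cfg, sampleId = "mut", seed = 74)
wt2  <- simulateFragments(truth,      cfg, sampleId = "wt",  seed = 73)
tracks2 <- quantileNormalize(list(
  computeOccupancy(shiftFragments(wt2,  147), ann, extend = 147),
  computeOccupancy(shiftFragments(mut2, 147), ann, extend = 147)))
pw <- metageneProfile(tracks2[[1]], ann, geneSet = planted)
pm <- metageneProfile(tracks2[[2]], ann, geneSet = planted)
locateMinus1(pw)
#> Minus1Estimate 'wt': 237 bp upstream of TSS (offset -237)
minus1Shift(pw, pm)   # positive = toward the TSS
#> [1] 18
```

At a 10-gene subset the profile-maximum estimator carries a few bp of
sampling noise (18 vs the planted 13); at the validation scale below (500
genes) it recovers 13 +/- 2 bp.

File-based analyses go through `runComparison()` with a YAML configuration
(see `?pipelineConfig`); it writes bedGraph tracks, NDR/delta TSVs, gene
sets, meta-profiles, dynamic regions and a run manifest, and reruns are
byte-identical.

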