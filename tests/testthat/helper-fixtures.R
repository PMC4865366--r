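# Shared helpers: tiny fixtures built in code.

suppressPackageStartupMessages(library(GenomicRanges))

# An OccupancyTrack over one small chromosome from a bare numeric vector.
toyTrack <- function(v, chrom = "chrI", sampleId = "toy",
                     normalization = "raw") {
  OccupancyTrack(setNames(list(as.numeric(v)), chrom), sampleId = sampleId,
                 normalization = normalization)
}

# A small annotation with a single gene on a given strand.
toyAnnotation <- function(tss, strand = "+", len = 10000, chrom = "chrI",
                          id = "g1") {
  GenomeAnnotation(data.frame(gene_id = id, chrom = chrom, tss = tss,
                              strand = strand),
                   chromLengths = setNames(len, chrom))
}

# A FragmentSet from parallel vectors, with seqlengths attached.
toyFragments <- function(start, end, strand = "+", chrom = "chrI",
                         len = 10000, sampleId = "toy", isPoint = FALSE) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                seqinfo = GenomeInfoDb::Seqinfo(chrom, len))
  FragmentSet(gr, sampleId = sampleId, isPoint = isPoint)
}

# Small simulated two-condition experiment with planted NDR shrinkage;
# returns everything downstream stages need.
simExperiment <- function(nGenes = 50, depth = 30, fuzz = 20, delta = 100,
                          plantFrac = 0.10, seed = 7, ndrSd = 25) {
  cfg <- simulationConfig(nGenes = nGenes, depth = depth, fuzzinessSd = fuzz,
                          ndrLengthSd = ndrSd, seed = seed)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  tr <- truthNdr(truth)
  eligible <- tr$gene_id[tr$length > delta + 10]
  set.seed(seed + 1000)
  planted <- sort(sample(eligible, max(1, round(plantFrac * nGenes))))
  truthB <- plantShrinkage(truth, planted, delta)
  fsA <- simulateFragments(truth, cfg, sampleId = "wt", seed = seed * 13 + 1)
  fsB <- simulateFragments(truthB, cfg, sampleId = "mut",
                           seed = seed * 13 + 2)
  occA <- computeOccupancy(shiftFragments(fsA, 147), ann)
  occB <- computeOccupancy(shiftFragments(fsB, 147), ann)
  qn <- quantileNormalize(list(occA, occB))
  list(cfg = cfg, ann = ann, truth = truth, truthB = truthB,
       planted = planted, fsA = fsA, fsB = fsB,
       trackA = qn[[1]], trackB = qn[[2]])
}

# Brute-force Poisson upper tail P(X >= c | lambda) by direct summation.
poissonTailBrute <- function(c, lambda, terms = 400) {
  i <- seq.int(c, c + terms)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}
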