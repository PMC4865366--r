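# Fragment-size estimation, clonal filtering, read shifting, occupancy
# counting and quantile normalisation, each checked against independent
# brute-force oracles.

test_that("fragment size: median for intervals, cross-correlation for
           single-end points", {
  expect_identical(estimateFragmentSize(
    toyFragments(rep(1, 5) * 100, rep(1, 5) * 100 + 146)), 147)
  fs <- toyFragments(c(100, 200, 300), c(100 + 139, 200 + 146, 300 + 153))
  expect_identical(estimateFragmentSize(fs), 147)
  expect_error(estimateFragmentSize(
    FragmentSet(GRanges(), "x")), "empty")

  # single-end reads from 150 bp fragments recover the size within 5 bp
  cfg <- simulationConfig(nGenes = 12, depth = 30, fragmentLengthMean = 150,
                          fragmentLengthSd = 5, seed = 31)
  truth <- generateTruthMap(generateAnnotation(cfg), cfg)
  se <- simulateFragments(truth, cfg, singleEnd = TRUE)
  expect_lt(abs(estimateFragmentSize(se) - 150), 5 + 1e-9)
})

test_that("Poisson clonal filter matches the brute-force tail threshold and
           trims stacks", {
  # threshold oracle: smallest c with sum_{i>=c} e^-lambda lambda^i/i! < p
  lambda <- 1
  thrOracle <- 1L
  while (poissonTailBrute(thrOracle, lambda) >= 1e-10)
    thrOracle <- thrOracle + 1L
  # genome sized so that lambda = n / genomeLength = 1
  n <- 500
  fs <- toyFragments(rep(seq_len(100), each = 5), rep(seq_len(100), each = 5),
                     len = n, isPoint = TRUE)
  res <- removeClonalReads(fs, pCutoff = 1e-10)
  expect_identical(res@lambda, 1)
  expect_identical(res@countThreshold, thrOracle)

  # all singletons at small lambda: nothing removed
  fs2 <- toyFragments(seq(1, 2000, by = 20), seq(1, 2000, by = 20) + 146,
                      len = 100000)
  res2 <- removeClonalReads(fs2)
  expect_identical(res2@removedCount, 0L)
  expect_identical(length(retainedFragments(res2)), length(fs2))

  # a 1000-deep stack among many singletons is trimmed exactly to the
  # threshold; on such data (removal a small fraction of the library) the
  # filter is idempotent
  bgStart <- seq(10000, 409960, by = 40)
  fs3 <- toyFragments(c(rep(5000, 1000), bgStart),
                      c(rep(5146, 1000), bgStart + 146),
                      len = 500000)
  res3 <- removeClonalReads(fs3)
  expect_identical(res3@removedCount, 1000L - res3@countThreshold)
  expect_identical(res3@removedCount + length(retainedFragments(res3)),
                   length(fs3))
  again <- removeClonalReads(retainedFragments(res3))
  expect_identical(again@removedCount, 0L)
  expect_identical(fragments(retainedFragments(again)),
                   fragments(retainedFragments(res3)))
})

test_that("read shifting moves points half a fragment 3'-ward and recentres
           intervals", {
  pts <- FragmentSet(GRanges("chrI", IRanges(c(1000, 1000), width = 1),
                             strand = c("+", "-"),
                             seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                     "s", isPoint = TRUE)
  sh <- shiftFragments(pts, 150)
  expect_identical(start(fragments(sh)), c(1075L, 925L))
  expect_identical(length(sh), length(pts))

  iv <- toyFragments(1001, 1150)  # midpoint 1075
  shIv <- shiftFragments(iv, 150)
  expect_identical(start(fragments(shIv)), 1075L)
  expect_true(shIv@isPoint)

  # out-of-range centres are clipped, count conserved
  edge <- FragmentSet(GRanges("chrI", IRanges(5, width = 1), strand = "-",
                              seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                      "s", isPoint = TRUE)
  expect_message(shE <- shiftFragments(edge, 150), "clipped")
  expect_identical(start(fragments(shE)), 1L)
})

test_that("occupancy counting equals a brute-force per-base recount", {
  ann <- toyAnnotation(5000, len = 10000)
  one <- FragmentSet(GRanges("chrI", IRanges(500, width = 1),
                             seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                     "s", isPoint = TRUE)
  occ <- computeOccupancy(one, ann, extend = 147)
  v <- trackValues(occ)$chrI
  expect_identical(sum(v), 147)
  expect_identical(unique(v[v > 0]), 1)
  expect_identical(which(v > 0), (500 - 73):(500 + 73))

  two <- FragmentSet(GRanges("chrI", IRanges(c(500, 500), width = 1),
                             seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                     "s", isPoint = TRUE)
  expect_identical(max(trackValues(computeOccupancy(two, ann))$chrI), 2)

  # random set vs brute force; also additivity over concatenation
  set.seed(32)
  pos <- sample(10000, 1000, replace = TRUE)
  fsAll <- FragmentSet(GRanges("chrI", IRanges(pos, width = 1),
                               seqinfo = GenomeInfoDb::Seqinfo("chrI",
                                                               10000)),
                       "s", isPoint = TRUE)
  vAll <- trackValues(computeOccupancy(fsAll, ann, extend = 147))$chrI
  brute <- numeric(10000)
  for (p in pos) {
    i <- max(1, p - 73):min(10000, p + 73)
    brute[i] <- brute[i] + 1
  }
  expect_equal(vAll, brute, tolerance = 1e-12)
  vA <- trackValues(computeOccupancy(
    FragmentSet(GRanges("chrI", IRanges(pos[1:400], width = 1),
                        seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                "s", isPoint = TRUE), ann))$chrI
  vB <- trackValues(computeOccupancy(
    FragmentSet(GRanges("chrI", IRanges(pos[401:1000], width = 1),
                        seqinfo = GenomeInfoDb::Seqinfo("chrI", 10000)),
                "s", isPoint = TRUE), ann))$chrI
  expect_equal(vA + vB, vAll, tolerance = 1e-12)
})

test_that("occupancy maxima sit on truth nucleosome midpoints in noiseless
           simulations", {
  cfg <- simulationConfig(nGenes = 6, depth = 20, fuzzinessSd = 0,
                          fragmentLengthSd = 0, seed = 33)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  fs <- simulateFragments(truth, cfg)
  occ <- computeOccupancy(shiftFragments(fs, 147), ann)
  nuc <- truthNucleosomes(truth)
  for (i in sample(nrow(nuc), 10)) {
    v <- trackValues(occ)[[nuc$chrom[i]]]
    m <- nuc$midpoint[i]
    expect_identical(v[m], max(v[(m - 77):(m + 77)]))
  }
})

test_that("quantile normalisation matches the sort-and-average definition", {
  t1 <- toyTrack(c(1, 2, 3)); t2 <- toyTrack(c(4, 5, 6))
  qn <- quantileNormalize(list(t1, t2))
  expect_equal(trackValues(qn[[1]])$chrI, c(2.5, 3.5, 4.5))
  expect_equal(trackValues(qn[[2]])$chrI, c(2.5, 3.5, 4.5))

  # identical tracks are a fixed point
  t3 <- toyTrack(c(5, 1, 1, 7))
  qn3 <- quantileNormalize(list(t3, t3))
  expect_equal(trackValues(qn3[[1]]), trackValues(t3))
  expect_equal(trackValues(qn3[[2]]), trackValues(t3))

  # ties get the mean of the tied reference values
  ta <- toyTrack(c(2, 2, 9)); tb <- toyTrack(c(1, 5, 30))
  qnT <- quantileNormalize(list(ta, tb))
  refv <- c(mean(c(1, 2)), mean(c(2, 5)), mean(c(9, 30)))
  expect_equal(trackValues(qnT[[1]])$chrI,
               c(mean(refv[1:2]), mean(refv[1:2]), refv[3]))

  # properties on random tracks: equal sorted vectors, idempotence,
  # permutation equivariance; limma agrees on tie-free input
  set.seed(34)
  x <- lapply(1:3, function(i) toyTrack(runif(400) * 10,
                                        sampleId = paste0("s", i)))
  qnX <- quantileNormalize(x)
  s1 <- sort(trackValues(qnX[[1]])$chrI)
  for (q in qnX[-1]) expect_equal(sort(trackValues(q)$chrI), s1)
  qnXX <- quantileNormalize(qnX)
  for (i in 1:3) expect_equal(trackValues(qnXX[[i]]), trackValues(qnX[[i]]))
  qnP <- quantileNormalize(x[c(2, 3, 1)])
  expect_equal(trackValues(qnP[[3]]), trackValues(qnX[[1]]))
  skip_if_not_installed("limma")
  mat <- vapply(x, function(t) trackValues(t)$chrI, numeric(400))
  lim <- limma::normalizeQuantiles(mat)
  for (i in 1:3)
    expect_equal(trackValues(qnX[[i]])$chrI, lim[, i], tolerance = 1e-12)
})

test_that("quantile normalisation rejects mismatched genomes", {
  expect_error(quantileNormalize(list(toyTrack(1:3))), "at least two")
  expect_error(quantileNormalize(list(toyTrack(1:3), toyTrack(1:4))),
               "different genomes")
})
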