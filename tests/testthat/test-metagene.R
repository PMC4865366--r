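# TSS-aligned meta-gene profiles and -1 nucleosome localisation.

test_that("profile of a single gene is its raw window, strand-flipped for
           '-' genes", {
  set.seed(61)
  v <- rpois(4000, 5) + 0.0
  tr <- toyTrack(v)
  annP <- toyAnnotation(2000, "+", len = 4000)
  p <- metageneProfile(tr, annP, window = 100)
  expect_equal(profileOccupancy(p), v[1900:2100])
  expect_identical(p@nGenes, 1L)

  annM <- toyAnnotation(2000, "-", len = 4000)
  m <- metageneProfile(tr, annM, window = 100)
  expect_equal(profileOccupancy(m), rev(v[1900:2100]))

  # mirror-image construction: one '+' and one '-' gene with mirrored
  # signal average to the common window
  vm <- c(v[1:2500], rev(v[1:2500]))
  tr2 <- toyTrack(vm)
  ann2 <- GenomeAnnotation(
    data.frame(gene_id = c("gp", "gm"), chrom = "chrI",
               tss = c(2000, 5001 - 2000), strand = c("+", "-")),
    chromLengths = c(chrI = 5000))
  p2 <- metageneProfile(tr2, ann2, window = 100)
  expect_equal(profileOccupancy(p2), v[1900:2100])
  expect_identical(p2@nGenes, 2L)
})

test_that("profile equals a brute-force per-gene recount and is linear and
           permutation-invariant", {
  sim <- simExperiment(nGenes = 12, seed = 62)
  ids <- geneIds(sim$ann)
  p <- metageneProfile(sim$trackA, sim$ann, window = 200)
  # brute force
  tss <- tssPositions(sim$ann); str <- geneStrands(sim$ann)
  chrom <- setNames(as.character(seqnames(genes(sim$ann))), ids)
  acc <- numeric(401)
  for (g in ids) {
    v <- trackValues(sim$trackA)[[chrom[g]]]
    w <- v[(tss[g] - 200):(tss[g] + 200)]
    if (str[g] == "-") w <- rev(w)
    acc <- acc + w
  }
  expect_equal(profileOccupancy(p), acc / length(ids), tolerance = 1e-12)

  # permutation invariance of the gene set
  p2 <- metageneProfile(sim$trackA, sim$ann, geneSet = rev(ids),
                        window = 200)
  expect_equal(profileOccupancy(p2), profileOccupancy(p))

  # linearity in the track
  dbl <- OccupancyTrack(lapply(trackValues(sim$trackA), `*`, 2), "dbl")
  pD <- metageneProfile(dbl, sim$ann, window = 200)
  expect_equal(profileOccupancy(pD), 2 * profileOccupancy(p))
})

test_that("-1 localisation: flags, tie rule, translation equivariance", {
  off <- -500:500
  flat <- new("MetaProfile", offsets = off,
              occupancy = rep(1, length(off)), nGenes = 5L,
              condition = "flat")
  expect_true(isFlagged(locateMinus1(flat)))
  expect_true(is.na(minus1Offset(locateMinus1(flat))))

  # two equal maxima at -80 and -120: the one closer to the TSS wins
  occ <- rep(0, length(off))
  occ[off %in% c(-120, -80)] <- 5
  prof <- new("MetaProfile", offsets = off, occupancy = occ, nGenes = 5L,
              condition = "ties")
  expect_identical(minus1Offset(locateMinus1(prof, smoothWindow = 1L)), -80)

  # a hump centred at -150 is found; translating it moves the estimate
  hump <- dnorm(off, -150, 40)
  pr <- new("MetaProfile", offsets = off, occupancy = hump, nGenes = 5L,
            condition = "a")
  expect_equal(minus1Offset(locateMinus1(pr)), -150, tolerance = 2)
  humpT <- dnorm(off, -130, 40)
  prT <- new("MetaProfile", offsets = off, occupancy = humpT, nGenes = 5L,
             condition = "b")
  expect_identical(minus1Shift(pr, prT), 20)
  expect_identical(minus1Shift(prT, pr), -20)
  expect_identical(minus1Shift(pr, pr), 0)
  expect_error(minus1Shift(pr, flat), "flagged")
})

test_that("planted 13-bp shrinkage moves the -1 estimate toward the TSS", {
  # all genes planted, moderate size: the paired profiles are translated
  cfg <- simulationConfig(nGenes = 300, depth = 60, fuzzinessSd = 20,
                          seed = 63)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  truthB <- plantShrinkage(truth, geneIds(ann), 13)
  occA <- computeOccupancy(shiftFragments(
    simulateFragments(truth, cfg, seed = 631), 147), ann)
  occB <- computeOccupancy(shiftFragments(
    simulateFragments(truthB, cfg, seed = 632), 147), ann)
  qn <- quantileNormalize(list(occA, occB))
  pa <- metageneProfile(qn[[1]], ann)
  pb <- metageneProfile(qn[[2]], ann)
  expect_lt(abs(minus1Shift(pa, pb) - 13), 3 + 1e-9)
})
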