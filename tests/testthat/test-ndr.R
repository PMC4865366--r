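# TSS-anchored NDR statistic: threshold, run selection, proximity rule,
# deltas and shrinkage ranking.

test_that("genome occupancy threshold is mean minus population sd, floored
           at zero", {
  expect_identical(genomeOccupancyThreshold(toyTrack(rep(5, 100))), 5)
  expect_identical(genomeOccupancyThreshold(toyTrack(rep(c(0, 2), 50))), 0)
  set.seed(51)
  v <- rgamma(1000, 2, 0.5)
  m <- mean(v); s <- sqrt(mean((v - m)^2))
  expect_equal(genomeOccupancyThreshold(toyTrack(v)), max(0, m - s),
               tolerance = 1e-12)
})

test_that("NDR run selection honours the proximity rule and maximality", {
  # TSS at 2000 ('+'); a 120-bp sub-threshold run ending 30 bp upstream
  v <- rep(10, 4000)
  v[(2000 - 30 - 119):(2000 - 30)] <- 1
  ann <- toyAnnotation(2000, len = 4000)
  rec <- ndrLengths(toyTrack(v), ann, threshold = 5)
  expect_identical(rec$length, 120L)
  expect_identical(rec$ndr_start, 2000L - 30L - 119L)
  expect_identical(rec$ndr_end, 2000L - 30L)
  # maximality: extending either border crosses the threshold
  expect_gte(v[rec$ndr_start - 1], 5)
  expect_gte(v[rec$ndr_end + 1], 5)

  # same run but 100 bp from the TSS does not qualify
  v2 <- rep(10, 4000)
  v2[(2000 - 100 - 119):(2000 - 100)] <- 1
  rec2 <- ndrLengths(toyTrack(v2), ann, threshold = 5)
  expect_identical(rec2$length, 0L)

  # border exactly at the proximity limit is excluded (strict inequality)
  v3 <- rep(10, 4000)
  v3[(2000 - 65 - 50):(2000 - 65)] <- 1
  expect_identical(ndrLengths(toyTrack(v3), ann, threshold = 5)$length, 0L)
  v4 <- rep(10, 4000)
  v4[(2000 - 64 - 50):(2000 - 64)] <- 1
  expect_identical(ndrLengths(toyTrack(v4), ann, threshold = 5)$length, 51L)

  # flat track at the mean: nothing below mean - sd
  flat <- toyTrack(rep(7, 4000))
  expect_identical(ndrLengths(flat, ann)$length, 0L)

  # runs spanning the TSS qualify with distance 0
  v5 <- rep(10, 4000)
  v5[1950:2100] <- 0
  expect_identical(ndrLengths(toyTrack(v5), ann, threshold = 5)$length, 151L)
})

test_that("NDR statistic respects strand orientation", {
  # '-' strand gene: upstream is to the right
  v <- rep(10, 4000)
  v[2030:2229] <- 1   # 200-bp run starting 30 bp 'upstream' (right) of TSS
  annM <- toyAnnotation(2000, strand = "-", len = 4000)
  rec <- ndrLengths(toyTrack(v), annM, threshold = 5)
  expect_identical(rec$length, 200L)
  expect_identical(rec$ndr_start, 2030L)
})

test_that("NDR length is invariant under joint monotone rescaling", {
  sim <- simExperiment(nGenes = 20, seed = 52)
  thr <- genomeOccupancyThreshold(sim$trackA)
  base <- ndrLengths(sim$trackA, sim$ann, threshold = thr)
  resc <- OccupancyTrack(lapply(trackValues(sim$trackA),
                                function(v) 3 * v + 2),
                         sampleId = "resc")
  resc2 <- ndrLengths(resc, sim$ann, threshold = 3 * thr + 2)
  expect_identical(base$length, resc2$length)
  expect_identical(base$ndr_start, resc2$ndr_start)
})

test_that("noiseless high-depth occupancy recovers planted NDR lengths", {
  cfg <- simulationConfig(nGenes = 30, depth = 100, fuzzinessSd = 0,
                          fragmentLengthSd = 0, seed = 53)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  fs <- simulateFragments(truth, cfg)
  occ <- computeOccupancy(shiftFragments(fs, 147), ann)
  rec <- ndrLengths(occ, ann)
  tr <- truthNdr(truth)
  err <- rec$length - tr$length[match(rec$gene_id, tr$gene_id)]
  expect_gte(mean(abs(err) <= 1), 0.95)
})

test_that("delta table arithmetic, exclusion flag and universe checks", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), length = c(300L, 0L, 150L))
  b <- data.frame(gene_id = c("g3", "g2", "g1"), length = c(150L, 0L, 200L))
  d <- deltaNdr(a, b)
  expect_identical(d$delta[d$gene_id == "g1"], -100L)
  expect_identical(d$delta[d$gene_id == "g3"], 0L)
  expect_identical(d$excluded, c(FALSE, TRUE, FALSE))
  expect_error(deltaNdr(a, b[1:2, ]), "different gene sets")

  # identical conditions give all-zero deltas
  dd <- deltaNdr(a, a)
  expect_true(all(dd$delta == 0L))
})

test_that("top shrinkage selection: count, tie rule, universes", {
  set.seed(54)
  d <- data.frame(gene_id = sprintf("g%03d", 1:100),
                  length_a = rep(200L, 100), length_b = rep(150L, 100))
  d$delta <- d$length_b - d$length_a
  d$excluded <- FALSE
  sel <- topShrinkageFraction(d, 0.10)
  expect_identical(length(sel), 10L)
  expect_identical(sel, sprintf("g%03d", 1:10))  # all tied: first 10 by id

  d2 <- d
  d2$delta[15] <- -500L
  expect_true("g015" %in% topShrinkageFraction(d2, 0.10))

  # genes without a reference NDR are outside the 'detected' universe
  d3 <- d
  d3$length_a[1:50] <- 0L
  expect_identical(length(topShrinkageFraction(d3, 0.10)), 5L)
  expect_identical(length(topShrinkageFraction(d3, 0.10, universe = "all")),
                   10L)
  expect_error(topShrinkageFraction(d[0, ], 0.10), "no usable genes")
})
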