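# Synthetic-data generator: determinism, geometry, planted perturbations,
# and the statistical contracts of the fragment sampler.

test_that("same seed gives byte-identical simulator output", {
  cfg <- simulationConfig(nGenes = 20, depth = 10, clonalFraction = 0.1,
                          seed = 5)
  a1 <- generateAnnotation(cfg); a2 <- generateAnnotation(cfg)
  expect_identical(a1, a2)
  t1 <- generateTruthMap(a1, cfg); t2 <- generateTruthMap(a2, cfg)
  expect_identical(t1, t2)
  f1 <- simulateFragments(t1, cfg); f2 <- simulateFragments(t2, cfg)
  expect_identical(fragments(f1), fragments(f2))
  expect_identical(plantShrinkage(t1, geneIds(a1)[1:3], 20),
                   plantShrinkage(t2, geneIds(a2)[1:3], 20))
})

test_that("degenerate and bounded annotation geometry", {
  empty <- generateAnnotation(simulationConfig(nGenes = 0, seed = 1))
  expect_identical(length(empty), 0L)
  expect_identical(length(chromLengths(empty)), 2L)

  cfg <- simulationConfig(nChromosomes = 1, chromosomeLength = 100000,
                          nGenes = 50, seed = 2)
  ann <- generateAnnotation(cfg)
  expect_identical(length(ann), 50L)
  tss <- tssPositions(ann)
  expect_true(all(tss > 1000 & tss <= 100000 - 1000))
  expect_setequal(unique(unname(geneStrands(ann))), c("+", "-"))
  # gene bodies do not overlap
  g <- genes(ann)
  o <- order(start(g))
  expect_true(all(start(g)[o][-1] > end(g)[o][-length(g)]))
})

test_that("infeasible gene packing is an explicit error", {
  cfg <- simulationConfig(nChromosomes = 1, chromosomeLength = 5000,
                          nGenes = 50, seed = 3)
  expect_error(generateAnnotation(cfg), "cannot place")
})

test_that("truth map geometry: spacing, NDR anchoring, strand convention", {
  cfg <- simulationConfig(nGenes = 10, fuzzinessSd = 0, linkerLength = 20,
                          nucleosomeFootprint = 147, ndrLengthSd = 0,
                          ndrLengthMean = 300, seed = 4)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  tr <- truthNdr(truth)
  expect_true(all(tr$length == 300))
  nuc <- truthNucleosomes(truth)
  # successive downstream midpoints exactly footprint + linker apart
  for (gid in tr$gene_id) {
    down <- nuc[nuc$gene_id == gid & grepl("^\\+", nuc$label), ]
    down <- down[order(as.integer(sub("\\+", "", down$label))), ]
    expect_true(all(abs(diff(down$midpoint)) == 167))
  }
  # minus-strand genes: the -1 nucleosome lies at coordinates > TSS
  minusG <- tr$gene_id[tr$strand == "-"]
  m1 <- nuc[nuc$label == "-1" & nuc$gene_id %in% minusG, ]
  expect_true(all(m1$midpoint > tr$tss[match(m1$gene_id, tr$gene_id)]))
  # proximal border abuts the TSS on both strands
  expect_true(all(ifelse(tr$strand == "+", tr$tss - 1 - tr$ndr_end,
                         tr$ndr_start - (tr$tss + 1)) == 0))
})

test_that("plantShrinkage moves the -1 midpoint toward the TSS only for
           the listed genes and validates delta", {
  cfg <- simulationConfig(nGenes = 10, ndrLengthSd = 0, seed = 6)
  ann <- generateAnnotation(cfg)
  truth <- generateTruthMap(ann, cfg)
  expect_identical(plantShrinkage(truth, geneIds(ann), 0), truth)

  shrunk <- plantShrinkage(truth, geneIds(ann), 13)
  m0 <- truthNucleosomes(truth); m1 <- truthNucleosomes(shrunk)
  str <- setNames(truthNdr(truth)$strand, truthNdr(truth)$gene_id)
  sel0 <- m0[m0$label == "-1", ]; sel1 <- m1[m1$label == "-1", ]
  disp <- (sel1$midpoint - sel0$midpoint) *
    ifelse(str[sel0$gene_id] == "+", 1, -1)
  expect_true(all(disp == 13))  # toward the TSS on both strands
  # downstream structure untouched
  expect_identical(m0[grepl("^\\+", m0$label), ],
                   m1[grepl("^\\+", m1$label), ])
  # NDR lengths reduced by exactly delta
  expect_true(all(truthNdr(truth)$length - truthNdr(shrunk)$length == 13))

  # partial subsets leave other genes identical
  some <- geneIds(ann)[1:3]
  part <- plantShrinkage(truth, some, 13)
  keep <- !truthNdr(truth)$gene_id %in% some
  expect_identical(truthNdr(part)[keep, ], truthNdr(truth)[keep, ])

  expect_error(plantShrinkage(truth, geneIds(ann)[1], 10000), "exceeds")
  expect_error(plantShrinkage(truth, "nope", 5), "unknown gene")
})

test_that("fragment sampler honours depth, noise and clonal contracts", {
  cfg0 <- simulationConfig(nGenes = 5, depth = 0, seed = 8)
  ann0 <- generateAnnotation(cfg0)
  expect_identical(length(simulateFragments(generateTruthMap(ann0, cfg0),
                                            cfg0)), 0L)

  # noiseless, fixed-length fragments from one nucleosome are identical
  cfg1 <- simulationConfig(nGenes = 2, depth = 10, fuzzinessSd = 0,
                           fragmentLengthSd = 0, seed = 9)
  truth1 <- generateTruthMap(generateAnnotation(cfg1), cfg1)
  fs1 <- simulateFragments(truth1, cfg1)
  key <- paste(seqnames(fragments(fs1)), start(fragments(fs1)),
               end(fragments(fs1)))
  expect_identical(length(unique(key)), nrow(truthNucleosomes(truth1)))
  expect_true(all(width(fragments(fs1)) == 147))

  # clonal duplicate fraction within binomial 99% bounds of the target
  cfg2 <- simulationConfig(nGenes = 40, depth = 30, clonalFraction = 0.5,
                           seed = 10)
  truth2 <- generateTruthMap(generateAnnotation(cfg2), cfg2)
  fs2 <- simulateFragments(truth2, cfg2)
  n <- length(fs2)
  base <- 40 * 9 * 30          # originals before duplication
  dupFrac <- (n - base) / n
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(dupFrac, ci[1]); expect_lte(dupFrac, ci[2])

  # empirical moments match configured moments within 3 standard errors
  cfg3 <- simulationConfig(nGenes = 50, depth = 30, fuzzinessSd = 20,
                           fragmentLengthMean = 147, fragmentLengthSd = 10,
                           seed = 11)
  truth3 <- generateTruthMap(generateAnnotation(cfg3), cfg3)
  fs3 <- simulateFragments(truth3, cfg3)
  w <- width(fragments(fs3))
  n3 <- length(w)
  expect_gt(n3, 10000)
  expect_lt(abs(mean(w) - 147), 3 * 10 / sqrt(n3) + 0.5)  # 0.5: rounding
  # midpoint deviation from the nearest truth nucleosome (output is sorted,
  # so fragments are matched by proximity; spacing >> fuzziness)
  mid <- (start(fragments(fs3)) + end(fragments(fs3))) / 2
  nuc3 <- truthNucleosomes(truth3)
  dev <- unlist(lapply(unique(nuc3$chrom), function(ch) {
    mids <- sort(nuc3$midpoint[nuc3$chrom == ch])
    x <- mid[as.character(seqnames(fragments(fs3))) == ch]
    i <- pmax(1, pmin(length(mids) - 1,
                      findInterval(x, mids)))
    near <- ifelse(abs(x - mids[i]) <= abs(x - mids[i + 1]),
                   mids[i], mids[i + 1])
    x - near
  }), use.names = FALSE)
  expect_lt(abs(mean(dev)), 3 * 20 / sqrt(n3) + 0.5)
  expect_lt(abs(sd(dev) - 20), 3 * 20 / sqrt(2 * n3) + 0.5)
})

test_that("single-end degradation keeps only the 5' base", {
  cfg <- simulationConfig(nGenes = 2, depth = 5, seed = 12)
  truth <- generateTruthMap(generateAnnotation(cfg), cfg)
  se <- simulateFragments(truth, cfg, singleEnd = TRUE)
  expect_true(all(width(fragments(se)) == 1L))
  expect_true(se@isPoint)
})
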