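#' @include AllClasses.R
NULL

#' Configuration of the synthetic nucleosome-map simulator
#'
#' The simulator emulates the data-generating assumptions behind MNase-seq
#' nucleosome maps of a compact, gene-dense fungal genome: per gene, a
#' TSS-anchored nucleosome-depleted region (NDR) whose proximal border abuts
#' the TSS, a phased array of nucleosomes on both flanks at a spacing of
#' `nucleosomeFootprint + linkerLength`, Gaussian positional fuzziness of the
#' sequenced fragment midpoints around each nucleosome midpoint, Gaussian
#' fragment lengths, and a configurable fraction of clonal (exact-duplicate)
#' fragments. Truth NDRs are occupancy-free gaps: no fragment is sampled
#' inside them, the simplest generative model under which the NDR length
#' statistic is identifiable.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromosomeLength length of each chromosome (bp); `NA` (default)
#'   sizes each chromosome to fit its genes plus the edge margin, keeping the
#'   simulated genome gene-dense as in fission yeast.
#' @param nGenes total number of genes (split evenly across chromosomes).
#' @param ndrLengthMean,ndrLengthSd mean and sd (bp) of per-gene true NDR
#'   lengths; draws are truncated at three sd from the mean.
#' @param nucleosomeFootprint nucleosome footprint (bp), default 147.
#' @param linkerLength linker DNA between adjacent nucleosomes (bp); the
#'   default 7 bp reproduces the short (~154 bp) nucleosome repeat length of
#'   fission yeast.
#' @param fuzzinessSd sd (bp) of fragment midpoints around their nucleosome
#'   midpoint.
#' @param fragmentLengthMean,fragmentLengthSd fragment length moments (bp).
#' @param depth fragments emitted per nucleosome (each nucleosome emits
#'   exactly `round(depth)` fragments).
#' @param clonalFraction fraction of the final fragment set that is an exact
#'   duplicate of an already-emitted fragment; in `[0, 1)`.
#' @param seed integer seed; all simulator stages derive their streams from
#'   it deterministically.
#' @param nucleosomesUpstream,nucleosomesDownstream phased nucleosomes
#'   placed upstream (-1, -2, ...) and downstream (+1, +2, ...) of each NDR.
#' @param intergenicGap unoccupied spacer between adjacent gene units (bp).
#' @param edgeMargin minimum distance (bp) of any TSS from a chromosome end;
#'   keep at least one meta-gene window.
#' @return A `SimulationConfig` object.
#' @seealso [generateAnnotation()], [generateTruthMap()],
#'   [simulateFragments()]
#' @examples
#' cfg <- simulationConfig(nGenes = 10, seed = 1)
#' @export
simulationConfig <- function(nChromosomes = 2,
                             chromosomeLength = NA,
                             nGenes = 100,
                             ndrLengthMean = 150,
                             ndrLengthSd = 25,
                             nucleosomeFootprint = 147,
                             linkerLength = 7,
                             fuzzinessSd = 20,
                             fragmentLengthMean = 147,
                             fragmentLengthSd = 10,
                             depth = 30,
                             clonalFraction = 0,
                             seed = 1,
                             nucleosomesUpstream = 3,
                             nucleosomesDownstream = 6,
                             intergenicGap = 10,
                             edgeMargin = 1000) {
  .assertScalarNumber(nChromosomes, "nChromosomes", min = 1)
  if (!is.na(chromosomeLength))
    .assertScalarNumber(chromosomeLength, "chromosomeLength", min = 1)
  .assertScalarNumber(nGenes, "nGenes", min = 0)
  .assertScalarNumber(ndrLengthMean, "ndrLengthMean", min = 1)
  .assertScalarNumber(ndrLengthSd, "ndrLengthSd", min = 0)
  .assertScalarNumber(nucleosomeFootprint, "nucleosomeFootprint", min = 1)
  .assertScalarNumber(linkerLength, "linkerLength", min = 0)
  .assertScalarNumber(fuzzinessSd, "fuzzinessSd", min = 0)
  .assertScalarNumber(fragmentLengthMean, "fragmentLengthMean", min = 1)
  .assertScalarNumber(fragmentLengthSd, "fragmentLengthSd", min = 0)
  .assertScalarNumber(depth, "depth", min = 0)
  .assertScalarNumber(clonalFraction, "clonalFraction", min = 0, max = 1,
                      strictMax = TRUE)
  .assertScalarNumber(nucleosomesUpstream, "nucleosomesUpstream", min = 1)
  .assertScalarNumber(nucleosomesDownstream, "nucleosomesDownstream", min = 1)
  .assertScalarNumber(intergenicGap, "intergenicGap", min = 0)
  .assertScalarNumber(edgeMargin, "edgeMargin", min = 0)
  new("SimulationConfig",
      nChromosomes = as.integer(nChromosomes),
      chromosomeLength = as.numeric(chromosomeLength),
      nGenes = as.integer(nGenes),
      ndrLengthMean = ndrLengthMean, ndrLengthSd = ndrLengthSd,
      nucleosomeFootprint = as.integer(nucleosomeFootprint),
      linkerLength = as.integer(linkerLength),
      fuzzinessSd = fuzzinessSd,
      fragmentLengthMean = fragmentLengthMean,
      fragmentLengthSd = fragmentLengthSd,
      depth = depth, clonalFraction = clonalFraction,
      seed = as.integer(seed),
      nucleosomesUpstream = as.integer(nucleosomesUpstream),
      nucleosomesDownstream = as.integer(nucleosomesDownstream),
      intergenicGap = as.integer(intergenicGap),
      edgeMargin = as.integer(edgeMargin))
}

#' @rdname simulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(nChromosomes = "integer", chromosomeLength = "numeric",
                   nGenes = "integer", ndrLengthMean = "numeric",
                   ndrLengthSd = "numeric", nucleosomeFootprint = "integer",
                   linkerLength = "integer", fuzzinessSd = "numeric",
                   fragmentLengthMean = "numeric",
                   fragmentLengthSd = "numeric", depth = "numeric",
                   clonalFraction = "numeric", seed = "integer",
                   nucleosomesUpstream = "integer",
                   nucleosomesDownstream = "integer",
                   intergenicGap = "integer", edgeMargin = "integer"))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes on", object@nChromosomes,
      "chromosomes; NDR ~ N(", object@ndrLengthMean, ",",
      object@ndrLengthSd, "); fuzziness", object@fuzzinessSd,
      "bp; depth", object@depth, "frags/nucleosome; seed",
      object@seed, "\n")
})

# Geometry helpers. Spacing between adjacent nucleosome midpoints and the
# extents of a gene unit measured from its TSS. halfF is floor(footprint/2),
# so a nucleosome at midpoint m occupies [m - halfF, m + halfF].
.simGeometry <- function(config) {
  halfF <- config@nucleosomeFootprint %/% 2L
  spacing <- config@nucleosomeFootprint + config@linkerLength
  dCap <- round(config@ndrLengthMean + 3 * config@ndrLengthSd)
  dMin <- max(1, round(config@ndrLengthMean - 3 * config@ndrLengthSd))
  # upstream extent from the TSS for NDR length d: NDR (d bp) + the upstream
  # array; downstream extent: the downstream array starting at the TSS.
  upExtent <- function(d) d + 2L * halfF + 1L +
    (config@nucleosomesUpstream - 1L) * spacing
  downExtent <- 2L * halfF + 1L +
    (config@nucleosomesDownstream - 1L) * spacing
  list(halfF = halfF, spacing = spacing, dCap = dCap, dMin = dMin,
       upExtent = upExtent, upExtentMax = upExtent(dCap),
       downExtent = downExtent)
}

#' Generate a synthetic gene annotation
#'
#' Places `nGenes` TSSs sequentially along the chromosomes, alternating
#' strands, with enough room for the largest possible NDR and the flanking
#' nucleosome arrays of each gene plus the configured intergenic gap, so
#' gene bodies never overlap. Every TSS lies at least `edgeMargin` bp from
#' both chromosome ends.
#'
#' @param config a [simulationConfig()].
#' @return A [GenomeAnnotation-class]; with `nGenes = 0` an empty annotation
#'   carrying only the chromosome lengths.
#' @examples
#' ann <- generateAnnotation(simulationConfig(nGenes = 6, seed = 1))
#' tssPositions(ann)
#' @export
generateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  geo <- .simGeometry(config)
  nChrom <- config@nChromosomes
  perChrom <- rep(config@nGenes %/% nChrom, nChrom)
  if (config@nGenes %% nChrom > 0)
    perChrom[seq_len(config@nGenes %% nChrom)] <-
      perChrom[seq_len(config@nGenes %% nChrom)] + 1L
  chromNames <- sprintf("chr%s", as.roman(seq_len(nChrom)))

  rows <- vector("list", nChrom)
  lens <- numeric(nChrom)
  idx <- 0L
  for (ci in seq_len(nChrom)) {
    n <- perChrom[ci]
    if (n == 0L) {
      lens[ci] <- if (is.na(config@chromosomeLength))
        2L * config@edgeMargin + 1L else config@chromosomeLength
      rows[[ci]] <- NULL
      next
    }
    strands <- rep_len(c("+", "-"), n)
    leftExt <- ifelse(strands == "+", geo$upExtentMax, geo$downExtent)
    rightExt <- ifelse(strands == "+", geo$downExtent, geo$upExtentMax)
    tss <- numeric(n)
    cursor <- 0  # last occupied position so far
    for (i in seq_len(n)) {
      tss[i] <- if (i == 1L)
        max(config@edgeMargin + 1, leftExt[i] + 1)
      else
        cursor + config@intergenicGap + leftExt[i] + 1
      cursor <- tss[i] + rightExt[i]
    }
    needed <- max(cursor, tss[n] + config@edgeMargin)
    if (is.na(config@chromosomeLength)) {
      lens[ci] <- needed
    } else {
      if (needed > config@chromosomeLength)
        stop(sprintf(
          "cannot place %d genes on a %d bp chromosome (need %d bp)",
          n, as.integer(config@chromosomeLength), as.integer(needed)))
      lens[ci] <- config@chromosomeLength
    }
    bodyStart <- ifelse(strands == "+", tss, tss - geo$downExtent + 1)
    bodyEnd <- ifelse(strands == "+", tss + geo$downExtent - 1, tss)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", idx + seq_len(n)),
      chrom = chromNames[ci], tss = tss, strand = strands,
      start = bodyStart, end = bodyEnd)
    idx <- idx + n
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(gene_id = character(), chrom = character(),
                     tss = numeric(), strand = character(),
                     start = numeric(), end = numeric())
  GenomeAnnotation(df, chromLengths = setNames(as.integer(lens), chromNames))
}

#' Generate the ground-truth nucleosome map
#'
#' Draws a true NDR length for every gene from
#' `N(ndrLengthMean, ndrLengthSd)` (rounded, truncated at three sd) and
#' anchors the NDR so that its TSS-proximal border abuts the TSS. Phased
#' nucleosomes are placed on both flanks at exact spacing
#' `nucleosomeFootprint + linkerLength`: the -1 nucleosome immediately
#' upstream of the NDR, the +1 nucleosome starting at the TSS.
#'
#' @param annotation a [GenomeAnnotation-class] from [generateAnnotation()].
#' @param config the same [simulationConfig()].
#' @return A [NucleosomeMap-class].
#' @examples
#' cfg <- simulationConfig(nGenes = 4, ndrLengthSd = 0, seed = 2)
#' truth <- generateTruthMap(generateAnnotation(cfg), cfg)
#' truthNdr(truth)
#' @export
generateTruthMap <- function(annotation, config) {
  stopifnot(is(annotation, "GenomeAnnotation"),
            is(config, "SimulationConfig"))
  geo <- .simGeometry(config)
  set.seed(.deriveSeed(config@seed, 1L))
  n <- length(annotation)
  ids <- geneIds(annotation)
  tss <- tssPositions(annotation)
  str <- geneStrands(annotation)
  chrom <- as.character(seqnames(genes(annotation)))
  d <- round(pmin(pmax(rnorm(n, config@ndrLengthMean, config@ndrLengthSd),
                       geo$dMin), geo$dCap))

  upLab <- -seq_len(config@nucleosomesUpstream)
  downLab <- seq_len(config@nucleosomesDownstream)
  sgn <- ifelse(str == "+", 1L, -1L)          # direction of transcription
  ns <- ifelse(str == "+", tss - d, tss + 1)
  ne <- ifelse(str == "+", tss - 1, tss + d)
  m1 <- ifelse(str == "+", ns - (geo$halfF + 1L), ne + (geo$halfF + 1L))
  p1 <- tss + sgn * geo$halfF
  nLab <- length(upLab) + length(downLab)
  # expand gene x label grids
  gi <- rep(seq_len(n), each = nLab)
  labNum <- rep(c(upLab, downLab), times = n)
  isUp <- labNum < 0
  mids <- ifelse(isUp,
                 m1[gi] + sgn[gi] * (labNum + 1L) * geo$spacing,
                 p1[gi] + sgn[gi] * (labNum - 1L) * geo$spacing)
  labChr <- ifelse(isUp, as.character(labNum), sprintf("+%d", labNum))
  new("NucleosomeMap",
      ndr = data.frame(gene_id = ids, chrom = chrom, strand = unname(str),
                       tss = unname(tss), ndr_start = ns, ndr_end = ne),
      nucleosomes = data.frame(gene_id = ids[gi], chrom = chrom[gi],
                               label = labChr, midpoint = mids),
      annotation = annotation,
      footprint = as.numeric(config@nucleosomeFootprint))
}

#' Plant NDR shrinkage in a subset of genes
#'
#' Models the perturbation of a chromatin-remodeller mutant in which promoter
#' NDRs shorten: for each listed gene the whole upstream nucleosome flank
#' (-1, -2, ...) slides `delta` bp toward the TSS, shrinking the NDR at its
#' distal border while the TSS-proximal border and the downstream (+1 side)
#' structure stay fixed. Other genes are untouched.
#'
#' @param truth a [NucleosomeMap-class].
#' @param geneIds character vector of gene ids to perturb.
#' @param delta shrinkage in bp (>= 0); must not exceed any selected gene's
#'   NDR length.
#' @return A new [NucleosomeMap-class].
#' @examples
#' cfg <- simulationConfig(nGenes = 4, ndrLengthSd = 0, seed = 3)
#' truth <- generateTruthMap(generateAnnotation(cfg), cfg)
#' shrunk <- plantShrinkage(truth, geneIds(generateAnnotation(cfg))[1], 50)
#' @export
plantShrinkage <- function(truth, geneIds, delta) {
  stopifnot(is(truth, "NucleosomeMap"))
  .assertScalarNumber(delta, "delta", min = 0)
  delta <- round(delta)
  ndr <- truth@ndr
  unknown <- setdiff(geneIds, ndr$gene_id)
  if (length(unknown))
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  if (delta == 0) return(truth)
  sel <- ndr$gene_id %in% geneIds
  lens <- ndr$ndr_end[sel] - ndr$ndr_start[sel] + 1
  if (any(delta > lens))
    stop(sprintf("delta (%d bp) exceeds the NDR length of gene(s): %s",
                 delta,
                 paste(ndr$gene_id[sel][delta > lens], collapse = ", ")))
  plus <- sel & ndr$strand == "+"
  minus <- sel & ndr$strand == "-"
  ndr$ndr_start[plus] <- ndr$ndr_start[plus] + delta
  ndr$ndr_end[minus] <- ndr$ndr_end[minus] - delta
  nucs <- truth@nucleosomes
  up <- grepl("^-", nucs$label) & nucs$gene_id %in% geneIds
  strOf <- setNames(ndr$strand, ndr$gene_id)
  sgn <- ifelse(strOf[nucs$gene_id[up]] == "+", 1, -1)
  nucs$midpoint[up] <- nucs$midpoint[up] + sgn * delta
  new("NucleosomeMap", ndr = ndr, nucleosomes = nucs,
      annotation = truth@annotation, footprint = truth@footprint)
}

#' Simulate MNase fragments from a truth map
#'
#' Each nucleosome emits exactly `round(depth)` fragments whose midpoints are
#' drawn from `N(midpoint, fuzzinessSd)` (rounded to integer bp) and whose
#' lengths from `N(fragmentLengthMean, fragmentLengthSd)` truncated at 1 bp.
#' A `clonalFraction` of the final set consists of exact duplicates of
#' already-emitted fragments, resampled uniformly, producing the per-position
#' duplicate stacks the Poisson clonal filter targets. Output is sorted by
#' coordinate.
#'
#' @param truth a [NucleosomeMap-class].
#' @param config the [simulationConfig()].
#' @param sampleId label for the resulting sample.
#' @param seed seed for this fragment draw; defaults to a stream derived
#'   from `config@seed`. Use different seeds for different
#'   conditions/replicates of the same truth map.
#' @param singleEnd if `TRUE`, degrade fragments to their 5' base only
#'   (width-1 point records), emulating a single-end library.
#' @return A [FragmentSet-class] (seqinfo carries the chromosome lengths).
#' @examples
#' cfg <- simulationConfig(nGenes = 2, depth = 5, seed = 4)
#' truth <- generateTruthMap(generateAnnotation(cfg), cfg)
#' simulateFragments(truth, cfg)
#' @export
simulateFragments <- function(truth, config, sampleId = "sim",
                              seed = .deriveSeed(config@seed, 2L),
                              singleEnd = FALSE) {
  stopifnot(is(truth, "NucleosomeMap"), is(config, "SimulationConfig"))
  set.seed(seed)
  sl <- chromLengths(truth@annotation)
  si <- Seqinfo(names(sl), sl)
  nPer <- as.integer(round(config@depth))
  nuc <- truth@nucleosomes
  if (nPer == 0L || nrow(nuc) == 0L) {
    gr <- GRanges(seqinfo = si)
    return(FragmentSet(gr, sampleId = sampleId, isPoint = singleEnd))
  }
  m <- nrow(nuc) * nPer
  mids <- rep(nuc$midpoint, each = nPer) +
    round(rnorm(m, 0, config@fuzzinessSd))
  lens <- pmax(1, round(rnorm(m, config@fragmentLengthMean,
                              config@fragmentLengthSd)))
  chrom <- rep(nuc$chrom, each = nPer)
  starts <- mids - lens %/% 2L
  ends <- starts + lens - 1L
  strands <- sample(c("+", "-"), m, replace = TRUE)
  # clip to chromosome bounds
  lim <- sl[chrom]
  starts <- pmax(starts, 1)
  ends <- pmin(ends, lim)
  keep <- starts <= ends
  chrom <- chrom[keep]; starts <- starts[keep]; ends <- ends[keep]
  strands <- strands[keep]
  m <- length(starts)
  cf <- config@clonalFraction
  if (cf > 0 && m > 0) {
    nDup <- round(cf / (1 - cf) * m)
    di <- sample.int(m, nDup, replace = TRUE)
    chrom <- c(chrom, chrom[di]); starts <- c(starts, starts[di])
    ends <- c(ends, ends[di]); strands <- c(strands, strands[di])
  }
  if (singleEnd) {
    p <- ifelse(strands == "+", starts, ends)
    starts <- p; ends <- p
  }
  gr <- GRanges(chrom, IRanges(starts, ends), strand = strands, seqinfo = si)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  FragmentSet(gr, sampleId = sampleId, isPoint = singleEnd)
}
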