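#' @include AllClasses.R
NULL

#' Estimate the fragment (mononucleosome) size of a library
#'
#' For full-interval fragments, the median interval length. For single-end
#' point records (5' ends), the size is recovered from the strand
#' cross-correlation of per-position 5'-end counts: the lag in
#' `lagRange` maximising the correlation between `+`-strand and `-`-strand
#' counts, plus one (a fragment of length L places its `-` 5' end L - 1 bp
#' downstream of its `+` 5' end).
#'
#' @param fragmentSet a [FragmentSet-class] with at least one record.
#' @param lagRange integer range of lags scanned for single-end data.
#' @return Estimated fragment size in bp.
#' @export
estimateFragmentSize <- function(fragmentSet, lagRange = c(50L, 300L)) {
  stopifnot(is(fragmentSet, "FragmentSet"))
  gr <- fragmentSet@fragments
  if (length(gr) == 0L) stop("cannot estimate fragment size of an empty set")
  if (!fragmentSet@isPoint)
    return(as.numeric(median(width(gr))))
  lags <- seq.int(lagRange[1], lagRange[2])
  score <- numeric(length(lags))
  for (chrom in unique(as.character(seqnames(gr)))) {
    sub <- gr[seqnames(gr) == chrom]
    n <- max(end(sub)) + lagRange[2] + 1L
    plusC <- tabulate(start(sub)[as.character(strand(sub)) == "+"], n)
    minusC <- tabulate(start(sub)[as.character(strand(sub)) == "-"], n)
    for (i in seq_along(lags)) {
      k <- lags[i]
      score[i] <- score[i] +
        sum(plusC[seq_len(n - k)] * minusC[(k + 1L):n])
    }
  }
  as.numeric(lags[which.max(score)] + 1L)
}

#' Remove clonal (duplicate) reads by a Poisson cutoff
#'
#' Clonal reads are amplification duplicates recognisable as towers of
#' identical fragments at a single position, far above the mean coverage of
#' the genome. Per (chromosome, start, strand) position with k identical
#' fragments, the filter computes the genome-wide rate
#' `lambda = total fragments / genome length`, finds the smallest count `c`
#' whose Poisson upper-tail probability `P(X >= c | lambda)` falls below
#' `pCutoff`, and trims any stack deeper than `c` down to `c` retained
#' fragments (the excess is removed; the position keeps its signal).
#'
#' @param fragmentSet a [FragmentSet-class]; its `seqinfo` must carry
#'   chromosome lengths (used for the genome size).
#' @param pCutoff Poisson p-value cutoff in (0, 1); default `1e-10`.
#' @return A [ClonalFilterResult-class].
#' @export
removeClonalReads <- function(fragmentSet, pCutoff = 1e-10) {
  stopifnot(is(fragmentSet, "FragmentSet"))
  .assertScalarNumber(pCutoff, "pCutoff", min = 0, max = 1,
                      strictMin = TRUE, strictMax = TRUE)
  gr <- fragmentSet@fragments
  sl <- GenomeInfoDb::seqlengths(gr)
  if (length(gr) > 0L && (length(sl) == 0L || anyNA(sl)))
    stop("fragment seqinfo must carry chromosome lengths")
  genomeLength <- sum(as.numeric(sl))
  n <- length(gr)
  lambda <- if (n == 0L) 0 else n / genomeLength
  thr <- 1L
  while (ppois(thr - 1L, lambda, lower.tail = FALSE) >= pCutoff)
    thr <- thr + 1L
  if (n == 0L)
    return(new("ClonalFilterResult", retained = fragmentSet,
               removedCount = 0L, lambda = lambda, countThreshold = thr))
  key <- paste(as.character(seqnames(gr)), start(gr),
               as.character(strand(gr)), sep = "\r")
  o <- order(key)
  r <- rle(key[o])
  within <- sequence(r$lengths)
  keepSorted <- within <= thr
  keep <- logical(n)
  keep[o] <- keepSorted
  res <- gr[keep]
  new("ClonalFilterResult",
      retained = FragmentSet(res, sampleId = fragmentSet@sampleId,
                             isPoint = fragmentSet@isPoint),
      removedCount = as.integer(n - length(res)),
      lambda = lambda, countThreshold = thr)
}

#' Shift reads by half the estimated fragment size
#'
#' MNase digestion leaves fragments whose sequenced ends sit half a fragment
#' away from the nucleosome dyad; each record is therefore converted to its
#' adjusted centre. Point records (single-end 5' ends) move
#' `floor(fragmentSize/2)` bp in the 3' direction of their strand;
#' full-interval fragments are replaced by their midpoint. The result is a
#' point-mode [FragmentSet-class] of adjusted centres, ready for
#' [computeOccupancy()]. Record count is conserved; centres shifted outside
#' a chromosome are clipped to its ends and counted in a message.
#'
#' @param fragmentSet a [FragmentSet-class].
#' @param fragmentSize estimated fragment size in bp (> 0), e.g. from
#'   [estimateFragmentSize()].
#' @return A point-mode [FragmentSet-class] of adjusted centres.
#' @export
shiftFragments <- function(fragmentSet, fragmentSize) {
  stopifnot(is(fragmentSet, "FragmentSet"))
  .assertScalarNumber(fragmentSize, "fragmentSize", min = 0, strictMin = TRUE)
  gr <- fragmentSet@fragments
  if (length(gr) == 0L)
    return(FragmentSet(gr, sampleId = fragmentSet@sampleId, isPoint = TRUE))
  half <- as.integer(fragmentSize) %/% 2L
  if (fragmentSet@isPoint) {
    minus <- as.character(strand(gr)) == "-"
    centre <- ifelse(minus, start(gr) - half, start(gr) + half)
  } else {
    centre <- (start(gr) + end(gr)) %/% 2L
  }
  sl <- GenomeInfoDb::seqlengths(gr)
  nClipped <- 0L
  if (length(sl) && !anyNA(sl)) {
    lim <- sl[as.character(seqnames(gr))]
    clipped <- centre < 1L | centre > lim
    nClipped <- sum(clipped)
    centre <- pmin(pmax(centre, 1L), lim)
  } else {
    clipped <- centre < 1L
    nClipped <- sum(clipped)
    centre <- pmax(centre, 1L)
  }
  if (nClipped > 0L)
    message("shiftFragments: ", nClipped,
            " adjusted centres clipped to chromosome ends")
  out <- GRanges(seqnames(gr), IRanges(centre, width = 1L),
                 strand = strand(gr), seqinfo = seqinfo(gr))
  FragmentSet(out, sampleId = fragmentSet@sampleId, isPoint = TRUE)
}

#' Compute the per-base-pair occupancy track
#'
#' Occupancy at base b is the number of adjusted fragment centres whose
#' `extend`-bp window covers b (windows are clipped at chromosome ends, no
#' wrap-around). With the default `extend` equal to one nucleosome footprint
#' this counts, for every base, the adjusted reads covering it.
#'
#' @param fragmentSet a point-mode [FragmentSet-class] of adjusted centres
#'   from [shiftFragments()].
#' @param annotation a [GenomeAnnotation-class] supplying chromosome lengths.
#' @param extend window width (bp) each adjusted centre covers; default 147.
#' @return A raw [OccupancyTrack-class] over the whole genome.
#' @export
computeOccupancy <- function(fragmentSet, annotation, extend = 147) {
  stopifnot(is(fragmentSet, "FragmentSet"), is(annotation, "GenomeAnnotation"))
  .assertScalarNumber(extend, "extend", min = 1)
  extend <- as.integer(extend)
  sl <- chromLengths(annotation)
  gr <- fragmentSet@fragments
  if (length(gr)) {
    bad <- setdiff(unique(as.character(seqnames(gr))), names(sl))
    if (length(bad))
      stop("fragments on chromosome(s) absent from the annotation: ",
           paste(bad, collapse = ", "))
    centre <- start(gr)
    lim <- sl[as.character(seqnames(gr))]
    ws <- pmax(centre - extend %/% 2L, 1L)
    we <- pmin(centre - extend %/% 2L + extend - 1L, lim)
    win <- GRanges(seqnames(gr), IRanges(ws, we))
    GenomeInfoDb::seqlevels(win) <- names(sl)
    seqinfo(win) <- Seqinfo(names(sl), sl)
    cov <- coverage(win)
  } else {
    cov <- lapply(sl, function(n) Rle(0L, n))
  }
  values <- lapply(names(sl), function(ch) as.numeric(cov[[ch]]))
  names(values) <- names(sl)
  OccupancyTrack(values, sampleId = fragmentSet@sampleId,
                 normalization = "raw")
}

#' Quantile-normalise occupancy tracks across samples
#'
#' Forces every track to share the same genome-wide value distribution: the
#' sorted value vector of each track is replaced by the across-track mean of
#' sorted vectors, preserving within-track rank order. Tied values within a
#' track all receive the mean of the reference values at the tied ranks.
#'
#' @param tracks list of two or more [OccupancyTrack-class] objects over the
#'   same genome (identical chromosome names and lengths).
#' @return A list of quantile-normalised [OccupancyTrack-class] objects, in
#'   the input order.
#' @export
quantileNormalize <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2L)
    stop("quantileNormalize needs a list of at least two tracks")
  for (t in tracks) stopifnot(is(t, "OccupancyTrack"))
  chromsRef <- names(tracks[[1]]@values)
  lensRef <- vapply(tracks[[1]]@values, length, 0L)
  for (t in tracks[-1]) {
    if (!identical(names(t@values), chromsRef) ||
        !identical(vapply(t@values, length, 0L), lensRef))
      stop("tracks cover different genomes (chromosome names/lengths differ)")
  }
  G <- sum(lensRef)
  flat <- lapply(tracks, function(t) unlist(t@values, use.names = FALSE))
  ords <- lapply(flat, function(x) order(x, method = "radix"))
  ref <- numeric(G)
  for (j in seq_along(tracks)) ref <- ref + flat[[j]][ords[[j]]]
  ref <- ref / length(tracks)
  out <- vector("list", length(tracks))
  for (j in seq_along(tracks)) {
    x <- flat[[j]]
    o <- ords[[j]]
    # tie groups are contiguous in sorted order and share the mean of the
    # reference values at their ranks
    r <- rle(x[o])
    csum <- cumsum(ref)[cumsum(r$lengths)]
    gm <- diff(c(0, csum)) / r$lengths
    y <- numeric(G)
    y[o] <- rep.int(gm, r$lengths)
    values <- vector("list", length(chromsRef))
    names(values) <- chromsRef
    at <- 0L
    for (ch in chromsRef) {
      n <- lensRef[[ch]]
      values[[ch]] <- y[at + seq_len(n)]
      at <- at + n
    }
    out[[j]] <- OccupancyTrack(values, sampleId = tracks[[j]]@sampleId,
                               normalization = "quantile")
  }
  out
}
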