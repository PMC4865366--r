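#' @include AllClasses.R
NULL

# Plateau-aware strict local maxima of a numeric vector: returns the middle
# index (left-of-centre for even plateaus) of every run that is higher than
# both neighbouring runs. Flat vectors and monotone stretches yield no
# maxima.
.localMaxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 2L) return(integer(0))
  leftOk <- c(FALSE, r$values[-1L] > r$values[-k])
  rightOk <- c(r$values[-k] > r$values[-1L], FALSE)
  isMax <- leftOk & rightOk
  # runs at the vector edges count if higher than their single neighbour
  isMax[1L] <- r$values[1L] > r$values[2L]
  isMax[k] <- r$values[k] > r$values[k - 1L]
  starts <- cumsum(c(1L, r$lengths[-k]))
  (starts + (r$lengths - 1L) %/% 2L)[isMax]
}

#' Call nucleosome positions on an occupancy track
#'
#' Local maxima of the moving-average-smoothed track are selected greedily by
#' descending summit height subject to a minimum pairwise distance; height
#' ties break toward the smaller coordinate. Call boundaries are the lowest
#' points of the smoothed track between a summit and its selected
#' neighbours (or `minDistance/2` from the summit at track ends).
#'
#' @param track an [OccupancyTrack-class] (raw or normalised).
#' @param smoothWindow odd moving-average window (bp), default 73 (half a
#'   nucleosome footprint).
#' @param minDistance minimum distance between called midpoints (bp),
#'   default 147.
#' @return data.frame with columns `chrom`, `midpoint`, `summit`
#'   (smoothed occupancy at the midpoint), `left`, `right` (boundaries) and
#'   `sample_id`, sorted by position.
#' @export
callNucleosomes <- function(track, smoothWindow = 73L, minDistance = 147L) {
  stopifnot(is(track, "OccupancyTrack"))
  .assertScalarNumber(smoothWindow, "smoothWindow", min = 1)
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  .assertScalarNumber(minDistance, "minDistance", min = 1)
  res <- list()
  for (chrom in names(track@values)) {
    v <- .runmean(track@values[[chrom]], as.integer(smoothWindow))
    cand <- .localMaxima(v)
    if (length(cand) == 0L) next
    o <- order(-v[cand], cand)
    cand <- cand[o]
    sel <- integer(0)
    for (p in cand) {
      if (length(sel) == 0L || min(abs(sel - p)) >= minDistance)
        sel <- c(sel, p)
    }
    sel <- sort(sel)
    left <- integer(length(sel))
    right <- integer(length(sel))
    for (i in seq_along(sel)) {
      ls <- if (i == 1L) max(1L, sel[i] - minDistance %/% 2L)
      else sel[i - 1L]
      rs <- if (i == length(sel))
        min(length(v), sel[i] + minDistance %/% 2L)
      else sel[i + 1L]
      segL <- v[ls:sel[i]]
      segR <- v[sel[i]:rs]
      left[i] <- ls + which.min(segL) - 1L
      right[i] <- sel[i] + which.min(segR) - 1L
    }
    res[[chrom]] <- data.frame(chrom = chrom, midpoint = sel,
                               summit = v[sel], left = left, right = right,
                               sample_id = track@sampleId)
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(), midpoint = integer(),
                      summit = numeric(), left = integer(),
                      right = integer(), sample_id = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-bp Poisson differential occupancy between two conditions
#'
#' At every base pair, the two occupancies (rounded half-to-even to
#' integers) are compared by an upper-tail Poisson test: with
#' `lo = min(a, b)` and `hi = max(a, b)`,
#' `p = P(X >= hi | lambda = lo + pseudocount)`; where the rounded values
#' are equal the base is a null base and p is 1 exactly. The sign records
#' the direction of change (+1 where `b > a`). Dynamic regions are maximal
#' runs of bases with `p < regionCutoff`; each region's summit is the peak
#' of `-log10 p` within it and its score the `-log10` of its minimum p.
#'
#' @param trackA,trackB [OccupancyTrack-class] objects over the same genome,
#'   quantile-normalised together.
#' @param pseudocount added to the Poisson rate so p stays defined at
#'   zero-coverage bases; default 1.
#' @param regionCutoff per-bp p-value cutoff defining dynamic regions;
#'   default `1e-10`.
#' @return A [DifferentialSignal-class].
#' @export
differentialSignal <- function(trackA, trackB, pseudocount = 1,
                               regionCutoff = 1e-10) {
  stopifnot(is(trackA, "OccupancyTrack"), is(trackB, "OccupancyTrack"))
  if (!identical(names(trackA@values), names(trackB@values)) ||
      !identical(vapply(trackA@values, length, 0L),
                 vapply(trackB@values, length, 0L)))
    stop("tracks cover different genomes (chromosome names/lengths differ)")
  pvals <- list()
  dirs <- list()
  regs <- list()
  for (chrom in names(trackA@values)) {
    a <- round(trackA@values[[chrom]])
    b <- round(trackB@values[[chrom]])
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    p <- ppois(hi - 1, lo + pseudocount, lower.tail = FALSE)
    p[a == b] <- 1
    s <- sign(b - a)
    pvals[[chrom]] <- p
    dirs[[chrom]] <- s
    hit <- p < regionCutoff
    if (any(hit)) {
      r <- rle(hit)
      e <- cumsum(r$lengths)
      st <- e - r$lengths + 1L
      sel <- which(r$values)
      score <- numeric(length(sel))
      summit <- integer(length(sel))
      dirReg <- integer(length(sel))
      for (i in seq_along(sel)) {
        ii <- st[sel[i]]:e[sel[i]]
        best <- ii[which.min(p[ii])]
        score[i] <- -log10(max(p[best], .Machine$double.xmin))
        summit[i] <- best
        dirReg[i] <- as.integer(sign(sum(s[ii])))
      }
      regs[[chrom]] <- GRanges(factor(chrom,
                                      levels = names(trackA@values)),
                               IRanges(st[sel], e[sel]),
                               direction = dirReg, score = score,
                               summit = summit)
    }
  }
  regions <- if (length(regs)) do.call(c, unname(regs)) else {
    gr0 <- GRanges()
    mcols(gr0) <- S4Vectors::DataFrame(direction = integer(0),
                                       score = numeric(0),
                                       summit = integer(0))
    gr0
  }
  new("DifferentialSignal", pvalues = pvals, direction = dirs,
      regions = regions, cutoff = regionCutoff)
}

#' Write dynamic regions as BED with -log10 p scores
#'
#' @param x a [DifferentialSignal-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDynamicRegionsBed <- function(x, path) {
  stopifnot(is(x, "DifferentialSignal"))
  gr <- x@regions
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr),
                   name = ifelse(mcols(gr)$direction >= 0, "gain", "loss"),
                   score = round(mcols(gr)$score, 3), strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
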