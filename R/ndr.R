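#' @include AllClasses.R
NULL

#' Genome-wide occupancy threshold for NDR calling
#'
#' The NDR threshold is the genome-wide mean occupancy minus one genome-wide
#' (population) standard deviation, floored at zero. Bases strictly below
#' this value count as nucleosome-depleted.
#'
#' @param track an [OccupancyTrack-class].
#' @return The threshold in occupancy units (single numeric).
#' @export
genomeOccupancyThreshold <- function(track) {
  stopifnot(is(track, "OccupancyTrack"))
  v <- unlist(track@values, use.names = FALSE)
  if (length(v) == 0L) stop("empty track")
  max(0, mean(v) - .popSd(v))
}

#' TSS-anchored NDR lengths
#'
#' For each gene, the NDR is the longest maximal run of consecutive base
#' pairs strictly below `threshold` within `window` bp of the TSS whose
#' TSS-proximal border (the run border nearest the TSS; distance 0 for runs
#' containing the TSS) lies strictly closer than `proximity` bp to the TSS.
#' Genes with no qualifying run get length 0. Length ties break toward the
#' run whose distal border is more upstream (against the direction of
#' transcription).
#'
#' @param track an [OccupancyTrack-class] (typically quantile-normalised).
#' @param annotation a [GenomeAnnotation-class].
#' @param threshold occupancy threshold; defaults to
#'   [genomeOccupancyThreshold()] of `track`.
#' @param geneSubset gene ids to quantify (default: all annotated genes).
#' @param proximity maximum TSS distance of the proximal border (bp,
#'   strict); default 65.
#' @param window search half-window around the TSS (bp); default 1000.
#' @param condition condition label stored in the output; defaults to the
#'   track's sample id.
#' @return data.frame with columns `gene_id`, `condition`, `ndr_start`,
#'   `ndr_end` (1-based, closed; `NA` when no NDR found), `length` (bp, 0
#'   when none found) and `threshold_used`.
#' @export
ndrLengths <- function(track, annotation, threshold = NULL, geneSubset = NULL,
                       proximity = 65L, window = 1000L, condition = NULL) {
  stopifnot(is(track, "OccupancyTrack"), is(annotation, "GenomeAnnotation"))
  if (is.null(threshold)) threshold <- genomeOccupancyThreshold(track)
  if (is.null(condition)) condition <- track@sampleId
  .assertScalarNumber(proximity, "proximity", min = 1)
  .assertScalarNumber(window, "window", min = 1)
  ids <- if (is.null(geneSubset)) geneIds(annotation) else geneSubset
  unknown <- setdiff(ids, geneIds(annotation))
  if (length(unknown))
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  tss <- tssPositions(annotation)[ids]
  str <- geneStrands(annotation)[ids]
  chrom <- setNames(as.character(seqnames(genes(annotation))),
                    geneIds(annotation))[ids]
  out <- data.frame(gene_id = ids, condition = condition,
                    ndr_start = NA_integer_, ndr_end = NA_integer_,
                    length = 0L, threshold_used = threshold)
  for (i in seq_along(ids)) {
    v <- track@values[[chrom[i]]]
    ws <- max(1L, tss[i] - window)
    we <- min(length(v), tss[i] + window)
    below <- v[ws:we] < threshold
    if (!any(below)) next
    r <- rle(below)
    e <- ws - 1L + cumsum(r$lengths)
    s <- e - r$lengths + 1L
    sel <- which(r$values)
    s <- s[sel]; e <- e[sel]
    dist <- ifelse(e < tss[i], tss[i] - e,
                   ifelse(s > tss[i], s - tss[i], 0L))
    q <- dist < proximity
    if (!any(q)) next
    s <- s[q]; e <- e[q]
    len <- e - s + 1L
    best <- which(len == max(len))
    if (length(best) > 1L) {
      # more upstream distal border: smaller start for '+', larger end for '-'
      best <- if (str[i] == "+") best[which.min(s[best])]
      else best[which.max(e[best])]
    }
    out$ndr_start[i] <- s[best]
    out$ndr_end[i] <- e[best]
    out$length[i] <- len[best]
  }
  out
}

#' Per-gene NDR length change between two conditions
#'
#' @param recordsA,recordsB per-gene NDR tables from [ndrLengths()] over the
#'   same gene universe (condition A is the reference, e.g. wild type).
#' @return data.frame with `gene_id`, `length_a`, `length_b`,
#'   `delta = length_b - length_a` (negative = shrinkage in B) and
#'   `excluded` (`TRUE` for genes with no NDR in either condition, which are
#'   dropped from rankings).
#' @export
deltaNdr <- function(recordsA, recordsB) {
  if (!setequal(recordsA$gene_id, recordsB$gene_id) ||
      nrow(recordsA) != nrow(recordsB))
    stop("the two NDR tables cover different gene sets")
  b <- recordsB[match(recordsA$gene_id, recordsB$gene_id), ]
  out <- data.frame(gene_id = recordsA$gene_id,
                    length_a = recordsA$length,
                    length_b = b$length,
                    delta = b$length - recordsA$length)
  out$excluded <- out$length_a == 0L & out$length_b == 0L
  out
}

#' Genes with the strongest NDR shrinkage
#'
#' Selects the `ceiling(fraction * n)` genes with the most negative NDR
#' length change (strongest shrinkage in condition B). Ties at the cut break
#' by lexicographic gene id, making the selection deterministic.
#'
#' @param deltas data.frame from [deltaNdr()].
#' @param fraction fraction of the universe to select, in (0, 1]; default
#'   0.10.
#' @param universe `"detected"` restricts the universe to genes with an NDR
#'   in condition A (the reference), `"all"` uses every non-excluded gene.
#' @return Character vector of selected gene ids.
#' @export
topShrinkageFraction <- function(deltas, fraction = 0.10,
                                 universe = c("detected", "all")) {
  universe <- match.arg(universe)
  .assertScalarNumber(fraction, "fraction", min = 0, max = 1,
                      strictMin = TRUE)
  d <- deltas[!deltas$excluded, , drop = FALSE]
  if (universe == "detected")
    d <- d[d$length_a > 0L, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable genes to rank")
  m <- ceiling(fraction * nrow(d))
  o <- order(d$delta, d$gene_id)
  d$gene_id[o[seq_len(m)]]
}

#' Write a per-gene NDR table as TSV
#'
#' @param records data.frame from [ndrLengths()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNdrTsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene set, one id per line
#'
#' @param ids character vector of gene ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneSet <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a gene set written by [writeGeneSet()]
#'
#' @param path input file.
#' @return Character vector of gene ids.
#' @export
readGeneSet <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
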