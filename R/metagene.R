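#' @include AllClasses.R
NULL

#' TSS-aligned meta-gene occupancy profile
#'
#' Averages the occupancy signal over a gene set after aligning genes on
#' their TSS: at signed offset o the profile is the mean over genes of the
#' occupancy at `TSS + o` for `+`-strand genes and `TSS - o` for `-`-strand
#' genes, so negative offsets are always upstream of the TSS in the
#' direction of transcription. Genes whose window falls outside their
#' chromosome are skipped and counted in a message.
#'
#' @param track an [OccupancyTrack-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param geneSet gene ids to average (default: all annotated genes).
#' @param window half-window (bp); offsets run from `-window` to `+window`.
#' @param scaleGenes if `TRUE`, z-scale each gene's window before averaging
#'   (off by default: the profile shows raw averaged occupancy).
#' @param condition label stored in the profile; defaults to the track's
#'   sample id.
#' @return A [MetaProfile-class].
#' @export
metageneProfile <- function(track, annotation, geneSet = NULL, window = 500L,
                            scaleGenes = FALSE, condition = NULL) {
  stopifnot(is(track, "OccupancyTrack"), is(annotation, "GenomeAnnotation"))
  .assertScalarNumber(window, "window", min = 1)
  window <- as.integer(window)
  if (is.null(condition)) condition <- track@sampleId
  ids <- if (is.null(geneSet)) geneIds(annotation) else geneSet
  if (length(ids) == 0L) stop("empty gene set")
  unknown <- setdiff(ids, geneIds(annotation))
  if (length(unknown))
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  tss <- tssPositions(annotation)[ids]
  str <- geneStrands(annotation)[ids]
  chrom <- setNames(as.character(seqnames(genes(annotation))),
                    geneIds(annotation))[ids]
  offsets <- seq.int(-window, window)
  acc <- numeric(length(offsets))
  used <- 0L
  skipped <- 0L
  for (i in seq_along(ids)) {
    v <- track@values[[chrom[i]]]
    if (tss[i] - window < 1L || tss[i] + window > length(v)) {
      skipped <- skipped + 1L
      next
    }
    w <- v[(tss[i] - window):(tss[i] + window)]
    if (str[i] == "-") w <- rev(w)
    if (scaleGenes) {
      s <- .popSd(w)
      w <- if (s > 0) (w - mean(w)) / s else w * 0
    }
    acc <- acc + w
    used <- used + 1L
  }
  if (skipped > 0L)
    message("metageneProfile: skipped ", skipped,
            " genes with windows outside their chromosome")
  if (used == 0L) stop("no usable genes: all windows out of bounds")
  new("MetaProfile", offsets = as.integer(offsets), occupancy = acc / used,
      nGenes = used, condition = condition)
}

#' Locate the -1 nucleosome in a meta-gene profile
#'
#' The -1 nucleosome midpoint is taken as the offset of the maximum of the
#' moving-average-smoothed profile within an upstream search range. Ties
#' break toward the TSS. When the maximum sits on a boundary of the search
#' range (monotone profile) or the smoothed profile is flat in the range,
#' the estimate is flagged as unreliable.
#'
#' @param profile a [MetaProfile-class].
#' @param search two-element numeric range of offsets searched (default
#'   `c(-300, -20)`, i.e. 20-300 bp upstream of the TSS).
#' @param smoothWindow odd moving-average window (bp), default 73, matching
#'   the peak-calling smoother.
#' @return A [Minus1Estimate-class].
#' @export
locateMinus1 <- function(profile, search = c(-300, -20), smoothWindow = 73L) {
  stopifnot(is(profile, "MetaProfile"))
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  search <- sort(as.numeric(search))
  if (search[1] < min(profile@offsets) || search[2] > max(profile@offsets))
    stop("search range outside the profile window")
  sm <- .runmean(profile@occupancy, as.integer(smoothWindow))
  sel <- which(profile@offsets >= search[1] & profile@offsets <= search[2])
  vals <- sm[sel]
  mx <- max(vals)
  hits <- sel[vals == mx]
  best <- hits[length(hits)]  # tie toward the TSS (largest offset)
  flagged <- all(vals == vals[1L]) ||
    best == sel[1L] || best == sel[length(sel)]
  new("Minus1Estimate", offset = as.numeric(profile@offsets[best]),
      flagged = flagged, condition = profile@condition)
}

#' Shift of the -1 nucleosome between two conditions
#'
#' Signed displacement of the -1 nucleosome from condition A to condition B,
#' positive when the -1 nucleosome moves toward the TSS (the signature of
#' NDR shrinkage). Both profiles must cover the same window and gene set.
#'
#' @param profileA,profileB [MetaProfile-class] objects (A = reference).
#' @param search,smoothWindow passed to [locateMinus1()].
#' @return Signed shift in bp.
#' @export
minus1Shift <- function(profileA, profileB, search = c(-300, -20),
                        smoothWindow = 73L) {
  stopifnot(is(profileA, "MetaProfile"), is(profileB, "MetaProfile"))
  if (!identical(profileA@offsets, profileB@offsets))
    stop("profiles cover different windows")
  ea <- locateMinus1(profileA, search = search, smoothWindow = smoothWindow)
  eb <- locateMinus1(profileB, search = search, smoothWindow = smoothWindow)
  if (ea@flagged || eb@flagged)
    stop("flagged -1 estimate (no interior maximum in the search range)")
  eb@offset - ea@offset
}

#' Per-gene -1 nucleosome positions from nucleosome calls
#'
#' Alternative -1 estimator: for each gene, the called nucleosome midpoint
#' (from [callNucleosomes()]) nearest to the TSS on its upstream side within
#' the search range; the population average of these per-gene offsets
#' estimates the average -1 midpoint.
#'
#' @param calls data.frame from [callNucleosomes()].
#' @param annotation a [GenomeAnnotation-class].
#' @param geneSet gene ids (default: all).
#' @param search upstream search range of signed offsets, default
#'   `c(-300, -20)`.
#' @return data.frame with `gene_id` and signed `offset` (`NA` when no call
#'   falls in the range).
#' @export
minus1PerGene <- function(calls, annotation, geneSet = NULL,
                          search = c(-300, -20)) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  ids <- if (is.null(geneSet)) geneIds(annotation) else geneSet
  tss <- tssPositions(annotation)[ids]
  str <- geneStrands(annotation)[ids]
  chrom <- setNames(as.character(seqnames(genes(annotation))),
                    geneIds(annotation))[ids]
  search <- sort(as.numeric(search))
  off <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    mid <- calls$midpoint[calls$chrom == chrom[i]]
    if (length(mid) == 0L) next
    o <- if (str[i] == "+") mid - tss[i] else tss[i] - mid
    o <- o[o >= search[1] & o <= search[2]]
    if (length(o)) off[i] <- max(o)  # nearest to the TSS
  }
  data.frame(gene_id = ids, offset = off)
}

#' Write a meta-gene profile as TSV
#'
#' @param profile a [MetaProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  df <- data.frame(offset = profile@offsets,
                   mean_occupancy = profile@occupancy,
                   n_genes = profile@nGenes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
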