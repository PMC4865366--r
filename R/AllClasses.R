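#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# GenomeAnnotation
# ---------------------------------------------------------------------------

#' Genome annotation: chromosome lengths and gene TSS records
#'
#' Holds the gene annotation the pipeline anchors on: a `GRanges` of gene
#' bodies whose `seqinfo` carries the chromosome lengths and whose metadata
#' column `gene_id` identifies each gene. The transcription start site (TSS)
#' of a gene is the 5' end of its range: `start` on the `+` strand, `end` on
#' the `-` strand.
#'
#' @slot genes `GRanges` of gene bodies with `mcols()$gene_id` and a fully
#'   specified `seqinfo` (all `seqlengths` known).
#' @seealso [readAnnotation()], [generateAnnotation()], [tssPositions()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation", slots = c(genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  sl <- GenomeInfoDb::seqlengths(g)
  if (length(sl) == 0L || anyNA(sl))
    msg <- c(msg, "all chromosome lengths must be known in seqinfo")
  if (length(g) > 0L) {
    if (is.null(mcols(g)$gene_id))
      msg <- c(msg, "genes must carry a 'gene_id' metadata column")
    else if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, sprintf(
        "duplicate gene_id: %s",
        paste(unique(mcols(g)$gene_id[duplicated(mcols(g)$gene_id)]),
              collapse = ", ")))
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    if (!anyNA(sl)) {
      lens <- sl[as.character(seqnames(g))]
      if (any(start(g) < 1L) || any(end(g) > lens))
        msg <- c(msg, "gene coordinates outside chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes either a `GRanges` with a `gene_id` metadata column, or a
#'   `data.frame` with columns `gene_id`, `chrom`, `tss` (1-based position of
#'   the TSS base), `strand` (`+`/`-`) and optionally `start`/`end` for the
#'   gene body (defaulting to the TSS base itself).
#' @param chromLengths named integer vector of chromosome lengths; required
#'   when `genes` is a `data.frame` or a `GRanges` without `seqlengths`.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' df <- data.frame(gene_id = "g1", chrom = "chrI", tss = 1000, strand = "+")
#' GenomeAnnotation(df, chromLengths = c(chrI = 5000))
#' @export
GenomeAnnotation <- function(genes, chromLengths = NULL) {
  if (is.data.frame(genes)) {
    if (is.null(chromLengths))
      stop("'chromLengths' is required when genes are given as a data.frame")
    if (nrow(genes) == 0L) {
      gr <- GRanges(seqinfo = Seqinfo(names(chromLengths),
                                      as.integer(chromLengths)))
      mcols(gr)$gene_id <- character(0)
    } else {
      startCol <- if ("start" %in% names(genes)) genes$start else genes$tss
      endCol <- if ("end" %in% names(genes)) genes$end else genes$tss
      gr <- GRanges(genes$chrom, IRanges(startCol, endCol),
                    strand = genes$strand,
                    seqinfo = Seqinfo(names(chromLengths),
                                      as.integer(chromLengths)))
      mcols(gr)$gene_id <- as.character(genes$gene_id)
    }
    genes <- gr
  } else if (!is.null(chromLengths)) {
    GenomeInfoDb::seqlengths(genes) <- as.integer(
      chromLengths[GenomeInfoDb::seqlevels(genes)])
  }
  new("GenomeAnnotation", genes = genes)
}

#' @describeIn GenomeAnnotation-class number of genes
#' @param x,object a `GenomeAnnotation`
#' @export
setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  sl <- GenomeInfoDb::seqlengths(object@genes)
  cat("GenomeAnnotation with", length(object@genes), "genes on",
      length(sl), "chromosomes (", sum(as.numeric(sl)), "bp )\n")
})

#' Accessors for GenomeAnnotation
#'
#' `genes()` returns the gene `GRanges`; `geneIds()` the gene identifiers;
#' `chromLengths()` the named chromosome length vector; `tssPositions()` the
#' 1-based TSS coordinate of each gene (start of the range on `+`, end on
#' `-`), named by `gene_id`.
#'
#' @param x a [GenomeAnnotation-class]
#' @return See each description.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
genes <- function(x) x@genes

#' @rdname annotation-accessors
#' @export
geneIds <- function(x) as.character(mcols(x@genes)$gene_id)

#' @rdname annotation-accessors
#' @export
chromLengths <- function(x) {
  sl <- GenomeInfoDb::seqlengths(x@genes)
  setNames(as.integer(sl), names(sl))
}

#' @rdname annotation-accessors
#' @export
tssPositions <- function(x) {
  g <- x@genes
  tss <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
  setNames(as.integer(tss), mcols(g)$gene_id)
}

#' @rdname annotation-accessors
#' @export
geneStrands <- function(x) {
  setNames(as.character(strand(x@genes)), mcols(x@genes)$gene_id)
}

# ---------------------------------------------------------------------------
# FragmentSet
# ---------------------------------------------------------------------------

#' A set of aligned MNase-seq fragments for one sample
#'
#' Wraps a `GRanges` of fragment intervals (1-based, closed) with a sample
#' identifier. When `isPoint` is `TRUE` the records are width-1 points: either
#' single-end 5' read ends (before shifting) or adjusted fragment centres
#' (after [shiftFragments()]).
#'
#' @slot fragments `GRanges` of fragment intervals or points, strand `+`/`-`.
#' @slot sampleId single character sample label.
#' @slot isPoint logical flag, see description.
#' @seealso [readFragments()], [simulateFragments()], [shiftFragments()]
#' @exportClass FragmentSet
setClass("FragmentSet",
         slots = c(fragments = "GRanges", sampleId = "character",
                   isPoint = "logical"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@isPoint) != 1L)
    msg <- c(msg, "isPoint must be a single logical")
  if (length(object@fragments) > 0L) {
    if (any(width(object@fragments) < 1L))
      msg <- c(msg, "fragments must have width >= 1 (start < end)")
    if (isTRUE(object@isPoint) && any(width(object@fragments) != 1L))
      msg <- c(msg, "point-mode fragments must have width 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#'
#' @param fragments `GRanges` of fragment intervals.
#' @param sampleId sample label.
#' @param isPoint are records width-1 points (single-end 5' ends or adjusted
#'   centres) rather than full fragments?
#' @return A [FragmentSet-class].
#' @export
FragmentSet <- function(fragments, sampleId = "sample", isPoint = FALSE) {
  new("FragmentSet", fragments = fragments, sampleId = sampleId,
      isPoint = isPoint)
}

#' @describeIn FragmentSet-class number of fragment records
#' @param x,object a `FragmentSet`
#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet '", object@sampleId, "': ", length(object@fragments),
      if (object@isPoint) " point records\n" else " fragments\n", sep = "")
})

#' Fragment records of a FragmentSet
#' @param x a [FragmentSet-class]
#' @return the underlying `GRanges`
#' @export
fragments <- function(x) x@fragments

#' Sample identifier
#' @param x a [FragmentSet-class] or [OccupancyTrack-class]
#' @return single character label
#' @export
sampleId <- function(x) x@sampleId

# ---------------------------------------------------------------------------
# OccupancyTrack
# ---------------------------------------------------------------------------

#' Per-base-pair nucleosome occupancy over a genome
#'
#' Dense per-chromosome numeric vectors of occupancy (adjusted reads covering
#' each base pair), either raw counts or quantile-normalised values.
#'
#' @slot values named list of per-chromosome numeric vectors; the length of
#'   each vector is the chromosome length.
#' @slot sampleId sample label.
#' @slot normalization `"raw"` or `"quantile"`.
#' @seealso [computeOccupancy()], [quantileNormalize()], [writeTrack()]
#' @exportClass OccupancyTrack
setClass("OccupancyTrack",
         slots = c(values = "list", sampleId = "character",
                   normalization = "character"))

setValidity("OccupancyTrack", function(object) {
  msg <- character()
  if (!object@normalization %in% c("raw", "quantile"))
    msg <- c(msg, "normalization must be 'raw' or 'quantile'")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must be a uniquely named list of chromosomes")
  for (v in object@values) {
    if (!is.numeric(v)) { msg <- c(msg, "values must be numeric"); break }
    if (anyNA(v) || any(!is.finite(v))) {
      msg <- c(msg, "occupancy values must be finite"); break
    }
    if (any(v < 0)) { msg <- c(msg, "occupancy values must be >= 0"); break }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OccupancyTrack
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param sampleId sample label.
#' @param normalization `"raw"` or `"quantile"`.
#' @return An [OccupancyTrack-class].
#' @export
OccupancyTrack <- function(values, sampleId = "sample",
                           normalization = "raw") {
  new("OccupancyTrack", values = values, sampleId = sampleId,
      normalization = normalization)
}

setMethod("show", "OccupancyTrack", function(object) {
  cat("OccupancyTrack '", object@sampleId, "' (", object@normalization,
      "): ", length(object@values), " chromosomes, ",
      sum(vapply(object@values, length, 0L)), " bp\n", sep = "")
})

#' Per-chromosome occupancy values
#' @param x an [OccupancyTrack-class]
#' @return named list of numeric vectors
#' @export
trackValues <- function(x) x@values

#' Normalization state of a track
#' @param x an [OccupancyTrack-class]
#' @return `"raw"` or `"quantile"`
#' @export
normalizationState <- function(x) x@normalization

# ---------------------------------------------------------------------------
# NucleosomeMap (simulation ground truth)
# ---------------------------------------------------------------------------

#' Ground-truth nucleosome map for simulated genomes
#'
#' Per gene: the true NDR interval and the midpoints of the phased
#' nucleosomes flanking it, labelled relative to the TSS (`-1` immediately
#' upstream of the NDR, `+1` immediately downstream, upstream meaning against
#' the direction of transcription).
#'
#' @slot ndr data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `ndr_start`, `ndr_end` (1-based, closed; length = end - start + 1).
#' @slot nucleosomes data.frame with columns `gene_id`, `chrom`, `label`
#'   (e.g. "-2", "-1", "+1"), `midpoint`.
#' @slot annotation the [GenomeAnnotation-class] the map was built on.
#' @slot footprint nucleosome footprint (bp) used to build the map.
#' @seealso [generateTruthMap()], [plantShrinkage()]
#' @exportClass NucleosomeMap
setClass("NucleosomeMap",
         slots = c(ndr = "data.frame", nucleosomes = "data.frame",
                   annotation = "GenomeAnnotation", footprint = "numeric"))

setValidity("NucleosomeMap", function(object) {
  msg <- character()
  need <- c("gene_id", "chrom", "strand", "tss", "ndr_start", "ndr_end")
  if (!all(need %in% names(object@ndr)))
    msg <- c(msg, "ndr table lacks required columns")
  needN <- c("gene_id", "chrom", "label", "midpoint")
  if (!all(needN %in% names(object@nucleosomes)))
    msg <- c(msg, "nucleosome table lacks required columns")
  if (length(msg) == 0L && nrow(object@ndr) > 0L) {
    if (any(object@ndr$ndr_end < object@ndr$ndr_start))
      msg <- c(msg, "NDR end before start")
    # adjacent midpoints at least one footprint apart
    sp <- split(object@nucleosomes$midpoint, object@nucleosomes$gene_id)
    gaps <- unlist(lapply(sp, function(m) diff(sort(m))), use.names = FALSE)
    if (length(gaps) && any(gaps < object@footprint))
      msg <- c(msg, "adjacent nucleosome midpoints closer than one footprint")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "NucleosomeMap", function(object) {
  cat("NucleosomeMap:", nrow(object@ndr), "genes,",
      nrow(object@nucleosomes), "nucleosomes, footprint",
      object@footprint, "bp\n")
})

#' Ground-truth NDR table
#' @param x a [NucleosomeMap-class]
#' @return data.frame of true NDR intervals (`length` column included)
#' @export
truthNdr <- function(x) {
  d <- x@ndr
  d$length <- d$ndr_end - d$ndr_start + 1L
  d
}

#' Ground-truth nucleosome midpoints
#' @param x a [NucleosomeMap-class]
#' @return data.frame of labelled midpoints
#' @export
truthNucleosomes <- function(x) x@nucleosomes

# ---------------------------------------------------------------------------
# ClonalFilterResult
# ---------------------------------------------------------------------------

#' Result of the Poisson clonal-read filter
#'
#' @slot retained the retained [FragmentSet-class].
#' @slot removedCount number of fragments removed.
#' @slot lambda genome-wide mean fragment count per base pair used as the
#'   Poisson rate.
#' @slot countThreshold smallest count whose Poisson upper-tail probability
#'   falls below the cutoff; per-position stacks are trimmed to this depth.
#' @seealso [removeClonalReads()]
#' @exportClass ClonalFilterResult
setClass("ClonalFilterResult",
         slots = c(retained = "FragmentSet", removedCount = "integer",
                   lambda = "numeric", countThreshold = "integer"))

setValidity("ClonalFilterResult", function(object) {
  if (object@countThreshold < 1L) "countThreshold must be >= 1" else TRUE
})

setMethod("show", "ClonalFilterResult", function(object) {
  cat("ClonalFilterResult: removed", object@removedCount,
      "of", length(object@retained) + object@removedCount,
      "fragments (lambda =", signif(object@lambda, 4),
      ", count threshold =", object@countThreshold, ")\n")
})

#' Retained fragments after clonal filtering
#' @param x a [ClonalFilterResult-class]
#' @return a [FragmentSet-class]
#' @export
retainedFragments <- function(x) x@retained

# ---------------------------------------------------------------------------
# DifferentialSignal
# ---------------------------------------------------------------------------

#' Per-bp Poisson differential occupancy between two conditions
#'
#' @slot pvalues named list of per-chromosome p-value vectors.
#' @slot direction named list of per-chromosome sign vectors (+1 where the
#'   second condition is higher, -1 lower, 0 equal).
#' @slot regions `GRanges` of called dynamic regions with metadata columns
#'   `direction` and `score` (-log10 of the minimum p in the region).
#' @slot cutoff per-bp p-value cutoff used to define regions.
#' @seealso [differentialSignal()]
#' @exportClass DifferentialSignal
setClass("DifferentialSignal",
         slots = c(pvalues = "list", direction = "list",
                   regions = "GRanges", cutoff = "numeric"))

setMethod("show", "DifferentialSignal", function(object) {
  cat("DifferentialSignal:", sum(vapply(object@pvalues, length, 0L)),
      "bp scored,", length(object@regions),
      "dynamic regions at p <", object@cutoff, "\n")
})

#' Dynamic regions of a differential signal
#' @param x a [DifferentialSignal-class]
#' @return `GRanges` with `direction` and `score`
#' @export
dynamicRegions <- function(x) x@regions

#' Per-bp p-values of a differential signal
#' @param x a [DifferentialSignal-class]
#' @return named list of numeric vectors
#' @export
signalPvalues <- function(x) x@pvalues

# ---------------------------------------------------------------------------
# MetaProfile / Minus1Estimate
# ---------------------------------------------------------------------------

#' TSS-aligned average occupancy profile
#'
#' Mean occupancy per signed TSS offset (negative = upstream of the TSS in
#' the direction of transcription) over a gene set.
#'
#' @slot offsets integer vector of signed offsets.
#' @slot occupancy mean occupancy at each offset.
#' @slot nGenes number of genes averaged.
#' @slot condition sample/condition label.
#' @seealso [metageneProfile()], [locateMinus1()]
#' @exportClass MetaProfile
setClass("MetaProfile",
         slots = c(offsets = "integer", occupancy = "numeric",
                   nGenes = "integer", condition = "character"))

setValidity("MetaProfile", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@occupancy))
    msg <- c(msg, "offsets and occupancy lengths differ")
  if (object@nGenes <= 0L) msg <- c(msg, "nGenes must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile '", object@condition, "': offsets ",
      min(object@offsets), "..", max(object@offsets), " over ",
      object@nGenes, " genes\n", sep = "")
})

#' Offsets / mean occupancy of a MetaProfile
#' @param x a [MetaProfile-class]
#' @return integer or numeric vector
#' @export
profileOffsets <- function(x) x@offsets

#' @rdname profileOffsets
#' @export
profileOccupancy <- function(x) x@occupancy

#' Location of the -1 nucleosome in a meta-profile
#'
#' @slot offset signed TSS offset (bp) of the -1 nucleosome midpoint
#'   (negative = upstream).
#' @slot flagged `TRUE` when no interior maximum was found in the search
#'   range (monotone or flat profile); the offset is then unreliable.
#' @slot condition sample/condition label.
#' @seealso [locateMinus1()], [minus1Shift()]
#' @exportClass Minus1Estimate
setClass("Minus1Estimate",
         slots = c(offset = "numeric", flagged = "logical",
                   condition = "character"))

setMethod("show", "Minus1Estimate", function(object) {
  cat("Minus1Estimate '", object@condition, "': ",
      if (object@flagged) "flagged (no interior maximum)"
      else paste0(abs(object@offset), " bp upstream of TSS (offset ",
                  object@offset, ")"), "\n", sep = "")
})

#' Signed TSS offset of a -1 nucleosome estimate
#' @param x a [Minus1Estimate-class]
#' @return numeric offset (negative = upstream); `NA` if flagged
#' @export
minus1Offset <- function(x) if (x@flagged) NA_real_ else x@offset

#' Is a -1 nucleosome estimate flagged as unreliable?
#' @param x a [Minus1Estimate-class]
#' @return logical
#' @export
isFlagged <- function(x) x@flagged
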