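#' @include AllClasses.R
NULL

#' Read aligned MNase-seq fragments from BED or SAM/BAM
#'
#' BED input (0-based, half-open) is converted to the internal 1-based,
#' closed convention. For SAM/BAM, unmapped, secondary and supplementary
#' records are skipped (and counted); properly paired reads yield one
#' fragment per template (leftmost position plus template length, counted
#' once via the mate with positive TLEN), while single-end reads become
#' width-1 point records at their 5' end, to be extended by the shifting
#' step.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"`, `"sam"` or `"bam"`.
#' @param sampleId sample label; defaults to the file base name.
#' @param chromLengths optional named vector of chromosome lengths to attach
#'   as seqinfo; chromosomes present in the file but absent from this vector
#'   raise an error.
#' @return A [FragmentSet-class]. The number of skipped alignment records is
#'   reported via `message()` and stored in `metadata` as attribute
#'   `skipped`.
#' @export
readFragments <- function(path, format = c("auto", "bed", "sam", "bam"),
                          sampleId = NULL,
                          chromLengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "bed") {
    fs <- .readFragmentsBed(path, sampleId)
  } else {
    fs <- .readFragmentsBam(path, format, sampleId)
  }
  if (!is.null(chromLengths)) {
    bad <- setdiff(GenomeInfoDb::seqlevels(fs@fragments),
                   names(chromLengths))
    if (length(bad))
      stop("unknown chromosome(s) in ", path, ": ",
           paste(bad, collapse = ", "))
    gr <- fs@fragments
    si <- Seqinfo(names(chromLengths), as.integer(chromLengths))
    GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
    seqinfo(gr) <- si
    fs@fragments <- gr
  }
  fs
}

.readFragmentsBed <- function(path, sampleId) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(FragmentSet(GRanges(), sampleId = sampleId, isPoint = FALSE))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], " in ", path)
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(s0) || anyNA(e0))
    stop("malformed BED line ", which(is.na(s0) | is.na(e0))[1],
         " in ", path)
  strandCol <- rep("*", length(lines))
  has6 <- nf >= 6L
  strandCol[has6] <- vapply(fields[has6], `[`, "", 6L)
  strandCol[!strandCol %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(s0 + 1, e0), strand = strandCol)
  FragmentSet(gr, sampleId = sampleId,
              isPoint = all(width(gr) == 1L) && length(gr) > 0L)
}

.readFragmentsBam <- function(path, format, sampleId) {
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(asBam(path, destination = dest,
                                  overwrite = TRUE, indexDestination = FALSE))
  }
  # count skipped records (unmapped/secondary/supplementary)
  allFlags <- scanBam(bam, param = ScanBamParam(what = "flag"))[[1]]$flag
  skipMask <- bitwAnd(allFlags, 0x4L) > 0 | bitwAnd(allFlags, 0x100L) > 0 |
    bitwAnd(allFlags, 0x800L) > 0
  nSkipped <- sum(skipMask)
  param <- ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "flag", "isize"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE))
  b <- scanBam(bam, param = param)[[1]]
  if (length(b$pos) == 0L) {
    message("readFragments: 0 records kept, ", nSkipped, " skipped")
    fs <- FragmentSet(GRanges(), sampleId = sampleId, isPoint = FALSE)
    attr(fs@fragments, "skipped") <- nSkipped
    return(fs)
  }
  paired <- bitwAnd(b$flag, 0x1L) > 0
  proper <- bitwAnd(b$flag, 0x2L) > 0
  if (any(paired & proper)) {
    # one fragment per template: take the mate with positive TLEN
    keep <- paired & proper & !is.na(b$isize) & b$isize > 0
    gr <- GRanges(b$rname[keep],
                  IRanges(b$pos[keep], width = b$isize[keep]), strand = "+")
    isPoint <- FALSE
    # single-end leftovers handled below as points
    se <- !paired
  } else {
    gr <- GRanges()
    se <- rep(TRUE, length(b$pos))
    isPoint <- TRUE
  }
  if (any(se)) {
    minus <- as.character(b$strand[se]) == "-"
    p5 <- ifelse(minus, b$pos[se] + b$qwidth[se] - 1L, b$pos[se])
    grSe <- GRanges(b$rname[se], IRanges(p5, width = 1L),
                    strand = ifelse(minus, "-", "+"))
    gr <- c(gr, grSe)
    isPoint <- length(gr) == length(grSe)
  }
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  message("readFragments: ", length(gr), " records kept, ",
          nSkipped, " skipped")
  fs <- FragmentSet(gr, sampleId = sampleId, isPoint = isPoint)
  attr(fs@fragments, "skipped") <- nSkipped
  fs
}

#' Write fragments as 6-column BED
#'
#' Converts from the internal 1-based closed convention to BED's 0-based
#' half-open coordinates. Name is `.`, score 0.
#'
#' @param x a [FragmentSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFragmentsBed <- function(x, path) {
  stopifnot(is(x, "FragmentSet"))
  gr <- x@fragments
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), name = ".",
                   score = 0L, strand = as.character(strand(gr)))
  df$strand[!df$strand %in% c("+", "-")] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from GFF3 or TSV
#'
#' GFF3 (1-based, inclusive) gene features must carry an `ID` attribute; the
#' TSS is `start` on the `+` strand and `end` on the `-` strand. Chromosome
#' lengths are taken from `##sequence-region` directives unless supplied.
#' The TSV dialect has columns `gene_id`, `chrom`, `tss` (1-based TSS base),
#' `strand`, with chromosome lengths either in `##chrom <name> <length>`
#' header lines or via `chromLengths`.
#'
#' @param path input file.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @param chromLengths optional named vector of chromosome lengths
#'   (overrides lengths found in the file).
#' @param featureType GFF3 feature type to keep (default `"gene"`).
#' @return A [GenomeAnnotation-class]. Duplicate gene ids or genes outside
#'   chromosome bounds raise errors.
#' @export
readAnnotation <- function(path, format = c("auto", "gff3", "tsv"),
                           chromLengths = NULL, featureType = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
    else if (ext %in% c("tsv", "txt")) "tsv"
    else stop("cannot infer format from extension '.", ext, "'")
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == featureType]
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(ids == ""))
      stop("GFF3 ", featureType, " features must carry an ID attribute")
    if (is.null(chromLengths)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (length(sl) && !anyNA(sl)) {
        chromLengths <- sl
      } else {
        # parse ##sequence-region pragmas ourselves
        prag <- grep("^##sequence-region", readLines(path), value = TRUE)
        if (length(prag) == 0L)
          stop("chromosome lengths unavailable: add ##sequence-region ",
               "directives or pass chromLengths")
        parts <- strsplit(trimws(prag), "[ \t]+")
        chromLengths <- setNames(
          as.integer(vapply(parts, `[`, "", 4L)),
          vapply(parts, `[`, "", 2L))
      }
    }
    df <- data.frame(gene_id = ids,
                     chrom = as.character(seqnames(gr)),
                     tss = ifelse(as.character(strand(gr)) == "+",
                                  start(gr), end(gr)),
                     strand = as.character(strand(gr)),
                     start = start(gr), end = end(gr))
  } else {
    lines <- readLines(path)
    clLines <- grep("^##chrom\t", lines, value = TRUE)
    if (is.null(chromLengths)) {
      if (length(clLines) == 0L)
        stop("chromosome lengths unavailable: add '##chrom name length' ",
             "header lines or pass chromLengths")
      parts <- strsplit(clLines, "\t")
      chromLengths <- setNames(
        as.integer(vapply(parts, `[`, "", 3L)),
        vapply(parts, `[`, "", 2L))
    }
    df <- read.table(text = lines[!startsWith(lines, "##")], sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df)))
      stop("TSV annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  badChrom <- setdiff(df$chrom, names(chromLengths))
  if (length(badChrom))
    stop("unknown chromosome(s): ", paste(badChrom, collapse = ", "))
  out <- df$tss < 1 | df$tss > chromLengths[df$chrom]
  if (any(out))
    stop("gene(s) outside chromosome bounds: ",
         paste(df$gene_id[out], collapse = ", "))
  GenomeAnnotation(df, chromLengths = chromLengths)
}

#' Write a gene annotation as TSV
#'
#' Writes `##chrom` header lines with chromosome lengths followed by a tab
#' table (`gene_id`, `chrom`, `tss`, `strand`), the dialect
#' [readAnnotation()] reads back.
#'
#' @param x a [GenomeAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(x, path) {
  stopifnot(is(x, "GenomeAnnotation"))
  cl <- chromLengths(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##chrom\t%s\t%d", names(cl), cl), con)
  df <- data.frame(gene_id = geneIds(x),
                   chrom = as.character(seqnames(genes(x))),
                   tss = unname(tssPositions(x)),
                   strand = unname(geneStrands(x)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an occupancy track as bedGraph or wiggle
#'
#' Runs of equal values are collapsed (bedGraph) or written as fixedStep
#' wiggle. Values are formatted with 17 significant digits so that
#' `readTrack(writeTrack(x))` reproduces every base-pair value bit-exactly.
#'
#' @param track an [OccupancyTrack-class] (finite, non-negative values).
#' @param path output file.
#' @param format `"bedGraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, format = c("bedGraph", "wig")) {
  stopifnot(is(track, "OccupancyTrack"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    if (length(v) == 0L) next
    if (format == "bedGraph") {
      r <- rle(v)
      e <- cumsum(r$lengths)
      s <- e - r$lengths  # 0-based starts
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, s, e,
                         .fmtNum(r$values)), con)
    } else {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
      writeLines(.fmtNum(v), con)
    }
  }
  invisible(path)
}

#' Read an occupancy track from bedGraph or wiggle
#'
#' @param path input file.
#' @param chromLengths named vector of chromosome lengths (defines the dense
#'   vectors; bases not covered by any interval get 0).
#' @param sampleId sample label; defaults to the file base name.
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @param normalization normalization state to record (`"raw"` or
#'   `"quantile"`).
#' @return An [OccupancyTrack-class].
#' @export
readTrack <- function(path, chromLengths, sampleId = NULL,
                      format = c("auto", "bedGraph", "wig"),
                      normalization = "raw") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(file_ext(path))
    format <- if (ext %in% c("bedgraph", "bg")) "bedGraph"
    else if (ext == "wig") "wig"
    else stop("cannot infer format from extension '.", ext, "'")
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  values <- lapply(chromLengths, function(n) numeric(n))
  names(values) <- names(chromLengths)
  if (format == "bedGraph") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "value"),
                     colClasses = c("character", "numeric", "numeric",
                                    "numeric"))
    bad <- setdiff(unique(df$chrom), names(chromLengths))
    if (length(bad))
      stop("unknown chromosome(s) in ", path, ": ",
           paste(bad, collapse = ", "))
    for (chrom in unique(df$chrom)) {
      sub <- df[df$chrom == chrom, ]
      v <- values[[chrom]]
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
      values[[chrom]] <- v
    }
  } else {
    lines <- readLines(path)
    heads <- grep("^fixedStep", lines)
    if (length(heads) == 0L) stop("no fixedStep headers in ", path)
    bounds <- c(heads, length(lines) + 1L)
    for (i in seq_along(heads)) {
      h <- lines[heads[i]]
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", h)
      startPos <- as.integer(sub(".*start=([0-9]+).*", "\\1", h))
      if (!chrom %in% names(chromLengths))
        stop("unknown chromosome in ", path, ": ", chrom)
      block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
      vals <- as.numeric(block)
      values[[chrom]][startPos + seq_along(vals) - 1L] <- vals
    }
  }
  OccupancyTrack(values, sampleId = sampleId, normalization = normalization)
}

#' Write a ground-truth nucleosome map as TSV
#'
#' One row per NDR (`nuc_label = "NDR"`, midpoint empty) and one row per
#' nucleosome with its labelled midpoint.
#'
#' @param truth a [NucleosomeMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthMapTsv <- function(truth, path) {
  stopifnot(is(truth, "NucleosomeMap"))
  ndr <- truth@ndr
  a <- data.frame(gene_id = ndr$gene_id, ndr_start = ndr$ndr_start,
                  ndr_end = ndr$ndr_end, nuc_label = "NDR",
                  midpoint = NA_real_)
  nuc <- truth@nucleosomes
  b <- data.frame(gene_id = nuc$gene_id, ndr_start = NA_real_,
                  ndr_end = NA_real_, nuc_label = nuc$label,
                  midpoint = nuc$midpoint)
  out <- rbind(a, b)
  out <- out[order(out$gene_id), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
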