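#' @include AllClasses.R
NULL

# Single-locus ChIP and qPCR quantifications. Quantities are post-standard-
# curve arbitrary units; Ct-to-quantity conversion is out of scope.

.checkAmplicons <- function(a, b) {
  if (!is.null(a) && !is.null(b) && !identical(as.character(a),
                                               as.character(b)))
    stop("amplicon mismatch between the two measurements")
}

#' Percent immunoprecipitation
#'
#' `100 * IP / (input * dilution)`: the percentage of input chromatin
#' recovered in the immunoprecipitate, the standard ChIP normalisation.
#' Vectorised over amplicons.
#'
#' @param ip,input qPCR quantities (> 0) for the IP and input samples.
#' @param inputDilution dilution factor of the input relative to the IP
#'   (> 0).
#' @param amplicon optional amplicon ids for both vectors; a mismatch is an
#'   error.
#' @return Numeric vector of percent-IP values.
#' @export
percentIp <- function(ip, input, inputDilution = 1, amplicon = NULL) {
  .assertScalarNumber(inputDilution, "inputDilution", min = 0,
                      strictMin = TRUE)
  if (any(ip < 0) || any(input <= 0))
    stop("quantities must be positive")
  100 * ip / (input * inputDilution)
}

#' Modified-over-unmodified histone ChIP ratio
#'
#' Ratio of a modification-specific ChIP signal to the matching unmodified
#' histone signal from the same chromatin sample (e.g. H2Bubi/H2B,
#' H3K4me3/H3, H3K14ac/H3), cancelling nucleosome occupancy differences.
#'
#' @param modified,unmodified normalised signals (e.g. percent IP) for the
#'   modification and the unmodified histone.
#' @param amplicon optional amplicon ids for both vectors.
#' @return Numeric vector of ratios.
#' @export
modifiedOverUnmodified <- function(modified, unmodified, amplicon = NULL) {
  if (any(unmodified == 0)) stop("unmodified signal of 0: ratio undefined")
  modified / unmodified
}

#' Nucleosome-scanning enrichment profile
#'
#' Per amplicon tile, the ratio of qPCR product from the gel-purified
#' mononucleosomal DNA to that from the total (input) DNA of the same
#' culture. Across an ordered tile set spanning a locus, the resulting
#' vector is the nucleosome-scanning profile: maxima mark positioned
#' nucleosomes, minima linkers and NDRs.
#'
#' @param mono,total qPCR quantities per tile (same amplicon order).
#' @param amplicon optional tile ids for both vectors.
#' @return Numeric vector of enrichment ratios, named by `amplicon` when
#'   given.
#' @export
scanningEnrichment <- function(mono, total, amplicon = NULL) {
  .checkAmplicons(amplicon, amplicon)
  if (length(mono) != length(total))
    stop("mono and total tile vectors differ in length")
  if (any(total == 0)) stop("total quantity of 0: ratio undefined")
  r <- mono / total
  if (!is.null(amplicon)) names(r) <- as.character(amplicon)
  r
}

#' Relative expression normalised to act1 and a reference sample
#'
#' Fold change of a target mRNA relative to a reference (untreated) sample,
#' with the act1 mRNA as internal normaliser:
#' `(target/act1) / (reference_target/reference_act1)`.
#'
#' @param targetQ,act1Q quantities in the sample of interest (> 0).
#' @param refTargetQ,refAct1Q quantities in the reference sample (> 0).
#' @return Numeric fold change (arbitrary units; 1 for the reference).
#' @export
relativeExpression <- function(targetQ, act1Q, refTargetQ, refAct1Q) {
  if (any(c(act1Q, refTargetQ, refAct1Q) <= 0))
    stop("all normaliser and reference quantities must be > 0")
  (targetQ / act1Q) / (refTargetQ / refAct1Q)
}

#' Mean and standard error over replicates
#'
#' The mean +/- SEM aggregation used for bar plots of n = 2-4 replicate
#' measurements; SEM uses the n-1 sample standard deviation.
#'
#' @param x numeric vector of replicate values (n >= 2).
#' @return list with `mean`, `sem` and `n`.
#' @export
replicateSummary <- function(x) {
  if (length(x) < 2L) stop("need at least two replicates")
  list(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
}

#' Read a tidy qPCR measurement table
#'
#' TSV with columns `sample_id`, `amplicon_id`, `role` (one of `IP`,
#' `input`, `mononucleosomal`, `total`) and `quantity` (> 0).
#'
#' @param path input file.
#' @return data.frame of measurements.
#' @export
readQpcrTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "amplicon_id", "role", "quantity")
  if (!all(need %in% names(df)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  if (any(df$quantity <= 0)) stop("quantities must be > 0")
  df
}

#' Nucleosome-scanning profile from a tidy measurement table
#'
#' Joins the `mononucleosomal` and `total` rows of one sample by amplicon
#' and returns the tile-ordered enrichment profile.
#'
#' @param measurements data.frame from [readQpcrTable()].
#' @param sample sample id to profile.
#' @return data.frame with `amplicon_id` and `enrichment`, in the amplicon
#'   order of the mononucleosomal rows.
#' @export
scanningProfile <- function(measurements, sample) {
  m <- measurements[measurements$sample_id == sample &
                      measurements$role == "mononucleosomal", ]
  t <- measurements[measurements$sample_id == sample &
                      measurements$role == "total", ]
  if (nrow(m) == 0L || nrow(t) == 0L)
    stop("sample '", sample, "' lacks mononucleosomal or total rows")
  t <- t[match(m$amplicon_id, t$amplicon_id), ]
  if (anyNA(t$quantity))
    stop("total rows missing for amplicon(s): ",
         paste(m$amplicon_id[is.na(t$quantity)], collapse = ", "))
  data.frame(amplicon_id = m$amplicon_id,
             enrichment = scanningEnrichment(m$quantity, t$quantity))
}
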