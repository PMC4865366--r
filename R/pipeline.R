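#' @include AllClasses.R
NULL

.pipelineDefaults <- list(
  p_cutoff = 1e-10, proximity = 65, fraction = 0.10, ndr_window = 1000,
  meta_window = 500, smooth_window = 73, min_distance = 147,
  extend = NA, region_cutoff = 1e-10, seed = 1)

#' Build or read a pipeline configuration
#'
#' `pipelineConfig()` assembles a validated configuration list;
#' `readPipelineConfig()` reads the same structure from a versioned YAML
#' file (schema version 1; unknown keys are errors, not warnings, so typos
#' cannot silently change an analysis).
#'
#' @param conditionA,conditionB named lists with elements `name` (condition
#'   label) and `fragments` (path to a BED/SAM/BAM fragment file).
#' @param annotation path to a GFF3/TSV gene annotation.
#' @param outDir output directory.
#' @param params named list overriding analysis parameters: `p_cutoff`
#'   (clonal filter, default 1e-10), `proximity` (NDR proximity rule, 65
#'   bp), `fraction` (shrinkage selection, 0.10), `ndr_window` (1000 bp),
#'   `meta_window` (500 bp), `smooth_window` (73 bp), `min_distance` (147
#'   bp), `extend` (occupancy window; `NA` = estimated fragment size),
#'   `region_cutoff` (1e-10), `seed`.
#' @param compareGeneList optional path to a gene list (one id per line) to
#'   test for overlap against the selected shrinkage set.
#' @return A validated configuration list of class `ndr_pipeline_config`.
#' @export
pipelineConfig <- function(conditionA, conditionB, annotation, outDir,
                           params = list(), compareGeneList = NULL) {
  bad <- setdiff(names(params), names(.pipelineDefaults))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(.pipelineDefaults, params)
  for (cond in list(conditionA, conditionB))
    if (!all(c("name", "fragments") %in% names(cond)))
      stop("each condition needs 'name' and 'fragments'")
  cfg <- list(version = 1L,
              conditionA = conditionA, conditionB = conditionB,
              annotation = annotation, outDir = outDir, params = p,
              compareGeneList = compareGeneList)
  class(cfg) <- "ndr_pipeline_config"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML configuration file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("version", "conditionA", "conditionB", "annotation", "outDir",
             "params", "compareGeneList")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(y$version) || y$version != 1L)
    stop("unsupported or missing config schema version (expected 1)")
  pipelineConfig(y$conditionA, y$conditionB, y$annotation, y$outDir,
                 params = if (is.null(y$params)) list() else y$params,
                 compareGeneList = y$compareGeneList)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full wild-type-versus-mutant NDR comparison
#'
#' Executes the whole pipeline on two conditions: read fragments and
#' annotation, remove clonal reads (Poisson cutoff), estimate the fragment
#' size, shift reads by half of it, compute per-bp occupancy, quantile-
#' normalise the two tracks together, quantify TSS-anchored NDR lengths in
#' both conditions, rank genes by NDR shrinkage and select the top
#' fraction, build meta-gene profiles (all genes and the selected subset)
#' with the -1 nucleosome shift, call the per-bp Poisson differential
#' signal, and optionally test the selected set for overlap against a
#' supplied gene list. All tables are TSV, tracks bedGraph, gene sets plain
#' text; a machine-readable JSON-like manifest (versions, parameters, input
#' checksums) accompanies the run. Reruns with an identical configuration
#' produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()] or path to a YAML config.
#' @return Invisibly, a list with the main results: `ndrA`, `ndrB`,
#'   `deltas`, `selected`, `minus1ShiftBp`, `overlap` (or `NULL`),
#'   `threshold`, and the paths of all written files.
#' @export
runComparison <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "ndr_pipeline_config"))
  p <- config$params
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)

  ann <- .stage("read_annotation", readAnnotation(config$annotation))
  loadCond <- function(cond) {
    fs <- .stage(paste0("read_fragments[", cond$name, "]"),
                 readFragments(cond$fragments,
                               chromLengths = chromLengths(ann),
                               sampleId = cond$name))
    filt <- .stage(paste0("clonal_filter[", cond$name, "]"),
                   removeClonalReads(fs, pCutoff = p$p_cutoff))
    fsize <- .stage(paste0("fragment_size[", cond$name, "]"),
                    estimateFragmentSize(retainedFragments(filt)))
    centres <- .stage(paste0("shift[", cond$name, "]"),
                      shiftFragments(retainedFragments(filt), fsize))
    extend <- if (is.na(p$extend)) fsize else p$extend
    track <- .stage(paste0("occupancy[", cond$name, "]"),
                    computeOccupancy(centres, ann, extend = extend))
    list(track = track, fsize = fsize, filter = filt)
  }
  a <- loadCond(config$conditionA)
  b <- loadCond(config$conditionB)
  norm <- .stage("quantile_normalize",
                 quantileNormalize(list(a$track, b$track)))
  trackA <- norm[[1]]; trackB <- norm[[2]]
  writeTrack(trackA, out(paste0(config$conditionA$name, ".bedGraph")))
  writeTrack(trackB, out(paste0(config$conditionB$name, ".bedGraph")))

  thr <- .stage("threshold", genomeOccupancyThreshold(trackA))
  ndrA <- .stage("ndr[A]", ndrLengths(trackA, ann, threshold = thr,
                                      proximity = p$proximity,
                                      window = p$ndr_window))
  ndrB <- .stage("ndr[B]", ndrLengths(trackB, ann, threshold = thr,
                                      proximity = p$proximity,
                                      window = p$ndr_window))
  writeNdrTsv(ndrA, out("ndr_A.tsv"))
  writeNdrTsv(ndrB, out("ndr_B.tsv"))
  deltas <- .stage("delta_ndr", deltaNdr(ndrA, ndrB))
  write.table(deltas, out("ndr_delta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  selected <- .stage("top_shrinkage",
                     topShrinkageFraction(deltas, fraction = p$fraction))
  writeGeneSet(selected, out("top_shrinkage_genes.txt"))

  profAllA <- .stage("metagene[A]",
                     metageneProfile(trackA, ann, window = p$meta_window))
  profAllB <- .stage("metagene[B]",
                     metageneProfile(trackB, ann, window = p$meta_window))
  profSelA <- .stage("metagene[A,selected]",
                     metageneProfile(trackA, ann, geneSet = selected,
                                     window = p$meta_window))
  profSelB <- .stage("metagene[B,selected]",
                     metageneProfile(trackB, ann, geneSet = selected,
                                     window = p$meta_window))
  writeProfileTsv(profAllA, out("metagene_all_A.tsv"))
  writeProfileTsv(profAllB, out("metagene_all_B.tsv"))
  writeProfileTsv(profSelA, out("metagene_selected_A.tsv"))
  writeProfileTsv(profSelB, out("metagene_selected_B.tsv"))
  shift <- tryCatch(
    minus1Shift(profSelA, profSelB, smoothWindow = p$smooth_window),
    error = function(e) NA_real_)

  diff <- .stage("differential_signal",
                 differentialSignal(trackA, trackB,
                                    regionCutoff = p$region_cutoff))
  writeDynamicRegionsBed(diff, out("dynamic_regions.bed"))

  overlap <- NULL
  if (!is.null(config$compareGeneList)) {
    other <- .stage("read_gene_list", readGeneSet(config$compareGeneList))
    overlap <- .stage("overlap_fisher",
                      overlapFisher(selected, other, geneIds(ann)))
  }

  manifest <- list(
    package = "NDRquant",
    version = as.character(packageVersion("NDRquant")),
    schema = 1L,
    parameters = p,
    fragment_size = list(A = a$fsize, B = b$fsize),
    clonal_removed = list(A = a$filter@removedCount,
                          B = b$filter@removedCount),
    threshold = thr,
    minus1_shift_bp = shift,
    overlap_p = if (is.null(overlap)) NULL else overlap$p.value,
    inputs = list(
      annotation = unname(md5sum(config$annotation)),
      A = unname(md5sum(config$conditionA$fragments)),
      B = unname(md5sum(config$conditionB$fragments))))
  writeLines(yaml::as.yaml(manifest), out("run_manifest.yaml"))

  invisible(list(ndrA = ndrA, ndrB = ndrB, deltas = deltas,
                 selected = selected, minus1ShiftBp = shift,
                 overlap = overlap, threshold = thr,
                 trackA = trackA, trackB = trackB,
                 outDir = config$outDir))
}
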