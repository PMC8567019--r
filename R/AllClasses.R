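#' MethylationExperiment: EPIC-like methylation container
#'
#' An S4 class extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. The mandatory `beta`
#' assay holds methylation fractions (probes x samples, values in \[0,1\]);
#' an optional `detectionP` assay of the same shape holds detection
#' p-values. `rowRanges()` is the probe manifest: a `GRanges` with metadata
#' columns `probeId`, `probeType` ("I"/"II" chemistry), `genes` and
#' `geneRegions` (parallel `CharacterList`s; region labels among TSS1500,
#' TSS200, 5UTR, Body, 3UTR, ExonBnd, IGR) and `islandContext` (Island,
#' Shore, Shelf, OpenSea). `colData()` is the sample sheet.
#'
#' @slot ... see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [MethylationExperiment()] the constructor, [betaValues()],
#'   [mValues()], [probeManifest()], [sampleSheet()]
#' @export
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

.validMethylationExperiment <- function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (anyNA(b))
      msg <- c(msg, "beta values must not contain missing values")
    else if (length(b) && (min(b) < 0 || max(b) > 1))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if ("detectionP" %in% SummarizedExperiment::assayNames(object)) {
    dp <- SummarizedExperiment::assay(object, "detectionP")
    if (length(dp) && (anyNA(dp) || min(dp) < 0 || max(dp) > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  needed <- c("probeId", "probeType", "genes", "geneRegions", "islandContext")
  missing <- setdiff(needed, colnames(mc))
  if (length(missing))
    msg <- c(msg, paste0("rowRanges() must carry metadata column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(missing) && nrow(mc)) {
    if (anyDuplicated(mc$probeId))
      msg <- c(msg, "probe ids must be unique")
    if (!all(mc$probeType %in% c("I", "II")))
      msg <- c(msg, "probeType must be 'I' or 'II'")
    if (!all(mc$islandContext %in% .ISLAND_CONTEXTS))
      msg <- c(msg, paste("islandContext must be one of",
                          paste(.ISLAND_CONTEXTS, collapse = ", ")))
    if (!all(lengths(mc$genes) == lengths(mc$geneRegions)))
      msg <- c(msg, "genes and geneRegions must have equal per-probe length")
    regs <- unlist(mc$geneRegions, use.names = FALSE)
    if (length(regs) && !all(regs %in% .GENE_REGIONS))
      msg <- c(msg, paste("gene region labels must be among",
                          paste(.GENE_REGIONS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("MethylationExperiment", .validMethylationExperiment)

#' ScoreModel: healthy-control reference for the methylation activity score
#'
#' Frozen parameters of the methylation disease-activity score: the selected
#' probes, their healthy-control means and standard deviations on the beta
#' scale, and the PASI selection correlations that admitted them. A sample's
#' score is the sum over selected probes of the standardized value
#' SV = (beta - meanHC) / sdHC.
#'
#' @slot probeIds character, selected probe ids.
#' @slot meanHC numeric, per-probe healthy-control mean beta.
#' @slot sdHC numeric, per-probe healthy-control SD (n-1 denominator), > 0.
#' @slot rSel numeric, per-probe Pearson correlation between beta and PASI
#'   used at selection time (NA when the model was built without selection).
#' @slot rThreshold numeric(1), the |r| cutoff applied at selection.
#' @seealso [fitScoreModel()], [computeScores()]
#' @export
setClass("ScoreModel",
         representation(probeIds = "character", meanHC = "numeric",
                        sdHC = "numeric", rSel = "numeric",
                        rThreshold = "numeric"),
         prototype(probeIds = character(), meanHC = numeric(),
                   sdHC = numeric(), rSel = numeric(), rThreshold = 0.8))

setValidity("ScoreModel", function(object) {
  msg <- character()
  n <- length(object@probeIds)
  if (length(object@meanHC) != n || length(object@sdHC) != n ||
      length(object@rSel) != n)
    msg <- c(msg, "probeIds, meanHC, sdHC and rSel must have equal length")
  if (anyDuplicated(object@probeIds))
    msg <- c(msg, "selected probe ids must be unique")
  if (length(object@sdHC) && any(object@sdHC <= 0))
    msg <- c(msg, "sdHC must be strictly positive for every selected probe")
  if (length(object@rThreshold) != 1L || object@rThreshold < 0 ||
      object@rThreshold >= 1)
    msg <- c(msg, "rThreshold must be a single value in [0, 1)")
  ok <- is.na(object@rSel) | abs(object@rSel) > object@rThreshold
  if (length(ok) && !all(ok))
    msg <- c(msg, "|rSel| must exceed rThreshold for every selected probe")
  if (length(msg)) msg else TRUE
})

#' CohortDesign: parameters of the synthetic EPIC-like cohort
#'
#' Describes the simulated study: group sizes (healthy controls, skin
#' psoriasis, psoriatic arthritis), paired before/after-treatment subjects,
#' array layout, planted probe- and region-level effects, batch structure,
#' activity-linked CpGs that generate the PASI score, and residual noise.
#' Defaults mirror a small biologics-treated psoriasis cohort (9 HC, 10 Pso,
#' 7 PsA, 5 treated subjects resampled after therapy).
#'
#' @slot nHC,nPso,nPsA integer group sizes.
#' @slot nPairedTreated integer, patients contributing an additional
#'   after-treatment sample (taken from the Pso then PsA groups in order).
#' @slot nProbes integer, total probes across the layout.
#' @slot chromLayout data.frame with columns `chrom`, `nProbes`,
#'   `meanSpacing` (bp between consecutive probes, exponential draws).
#' @slot fracDmp fraction of probes carrying a planted group effect.
#' @slot deltaBetaEffect planted group difference on the beta scale.
#' @slot dmrBlocks data.frame with columns `chrom`, `startIndex`, `nCpgs`,
#'   `effect`: runs of consecutive probes sharing a planted effect.
#' @slot nBatches integer; `batchShiftSd` SD of per-(batch, probe) offsets on
#'   the M scale.
#' @slot nActivityCpgs integer, CpGs whose methylation tracks disease
#'   activity; `activitySlope` beta change per PASI unit (negative: higher
#'   activity, lower methylation).
#' @slot noiseSdM residual SD on the M scale.
#' @slot seed integer RNG seed.
#' @seealso [cohortDesign()], [generateManifest()], [generateCohort()]
#' @export
setClass("CohortDesign",
         representation(nHC = "integer", nPso = "integer", nPsA = "integer",
                        nPairedTreated = "integer", nProbes = "integer",
                        chromLayout = "data.frame", fracDmp = "numeric",
                        deltaBetaEffect = "numeric", dmrBlocks = "data.frame",
                        nBatches = "integer", batchShiftSd = "numeric",
                        nActivityCpgs = "integer", activitySlope = "numeric",
                        noiseSdM = "numeric", seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@nProbes < 1L) msg <- c(msg, "nProbes must be >= 1")
  if (any(c(object@nHC, object@nPso, object@nPsA) < 0L))
    msg <- c(msg, "group sizes must be non-negative")
  if (object@nPairedTreated > object@nPso + object@nPsA)
    msg <- c(msg, "nPairedTreated cannot exceed the number of patients")
  if (object@fracDmp < 0 || object@fracDmp > 1)
    msg <- c(msg, "fracDmp must lie in [0, 1]")
  if (sum(object@chromLayout$nProbes) != object@nProbes)
    msg <- c(msg, "chromLayout probe counts must sum to nProbes")
  if (nrow(object@dmrBlocks) &&
      sum(object@dmrBlocks$nCpgs) > object@nProbes)
    msg <- c(msg, "DMR blocks cannot cover more probes than nProbes")
  if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
  if (object@noiseSdM <= 0) msg <- c(msg, "noiseSdM must be > 0")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: pipeline thresholds
#'
#' Plain-list configuration validated by [analysisConfig()]; carries the
#' thresholds shared across stages (FDR, minimum |delta beta|, DMR sizes and
#' kernel settings, detection-p cutoff, score selection |r| threshold,
#' enrichment alpha, seed).
#'
#' @name AnalysisConfig
#' @keywords internal
NULL
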