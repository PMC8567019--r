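#' Construct a MethylationExperiment
#'
#' Assembles a beta-value matrix, a probe manifest and a sample sheet into
#' the package's central container, aligning probes and samples by id and
#' validating every invariant (beta in \[0,1\], unique probe ids, legal
#' region/island labels, sample-sheet consistency).
#'
#' @param beta numeric matrix, probes x samples, dimnames required.
#' @param manifest `GRanges` as returned by [readManifest()] or
#'   [generateManifest()], or a data.frame in manifest layout.
#' @param sampleSheet data.frame as returned by [readSampleSheet()]; rows are
#'   matched to `colnames(beta)` by `sample_id`. Optional: when omitted a
#'   minimal sheet with only sample ids is created.
#' @param detectionP optional numeric matrix of detection p-values with the
#'   same dimnames as `beta`.
#' @param assembly optional genome-assembly label stored as pass-through
#'   metadata (the pipeline itself is assembly-agnostic).
#' @return A [MethylationExperiment].
#' @examples
#' design <- cohortDesign(nProbes = 200L,
#'   chromLayout = data.frame(chrom = "chr1", nProbes = 200L,
#'                            meanSpacing = 500))
#' man <- generateManifest(design)
#' sim <- generateCohort(design, man)
#' me <- MethylationExperiment(betaValues(sim$experiment), man,
#'                             sampleSheet(sim$experiment))
#' me
#' @export
MethylationExperiment <- function(beta, manifest, sampleSheet = NULL,
                                  detectionP = NULL, assembly = NA_character_) {
  if (!is.matrix(beta) || !is.numeric(beta))
    .err("'beta' must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .err("'beta' must have probe ids as rownames and sample ids as colnames")
  if (is.data.frame(manifest)) manifest <- .manifestToGRanges(manifest)
  if (!methods::is(manifest, "GRanges"))
    .err("'manifest' must be a GRanges or a manifest data.frame")
  idx <- match(rownames(beta), S4Vectors::mcols(manifest)$probeId)
  if (anyNA(idx))
    .err("probes absent from manifest: ",
         paste(utils::head(rownames(beta)[is.na(idx)], 5L), collapse = ", "))
  manifest <- manifest[idx]
  if (is.null(sampleSheet)) {
    sampleSheet <- data.frame(sample_id = colnames(beta))
  }
  sampleSheet <- .validateSampleSheet(sampleSheet)
  sidx <- match(colnames(beta), sampleSheet$sample_id)
  if (anyNA(sidx))
    .err("samples absent from sample sheet: ",
         paste(colnames(beta)[is.na(sidx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(sampleSheet[sidx, , drop = FALSE],
                             row.names = colnames(beta))
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    if (!identical(dim(detectionP), dim(beta)))
      .err("'detectionP' must have the same shape as 'beta'")
    detectionP <- detectionP[rownames(beta), colnames(beta), drop = FALSE]
    assays$detectionP <- detectionP
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = manifest, colData = cd)
  out <- methods::new("MethylationExperiment", se)
  S4Vectors::metadata(out)$assembly <- assembly
  methods::validObject(out)
  out
}

#' Accessors for MethylationExperiment
#'
#' `betaValues()` returns the beta assay; `mValues()` its logit2 transform
#' (see [betaToM()]); `detectionP()` the detection-p assay or `NULL`;
#' `probeManifest()` the probe `GRanges`; `sampleSheet()` the sample sheet as
#' a base data.frame.
#'
#' @param x a [MethylationExperiment].
#' @param epsilon clipping bound passed to [betaToM()].
#' @return See individual descriptions.
#' @name betaValues
#' @aliases mValues detectionP
NULL

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationExperiment", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname betaValues
#' @export
setMethod("mValues", "MethylationExperiment", function(x, epsilon = 1e-6)
  betaToM(SummarizedExperiment::assay(x, "beta"), epsilon = epsilon))

#' @rdname betaValues
#' @export
setMethod("detectionP", "MethylationExperiment", function(x) {
  if ("detectionP" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detectionP")
  else NULL
})

#' Probe manifest and sample sheet accessors
#'
#' @param x a [MethylationExperiment].
#' @return `probeManifest()` a `GRanges`; `sampleSheet()` a data.frame.
#' @name probeManifest
#' @aliases sampleSheet
NULL

#' @rdname probeManifest
#' @export
setMethod("probeManifest", "MethylationExperiment", function(x)
  SummarizedExperiment::rowRanges(x))

#' @rdname probeManifest
#' @export
setMethod("sampleSheet", "MethylationExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "MethylationExperiment", function(object) {
  cat(sprintf("MethylationExperiment: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  grp <- SummarizedExperiment::colData(object)$group
  if (!is.null(grp))
    cat("  groups:",
        paste(sprintf("%s=%d", names(table(grp)), table(grp)),
              collapse = " "), "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  asm <- S4Vectors::metadata(object)$assembly
  if (!is.null(asm) && !is.na(asm)) cat("  assembly:", asm, "\n")
  invisible(NULL)
})

## Sample-sheet validation shared by the constructor and readSampleSheet().
.validateSampleSheet <- function(df) {
  if (!"sample_id" %in% colnames(df))
    .err("sample sheet must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    .err("duplicate sample ids in sample sheet")
  defaults <- list(subject_id = df$sample_id, group = "HC",
                   timepoint = "none", treatment = "none", sex = "F",
                   age = NA_real_, pasi = NA_real_, batch = "b1")
  for (nm in names(defaults))
    if (!nm %in% colnames(df)) df[[nm]] <- defaults[[nm]]
  if (!all(df$group %in% .GROUPS))
    .err("group must be one of ", paste(.GROUPS, collapse = ", "))
  if (!all(df$timepoint %in% c("none", "before", "after")))
    .err("timepoint must be none, before or after")
  if (!all(df$treatment %in% c("none", "antiTNF", "antiIL17")))
    .err("treatment must be none, antiTNF or antiIL17")
  if (!all(df$sex %in% c("M", "F"))) .err("sex must be M or F")
  df$pasi <- suppressWarnings(as.numeric(df$pasi))
  if (any(!is.na(df$pasi) & df$pasi < 0)) .err("pasi must be non-negative")
  hc <- df$group == "HC"
  if (any(hc & df$timepoint != "none"))
    .err("HC samples must have timepoint 'none'")
  if (any(hc & !is.na(df$pasi)))
    .err("HC samples must have no PASI value")
  aft <- df$subject_id[df$timepoint == "after"]
  bef <- df$subject_id[df$timepoint == "before"]
  bad <- setdiff(aft, bef)
  if (length(bad))
    .err("after-treatment samples without a before mate for subject(s): ",
         paste(bad, collapse = ", "))
  df$batch <- as.character(df$batch)
  df
}
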