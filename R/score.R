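## The methylation disease-activity score: pathway-restricted DMP
## selection by PASI correlation, healthy-control z-standardization,
## summation, and correlation with PASI.

#' Select activity-linked DMPs
#'
#' Restricts a DMP list to probes annotated to genes of a supplied pathway
#' set (e.g. TNF / IL-17 signalling) and keeps only probes whose beta
#' values correlate strongly with the PASI skin score across patient
#' samples: Pearson |r| above `rThreshold` (default 0.8). Selection uses
#' every sample with a PASI value by default; `timepoints` restricts (e.g.
#' to before-treatment samples only). Note the selection correlations are
#' computed on the same samples typically used for the downstream
#' score-PASI correlation; [correlateScoreActivity()] reports that
#' overlap.
#'
#' @param dmps data.frame of retained DMPs ([callDMPs()] `$dmps`).
#' @param pathwayGenes character vector of pathway gene symbols.
#' @param object a [MethylationExperiment] providing beta values and the
#'   sample sheet (with `pasi`).
#' @param rThreshold absolute-correlation cutoff in \[0, 1) (default 0.8).
#' @param timepoints optional timepoint labels to restrict the selection
#'   samples.
#' @return A data.frame with `probe_id`, `gene` (first matching pathway
#'   gene) and `r_sel`, retained rows only; zero rows (with a warning)
#'   when the pathway restriction leaves no candidate.
#' @export
selectActivityDMPs <- function(dmps, pathwayGenes, object, rThreshold = 0.8,
                               timepoints = NULL) {
  stopifnot(methods::is(object, "MethylationExperiment"))
  if (rThreshold < 0 || rThreshold >= 1)
    .err("'rThreshold' must lie in [0, 1)")
  mc <- S4Vectors::mcols(probeManifest(object))
  sheet <- sampleSheet(object)
  use <- !is.na(sheet$pasi)
  if (!is.null(timepoints)) use <- use & sheet$timepoint %in% timepoints
  if (sum(use) < 3L)
    .err("need >= 3 samples with a PASI value for selection")
  empty <- data.frame(probe_id = character(), gene = character(),
                      r_sel = numeric(), stringsAsFactors = FALSE)
  if (!nrow(dmps)) {
    .warn("no DMPs supplied; score undefined")
    return(empty)
  }
  idx <- match(dmps$probe_id, mc$probeId)
  if (anyNA(idx)) .err("DMP probe(s) absent from manifest")
  genesHit <- lapply(as.list(mc$genes[idx]), intersect, x = pathwayGenes)
  inPathway <- lengths(genesHit) > 0L
  if (!any(inPathway)) {
    .warn("no DMP maps to the pathway gene set; score undefined")
    return(empty)
  }
  cand <- dmps$probe_id[inPathway]
  beta <- betaValues(object)[cand, use, drop = FALSE]
  pasi <- sheet$pasi[use]
  r <- apply(beta, 1L, function(b)
    if (stats::sd(b) == 0) 0 else stats::cor(b, pasi))
  keep <- abs(r) > rThreshold
  data.frame(probe_id = cand[keep],
             gene = vapply(genesHit[inPathway][keep], `[`, character(1L),
                           1L),
             r_sel = unname(r[keep]), stringsAsFactors = FALSE)
}

#' Fit the healthy-control reference of the activity score
#'
#' Computes, on the beta scale and over healthy-control samples only, the
#' per-probe mean and standard deviation (n-1 denominator) used to
#' standardize values as SV = (beta - meanHC) / sdHC. Probes constant
#' across the controls are dropped with a warning.
#'
#' @param object a [MethylationExperiment].
#' @param probes data.frame from [selectActivityDMPs()] or a character
#'   vector of probe ids.
#' @param hcSamples sample ids of the reference group; default all samples
#'   with `group == "HC"`.
#' @param rThreshold the |r| cutoff that produced `probes`, recorded in
#'   the model (default 0 when the probes were not correlation-selected).
#' @return A [ScoreModel].
#' @export
fitScoreModel <- function(object, probes, hcSamples = NULL,
                          rThreshold = 0) {
  stopifnot(methods::is(object, "MethylationExperiment"))
  rSel <- NULL
  if (is.data.frame(probes)) {
    rSel <- probes$r_sel
    probes <- probes$probe_id
  }
  sheet <- sampleSheet(object)
  if (is.null(hcSamples)) hcSamples <- sheet$sample_id[sheet$group == "HC"]
  if (length(hcSamples) < 2L) .err("need >= 2 healthy-control samples")
  missing <- setdiff(probes, rownames(object))
  if (length(missing))
    .err("selected probe(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  beta <- betaValues(object)[probes, hcSamples, drop = FALSE]
  mu <- rowMeans(beta)
  sdv <- sqrt(.rowVars(beta))
  keep <- sdv > 0
  if (!all(keep))
    .warn("dropping probe(s) constant across healthy controls: ",
          paste(probes[!keep], collapse = ", "))
  if (is.null(rSel)) rSel <- rep(NA_real_, length(probes))
  methods::new("ScoreModel", probeIds = probes[keep], meanHC = mu[keep],
               sdHC = sdv[keep], rSel = rSel[keep],
               rThreshold = rThreshold)
}

#' @rdname ScoreModel-accessors
#' @param object a [ScoreModel].
#' @return `selectedProbes()`: character vector of probe ids.
#' @export
setMethod("selectedProbes", "ScoreModel", function(object) object@probeIds)

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel: %d probe(s), |r| threshold %.2f\n",
              length(object@probeIds), object@rThreshold))
  if (length(object@probeIds)) {
    df <- data.frame(probe_id = object@probeIds,
                     mean_HC = round(object@meanHC, 4),
                     SD_HC = round(object@sdHC, 4),
                     r_sel = round(object@rSel, 3))
    print(utils::head(df, 10L), row.names = FALSE)
    if (length(object@probeIds) > 10L) cat("  ...\n")
  }
  invisible(NULL)
})

#' Compute per-sample methylation activity scores
#'
#' The score of a sample is the sum over the model's probes of the
#' standardized value SV = (beta - meanHC) / sdHC. Samples equal to the
#' healthy-control means score 0, and the mean score of the reference
#' cohort itself is 0 up to rounding.
#'
#' @param object a [MethylationExperiment].
#' @param model a [ScoreModel].
#' @param ... unused.
#' @return Named numeric vector of scores, one per sample.
#' @export
setMethod("computeScores", "MethylationExperiment",
          function(object, model, ...) {
  stopifnot(methods::is(model, "ScoreModel"))
  missing <- setdiff(model@probeIds, rownames(object))
  if (length(missing))
    .err("model probe(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (!length(model@probeIds))
    .err("score model contains no probes")
  beta <- betaValues(object)[model@probeIds, , drop = FALSE]
  sv <- (beta - model@meanHC) / model@sdHC
  colSums(sv)
})

#' Correlate scores with disease activity
#'
#' Pearson correlation between the methylation scores and PASI with the
#' two-sided p-value from the t transform (`stats::cor.test`); pairs
#' without a PASI value are excluded. The returned object also reports how
#' many of the correlated samples were used during probe selection, making
#' the selection/evaluation overlap explicit rather than hidden.
#'
#' @param scores named numeric vector ([computeScores()]).
#' @param pasi named numeric vector of PASI values (NA for controls), or a
#'   sample sheet data.frame with `sample_id` and `pasi`.
#' @param selectionSamples optional sample ids used at selection time.
#' @return A list with `r`, `p`, `n` and `nSharedWithSelection`.
#' @export
correlateScoreActivity <- function(scores, pasi, selectionSamples = NULL) {
  if (is.data.frame(pasi))
    pasi <- stats::setNames(pasi$pasi, pasi$sample_id)
  common <- intersect(names(scores), names(pasi))
  s <- scores[common]
  y <- pasi[common]
  ok <- !is.na(y) & !is.na(s)
  s <- s[ok]
  y <- y[ok]
  if (length(s) < 3L) .err("need >= 3 paired observations")
  if (stats::sd(s) == 0 || stats::sd(y) == 0)
    .err("zero variance in scores or PASI; correlation undefined")
  ct <- stats::cor.test(s, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(s),
       nSharedWithSelection =
         if (is.null(selectionSamples)) NA_integer_
         else length(intersect(names(s), selectionSamples)))
}
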