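## Synthetic EPIC-like cohort generator with planted ground truth.
##
## The generative model works on the M (logit2 beta) scale throughout:
## sample M = logit2(baseline beta) + group effect + batch offset
##            + activity term + N(0, noiseSdM),
## then back-transforms, so beta stays inside (0, 1) without truncation.
## PASI is derived from the mean beta over the activity CpGs with a negative
## slope, so hypomethylation at those CpGs tracks higher disease activity,
## and the activity term is attenuated in after-treatment samples.

#' Create a synthetic cohort design
#'
#' Returns a validated [CohortDesign]. Defaults describe the study
#' conditions the package is tested under: 9 healthy controls, 10 skin
#' psoriasis and 7 psoriatic arthritis patients, 5 treated subjects
#' resampled after cytokine-blocker therapy, 20,000 probes over four
#' chromosomes, 1% planted DMPs at |delta beta| = 0.2, three 8-CpG planted
#' DMR blocks, two batches, and 10 activity-linked CpGs whose
#' hypomethylation generates the PASI score.
#'
#' @param nHC,nPso,nPsA group sizes.
#' @param nPairedTreated treated patients with before/after samples.
#' @param nProbes total probes; must equal `sum(chromLayout$nProbes)`.
#' @param chromLayout data.frame(chrom, nProbes, meanSpacing).
#' @param fracDmp fraction of probes with planted group effects.
#' @param deltaBetaEffect planted group difference on the beta scale.
#' @param dmrBlocks data.frame(chrom, startIndex, nCpgs, effect).
#' @param nBatches,batchShiftSd batch structure (offsets on the M scale).
#' @param nActivityCpgs,activitySlope activity CpGs and beta change per PASI
#'   unit (negative by default).
#' @param noiseSdM residual SD on the M scale.
#' @param seed RNG seed.
#' @return A [CohortDesign].
#' @export
cohortDesign <- function(nHC = 9L, nPso = 10L, nPsA = 7L,
                         nPairedTreated = 5L, nProbes = 20000L,
                         chromLayout = NULL,
                         fracDmp = 0.01, deltaBetaEffect = 0.2,
                         dmrBlocks = NULL,
                         nBatches = 2L, batchShiftSd = 0.3,
                         nActivityCpgs = 10L, activitySlope = -0.03,
                         noiseSdM = 0.25, seed = 1L) {
  nProbes <- as.integer(nProbes)
  if (is.null(chromLayout)) {
    nChrom <- min(4L, max(1L, nProbes %/% 50L))
    per <- rep(nProbes %/% nChrom, nChrom)
    per[1L] <- per[1L] + nProbes - sum(per)
    chromLayout <- data.frame(chrom = paste0("chr", seq_len(nChrom)),
                              nProbes = per, meanSpacing = 2000)
  }
  chromLayout$nProbes <- as.integer(chromLayout$nProbes)
  if (is.null(dmrBlocks)) {
    dmrBlocks <-
      if (nProbes >= 2000L && nrow(chromLayout) >= 3L)
        data.frame(chrom = chromLayout$chrom[1:3],
                   startIndex = c(120L, 220L, 320L),
                   nCpgs = 8L, effect = deltaBetaEffect)
      else data.frame(chrom = character(), startIndex = integer(),
                      nCpgs = integer(), effect = numeric())
  }
  methods::new("CohortDesign", nHC = as.integer(nHC),
               nPso = as.integer(nPso), nPsA = as.integer(nPsA),
               nPairedTreated = as.integer(nPairedTreated),
               nProbes = nProbes, chromLayout = chromLayout,
               fracDmp = fracDmp, deltaBetaEffect = deltaBetaEffect,
               dmrBlocks = dmrBlocks, nBatches = as.integer(nBatches),
               batchShiftSd = batchShiftSd,
               nActivityCpgs = as.integer(nActivityCpgs),
               activitySlope = activitySlope, noiseSdM = noiseSdM,
               seed = as.integer(seed))
}

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf(paste0("CohortDesign: %d HC / %d Pso / %d PsA",
                     " (+%d after-treatment), %d probes\n"),
              object@nHC, object@nPso, object@nPsA, object@nPairedTreated,
              object@nProbes))
  cat(sprintf("  planted: %.1f%% DMPs (|db|=%.2f), %d DMR blocks, %d activity CpGs\n",
              100 * object@fracDmp, object@deltaBetaEffect,
              nrow(object@dmrBlocks), object@nActivityCpgs))
  cat(sprintf("  batches: %d (sd %.2f M), noise sd %.2f M, seed %d\n",
              object@nBatches, object@batchShiftSd, object@noiseSdM,
              object@seed))
  invisible(NULL)
})

## probe indices (within the manifest order) covered by the DMR blocks
.dmrBlockIndices <- function(design) {
  if (!nrow(design@dmrBlocks)) return(list())
  offsets <- c(0L, cumsum(design@chromLayout$nProbes))
  names(offsets) <- c(design@chromLayout$chrom, "end")
  lapply(seq_len(nrow(design@dmrBlocks)), function(i) {
    b <- design@dmrBlocks[i, ]
    off <- offsets[[as.character(b$chrom)]]
    if (is.null(off)) .err("DMR block chromosome not in layout: ", b$chrom)
    idx <- off + seq.int(b$startIndex, length.out = b$nCpgs)
    if (max(idx) > off + design@chromLayout$nProbes[
          design@chromLayout$chrom == b$chrom])
      .err("DMR block extends past its chromosome")
    idx
  })
}

#' Generate a synthetic probe manifest
#'
#' Probe positions are laid down per chromosome as a two-state (dense /
#' sparse) gap process, which yields CpG-island-like clusters; island
#' context is then derived from neighbour distance exactly as on real
#' arrays (Island <= 200 bp to nearest neighbour, Shore <= 2 kb, Shelf
#' <= 4 kb, OpenSea beyond). Genes are consecutive probe runs; about one
#' third of probes receive promoter labels (TSS1500/TSS200/5UTR), one third
#' Body (with occasional 3UTR/ExonBnd), one third are intergenic. Probes
#' covered by the design's planted DMR blocks are forced into dense
#' clusters. About 1% of probes are non-CpG-context ("ch.") probes, which
#' the QC filter removes.
#'
#' @param design a [CohortDesign].
#' @return A `GRanges` manifest (see [MethylationExperiment]).
#' @export
generateManifest <- function(design) {
  stopifnot(methods::is(design, "CohortDesign"))
  methods::validObject(design)
  if (design@nProbes < 1L) .err("design has zero probes")
  blockIdx <- unlist(.dmrBlockIndices(design))
  .withSeed(.childSeed(design@seed, "manifest"), {
    layout <- design@chromLayout
    dfs <- vector("list", nrow(layout))
    probe0 <- 0L
    for (ci in seq_len(nrow(layout))) {
      n <- layout$nProbes[ci]
      s <- layout$meanSpacing[ci]
      ## two-state gap chain: dense ~Exp(110 bp), sparse tuned to hit the
      ## requested overall mean spacing
      dense <- logical(n)
      dense[1L] <- runif(1) < 0.57
      for (i in seq_len(n - 1L))
        dense[i + 1L] <- if (dense[i]) runif(1) < 0.85 else runif(1) < 0.2
      sparseMean <- max(200, (s - 0.57 * 110) / 0.43)
      gaps <- ifelse(dense, stats::rexp(n, 1 / 110),
                     stats::rexp(n, 1 / sparseMean))
      ## planted DMR blocks must be mergeable: force dense, capped gaps
      within <- which((probe0 + seq_len(n)) %in% blockIdx)
      if (length(within))
        gaps[within] <- pmin(stats::rexp(length(within), 1 / 100) + 20, 350)
      pos <- cumsum(pmax(2, round(gaps))) + 10000L
      df <- data.frame(chrom = layout$chrom[ci], pos = as.integer(pos))
      dfs[[ci]] <- df
      probe0 <- probe0 + n
    }
    df <- do.call(rbind, dfs)
    n <- nrow(df)
    df$probe_id <- sprintf("cg%07d", seq_len(n))
    ## ~1% non-CpG-context probes, never on planted-block positions
    nonCpG <- sample(setdiff(seq_len(n), blockIdx),
                     max(0L, round(0.01 * n)))
    df$probe_id[nonCpG] <- sprintf("ch.%d.%06d", 1L +
                                     (seq_along(nonCpG) %% 22L), nonCpG)
    df$strand <- "*"
    df$probe_type <- ifelse(runif(n) < 0.28, "I", "II")
    ## island context from neighbour distances, per chromosome
    ctx <- character(n)
    for (ch in unique(df$chrom)) {
      i <- which(df$chrom == ch)
      p <- df$pos[i]
      gapL <- c(Inf, diff(p))
      gapR <- c(diff(p), Inf)
      d <- pmin(gapL, gapR)
      ctx[i] <- ifelse(d <= 200, "Island",
                ifelse(d <= 2000, "Shore",
                ifelse(d <= 4000, "Shelf", "OpenSea")))
    }
    df$island_context <- ctx
    ## genes as consecutive runs; ~2/3 of runs carry a gene
    genes <- character(n)
    regions <- character(n)
    geneCounter <- 0L
    i <- 1L
    while (i <= n) {
      runLen <- min(n - i + 1L, 4L + stats::rpois(1L, 5L))
      if (runif(1) < 2 / 3) {
        geneCounter <- geneCounter + 1L
        gname <- sprintf("GENE%04d", geneCounter)
        for (j in seq.int(i, length.out = runLen)) {
          lab <- if (runif(1) < 0.5)
            sample(.PROMOTER_REGIONS, 1L)
          else sample(c("Body", "3UTR", "ExonBnd"), 1L,
                      prob = c(0.9, 0.07, 0.03))
          genes[j] <- gname
          regions[j] <- lab
        }
        ## occasional overlapping second gene
        if (runif(1) < 0.1 && runLen >= 2L) {
          geneCounter <- geneCounter + 1L
          g2 <- sprintf("GENE%04d", geneCounter)
          j <- i + runLen - 1L
          genes[j] <- paste(genes[j], g2, sep = ";")
          regions[j] <- paste(regions[j], "TSS1500", sep = ";")
        }
      }
      i <- i + runLen
    }
    df$genes <- genes
    df$gene_regions <- regions
    .manifestToGRanges(df[, c("probe_id", "chrom", "pos", "strand",
                              "probe_type", "genes", "gene_regions",
                              "island_context")])
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates beta values, detection p-values, a sample sheet and a truth
#' object for the design. Group effects (planted DMPs and DMR blocks),
#' batch offsets and the disease-activity term are additive on the M scale;
#' see the package vignette for the full generative model. PASI is derived
#' from the mean beta over the activity CpGs (negative slope), and
#' after-treatment samples carry an attenuated activity term, so scores
#' computed downstream rise after treatment.
#'
#' @param design a [CohortDesign].
#' @param manifest the manifest from [generateManifest()] (regenerated when
#'   omitted).
#' @return A list with elements `experiment` (a [MethylationExperiment]
#'   with `beta` and `detectionP` assays) and `truth` (planted effects:
#'   `dmpProbes` per contrast, `dmrIntervals` (GRanges), `batchOffsets`,
#'   `activityProbes`, per-sample `severity`, and `excludedSnp` /
#'   `excludedCrossreactive` label lists).
#' @export
generateCohort <- function(design, manifest = generateManifest(design)) {
  stopifnot(methods::is(design, "CohortDesign"))
  mc <- S4Vectors::mcols(manifest)
  nP <- length(manifest)
  if (nP != design@nProbes)
    .err("manifest size does not match design nProbes")
  .withSeed(.childSeed(design@seed, "cohort"), {
    ## ---- sample sheet -------------------------------------------------
    subjects <- c(sprintf("HC%02d", seq_len(design@nHC)),
                  sprintf("Pso%02d", seq_len(design@nPso)),
                  sprintf("PsA%02d", seq_len(design@nPsA)))
    group <- rep(c("HC", "Pso", "PsA"),
                 c(design@nHC, design@nPso, design@nPsA))
    patients <- subjects[group != "HC"]
    treated <- patients[seq_len(min(design@nPairedTreated,
                                    length(patients)))]
    sheet <- data.frame(
      sample_id = subjects, subject_id = subjects, group = group,
      timepoint = ifelse(group == "HC", "none", "before"),
      treatment = "none", stringsAsFactors = FALSE)
    if (length(treated)) {
      tx <- sample(c("antiTNF", "antiIL17"), length(treated), replace = TRUE)
      sheet$treatment[match(treated, sheet$subject_id)] <- tx
      after <- data.frame(
        sample_id = paste0(treated, "_T2"), subject_id = treated,
        group = sheet$group[match(treated, sheet$subject_id)],
        timepoint = "after", treatment = tx, stringsAsFactors = FALSE)
      sheet <- rbind(sheet, after)
    }
    nS <- nrow(sheet)
    sheet$sex <- sample(c("M", "F"), nS, replace = TRUE)
    sheet$age <- round(runif(nS, 22, 68))
    sheet$batch <- paste0("b", rep_len(seq_len(design@nBatches), nS))
    ## ---- baseline trimodal beta --------------------------------------
    comp <- sample.int(3L, nP, replace = TRUE, prob = c(0.45, 0.15, 0.40))
    baseBeta <- c(runif(nP, 0.04, 0.18), runif(nP, 0.40, 0.60),
                  runif(nP, 0.80, 0.96))[seq_len(nP) + (comp - 1L) * nP]
    ## ---- planted effects ---------------------------------------------
    blockIdxList <- .dmrBlockIndices(design)
    blockIdx <- unlist(blockIdxList)
    isCpG <- startsWith(mc$probeId, "cg")
    free <- setdiff(which(isCpG), blockIdx)
    nDmp <- round(design@fracDmp * nP)
    dmpIdx <- if (nDmp > 0) sort(sample(free, min(nDmp, length(free))))
              else integer()
    free <- setdiff(free, dmpIdx)
    withGene <- free[lengths(mc$genes[free]) > 0]
    actIdx <- sort(sample(withGene, min(design@nActivityCpgs,
                                        length(withGene))))
    ## activity CpGs get a mid-high baseline so hypomethylation has room
    baseBeta[actIdx] <- runif(length(actIdx), 0.60, 0.72)
    ## DMR blocks are directionally coherent: one sign per block, with
    ## baselines re-drawn so the common-sign effect stays inside (0, 1)
    blockSign <- sample(c(-1, 1), length(blockIdxList), replace = TRUE)
    for (bi in seq_along(blockIdxList)) {
      idx <- blockIdxList[[bi]]
      baseBeta[idx] <- if (blockSign[bi] < 0) runif(length(idx), 0.60, 0.85)
                       else runif(length(idx), 0.15, 0.40)
    }
    baseM <- betaToM(baseBeta)
    ## group effect matrix (probes x 3 groups), on the M scale, targeting a
    ## beta-scale difference of deltaBetaEffect in the affected group(s)
    effM <- matrix(0, nP, 3L, dimnames = list(NULL, .GROUPS))
    applyEffect <- function(idx, who, delta, sgn = NULL) {
      if (is.null(sgn)) sgn <- ifelse(baseBeta[idx] > 0.5, -1, 1)
      target <- pmin(0.97, pmax(0.03, baseBeta[idx] + sgn * delta))
      shift <- betaToM(target) - baseM[idx]
      for (g in who) effM[idx, g] <<- effM[idx, g] + shift
      sgn * delta
    }
    pattern <- sample(c("Pso", "PsA", "both"), length(dmpIdx),
                      replace = TRUE, prob = c(0.4, 0.4, 0.2))
    for (pat in c("Pso", "PsA", "both")) {
      idx <- dmpIdx[pattern == pat]
      if (length(idx))
        applyEffect(idx, if (pat == "both") c("Pso", "PsA") else pat,
                    design@deltaBetaEffect)
    }
    for (bi in seq_along(blockIdxList))
      applyEffect(blockIdxList[[bi]], "Pso", design@dmrBlocks$effect[bi],
                  sgn = blockSign[bi])
    ## ---- batch offsets and activity term -----------------------------
    batchOff <- matrix(rnorm(design@nBatches * nP, 0, design@batchShiftSd),
                       nrow = design@nBatches,
                       dimnames = list(paste0("b", seq_len(design@nBatches)),
                                       mc$probeId))
    if (design@nBatches == 1L) batchOff[] <- 0
    severity <- stats::setNames(rep(0, nS), sheet$sample_id)
    isPat <- sheet$group != "HC"
    subjSev <- stats::setNames(runif(length(patients), 0.5, 1.5), patients)
    severity[isPat] <- subjSev[sheet$subject_id[isPat]]
    severity[sheet$timepoint == "after"] <-
      0.15 * severity[sheet$timepoint == "after"]
    actLoad <- runif(length(actIdx), 0.8, 1.2)
    ## ---- assemble M, back-transform ----------------------------------
    M <- matrix(baseM, nP, nS) +
      effM[, match(sheet$group, .GROUPS)] +
      t(batchOff[match(sheet$batch, rownames(batchOff)), , drop = FALSE]) +
      matrix(rnorm(nP * nS, 0, design@noiseSdM), nP, nS)
    if (length(actIdx))
      M[actIdx, ] <- M[actIdx, ] -
        2.2 * outer(actLoad, severity)
    beta <- mToBeta(M)
    dimnames(beta) <- list(mc$probeId, sheet$sample_id)
    ## ---- PASI from mean beta over activity CpGs ----------------------
    if (length(actIdx) && any(isPat)) {
      meanAct <- colMeans(beta[actIdx, , drop = FALSE])
      beta0 <- mean(baseBeta[actIdx])
      pasi <- pmax(0, (meanAct - beta0) / design@activitySlope +
                        rnorm(nS, 0, 0.6))
      sheet$pasi <- ifelse(sheet$group == "HC", NA_real_, round(pasi, 1))
    } else sheet$pasi <- NA_real_
    ## ---- detection p-values ------------------------------------------
    detP <- matrix(runif(nP * nS, 0, 0.005), nP, nS,
                   dimnames = dimnames(beta))
    nFail <- max(1L, round(0.002 * nP))
    failIdx <- sample(setdiff(seq_len(nP), c(blockIdx, dmpIdx, actIdx)),
                      nFail)
    detP[cbind(failIdx, sample.int(nS, nFail, replace = TRUE))] <-
      runif(nFail, 0.02, 0.5)
    ## ---- synthetic exclusion labels ----------------------------------
    pool <- setdiff(seq_len(nP), c(blockIdx, dmpIdx, actIdx, failIdx))
    snpIdx <- sample(pool, max(1L, round(0.005 * nP)))
    xrIdx <- sample(setdiff(pool, snpIdx), max(1L, round(0.005 * nP)))
    ## ---- truth ---------------------------------------------------------
    ids <- mc$probeId
    dmrGR <- GenomicRanges::GRanges()
    if (length(blockIdxList)) {
      dmrGR <- GenomicRanges::GRanges(
        seqnames = design@dmrBlocks$chrom,
        ranges = IRanges::IRanges(
          start = vapply(blockIdxList, function(i)
            min(GenomicRanges::start(manifest[i])), numeric(1L)),
          end = vapply(blockIdxList, function(i)
            max(GenomicRanges::start(manifest[i])), numeric(1L))))
      S4Vectors::mcols(dmrGR)$nCpgs <- design@dmrBlocks$nCpgs
      S4Vectors::mcols(dmrGR)$effect <- design@dmrBlocks$effect
    }
    truth <- list(
      ## activity CpGs differ between HC and patients (patients carry the
      ## severity term), so they belong to the HC-vs-patient truth sets;
      ## severity is identically distributed in Pso and PsA, so they do
      ## not separate those two groups
      dmpProbes = list(
        HC_vs_Pso = ids[sort(c(dmpIdx[pattern %in% c("Pso", "both")],
                               blockIdx, actIdx))],
        HC_vs_PsA = ids[sort(c(dmpIdx[pattern %in% c("PsA", "both")],
                               actIdx))],
        Pso_vs_PsA = ids[sort(c(dmpIdx[pattern %in% c("Pso", "PsA")],
                                blockIdx))],
        before_vs_after = ids[actIdx]),
      dmrIntervals = list(HC_vs_Pso = dmrGR),
      batchOffsets = batchOff,
      activityProbes = ids[actIdx],
      severity = severity,
      excludedSnp = ids[sort(snpIdx)],
      excludedCrossreactive = ids[sort(xrIdx)])
    me <- MethylationExperiment(beta, manifest, sheet, detectionP = detP,
                                assembly = "synthetic")
    list(experiment = me, truth = truth)
  })
}

#' Generate synthetic gene-set collections (GMT-style)
#'
#' Draws random gene sets from the manifest's gene universe and, when
#' `activityProbes` is supplied, prepends an "ACTIVITY_PATHWAY" set
#' containing exactly the genes hosting those CpGs — a stand-in for a
#' curated cytokine-signalling pathway with a planted signal.
#'
#' @param manifest a probe `GRanges`.
#' @param nTerms number of random sets (>= 1).
#' @param activityProbes optional probe ids whose genes form the activity
#'   set (e.g. `truth$activityProbes`).
#' @param setSize integer range of random set sizes.
#' @param seed RNG seed.
#' @return Named list of character vectors (a GMT collection).
#' @export
generatePathwaySets <- function(manifest, nTerms = 20L,
                                activityProbes = NULL,
                                setSize = c(10L, 40L), seed = 1L) {
  if (nTerms < 1L) .err("nTerms must be >= 1")
  mc <- S4Vectors::mcols(manifest)
  universe <- sort(unique(unlist(mc$genes, use.names = FALSE)))
  if (!length(universe)) .err("manifest carries no gene labels")
  .withSeed(.childSeed(seed, "pathways"), {
    sets <- lapply(seq_len(nTerms), function(i)
      sort(sample(universe, min(length(universe),
                                sample(seq(setSize[1L], setSize[2L]), 1L)))))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(nTerms))
    if (!is.null(activityProbes)) {
      idx <- match(activityProbes, mc$probeId)
      if (anyNA(idx)) .err("activity probe absent from manifest")
      act <- sort(unique(unlist(mc$genes[idx], use.names = FALSE)))
      sets <- c(list(ACTIVITY_PATHWAY = act), sets)
    }
    sets
  })
}

#' Write a simulated cohort to disk
#'
#' Writes `beta.csv`, `detection_p.csv`, `manifest.csv`, `samples.csv`,
#' `snp_probes.txt`, `crossreactive_probes.txt` and `truth.json` into a
#' directory, the on-disk interface consumed by [runPipeline()].
#'
#' @param sim result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  me <- sim$experiment
  writeBetaMatrix(betaValues(me), file.path(dir, "beta.csv"))
  dp <- detectionP(me)
  if (!is.null(dp)) writeBetaMatrix(dp, file.path(dir, "detection_p.csv"))
  writeManifest(probeManifest(me), file.path(dir, "manifest.csv"))
  writeSampleSheet(sampleSheet(me), file.path(dir, "samples.csv"))
  writeLines(sim$truth$excludedSnp, file.path(dir, "snp_probes.txt"))
  writeLines(sim$truth$excludedCrossreactive,
             file.path(dir, "crossreactive_probes.txt"))
  truth <- sim$truth
  truth$dmrIntervals <- lapply(truth$dmrIntervals, function(gr)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr)))
  truth$batchOffsets <- NULL        # large and reconstructible from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
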