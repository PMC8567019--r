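## End-to-end orchestration: simulate -> preprocess -> dmp -> dmr ->
## annotate/enrich -> score, driven by one (YAML) config, with per-stage
## caching keyed on input digests and a JSON run manifest.

#' Validate analysis thresholds
#'
#' Returns a validated named list of the pipeline thresholds, filling in
#' defaults: FDR 0.05, minimum |delta beta| 0.1, DMR minimum CpG counts
#' {5, 10, 20}, kernel bandwidth 1000 bp with scaling C = 2 (kernel SD =
#' lambda / C), detection-p cutoff 0.01, score selection |r| threshold
#' 0.8, enrichment alpha 0.05.
#'
#' @param ... named overrides of `fdrThreshold`, `minDeltaBeta`,
#'   `dmrMinCpgs`, `dmrLambda`, `dmrScalingC`, `detectionPCutoff`,
#'   `scoreRThreshold`, `enrichmentAlpha`, `seed`.
#' @return Named list.
#' @export
analysisConfig <- function(...) {
  cfg <- list(fdrThreshold = 0.05, minDeltaBeta = 0.1,
              dmrMinCpgs = c(5L, 10L, 20L), dmrLambda = 1000,
              dmrScalingC = 2, detectionPCutoff = 0.01,
              scoreRThreshold = 0.8, enrichmentAlpha = 0.05, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    .err("unknown analysis option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (nm in c("fdrThreshold", "detectionPCutoff", "scoreRThreshold",
               "enrichmentAlpha"))
    .assertScalarProb(cfg[[nm]], nm)
  if (any(cfg$dmrMinCpgs < 2L)) .err("dmrMinCpgs must all be >= 2")
  if (cfg$dmrLambda <= 0 || cfg$dmrScalingC <= 0)
    .err("dmrLambda and dmrScalingC must be positive")
  if (cfg$minDeltaBeta < 0 || cfg$minDeltaBeta >= 1)
    .err("minDeltaBeta must lie in [0, 1)")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.defaultContrasts <- function() list(
  list(name = "HC_vs_Pso", groupBy = "group",
       levels = c("HC", "Pso"), paired = FALSE),
  list(name = "HC_vs_PsA", groupBy = "group",
       levels = c("HC", "PsA"), paired = FALSE),
  list(name = "Pso_vs_PsA", groupBy = "group",
       levels = c("Pso", "PsA"), paired = FALSE),
  list(name = "before_vs_after", groupBy = "timepoint",
       levels = c("before", "after"), paired = TRUE))

.stageKey <- function(inputFiles, extra = NULL) {
  dig <- tools::md5sum(inputFiles[file.exists(inputFiles)])
  paste(c(dig, vapply(extra, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1L))),
    collapse = "|")
}

## Run a cacheable stage: skipped when all outputs exist and the stored
## key (digests of inputs + config slice) is unchanged.
.runStage <- function(state, name, inputs, outputs, extra, fun) {
  keyFile <- file.path(state$dir, paste0(".", name, ".key"))
  key <- .stageKey(inputs, extra)
  cached <- all(file.exists(outputs)) && file.exists(keyFile) &&
    identical(readLines(keyFile, warn = FALSE)[1L], key)
  t0 <- proc.time()[["elapsed"]]
  if (!cached) {
    fun()
    writeLines(key, keyFile)
  }
  rec <- list(stage = name, cached = cached,
              seconds = round(proc.time()[["elapsed"]] - t0, 3),
              outputs = basename(outputs))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = state$log, append = TRUE, sep = "")
  rec
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> preprocess (QC filter, probe-type
#' normalization, batch correction) -> DMP calling per contrast -> DMR
#' calling per contrast and minimum CpG count -> functional distribution,
#' set overlaps and over-representation analysis -> activity score, writing
#' every stage's tables into `outDir`. Stages are cached: a stage is
#' skipped when its outputs exist and the digests of its inputs and config
#' are unchanged, so deleting one intermediate recomputes only downstream
#' stages. A JSON run manifest records the config snapshot, input file
#' digests, per-stage row counts, package version and seed; a JSON-lines
#' log records per-stage timings.
#'
#' @param config path to a YAML file or an equivalent list, with optional
#'   sections `simulate` (arguments of [cohortDesign()]), `input`
#'   (directory holding beta.csv / manifest.csv / samples.csv /
#'   detection_p.csv / snp_probes.txt / crossreactive_probes.txt /
#'   pathways.gmt), `analysis` (see [analysisConfig()]), `contrasts`, and
#'   `score` (`contrast`, `pathway` set name).
#' @param outDir output directory (default `config$output`, falling back
#'   to `tempfile("methcd8_run")`).
#' @return The run manifest, invisibly (a list; element `stages` records
#'   which stages ran vs. were cached).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .err("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .err("'config' must be a list or a YAML path")
  cfg <- do.call(analysisConfig, as.list(config$analysis))
  if (is.null(config$simulate) && is.null(config$input))
    .err("config must provide either 'simulate' or 'input'")
  outDir <- outDir %||% config$output %||% tempfile("methcd8_run")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$dir <- outDir
  state$log <- file.path(outDir, "pipeline_log.jsonl")
  if (file.exists(state$log)) unlink(state$log)
  stages <- list()
  counts <- list()

  ## ---- stage: simulate / locate inputs --------------------------------
  if (!is.null(config$simulate)) {
    simArgs <- as.list(config$simulate)
    if (is.null(simArgs$seed)) simArgs$seed <- .childSeed(cfg$seed, "simulate")
    dataDir <- file.path(outDir, "data")
    simFiles <- file.path(dataDir, c("beta.csv", "manifest.csv",
                                     "samples.csv", "detection_p.csv",
                                     "snp_probes.txt",
                                     "crossreactive_probes.txt",
                                     "pathways.gmt", "truth.json"))
    stages$simulate <- .runStage(state, "simulate", character(), simFiles,
                                 simArgs, function() {
      design <- do.call(cohortDesign, simArgs)
      sim <- generateCohort(design)
      writeCohort(sim, dataDir)
      sets <- generatePathwaySets(probeManifest(sim$experiment),
                                  nTerms = 20L,
                                  activityProbes = sim$truth$activityProbes,
                                  seed = design@seed)
      writeGMT(sets, file.path(dataDir, "pathways.gmt"))
    })
  } else {
    dataDir <- config$input
    if (!dir.exists(dataDir)) .err("input directory not found: ", dataDir)
  }
  pth <- function(f) file.path(dataDir, f)
  for (f in c("beta.csv", "manifest.csv", "samples.csv"))
    if (!file.exists(pth(f)))
      .err("missing input file '", f, "' for stage preprocess")

  ## ---- stage: preprocess ----------------------------------------------
  inFiles <- pth(c("beta.csv", "manifest.csv", "samples.csv",
                   "detection_p.csv", "snp_probes.txt",
                   "crossreactive_probes.txt"))
  filtBeta <- file.path(outDir, "filtered_beta.csv")
  filtRep <- file.path(outDir, "filter_report.json")
  stages$preprocess <- .runStage(
    state, "preprocess", inFiles, c(filtBeta, filtRep),
    cfg[c("detectionPCutoff")], function() {
    beta <- readBetaMatrix(pth("beta.csv"))
    manifest <- readManifest(pth("manifest.csv"))
    sheet <- readSampleSheet(pth("samples.csv"))
    dp <- if (file.exists(pth("detection_p.csv")))
      readBetaMatrix(pth("detection_p.csv")) else NULL
    me <- MethylationExperiment(beta, manifest, sheet, detectionP = dp)
    snp <- if (file.exists(pth("snp_probes.txt")))
      readIdList(pth("snp_probes.txt")) else character()
    xr <- if (file.exists(pth("crossreactive_probes.txt")))
      readIdList(pth("crossreactive_probes.txt")) else character()
    flt <- filterProbes(me, snpList = snp, crossreactiveList = xr,
                        detectionPCutoff = cfg$detectionPCutoff)
    me <- normalizeProbeTypes(flt$experiment)
    sheet2 <- sampleSheet(me)
    if (length(unique(sheet2$batch)) > 1L) {
      M <- combatCorrect(mValues(me), sheet2$batch, sheet2$group)
      b <- mToBeta(M)
      SummarizedExperiment::assay(me, "beta") <- b
    }
    writeBetaMatrix(betaValues(me), filtBeta)
    jsonlite::write_json(flt$report, filtRep, auto_unbox = TRUE, digits = NA)
  })

  loadProcessed <- function() {
    beta <- readBetaMatrix(filtBeta)
    manifest <- readManifest(pth("manifest.csv"))
    sheet <- readSampleSheet(pth("samples.csv"))
    MethylationExperiment(beta, manifest, sheet)
  }

  contrasts <- config$contrasts %||% .defaultContrasts()

  ## ---- stage: dmp ------------------------------------------------------
  dmpFiles <- file.path(outDir, c(
    vapply(contrasts, function(ct) sprintf("dmp_%s.tsv", ct$name), ""),
    vapply(contrasts, function(ct) sprintf("stats_%s.tsv", ct$name), "")))
  stages$dmp <- .runStage(
    state, "dmp", c(filtBeta, pth(c("manifest.csv", "samples.csv"))),
    dmpFiles, cfg[c("fdrThreshold", "minDeltaBeta")], function() {
    me <- loadProcessed()
    sheet <- sampleSheet(me)
    for (ct in contrasts) {
      if (!all(ct$levels %in% sheet[[ct$groupBy]])) {
        ## contrast not represented in this cohort: write empty tables
        .writeDelim(data.frame(), file.path(outDir,
                                            sprintf("dmp_%s.tsv", ct$name)))
        .writeDelim(data.frame(), file.path(outDir,
                                            sprintf("stats_%s.tsv", ct$name)))
        next
      }
      res <- callDMPs(me, contrast = ct$levels, groupBy = ct$groupBy,
                      paired = isTRUE(ct$paired),
                      fdrThreshold = cfg$fdrThreshold,
                      minDeltaBeta = cfg$minDeltaBeta)
      .writeDelim(res$dmps, file.path(outDir,
                                      sprintf("dmp_%s.tsv", ct$name)))
      .writeDelim(res$stats, file.path(outDir,
                                       sprintf("stats_%s.tsv", ct$name)))
    }
  })

  ## ---- stage: dmr ------------------------------------------------------
  dmrFiles <- unlist(lapply(contrasts, function(ct)
    file.path(outDir, c(sprintf("dmr_%s_min%d.tsv", ct$name, cfg$dmrMinCpgs),
                        sprintf("dmr_%s_min%d.bed", ct$name,
                                cfg$dmrMinCpgs)))))
  statFiles <- file.path(outDir, vapply(contrasts, function(ct)
    sprintf("stats_%s.tsv", ct$name), ""))
  stages$dmr <- .runStage(
    state, "dmr", c(statFiles, pth("manifest.csv")), dmrFiles,
    cfg[c("fdrThreshold", "dmrMinCpgs", "dmrLambda", "dmrScalingC",
          "minDeltaBeta")], function() {
    manifest <- readManifest(pth("manifest.csv"))
    for (ct in contrasts) {
      stats <- tryCatch(.readDelim(file.path(outDir,
                                             sprintf("stats_%s.tsv",
                                                     ct$name))),
                        error = function(e) data.frame())
      for (mc in cfg$dmrMinCpgs) {
        gr <- if (nrow(stats)) callDMRs(
          stats, manifest, minCpgs = mc, fdrThreshold = cfg$fdrThreshold,
          minMeanAbsDeltaBeta = cfg$minDeltaBeta, lambda = cfg$dmrLambda,
          C = cfg$dmrScalingC)
        else callDMRs(data.frame(), manifest)
        .writeDelim(.dmrsToTable(gr),
                    file.path(outDir, sprintf("dmr_%s_min%d.tsv",
                                              ct$name, mc)))
        exportDMRsBed(gr, file.path(outDir, sprintf("dmr_%s_min%d.bed",
                                                    ct$name, mc)))
      }
    }
  })

  ## ---- stage: annotate + enrich ---------------------------------------
  gmtFile <- pth("pathways.gmt")
  annFiles <- file.path(outDir, c(
    vapply(contrasts, function(ct)
      sprintf("distribution_%s.tsv", ct$name), ""),
    "overlap_dmps.tsv",
    vapply(contrasts, function(ct)
      sprintf("enrichment_%s.tsv", ct$name), "")))
  stages$annotate <- .runStage(
    state, "annotate",
    c(file.path(outDir, vapply(contrasts, function(ct)
        sprintf("dmp_%s.tsv", ct$name), "")),
      pth("manifest.csv"), if (file.exists(gmtFile)) gmtFile),
    annFiles, cfg["enrichmentAlpha"], function() {
    manifest <- readManifest(pth("manifest.csv"))
    universe <- sort(unique(unlist(S4Vectors::mcols(manifest)$genes,
                                   use.names = FALSE)))
    sets <- if (file.exists(gmtFile)) readGMT(gmtFile) else NULL
    dmpSets <- list()
    for (ct in contrasts) {
      dmps <- tryCatch(.readDelim(file.path(outDir,
                                            sprintf("dmp_%s.tsv", ct$name))),
                       error = function(e) data.frame())
      dist <- if (nrow(dmps)) distributionTable(dmps, manifest) else NULL
      tab <- if (is.null(dist)) data.frame() else
        cbind(axis = rep(c("geneRegion", "island"),
                         c(nrow(dist$geneRegion), nrow(dist$island))),
              class = c(rownames(dist$geneRegion), rownames(dist$island)),
              rbind(dist$geneRegion, dist$island))
      .writeDelim(tab, file.path(outDir, sprintf("distribution_%s.tsv",
                                                 ct$name)))
      dmpSets[[ct$name]] <- if (nrow(dmps)) dmps$probe_id else character()
      enr <- data.frame()
      if (nrow(dmps) && !is.null(sets)) {
        genes <- genesWithPromoterDMP(dmps, manifest)
        if (length(genes))
          enr <- hypergeometricEnrichment(genes, universe, sets,
                                          alpha = cfg$enrichmentAlpha)
      }
      .writeDelim(enr, file.path(outDir, sprintf("enrichment_%s.tsv",
                                                 ct$name)))
    }
    nonEmpty <- dmpSets[lengths(dmpSets) > 0]
    ov <- if (length(nonEmpty) >= 2L) overlapSets(nonEmpty) else data.frame()
    .writeDelim(ov, file.path(outDir, "overlap_dmps.tsv"))
  })

  ## ---- stage: score ----------------------------------------------------
  scoreCfg <- config$score %||% list()
  scoreContrast <- scoreCfg$contrast %||% "before_vs_after"
  pathwayName <- scoreCfg$pathway %||% "ACTIVITY_PATHWAY"
  scoreFiles <- file.path(outDir, c("score_model.json", "scores.tsv",
                                    "score_correlation.json"))
  stages$score <- .runStage(
    state, "score",
    c(filtBeta, file.path(outDir, sprintf("dmp_%s.tsv", scoreContrast)),
      pth(c("manifest.csv", "samples.csv")),
      if (file.exists(gmtFile)) gmtFile),
    scoreFiles, cfg["scoreRThreshold"], function() {
    me <- loadProcessed()
    dmps <- tryCatch(.readDelim(file.path(outDir,
                                          sprintf("dmp_%s.tsv",
                                                  scoreContrast))),
                     error = function(e) data.frame())
    sets <- if (file.exists(gmtFile)) readGMT(gmtFile) else list()
    pathwayGenes <- sets[[pathwayName]] %||% character()
    sel <- if (nrow(dmps) && length(pathwayGenes))
      selectActivityDMPs(dmps, pathwayGenes, me,
                         rThreshold = cfg$scoreRThreshold)
    else data.frame(probe_id = character(), gene = character(),
                    r_sel = numeric())
    if (nrow(sel)) {
      model <- fitScoreModel(me, sel, rThreshold = cfg$scoreRThreshold)
      scores <- computeScores(me, model)
      sheet <- sampleSheet(me)
      corr <- tryCatch(
        correlateScoreActivity(scores, sheet,
                               selectionSamples =
                                 sheet$sample_id[!is.na(sheet$pasi)]),
        error = function(e) list(r = NA_real_, p = NA_real_, n = 0L,
                                 nSharedWithSelection = NA_integer_))
      jsonlite::write_json(
        list(probe_ids = model@probeIds, mean_HC = model@meanHC,
             SD_HC = model@sdHC, r_sel = model@rSel,
             r_threshold = model@rThreshold),
        scoreFiles[1L], auto_unbox = FALSE, digits = NA)
      .writeDelim(data.frame(sample_id = names(scores), score = scores,
                             pasi = sheet$pasi[match(names(scores),
                                                     sheet$sample_id)]),
                  scoreFiles[2L])
      jsonlite::write_json(corr, scoreFiles[3L], auto_unbox = TRUE,
                           digits = NA)
    } else {
      jsonlite::write_json(list(probe_ids = character()), scoreFiles[1L])
      .writeDelim(data.frame(), scoreFiles[2L])
      jsonlite::write_json(list(r = NA, p = NA, n = 0), scoreFiles[3L],
                           auto_unbox = TRUE)
    }
  })

  ## ---- run manifest ----------------------------------------------------
  inputDigests <- tools::md5sum(Filter(file.exists,
                                       pth(c("beta.csv", "manifest.csv",
                                             "samples.csv",
                                             "detection_p.csv",
                                             "pathways.gmt"))))
  rowCount <- function(f) if (file.exists(f))
    max(0L, length(readLines(f, warn = FALSE)) - 1L) else NA_integer_
  manifestOut <- list(
    tool = "methylCD8",
    version = as.character(utils::packageVersion("methylCD8")),
    seed = cfg$seed,
    config = list(analysis = cfg, score = scoreCfg,
                  simulate = config$simulate),
    inputDigests = as.list(inputDigests),
    stageRowCounts = list(
      filtered_probes = rowCount(filtBeta),
      dmps = lapply(stats::setNames(nm = vapply(contrasts, `[[`, "",
                                                "name")),
                    function(nm) rowCount(
                      file.path(outDir, sprintf("dmp_%s.tsv", nm))))),
    stages = stages)
  jsonlite::write_json(manifestOut, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifestOut)
}

## DMR GRanges -> flat table mirroring the region-report layout
.dmrsToTable <- function(gr) {
  if (!length(gr))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), width = integer(), strand = character(),
                      n_cpgs = integer(), stouffer = numeric(),
                      hmfdr = numeric(), fisher = numeric(),
                      maxdiff = numeric(), meandiff = numeric(),
                      overlapping_genes = character()))
  mc <- S4Vectors::mcols(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    width = GenomicRanges::width(gr), strand = "*",
    n_cpgs = mc$nCpgs, stouffer = mc$stouffer, hmfdr = mc$hmfdr,
    fisher = mc$fisher, maxdiff = mc$maxdiff, meandiff = mc$meandiff,
    overlapping_genes = vapply(mc$genes, paste, character(1L),
                               collapse = ";"),
    stringsAsFactors = FALSE)
}
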