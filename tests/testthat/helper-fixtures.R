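## Shared fixtures, built in code. Everything is seeded and small.

## a hand-written 6-probe manifest covering all region/island labels
tinyManifest <- function() {
  df <- data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05", "cg06"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    pos = c(100L, 300L, 900L, 150L, 600L, 5000L),
    strand = "*",
    probe_type = c("I", "II", "II", "I", "II", "II"),
    genes = c("GENE1", "GENE1", "GENE2", "", "GENE3;GENE4", "GENE5"),
    gene_regions = c("TSS200", "Body", "5UTR", "", "Body;TSS1500", "3UTR"),
    island_context = c("Island", "Shore", "OpenSea", "Shelf", "Island",
                       "OpenSea"),
    stringsAsFactors = FALSE)
  methylCD8:::.manifestToGRanges(df)
}

## a deterministic experiment over the tiny manifest
tinyExperiment <- function(nSamples = 6L, seed = 1L) {
  set.seed(seed)
  man <- tinyManifest()
  ids <- S4Vectors::mcols(man)$probeId
  beta <- matrix(runif(length(ids) * nSamples, 0.1, 0.9),
                 nrow = length(ids),
                 dimnames = list(ids, sprintf("s%02d", seq_len(nSamples))))
  sheet <- data.frame(
    sample_id = colnames(beta),
    subject_id = colnames(beta),
    group = rep(c("HC", "Pso"), length.out = nSamples),
    stringsAsFactors = FALSE)
  MethylationExperiment(beta, man, sheet)
}

## small cohort design used across tests (fast, keeps planted structure)
smallDesign <- function(seed = 1L, nProbes = 4000L, ...) {
  cohortDesign(nProbes = nProbes, seed = seed, ...)
}

## design with no planted effects at all (pure null)
nullDesign <- function(seed, nProbes = 5000L, nHC = 9L, nPso = 10L) {
  cohortDesign(nHC = nHC, nPso = nPso, nPsA = 0L, nPairedTreated = 0L,
               nProbes = nProbes, fracDmp = 0, deltaBetaEffect = 0,
               dmrBlocks = data.frame(chrom = character(),
                                      startIndex = integer(),
                                      nCpgs = integer(), effect = numeric()),
               nBatches = 1L, batchShiftSd = 0, nActivityCpgs = 0L,
               seed = seed)
}

## interval Jaccard between one truth interval and a set of called DMRs
intervalJaccard <- function(truthGr, calledGr) {
  if (!length(calledGr)) return(0)
  hits <- GenomicRanges::findOverlaps(calledGr, truthGr)
  if (!length(hits)) return(0)
  cl <- calledGr[unique(S4Vectors::queryHits(hits))]
  inter <- sum(GenomicRanges::width(GenomicRanges::pintersect(
    rep(truthGr, length(cl)), cl)))
  lo <- min(GenomicRanges::start(cl), GenomicRanges::start(truthGr))
  hi <- max(GenomicRanges::end(cl), GenomicRanges::end(truthGr))
  inter / (hi - lo + 1)
}

## full preprocess + paired treatment DMP + score chain on one cohort;
## returns the pieces the end-to-end tests assert on
runScoreChain <- function(seed, nProbes = 20000L) {
  design <- cohortDesign(seed = seed, nProbes = nProbes)
  sim <- generateCohort(design)
  flt <- filterProbes(sim$experiment, sim$truth$excludedSnp,
                      sim$truth$excludedCrossreactive)
  me <- normalizeProbeTypes(flt$experiment)
  sheet <- sampleSheet(me)
  M <- combatCorrect(mValues(me), sheet$batch, sheet$group)
  SummarizedExperiment::assay(me, "beta") <- mToBeta(M)
  dm <- callDMPs(me, c("before", "after"), groupBy = "timepoint",
                 paired = TRUE)
  sets <- generatePathwaySets(probeManifest(me),
                              activityProbes = sim$truth$activityProbes,
                              seed = seed)
  sel <- selectActivityDMPs(dm$dmps, sets$ACTIVITY_PATHWAY, me)
  out <- list(sim = sim, me = me, dmps = dm$dmps, sel = sel,
              sheet = sheet, r = NA_real_, p = NA_real_,
              afterHigher = logical())
  if (nrow(sel)) {
    model <- fitScoreModel(me, sel, rThreshold = 0.8)
    scores <- computeScores(me, model)
    corr <- correlateScoreActivity(scores, sheet)
    pairsSub <- sheet$subject_id[sheet$timepoint == "after"]
    out$afterHigher <- vapply(pairsSub, function(s) {
      sa <- scores[sheet$sample_id[sheet$subject_id == s &
                                     sheet$timepoint == "after"]]
      sb <- scores[sheet$sample_id[sheet$subject_id == s &
                                     sheet$timepoint == "before"]]
      unname(sa > sb)
    }, logical(1L))
    out$r <- corr$r
    out$p <- corr$p
    out$scores <- scores
  }
  out
}

## memoized expensive simulations shared between test files
.simCache <- new.env(parent = emptyenv())

## 200 effect-free replicates: per-replicate p-values fraction, DMP count
## and DMR count (HC vs Pso, n = 9 vs 10, 5000 probes)
nullSimulation <- function(nReps = 200L) {
  key <- paste0("null", nReps)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  res <- lapply(seq_len(nReps), function(i) {
    sim <- generateCohort(nullDesign(seed = 1000L + i))
    dm <- callDMPs(sim$experiment, c("HC", "Pso"))
    gr <- callDMRs(dm$stats, probeManifest(sim$experiment), minCpgs = 5L)
    list(fracP05 = mean(dm$stats$p < 0.05), nDmp = nrow(dm$dmps),
         nDmr = length(gr))
  })
  out <- list(fracP05 = vapply(res, `[[`, numeric(1L), "fracP05"),
              nDmp = vapply(res, `[[`, numeric(1L), "nDmp"),
              nDmr = vapply(res, `[[`, numeric(1L), "nDmr"))
  .simCache[[key]] <- out
  out
}
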