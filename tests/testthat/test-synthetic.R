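test_that("generated manifests respect layout, ordering and determinism", {
  d1 <- cohortDesign(nProbes = 100L,
                     chromLayout = data.frame(chrom = "chr1",
                                              nProbes = 100L,
                                              meanSpacing = 500),
                     dmrBlocks = data.frame(chrom = character(),
                                            startIndex = integer(),
                                            nCpgs = integer(),
                                            effect = numeric()),
                     seed = 2L)
  man <- generateManifest(d1)
  expect_length(man, 100L)
  expect_identical(unique(as.character(GenomicRanges::seqnames(man))),
                   "chr1")
  expect_true(all(diff(GenomicRanges::start(man)) > 0))

  d2 <- cohortDesign(nProbes = 200L,
                     chromLayout = data.frame(chrom = c("chrA", "chrB"),
                                              nProbes = c(120L, 80L),
                                              meanSpacing = 500),
                     dmrBlocks = data.frame(chrom = character(),
                                            startIndex = integer(),
                                            nCpgs = integer(),
                                            effect = numeric()),
                     seed = 2L)
  man2 <- generateManifest(d2)
  for (ch in c("chrA", "chrB")) {
    p <- GenomicRanges::start(man2[GenomicRanges::seqnames(man2) == ch])
    expect_true(all(diff(p) > 0))
  }

  expect_identical(generateManifest(d1), generateManifest(d1))
  d3 <- d1; d3@seed <- 99L
  expect_false(identical(generateManifest(d1), generateManifest(d3)))
})

test_that("cohort generation is deterministic and respects invariants", {
  design <- smallDesign(seed = 8L, nProbes = 2000L)
  sim1 <- generateCohort(design)
  sim2 <- generateCohort(design)
  expect_identical(betaValues(sim1$experiment), betaValues(sim2$experiment))
  expect_identical(sim1$truth, sim2$truth)

  beta <- betaValues(sim1$experiment)
  expect_true(min(beta) >= 0 && max(beta) <= 1)
  manIds <- S4Vectors::mcols(probeManifest(sim1$experiment))$probeId
  for (ids in sim1$truth$dmpProbes) expect_true(all(ids %in% manIds))
  expect_true(all(sim1$truth$activityProbes %in% manIds))

  ## every truth DMR interval covers at least its declared CpG count
  tr <- sim1$truth$dmrIntervals$HC_vs_Pso
  man <- probeManifest(sim1$experiment)
  for (i in seq_along(tr)) {
    n <- sum(GenomicRanges::countOverlaps(man, tr[i]))
    expect_gte(n, S4Vectors::mcols(tr)$nCpgs[i])
  }

  ## HC samples: no PASI, timepoint none; pairs share subject ids
  sheet <- sampleSheet(sim1$experiment)
  expect_true(all(is.na(sheet$pasi[sheet$group == "HC"])))
  expect_true(all(sheet$timepoint[sheet$group == "HC"] == "none"))
  aft <- sheet$subject_id[sheet$timepoint == "after"]
  expect_true(all(aft %in% sheet$subject_id[sheet$timepoint == "before"]))
})

test_that("planted group effects land near the requested delta beta", {
  design <- cohortDesign(nHC = 10L, nPso = 10L, nPsA = 0L,
                         nPairedTreated = 0L, nProbes = 10000L,
                         fracDmp = 0.01, deltaBetaEffect = 0.2,
                         nBatches = 1L, batchShiftSd = 0,
                         nActivityCpgs = 0L, seed = 21L)
  sim <- generateCohort(design)
  sheet <- sampleSheet(sim$experiment)
  beta <- betaValues(sim$experiment)
  planted <- sim$truth$dmpProbes$HC_vs_Pso   # isolated DMPs + block CpGs
  dBeta <- rowMeans(beta[planted, sheet$group == "Pso", drop = FALSE]) -
    rowMeans(beta[planted, sheet$group == "HC", drop = FALSE])
  expect_true(median(abs(abs(dBeta) - 0.2)) < 0.05)
  expect_gt(mean(abs(abs(dBeta) - 0.2) < 0.05), 0.8)
})

test_that("null generator yields exchangeable groups at the nominal rate", {
  sim <- generateCohort(nullDesign(seed = 77L))
  dm <- callDMPs(sim$experiment, c("HC", "Pso"))
  ## ~ alpha * n_probes uncorrected positives, none after the joint rule
  expect_equal(mean(dm$stats$p < 0.05), 0.05, tolerance = 0.35)
  expect_lte(nrow(dm$dmps), 1L)
})

test_that("marginal beta distribution is trimodal", {
  sim <- generateCohort(smallDesign(seed = 13L, nProbes = 8000L))
  sheet <- sampleSheet(sim$experiment)
  hc <- betaValues(sim$experiment)[, sheet$group == "HC", drop = FALSE]
  d <- stats::density(rowMeans(hc), n = 512)
  y <- d$y
  localMax <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- localMax[y[localMax] > 0.15 * max(y)]
  expect_gte(length(peaks), 3L)
  ## one peak per canonical band: low, mid, high methylation
  expect_true(any(d$x[peaks] < 0.25))
  expect_true(any(d$x[peaks] > 0.35 & d$x[peaks] < 0.65))
  expect_true(any(d$x[peaks] > 0.75))
})

test_that("pathway set generation plants the activity set and is seeded", {
  design <- smallDesign(seed = 4L, nProbes = 2000L)
  sim <- generateCohort(design)
  man <- probeManifest(sim$experiment)
  sets <- generatePathwaySets(man, nTerms = 10L,
                              activityProbes = sim$truth$activityProbes,
                              seed = 4L)
  mc <- S4Vectors::mcols(man)
  actGenes <- sort(unique(unlist(
    mc$genes[match(sim$truth$activityProbes, mc$probeId)],
    use.names = FALSE)))
  expect_identical(sets$ACTIVITY_PATHWAY, actGenes)
  universe <- unique(unlist(mc$genes, use.names = FALSE))
  for (s in sets) expect_true(all(s %in% universe))
  expect_identical(sets, generatePathwaySets(
    man, nTerms = 10L, activityProbes = sim$truth$activityProbes,
    seed = 4L))
  expect_error(generatePathwaySets(man, nTerms = 0L), "nTerms")
})

test_that("cohort design validates its own invariants", {
  expect_error(cohortDesign(nProbes = 0L), "nProbes|sum")
  expect_error(cohortDesign(fracDmp = 1.5), "fracDmp")
  expect_error(cohortDesign(nProbes = 100L,
                            chromLayout = data.frame(chrom = "chr1",
                                                     nProbes = 99L,
                                                     meanSpacing = 500)),
               "sum to nProbes")
})
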