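## hand-built experiment where probe-PASI correlations are controlled
scoreFixture <- function() {
  ids <- c("cg01", "cg02", "cg03", "cg04")
  man <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids, chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    strand = "*", probe_type = "II",
    genes = c("TNFG1", "TNFG1", "OTHER", "TNFG2"),
    gene_regions = "Body", island_context = "OpenSea"))
  pasi <- c(2, 5, 8, 11, 14, 17)
  set.seed(101)
  ## cg01: strong negative; cg02: weak; cg03: strong but outside pathway;
  ## cg04: strong positive
  beta <- rbind(
    cg01 = 0.8 - 0.03 * pasi + rnorm(6, 0, 0.005),
    cg02 = 0.5 + c(0.1, -0.1, 0.12, -0.12, 0.09, -0.09),
    cg03 = 0.2 + 0.03 * pasi,
    cg04 = 0.1 + 0.03 * pasi + rnorm(6, 0, 0.005))
  hcBeta <- matrix(runif(4 * 4, 0.35, 0.65), 4L)
  beta <- cbind(beta, hcBeta)
  dimnames(beta) <- list(ids, c(sprintf("P%d", 1:6), sprintf("H%d", 1:4)))
  sheet <- data.frame(
    sample_id = colnames(beta),
    subject_id = colnames(beta),
    group = rep(c("Pso", "HC"), c(6L, 4L)),
    timepoint = rep(c("before", "none"), c(6L, 4L)),
    pasi = c(pasi, rep(NA, 4L)))
  list(me = MethylationExperiment(beta, man, sheet),
       dmps = data.frame(probe_id = ids,
                         direction = c("hypo", "hyper", "hyper", "hyper")),
       pathway = c("TNFG1", "TNFG2"))
}

test_that("activity DMP selection applies pathway and |r| rules", {
  fx <- scoreFixture()
  sel <- selectActivityDMPs(fx$dmps, fx$pathway, fx$me, rThreshold = 0.8)
  ## cg01 (r ~ -1) and cg04 (r ~ +1) pass; cg02 weak; cg03 not in pathway
  expect_setequal(sel$probe_id, c("cg01", "cg04"))
  expect_lt(sel$r_sel[sel$probe_id == "cg01"], -0.8)
  expect_gt(sel$r_sel[sel$probe_id == "cg04"], 0.8)
  expect_false("cg03" %in% sel$probe_id)

  ## a zero threshold admits every pathway candidate with any correlation
  selAll <- selectActivityDMPs(fx$dmps, fx$pathway, fx$me, rThreshold = 0)
  expect_setequal(selAll$probe_id, c("cg01", "cg02", "cg04"))

  ## no candidates after pathway restriction -> empty with warning
  expect_warning(
    out <- selectActivityDMPs(fx$dmps, "UNRELATED_GENE", fx$me),
    "score undefined")
  expect_identical(nrow(out), 0L)
})

test_that("score model captures healthy-control moments exactly", {
  ids <- c("cg01", "cg02")
  man <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids, chrom = "chr1", pos = c(1L, 2L), strand = "*",
    probe_type = "II", genes = "G", gene_regions = "Body",
    island_context = "OpenSea"))
  beta <- matrix(c(0.4, 0.3, 0.6, 0.3), 2L,
                 dimnames = list(ids, c("H1", "H2")))
  sheet <- data.frame(sample_id = c("H1", "H2"), group = "HC")
  me <- MethylationExperiment(beta, man, sheet)
  expect_warning(model <- fitScoreModel(me, ids), "constant")
  expect_identical(selectedProbes(model), "cg01")
  expect_equal(model@meanHC, c(cg01 = 0.5))
  expect_equal(model@sdHC, c(cg01 = stats::sd(c(0.4, 0.6))),
               tolerance = 1e-12)
  expect_equal(unname(model@sdHC), 0.1414, tolerance = 1e-3)
  ## refit is identical
  expect_warning(model2 <- fitScoreModel(me, ids))
  expect_identical(model, model2)
})

test_that("score algebra: zero at HC means, +1 per SD, HC cohort centred", {
  set.seed(55)
  n <- 12L
  ids <- sprintf("cg%02d", 1:5)
  man <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids, chrom = "chr1", pos = 1:5 * 10L, strand = "*",
    probe_type = "II", genes = "G", gene_regions = "Body",
    island_context = "OpenSea"))
  beta <- matrix(runif(5 * n, 0.2, 0.8), 5L,
                 dimnames = list(ids, sprintf("H%02d", 1:n)))
  sheet <- data.frame(sample_id = colnames(beta), group = "HC")
  me <- MethylationExperiment(beta, man, sheet)
  model <- fitScoreModel(me, ids)

  ## a sample sitting exactly on the HC means scores 0
  atMean <- matrix(model@meanHC, 5L, 2L,
                   dimnames = list(ids, c("x1", "x2")))
  ## one probe exactly 1 SD above its mean shifts the score by +1
  atMean[3L, 2L] <- atMean[3L, 2L] + model@sdHC[3L]
  me2 <- MethylationExperiment(atMean, man,
                               data.frame(sample_id = c("x1", "x2")))
  sc <- computeScores(me2, model)
  expect_equal(unname(sc["x1"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc["x2"]), 1, tolerance = 1e-12)

  ## the reference cohort itself is centred at 0
  scHC <- computeScores(me, model)
  expect_equal(mean(scHC), 0, tolerance = 1e-10)

  ## affine invariance: shifting one probe everywhere moves all scores
  ## equally, so correlations with any covariate are unchanged
  shifted <- pmin(pmax(betaValues(me) +
                         c(0.05, 0, 0, 0, 0), 0), 1)
  me3 <- MethylationExperiment(shifted, man, sheet)
  sc3 <- computeScores(me3, model)
  expect_equal(stats::var(sc3 - scHC), 0, tolerance = 1e-20)

  ## missing probe is named
  expect_error(computeScores(me2[ids[-3L], ], model), "cg03")
})

test_that("score-PASI correlation handles exact and degenerate cases", {
  pasi <- stats::setNames(c(3, 7, 11, 15), sprintf("s%d", 1:4))
  scores <- -pasi
  corr <- correlateScoreActivity(scores, pasi)
  expect_equal(corr$r, -1, tolerance = 1e-12)
  expect_identical(corr$n, 4L)
  ## NA PASI pairs are excluded
  pasi2 <- c(pasi, s5 = NA_real_)
  scores2 <- c(scores, s5 = 99)
  expect_identical(correlateScoreActivity(scores2, pasi2)$n, 4L)
  expect_error(correlateScoreActivity(scores[1:2], pasi[1:2]), ">= 3")
  expect_error(correlateScoreActivity(
    stats::setNames(rep(1, 4), names(pasi)), pasi), "zero variance")
  ## selection overlap is reported, not hidden
  corr3 <- correlateScoreActivity(scores, pasi,
                                  selectionSamples = names(pasi)[1:3])
  expect_identical(corr3$nSharedWithSelection, 3L)
})

test_that("uninformative scores rarely show strong PASI correlation", {
  set.seed(77)
  hits <- vapply(1:60, function(i) {
    s <- stats::setNames(rnorm(100), sprintf("s%d", 1:100))
    p <- stats::setNames(runif(100, 0, 20), names(s))
    abs(correlateScoreActivity(s, p)$r) < 0.3
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})
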