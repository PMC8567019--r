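test_that("beta/M transforms are exact, monotone and mutually inverse", {
  expect_equal(betaToM(0.5), 0)
  expect_equal(betaToM(0.8), 2)
  expect_equal(betaToM(0.2), -2)
  b <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  expect_true(all(diff(betaToM(b)) > 0))
  expect_equal(mToBeta(betaToM(b)), b, tolerance = 1e-10)
  ## boundary values stay finite through clipping
  expect_true(all(is.finite(betaToM(c(0, 1)))))
  expect_lt(max(abs(betaToM(c(0, 1)))), 20)
  expect_error(betaToM(1.2), "\\[0, 1\\]")
})

test_that("probe filter applies the four rules in order with exact counts", {
  ids <- sprintf("cg%02d", 1:10)
  beta <- matrix(0.5, 10, 3, dimnames = list(ids, c("a", "b", "c")))
  detP <- matrix(0, 10, 3, dimnames = dimnames(beta))
  detP[4L, 2L] <- 0.02                      # fails detection in one sample
  man <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids, chrom = "chr1", pos = 1:10 * 100L, strand = "*",
    probe_type = "II", genes = "", gene_regions = "",
    island_context = "OpenSea"))
  me <- MethylationExperiment(beta, man, detectionP = detP)
  ## 10-probe toy: 2 SNP, 1 cross-reactive, 1 failing detection -> 6 kept
  res <- filterProbes(me, snpList = ids[c(1L, 2L)],
                      crossreactiveList = ids[9L])
  expect_identical(res$report$nRemovedDetection, 1L)
  expect_identical(res$report$nRemovedSnp, 2L)
  expect_identical(res$report$nRemovedNonCpg, 0L)
  expect_identical(res$report$nRemovedCrossreactive, 1L)
  expect_identical(res$report$nRetained, 6L)
  with(res$report, expect_identical(
    nInput - nRemovedDetection - nRemovedSnp - nRemovedNonCpg -
      nRemovedCrossreactive, nRetained))
  ## order preserved
  expect_identical(rownames(res$experiment), ids[-c(1, 2, 4, 9)])

  ## non-CpG-context probes (ch./rs. ids) are removed by rule (iii)
  ids2 <- ids; ids2[7L] <- "ch.1.000007"
  beta2 <- beta; rownames(beta2) <- ids2
  man2 <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids2, chrom = "chr1", pos = 1:10 * 100L, strand = "*",
    probe_type = "II", genes = "", gene_regions = "",
    island_context = "OpenSea"))
  me2 <- MethylationExperiment(beta2, man2)
  res2 <- filterProbes(me2)
  expect_identical(res2$report$nRemovedNonCpg, 1L)
  expect_identical(res2$report$removedIds$noncpg, "ch.1.000007")
  expect_identical(res2$report$nRetained, 9L)

  ## precedence: a probe failing detection AND on the SNP list counts once,
  ## under the first matching rule (detection)
  detP3 <- detP; detP3[1L, 1L] <- 0.5
  me3 <- MethylationExperiment(beta, man, detectionP = detP3)
  res3 <- filterProbes(me3, snpList = ids[1L])
  expect_identical(res3$report$nRemovedDetection, 2L)
  expect_identical(res3$report$nRemovedSnp, 0L)

  ## empty lists and clean detection p -> identity
  me4 <- MethylationExperiment(beta, man)
  res4 <- filterProbes(me4)
  expect_identical(res4$report$nRetained, 10L)
  expect_identical(betaValues(res4$experiment), beta)

  ## unknown exclusion ids are ignored with a warning
  expect_warning(filterProbes(me4, snpList = "cg_not_here"), "absent")
})

test_that("probe-type normalization maps type II onto type I quantiles", {
  set.seed(31)
  n1 <- 200L; n2 <- 400L
  ids <- sprintf("cg%04d", seq_len(n1 + n2))
  type <- rep(c("I", "II"), c(n1, n2))
  man <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids, chrom = "chr1", pos = seq_len(n1 + n2) * 50L,
    strand = "*", probe_type = type, genes = "", gene_regions = "",
    island_context = "OpenSea"))

  ## identical empirical distributions -> identity
  ids0 <- sprintf("cg9%03d", seq_len(2L * n1))
  man0 <- methylCD8:::.manifestToGRanges(data.frame(
    probe_id = ids0, chrom = "chr1", pos = seq_len(2L * n1) * 50L,
    strand = "*", probe_type = rep(c("I", "II"), each = n1), genes = "",
    gene_regions = "", island_context = "OpenSea"))
  v <- runif(n1)
  beta0 <- matrix(c(v, sample(v)), ncol = 1L, dimnames = list(ids0, "s1"))
  me0 <- MethylationExperiment(beta0, man0)
  expect_equal(betaValues(normalizeProbeTypes(me0)), beta0,
               tolerance = 1e-9)

  ## type II shifted on the M scale: KS distance shrinks, type I untouched
  b1 <- runif(n1, 0.05, 0.95)
  b2 <- mToBeta(betaToM(runif(n2, 0.05, 0.95)) + 1)
  beta <- matrix(c(b1, b2), ncol = 1L, dimnames = list(ids, "s1"))
  me <- MethylationExperiment(beta, man)
  out <- betaValues(normalizeProbeTypes(me))
  ksBefore <- suppressWarnings(stats::ks.test(b1, b2)$statistic)
  ksAfter <- suppressWarnings(stats::ks.test(
    out[type == "I", 1L], out[type == "II", 1L])$statistic)
  expect_lt(ksAfter, ksBefore)
  expect_identical(out[type == "I", 1L], beta[type == "I", 1L])
  expect_true(all(out >= 0 & out <= 1))

  ## monotone: order of any two type II probes preserved
  o <- order(beta[type == "II", 1L])
  expect_true(all(diff(out[type == "II", 1L][o]) >= 0))

  expect_error(normalizeProbeTypes(tinyExperiment()), "at least 10")
})

test_that("batch correction removes planted shifts and guards its inputs", {
  set.seed(7)
  ## methylation-scale residual noise (M-value probe noise ~0.25): a +1
  ## constant batch shift is then an order of magnitude above the noise
  p <- 2000L; n <- 40L
  batch <- rep(c("A", "B"), each = n / 2)
  group <- rep(rep(c("g1", "g2"), each = n / 4), 2L)
  M <- matrix(rnorm(p * n, sd = 0.25), p, n) + 2
  M[, batch == "B"] <- M[, batch == "B"] + 1

  ## single batch -> identity
  expect_identical(combatCorrect(M, rep("A", n)), M)

  Mc <- combatCorrect(M, batch, group)
  expect_identical(dim(Mc), dim(M))
  d <- abs(rowMeans(Mc[, batch == "B"]) - rowMeans(Mc[, batch == "A"]))
  expect_lt(median(d), 0.05)

  expect_error(combatCorrect(M, c("A", rep("B", n - 1L))),
               "single sample")
  expect_error(combatCorrect(M, batch, batch), "confounded")
})

test_that("batch correction agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  set.seed(8)
  p <- 500L; n <- 24L
  batch <- rep(c("A", "B"), each = n / 2)
  group <- rep(rep(c("g1", "g2"), each = n / 4), 2L)
  M <- matrix(rnorm(p * n, sd = sqrt(rchisq(p, 6) / 6)), p, n) + 4
  M[, batch == "B"] <- M[, batch == "B"] + rnorm(1, 0.8, 0.1)
  mine <- combatCorrect(M, batch, group)
  ref <- suppressMessages(sva::ComBat(
    M, batch = batch, mod = stats::model.matrix(~ factor(group)),
    par.prior = TRUE))
  expect_lt(max(abs(mine - ref)), 1e-3)
})

test_that("batch correction preserves balanced group effects and is a
           near fixed point on corrected data", {
  set.seed(9)
  p <- 3000L; n <- 40L
  batch <- rep(c("A", "B"), each = n / 2)
  group <- rep(rep(c("g1", "g2"), each = n / 4), 2L)
  M <- matrix(rnorm(p * n), p, n)
  M[, group == "g2"] <- M[, group == "g2"] + 0.5
  M[, batch == "B"] <- M[, batch == "B"] + 1
  Mc <- combatCorrect(M, batch, group)
  est <- rowMeans(Mc[, group == "g2"]) - rowMeans(Mc[, group == "g1"])
  expect_equal(median(est), 0.5, tolerance = 0.05)
  ## second application only rescales by residual shrinkage noise: the
  ## median shift is far below the planted batch shift
  M2 <- combatCorrect(Mc, batch, group)
  expect_lt(median(abs(M2 - Mc)), 0.05)
})
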