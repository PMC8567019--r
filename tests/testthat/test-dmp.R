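test_that("trigamma inversion is exact across the useful range", {
  x <- c(1e-5, 1e-3, 0.1, 0.5, 1, 2, 10, 1e3, 1e6)
  expect_equal(trigamma(trigammaInverse(x)), x, tolerance = 1e-8)
})

test_that("moderation prior handles degenerate and planted cases", {
  expect_identical(fitModerationPrior(rep(2, 100), 10),
                   list(d0 = Inf, s0Sq = 2))
  expect_error(fitModerationPrior(rep(0, 50), 10), "zero")
  expect_error(fitModerationPrior(2, 10), "at least 2")

  ## parameter recovery from the stated generative model
  set.seed(1)
  s2 <- 1 * stats::rchisq(1e4, 4) / 4
  pr <- fitModerationPrior(s2, Inf)
  expect_true(pr$d0 >= 3 && pr$d0 <= 5)
  expect_true(pr$s0Sq >= 0.9 && pr$s0Sq <= 1.1)
})

test_that("d0 = 0 reproduces the classical pooled two-sample t exactly", {
  set.seed(2)
  M <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("p%02d", 1:50),
                              sprintf("s%02d", 1:12)))
  lab <- rep(c("A", "B"), each = 6)
  st <- moderatedTTest(M, lab, c("A", "B"), priorDf = 0)
  oracle <- t(apply(M, 1L, function(x) {
    tt <- stats::t.test(x[lab == "B"], x[lab == "A"], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  }))
  expect_equal(st$t, unname(oracle[, "t"]), tolerance = 1e-10)
  expect_equal(st$p, unname(oracle[, "p"]), tolerance = 1e-10)
  expect_equal(st$df_total, rep(10, 50))
})

test_that("d0 = Inf gives the pooled-prior z-like statistic", {
  set.seed(3)
  M <- matrix(rnorm(30 * 10), 30, 10)
  lab <- rep(c("A", "B"), each = 5)
  st <- moderatedTTest(M, lab, c("A", "B"), priorDf = Inf)
  s0 <- attr(st, "prior")$s0Sq
  eff <- rowMeans(M[, lab == "B"]) - rowMeans(M[, lab == "A"])
  expect_equal(st$t, eff / (sqrt(s0) * sqrt(2 / 5)), tolerance = 1e-12)
  expect_equal(st$p, 2 * stats::pnorm(-abs(st$t)), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma reference where the models
           coincide", {
  skip_if_not_installed("limma")
  set.seed(4)
  M <- matrix(rnorm(2000 * 12), 2000, 12) * sqrt(stats::rchisq(2000, 4) / 4)
  lab <- rep(c("A", "B"), each = 6)
  st <- moderatedTTest(M, lab, c("A", "B"))
  fit <- limma::eBayes(limma::lmFit(
    M, stats::model.matrix(~ factor(lab, levels = c("A", "B")))))
  ## the trigamma moment match for d0 is shared by both formulations
  expect_equal(attr(st, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_gt(stats::cor(st$t, fit$t[, 2L]), 0.998)
  ## homoscedastic data: both push d0 towards the no-moderation-needed
  ## regime and the statistics coincide (the two prior parameterizations
  ## agree as d0 grows)
  Mh <- matrix(rnorm(500 * 12), 500, 12)
  sth <- moderatedTTest(Mh, lab, c("A", "B"))
  fith <- limma::eBayes(limma::lmFit(
    Mh, stats::model.matrix(~ factor(lab, levels = c("A", "B")))))
  expect_true(attr(sth, "prior")$d0 > 50)
  expect_equal(attr(sth, "prior")$d0, fith$df.prior, tolerance = 1e-6)
  expect_equal(sth$t, unname(fith$t[, 2L]), tolerance = 0.01)
})

test_that("moderated t is symmetric, exchangeable and null-calibrated", {
  set.seed(5)
  M <- matrix(rnorm(200 * 19), 200, 19)
  lab <- rep(c("A", "B"), c(9, 10))
  st <- moderatedTTest(M, lab, c("A", "B"))
  ## permuting sample order leaves statistics unchanged
  perm <- sample(ncol(M))
  st2 <- moderatedTTest(M[, perm], lab[perm], c("A", "B"))
  expect_equal(st$t, st2$t, tolerance = 1e-12)
  ## swapping the contrast flips the sign
  st3 <- moderatedTTest(M, lab, c("B", "A"))
  expect_equal(st$t, -st3$t, tolerance = 1e-12)
  ## identical group means -> t = 0, p = 1
  M0 <- M
  M0[1L, lab == "B"] <- M0[1L, lab == "A"][c(1:9, 1)] # same mean by copy
  M0[1L, 19L] <- mean(M0[1L, lab == "A"])
  st4 <- moderatedTTest(M0, lab, c("A", "B"))
  expect_equal(st4$t[1L], 0, tolerance = 1e-10)
  expect_equal(st4$p[1L], 1, tolerance = 1e-10)
})

test_that("paired mode runs the one-sample analogue on differences", {
  set.seed(6)
  k <- 8L
  M <- matrix(rnorm(100 * 2 * k), 100, 2 * k)
  lab <- rep(c("before", "after"), each = k)
  subj <- rep(sprintf("s%d", 1:k), 2L)
  st <- moderatedTTest(M, lab, c("before", "after"), paired = TRUE,
                       subject = subj, priorDf = 0)
  D <- M[, lab == "after"] - M[, lab == "before"]
  oracle <- apply(D, 1L, function(d) unname(stats::t.test(d)$statistic))
  expect_equal(st$t, oracle, tolerance = 1e-10)
  expect_error(moderatedTTest(M, lab, c("before", "after"), paired = TRUE),
               "subject")
})

test_that("BH adjustment matches the hand-executed step-up", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  p <- c(0.02, 0.5, 0.02, 0.9)
  fdr <- bhAdjust(p)
  expect_equal(fdr[1L], fdr[3L])      # ties get equal fdr
  expect_true(all(fdr >= p))
  expect_identical(bhAdjust(numeric()), numeric())
})

test_that("DMP calling applies the joint FDR and delta-beta rule", {
  set.seed(7)
  design <- cohortDesign(nHC = 10L, nPso = 10L, nPsA = 0L,
                         nPairedTreated = 0L, nProbes = 3000L,
                         fracDmp = 0.02, deltaBetaEffect = 0.2,
                         nBatches = 1L, batchShiftSd = 0,
                         nActivityCpgs = 0L, seed = 7L)
  sim <- generateCohort(design)
  res <- callDMPs(sim$experiment, c("HC", "Pso"))
  dmps <- res$dmps
  expect_gt(nrow(dmps), 0L)
  expect_true(all(dmps$fdr < 0.05))
  expect_true(all(abs(dmps$delta_beta) > 0.1))
  expect_true(all(dmps$fdr >= dmps$p))
  expect_true(all(abs(dmps$delta_beta) <= 1))
  expect_identical(dmps$direction,
                   ifelse(dmps$delta_beta > 0, "hyper", "hypo"))
  expect_true(!is.unsorted(dmps$fdr))
  ## excluded: significant but small effect, or large effect but not
  ## significant
  st <- res$stats
  excluded <- st[st$fdr < 0.05 & abs(st$delta_beta) <= 0.1, "probe_id"]
  expect_true(!any(excluded %in% dmps$probe_id))
  ## statistics computed on M, effects on beta: the t-rank and the
  ## delta-beta-rank of probes disagree, yet each column matches its scale
  beta <- betaValues(sim$experiment)
  sheet <- sampleSheet(sim$experiment)
  dB <- rowMeans(beta[, sheet$group == "Pso"]) -
    rowMeans(beta[, sheet$group == "HC"])
  expect_equal(unname(st$delta_beta), unname(dB), tolerance = 1e-12)
  expect_false(identical(order(abs(st$t)), order(abs(st$delta_beta))))
  expect_error(callDMPs(sim$experiment, c("HC", "Pso"), fdrThreshold = 1.5),
               "fdrThreshold")
})
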