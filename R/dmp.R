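## Probe-wise differential methylation: empirical-Bayes moderated t-tests
## on M values, BH-FDR, and the |delta beta| effect filter on beta values.

#' Invert the trigamma function
#'
#' Solves trigamma(y) = x by Newton iteration on a monotone transform;
#' used when fitting the moderation prior by matching moments of log s^2.
#'
#' @param x positive numeric vector.
#' @return y with `trigamma(y) = x` (Inf maps to 0+, 0 maps to Inf).
#' @export
trigammaInverse <- function(x) {
  y <- x
  hi <- x > 1e7
  lo <- x < 1e-6 & x > 0
  y[hi] <- 1 / sqrt(x[hi])
  y[lo] <- 1 / x[lo]
  mid <- which(!hi & !lo & x > 0 & is.finite(x))
  if (length(mid)) {
    z <- 0.5 + 1 / x[mid]
    for (it in 1:60) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / x[mid]) / psigamma(z, 2L)
      z <- z + dif
      if (max(-dif / z) < 1e-10) break
    }
    y[mid] <- z
  }
  y[x <= 0] <- Inf
  y[is.infinite(x) & x > 0] <- 0
  y
}

#' Fit the variance-moderation prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0Sq`
#' of the hierarchical variance model: per-probe true variances follow the
#' scaled chi-squared prior sigma^2 ~ s0^2 * chisq(d0)/d0, and the observed
#' residual variances follow s^2 | sigma^2 ~ sigma^2 * chisq(d)/d. Both
#' hyperparameters are obtained by matching the empirical mean and variance
#' of log s^2 to the model's digamma/trigamma moments (the variance match
#' requires inverting the trigamma function). When the observed log s^2
#' carry no excess dispersion beyond chi-squared sampling noise, `d0` is
#' +Inf and `s0Sq` the common variance.
#'
#' @param s2 per-probe residual variances (>= 0; not all zero).
#' @param df residual degrees of freedom (scalar or per-probe; `Inf` means
#'   the variances are observed without sampling noise).
#' @return A list with `d0` and `s0Sq`.
#' @export
fitModerationPrior <- function(s2, df) {
  if (length(s2) < 2L) .err("need at least 2 probes to fit the prior")
  if (all(s2 == 0)) .err("all residual variances are zero (degenerate data)")
  if (any(s2 < 0)) .err("negative residual variance")
  if (any(s2 == 0)) s2 <- pmax(s2, min(s2[s2 > 0]) * 1e-3)
  df <- rep_len(df, length(s2))
  if (any(df < 1)) .err("residual df must be >= 1")
  if (stats::var(log(s2)) == 0)
    return(list(d0 = Inf, s0Sq = s2[[1L]]))
  ## E log chisq(k)/k = digamma(k/2) - log(k/2); vanishes as k -> Inf
  corr <- ifelse(is.finite(df), digamma(df / 2) - log(df / 2), 0)
  tri <- ifelse(is.finite(df), trigamma(df / 2), 0)
  e <- log(s2) - corr
  emean <- mean(e)
  evar <- stats::var(e) - mean(tri)
  if (evar <= 0) return(list(d0 = Inf, s0Sq = mean(s2)))
  d0 <- 2 * trigammaInverse(evar)
  s0Sq <- exp(emean - digamma(d0 / 2) + log(d0 / 2))
  list(d0 = d0, s0Sq = s0Sq)
}

#' Empirical-Bayes moderated t-tests
#'
#' Per-probe two-group comparison on M values with variance moderation:
#' the posterior variance s~^2 = (d0*s0^2 + d*s^2) / (d0 + d) replaces the
#' per-probe variance, and the statistic
#' t = (mean_b - mean_a) / (s~ * sqrt(1/n_a + 1/n_b)) is referred to a t
#' distribution with d0 + d degrees of freedom (two-sided). In paired mode
#' the one-sample analogue is applied to within-subject differences
#' (b minus a). Forcing `priorDf = 0` recovers the classical pooled t-test
#' exactly; `priorDf = Inf` gives a z-like statistic with the pooled prior
#' variance.
#'
#' @param M numeric matrix of M values, probes x samples.
#' @param labels character/factor, one label per sample.
#' @param contrast length-2 character `c(a, b)`; effects are b minus a.
#' @param paired logical; when TRUE `subject` pairs the samples.
#' @param subject subject ids, one per sample (paired mode only).
#' @param priorDf optional override of the fitted prior df (0, finite,
#'   or Inf).
#' @return A data.frame with one row per probe: `probe_id`, `mean_a`,
#'   `mean_b` (M scale), `t`, `df_total`, `p`, `s2` and `s2_post`, plus
#'   attributes `prior` (the [fitModerationPrior()] result actually used)
#'   and `contrast`.
#' @export
moderatedTTest <- function(M, labels, contrast, paired = FALSE,
                           subject = NULL, priorDf = NULL) {
  if (!is.matrix(M)) .err("'M' must be a matrix")
  if (length(labels) != ncol(M)) .err("one label per sample required")
  if (length(contrast) != 2L) .err("'contrast' must name two groups")
  labels <- as.character(labels)
  a <- which(labels == contrast[1L])
  b <- which(labels == contrast[2L])
  if (paired) {
    if (is.null(subject)) .err("paired mode requires 'subject'")
    subject <- as.character(subject)
    common <- intersect(subject[a], subject[b])
    if (length(common) < 2L) .err("paired mode needs >= 2 complete pairs")
    ia <- a[match(common, subject[a])]
    ib <- b[match(common, subject[b])]
    D <- M[, ib, drop = FALSE] - M[, ia, drop = FALSE]
    k <- length(common)
    meanA <- rowMeans(M[, ia, drop = FALSE])
    meanB <- rowMeans(M[, ib, drop = FALSE])
    eff <- rowMeans(D)
    s2 <- .rowVars(D)
    d <- k - 1L
    seScale <- 1 / sqrt(k)
  } else {
    if (length(a) < 2L || length(b) < 2L)
      .err("each contrast group needs >= 2 samples")
    meanA <- rowMeans(M[, a, drop = FALSE])
    meanB <- rowMeans(M[, b, drop = FALSE])
    eff <- meanB - meanA
    va <- .rowVars(M[, a, drop = FALSE])
    vb <- .rowVars(M[, b, drop = FALSE])
    d <- length(a) + length(b) - 2L
    s2 <- ((length(a) - 1L) * va + (length(b) - 1L) * vb) / d
    seScale <- sqrt(1 / length(a) + 1 / length(b))
  }
  prior <- if (is.null(priorDf)) fitModerationPrior(s2, d)
           else if (is.infinite(priorDf))
             list(d0 = Inf, s0Sq = fitModerationPrior(s2, d)$s0Sq)
           else if (priorDf == 0) list(d0 = 0, s0Sq = NA_real_)
           else list(d0 = priorDf, s0Sq = fitModerationPrior(s2, d)$s0Sq)
  s2Post <- if (is.infinite(prior$d0)) rep(prior$s0Sq, length(s2))
            else if (prior$d0 == 0) s2
            else (prior$d0 * prior$s0Sq + d * s2) / (prior$d0 + d)
  se <- sqrt(s2Post) * seScale
  t <- ifelse(se > 0, eff / se, 0)
  dfTotal <- prior$d0 + d
  p <- 2 * stats::pt(-abs(t), df = dfTotal)
  out <- data.frame(probe_id = rownames(M) %||% as.character(seq_len(nrow(M))),
                    mean_a = meanA, mean_b = meanB, t = t,
                    df_total = dfTotal, p = p, s2 = s2, s2_post = s2Post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "contrast") <- contrast
  attr(out, "paired") <- paired
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' `stats::p.adjust(method = "BH")` kept as the package's single FDR entry
#' point.
#'
#' @param p p-values in \[0,1\].
#' @return Adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated positions
#'
#' Runs [moderatedTTest()] on the M values of a contrast, computes effect
#' sizes as differences of group-mean beta values (statistics on M, effects
#' on beta), BH-adjusts the p-values within the contrast, and retains
#' probes with `fdr < fdrThreshold` and `|delta beta| > minDeltaBeta`.
#' Direction is "hyper" when the second-listed contrast group is the more
#' methylated (delta beta > 0), "hypo" otherwise.
#'
#' @param object a [MethylationExperiment] (post-QC/normalization).
#' @param contrast length-2 character; labels of `groupBy` to compare,
#'   effects reported as second minus first.
#' @param groupBy sample-sheet column holding the labels (default "group";
#'   use "timepoint" with `contrast = c("before", "after")` for the
#'   treatment comparison).
#' @param paired run the paired analysis keyed on `subject_id`.
#' @param fdrThreshold,minDeltaBeta retention thresholds (defaults 0.05 and
#'   0.1).
#' @param priorDf optional moderation-prior override (see
#'   [moderatedTTest()]).
#' @return A list with `dmps` (retained records sorted by ascending FDR:
#'   `probe_id`, `mean_beta_a`, `mean_beta_b`, `delta_beta`, `t`,
#'   `df_total`, `p`, `fdr`, `direction`) and `stats` (the full per-probe
#'   table with `delta_beta` and `fdr` added, for region calling).
#' @export
callDMPs <- function(object, contrast, groupBy = "group", paired = FALSE,
                     fdrThreshold = 0.05, minDeltaBeta = 0.1,
                     priorDf = NULL) {
  stopifnot(methods::is(object, "MethylationExperiment"))
  .assertScalarProb(fdrThreshold, "fdrThreshold")
  if (!is.numeric(minDeltaBeta) || minDeltaBeta < 0 || minDeltaBeta >= 1)
    .err("'minDeltaBeta' must lie in [0, 1)")
  sheet <- sampleSheet(object)
  if (!groupBy %in% colnames(sheet))
    .err("sample sheet has no column '", groupBy, "'")
  labels <- as.character(sheet[[groupBy]])
  keep <- labels %in% contrast
  beta <- betaValues(object)[, keep, drop = FALSE]
  labels <- labels[keep]
  subject <- sheet$subject_id[keep]
  M <- betaToM(beta)
  st <- moderatedTTest(M, labels, contrast, paired = paired,
                       subject = subject, priorDf = priorDf)
  ## effect sizes on the beta scale
  a <- which(labels == contrast[1L])
  b <- which(labels == contrast[2L])
  if (paired) {
    common <- intersect(subject[a], subject[b])
    a <- a[match(common, subject[a])]
    b <- b[match(common, subject[b])]
  }
  meanBetaA <- rowMeans(beta[, a, drop = FALSE])
  meanBetaB <- rowMeans(beta[, b, drop = FALSE])
  st$mean_beta_a <- meanBetaA
  st$mean_beta_b <- meanBetaB
  st$delta_beta <- meanBetaB - meanBetaA
  st$fdr <- bhAdjust(st$p)
  sel <- st$fdr < fdrThreshold & abs(st$delta_beta) > minDeltaBeta
  dmps <- st[sel, c("probe_id", "mean_beta_a", "mean_beta_b", "delta_beta",
                    "t", "df_total", "p", "fdr"), drop = FALSE]
  dmps$direction <- ifelse(dmps$delta_beta > 0, "hyper", "hypo")
  dmps <- dmps[order(dmps$fdr, dmps$p), , drop = FALSE]
  rownames(dmps) <- NULL
  list(dmps = dmps, stats = st)
}
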