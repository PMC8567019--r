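## Probe QC, beta/M transforms, probe-type normalization and parametric
## empirical-Bayes batch correction.

#' Beta / M value transforms
#'
#' `betaToM()` is the logit2 transform M = log2(beta / (1 - beta)); beta is
#' first clipped into \[epsilon, 1 - epsilon\] so boundary values stay
#' finite (|M| <= ~19.9 at the default epsilon, far outside the biological
#' range). `mToBeta()` is the inverse logistic; the pair is an identity to
#' within 1e-10 on the clipped domain.
#'
#' @param beta,m numeric vector/matrix.
#' @param epsilon clipping bound, default 1e-6.
#' @return Numeric object of the same shape.
#' @examples
#' betaToM(c(0.2, 0.5, 0.8))   # -2, 0, 2
#' @export
betaToM <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    .err("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  attributes(out) <- attributes(beta)
  out
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  attributes(out) <- attributes(m)
  out
}

#' Quality-control probe filtering
#'
#' Removes, in this fixed order: (i) probes failing the detection p-value
#' cutoff (any sample above `detectionPCutoff`), (ii) probes on a known-SNP
#' exclusion list, (iii) probes not in CpG context (probe ids not starting
#' with "cg", i.e. Illumina "ch"/"rs" probes), and (iv) cross-reactive
#' probes. A probe matching several rules is counted once, at the first
#' matching rule. Exclusion-list ids absent from the matrix are ignored
#' with a warning. Row order of the retained probes is preserved.
#'
#' @param object a [MethylationExperiment].
#' @param snpList,crossreactiveList character vectors of probe ids (may be
#'   empty); see [readIdList()].
#' @param detectionPCutoff detection p-value cutoff, default 0.01.
#' @return A list with `experiment` (the filtered object) and `report`, a
#'   list with counts `nInput`, `nRemovedDetection`, `nRemovedSnp`,
#'   `nRemovedNonCpg`, `nRemovedCrossreactive`, `nRetained` (which
#'   reconcile exactly) and `removedIds` per reason.
#' @export
filterProbes <- function(object, snpList = character(),
                         crossreactiveList = character(),
                         detectionPCutoff = 0.01) {
  stopifnot(methods::is(object, "MethylationExperiment"))
  .assertScalarProb(detectionPCutoff, "detectionPCutoff")
  ids <- rownames(object)
  for (nm in c("snpList", "crossreactiveList")) {
    lst <- get(nm)
    missing <- setdiff(lst, ids)
    if (length(missing))
      .warn(sprintf("%d id(s) on %s absent from the matrix; ignored",
                    length(missing), nm))
  }
  dp <- detectionP(object)
  failDet <- if (is.null(dp)) rep(FALSE, length(ids))
             else apply(dp > detectionPCutoff, 1L, any)
  isSnp <- ids %in% snpList
  nonCpg <- !startsWith(ids, "cg")
  isXr <- ids %in% crossreactiveList
  ## first-matching-rule precedence
  reason <- rep("keep", length(ids))
  reason[isXr] <- "crossreactive"
  reason[nonCpg] <- "noncpg"
  reason[isSnp] <- "snp"
  reason[failDet] <- "detection"
  keep <- reason == "keep"
  report <- list(
    nInput = length(ids),
    nRemovedDetection = sum(reason == "detection"),
    nRemovedSnp = sum(reason == "snp"),
    nRemovedNonCpg = sum(reason == "noncpg"),
    nRemovedCrossreactive = sum(reason == "crossreactive"),
    nRetained = sum(keep),
    removedIds = list(detection = ids[reason == "detection"],
                      snp = ids[reason == "snp"],
                      noncpg = ids[reason == "noncpg"],
                      crossreactive = ids[reason == "crossreactive"]))
  list(experiment = object[keep, ], report = report)
}

#' Probe-type quantile normalization
#'
#' Within each sample, type II beta values are mapped monotonically onto
#' the type I empirical quantile function (rank of each type II value,
#' rescaled to \[0,1\], evaluated against the type I quantiles); type I
#' values are left unchanged. This removes the systematic distributional
#' difference between the two probe chemistries while preserving the
#' within-sample ordering of type II probes. When both chemistries already
#' share the same empirical distribution the mapping is the identity.
#'
#' @param object a [MethylationExperiment] whose manifest labels every
#'   probe "I" or "II".
#' @return A [MethylationExperiment] with the normalized `beta` assay.
#' @export
normalizeProbeTypes <- function(object) {
  stopifnot(methods::is(object, "MethylationExperiment"))
  beta <- betaValues(object)
  type <- S4Vectors::mcols(probeManifest(object))$probeType
  i1 <- type == "I"
  i2 <- type == "II"
  if (sum(i1) < 10L || sum(i2) < 10L)
    .err("need at least 10 probes of each chemistry type to normalize")
  out <- beta
  for (j in seq_len(ncol(beta))) {
    t1 <- beta[i1, j]
    t2 <- beta[i2, j]
    probs <- (rank(t2, ties.method = "average") - 1) / (length(t2) - 1)
    out[i2, j] <- stats::quantile(t1, probs, type = 7, names = FALSE)
  }
  res <- object
  SummarizedExperiment::assay(res, "beta") <- out
  res
}

#' Empirical-Bayes batch correction on M values
#'
#' A parametric empirical-Bayes location/scale batch adjustment of the
#' ComBat family. Per probe, the data are standardized against a model that
#' retains the biological group structure; per-(batch, probe) location
#' (gamma) and scale (delta^2) estimates are shrunk towards normal /
#' inverse-gamma priors whose hyperparameters are fitted by moments across
#' probes, with a fixed-point iteration for the conditional posterior
#' modes; the adjusted data are back-transformed. The group covariate is
#' part of the standardization design, so balanced biological contrasts are
#' preserved. A single-batch input is returned unchanged.
#'
#' @param M numeric matrix of M values, probes x samples.
#' @param batch character/factor of batch labels, one per sample; every
#'   batch needs >= 2 samples.
#' @param group optional character/factor of biological group labels to
#'   protect during standardization. An error is raised when batch and
#'   group are perfectly confounded.
#' @param tol,maxIter fixed-point iteration control (defaults 1e-4, 100).
#' @return The adjusted M matrix (same shape and dimnames).
#' @export
combatCorrect <- function(M, batch, group = NULL, tol = 1e-4,
                          maxIter = 100L) {
  if (!is.matrix(M) || !is.numeric(M)) .err("'M' must be a numeric matrix")
  n <- ncol(M)
  if (length(batch) != n) .err("'batch' must have one label per sample")
  batch <- factor(batch)
  nb <- nlevels(batch)
  if (nb == 1L) return(M)
  sizes <- table(batch)
  if (any(sizes < 2L))
    .err("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  Xb <- stats::model.matrix(~ 0 + batch)
  X <- Xb
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) > 1L) {
      Xg <- stats::model.matrix(~ group)[, -1L, drop = FALSE]
      X <- cbind(Xb, Xg)
      if (qr(X)$rank < ncol(X)) {
        tab <- table(batch, group)
        .err("batch is confounded with group (cannot separate effects); ",
             "batch x group table: ",
             paste(apply(tab, 1L, paste, collapse = "/"), collapse = " | "))
      }
    }
  }
  ## per-probe OLS fit of batch + group
  XtXi <- solve(crossprod(X))
  Bhat <- M %*% X %*% XtXi                       # probes x coef
  gammaHat0 <- Bhat[, seq_len(nb), drop = FALSE] # batch location estimates
  ## grand mean: batch effects averaged with batch-size weights
  w <- as.numeric(sizes) / n
  grand <- as.numeric(gammaHat0 %*% w)
  standMean <- matrix(grand, nrow(M), n)
  if (ncol(X) > nb)
    standMean <- standMean +
      Bhat[, -seq_len(nb), drop = FALSE] %*%
        t(X[, -seq_len(nb), drop = FALSE])
  varPooled <- rowMeans((M - Bhat %*% t(X))^2)
  if (any(!is.finite(varPooled)) || any(varPooled <= 0))
    .err("degenerate probe variance; cannot standardize")
  Z <- (M - standMean) / sqrt(varPooled)
  ## EB shrinkage per batch
  Zadj <- Z
  for (b in levels(batch)) {
    cols <- which(batch == b)
    ni <- length(cols)
    gHat <- rowMeans(Z[, cols, drop = FALSE])
    dHat <- .rowVars(Z[, cols, drop = FALSE])
    gBar <- mean(gHat)
    t2 <- stats::var(gHat)
    m <- mean(dHat)
    s2 <- stats::var(dHat)
    a <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
      ## (near-)zero dispersion across probes: use the raw estimates
      gStar <- gHat
      dStar <- pmax(dHat, 1e-8)
    } else {
      gStar <- gHat
      dStar <- dHat
      for (it in seq_len(maxIter)) {
        gNew <- (ni * t2 * gHat + dStar * gBar) / (ni * t2 + dStar)
        sum2 <- rowSums((Z[, cols, drop = FALSE] - gNew)^2)
        dNew <- (0.5 * sum2 + bPrior) / (ni / 2 + a - 1)
        change <- max(abs(gNew - gStar) / pmax(abs(gStar), 1e-8),
                      abs(dNew - dStar) / dStar)
        gStar <- gNew
        dStar <- dNew
        if (change < tol) break
      }
    }
    Zadj[, cols] <- (Z[, cols, drop = FALSE] - gStar) / sqrt(dStar)
  }
  out <- Zadj * sqrt(varPooled) + standMean
  dimnames(out) <- dimnames(M)
  out
}
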