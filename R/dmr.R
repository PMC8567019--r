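## Region-level differential methylation: Gaussian-kernel smoothing of
## probe statistics, candidate merging along the chromosome, and combined
## region p-values (Stouffer, Fisher, harmonic-mean FDR).

#' Gaussian-kernel smoothing of probe statistics
#'
#' Smooths a per-probe statistic (typically t^2) along one chromosome with
#' a Gaussian kernel of standard deviation `lambda / C`, normalizing the
#' weights so every output value is a convex combination of the inputs.
#' With `lambda` near zero the kernel degenerates and the input is
#' returned.
#'
#' @param x numeric per-probe statistic.
#' @param pos probe positions (bp), sorted ascending.
#' @param lambda kernel bandwidth in bp (default 1000).
#' @param C scaling factor; the kernel SD is `lambda / C` (default 2).
#' @return Smoothed values, same length as `x`.
#' @export
smoothStatistics <- function(x, pos, lambda = 1000, C = 2) {
  if (length(x) != length(pos)) .err("'x' and 'pos' must have equal length")
  if (is.unsorted(pos, strictly = FALSE)) .err("'pos' must be sorted ascending")
  if (lambda <= 0 || C <= 0) .err("'lambda' and 'C' must be positive")
  n <- length(x)
  if (n <= 1L) return(x)
  sdk <- lambda / C
  out <- numeric(n)
  ## kernel support truncated at 4 sd; probes are sorted, so a sliding
  ## window keeps this O(n * window)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (pos[i] - pos[lo] > 4 * sdk) lo <- lo + 1L
    while (hi < n && pos[hi + 1L] - pos[i] <= 4 * sdk) hi <- hi + 1L
    w <- stats::dnorm(pos[lo:hi], mean = pos[i], sd = sdk)
    out[i] <- sum(w * x[lo:hi]) / sum(w)
  }
  out
}

#' Combine probe p-values and FDRs for a region
#'
#' Stouffer: z_i = qnorm(1 - p_i), combined p = 1 - pnorm(sum(z_i)/sqrt(k));
#' Fisher: X = -2 * sum(log p_i) referred to chisq with 2k df (upper tail);
#' HMFDR: the harmonic mean k / sum(1/fdr_i) of the probe FDR values.
#' Zero p-values are clipped to 1e-300 with a warning.
#'
#' @param p probe p-values in (0, 1].
#' @param fdr probe FDR values in (0, 1].
#' @return A list with `stouffer`, `fisher` and `hmfdr`.
#' @export
combinePValues <- function(p, fdr) {
  if (!length(p)) .err("need at least one p-value")
  if (length(fdr) != length(p)) .err("'p' and 'fdr' must have equal length")
  if (any(p < 0 | p > 1) || any(fdr < 0 | fdr > 1))
    .err("p-values and FDRs must lie in [0, 1]")
  if (any(p == 0)) {
    .warn("zero p-value(s) clipped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  fdr <- pmax(fdr, 1e-300)
  k <- length(p)
  z <- stats::qnorm(1 - p)
  stouffer <- stats::pnorm(sum(z) / sqrt(k), lower.tail = FALSE)
  fisher <- stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
  hmfdr <- k / sum(1 / fdr)
  list(stouffer = max(stouffer, 1e-300), fisher = max(fisher, 1e-300),
       hmfdr = hmfdr)
}

#' Call differentially methylated regions
#'
#' From a full per-probe statistics table (as produced by [callDMPs()]
#' `$stats`), candidate probes are those with probe-level `fdr` below
#' `fdrThreshold` whose kernel-smoothed t^2 ([smoothStatistics()]) exceeds
#' the squared-normal 5% critical value; consecutive candidates on one
#' chromosome are merged while the inter-probe gap is at most `lambda`.
#' Merged runs are reported as DMRs when they contain at least `minCpgs`
#' probes and their mean |delta beta| reaches `minMeanAbsDeltaBeta`.
#' Regions carry the combined statistics of [combinePValues()], the signed
#' largest-|delta beta| probe effect (`maxdiff`), the mean effect
#' (`meandiff`) and the union of member-probe gene labels; output is
#' sorted by Fisher p.
#'
#' @param stats data.frame with columns `probe_id`, `p`, `fdr`,
#'   `delta_beta`, `t`.
#' @param manifest probe `GRanges` covering every probe in `stats`.
#' @param minCpgs minimum probes per region (default 5).
#' @param fdrThreshold probe-level FDR gate (default 0.05).
#' @param minMeanAbsDeltaBeta region mean-effect gate (default 0.1).
#' @param lambda,C kernel bandwidth and scaling (defaults 1000 bp, 2).
#' @return A `GRanges` of DMRs (1-based inclusive coordinates) with
#'   metadata columns `nCpgs`, `stouffer`, `hmfdr`, `fisher`, `maxdiff`,
#'   `meandiff`, `genes` (CharacterList) and `probeIds` (CharacterList).
#' @export
callDMRs <- function(stats, manifest, minCpgs = 5L, fdrThreshold = 0.05,
                     minMeanAbsDeltaBeta = 0.1, lambda = 1000, C = 2) {
  if (minCpgs < 2L) .err("'minCpgs' must be >= 2")
  .assertScalarProb(fdrThreshold, "fdrThreshold")
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    nCpgs = integer(), stouffer = numeric(), hmfdr = numeric(),
    fisher = numeric(), maxdiff = numeric(), meandiff = numeric(),
    genes = IRanges::CharacterList(), probeIds = IRanges::CharacterList())
  if (!nrow(stats)) return(empty)
  idx <- match(stats$probe_id, S4Vectors::mcols(manifest)$probeId)
  if (anyNA(idx))
    .err("probe(s) in stats absent from manifest: ",
         paste(utils::head(stats$probe_id[is.na(idx)], 5L), collapse = ", "))
  man <- manifest[idx]
  df <- data.frame(i = seq_len(nrow(stats)),
                   chrom = as.character(GenomicRanges::seqnames(man)),
                   pos = GenomicRanges::start(man))
  ord <- order(df$chrom, df$pos)
  df <- df[ord, ]
  regions <- list()
  tcrit <- stats::qchisq(0.95, df = 1)   # smoothing-elevated gate
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    srow <- stats[sub$i, ]
    smt <- smoothStatistics(srow$t^2, sub$pos, lambda = lambda, C = C)
    cand <- which(srow$fdr < fdrThreshold & smt >= tcrit)
    if (!length(cand)) next
    gap <- c(Inf, diff(sub$pos[cand]))
    runId <- cumsum(gap > lambda)
    for (r in split(cand, runId)) {
      memb <- srow[r, ]
      cp <- combinePValues(memb$p, memb$fdr)
      mx <- memb$delta_beta[which.max(abs(memb$delta_beta))]
      regions[[length(regions) + 1L]] <- list(
        chrom = ch, start = min(sub$pos[r]), end = max(sub$pos[r]),
        nCpgs = length(r), stouffer = cp$stouffer, hmfdr = cp$hmfdr,
        fisher = cp$fisher, maxdiff = mx,
        meandiff = mean(memb$delta_beta),
        genes = sort(unique(unlist(
          S4Vectors::mcols(man)$genes[match(memb$probe_id,
                                            S4Vectors::mcols(man)$probeId)],
          use.names = FALSE))),
        probeIds = memb$probe_id)
    }
  }
  if (!length(regions)) return(empty)
  keep <- vapply(regions, function(r)
    r$nCpgs >= minCpgs && abs(r$meandiff) >= minMeanAbsDeltaBeta,
    logical(1L))
  regions <- regions[keep]
  if (!length(regions)) return(empty)
  regions <- regions[order(vapply(regions, `[[`, numeric(1L), "fisher"))]
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(regions, `[[`, character(1L), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(regions, `[[`, numeric(1L), "start"),
      end = vapply(regions, `[[`, numeric(1L), "end")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    nCpgs = vapply(regions, `[[`, integer(1L), "nCpgs"),
    stouffer = vapply(regions, `[[`, numeric(1L), "stouffer"),
    hmfdr = vapply(regions, `[[`, numeric(1L), "hmfdr"),
    fisher = vapply(regions, `[[`, numeric(1L), "fisher"),
    maxdiff = vapply(regions, `[[`, numeric(1L), "maxdiff"),
    meandiff = vapply(regions, `[[`, numeric(1L), "meandiff"),
    genes = IRanges::CharacterList(lapply(regions, `[[`, "genes")),
    probeIds = IRanges::CharacterList(lapply(regions, `[[`, "probeIds")))
  gr
}
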