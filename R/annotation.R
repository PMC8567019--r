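## Functional genomic distribution of DMPs, set overlaps, and
## hypergeometric over-representation analysis.

#' Genes carrying a promoter DMP
#'
#' Returns the genes with at least one retained DMP annotated to a
#' promoter region (TSS1500, TSS200, 5UTR); with `includeBody = TRUE`
#' gene-body DMPs qualify as well. All annotated genes of a multi-gene
#' probe are considered, and the result is deduplicated.
#'
#' @param dmps data.frame of retained DMPs ([callDMPs()] `$dmps`).
#' @param manifest probe `GRanges`.
#' @param includeBody also accept Body-annotated DMPs.
#' @return Sorted character vector of gene symbols.
#' @export
genesWithPromoterDMP <- function(dmps, manifest, includeBody = FALSE) {
  if (!nrow(dmps)) return(character())
  mc <- S4Vectors::mcols(manifest)
  idx <- match(dmps$probe_id, mc$probeId)
  if (anyNA(idx)) .err("DMP probe(s) absent from manifest")
  qualifying <- .PROMOTER_REGIONS
  if (includeBody) qualifying <- c(qualifying, "Body")
  hits <- mapply(function(g, r) g[r %in% qualifying],
                 as.list(mc$genes[idx]), as.list(mc$geneRegions[idx]),
                 SIMPLIFY = FALSE)
  sort(unique(unlist(hits, use.names = FALSE)))
}

## single-count classification of a probe on the gene-region axis:
## precedence promoter > 3UTR > ExonBnd > Body > IGR
.regionClass <- function(regions) {
  if (!length(regions)) return("IGR")
  if (any(regions %in% .PROMOTER_REGIONS)) return("Promoter")
  if ("3UTR" %in% regions) return("3UTR")
  if ("ExonBnd" %in% regions) return("ExonBnd")
  if ("Body" %in% regions) return("Body")
  "IGR"
}

#' Functional genomic distribution of DMPs
#'
#' Percentages of DMPs over gene-region classes (Promoter = TSS1500 /
#' TSS200 / 5UTR, 3UTR, Body, ExonBnd, IGR) and CpG island classes
#' (Island, Shore, Shelf, OpenSea), split into all / hypermethylated /
#' hypomethylated. Each probe counts once per axis; a multi-gene probe is
#' classified by precedence Promoter > 3UTR > ExonBnd > Body > IGR.
#' Percentages sum to 100 within every split.
#'
#' @param dmps data.frame of retained DMPs with `probe_id` and `direction`.
#' @param manifest probe `GRanges`.
#' @return A list of two data.frames, `geneRegion` and `island`, with rows
#'   per class and columns `all`, `hyper`, `hypo` (percentages).
#' @export
distributionTable <- function(dmps, manifest) {
  mc <- S4Vectors::mcols(manifest)
  idx <- match(dmps$probe_id, mc$probeId)
  if (anyNA(idx))
    .err("unknown probe id(s): ",
         paste(utils::head(dmps$probe_id[is.na(idx)], 5L), collapse = ", "))
  regClass <- vapply(as.list(mc$geneRegions[idx]), .regionClass,
                     character(1L))
  island <- mc$islandContext[idx]
  regionLevels <- c("Promoter", "3UTR", "Body", "ExonBnd", "IGR")
  pct <- function(x, levels) {
    if (!length(x)) return(stats::setNames(rep(NA_real_, length(levels)),
                                           levels))
    100 * table(factor(x, levels = levels)) / length(x)
  }
  splits <- list(all = rep(TRUE, nrow(dmps)),
                 hyper = dmps$direction == "hyper",
                 hypo = dmps$direction == "hypo")
  geneRegion <- as.data.frame(lapply(splits, function(s)
    as.numeric(pct(regClass[s], regionLevels))))
  rownames(geneRegion) <- regionLevels
  islandTab <- as.data.frame(lapply(splits, function(s)
    as.numeric(pct(island[s], .ISLAND_CONTEXTS))))
  rownames(islandTab) <- .ISLAND_CONTEXTS
  list(geneRegion = geneRegion, island = islandTab)
}

#' Overlap counts of labeled DMP sets
#'
#' Computes, for two or more named id sets, the size of every region of
#' the inclusion-exclusion lattice: for each non-empty subset S of set
#' names, the number of elements belonging to exactly the sets in S (the
#' Venn-diagram region counts). Region counts reconcile with the set
#' sizes by construction.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return A data.frame with one row per lattice region: logical membership
#'   columns (one per set) and `count`.
#' @export
overlapSets <- function(sets) {
  if (length(sets) < 2L) .err("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .err("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (!is.matrix(member)) member <- matrix(member, nrow = length(universe))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  colnames(grid) <- names(sets)
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  grid$count <- apply(grid, 1L, function(row)
    sum(apply(member, 1L, function(m) all(m == as.logical(row)))))
  rownames(grid) <- NULL
  grid
}

#' Hypergeometric over-representation analysis
#'
#' For each term of a gene-set collection, tests whether the query genes
#' over-represent the term within the universe: p = P(X >= k) with
#' X ~ Hypergeometric(N = universe size, K = term size in universe,
#' n = query size). Terms are intersected with the universe before
#' testing; Bonferroni correction multiplies by the number of terms
#' tested. Records are sorted by p.
#'
#' @param query character vector of genes (must be a subset of universe).
#' @param universe character vector, the background gene universe.
#' @param sets named list of gene sets (e.g. [readGMT()]).
#' @param alpha significance level applied to the Bonferroni-corrected p
#'   (default 0.05).
#' @return A data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
hypergeometricEnrichment <- function(query, universe, sets, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) .err("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    .err("query gene(s) outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  .assertScalarProb(alpha, "alpha")
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    term <- intersect(unique(sets[[nm]]), universe)
    K <- length(term)
    k <- length(intersect(query, term))
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * length(sets))
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
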