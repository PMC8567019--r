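## Readers/writers for the delimited-text interchange formats.
## Delimiter is auto-detected from the extension: .tsv/.txt/.bed tab,
## anything else comma. Internal coordinates are 1-based inclusive
## (Illumina manifest convention); BED export converts to 0-based half-open.

#' Read / write a beta-value matrix
#'
#' The file has a header row of sample ids and a first column of probe ids;
#' all remaining cells are methylation fractions in \[0,1\]. Row and column
#' order are preserved; malformed numeric cells and out-of-range values are
#' rejected with the offending probe/sample named. Missing values are not
#' supported: probe filtering is expected to precede analysis.
#'
#' @param path file path (`.csv` comma, `.tsv`/`.txt` tab).
#' @return `readBetaMatrix()`: a numeric matrix with dimnames.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' m <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.4, 0.8), nrow = 3,
#'             dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
#' writeBetaMatrix(m, tf)
#' stopifnot(identical(readBetaMatrix(tf), m))
#' @export
readBetaMatrix <- function(path) {
  df <- .readDelim(path)
  if (ncol(df) < 2L) .err("beta matrix needs a probe-id column and >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) .err("duplicate probe ids in beta matrix")
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        .err(sprintf("malformed numeric value '%s' at probe %s, sample %s",
                     v[bad[1L]], ids[bad[1L]], colnames(vals)[j]))
      v <- num
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    .err(sprintf("missing beta value at probe %s, sample %s",
                 ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (min(m) < 0 || max(m) > 1) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    .err(sprintf("beta value %.4g outside [0, 1] at probe %s, sample %s",
                 m[bad[1L], bad[2L]], ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  m
}

#' @param m numeric matrix with probe-id rownames and sample-id colnames.
#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  .writeDelim(df, path)
  invisible(path)
}

## manifest data.frame <-> GRanges; genes/geneRegions ';'-joined on disk
.manifestToGRanges <- function(df) {
  needed <- c("probe_id", "chrom", "pos", "strand", "probe_type", "genes",
              "gene_regions", "island_context")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    .err("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    .err("duplicate probe id(s) in manifest: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  pos <- df$pos
  if (!is.numeric(pos) || any(pos != floor(pos)) || any(pos < 1))
    .err("manifest 'pos' must be positive integers (1-based bp)")
  if (!all(df$strand %in% c("+", "-", "*")))
    .err("strand must be '+', '-' or '*'")
  split2 <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    IRanges::CharacterList(lapply(strsplit(x, ";", fixed = TRUE),
                                  function(g) g[nzchar(g)]))
  }
  genes <- split2(df$genes)
  regions <- split2(df$gene_regions)
  if (!all(lengths(genes) == lengths(regions)))
    .err("genes and gene_regions must have equal per-probe length")
  badReg <- setdiff(unlist(regions, use.names = FALSE), .GENE_REGIONS)
  if (length(badReg))
    .err("unknown gene region label(s): ", paste(badReg, collapse = ", "))
  if (!all(df$island_context %in% .ISLAND_CONTEXTS))
    .err("unknown island context label(s): ",
         paste(setdiff(df$island_context, .ISLAND_CONTEXTS), collapse = ", "))
  if (!all(df$probe_type %in% c("I", "II")))
    .err("probe_type must be 'I' or 'II'")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    probeId = as.character(df$probe_id),
    probeType = as.character(df$probe_type),
    genes = genes, geneRegions = regions,
    islandContext = as.character(df$island_context))
  names(gr) <- S4Vectors::mcols(gr)$probeId
  gr
}

.manifestToDataFrame <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  join <- function(cl) vapply(cl, paste, character(1L), collapse = ";")
  data.frame(
    probe_id = mc$probeId,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    probe_type = mc$probeType,
    genes = join(mc$genes),
    gene_regions = join(mc$geneRegions),
    island_context = mc$islandContext,
    stringsAsFactors = FALSE)
}

#' Read / write a probe manifest
#'
#' The manifest is a delimited table with columns `probe_id`, `chrom`,
#' `pos` (1-based bp), `strand` (+/-/*; carried but ignored by all
#' computations), `probe_type` (I/II chemistry), `genes` and `gene_regions`
#' (";"-joined parallel lists; region labels among TSS1500, TSS200, 5UTR,
#' Body, 3UTR, ExonBnd, IGR) and `island_context` (Island, Shore, Shelf,
#' OpenSea). Duplicate probe ids, non-integer positions and unknown labels
#' are rejected.
#'
#' @param path file path.
#' @return `readManifest()`: a `GRanges`, one probe per range, with the
#'   metadata columns described in [MethylationExperiment].
#' @export
readManifest <- function(path) {
  .manifestToGRanges(.readDelim(path))
}

#' @param manifest `GRanges` in manifest layout.
#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  .writeDelim(.manifestToDataFrame(manifest), path)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Columns: `sample_id`, `subject_id`, `group` (HC/Pso/PsA), `timepoint`
#' (none/before/after), `treatment` (none/antiTNF/antiIL17), `sex`, `age`,
#' `pasi` (empty for healthy controls), `batch`. Healthy controls must have
#' timepoint "none" and no PASI; every after-treatment sample needs a
#' before-treatment mate sharing `subject_id`.
#'
#' @param path file path.
#' @return `readSampleSheet()`: a validated data.frame.
#' @export
readSampleSheet <- function(path) {
  .validateSampleSheet(.readDelim(path))
}

#' @param sheet data.frame in sample-sheet layout.
#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
  .writeDelim(sheet, path)
  invisible(path)
}

#' Read a plain-text probe exclusion list
#'
#' One probe id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of probe ids.
#' @export
readIdList <- function(path) {
  if (!file.exists(path)) .err("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read / write gene-set collections in GMT format
#'
#' Tab-separated: set name, description, then member genes. Used for the
#' over-representation analysis and the TNF/IL-17 pathway restriction of the
#' activity score.
#'
#' @param path file path.
#' @return `readGMT()`: a named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .err("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 2L) .err("malformed GMT line: ", f[1L])
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                        character(1L), 1L)
  sets
}

#' @param sets named list of character vectors.
#' @rdname readGMT
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export DMRs as BED6
#'
#' Converts the internal 1-based inclusive DMR coordinates to BED's 0-based
#' half-open convention (`chromStart = start - 1`, `chromEnd = end`), so BED
#' width equals the internal `end - start + 1`. The score column is
#' `-10 * log10(Fisher p)` capped at 1000; the name column joins overlapping
#' genes with ";" ("." when none).
#'
#' @param dmrs `GRanges` of DMRs as returned by [callDMRs()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportDMRsBed <- function(dmrs, path) {
  header <- "# chrom\tchromStart\tchromEnd\tname\tscore\tstrand"
  if (length(dmrs) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(GenomicRanges::end(dmrs) < GenomicRanges::start(dmrs)))
    .err("DMR with end < start")
  mc <- S4Vectors::mcols(dmrs)
  genes <- if ("genes" %in% colnames(mc))
    vapply(mc$genes, function(g)
      if (length(g)) paste(g, collapse = ";") else ".", character(1L))
  else rep(".", length(dmrs))
  fisher <- if ("fisher" %in% colnames(mc)) mc$fisher else rep(NA_real_,
                                                               length(dmrs))
  score <- ifelse(is.na(fisher), 0, pmin(1000, -10 * log10(pmax(fisher,
                                                                1e-300))))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    chromStart = GenomicRanges::start(dmrs) - 1L,
    chromEnd = GenomicRanges::end(dmrs),
    name = genes,
    score = round(score, 2),
    strand = ".", stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
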