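## Internal helpers shared across modules.

#' @noRd
.GENE_REGIONS <- c("TSS1500", "TSS200", "5UTR", "Body", "3UTR", "ExonBnd",
                   "IGR")

#' @noRd
.ISLAND_CONTEXTS <- c("Island", "Shore", "Shelf", "OpenSea")

#' @noRd
.PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5UTR")

#' @noRd
.GROUPS <- c("HC", "Pso", "PsA")

## stop()/warning() wrappers that keep call noise out of user messages
.err <- function(...) stop(..., call. = FALSE)
.warn <- function(...) warning(..., call. = FALSE)

#' @noRd
.assertScalarProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    .err(sprintf("'%s' must be a single value in (0, 1), got %s",
                 name, paste(format(x), collapse = ", ")))
  invisible(x)
}

## Deterministic child seed derived from a parent seed and a stage label.
## Stable across platforms (pure integer arithmetic on the label bytes),
## and kept within the 32-bit signed range expected by set.seed().
#' @noRd
.childSeed <- function(seed, label) {
  bytes <- as.integer(charToRaw(label))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
#' @noRd
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## row-wise variance without apply() overhead (n-1 denominator)
#' @noRd
.rowVars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1L)
}

#' @noRd
.delimFor <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("tsv", "bed", "txt")) "\t" else ","
}

#' @noRd
.readDelim <- function(path, ...) {
  if (!file.exists(path)) .err("file not found: ", path)
  utils::read.table(path, sep = .delimFor(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", ...)
}

#' @noRd
.writeDelim <- function(df, path, row.names = FALSE) {
  if (!ncol(df)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  utils::write.table(df, path, sep = .delimFor(path), quote = FALSE,
                     row.names = row.names, col.names = TRUE)
}
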