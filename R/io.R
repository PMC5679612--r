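#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' genes. Duplicate genes within a set are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT file")
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (recycled; default `"na"`).
#' @return invisibly, `path`.
#' @export
writeGmt <- function(collection, path, descriptions = "na") {
  stopifnot(!is.null(names(collection)), all(nzchar(names(collection))),
            all(lengths(collection) >= 1L))
  descriptions <- rep_len(descriptions, length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column RNK ranked-list file
#'
#' @param path tab-separated file with columns gene and score, no header.
#' @return a [RankedList-class] (re-sorted by descending score).
#' @export
readRnk <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("gene", "score"),
                  stringsAsFactors = FALSE)
  RankedList(d$gene, d$score)
}

#' Write a RankedList in RNK format
#'
#' @param ranked a [RankedList-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRnk <- function(ranked, path) {
  stopifnot(is(ranked, "RankedList"))
  write.table(as.data.frame(ranked), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV with a unit sidecar line
#'
#' The first line is `#unit=<unit>`; then a header row of sample identifiers
#' and one row per gene.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExpressionTsv <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#unit=%s", exprUnit(x)), con)
  v <- exprValues(x)
  writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
  write.table(data.frame(gene = rownames(v), v, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [writeExpressionTsv()]
#'
#' @param path input path.
#' @param unit overrides the unit recorded in the `#unit=` sidecar line
#'   (mandatory if the file has none).
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionTsv <- function(path, unit = NULL) {
  first <- readLines(path, n = 1L)
  hasSidecar <- startsWith(first, "#unit=")
  if (is.null(unit)) {
    if (!hasSidecar) stop("no #unit= line in ", path, "; pass unit explicitly")
    unit <- sub("^#unit=", "", first)
  }
  d <- read.delim(path, skip = if (hasSidecar) 1L else 0L, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  ExpressionMatrix(m, unit)
}

#' Read a variant or sample TSV table
#'
#' Plain `read.delim` with an optional column-name mapping for externally
#' produced tables (e.g. `c(maf = "allele_frequency")` renames
#' `allele_frequency` to `maf`).
#'
#' @param path input path.
#' @param columnMap optional named character vector, `internal = external`.
#' @return `data.frame`.
#' @export
readTableTsv <- function(path, columnMap = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columnMap)) {
    miss <- setdiff(unname(columnMap), names(d))
    if (length(miss)) stop("mapped columns absent: ", paste(miss, collapse = ", "))
    names(d)[match(columnMap, names(d))] <- names(columnMap)
  }
  d
}
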