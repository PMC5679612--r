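#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom methods new is validObject setClass setValidity setMethod setGeneric show slot
#' @importFrom stats rbinom rlnorm rnorm runif sd cor.test fisher.test wilcox.test
#'   pnorm ks.test p.adjust quantile median
#' @importFrom utils head read.delim write.table combn packageVersion
NULL

.EXPR_UNITS <- c("fpkm", "tpm", "scaled_estimate", "log2", "zscore")
.ABUNDANCE_UNITS <- c("fpkm", "tpm", "scaled_estimate")
.CLONALITY_SCENARIOS <- c("homozygous", "double_partial", "single_partial", "subclonal")
.ZYGOSITY_CATEGORIES <- c("homozygous_all_copies", "double_truncation_partial",
                          "partial_single_copy", "subclonal")
.TRUNCATING_EFFECTS <- c("frameshift_del", "frameshift_ins", "nonsense")
.FRAMESHIFT_EFFECTS <- c("frameshift_del", "frameshift_ins")

#' Gene-by-sample expression matrix with a recorded unit
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay plus the unit of measurement (`fpkm`, `tpm`,
#' `scaled_estimate`, `log2` or `zscore`) in its metadata. Abundance units must
#' be non-negative; `zscore` matrices must have per-gene mean 0 and population
#' SD 1 (tolerance 1e-8) except for rows that are identically zero (constant
#' genes flagged by [zscoreRows()]).
#'
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  u <- S4Vectors::metadata(object)$unit
  if (is.null(u) || !is.character(u) || length(u) != 1L || !(u %in% .EXPR_UNITS))
    return(sprintf("metadata unit must be one of: %s", paste(.EXPR_UNITS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, "exprs")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("sample identifiers (colnames) must be present and unique")
  if (u %in% .ABUNDANCE_UNITS && any(v < 0))
    return(sprintf("unit '%s' requires non-negative values", u))
  if (u == "zscore" && ncol(v) >= 2L) {
    rm <- rowMeans(v)
    rs <- sqrt(rowMeans((v - rm)^2))
    bad <- !(abs(rm) < 1e-8 & (abs(rs - 1) < 1e-8 | rs < 1e-8))
    if (any(bad))
      return("zscore unit requires per-gene mean 0 and population SD 1 (or all-zero rows)")
  }
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param unit unit of measurement; one of `"fpkm"`, `"tpm"`,
#'   `"scaled_estimate"`, `"log2"`, `"zscore"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' ExpressionMatrix(m, "fpkm")
#' @export
ExpressionMatrix <- function(values, unit = c("fpkm", "tpm", "scaled_estimate",
                                              "log2", "zscore")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(exprs = values),
    metadata = list(unit = unit))
  new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix the unit of measurement.
#' @param x an `ExpressionMatrix`.
#' @export
exprUnit <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  S4Vectors::metadata(x)$unit
}

#' @describeIn ExpressionMatrix the numeric gene-by-sample matrix.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  SummarizedExperiment::assay(x, "exprs")
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              exprUnit(object), nrow(object), ncol(object)))
})

#' Ranked gene list
#'
#' Genes ordered by a two-group differential statistic, descending. Ties in the
#' score are broken by gene identifier (ascending) so the order is fully
#' reproducible. The constructor sorts its input.
#'
#' @name RankedList-class
#' @aliases RankedList-class
#' @exportClass RankedList
setClass("RankedList", representation(gene = "character", score = "numeric"))

setValidity("RankedList", function(object) {
  if (length(object@gene) != length(object@score))
    return("gene and score must have equal length")
  if (anyDuplicated(object@gene)) return("genes must be unique")
  if (anyNA(object@score)) return("scores must be finite")
  if (is.unsorted(rev(object@score))) return("scores must be in descending order")
  TRUE
})

#' Construct a RankedList
#'
#' @param gene character vector of unique gene identifiers.
#' @param score numeric scores (e.g. Student's t); the list is sorted by
#'   descending score, ties broken by gene identifier ascending.
#' @return A [RankedList-class].
#' @examples
#' RankedList(c("A", "B", "C"), c(0.5, 2, -1))
#' @export
RankedList <- function(gene, score) {
  stopifnot(length(gene) == length(score), !anyNA(score), is.finite(score))
  o <- order(-score, gene)
  new("RankedList", gene = as.character(gene)[o], score = as.numeric(score)[o])
}

#' @describeIn RankedList gene identifiers in rank order.
#' @param x a `RankedList`.
#' @export
rankedGenes <- function(x) {
  stopifnot(is(x, "RankedList"))
  x@gene
}

#' @describeIn RankedList scores in rank order.
#' @export
rankedScores <- function(x) {
  stopifnot(is(x, "RankedList"))
  x@score
}

setMethod("show", "RankedList", function(object) {
  n <- length(object@gene)
  cat(sprintf("RankedList with %d genes; score range [%.4g, %.4g]\n",
              n, min(object@score), max(object@score)))
})

#' @describeIn RankedList length (number of genes).
#' @export
setMethod("length", "RankedList", function(x) length(x@gene))

#' Coerce a RankedList to a two-column data.frame
#'
#' @param x a `RankedList`.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return `data.frame` with columns `gene` and `score`.
#' @export
as.data.frame.RankedList <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(gene = x@gene, score = x@score, stringsAsFactors = FALSE)
}

#' Configuration of a synthetic MSI cohort
#'
#' Holds every knob of the synthetic-cohort generator: per-stratum sample
#' counts and frameshift probabilities (MSS / MSI-L / MSI-H), the tumor purity
#' range, the gene copy-number distribution, per-stratum log-normal TMB
#' parameters (mutations/Mb), the clonality scenario mix for carriers, the
#' expression model (number of genes, planted-set size, suppression effect in
#' noise-SD units, per-sample expression noise), MAF noise, the sequenced
#' panel size, and the mandatory seed.
#'
#' @name CohortConfig-class
#' @aliases CohortConfig-class
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nPerStratum = "numeric", fsProb = "numeric", purityRange = "numeric",
  copyNumberProb = "numeric", tmbMeanlog = "numeric", tmbSdlog = "numeric",
  clonalityMix = "numeric", nGenes = "integer", plantedSetSize = "integer",
  effectSize = "numeric", noiseSd = "numeric", mafNoiseSd = "numeric",
  panelMb = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  st <- names(object@nPerStratum)
  if (is.null(st) || anyDuplicated(st)) return("nPerStratum must have unique stratum names")
  if (all(object@nPerStratum <= 0)) return("at least one stratum must contain samples")
  if (any(object@nPerStratum < 0)) return("stratum sizes must be non-negative")
  if (!all(st %in% names(object@fsProb)))
    return("fsProb must name every stratum in nPerStratum")
  pr <- c(object@fsProb, object@copyNumberProb, object@clonalityMix)
  if (any(pr < 0 | pr > 1)) return("all probabilities must lie in [0, 1]")
  if (length(object@purityRange) != 2L || object@purityRange[1] <= 0 ||
      object@purityRange[2] > 1 || diff(object@purityRange) < 0)
    return("purityRange must be an interval within (0, 1]")
  if (!all(names(object@copyNumberProb) %in% as.character(1:4)) ||
      abs(sum(object@copyNumberProb) - 1) > 1e-8)
    return("copyNumberProb must be a distribution over copy numbers 1-4")
  if (!setequal(names(object@clonalityMix), .CLONALITY_SCENARIOS) ||
      abs(sum(object@clonalityMix) - 1) > 1e-8)
    return("clonalityMix must be a distribution over the four clonality scenarios")
  if (!all(st %in% names(object@tmbMeanlog)) || !all(st %in% names(object@tmbSdlog)))
    return("tmbMeanlog and tmbSdlog must name every stratum")
  if (object@effectSize > 0) return("effectSize must be <= 0 (suppression or null)")
  if (object@noiseSd <= 0 || object@mafNoiseSd < 0) return("noise SDs must be positive")
  if (object@nGenes < object@plantedSetSize + 1L)
    return("nGenes must exceed plantedSetSize")
  if (object@panelMb <= 0) return("panelMb must be positive")
  if (length(object@seed) != 1L || is.na(object@seed)) return("seed is mandatory")
  TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat("  strata:      ", paste(sprintf("%s=%d", names(object@nPerStratum),
                                       object@nPerStratum), collapse = ", "), "\n")
  cat("  fs prob:     ", paste(sprintf("%s=%.3g", names(object@fsProb),
                                       object@fsProb), collapse = ", "), "\n")
  cat(sprintf("  genes: %d (planted set %d), effect %.2f SD, seed %d\n",
              object@nGenes, object@plantedSetSize, object@effectSize, object@seed))
})

#' A synthetic cohort bundle
#'
#' Output of [generateCohort()]: sample metadata, somatic variant calls, an
#' FPKM [ExpressionMatrix-class], the per-sample truth table of planted labels,
#' the planted gene set, and the generating [CohortConfig-class].
#'
#' @name SyntheticCohort-class
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  samples = "data.frame", variants = "data.frame", expression = "ExpressionMatrix",
  truth = "data.frame", plantedSet = "character", config = "CohortConfig"))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d samples, %d variant calls, %d carriers\n",
              nrow(object@samples), nrow(object@variants), sum(object@truth$carrier)))
  show(object@expression)
})

#' @describeIn SyntheticCohort sample metadata table.
#' @param x a `SyntheticCohort`.
#' @export
cohortSamples <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@samples }

#' @describeIn SyntheticCohort variant call table.
#' @export
cohortVariants <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@variants }

#' @describeIn SyntheticCohort the FPKM expression matrix.
#' @export
cohortExpression <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@expression }

#' @describeIn SyntheticCohort per-sample planted truth labels.
#' @export
cohortTruth <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@truth }

#' @describeIn SyntheticCohort gene identifiers of the planted suppressed set.
#' @export
plantedGenes <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@plantedSet }
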