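#' Convert FPKM to transcripts per million
#'
#' `TPM_i = FPKM_i / sum_j FPKM_j * 1e6` per sample, so every column sums to
#' one million. Renormalizing a TPM matrix is a no-op beyond floating-point
#' tolerance, so TPM input is accepted.
#'
#' @param x an [ExpressionMatrix-class] with unit `fpkm` (or `tpm`).
#' @return an `ExpressionMatrix` with unit `tpm`.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
#' exprValues(fpkmToTpm(ExpressionMatrix(m, "fpkm")))
#' @export
fpkmToTpm <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!exprUnit(x) %in% c("fpkm", "tpm"))
    stop("fpkmToTpm requires fpkm (or tpm) input, got ", exprUnit(x))
  v <- exprValues(x)
  cs <- colSums(v)
  if (any(cs <= 0))
    stop("all-zero expression column(s): ",
         paste(colnames(v)[cs <= 0], collapse = ", "))
  ExpressionMatrix(sweep(v, 2, cs, "/") * 1e6, "tpm")
}

#' Log2-transform an abundance matrix
#'
#' `log2(x + pseudocount)` entrywise.
#'
#' @param x an [ExpressionMatrix-class] in an abundance unit (`fpkm`, `tpm` or
#'   `scaled_estimate`).
#' @param pseudocount added before taking logs (default 1, so 0 maps to 0).
#' @return an `ExpressionMatrix` with unit `log2`.
#' @export
log2Transform <- function(x, pseudocount = 1) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!exprUnit(x) %in% .ABUNDANCE_UNITS)
    stop("log2Transform requires an abundance unit, got ", exprUnit(x))
  v <- exprValues(x)
  if (any(v < 0)) stop("negative entries cannot be log-transformed")
  ExpressionMatrix(log2(v + pseudocount), "log2")
}

#' Z-score each gene across samples
#'
#' Per-gene `(x - mean) / SD` with the population SD (denominator `n`).
#' Constant genes map to all-zero rows and are flagged in the
#' `"constantGenes"` attribute of the result. Idempotent: z-scoring a z-scored
#' matrix changes nothing.
#'
#' @param x an [ExpressionMatrix-class] with at least two samples.
#' @return an `ExpressionMatrix` with unit `zscore`.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, dimnames = list("A", c("s1", "s2", "s3")))
#' exprValues(zscoreRows(ExpressionMatrix(m, "tpm")))
#' @export
zscoreRows <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (ncol(v) < 2L) stop("z-scoring requires at least two samples")
  rm <- rowMeans(v)
  rs <- sqrt(rowMeans((v - rm)^2))
  constant <- rs < 1e-12
  z <- (v - rm) / ifelse(constant, 1, rs)
  z[constant, ] <- 0
  out <- ExpressionMatrix(z, "zscore")
  attr(out, "constantGenes") <- rownames(v)[constant]
  out
}

#' Rank genes by a two-group Student's t statistic
#'
#' Per gene, `t = (mean_fs - mean_wt) / SD` where `SD` is the pooled standard
#' deviation (square root of the degrees-of-freedom-weighted average of the
#' two group variances; `metric = "s2n"` instead uses the sum of the two group
#' SDs, the signal-to-noise flavour). The denominator is floored at
#' `max(eps, 0.01 * |mean_fs - mean_wt|)` so near-constant genes cannot blow
#' up. The resulting list is sorted descending, ties broken by gene
#' identifier.
#'
#' @param x an [ExpressionMatrix-class].
#' @param groupFs,groupWt disjoint character vectors of sample identifiers,
#'   each of length >= 2.
#' @param metric `"pooled_t"` (default) or `"s2n"`.
#' @param eps absolute floor on the denominator.
#' @return a [RankedList-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 1,
#'             dimnames = list("A", sprintf("s%d", 1:6)))
#' x <- ExpressionMatrix(m, "tpm")
#' rankedScores(rankByT(x, sprintf("s%d", 1:3), sprintf("s%d", 4:6)))  # -3
#' @export
rankByT <- function(x, groupFs, groupWt, metric = c("pooled_t", "s2n"),
                    eps = 1e-8) {
  stopifnot(is(x, "ExpressionMatrix"))
  metric <- match.arg(metric)
  if (length(intersect(groupFs, groupWt)) > 0L)
    stop("groups must be disjoint")
  if (length(groupFs) < 2L || length(groupWt) < 2L)
    stop("both groups need at least two samples")
  v <- exprValues(x)
  miss <- setdiff(c(groupFs, groupWt), colnames(v))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  a <- v[, groupFs, drop = FALSE]
  b <- v[, groupWt, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  denom <- if (metric == "pooled_t")
    sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  else
    sqrt(v1) + sqrt(v2)
  diff <- m1 - m2
  denom <- pmax(denom, pmax(eps, 0.01 * abs(diff)))
  RankedList(rownames(v), diff / denom)
}
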