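#' Per-sample interferon-response signature score
#'
#' Quantifies loss of an interferon-response program in each sample as the sum
#' of expression z-scores over the `k` most suppressed genes of a named set:
#' the set's genes are ordered by their differential statistic (most negative
#' first, i.e. the direction of loss in frameshift carriers; use
#' `direction = "absolute"` to rank by `|t|` instead) and the top `k` are
#' summed per sample. If fewer than `k` set genes are available in both the
#' ranked list and the matrix, all of them are used and the `k` column records
#' how many.
#'
#' @param zmatrix an [ExpressionMatrix-class] with unit `zscore`.
#' @param ranked a [RankedList-class] (the same comparison that feeds GSEA).
#' @param geneSet character vector of gene identifiers.
#' @param k number of genes to sum (default 25).
#' @param direction `"suppressed"` (most negative t; default) or
#'   `"absolute"`.
#' @param setName label recorded in the output.
#' @return `data.frame` with columns `sample_id`, `score`, `set_name`, `k`;
#'   the genes used are in the `"genesUsed"` attribute.
#' @export
ifnResponseScore <- function(zmatrix, ranked, geneSet, k = 25L,
                             direction = c("suppressed", "absolute"),
                             setName = "IFN_RESPONSE") {
  stopifnot(is(zmatrix, "ExpressionMatrix"), is(ranked, "RankedList"))
  direction <- match.arg(direction)
  if (exprUnit(zmatrix) != "zscore") stop("zmatrix must be in zscore units")
  v <- exprValues(zmatrix)
  avail <- intersect(intersect(geneSet, ranked@gene), rownames(v))
  if (length(avail) == 0L)
    stop("gene set does not intersect the ranked list and expression matrix")
  t <- ranked@score[match(avail, ranked@gene)]
  o <- if (direction == "suppressed") order(t, avail) else order(-abs(t), avail)
  sel <- avail[o][seq_len(min(k, length(avail)))]
  out <- data.frame(
    sample_id = colnames(v),
    score = colSums(v[sel, , drop = FALSE]),
    set_name = setName, k = length(sel), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "genesUsed") <- sel
  out
}

#' Per-sample summed frameshift MAF in a gene
#'
#' The sum of mutant allele fractions over all frameshift calls in `gene` for
#' each requested sample; 0 for samples with none. Low values indicate
#' subclonal or heterozygous events, high values homozygous loss.
#'
#' @param variants cohort variant table.
#' @param sampleIds samples to report (defaults to those present in
#'   `variants`).
#' @param gene gene of interest.
#' @return `data.frame` with columns `sample_id`, `maf_sum`.
#' @examples
#' v <- data.frame(sample_id = c("a", "a"), gene = "JAK1",
#'                 protein_pos = c(430, 861),
#'                 effect = c("frameshift_del", "frameshift_ins"),
#'                 maf = c(0.3, 0.4))
#' sampleFrameshiftMaf(v, c("a", "b"))
#' @export
sampleFrameshiftMaf <- function(variants, sampleIds = unique(variants$sample_id),
                                gene = "JAK1") {
  fs <- variants[variants$gene == gene &
                 variants$effect %in% .FRAMESHIFT_EFFECTS, , drop = FALSE]
  sums <- vapply(sampleIds, function(s) sum(fs$maf[fs$sample_id == s]), numeric(1))
  data.frame(sample_id = as.character(sampleIds), maf_sum = unname(sums),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r with the two-sided p-value from the t transform on
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least three observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
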