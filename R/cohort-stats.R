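#' Two-sided Fisher's exact test on a 2x2 table
#'
#' P-value by the minimum-likelihood convention (sum of hypergeometric
#' probabilities no larger than that of the observed table; the convention of
#' `stats::fisher.test` and of the cohort comparisons this package
#' reproduces). The odds ratio is the sample cross-product `(a*d)/(b*c)`:
#' infinite when `b*c = 0` with a non-zero numerator, undefined (`NaN`) for
#' `0/0`. A table with an empty row or column carries no information: `p = 1`
#' and the odds ratio is `NA`, flagged in `note`.
#'
#' @param a,b,c,d the four cell counts (rows: frameshift +/-, columns e.g.
#'   MSI-H/MSS), or give `a` as a 2x2 matrix.
#' @return list with `odds_ratio`, `p`, and `note` (`"ok"` or `"degenerate"`).
#' @examples
#' fisherExact2x2(50, 81, 3, 654)
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("table total must be positive")
  m <- matrix(cells, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(odds_ratio = NA_real_, p = 1, note = "degenerate"))
  or <- (a * d) / (b * c)   # Inf when b*c == 0, NaN for 0/0
  list(odds_ratio = or, p = stats::fisher.test(m)$p.value, note = "ok")
}

# exact two-sided permutation p for the Mann-Whitney U with ties, by full
# enumeration of group assignments; feasible only for small total n
.mwExactTies <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(length(pooled), n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Rank-sum statistic `U = #\{(i,j): x_i > y_j\} + 0.5 * #ties` (the number of
#' pairs won by the first group; `U = 0` when every `x` is below every `y`).
#' Midranks handle ties. The p-value is exact when both groups have at most 20
#' observations: by the exact rank-sum distribution when there are no ties,
#' and by full enumeration of group assignments when there are ties and the
#' total sample is at most 12. Otherwise the normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return list with `U` and `p` (two-sided).
#' @examples
#' mannWhitneyU(1:5, 6:10)   # U = 0, p = 2/252
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (max(pooled) == min(pooled))           # all values identical
    return(list(U = U, p = 1))
  ties <- anyDuplicated(pooled) > 0L
  small <- length(x) <= 20L && length(y) <= 20L
  p <- if (small && !ties) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else if (small && length(pooled) <= 12L) {
    .mwExactTies(x, y)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  list(U = U, p = min(1, p))
}

#' Proportion with binomial standard error
#'
#' `p = k/n` with `SE = sqrt(p (1 - p) / n)`. Vectorized.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @return list with `proportion` and `se`.
#' @examples
#' frequencyWithSe(50, 131)
#' @export
frequencyWithSe <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive")
  stopifnot(all(k >= 0), all(k <= n))
  p <- k / n
  list(proportion = p, se = sqrt(p * (1 - p) / n))
}

#' Frameshift/MSI association tables for a cohort
#'
#' For each disease, builds the frameshift-by-MSI 2x2 table comparing the two
#' `compare` strata (MSI-L is excluded from the test but reported in the
#' per-stratum frequency columns), with the sample odds ratio, the two-sided
#' Fisher exact P and per-stratum frequencies with binomial standard errors.
#'
#' @param variants cohort variant table.
#' @param samples sample metadata with columns `sample_id`, `disease`,
#'   `msi_status`.
#' @param gene gene of interest.
#' @param compare length-2 character: the strata entering the 2x2 test.
#' @return `data.frame` with one row per disease x stratum plus per-disease
#'   test columns (`odds_ratio`, `fisher_p` repeated on each stratum row).
#' @export
associateFrameshifts <- function(variants, samples, gene = "JAK1",
                                 compare = c("MSI-H", "MSS")) {
  fs <- unique(variants$sample_id[variants$gene == gene &
                                  variants$effect %in% .FRAMESHIFT_EFFECTS])
  samples$has_fs <- samples$sample_id %in% fs
  out <- lapply(split(samples, samples$disease), function(sd) {
    k <- vapply(split(sd$has_fs, sd$msi_status), sum, numeric(1))
    n <- vapply(split(sd$has_fs, sd$msi_status), length, numeric(1))
    fr <- frequencyWithSe(k, n)
    tst <- if (all(compare %in% names(n))) {
      fisherExact2x2(k[compare[1]], n[compare[1]] - k[compare[1]],
                     k[compare[2]], n[compare[2]] - k[compare[2]])
    } else list(odds_ratio = NA_real_, p = NA_real_, note = "missing stratum")
    data.frame(disease = sd$disease[1], msi_status = names(n),
               n = as.integer(n), n_frameshift = as.integer(k),
               frequency = fr$proportion, se = fr$se,
               odds_ratio = tst$odds_ratio, fisher_p = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
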