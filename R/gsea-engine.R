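#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom. A gene in the set ("hit") at rank
#' `i` adds `|t_i|^p / N_R` where `N_R = sum over hits of |t_i|^p`; any other
#' gene subtracts `1 / (N - N_H)`. The enrichment score is the running sum's
#' maximum deviation from zero, signed. With `weightP = 0` and equal scores
#' this is the classical Kolmogorov-Smirnov statistic between the hit and miss
#' rank distributions. When every hit has score exactly zero the hit weights
#' degenerate; equal weights `1 / N_H` are used in that case.
#'
#' @param ranked a [RankedList-class].
#' @param geneSet character vector of gene identifiers.
#' @param weightP weighting exponent `p` (0, 1 = "weighted", 2 = "weighted
#'   p2").
#' @return list with `es`, the full `running_sum` profile (length `N`) and
#'   `peak`, the 1-based index at which `|running sum|` is maximal (first such
#'   index on ties).
#' @examples
#' rl <- RankedList(sprintf("G%d", 1:5), c(5, 4, 3, 2, 1))
#' enrichmentScore(rl, c("G1", "G4"), weightP = 1)$es
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
  stopifnot(is(ranked, "RankedList"), weightP >= 0)
  genes <- ranked@gene
  N <- length(genes)
  hit <- genes %in% geneSet
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == N) stop("gene set covers the whole ranked list; miss decrement undefined")
  w <- abs(ranked@score)^weightP
  nr <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  rsMax <- max(rs)
  rsMin <- min(rs)
  # on an exact magnitude tie the positive extreme wins (documented convention)
  es <- if (rsMax + rsMin >= -1e-12) rsMax else rsMin
  peak <- which(rs == es)[1]
  list(es = es, running_sum = rs, peak = peak)
}

# Permutation enrichment scores for one set size, vectorized across
# permutations. Membership is reassigned uniformly over the ranked genes with
# scores fixed. Uses the closed form of the running-sum extremes: with sorted
# hit positions pos_1 < ... < pos_k, the profile's local maxima lie just after
# a hit, H_j/NR - (pos_j - j)/(N - k), and its local minima just before one,
# H_{j-1}/NR - (pos_j - j)/(N - k); the signed larger deviation is the ES.
.permEs <- function(wp, k, nPerm) {
  N <- length(wp)
  P <- vapply(seq_len(nPerm), function(i) sample.int(N, k), integer(k))
  P <- matrix(P, nrow = k)                       # k x nPerm (k = 1 safe)
  P <- matrix(P[order(col(P), P)], nrow = k)     # sort within each column
  W <- matrix(wp[P], nrow = k)
  csf <- cumsum(as.numeric(W))
  off <- c(0, csf[seq(k, by = k, length.out = nPerm - 1L)])
  CS <- matrix(csf, nrow = k) - rep(off, each = k)
  NR <- CS[k, ]
  invNR <- ifelse(NR > 0, 1 / NR, 0)
  hitAfter <- CS * rep(invNR, each = k)
  if (any(NR <= 0))                              # all-zero hit scores: equal weights
    hitAfter[, NR <= 0] <- matrix(seq_len(k) / k, k, sum(NR <= 0))
  missTerm <- (P - seq_len(k)) / (N - k)
  after <- hitAfter - missTerm
  before <- hitAfter - W * rep(invNR, each = k) - missTerm
  if (any(NR <= 0))
    before[, NR <= 0] <- matrix((seq_len(k) - 1) / k, k, sum(NR <= 0)) -
      missTerm[, NR <= 0, drop = FALSE]
  esPos <- Reduce(pmax, asplit(after, 1))
  esNeg <- Reduce(pmin, asplit(before, 1))
  ifelse(esPos + esNeg >= -1e-12, esPos, esNeg)
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For every set passing the size filter, computes the observed enrichment
#' score, then a permutation null in which set membership is reassigned
#' uniformly at random over the ranked genes (scores fixed) `nPerm` times.
#' The normalized enrichment score divides the observed ES by the mean
#' magnitude of the same-sign permutation scores of that set. The nominal
#' p-value is the add-one-corrected fraction of same-sign permutation scores
#' at least as extreme as the observed one. The family-wise error rate
#' p-value counts, over permutations, how often the maximum same-sign |NES|
#' across the whole collection reaches the observed |NES|, on the same
#' same-sign add-one denominator (capped at 1), so for a single-set
#' collection it equals the nominal p exactly and it can never fall below it.
#'
#' Results carry one row per set, positive enrichments first (by decreasing
#' NES), then negative ones (most negative first).
#'
#' @param ranked a [RankedList-class].
#' @param collection named list of character vectors.
#' @param weightP weighting exponent (1 for Hallmark-sized sets, 2 for small
#'   immune-style sets).
#' @param nPerm number of permutations (>= 10; default 1000).
#' @param minSize,maxSize effective set-size filter (after intersection with
#'   the ranked list).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return `data.frame` with columns `set`, `size`, `es`, `nes`, `p_nominal`,
#'   `p_fwer`, `direction` (`"pos"`/`"neg"`).
#' @export
runPreranked <- function(ranked, collection, weightP = 1, nPerm = 1000L,
                         minSize = 5L, maxSize = 500L, seed) {
  stopifnot(is(ranked, "RankedList"), length(collection) >= 1L,
            !is.null(names(collection)))
  if (nPerm < 10L) stop("nPerm must be at least 10")
  if (missing(seed)) stop("seed is mandatory")
  genes <- ranked@gene
  N <- length(genes)
  eff <- lapply(collection, intersect, x = genes)
  sizes <- lengths(eff)
  keep <- sizes >= minSize & sizes <= min(maxSize, N - 1L)
  if (!any(keep)) stop("no gene set passes the size filter")
  eff <- eff[keep]
  sizes <- sizes[keep]
  nSets <- length(eff)

  obs <- vapply(eff, function(s) enrichmentScore(ranked, s, weightP)$es, numeric(1))
  wp <- abs(ranked@score)^weightP

  permEs <- withr::with_seed(seed, {
    out <- matrix(0, nPerm, nSets)
    for (j in seq_len(nSets)) out[, j] <- .permEs(wp, sizes[j], nPerm)
    out
  })

  posMean <- vapply(seq_len(nSets), function(j) {
    v <- permEs[, j]; mean(v[v > 0])
  }, numeric(1))
  negMean <- vapply(seq_len(nSets), function(j) {
    v <- permEs[, j]; mean(-v[v < 0])
  }, numeric(1))

  # family-wide max normalized score per permutation, within each sign family
  posNorm <- sweep(permEs, 2, posMean, "/")
  posNorm[permEs <= 0] <- -Inf
  maxPos <- do.call(pmax, c(asplit(posNorm, 2), list(na.rm = TRUE)))
  negNorm <- sweep(-permEs, 2, negMean, "/")
  negNorm[permEs >= 0] <- -Inf
  maxNeg <- do.call(pmax, c(asplit(negNorm, 2), list(na.rm = TRUE)))

  nes <- pNom <- pFwer <- numeric(nSets)
  for (j in seq_len(nSets)) {
    v <- permEs[, j]
    if (obs[j] >= 0) {
      same <- v[v > 0]
      nes[j] <- if (length(same)) obs[j] / posMean[j] else NA_real_
      b <- sum(same >= obs[j])
      B <- if (is.na(nes[j])) b else sum(maxPos >= nes[j])
    } else {
      same <- -v[v < 0]
      nes[j] <- if (length(same)) obs[j] / negMean[j] else NA_real_
      b <- sum(same >= -obs[j])
      B <- if (is.na(nes[j])) b else sum(maxNeg >= -nes[j])
    }
    pNom[j] <- (b + 1) / (length(same) + 1)
    pFwer[j] <- min(1, (B + 1) / (length(same) + 1))
  }

  res <- data.frame(set = names(eff), size = as.integer(sizes), es = obs,
                    nes = nes, p_nominal = pNom, p_fwer = pFwer,
                    direction = ifelse(obs >= 0, "pos", "neg"),
                    stringsAsFactors = FALSE)
  pos <- res[res$direction == "pos", , drop = FALSE]
  neg <- res[res$direction == "neg", , drop = FALSE]
  res <- rbind(pos[order(-pos$nes), , drop = FALSE],
               neg[order(neg$nes), , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Remove a reference set's genes from a collection
#'
#' Every set is replaced by its difference with the reference; sets left with
#' fewer than `minSize` genes are dropped and reported in the `"dropped"`
#' attribute of the result (and via a message).
#'
#' @param collection named list of character vectors.
#' @param reference nonempty character vector.
#' @param minSize minimum surviving size.
#' @return the pruned collection (named list) with attribute `"dropped"`.
#' @export
removeOverlap <- function(collection, reference, minSize) {
  stopifnot(length(reference) >= 1L)
  trimmed <- lapply(collection, setdiff, y = reference)
  drop <- lengths(trimmed) < minSize
  if (any(drop))
    message("dropped after overlap removal (below min size ", minSize, "): ",
            paste(names(trimmed)[drop], collapse = ", "))
  out <- trimmed[!drop]
  attr(out, "dropped") <- names(trimmed)[drop]
  out
}
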