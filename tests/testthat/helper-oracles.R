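# Independent oracles kept deliberately naive: plain loops, no shared code
# with the package implementations they check.

# running-sum enrichment score by explicit element-by-element walk
esOracle <- function(scores, isHit, p) {
  N <- length(scores)
  nh <- sum(isHit)
  nr <- sum(abs(scores[isHit])^p)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (isHit[i]) {
      run <- run + (if (nr > 0) abs(scores[i])^p / nr else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    if (abs(run) > abs(best) + 1e-12 ||
        (abs(abs(run) - abs(best)) <= 1e-12 && run > best)) best <- run
  }
  best
}

# two-sided Mann-Whitney p by enumerating every assignment of the pooled
# values to the first group (midranks for ties)
mwOracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  extreme <- 0
  for (j in seq_len(ncol(idx))) {
    u <- sum(r[idx[, j]]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(uObs - mu) - 1e-9) extreme <- extreme + 1
  }
  extreme / ncol(idx)
}

# small cohort configuration for fast tests
smallConfig <- function(seed, ...) {
  args <- list(nPerStratum = c("MSI-H" = 40, "MSS" = 60),
               fsProb = c("MSI-H" = 0.4, "MSS" = 0.01),
               tmbMeanlog = c("MSI-H" = log(23.1), "MSS" = log(4.5)),
               tmbSdlog = c("MSI-H" = 0.6, "MSS" = 0.6),
               nGenes = 60L, plantedSetSize = 10L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohortConfig, args)
}

expectedCategory <- c(homozygous = "homozygous_all_copies",
                      double_partial = "double_truncation_partial",
                      single_partial = "partial_single_copy",
                      subclonal = "subclonal")
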