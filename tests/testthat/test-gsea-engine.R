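test_that("enrichment score matches explicit running sums on canonical cases", {
  rl <- RankedList(sprintf("G%d", 1:5), c(5, 4, 3, 2, 1))
  # hits at ranks 1 and 4 with p = 1: peak 5/7 after the first hit
  r <- enrichmentScore(rl, c("G1", "G4"), weightP = 1)
  expect_equal(r$es, 5 / 7, tolerance = 1e-12)
  expect_equal(r$peak, 1L)
  expect_equal(r$running_sum, cumsum(c(5 / 7, -1 / 3, -1 / 3, 2 / 7, -1 / 3)),
               tolerance = 1e-12)
  # all hits on top / bottom of the list
  expect_equal(enrichmentScore(rl, c("G1", "G2"), 1)$es, 1)
  expect_equal(enrichmentScore(rl, c("G4", "G5"), 1)$es, -1)
  expect_error(enrichmentScore(rl, c("X1", "X2"), 1), "intersect")
  expect_error(enrichmentScore(rl, sprintf("G%d", 1:5), 1), "whole")
})

test_that("enrichment score agrees with a brute-force oracle on random instances", {
  set.seed(6)
  for (i in 1:500) {
    N <- sample(5:50, 1)
    k <- sample(1:(N - 1), 1)
    p <- sample(c(0, 1, 2), 1)
    rl <- RankedList(sprintf("g%03d", 1:N), round(rnorm(N), 3))
    hitIdx <- sort(sample.int(N, k))
    got <- enrichmentScore(rl, rl@gene[hitIdx], p)$es
    want <- esOracle(rl@score, seq_len(N) %in% hitIdx, p)
    expect_equal(got, want, tolerance = 1e-9, label = sprintf("instance %d", i))
    expect_lte(abs(got), 1 + 1e-12)
  }
})

test_that("enrichment score matches an independent library implementation", {
  skip_if_not_installed("fgsea")
  set.seed(61)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    k <- sample(3:15, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", 1:N)
    rl <- RankedList(names(stats), stats)
    sel <- sort(sample.int(N, k))
    ours <- enrichmentScore(rl, names(stats)[sel], weightP = 1)$es
    theirs <- fgsea::calcGseaStat(stats, sel, gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("reversing the list and negating scores negates the enrichment score", {
  set.seed(15)
  for (i in 1:50) {
    N <- sample(8:40, 1)
    sc <- rnorm(N)
    # continuous distinct scores and p > 0 keep running-sum extremes free of
    # exact magnitude ties, where the documented positive-wins convention
    # (not antisymmetry) decides
    sc <- sc + seq_len(N) * 1e-7
    rl <- RankedList(sprintf("g%03d", 1:N), sc)
    rl2 <- RankedList(rl@gene, -rl@score)
    set <- rl@gene[sample.int(N, sample(2:(N - 2), 1))]
    p <- sample(c(1, 2), 1)
    expect_equal(enrichmentScore(rl2, set, p)$es,
                 -enrichmentScore(rl, set, p)$es, tolerance = 1e-9)
  }
})

test_that("with p = 0 and equal scores the ES equals the KS statistic", {
  set.seed(23)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    rl <- RankedList(sprintf("g%03d", 1:N), rep(1, N))
    k <- sample(2:(N - 2), 1)
    hitIdx <- sort(sample.int(N, k))
    es <- enrichmentScore(rl, rl@gene[hitIdx], weightP = 0)$es
    D <- suppressWarnings(
      ks.test(hitIdx, setdiff(seq_len(N), hitIdx))$statistic)
    expect_equal(abs(es), unname(D), tolerance = 1e-9)
  }
})

test_that("permutation machinery satisfies its structural contracts", {
  set.seed(70)
  rl <- RankedList(sprintf("g%04d", 1:300), rnorm(300))
  coll <- generateGeneSets(8, c(10, 40), 0, rl@gene, seed = 71)$collection
  res <- runPreranked(rl, coll, weightP = 1, nPerm = 200, seed = 5)
  expect_setequal(res$set, names(coll))
  expect_true(all(res$p_fwer >= res$p_nominal - 1e-12))
  expect_true(all(res$p_nominal > 0 & res$p_nominal <= 1))
  expect_true(all(abs(res$es) <= 1))
  expect_equal(res$direction, ifelse(res$es >= 0, "pos", "neg"))
  # positives first by decreasing NES, then negatives most extreme first
  pos <- res$nes[res$direction == "pos"]
  neg <- res$nes[res$direction == "neg"]
  expect_false(is.unsorted(rev(pos)))
  expect_false(is.unsorted(neg))
  # single-set collection: the family max is the set itself
  one <- runPreranked(rl, coll[1], weightP = 1, nPerm = 200, seed = 5)
  expect_equal(one$p_fwer, one$p_nominal)
  # reproducibility and argument validation
  expect_identical(res, runPreranked(rl, coll, weightP = 1, nPerm = 200, seed = 5))
  expect_error(runPreranked(rl, coll, nPerm = 5, seed = 1), "at least 10")
  expect_error(runPreranked(rl, coll, nPerm = 100, minSize = 100, seed = 1),
               "size filter")
})

test_that("a planted suppressed set is recovered with small FWER", {
  co <- generateCohort(smallConfig(seed = 42, nGenes = 1000L,
                                   plantedSetSize = 25L,
                                   nPerStratum = c("MSI-H" = 80),
                                   fsProb = c("MSI-H" = 0.5),
                                   tmbMeanlog = c("MSI-H" = log(23.1)),
                                   tmbSdlog = c("MSI-H" = 0.6)))
  tr <- cohortTruth(co)
  lg <- log2Transform(fpkmToTpm(cohortExpression(co)))
  rk <- rankByT(lg, tr$sample_id[tr$carrier], tr$sample_id[!tr$carrier])
  coll <- c(list(PLANTED = plantedGenes(co)),
            generateGeneSets(15, c(16, 61), 0, rk@gene, seed = 43)$collection)
  res <- runPreranked(rk, coll, weightP = 1, nPerm = 1000, seed = 44)
  planted <- res[res$set == "PLANTED", ]
  expect_equal(planted$direction, "neg")
  expect_lte(planted$p_fwer, 0.05)
})

test_that("overlap removal trims sets and drops the too-small ones", {
  ref <- sprintf("R%03d", 1:200)
  small <- c(ref[1:9], sprintf("X%02d", 1:7))           # 16 genes, 9 shared
  big <- c(ref[1:73], sprintf("Y%02d", 1:24))           # 97 genes, 73 shared
  off <- sprintf("Z%02d", 1:12)                         # disjoint
  coll <- list(small = small, big = big, off = off)
  out <- suppressMessages(removeOverlap(coll, ref, minSize = 8))
  expect_equal(attr(out, "dropped"), "small")           # 7 survivors < 8
  expect_length(out$big, 24L)
  expect_equal(out$off, off)
})

test_that("GMT and RNK files round-trip", {
  dir <- withr::local_tempdir()
  coll <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g4", "g5"))
  gmt <- file.path(dir, "sets.gmt")
  writeGmt(coll, gmt, descriptions = c("alpha", "beta"))
  back <- readGmt(gmt)
  expect_equal(back[], coll, ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions"), c("alpha", "beta"))
  rl <- RankedList(c("g2", "g1", "g3"), c(1.5, -0.25, 0))
  rnk <- file.path(dir, "r.rnk")
  writeRnk(rl, rnk)
  back2 <- readRnk(rnk)
  expect_equal(rankedGenes(back2), rankedGenes(rl))
  expect_equal(rankedScores(back2), rankedScores(rl))
})
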