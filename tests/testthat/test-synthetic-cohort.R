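test_that("identical configurations reproduce byte-identical cohorts", {
  cfg <- smallConfig(seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cohortSamples(a), cohortSamples(b))
  expect_identical(cohortVariants(a), cohortVariants(b))
  expect_identical(exprValues(cohortExpression(a)), exprValues(cohortExpression(b)))
  expect_identical(cohortTruth(a), cohortTruth(b))
  # a different seed changes the draw
  expect_false(identical(cohortVariants(a),
                         cohortVariants(generateCohort(smallConfig(seed = 12)))))
})

test_that("carrier fractions track the configured frameshift probabilities", {
  cfg <- cohortConfig(nPerStratum = c("MSI-H" = 200, "MSS" = 600),
                      fsProb = c("MSI-H" = 0.4, "MSS" = 0.005),
                      tmbMeanlog = c("MSI-H" = log(23.1), "MSS" = log(4.5)),
                      tmbSdlog = c("MSI-H" = 0.6, "MSS" = 0.6),
                      nGenes = 40L, plantedSetSize = 5L, seed = 7)
  co <- generateCohort(cfg)
  d <- merge(cohortSamples(co), cohortTruth(co), by = "sample_id")
  for (st in c("MSI-H", "MSS")) {
    n <- sum(d$msi_status == st)
    phat <- mean(d$carrier[d$msi_status == st])
    p0 <- cfg@fsProb[[st]]
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n) + 1e-12)
  }
})

test_that("every carrier has a frameshift call at a configured tract position", {
  co <- generateCohort(smallConfig(seed = 3))
  tr <- cohortTruth(co)
  v <- cohortVariants(co)
  tracts <- jak1Tracts()
  valid <- c(tracts$codon_start, tracts$codon_start + 1L)
  for (s in tr$sample_id[tr$carrier]) {
    sv <- v[v$sample_id == s, ]
    expect_gte(nrow(sv), 1L)
    expect_true(all(sv$protein_pos %in% valid))
    expect_true(all(sv$effect %in% c("frameshift_del", "frameshift_ins")))
  }
  # non-carriers have no calls
  expect_length(intersect(v$sample_id, tr$sample_id[!tr$carrier]), 0L)
  # MAFs inside (0, 1]
  expect_true(all(v$maf > 0 & v$maf <= 1))
})

test_that("generated TMB recovers the configured log-normal median", {
  cfg <- cohortConfig(nPerStratum = c("MSI-H" = 400, "MSS" = 400),
                      fsProb = c("MSI-H" = 0.4, "MSS" = 0.005),
                      tmbMeanlog = c("MSI-H" = log(23.1), "MSS" = log(4.5)),
                      tmbSdlog = c("MSI-H" = 0.6, "MSS" = 0.6),
                      nGenes = 40L, plantedSetSize = 5L, seed = 21)
  s <- cohortSamples(generateCohort(cfg))
  for (st in c("MSI-H", "MSS")) {
    med <- median(s$tmb[s$msi_status == st])
    target <- exp(cfg@tmbMeanlog[[st]])
    expect_lt(abs(med - target) / target, 0.10)
  }
  # the integer mutation counts stay consistent with the drawn burden up to
  # panel quantization (half a mutation over the panel size)
  expect_true(all(abs(computeTmb(s$mutation_count, s$panel_mb) - s$tmb)
                  <= 0.5 / s$panel_mb + 1e-9))
})

test_that("a null effect size plants no expression signal", {
  co <- generateCohort(smallConfig(seed = 5, effectSize = 0,
                                   nGenes = 200L, plantedSetSize = 25L))
  tr <- cohortTruth(co)
  z <- exprValues(zscoreRows(log2Transform(fpkmToTpm(cohortExpression(co)))))
  perSample <- colMeans(z[plantedGenes(co), ])
  p <- t.test(perSample[tr$carrier], perSample[!tr$carrier])$p.value
  expect_gt(p, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(seed = 1, nPerStratum = c("MSI-H" = 0, "MSS" = 0),
                            fsProb = c("MSI-H" = 0.4, "MSS" = 0.01),
                            tmbMeanlog = c("MSI-H" = 3, "MSS" = 1.5),
                            tmbSdlog = c("MSI-H" = 0.6, "MSS" = 0.6)),
               "at least one stratum")
  expect_error(smallConfig(seed = 1, fsProb = c("MSI-H" = 1.4, "MSS" = 0.01)),
               "probabilities")
  expect_error(smallConfig(seed = 1, effectSize = 0.5), "effectSize")
  expect_error(cohortConfig(), "seed is mandatory")
})

test_that("gene-set generation hits requested overlaps exactly", {
  universe <- sprintf("G%04d", 1:800)
  gs <- generateGeneSets(5, c(97, 97), 73 / 97, universe, seed = 2)
  expect_length(gs$reference, 200L)
  for (set in gs$collection) {
    expect_length(set, 97L)
    expect_length(intersect(set, gs$reference), 73L)
    expect_false(anyDuplicated(set) > 0)
  }
  disjoint <- generateGeneSets(4, c(16, 61), 0, universe, seed = 3)
  expect_true(all(vapply(disjoint$collection,
                         function(s) length(intersect(s, disjoint$reference)),
                         numeric(1)) == 0))
  expect_true(all(lengths(disjoint$collection) >= 16 &
                  lengths(disjoint$collection) <= 61))
  expect_error(generateGeneSets(1, c(900, 900), 0, universe, seed = 1),
               "exceeds")
})

test_that("cohort tables round-trip through the TSV writers", {
  co <- generateCohort(smallConfig(seed = 9))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  v <- readTableTsv(file.path(dir, "variants.tsv"))
  expect_equal(v$maf, cohortVariants(co)$maf, tolerance = 1e-12)
  e <- readExpressionTsv(file.path(dir, "expression.tsv"))
  expect_equal(exprUnit(e), "fpkm")
  expect_equal(exprValues(e), exprValues(cohortExpression(co)), tolerance = 1e-12)
})

test_that("YAML cohort configuration is read faithfully and requires a seed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nPerStratum: {MSI-H: 30, MSS: 50}",
               "fsProb: {MSI-H: 0.4, MSS: 0.01}",
               "tmbMeanlog: {MSI-H: 3.14, MSS: 1.5}",
               "tmbSdlog: {MSI-H: 0.6, MSS: 0.6}",
               "nGenes: 60", "plantedSetSize: 10",
               "seed: 77"), path)
  cfg <- readCohortConfig(path)
  expect_s4_class(cfg, "CohortConfig")
  expect_identical(cfg@seed, 77L)
  expect_identical(cfg@nPerStratum[["MSI-H"]], 30)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nGenes: 60", path2)
  expect_error(readCohortConfig(path2), "seed")
})
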