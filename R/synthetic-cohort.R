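#' JAK1 homopolymer tract fixture
#'
#' The four slippage-prone mononucleotide tracts in the JAK1 coding sequence at
#' which recurrent frameshifts arise in mismatch-repair-deficient tumors: an
#' 8-mer poly-T at K142/I143, a 7-mer poly-T at N339, a 7-mer poly-G at
#' P430/L431 and an 8-mer poly-T at K860/P861. `codon_start` is the 1-based
#' amino-acid position of the frameshift-deletion call; insertions are called
#' one codon downstream.
#'
#' @return `data.frame` with columns `gene`, `codon_start`, `base`, `length`.
#' @examples
#' jak1Tracts()
#' @export
jak1Tracts <- function() {
  data.frame(
    gene = "JAK1",
    codon_start = c(142L, 339L, 430L, 860L),
    base = c("T", "T", "G", "T"),
    length = c(8L, 7L, 7L, 8L),
    stringsAsFactors = FALSE)
}

# Observed recurrence of the four tracts (K142/I143, N339, P430/L431,
# K860/P861) used as sampling weights when assigning a carrier's frameshift.
.TRACT_WEIGHTS <- c(24, 17, 90, 135)

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate an MSI-stratified endometrial-like cohort: frameshift
#' probability 0.38 in MSI-H, 0.09 in MSI-L and 0.005 in MSS tumors; log-normal
#' TMB with medians 23.1 (MSI-H), 8 (MSI-L) and 4.5 (MSS) mutations/Mb;
#' carrier clonality mix 38.1% homozygous, 19.4% double partial, 31.3% single
#' partial, 11.2% subclonal; purity uniform on (0.45, 0.95); gene copy number
#' on 1..4 with probabilities .10/.60/.20/.10; a 1.2 Mb sequencing panel; and a
#' planted 25-gene interferon-like set suppressed in carriers by `effectSize`
#' noise-SDs scaled by each carrier's clonal mutant fraction.
#'
#' @param nPerStratum named sample counts per MSI stratum.
#' @param fsProb named per-stratum frameshift probability.
#' @param purityRange tumor purity interval within (0, 1].
#' @param copyNumberProb distribution over gene copy numbers 1-4.
#' @param tmbMeanlog,tmbSdlog per-stratum log-normal TMB parameters
#'   (mutations/Mb).
#' @param clonalityMix probabilities over the four carrier clonality scenarios
#'   `homozygous`, `double_partial`, `single_partial`, `subclonal`.
#' @param nGenes number of genes in the expression matrix (including JAK1 and
#'   the planted set).
#' @param plantedSetSize size of the planted suppressed gene set.
#' @param effectSize mean z-shift (in units of `noiseSd`, must be <= 0) applied
#'   to planted-set genes in clonal frameshift carriers.
#' @param noiseSd per-sample expression noise SD on the log scale.
#' @param mafNoiseSd SD of the truncated Gaussian noise added to the ideal MAF.
#' @param panelMb sequenced panel size in megabases.
#' @param seed mandatory integer seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cohortConfig(seed = 1)
#' @export
cohortConfig <- function(nPerStratum = c("MSS" = 600, "MSI-L" = 60, "MSI-H" = 200),
                         fsProb = c("MSS" = 0.005, "MSI-L" = 0.09, "MSI-H" = 0.38),
                         purityRange = c(0.45, 0.95),
                         copyNumberProb = c("1" = 0.10, "2" = 0.60, "3" = 0.20, "4" = 0.10),
                         tmbMeanlog = c("MSS" = log(4.5), "MSI-L" = log(8), "MSI-H" = log(23.1)),
                         tmbSdlog = c("MSS" = 0.6, "MSI-L" = 0.6, "MSI-H" = 0.6),
                         clonalityMix = c(homozygous = 0.381, double_partial = 0.194,
                                          single_partial = 0.313, subclonal = 0.112),
                         nGenes = 2000L, plantedSetSize = 25L, effectSize = -1,
                         noiseSd = 1, mafNoiseSd = 0.03, panelMb = 1.2,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  asNamedNum <- function(x) { storage.mode(x) <- "double"; x }
  nPerStratum <- asNamedNum(nPerStratum); fsProb <- asNamedNum(fsProb)
  tmbMeanlog <- asNamedNum(tmbMeanlog); tmbSdlog <- asNamedNum(tmbSdlog)
  copyNumberProb <- asNamedNum(copyNumberProb)
  clonalityMix <- asNamedNum(clonalityMix)
  cfg <- new("CohortConfig",
             nPerStratum = nPerStratum, fsProb = fsProb, purityRange = purityRange,
             copyNumberProb = copyNumberProb, tmbMeanlog = tmbMeanlog,
             tmbSdlog = tmbSdlog, clonalityMix = clonalityMix / sum(clonalityMix),
             nGenes = as.integer(nGenes), plantedSetSize = as.integer(plantedSetSize),
             effectSize = effectSize, noiseSd = noiseSd, mafNoiseSd = mafNoiseSd,
             panelMb = panelMb, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Read a cohort configuration from a YAML file
#'
#' Field names match the arguments of [cohortConfig()]; named vectors are given
#' as YAML maps. The `seed` field is mandatory.
#'
#' @param path path to a YAML file.
#' @return A [CohortConfig-class].
#' @export
readCohortConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("configuration file must set a seed")
  args <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohortConfig, args)
}

# ideal MAF for m mutant copies at given purity and tumor copy number,
# assuming diploid normal contamination
.idealMaf <- function(m, purity, cn) {
  m * purity / (purity * cn + 2 * (1 - purity))
}

# draw mutant-copy values for one carrier under a clonality scenario;
# returns a numeric vector (one entry per truncating variant)
.scenarioMutantCopies <- function(scenario, cn) {
  switch(scenario,
         homozygous = cn,
         double_partial = runif(2, 0.5, 0.85),
         single_partial = runif(1, 1.0, 1.3),
         subclonal = runif(1, 0.1, 0.5),
         stop("unknown clonality scenario: ", scenario))
}

#' Generate a seeded synthetic cohort
#'
#' Draws sample metadata, JAK1 frameshift variant calls, an FPKM expression
#' matrix and a planted-label truth table carrying the statistical structure
#' the downstream analysis assumes: MSI-status-dependent frameshift
#' probability at the four JAK1 homopolymer tracts, purity/copy-number
#' dependent MAFs obtained by inverting the mutant-copy formula under a drawn
#' clonality scenario (plus truncated Gaussian noise, clipped to (0, 1]),
#' log-normal TMB with an MSI-H shift, and suppression of the planted gene set
#' (and of JAK1 itself) in carriers proportional to the clonal mutant
#' fraction: the shift is `effectSize * noiseSd * (sample MAF / homozygous
#' MAF)`, so homozygous carriers receive the full effect and partial or
#' subclonal carriers proportionally less.
#'
#' Identical configurations (including the seed) yield identical cohorts; the
#' caller's RNG state is untouched.
#'
#' @param config a [CohortConfig-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- generateCohort(cohortConfig(
#'   nPerStratum = c("MSI-H" = 20, "MSS" = 30), nGenes = 50L, seed = 7))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withr::with_seed(config@seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
  strata <- names(config@nPerStratum)
  n <- sum(config@nPerStratum)
  msi <- rep(strata, times = config@nPerStratum)
  sampleId <- sprintf("S%05d", seq_len(n))

  purity <- runif(n, config@purityRange[1], config@purityRange[2])
  tmb <- rlnorm(n, config@tmbMeanlog[msi], config@tmbSdlog[msi])
  mutationCount <- pmax(0L, as.integer(round(tmb * config@panelMb)))
  samples <- data.frame(
    sample_id = sampleId, disease = "endometrial", msi_status = msi,
    purity = purity, tmb = tmb, mutation_count = mutationCount,
    panel_mb = config@panelMb, stringsAsFactors = FALSE)

  carrier <- rbinom(n, 1L, config@fsProb[msi]) == 1L
  scenario <- rep(NA_character_, n)
  scenario[carrier] <- sample(names(config@clonalityMix), sum(carrier),
                              replace = TRUE, prob = config@clonalityMix)

  tracts <- jak1Tracts()
  cnLevels <- as.integer(names(config@copyNumberProb))
  varRows <- vector("list", n)
  copyNumber <- rep(NA_integer_, n)
  sampleMaf <- numeric(n)
  for (i in which(carrier)) {
    sc <- scenario[i]
    # partial scenarios need >= 2 tumor copies for an intact residual copy
    ok <- if (sc %in% c("double_partial", "single_partial")) cnLevels >= 2L else rep(TRUE, length(cnLevels))
    cn <- if (sum(ok) == 1L) cnLevels[ok] else
      sample(cnLevels[ok], 1L, prob = config@copyNumberProb[ok])
    copyNumber[i] <- cn
    m <- .scenarioMutantCopies(sc, cn)
    ti <- sample.int(nrow(tracts), length(m), replace = TRUE, prob = .TRACT_WEIGHTS)
    isDel <- runif(length(m)) < 0.5
    maf <- .idealMaf(m, purity[i], cn) + rnorm(length(m), 0, config@mafNoiseSd)
    maf <- pmin(1, pmax(1e-4, maf))
    varRows[[i]] <- data.frame(
      sample_id = sampleId[i], gene = "JAK1",
      protein_pos = tracts$codon_start[ti] + ifelse(isDel, 0L, 1L),
      effect = ifelse(isDel, "frameshift_del", "frameshift_ins"),
      maf = maf, copy_number = cn, stringsAsFactors = FALSE)
    sampleMaf[i] <- sum(maf)
  }
  variants <- do.call(rbind, c(varRows[!vapply(varRows, is.null, logical(1))],
                               list(make.row.names = FALSE)))
  if (is.null(variants))
    variants <- data.frame(sample_id = character(), gene = character(),
                           protein_pos = integer(), effect = character(),
                           maf = numeric(), copy_number = integer(),
                           stringsAsFactors = FALSE)

  # suppression weight: observed sample MAF relative to the MAF a fully
  # homozygous event would show at this sample's purity and copy number
  weight <- numeric(n)
  idx <- which(carrier)
  weight[idx] <- sampleMaf[idx] /
    .idealMaf(copyNumber[idx], purity[idx], copyNumber[idx])

  planted <- sprintf("IFNRSP%03d", seq_len(config@plantedSetSize))
  genes <- c("JAK1", planted,
             sprintf("GENE%05d", seq_len(config@nGenes - 1L - config@plantedSetSize)))
  muG <- rnorm(length(genes), 2, 1)
  logx <- matrix(rnorm(length(genes) * n, muG, config@noiseSd),
                 nrow = length(genes), dimnames = list(genes, sampleId))
  shift <- config@effectSize * config@noiseSd * weight   # <= 0 per validity
  target <- c("JAK1", planted)
  logx[target, ] <- logx[target, ] + rep(shift, each = length(target))
  expr <- ExpressionMatrix(exp(logx), "fpkm")

  truth <- data.frame(
    sample_id = sampleId, carrier = carrier, scenario = scenario,
    copy_number = copyNumber, suppression_weight = weight,
    sample_maf = sampleMaf, stringsAsFactors = FALSE)

  new("SyntheticCohort", samples = samples, variants = variants,
      expression = expr, truth = truth, plantedSet = planted, config = config)
}

#' Generate random gene-set collections with controlled reference overlap
#'
#' Builds `nSets` random gene sets over a gene universe together with a
#' designated Hallmark-sized reference set, with the pairwise overlap of each
#' set with the reference fixed exactly at `floor(overlap * size)` genes. This
#' enables overlap-control experiments in which shared genes are removed and
#' the enrichment analysis re-run.
#'
#' @param nSets number of sets to generate.
#' @param sizeRange integer interval of set sizes (each >= 2).
#' @param overlapWithReference fraction in `[0, 1]` (scalar, recycled) of each
#'   set drawn from the reference set.
#' @param universe character vector of available gene identifiers.
#' @param seed integer seed.
#' @param referenceSize size of the designated reference set (default 200,
#'   mimicking a Hallmark collection set).
#' @return list with elements `collection` (named list of character vectors)
#'   and `reference` (character vector).
#' @examples
#' gs <- generateGeneSets(3, c(16, 61), 0.25, sprintf("G%03d", 1:500), seed = 1)
#' lengths(gs$collection)
#' @export
generateGeneSets <- function(nSets, sizeRange, overlapWithReference, universe,
                             seed, referenceSize = 200L) {
  stopifnot(nSets >= 1, length(sizeRange) == 2L, sizeRange[1] >= 2,
            all(overlapWithReference >= 0 & overlapWithReference <= 1))
  if (referenceSize > length(universe))
    stop("requested reference size exceeds the gene universe")
  if (sizeRange[2] > length(universe))
    stop("requested set size exceeds the number of available genes")
  overlapWithReference <- rep_len(overlapWithReference, nSets)
  withr::with_seed(seed, {
    reference <- sample(universe, referenceSize)
    rest <- setdiff(universe, reference)
    sizes <- if (sizeRange[1] == sizeRange[2]) rep(sizeRange[1], nSets) else
      sample(seq(sizeRange[1], sizeRange[2]), nSets, replace = TRUE)
    collection <- lapply(seq_len(nSets), function(i) {
      nOv <- floor(overlapWithReference[i] * sizes[i] + 1e-9)
      nOut <- sizes[i] - nOv
      if (nOv > referenceSize || nOut > length(rest))
        stop("requested set size exceeds the available genes")
      c(sample(reference, nOv), sample(rest, nOut))
    })
    names(collection) <- sprintf("RANDSET_%04d", seq_len(nSets))
    list(collection = collection, reference = reference)
  })
}

#' Write the tables of a synthetic cohort to a directory
#'
#' Writes `samples.tsv`, `variants.tsv`, `expression.tsv` (genes x samples,
#' with a `#unit=` sidecar metadata line) and `truth.tsv`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("samples.tsv", "variants.tsv", "expression.tsv", "truth.tsv"))
  write.table(cohort@samples, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort@variants, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  writeExpressionTsv(cohort@expression, paths[3])
  write.table(cohort@truth, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
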