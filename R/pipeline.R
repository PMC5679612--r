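# run a pipeline stage; on error, leave a FAILED marker naming the stage so
# partial output directories are self-describing
.stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.formatFwer <- function(p) ifelse(p < 0.001, "0.000", sprintf("%.3f", p))

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full frameshift immune-evasion pipeline
#'
#' Orchestrates simulate (or load) -> hotspot calling -> zygosity ->
#' association -> expression prep -> preranked enrichment -> signature scoring
#' -> correlations -> report, writing every result table plus a content-hash
#' manifest under `outdir`. The comparison groups are frameshift carriers
#' versus wild-type samples within `stratum` (default MSI-H). Any stage error
#' aborts with the stage name; partial outputs are retained next to a
#' `FAILED` marker file.
#'
#' @param config either a [CohortConfig-class] (the cohort is simulated) or a
#'   named list of file paths with elements `variants`, `samples`,
#'   `expression` and `gmt` (a gene-set collection whose first set is scored).
#' @param outdir output directory, created if missing.
#' @param gene gene of interest.
#' @param stratum MSI stratum within which carriers and wild-type samples are
#'   compared.
#' @param weightP enrichment weighting exponent.
#' @param nPerm,minSize,maxSize,scoreK,minRecurrence tuning knobs passed to
#'   the respective stages.
#' @param nRandomSets for simulated cohorts, how many random background sets
#'   accompany the planted set in the tested collection.
#' @param seed seed for the enrichment permutations (and, via the
#'   configuration, the simulation); defaults to the configuration seed.
#' @return invisibly, a list with the in-memory stage results and the output
#'   paths.
#' @export
runPipeline <- function(config, outdir, gene = "JAK1", stratum = "MSI-H",
                        weightP = 1, nPerm = 1000L, minSize = 5L,
                        maxSize = 500L, scoreK = 25L, minRecurrence = 3L,
                        nRandomSets = 20L, seed = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  paths <- character(0)
  simulated <- is(config, "CohortConfig")
  if (is.null(seed)) {
    if (!simulated) stop("seed is mandatory when running from files")
    seed <- config@seed
  }

  inputs <- .stage("input", outdir, {
    if (simulated) {
      cohort <- generateCohort(config)
      universe <- rownames(exprValues(cohortExpression(cohort)))
      gs <- generateGeneSets(nRandomSets, c(16, 61), 0, universe,
                             seed = seed + 1L)
      collection <- c(list(PLANTED_IFN_RESPONSE = plantedGenes(cohort)),
                      gs$collection)
      list(samples = cohortSamples(cohort), variants = cohortVariants(cohort),
           expression = cohortExpression(cohort), collection = collection,
           truth = cohortTruth(cohort))
    } else {
      stopifnot(all(c("variants", "samples", "expression", "gmt") %in% names(config)))
      list(samples = readTableTsv(config$samples),
           variants = readTableTsv(config$variants),
           expression = readExpressionTsv(config$expression),
           collection = readGmt(config$gmt), truth = NULL)
    }
  })
  configPath <- file.path(outdir, "config.yaml")
  yaml::write_yaml(list(
    mode = if (simulated) "simulate" else "files",
    gene = gene, stratum = stratum, weight_p = weightP, n_perm = nPerm,
    min_size = minSize, max_size = maxSize, score_k = scoreK,
    min_recurrence = minRecurrence, seed = seed,
    source = if (simulated) list(seed = config@seed) else config), configPath)
  paths <- c(paths, configPath,
             .writeTsv(inputs$samples, file.path(outdir, "samples.tsv")),
             .writeTsv(inputs$variants, file.path(outdir, "variants.tsv")))
  if (!is.null(inputs$truth))
    paths <- c(paths, .writeTsv(inputs$truth, file.path(outdir, "truth.tsv")))

  hotspots <- .stage("hotspots", outdir, {
    h <- collapseHotspots(inputs$variants[inputs$variants$gene == gene, ,
                                          drop = FALSE], minRecurrence)
    annotateHomopolymer(h, jak1Tracts())
  })
  paths <- c(paths, .writeTsv(hotspots, file.path(outdir, "hotspots.tsv")))

  zygosity <- .stage("zygosity", outdir,
                     classifyCohortZygosity(inputs$variants, inputs$samples, gene))
  kept <- zygosity[zygosity$category != "filtered", , drop = FALSE]
  zygFrac <- if (nrow(kept)) {
    counts <- table(factor(kept$category, levels = .ZYGOSITY_CATEGORIES))
    data.frame(category = names(counts), n = as.integer(counts),
               fraction = as.numeric(counts) / nrow(kept),
               stringsAsFactors = FALSE)
  } else data.frame(category = character(), n = integer(), fraction = numeric())
  paths <- c(paths, .writeTsv(zygosity, file.path(outdir, "zygosity.tsv")),
             .writeTsv(zygFrac, file.path(outdir, "zygosity_fractions.tsv")))

  association <- .stage("associate", outdir,
                        associateFrameshifts(inputs$variants, inputs$samples, gene))
  paths <- c(paths, .writeTsv(association, file.path(outdir, "association.tsv")))

  prep <- .stage("prep", outdir, {
    expr <- inputs$expression
    if (exprUnit(expr) == "fpkm") expr <- fpkmToTpm(expr)
    lg <- if (exprUnit(expr) %in% .ABUNDANCE_UNITS) log2Transform(expr) else expr
    inStratum <- inputs$samples$sample_id[inputs$samples$msi_status == stratum]
    inStratum <- intersect(inStratum, colnames(exprValues(lg)))
    carriers <- unique(inputs$variants$sample_id[
      inputs$variants$gene == gene &
      inputs$variants$effect %in% .FRAMESHIFT_EFFECTS])
    grpFs <- intersect(inStratum, carriers)
    grpWt <- setdiff(inStratum, carriers)
    if (length(grpFs) < 2L || length(grpWt) < 2L)
      stop(sprintf("need >= 2 carriers and >= 2 wild-type samples in stratum %s (got %d/%d)",
                   stratum, length(grpFs), length(grpWt)))
    lgStratum <- ExpressionMatrix(exprValues(lg)[, inStratum, drop = FALSE],
                                  "log2")
    ranked <- rankByT(lgStratum, grpFs, grpWt)
    list(log2 = lgStratum, z = zscoreRows(lgStratum), ranked = ranked,
         groupFs = grpFs, groupWt = grpWt)
  })
  paths <- c(paths, writeRnk(prep$ranked, file.path(outdir, "ranked.rnk")))
  gmtPath <- file.path(outdir, "gene_sets.gmt")
  writeGmt(inputs$collection, gmtPath)
  paths <- c(paths, gmtPath)

  gsea <- .stage("gsea", outdir,
                 runPreranked(prep$ranked, inputs$collection, weightP = weightP,
                              nPerm = nPerm, minSize = minSize,
                              maxSize = maxSize, seed = seed))
  paths <- c(paths, .writeTsv(gsea, file.path(outdir, "gsea.tsv")))

  scoreSetName <- names(inputs$collection)[1]
  scores <- .stage("score", outdir,
                   ifnResponseScore(prep$z, prep$ranked,
                                    inputs$collection[[scoreSetName]],
                                    k = scoreK, setName = scoreSetName))
  paths <- c(paths, .writeTsv(scores, file.path(outdir, "scores.tsv")))

  correlations <- .stage("correlate", outdir, {
    mafs <- sampleFrameshiftMaf(inputs$variants, scores$sample_id, gene)
    lgv <- exprValues(prep$log2)
    jak1 <- if (gene %in% rownames(lgv)) lgv[gene, scores$sample_id] else NULL
    carrier <- scores$sample_id %in% prep$groupFs
    one <- function(label, x, y) {
      res <- tryCatch(pearsonWithP(x, y),
                      error = function(e) list(r = NA_real_, p = NA_real_))
      data.frame(comparison = label, n = length(x), r = res$r, p = res$p,
                 stringsAsFactors = FALSE)
    }
    rows <- list()
    if (!is.null(jak1)) {
      rows <- c(rows, list(
        one("expression_vs_score_carrier", jak1[carrier], scores$score[carrier]),
        one("expression_vs_score_wildtype", jak1[!carrier], scores$score[!carrier]),
        one("expression_vs_maf_carrier", jak1[carrier], mafs$maf_sum[carrier])))
    }
    rows <- c(rows, list(
      one("maf_vs_score_carrier", mafs$maf_sum[carrier], scores$score[carrier])))
    do.call(rbind, rows)
  })
  paths <- c(paths, .writeTsv(correlations, file.path(outdir, "correlations.tsv")))

  heatmap <- .stage("report", outdir, {
    sel <- attr(scores, "genesUsed")
    tSel <- prep$ranked@score[match(sel, prep$ranked@gene)]
    geneOrder <- sel[order(tSel, sel)]
    carrier <- scores$sample_id %in% prep$groupFs
    sampleOrder <- c(scores$sample_id[carrier][order(scores$score[carrier])],
                     scores$sample_id[!carrier][order(scores$score[!carrier])])
    rbind(data.frame(kind = "gene", id = geneOrder,
                     position = seq_along(geneOrder), stringsAsFactors = FALSE),
          data.frame(kind = "sample", id = sampleOrder,
                     position = seq_along(sampleOrder), stringsAsFactors = FALSE))
  })
  paths <- c(paths, .writeTsv(heatmap, file.path(outdir, "heatmap_order.tsv")))

  reportPath <- file.path(outdir, "report.txt")
  gseaFmt <- gsea
  gseaFmt$p_fwer <- .formatFwer(gsea$p_fwer)
  gseaFmt$p_nominal <- .formatFwer(gsea$p_nominal)
  lines <- c(
    sprintf("fsevade run (seed %d)", seed),
    sprintf("samples: %d | variants: %d | hotspots: %d | zygosity-classified: %d",
            nrow(inputs$samples), nrow(inputs$variants), nrow(hotspots),
            nrow(kept)),
    sprintf("groups in %s: %d carriers vs %d wild-type", stratum,
            length(prep$groupFs), length(prep$groupWt)),
    "", "zygosity fractions:",
    sprintf("  %-28s %3d  %5.1f%%", zygFrac$category, zygFrac$n,
            100 * zygFrac$fraction),
    "", "enrichment (FWER < 0.001 shown as 0.000):",
    sprintf("  %-28s size %3d  ES % .3f  NES % .3f  FWER %s",
            gseaFmt$set, gseaFmt$size, gseaFmt$es, gseaFmt$nes, gseaFmt$p_fwer))
  writeLines(lines, reportPath)
  paths <- c(paths, reportPath)

  md5 <- tools::md5sum(paths)
  manifest <- data.frame(
    file = basename(paths), md5 = unname(md5),
    bytes = unname(file.size(paths)), stringsAsFactors = FALSE)
  info <- data.frame(file = c("#seed", "#config_md5", "#package"),
                     md5 = c(as.character(seed),
                             unname(tools::md5sum(configPath)),
                             as.character(packageVersion("fsevade"))),
                     bytes = NA_real_, stringsAsFactors = FALSE)
  .writeTsv(rbind(info, manifest), file.path(outdir, "manifest.tsv"))

  invisible(list(hotspots = hotspots, zygosity = zygosity,
                 zygosity_fractions = zygFrac, association = association,
                 ranked = prep$ranked, gsea = gsea, scores = scores,
                 correlations = correlations, heatmap_order = heatmap,
                 paths = c(paths, file.path(outdir, "manifest.tsv"))))
}
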