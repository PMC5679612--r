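#' Collapse frameshift calls into recurrent hotspots
#'
#' Frameshift deletions at amino-acid position `d` and frameshift insertions at
#' `d + 1` arise from slippage at the same homopolymer tract and are merged
#' into one hotspot keyed by the deletion position: a deletion at `d`
#' contributes to hotspot `(d, d+1)`, an insertion at `i` to hotspot
#' `(i-1, i)`. Nonsense mutations never pair. Hotspots observed fewer than
#' `minRecurrence` times are dropped; the result is sorted by count descending,
#' ties by position ascending.
#'
#' @param variants variant table with columns `sample_id`, `gene`,
#'   `protein_pos`, `effect`; only `frameshift_del`/`frameshift_ins` rows are
#'   counted.
#' @param minRecurrence minimum number of supporting calls (default 3,
#'   i.e. "more than 2 tumors mutated").
#' @return `data.frame` with columns `gene`, `del_pos`, `ins_pos`, `count`.
#' @examples
#' v <- data.frame(sample_id = sprintf("S%d", 1:15), gene = "JAK1",
#'                 protein_pos = c(rep(860, 10), rep(861, 5)),
#'                 effect = rep(c("frameshift_del", "frameshift_ins"), c(10, 5)))
#' collapseHotspots(v)
#' @export
collapseHotspots <- function(variants, minRecurrence = 3L) {
  empty <- data.frame(gene = character(), del_pos = integer(),
                      ins_pos = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0L) return(empty)
  fs <- variants[variants$effect %in% .FRAMESHIFT_EFFECTS, , drop = FALSE]
  if (nrow(fs) == 0L) return(empty)
  delPos <- ifelse(fs$effect == "frameshift_del", fs$protein_pos, fs$protein_pos - 1L)
  key <- paste(fs$gene, delPos, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 1L),
    del_pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  out$ins_pos <- out$del_pos + 1L
  out <- out[out$count >= minRecurrence, c("gene", "del_pos", "ins_pos", "count")]
  out <- out[order(-out$count, out$del_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate hotspots with their homopolymer tract context
#'
#' Each hotspot is matched against the tract whose codon span (the amino acids
#' encoded across the tract's nucleotides, `codon_start` through
#' `codon_start + ceiling(length/3) - 1`) contains the deletion position. Two
#' tracts covering the same position is an error.
#'
#' @param hotspots output of [collapseHotspots()].
#' @param tracts tract table with columns `gene`, `codon_start`, `base`,
#'   `length` (see [jak1Tracts()]).
#' @return the hotspot table with columns `tract_base`, `tract_length`,
#'   `tract_start` appended (`NA` where no tract covers the hotspot).
#' @export
annotateHomopolymer <- function(hotspots, tracts) {
  hotspots$tract_base <- NA_character_
  hotspots$tract_length <- NA_integer_
  hotspots$tract_start <- NA_integer_
  if (nrow(hotspots) == 0L) return(hotspots)
  span <- ceiling(tracts$length / 3) - 1L
  for (i in seq_len(nrow(hotspots))) {
    hit <- which(tracts$gene == hotspots$gene[i] &
                 tracts$codon_start <= hotspots$del_pos[i] &
                 tracts$codon_start + span >= hotspots$del_pos[i])
    if (length(hit) > 1L)
      stop(sprintf("ambiguous tract annotation at %s:%d (%d tracts match)",
                   hotspots$gene[i], hotspots$del_pos[i], length(hit)))
    if (length(hit) == 1L) {
      hotspots$tract_base[i] <- tracts$base[hit]
      hotspots$tract_length[i] <- tracts$length[hit]
      hotspots$tract_start[i] <- tracts$codon_start[hit]
    }
  }
  hotspots
}

#' Estimate the number of tumor copies carrying a mutation
#'
#' Standard purity/ploidy correction with diploid normal contamination:
#' `m = maf * (purity * CN + 2 * (1 - purity)) / purity`, capped at the tumor
#' copy number. Vectorized.
#'
#' @param maf mutant allele fraction(s) in (0, 1].
#' @param purity tumor purity in (0, 1].
#' @param copyNumber tumor gene copy number (integer >= 1).
#' @return estimated mutant copies (real, in `[0, copyNumber]`).
#' @examples
#' estimateMutantCopies(0.5, 1, 2)    # heterozygous pure tumor -> 1
#' estimateMutantCopies(0.25, 0.5, 2) # 1 mutant copy at 50% purity
#' @export
estimateMutantCopies <- function(maf, purity, copyNumber) {
  if (any(purity <= 0)) stop("purity must be positive")
  stopifnot(all(purity <= 1), all(maf > 0), all(maf <= 1), all(copyNumber >= 1))
  m <- maf * (purity * copyNumber + 2 * (1 - purity)) / purity
  pmin(m, copyNumber)
}

#' Classify the zygosity/clonality of truncating mutations in one sample
#'
#' Per-variant mutant-copy estimates are summed into a total `M`. The sample is
#' `subclonal` when `M < subclonalThreshold` (default 0.75 copies);
#' `homozygous_all_copies` when any single variant reaches
#' `copyNumber - homozygousTolerance` copies; otherwise
#' `double_truncation_partial` with two or more truncating variants, else
#' `partial_single_copy`. Samples at or below `minPurity` (default 0.40) are
#' excluded from the analysis and flagged `"filtered"`, mirroring the
#' accuracy-motivated purity filter.
#'
#' @param sampleVariants variant rows for one sample (columns `effect`, `maf`).
#' @param purity tumor purity in (0, 1].
#' @param copyNumber gene copy number in the tumor.
#' @param subclonalThreshold total mutant copies below which the event is
#'   called subclonal.
#' @param homozygousTolerance copies of slack absorbed when calling a variant
#'   present in all copies.
#' @param minPurity purity filter; `applyPurityFilter = FALSE` disables it.
#' @param applyPurityFilter logical.
#' @return one-row `data.frame` with columns `category` and `mutant_copies`.
#' @export
classifyZygosity <- function(sampleVariants, purity, copyNumber,
                             subclonalThreshold = 0.75, homozygousTolerance = 0.25,
                             minPurity = 0.40, applyPurityFilter = TRUE) {
  trunc <- sampleVariants[sampleVariants$effect %in% .TRUNCATING_EFFECTS, , drop = FALSE]
  if (nrow(trunc) == 0L) stop("no truncating variant to classify")
  if (applyPurityFilter && purity <= minPurity)
    return(data.frame(category = "filtered", mutant_copies = NA_real_,
                      stringsAsFactors = FALSE))
  m <- estimateMutantCopies(trunc$maf, purity, copyNumber)
  M <- sum(m)
  category <- if (M < subclonalThreshold) "subclonal"
    else if (any(m >= copyNumber - homozygousTolerance)) "homozygous_all_copies"
    else if (nrow(trunc) >= 2L) "double_truncation_partial"
    else "partial_single_copy"
  data.frame(category = category, mutant_copies = M, stringsAsFactors = FALSE)
}

#' Classify zygosity for every carrier in a cohort
#'
#' Applies [classifyZygosity()] to each sample with at least one truncating
#' variant in `gene`, using the sample's purity from the metadata table and
#' the per-gene copy number recorded on its variant rows.
#'
#' @param variants cohort variant table.
#' @param samples sample metadata with columns `sample_id`, `purity`.
#' @param gene gene of interest (default `"JAK1"`).
#' @param ... passed to [classifyZygosity()].
#' @return `data.frame` with one row per carrier: `sample_id`, `category`,
#'   `mutant_copies`.
#' @export
classifyCohortZygosity <- function(variants, samples, gene = "JAK1", ...) {
  v <- variants[variants$gene == gene &
                variants$effect %in% .TRUNCATING_EFFECTS, , drop = FALSE]
  ids <- unique(v$sample_id)
  rows <- lapply(ids, function(s) {
    sv <- v[v$sample_id == s, , drop = FALSE]
    p <- samples$purity[match(s, samples$sample_id)]
    cbind(sample_id = s,
          classifyZygosity(sv, purity = p, copyNumber = sv$copy_number[1], ...))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), category = character(),
               mutant_copies = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' Mutations per sequenced megabase. Vectorized.
#'
#' @param mutationCount non-negative mutation count(s).
#' @param panelMb sequenced territory in megabases (> 0).
#' @return mutations per Mb.
#' @examples
#' computeTmb(30, 1.3)
#' @export
computeTmb <- function(mutationCount, panelMb) {
  if (any(panelMb <= 0)) stop("panelMb must be positive")
  stopifnot(all(mutationCount >= 0))
  mutationCount / panelMb
}
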