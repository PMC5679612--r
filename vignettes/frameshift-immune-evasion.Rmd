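---
title: "Frameshift-driven immune evasion in MSI tumors: models and methods"
author: "fsevade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift-driven immune evasion in MSI tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsevade)
```

## The scientific question

Mismatch-repair-deficient tumors (microsatellite-instable, MSI-H) accumulate
frameshift mutations by replication slippage at homopolymer tracts. In JAK1
these frameshifts concentrate at four tracts — an 8-mer poly-T at K142/I143, a
7-mer poly-T at N339, a 7-mer poly-G at P430/L431 and an 8-mer poly-T at
K860/P861 (`jak1Tracts()`) — and, because deletions are annotated at the
first codon of the tract and insertions one codon downstream, every hotspot
appears as an adjacent deletion/insertion position pair. JAK1 transduces
interferon signaling; when a tumor loses every JAK1 copy, interferon-response
transcription collapses, which plausibly shields a highly antigenic MSI-H
tumor from immune attack. The package provides the full analytical chain
needed to test this picture on a variant table plus an expression matrix:
hotspot calling, zygosity/clonality classification, association statistics,
preranked gene-set enrichment, and a per-sample interferon-response score —
and a synthetic-cohort generator so everything runs and is validated without
controlled clinical data.

## The synthetic-cohort generator

`generateCohort()` draws, per sample: an MSI stratum (MSS / MSI-L / MSI-H), a
tumor purity, a log-normal tumor mutational burden (TMB, mutations/Mb), a
carrier indicator with stratum-specific frameshift probability, and, for
carriers, a clonality scenario, gene copy number, tract(s) and MAF(s). The
defaults are the study conditions this package is validated under:

* frameshift probability 0.38 (MSI-H), 0.09 (MSI-L), 0.005 (MSS) — the
  reported MSI-stratified endometrial frequencies; MSI-L is generated as a
  genuine third stratum with intermediate probability because the cohorts
  report it separately;
* TMB log-normal with medians 23.1 (MSI-H), 8 (MSI-L, an interpolated
  stand-in) and 4.5 (MSS) mutations/Mb, `sdlog` 0.6; the samples table keeps
  both the continuous draw (`tmb`) and the integer `mutation_count` implied
  by the 1.2 Mb panel, because integer counts quantize TMB in steps of
  1/1.2 ≈ 0.83 mutations/Mb, which is material at MSS-like burdens;
* carrier clonality mix 38.1% homozygous, 19.4% double partial truncation,
  31.3% single partial, 11.2% subclonal — the reported zygosity pie;
* tract choice weighted 24 : 17 : 90 : 135 (K142/I143 : N339 : P430/L431 :
  K860/P861), the reported hotspot recurrences; deletion or insertion with
  equal probability;
* purity uniform on (0.45, 0.95) and copy number on 1–4 with probabilities
  0.10/0.60/0.20/0.10 — field-realistic stand-ins, exposed in the
  configuration, since the source cohorts publish no distributions for
  either.

MAFs are generated by *inverting* the mutant-copy model (below): a scenario
fixes the mutant copies `m` (homozygous: `m = CN`; double partial: two
variants with `m ~ U(0.5, 0.85)` each; single partial: `m ~ U(1.0, 1.3)`;
subclonal: `m ~ U(0.1, 0.5)`), the ideal MAF follows from purity and copy
number, and truncated Gaussian noise (sd 0.03, clipped to (0, 1]) emulates
sequencing scatter. The ranges were chosen once so that each planted class
sits well clear of the classification boundaries (0.75 and `CN − 0.25`
copies) relative to that noise; partial scenarios require CN ≥ 2 so an
intact copy can exist.

Expression is per-gene log-normal (`meanlog` 2, `sdlog` 1 on the natural-log
scale) with per-sample noise SD `noiseSd` — heavy-tailed like RNA-seq
abundances. In carriers, the planted gene set and JAK1 itself are shifted on
the log scale by `effectSize × noiseSd × w`, where the suppression weight
`w` is the carrier's summed frameshift MAF divided by the MAF a fully
homozygous event would show at the same purity and copy number. Homozygous
carriers therefore receive the full effect and partial or subclonal carriers
proportionally less — the dose–response that makes the signature-score
distribution bimodal and couples it negatively to sample MAF.

What the generator does *not* emulate: read-level errors, FFPE artifacts,
germline variation, gene–gene expression correlation, batch effects, and
compositional structure of real RNA-seq. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to every failure mode of real data.

## Mutant copies and zygosity

With tumor purity `ρ`, tumor copy number `CN` and a diploid contaminating
normal, a variant on `m` tumor copies has expected MAF
`m·ρ / (ρ·CN + 2(1 − ρ))`; `estimateMutantCopies()` inverts this and caps the
estimate at `CN` (the cohorts state the analysis but not the formula; this is
the standard purity/ploidy correction). `classifyZygosity()` sums per-variant
estimates into `M` and calls: subclonal when `M < 0.75` copies; homozygous
(all copies) when any single variant reaches `CN − 0.25` copies — the 0.25
tolerance absorbs MAF noise without misclassifying a true heterozygote
(`m ≈ 1` at `CN = 2`); otherwise double partial truncation with two or more
truncating variants, else single partial. Samples at ≤ 40% purity are
excluded (flagged `"filtered"`, not an error) because copy estimates degrade
with contamination; the filter can be disabled. Nonsense variants count
toward zygosity but never toward del/ins hotspot pairing.

## Association statistics

`fisherExact2x2()` reports the two-sided minimum-likelihood exact P (the
`stats::fisher.test` convention, which reproduces the published cohort
P-values) together with the *sample* odds ratio `ad/bc` — not the
conditional-MLE odds ratio — because the cross-product is what the 2×2
summaries tabulate. Degenerate tables (an empty row or column) yield `p = 1`
and a flagged `NA` odds ratio. `mannWhitneyU()` uses the convention
`U = #{(i, j): x_i > y_j} + ½·ties` with midranks; p-values are exact up to
group sizes of 20 (rank-sum distribution without ties; full enumeration of
assignments when ties are present and the pooled sample is ≤ 12) and use the
tie- and continuity-corrected normal approximation beyond. Binomial
frequencies carry `SE = sqrt(p̂(1 − p̂)/n)`. MSI-L samples are excluded from
the MSS-vs-MSI-H tests and reported separately in the three-way frequency
table, mirroring the cohort analyses. No multiple-testing correction is
applied across diseases because the reference analyses report unadjusted
per-disease tests.

## Ranking genes

`rankByT()` scores each gene by `t = (mean_fs − mean_wt) / SD`. "Student's t
… divided by standard deviation" is ambiguous between the pooled SD and the
sum of group SDs; the default is the pooled SD (the classical Student
numerator/denominator without the `sqrt(1/n1 + 1/n2)` factor), with the
GSEA-native signal-to-noise alternative behind `metric = "s2n"` — the choice
only perturbs ranks, which the downstream statistics tolerate. The
denominator is floored at `max(1e-8, 0.01·|Δmean|)` so near-constant genes
cannot dominate the tails. Ties are broken by gene identifier, making every
ranking (and everything downstream of it) reproducible. The log2 transform
uses pseudocount 1 (unstated upstream; the conventional choice), and row
z-scores use the population SD, which makes z-scoring idempotent and maps
constant genes to flagged all-zero rows.

## The enrichment engine

`enrichmentScore()` walks the ranked list: a set gene at rank `i` adds
`|t_i|^p / N_R` (`N_R` the sum over set genes of `|t_i|^p`), any other gene
subtracts `1/(N − N_H)`; the ES is the running sum's signed maximum
deviation. `p = 1` is the "weighted" statistic used for Hallmark-sized sets;
`p = 2` ("weighted p2") is appropriate for small immune-style sets, where
the higher penalty demands stronger concentration at the list front. With
`p = 0` and equal scores the ES reduces to the classical two-sample
Kolmogorov–Smirnov statistic. Degenerate inputs are rejected (empty
intersection; a set covering the whole list leaves the miss decrement
undefined); an all-zero-score hit total falls back to equal hit weights. On
an exact tie between the positive and negative extremes the positive one is
returned — a documented convention, which is also why exact antisymmetry
under list reversal holds only off ties.

`runPreranked()` builds the null by gene-label permutation: membership is
reassigned uniformly over the ranked genes with scores fixed (phenotype
permutation is impossible at the preranked stage). Permutation scores use a
closed form of the running-sum extremes (the profile is piecewise linear, so
its extremes occur just before or just after a hit), vectorized across
permutations; a property test pins this fast path to the full cumulative
sum. Per set, `NES = ES / mean(|same-sign permuted ES|)`, and the nominal p
is the add-one-corrected fraction of same-sign permutation scores at least
as extreme. The FWER p counts permutations whose family-wide maximum
same-sign |NES| across the collection reaches the observed |NES|, on the
same same-sign add-one denominator, capped at 1. This denominator choice is
deliberate: it makes two properties exact theorems — a single-set
collection has `FWER p = nominal p`, and `FWER p ≥ nominal p` always —
which the more common all-permutations denominator violates. The cost is
that strict monotonicity of p in |NES| across sets holds only up to the
per-set variation in same-sign counts (this is equally true of the nominal
p under any same-sign definition), so it is verified as a rank correlation
rather than an exact ordering. Under a true null the family-wise rejection
rate at threshold α is approximately α by exchangeability of the observed
ranking with the permutations — the FWER is calibrated, not conservative —
so across 20 independent null runs the expected number with any set below
0.05 is about one, and occasional excursions to two or three are ordinary
binomial variation rather than miscalibration. Calibration of the nominal
p-values is checked by pooling 50 random set-tests from each of 20
independent null cohorts rather than drawing many sets over one ranked
list: sets sharing a single list reuse its extreme-tail genes, and the
resulting dependence would fail an independence-assuming uniformity test
even though every marginal p-value is exactly uniform. Add-one corrections keep
every p strictly positive; the report layer prints FWER below 0.001 as
"0.000" while the machine-readable tables keep full precision.

`removeOverlap()` supports the overlap-control rerun: subtract a reference
set (e.g. a 200-gene interferon-γ response set) from every other set, drop
sets falling below the size filter, and rerun the enrichment to see which
signals were merely borrowed.

## The signature score

`ifnResponseScore()` sums, per sample, the expression z-scores of the `k`
(default 25) most *suppressed* genes of a named set — the set genes with the
most negative ranking statistic. "Top k by t" is directionally ambiguous;
the most-negative reading is used because the score quantifies loss of the
interferon program in carriers (an `|t|` option exists). Taking the top 25
within the set is equivalent to restricting the global ranking to the set,
and is the reading implemented. If fewer than `k` set genes are available,
all are used and the output records the count. `sampleFrameshiftMaf()` sums
frameshift MAFs per sample (0 for non-carriers) as the clonality proxy, and
`pearsonWithP()` supplies the score–MAF and score–expression correlations
with t-transform p-values on `n − 2` degrees of freedom. The score histogram
contract is descriptive only: the bimodality of carrier scores is a
consequence of the clonality mix, and no formal mixture test is attempted.

## The pipeline

`runPipeline()` chains the stages on either a simulated cohort or on-disk
tables, writing per-stage TSVs, an RNK file, a GMT of the tested collection,
a human-readable report, a heatmap ordering file (genes by increasing t;
carrier samples first, each block ordered by signature score) and a manifest
with an MD5 for every output, the seed and the configuration hash —
re-running with the same configuration reproduces the hashes byte for byte.
Any stage error aborts with the stage name and leaves a `FAILED` marker next
to the partial outputs. A thin command-line wrapper over these functions
ships in `inst/scripts/fsevade.R`.

## Problem sizes and numerical choices

The validation suite runs cohorts of 80–1000 samples with 30–2000 genes,
1000 permutations per enrichment run, 500-instance oracle sweeps for the ES,
and 20-run recovery/calibration experiments — sizes chosen so the full suite
completes in a couple of minutes on one CPU while keeping every statistical
check adequately powered. Floating-point contracts are explicit: TPM columns
sum to 1e6 within 1e-6 relative; z-score validity is enforced at 1e-8;
ES ties are resolved at 1e-12.

## Known limitations

Variant calling, germline filtering and copy-number integerization are out
of scope — variants, purity and copy number are inputs. Double truncations
cannot be phased onto alleles from MAF alone. The FWER convention follows
the contract above; other tools' FWER values can differ by their choice of
denominator even on identical permutations. FDR q-values, leading-edge
extraction and phenotype-permutation GSEA are intentionally not provided.
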