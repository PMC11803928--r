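#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowRanges colData rowData
#' @importFrom Rcpp sourceCpp
#' @useDynLib fawpopgen, .registration = TRUE
NULL

#' Genotype container for the two-strain analysis
#'
#' `StrainGenotypes` extends `RangedSummarizedExperiment`: rows are sites
#' (a `GRanges` with `REF`, `ALT` and a `multiallelic` flag in its metadata
#' columns), columns are samples, and the assays hold the diploid dosage
#' matrix `GT` (integer 0/1/2, `NA` = missing genotype) plus optional
#' per-genotype sequencing depth `DP` and phred genotype quality `GQ`.
#' Chromosomes are named "1".."31"; "31" is the Z (all sampled moths are
#' male and therefore ZZ, so the Z is an ordinary diploid chromosome here).
#'
#' @export
setClass("StrainGenotypes", contains = "RangedSummarizedExperiment")

setValidity("StrainGenotypes", function(object) {
  if (!"GT" %in% assayNames(object))
    return("assay 'GT' (dosage matrix) is required")
  gt <- assay(object, "GT")
  bad <- !is.na(gt) & !(gt %in% 0:2)
  if (any(bad))
    return("dosages must be 0, 1, 2 or NA")
  if (nrow(object) > 1L) {
    chr <- as.character(seqnames(rowRanges(object)))
    pos <- start(rowRanges(object))
    ord <- order(factor(chr, levels = unique(chr)), pos)
    if (is.unsorted(ord))
      return("sites must be sorted by position within each chromosome")
    same <- chr[-1L] == chr[-length(chr)]
    if (any(same & diff(pos) <= 0L))
      return("positions must be strictly increasing within a chromosome")
  }
  TRUE
})

#' Simulation configuration for the two-strain cohort generator
#'
#' Holds the generative parameters of the synthetic two-strain genome:
#' Balding-Nichols differentiation with separate autosomal and Z-linked
#' Fst, C-strain flyway sub-structure, an F1-like hybrid fraction, fixed
#' diagnostic markers on the Z, genotype-quality noise, and injectable
#' hard sweeps. Defaults mirror the genome-wide estimates for the North
#' American fall armyworm strains (autosomal Fst 0.086, Z Fst 0.671,
#' C-strain flyway Fst 0.047).
#'
#' @slot n_samples_per_group diploid samples per strain
#' @slot chrom_lengths lengths in bp of the 31 chromosomes (31 = Z)
#' @slot n_sites_per_chrom polymorphic sites simulated per chromosome
#' @slot fst_autosome,fst_z,fst_subpop Balding-Nichols F parameters
#' @slot hybrid_fraction fraction of F1-like hybrids added to the cohort
#' @slot n_subpops_c number of C-strain flyway subpopulations
#' @slot n_markers diagnostic fixed-difference markers placed on the Z
#' @slot missing_rate,depth_mean,gq_mean,gq_sd genotype-level noise model
#' @slot spectrum ancestral-frequency model: "uniform" (p ~ U(0.05,0.95),
#'   SFS-agnostic) or "neutral" (1/p-density ancestral frequencies; at
#'   zero differentiation, exact 1/j minor-count assignment)
#' @slot sweep_specs list of `list(chrom=, center_bp=, strength=)` hard
#'   sweeps injected into the C strain
#' @slot seed integer; fully determines the output
#' @export
setClass("SimConfig", representation(
  n_samples_per_group = "numeric",
  chrom_lengths       = "numeric",
  n_sites_per_chrom   = "numeric",
  fst_autosome        = "numeric",
  fst_z               = "numeric",
  fst_subpop          = "numeric",
  hybrid_fraction     = "numeric",
  n_subpops_c         = "numeric",
  n_markers           = "numeric",
  missing_rate        = "numeric",
  depth_mean          = "numeric",
  gq_mean             = "numeric",
  gq_sd               = "numeric",
  spectrum            = "character",
  sweep_specs         = "list",
  seed                = "numeric"
))

setValidity("SimConfig", function(object) {
  pr <- c(fst_autosome = object@fst_autosome, fst_z = object@fst_z,
          fst_subpop = object@fst_subpop,
          hybrid_fraction = object@hybrid_fraction,
          missing_rate = object@missing_rate)
  if (any(pr < 0 | pr > 1))
    return("all proportions must lie in [0, 1]")
  if (length(object@chrom_lengths) != 31L)
    return("chrom_lengths must give the 31 chromosomes (31 = Z)")
  if (any(object@chrom_lengths <= 0))
    return("chromosome lengths must be positive")
  if (object@n_samples_per_group < 1 || object@n_sites_per_chrom < 1)
    return("need at least one sample per group and one site per chromosome")
  if (!object@spectrum %in% c("uniform", "neutral"))
    return("spectrum must be 'uniform' or 'neutral'")
  TRUE
})
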