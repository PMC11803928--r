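#' Genotype-quality site filter
#'
#' Reproduces the study's quality screen: genotypes with sequencing depth
#' below `min_depth` or genotype quality below `min_gq` are set missing,
#' and sites whose post-masking missing fraction exceeds `max_missing`
#' are removed (ties at exactly the threshold are retained: the rule is
#' "more than" 50% missing). Site order is preserved and retained
#' genotypes are never altered except by the DP/GQ masking itself.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param min_depth minimum per-genotype DP (default 6)
#' @param min_gq minimum per-genotype GQ (default 10)
#' @param max_missing maximum site missing fraction (default 0.5)
#' @return the filtered [StrainGenotypes-class]; a `filter_log` entry in
#'   its metadata records sites in/out.
#' @export
filterSiteQuality <- function(gm, min_depth = 6, min_gq = 10,
                              max_missing = 0.5) {
  gt <- dosages(gm)
  dp <- depthMatrix(gm); gq <- gqMatrix(gm)
  if (is.null(dp) && is.null(gq))
    warning("no DP/GQ annotations; applying the missingness rule only")
  mask <- matrix(FALSE, nrow(gt), ncol(gt))
  if (!is.null(dp)) mask <- mask | (!is.na(dp) & dp < min_depth)
  if (!is.null(gq)) mask <- mask | (!is.na(gq) & gq < min_gq)
  gt[mask] <- NA_integer_
  miss <- rowMeans(is.na(gt))
  keep <- miss <= max_missing
  assays(gm)$GT <- gt
  out <- gm[keep, ]
  metadata(out)$filter_log <- rbind(metadata(gm)$filter_log, data.frame(
    rule = "site_quality", sites_in = nrow(gm), sites_out = sum(keep)))
  out
}

#' Biallelic minor-allele-frequency filter
#'
#' Retains sites with exactly one ALT allele and a global minor allele
#' frequency (computed over the non-missing dosages of all samples) of at
#' least `maf_min`.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param maf_min minimum global minor allele frequency (default 0.01;
#'   sites with maf < 0.01 are removed, maf == 0.01 is retained)
#' @return the filtered [StrainGenotypes-class].
#' @export
filterBiallelicMaf <- function(gm, maf_min = 0.01) {
  si <- siteInfo(gm)
  keep <- !si$multiallelic & !is.na(si$maf) & si$maf >= maf_min
  out <- gm[keep, ]
  metadata(out)$filter_log <- rbind(metadata(gm)$filter_log, data.frame(
    rule = "biallelic_maf", sites_in = nrow(gm), sites_out = sum(keep)))
  out
}

#' Restrict to placed chromosomes
#'
#' Drops sites that did not map to one of the 31 chromosomes (unplaced
#' scaffolds and the like).
#'
#' @param gm a [StrainGenotypes-class] object
#' @param keep chromosome names to retain (default "1".."31")
#' @return the restricted [StrainGenotypes-class].
#' @export
restrictChromosomes <- function(gm, keep = as.character(1:31)) {
  sel <- chromOf(gm) %in% as.character(keep)
  out <- gm[sel, ]
  metadata(out)$filter_log <- rbind(metadata(gm)$filter_log, data.frame(
    rule = "chromosomes", sites_in = nrow(gm), sites_out = sum(sel)))
  out
}

#' Declared missing-data policy (stand-in for genotype imputation)
#'
#' Either records that missing genotypes will be handled by pairwise
#' deletion inside each statistic (`"drop-missing-pairwise"`, the default
#' policy throughout this package) or fills each missing genotype with
#' the site's most frequent observed dosage (`"major-genotype-fill"`;
#' ties broken toward the lower dosage). The chosen mode is recorded in
#' the object's metadata.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param mode "drop-missing-pairwise" or "major-genotype-fill"
#' @return the (possibly filled) [StrainGenotypes-class].
#' @export
naiveImpute <- function(gm, mode = c("drop-missing-pairwise",
                                     "major-genotype-fill")) {
  mode <- match.arg(mode)
  if (mode == "major-genotype-fill") {
    gt <- dosages(gm)
    for (s in which(rowSums(is.na(gt)) > 0)) {
      tab <- tabulate(gt[s, ] + 1L, nbins = 3L)
      if (sum(tab) == 0L) next
      gt[s, is.na(gt[s, ])] <- which.max(tab) - 1L
    }
    assays(gm)$GT <- gt
  }
  metadata(gm)$impute_mode <- mode
  gm
}
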