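#' Call strain from Z-linked diagnostic markers
#'
#' Classifies every sample against a panel of Z-linked strain-diagnostic
#' markers (e.g. Tpi plus diagnostic SNPs). The rules: a sample with
#' fewer than two non-missing marker genotypes is `unknown` (removed from
#' composition denominators); a sample heterozygous at one or more
#' markers is a putative `hybrid`; otherwise all observed markers
#' homozygous for C alleles gives `C`, all for R alleles gives `R`; and
#' discordant homozygous calls (some C-hom, some R-hom, no het) give
#' `unknown` with a discordance flag — the conservative choice, so as
#' not to inflate hybrid counts.
#'
#' @param gm a [StrainGenotypes-class] object containing the marker sites
#' @param panel data.frame with columns chrom, pos, C_allele, R_allele,
#'   name (at least two markers)
#' @return data.frame with one row per sample: sample, label (C / R /
#'   hybrid / unknown), n_markers_observed, discordant, plus one column
#'   per marker holding its genotype class (C-hom / het / R-hom / missing).
#' @export
callStrains <- function(gm, panel) {
  if (nrow(panel) < 2) stop("the marker panel needs at least 2 markers")
  key <- paste(chromOf(gm), posOf(gm))
  idx <- match(paste(as.character(panel$chrom), panel$pos), key)
  if (anyNA(idx))
    stop("panel marker(s) absent from the genotype data: ",
         paste(panel$name[is.na(idx)], collapse = ", "))
  ref <- mcols(rowRanges(gm))$REF[idx]
  alt <- mcols(rowRanges(gm))$ALT[idx]
  ## orientation: does dosage 0 (hom-REF) mean C-hom at this marker?
  c_is_ref <- panel$C_allele == ref & panel$R_allele == alt
  r_is_ref <- panel$R_allele == ref & panel$C_allele == alt
  if (any(!c_is_ref & !r_is_ref)) {
    bad <- which(!c_is_ref & !r_is_ref)[1]
    stop("marker ", panel$name[bad],
         ": panel alleles do not match the site's REF/ALT alleles")
  }
  gt <- dosages(gm)[idx, , drop = FALSE]
  cls <- matrix("missing", nrow(panel), ncol(gt),
                dimnames = list(panel$name, colnames(gt)))
  for (m in seq_len(nrow(panel))) {
    g <- gt[m, ]
    lab <- c("C-hom", "het", "R-hom")
    if (!c_is_ref[m]) lab <- rev(lab)
    cls[m, !is.na(g)] <- lab[g[!is.na(g)] + 1L]
  }
  n_obs <- colSums(cls != "missing")
  n_het <- colSums(cls == "het")
  n_c <- colSums(cls == "C-hom")
  n_r <- colSums(cls == "R-hom")
  label <- rep("unknown", ncol(gt))
  discord <- n_het == 0 & n_c > 0 & n_r > 0
  label[n_obs >= 2 & n_het >= 1] <- "hybrid"
  label[n_obs >= 2 & n_het == 0 & n_c > 0 & n_r == 0] <- "C"
  label[n_obs >= 2 & n_het == 0 & n_r > 0 & n_c == 0] <- "R"
  label[n_obs < 2] <- "unknown"
  out <- data.frame(sample = colnames(gt), label = label,
                    n_markers_observed = n_obs,
                    discordant = discord & n_obs >= 2,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(t(cls), stringsAsFactors = FALSE))
}

#' Aggregate strain calls into group compositions
#'
#' Tallies strain calls per group, excluding `unknown` samples from the
#' denominators, and reports integer percentages rounded half-up —
#' the convention behind printed compositions such as "30% C-strain,
#' 66% R-strain and 4% putative hybrids".
#'
#' @param calls data.frame from [callStrains()] (columns sample, label)
#' @param groups named character vector or data.frame(sample, group)
#'   assigning each sample to a group (flyway, region, ...)
#' @return data.frame per group: n (called), n_C, n_R, n_hybrid,
#'   n_unknown, pct_C, pct_R, pct_hybrid.
#' @export
aggregateComposition <- function(calls, groups) {
  if (is.data.frame(groups)) {
    g <- groups$group[match(calls$sample, groups$sample)]
  } else {
    g <- unname(groups[calls$sample])
  }
  if (anyNA(g)) stop("every sample needs a group label")
  res <- lapply(split(calls$label, g), function(lab) {
    n_unknown <- sum(lab == "unknown")
    lab <- lab[lab != "unknown"]
    n <- length(lab)
    cnt <- c(C = sum(lab == "C"), R = sum(lab == "R"),
             hybrid = sum(lab == "hybrid"))
    pct <- if (n > 0) roundHalfUp(100 * cnt / n) else rep(NA_real_, 3)
    data.frame(n = n, n_C = cnt[["C"]], n_R = cnt[["R"]],
               n_hybrid = cnt[["hybrid"]], n_unknown = n_unknown,
               pct_C = pct[[1]], pct_R = pct[[2]], pct_hybrid = pct[[3]])
  })
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  rownames(out) <- NULL
  out
}

#' The study's collection table
#'
#' Returns the packaged 2021 pheromone-trap collection table: 24
#' collections (county, state, flyway, month, host plants) with the
#' number of samples successfully strain-typed and their C / hybrid / R
#' breakdown. The `region` column separates Puerto Rico from the
#' continental eastern flyway, matching how compositions are reported.
#'
#' @return data.frame with columns county, state, flyway, region, month,
#'   host, n, n_C, n_hybrid, n_R; every row satisfies
#'   `n == n_C + n_hybrid + n_R`.
#' @export
collectionTable <- function() {
  path <- system.file("extdata", "collections_2021.csv",
                      package = "fawpopgen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Strain composition of pooled collection-table groups
#'
#' Pools the collection table's per-collection counts by a grouping
#' column and reports integer percentages (rounded half-up) of C-strain,
#' R-strain and putative hybrids.
#'
#' @param tbl a collection table, as from [collectionTable()]
#' @param by grouping column name (default "region")
#' @return data.frame per group: n, n_C, n_hybrid, n_R, pct_C, pct_R,
#'   pct_hybrid.
#' @export
aggregateCollectionTable <- function(tbl, by = "region") {
  res <- lapply(split(tbl, tbl[[by]]), function(d) {
    n <- sum(d$n)
    data.frame(n = n, n_C = sum(d$n_C), n_hybrid = sum(d$n_hybrid),
               n_R = sum(d$n_R),
               pct_C = roundHalfUp(100 * sum(d$n_C) / n),
               pct_R = roundHalfUp(100 * sum(d$n_R) / n),
               pct_hybrid = roundHalfUp(100 * sum(d$n_hybrid) / n))
  })
  out <- cbind(group = names(res), do.call(rbind, res))
  rownames(out) <- NULL
  out
}
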