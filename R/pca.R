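#' Patterson normalisation of a genotype matrix
#'
#' Normalises each biallelic site as (g - 2*p_hat)/sqrt(p_hat(1-p_hat))
#' with the shrunk frequency estimate p_hat = (1 + sum(g))/(2 + 2*n_obs),
#' the convention of smartpca-style PCA. Missing entries are set to zero
#' after centring; monomorphic sites (zero observed variance) are
#' dropped.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param samples samples to include (default: all)
#' @return normalised sites-x-samples matrix with a `"kept"` attribute
#'   giving the retained site indices.
#' @export
pattersonNormalize <- function(gm, samples = NULL) {
  idx <- resolveSamples(gm, samples)
  gt <- dosages(gm)[, idx, drop = FALSE]
  n_obs <- rowSums(!is.na(gt))
  p_hat <- (1 + rowSums(gt, na.rm = TRUE)) / (2 + 2 * n_obs)
  v <- apply(gt, 1, stats::var, na.rm = TRUE)
  keep <- n_obs > 0 & !is.na(v) & v > 0
  x <- (gt[keep, , drop = FALSE] - 2 * p_hat[keep]) /
    sqrt(p_hat[keep] * (1 - p_hat[keep]))
  x[is.na(x)] <- 0
  attr(x, "kept") <- which(keep)
  x
}

#' Principal component analysis of genotypes
#'
#' Eigendecomposition of the sample-sample covariance of the
#' Patterson-normalised genotype matrix, on the full data, autosomes
#' only, or the Z-chromosome only. Coordinates are deterministic up to
#' the sign of each component.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param k number of components (default 10; must be < n_samples)
#' @param dataset "all", "autosomes" or "z"
#' @param samples samples to include (default: all)
#' @return list: `coords` (samples x k), `eigenvalues` (length k),
#'   `pct_variance` (percent of total variance per component),
#'   `dataset`, `n_sites`.
#' @export
genotypePca <- function(gm, k = 10, dataset = c("all", "autosomes", "z"),
                        samples = NULL) {
  dataset <- match.arg(dataset)
  sel <- switch(dataset,
                all = rep(TRUE, nrow(gm)),
                autosomes = chromOf(gm) %in% as.character(1:30),
                z = chromOf(gm) == "31")
  sub <- gm[sel, ]
  idx <- resolveSamples(sub, samples)
  if (k > length(idx) - 1) stop("k must be at most n_samples - 1")
  x <- pattersonNormalize(sub, idx)
  cv <- crossprod(x) / nrow(x)
  eig <- eigen(cv, symmetric = TRUE)
  coords <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- colnames(sub)[idx]
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, eigenvalues = eig$values[seq_len(k)],
       pct_variance = 100 * eig$values[seq_len(k)] /
         sum(pmax(eig$values, 0)),
       dataset = dataset, n_sites = nrow(x))
}

#' Pairwise weighted Fst between a-priori groups
#'
#' Weighted Weir-Cockerham Fst for every pair of groups (strain, flyway,
#' or strain-x-flyway), on the requested chromosome set. Pairs where
#' either group has fewer than two samples are reported missing.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param grouping named character vector (names = sample names) or
#'   the name of a `colData` column
#' @param dataset "all", "autosomes" or "z"
#' @return symmetric matrix of weighted Fst values (diagonal 0).
#' @export
pairwiseGroupFst <- function(gm, grouping, dataset = c("all", "autosomes", "z")) {
  dataset <- match.arg(dataset)
  sel <- switch(dataset,
                all = rep(TRUE, nrow(gm)),
                autosomes = chromOf(gm) %in% as.character(1:30),
                z = chromOf(gm) == "31")
  sub <- gm[sel, ]
  if (length(grouping) == 1 && is.character(grouping))
    grouping <- setNames(as.character(colData(sub)[[grouping]]), colnames(sub))
  groups <- split(names(grouping), grouping)
  gn <- names(groups)
  if (length(gn) < 2) stop("need at least 2 groups")
  out <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  diag(out) <- 0
  for (i in seq_along(gn)) for (j in seq_len(i - 1)) {
    if (length(groups[[i]]) < 2 || length(groups[[j]]) < 2) next
    f <- wcFst(sub, groups[[i]], groups[[j]])$global
    out[i, j] <- out[j, i] <- f
  }
  out
}
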