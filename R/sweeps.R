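## ---- site frequency spectrum ----------------------------------------------

#' Hypergeometric projection of a site's allele counts
#'
#' Probability distribution of the minor/derived allele count after
#' projecting a site with `c1` copies among `m` observed alleles down to
#' a sample of `n_to` alleles drawn without replacement.
#'
#' @param c1 allele count at the site
#' @param m observed alleles at the site (>= n_to)
#' @param n_to projection sample size
#' @return numeric vector of probabilities over counts 0..n_to.
#' @export
projectCounts <- function(c1, m, n_to) {
  if (m < n_to) stop("cannot project ", m, " alleles up to ", n_to)
  stats::dhyper(0:n_to, c1, m - c1, n_to)
}

#' Background site frequency spectrum
#'
#' Estimates the genome-wide background SFS of a population by
#' hypergeometric projection of every site down to a common sample size
#' (the median observed allele number by default). Sites with fewer
#' observed alleles than the projection size are skipped. The folded
#' spectrum is returned over minor-allele classes 0..floor(n/2); class 0
#' (monomorphic within the population) is included by default because
#' the scan operates on the full SNP set restricted to one population,
#' where fixed and swept sites are monomorphic within the group —
#' exactly where sweep evidence accumulates. Set
#' `include_monomorphic = FALSE` for the classical polymorphic-only
#' spectrum.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param samples population sample names (default: all)
#' @param n_project projection size in alleles (default: median observed)
#' @param folded fold the spectrum (default TRUE; ancestral states are
#'   unknown in the VCF)
#' @param include_monomorphic keep the monomorphic class (default TRUE)
#' @return list: `phi` (named probability vector over count classes),
#'   `n` (projection size), `folded`, `include_monomorphic`,
#'   `n_sites_used`, `n_sites_skipped`.
#' @export
backgroundSFS <- function(gm, samples = NULL, n_project = NULL,
                          folded = TRUE, include_monomorphic = TRUE) {
  idx <- resolveSamples(gm, samples)
  ac <- alleleCounts(dosages(gm), idx)
  if (sum(ac$m >= 4) == 0) stop("need sites with at least 4 observed alleles")
  if (is.null(n_project)) {
    n_project <- as.integer(stats::median(ac$m[ac$m > 0]))
    if (n_project %% 2L == 1L) n_project <- n_project - 1L
  }
  use <- ac$m >= n_project
  spec <- numeric(n_project + 1)
  for (m in unique(ac$m[use])) {
    sel <- use & ac$m == m
    cnt_tab <- tabulate(ac$c1[sel] + 1L, nbins = m + 1L)
    H <- vapply(0:m, function(cc) projectCounts(cc, m, n_project),
                numeric(n_project + 1))
    spec <- spec + drop(H %*% cnt_tab)
  }
  names(spec) <- 0:n_project
  if (folded) {
    half <- n_project %/% 2
    phi <- vapply(0:half, function(j) {
      if (j == n_project - j) spec[[j + 1]]
      else spec[[j + 1]] + spec[[n_project - j + 1]]
    }, numeric(1))
    names(phi) <- 0:half
  } else phi <- spec
  if (!include_monomorphic) {
    phi <- phi[names(phi) != "0"]
    if (!folded) phi <- phi[names(phi) != as.character(n_project)]
  }
  phi <- phi / sum(phi)
  list(phi = phi, n = n_project, folded = folded,
       include_monomorphic = include_monomorphic,
       n_sites_used = sum(use), n_sites_skipped = sum(!use))
}

## ---- composite likelihood ratio scan --------------------------------------

## Build the log-likelihood-ratio lookup table over a uniform pe grid.
## Star-tree sweep model: of n lineages, k escape the sweep
## (Binomial(n, pe)) and retain the background spectrum; the n-k
## hitchhiked lineages all carry the swept haplotype's allele, which is
## the derived allele with probability i/n given pre-sweep derived count
## i. Pre-sweep counts are drawn from the symmetrised background
## spectrum.
sweepLogRatioTable <- function(sfs, n_pe = 512L) {
  n <- sfs$n
  stopifnot(sfs$folded)
  half <- n %/% 2
  ## unfolded symmetric spectrum psi over 0..n
  psi <- numeric(n + 1)
  for (i in 0:n) {
    f <- min(i, n - i)
    p <- if (as.character(f) %in% names(sfs$phi)) sfs$phi[[as.character(f)]] else 0
    psi[i + 1] <- if (i == n - i) p else p / 2
  }
  ## P_k(b): outcome distribution given k escapees
  Pk <- matrix(0, n + 1, n + 1)  # rows k, cols b
  for (k in 0:n) {
    for (i in which(psi > 0) - 1L) {
      hj <- stats::dhyper(0:k, i, n - i, k)
      w <- psi[i + 1]
      Pk[k + 1, 1:(k + 1)] <- Pk[k + 1, 1:(k + 1)] + w * (1 - i / n) * hj
      lo <- (n - k) + 1L
      Pk[k + 1, lo:(lo + k)] <- Pk[k + 1, lo:(lo + k)] + w * (i / n) * hj
    }
  }
  pe <- seq(0, 1, length.out = n_pe)
  B <- t(vapply(pe, function(p) stats::dbinom(0:n, n, p), numeric(n + 1)))
  S <- B %*% Pk                       # n_pe x (n+1) outcome probabilities
  ## fold, and optionally condition on polymorphism
  classes <- 0:half
  Sf <- vapply(classes, function(j) {
    if (j == n - j) S[, j + 1] else S[, j + 1] + S[, n - j + 1]
  }, numeric(n_pe))
  phi0 <- setNames(rep(0, half + 1), 0:half)
  phi0[names(sfs$phi)] <- sfs$phi
  if (!sfs$include_monomorphic) {
    keepc <- classes >= 1
    Sf <- Sf[, keepc, drop = FALSE] / (1 - Sf[, 1])
    phi0 <- phi0[keepc]
    classes <- classes[keepc]
  }
  tiny <- 1e-12
  L <- log(pmax(Sf, tiny)) -
    matrix(log(pmax(phi0, tiny)), n_pe, length(classes), byrow = TRUE)
  ## classes with zero background probability carry no usable signal
  L[, phi0 <= 0] <- 0
  list(L = L, classes = classes, n = n)
}

## default alpha ladder: log-spaced sweep intensities (1/bp scale)
defaultAlphaLadder <- function(n_alpha = 40)
  10^seq(-7, -1, length.out = n_alpha)

#' Composite likelihood ratio sweep scan
#'
#' SFS-based scan for completed hard sweeps. The chromosome is divided
#' into `floor(length / grid_bp)` evenly spaced grid points; at each
#' point the composite log-likelihood ratio between a star-tree
#' hitchhiking model (sites escape the sweep with probability
#' 1 - exp(-alpha d)) and the genome-wide background spectrum is
#' maximised over a fixed logarithmic ladder of alpha values and floored
#' at zero.
#'
#' @param gm a [StrainGenotypes-class] object (full SNP set; sites
#'   monomorphic within the group are informative and retained when the
#'   background spectrum includes the monomorphic class)
#' @param samples population sample names
#' @param chroms chromosomes to scan (default: all present)
#' @param grid_bp grid spacing in bp (default 5000)
#' @param sfs background spectrum from [backgroundSFS()] (computed over
#'   `gm` if omitted)
#' @param alphas alpha ladder (default 40 log-spaced values)
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the last site position per chromosome
#' @return data.frame: chrom, pos, clr, alpha (the maximising ladder
#'   value).
#' @export
clrScan <- function(gm, samples = NULL, chroms = NULL, grid_bp = 5000,
                    sfs = NULL, alphas = defaultAlphaLadder(),
                    chrom_lengths = NULL) {
  idx <- resolveSamples(gm, samples)
  if (is.null(sfs)) sfs <- backgroundSFS(gm, samples)
  tab <- sweepLogRatioTable(sfs)
  ac <- alleleCounts(dosages(gm), idx)
  chrom <- chromOf(gm); pos <- posOf(gm)
  if (is.null(chroms)) chroms <- unique(chrom)
  out <- lapply(as.character(chroms), function(ch) {
    sel <- chrom == ch & ac$m > 0
    if (!any(sel)) return(NULL)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(pos[sel])
    G <- max(1L, floor(len / grid_bp))
    grid <- (seq_len(G) - 0.5) * len / G
    b <- siteClassIndex(ac$c1[sel], ac$m[sel], sfs, tab)
    ok <- !is.na(b)
    res <- clr_scan_cpp(as.numeric(pos[sel][ok]), b[ok] - 1L, tab$L,
                        as.numeric(grid), alphas)
    data.frame(chrom = ch, pos = grid, clr = res[, 1],
               alpha = alphas[res[, 2]])
  })
  do.call(rbind, out)
}

## map each site's (c1, m) to a folded class column of the lookup table;
## sites with m != n are rescaled to the projection size
siteClassIndex <- function(c1, m, sfs, tab) {
  n <- sfs$n
  b <- ifelse(m == n, c1, round(c1 * n / pmax(m, 1)))
  bf <- pmin(b, n - b)
  col <- match(bf, tab$classes)
  col
}

#' Genome-wide CLR outliers
#'
#' Pools CLR values across chromosomes for one population and flags grid
#' points at or above the stated empirical percentile. If every value is
#' identical the grid is degenerate and no outliers are reported.
#'
#' @param grid data.frame from [clrScan()] (possibly rbind-ed over
#'   chromosomes)
#' @param percentile outlier percentile (default 99.99)
#' @return the outlier rows, with the threshold as attribute
#'   `"threshold"` and a `"degenerate"` flag.
#' @export
findClrOutliers <- function(grid, percentile = 99.99) {
  if (nrow(grid) < 1e4)
    warning("fewer than 10,000 grid points; the ", percentile,
            "th percentile is coarse")
  v <- grid$clr
  if (max(v) == min(v)) {
    out <- grid[0, ]
    attr(out, "degenerate") <- TRUE
    attr(out, "threshold") <- max(v)
    return(out)
  }
  thr <- stats::quantile(v, percentile / 100, names = FALSE)
  out <- grid[v >= thr, ]
  attr(out, "degenerate") <- FALSE
  attr(out, "threshold") <- thr
  out
}

#' Refine a sweep region around an outlier grid point
#'
#' Re-runs the CLR scan on the outlier's chromosome at fine (1 kb)
#' spacing and delineates the sweep region as the maximal run of
#' consecutive fine windows containing the outlier whose CLR reaches the
#' chromosome's `region_percentile` fine-grid percentile. An outlier
#' that is not elevated on the fine grid yields an empty region.
#'
#' @param gm,samples,sfs,alphas,chrom_lengths as in [clrScan()]
#' @param chrom chromosome of the outlier
#' @param outlier_pos outlier grid position (bp)
#' @param fine_bp fine grid spacing (default 1000)
#' @param region_percentile run-elevation percentile (default 99)
#' @param population optional population label carried into the result
#' @return one-row data.frame: population, chrom, focal_pos, start, end,
#'   peak_clr, threshold, n_windows (0 for an empty region).
#' @export
refineSweepRegion <- function(gm, samples = NULL, chrom, outlier_pos,
                              fine_bp = 1000, region_percentile = 99,
                              sfs = NULL, alphas = defaultAlphaLadder(),
                              chrom_lengths = NULL, population = NA_character_) {
  fine <- clrScan(gm, samples, chroms = chrom, grid_bp = fine_bp,
                  sfs = sfs, alphas = alphas, chrom_lengths = chrom_lengths)
  thr <- stats::quantile(fine$clr, region_percentile / 100, names = FALSE)
  focal <- which.min(abs(fine$pos - outlier_pos))
  above <- fine$clr >= thr
  if (!above[focal]) {
    message("outlier at ", outlier_pos, " on chromosome ", chrom,
            " is not elevated on the fine grid; empty region")
    return(data.frame(population = population, chrom = chrom,
                      focal_pos = outlier_pos, start = NA_real_,
                      end = NA_real_, peak_clr = fine$clr[focal],
                      threshold = thr, n_windows = 0L))
  }
  lo <- focal; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- focal; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  half <- fine_bp / 2
  data.frame(population = population, chrom = chrom,
             focal_pos = outlier_pos,
             start = fine$pos[lo] - half, end = fine$pos[hi] + half,
             peak_clr = max(fine$clr[lo:hi]), threshold = thr,
             n_windows = hi - lo + 1L)
}

## ---- omega statistic ------------------------------------------------------

#' Omega-statistic LD sweep scan (autosomes)
#'
#' Within each evaluation window the SNPs are split into a left and a
#' right block around every possible split point; omega is the ratio of
#' the average within-block r-squared to the average between-block
#' r-squared, maximised over splits and over block extents (blocks span
#' at most `maxwin` bp each and the two blocks together at least
#' `minwin` bp). A completed sweep leaves high LD within each flank but
#' little between them, so omega spikes at sweep edges. Because the
#' Z-chromosome carries strain-level LD that would flood an LD-based
#' scan with false positives, the scan is restricted to autosomes.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param samples population sample names
#' @param window_bp evaluation window (default 5000)
#' @param minwin,maxwin block extent bounds in bp (defaults 500 / 2500)
#' @param cap reported omega when the between-block r-squared sum is
#'   zero (default 100); such windows are flagged
#' @param chroms chromosome subset (default: autosomes "1".."30")
#' @param max_snps per-window SNP cap; denser windows are evenly thinned
#' @return data.frame: chrom, start, end, omega (NA when fewer than 4
#'   usable SNPs), n_snps, capped.
#' @export
omegaScan <- function(gm, samples = NULL, window_bp = 5000, minwin = 500,
                      maxwin = 2500, cap = 100, chroms = as.character(1:30),
                      max_snps = 60) {
  idx <- resolveSamples(gm, samples)
  gt <- dosages(gm)[, idx, drop = FALSE]
  chrom <- chromOf(gm); pos <- posOf(gm)
  sel <- chrom %in% as.character(chroms)
  if (!any(sel)) stop("no sites on the requested autosomes")
  gt <- gt[sel, , drop = FALSE]; chrom <- chrom[sel]; pos <- pos[sel]
  widx <- windowIndex(pos, window_bp)
  keys <- split(seq_along(pos), paste(chrom, widx))
  tiles <- fullTiling(chrom, pos, window_bp)
  tkey <- paste(tiles$chrom, tiles$widx)
  res <- data.frame(chrom = tiles$chrom, start = tiles$widx * window_bp,
                    end = (tiles$widx + 1) * window_bp, omega = NA_real_,
                    n_snps = 0L, capped = FALSE)
  for (w in seq_len(nrow(res))) {
    rows <- keys[[tkey[w]]]
    if (is.null(rows)) next
    sub <- gt[rows, , drop = FALSE]
    v <- apply(sub, 1, stats::var, na.rm = TRUE)
    rows <- rows[!is.na(v) & v > 0]
    if (length(rows) > max_snps)
      rows <- rows[round(seq(1, length(rows), length.out = max_snps))]
    res$n_snps[w] <- length(rows)
    if (length(rows) < 4) next
    r2 <- suppressWarnings(
      stats::cor(t(gt[rows, , drop = FALSE]),
                 use = "pairwise.complete.obs")^2)
    r2[is.na(r2)] <- 0
    om <- omegaMax(r2, pos[rows], minwin, maxwin)
    if (is.null(om)) next
    if (is.infinite(om)) { res$omega[w] <- cap; res$capped[w] <- TRUE }
    else res$omega[w] <- om
  }
  res
}

## maximise omega over split points and block extents using 2D cumulative
## sums of the r2 matrix; returns Inf when the best split has zero
## between-block sum, NULL when no admissible split exists
omegaMax <- function(r2, pos, minwin, maxwin) {
  W <- nrow(r2)
  cs <- apply(apply(r2, 2, cumsum), 1, cumsum)  # cs[j, i] = sum r2[1:i,1:j]
  bsum <- function(r1, r2_, c1, c2) {           # sum over rows r1:r2_, cols c1:c2
    f <- function(i, j) if (i < 1 || j < 1) 0 else cs[j, i]
    f(r2_, c2) - f(r1 - 1, c2) - f(r2_, c1 - 1) + f(r1 - 1, c1 - 1)
  }
  best <- NULL
  for (l in 2:(W - 2)) {
    for (a in 1:(l - 1)) {
      nL <- l - a + 1
      if (nL < 2 || pos[l] - pos[a] > maxwin) next
      for (b in (l + 2):W) {
        nR <- b - l
        if (nR < 2 || pos[b] - pos[l + 1] > maxwin) next
        if (pos[b] - pos[a] < minwin) next
        SL <- (bsum(a, l, a, l) - nL) / 2
        SR <- (bsum(l + 1, b, l + 1, b) - nR) / 2
        SB <- bsum(l + 1, b, a, l)
        num <- (SL + SR) / (choose(nL, 2) + choose(nR, 2))
        om <- if (SB == 0) Inf else num / (SB / (nL * nR))
        if (is.null(best) || om > best) best <- om
      }
    }
  }
  best
}
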