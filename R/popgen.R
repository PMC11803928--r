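## ---- internal helpers -----------------------------------------------------

## per-site group summaries used by the Weir-Cockerham components
groupSummaries <- function(gt, idx) {
  sub <- gt[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

## full tiling of windows for the chromosomes present in the data
fullTiling <- function(chrom, pos, window_bp) {
  out <- lapply(split(pos, factor(chrom, levels = unique(chrom))), function(p)
    seq(0L, max(windowIndex(p, window_bp))))
  data.frame(chrom = rep(names(out), lengths(out)),
             widx = unlist(out, use.names = FALSE))
}

## aggregate per-site numerators/denominators into windows by ratio of sums
windowRatio <- function(chrom, pos, num, den, window_bp, stat,
                        usable = NULL) {
  if (is.null(usable)) usable <- den > 0
  widx <- windowIndex(pos, window_bp)
  key <- paste(chrom, widx)
  tiles <- fullTiling(chrom, pos, window_bp)
  tkey <- paste(tiles$chrom, tiles$widx)
  sn <- rowsum(ifelse(usable, num, 0), key, reorder = FALSE)
  sd_ <- rowsum(ifelse(usable, den, 0), key, reorder = FALSE)
  cnt <- rowsum(as.numeric(usable), key, reorder = FALSE)
  i <- match(tkey, rownames(sn))
  val <- ifelse(!is.na(i) & sd_[i] > 0, sn[i] / sd_[i], NA_real_)
  data.frame(chrom = tiles$chrom,
             start = tiles$widx * window_bp,
             end = (tiles$widx + 1) * window_bp,
             stat = stat, value = as.numeric(val),
             n_sites = ifelse(is.na(i), 0, as.numeric(cnt[i])))
}

## ---- Weir-Cockerham Fst ---------------------------------------------------

#' Weir-Cockerham Fst between two groups
#'
#' Computes the Weir & Cockerham (1984) variance components at every
#' usable site — a (among populations), b (among individuals within
#' populations), c (within individuals) — from per-group sample sizes,
#' allele frequencies and observed heterozygosities, and reports the
#' per-site estimator theta = a/(a+b+c), windowed weighted estimates
#' (ratio of summed components across the window's sites, not a mean of
#' ratios) and the genome-wide weighted estimate. Hybrid individuals are
#' expected to have been excluded from the two groups upstream.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param groupA,groupB sample names (or indices) of the two populations
#' @param window_bp window width in bp (default 10000); windows tile each
#'   chromosome from position 0, half-open
#' @return list with `sites` (per-site chrom/pos/a/b/c/theta), `windows`
#'   (a window table of weighted theta) and `global` (the weighted
#'   genome-wide theta). Sites where no component is defined are skipped
#'   and counted in `n_skipped`.
#' @export
wcFst <- function(gm, groupA, groupB, window_bp = 10000) {
  gt <- dosages(gm)
  ia <- resolveSamples(gm, groupA); ib <- resolveSamples(gm, groupB)
  A <- groupSummaries(gt, ia); B <- groupSummaries(gt, ib)
  comp <- wcComponents(A$n, A$p, A$h, B$n, B$p, B$h)
  usable <- comp$usable
  theta <- ifelse(usable, comp$a / comp$tot, NA_real_)
  sites <- data.frame(chrom = chromOf(gm), pos = posOf(gm),
                      a = comp$a, b = comp$b, c = comp$c, theta = theta)
  windows <- windowRatio(sites$chrom, sites$pos,
                         ifelse(usable, comp$a, 0),
                         ifelse(usable, comp$tot, 0),
                         window_bp, "wc_fst", usable = usable)
  global <- sum(comp$a[usable]) / sum(comp$tot[usable])
  list(sites = sites, windows = windows, global = global,
       n_skipped = sum(!usable))
}

## vectorised Weir-Cockerham (1984) components for r = 2 populations
wcComponents <- function(nA, pA, hA, nB, pB, hB) {
  ok <- nA >= 2 & nB >= 2
  nt <- nA + nB
  n_bar <- nt / 2
  n_c <- nt - (nA^2 + nB^2) / nt          # (r-1) = 1
  p_bar <- (nA * pA + nB * pB) / nt
  s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / n_bar
  h_bar <- (nA * hA + nB * hB) / nt
  pq <- p_bar * (1 - p_bar)
  a <- (n_bar / n_c) * (s2 - (pq - s2 / 2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (pq - s2 / 2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  tot <- a + b + c_
  usable <- ok & !is.na(tot) & tot != 0
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c_[!ok] <- NA_real_
  list(a = a, b = b, c = c_, tot = tot, usable = usable)
}

## ---- pi and Dxy (invariant-site denominators) -----------------------------

#' Windowed nucleotide diversity
#'
#' Per-site numerator/denominator convention with explicit denominators
#' (the "pixy" convention): with k non-missing diploid genotypes a site
#' contributes diffs = c_ref * c_alt and comps = m(m-1)/2 where m = 2k;
#' window pi = sum(diffs)/sum(comps) over all genotyped sites, so
#' invariant genotyped sites contribute to the denominator only and
#' missing data shrink it honestly.
#'
#' @param gm a [StrainGenotypes-class] object (may include invariant
#'   sites)
#' @param samples population sample names (default: all)
#' @param window_bp window width in bp (default 5000)
#' @return window table (chrom, start, end, stat, value, n_sites);
#'   windows with zero comparisons get a missing value.
#' @export
piWindowed <- function(gm, samples = NULL, window_bp = 5000) {
  gt <- dosages(gm)
  idx <- resolveSamples(gm, samples)
  ac <- alleleCounts(gt, idx)
  diffs <- ac$c1 * (ac$m - ac$c1)
  comps <- ac$m * (ac$m - 1) / 2
  windowRatio(chromOf(gm), posOf(gm), diffs, comps, window_bp, "pi")
}

#' Windowed absolute divergence (Dxy)
#'
#' Between-population average per-site difference including invariant
#' sites: per site diffs = c1A*c0B + c0A*c1B and comps = mA*mB over the
#' observed alleles of each group; window Dxy = sum(diffs)/sum(comps).
#' Sites with more than `site_missing_max` missing genotypes (over the
#' two groups' samples) are removed before computation.
#'
#' @param gm a [StrainGenotypes-class] object with invariant sites
#' @param groupA,groupB sample names of the two populations
#' @param window_bp window width (default 10000)
#' @param site_missing_max maximum per-site missing fraction (default 0.2)
#' @return window table as in [piWindowed()].
#' @export
dxyWindowed <- function(gm, groupA, groupB, window_bp = 10000,
                        site_missing_max = 0.2) {
  gt <- dosages(gm)
  ia <- resolveSamples(gm, groupA); ib <- resolveSamples(gm, groupB)
  miss <- rowMeans(is.na(gt[, c(ia, ib), drop = FALSE]))
  A <- alleleCounts(gt, ia); B <- alleleCounts(gt, ib)
  diffs <- A$c1 * (B$m - B$c1) + (A$m - A$c1) * B$c1
  comps <- A$m * B$m
  usable <- miss <= site_missing_max & comps > 0
  windowRatio(chromOf(gm), posOf(gm), diffs, comps, window_bp, "dxy",
              usable = usable)
}

## ---- Tajima's D -----------------------------------------------------------

tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D per window:
#' D = (pi_hat - S/a1) / sqrt(e1*S + e2*S*(S-1)), with pi_hat the average
#' number of pairwise differences summed over the window's segregating
#' sites and the constants evaluated at the window's effective sample
#' size — the median number of observed alleles across its segregating
#' sites (missing data make the allele number site-specific). Windows
#' with no segregating site, fewer than 4 effective alleles, or a
#' non-positive variance are reported missing.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param samples population sample names (default: all)
#' @param window_bp window width (default 5000)
#' @return window table (chrom, start, end, stat, value, n_sites), with
#'   n_sites the number of segregating sites.
#' @export
tajimasDWindowed <- function(gm, samples = NULL, window_bp = 5000) {
  gt <- dosages(gm)
  idx <- resolveSamples(gm, samples)
  ac <- alleleCounts(gt, idx)
  seg <- ac$c1 > 0 & ac$c1 < ac$m
  pi_site <- ifelse(ac$m > 1, ac$c1 * (ac$m - ac$c1) / (ac$m * (ac$m - 1) / 2), 0)
  chrom <- chromOf(gm); pos <- posOf(gm)
  widx <- windowIndex(pos, window_bp)
  key <- paste(chrom, widx)
  tiles <- fullTiling(chrom, pos, window_bp)
  tkey <- paste(tiles$chrom, tiles$widx)
  segn <- rowsum(as.numeric(seg), key, reorder = FALSE)
  pisum <- rowsum(ifelse(seg, pi_site, 0), key, reorder = FALSE)
  m_med <- vapply(split(ifelse(seg, ac$m, NA_real_), key)[rownames(segn)],
                  function(v) stats::median(v, na.rm = TRUE), numeric(1))
  i <- match(tkey, rownames(segn))
  val <- rep(NA_real_, length(i))
  for (w in seq_along(i)) {
    if (is.na(i[w])) next
    S <- segn[i[w]]
    n_eff <- round(m_med[i[w]])
    if (S < 1 || is.na(n_eff) || n_eff < 4) next
    k <- tajimaConstants(n_eff)
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v <= 0) next
    val[w] <- (pisum[i[w]] - S / k$a1) / sqrt(v)
  }
  data.frame(chrom = tiles$chrom, start = tiles$widx * window_bp,
             end = (tiles$widx + 1) * window_bp, stat = "tajimas_d",
             value = val,
             n_sites = ifelse(is.na(i), 0, as.numeric(segn[i])))
}

## ---- linkage disequilibrium -----------------------------------------------

#' Squared dosage correlation between two sites
#'
#' Composite (genotype-dosage) r-squared with pairwise deletion of
#' missing genotypes; returns NA when either site is monomorphic among
#' the jointly observed samples.
#'
#' @param x,y dosage vectors
#' @return squared Pearson correlation, or NA.
#' @export
pairR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay across fixed distance bins
#'
#' Mean and median genotype-dosage r-squared for site pairs whose
#' separation falls within +/- `tol` bp of each nominal distance — by
#' default the eleven intervals 100, 250, 500, 1000, 2500, 5000, 7500,
#' 10000, 25000, 50000 and 75000 bp with a +/- 50 bp tolerance. Pairs
#' with a monomorphic member are skipped.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param samples population sample names (default: all)
#' @param distances nominal distances in bp
#' @param tol half-width of each bin in bp (default 50)
#' @param chroms optional chromosome subset
#' @param max_pairs_per_bin optional cap on pairs per bin (seeded
#'   subsample) to bound compute on dense data; default Inf
#' @return data.frame: distance, mean_r2, median_r2, n_pairs.
#' @export
ldDecay <- function(gm, samples = NULL,
                    distances = c(100, 250, 500, 1000, 2500, 5000, 7500,
                                  10000, 25000, 50000, 75000),
                    tol = 50, chroms = NULL, max_pairs_per_bin = Inf) {
  idx <- resolveSamples(gm, samples)
  gt <- dosages(gm)[, idx, drop = FALSE]
  chrom <- chromOf(gm); pos <- posOf(gm)
  if (!is.null(chroms)) {
    sel <- chrom %in% as.character(chroms)
    gt <- gt[sel, , drop = FALSE]; chrom <- chrom[sel]; pos <- pos[sel]
  }
  out <- lapply(distances, function(d) {
    pi_ <- integer(0); pj_ <- integer(0)
    for (ch in unique(chrom)) {
      w <- which(chrom == ch)
      p <- pos[w]
      lo <- findInterval(p + d - tol - 0.5, p) + 1L
      hi <- findInterval(p + d + tol + 0.5, p)
      has <- hi >= lo
      if (!any(has)) next
      reps <- hi[has] - lo[has] + 1L
      pi_ <- c(pi_, rep(w[has], reps))
      pj_ <- c(pj_, w[unlist(Map(seq, lo[has], hi[has]))])
    }
    if (length(pi_) > max_pairs_per_bin) {
      keep <- sample.int(length(pi_), max_pairs_per_bin)
      pi_ <- pi_[keep]; pj_ <- pj_[keep]
    }
    r2 <- vapply(seq_along(pi_),
                 function(k) pairR2(gt[pi_[k], ], gt[pj_[k], ]), numeric(1))
    r2 <- r2[!is.na(r2)]
    data.frame(distance = d,
               mean_r2 = if (length(r2)) mean(r2) else NA_real_,
               median_r2 = if (length(r2)) stats::median(r2) else NA_real_,
               n_pairs = length(r2))
  })
  do.call(rbind, out)
}
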