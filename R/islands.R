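#' Gaussian kernel smoothing of windowed values
#'
#' Nadaraya-Watson estimate with a Gaussian kernel,
#' s(x) = sum_i K((x - x_i)/h) v_i / sum_i K((x - x_i)/h), evaluated at
#' the input positions themselves (window midpoints). Missing values are
#' skipped with weight zero.
#'
#' @param positions strictly increasing positions (bp)
#' @param values values at those positions (NA allowed)
#' @param bandwidth Gaussian kernel bandwidth h in bp (> 0)
#' @param eval_at positions at which to evaluate (default: `positions`)
#' @return numeric vector of smoothed values at `eval_at`.
#' @export
kernelSmooth <- function(positions, values, bandwidth, eval_at = positions) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (all(is.na(values))) stop("all values are missing")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  ok <- !is.na(values)
  K <- stats::dnorm(outer(eval_at, positions[ok], "-") / bandwidth)
  drop(K %*% values[ok]) / rowSums(K)
}

#' Permutation test for genomic islands of divergence
#'
#' Smooths windowed Dxy values along one chromosome, then permutes the
#' order of the values over the same positions `n_perm` times, smooths
#' each permutation identically, and takes the threshold as the single
#' most extreme smoothed value over every position of every permutation
#' (a family-wise max-null). Islands are the maximal runs of windows
#' whose observed smoothed value exceeds that threshold.
#'
#' @param windows window table for one chromosome (columns chrom, start,
#'   end, value), e.g. from [dxyWindowed()]
#' @param n_perm number of order permutations (default 10000)
#' @param bandwidth Gaussian bandwidth in bp (default 50000)
#' @param seed RNG seed
#' @return list: `threshold`, `islands` (chrom, start, end, peak),
#'   `smoothed` (per-window midpoint and smoothed value), `n_perm`,
#'   `seed`.
#' @export
islandScan <- function(windows, n_perm = 10000, bandwidth = 50000,
                       seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (length(unique(windows$chrom)) != 1)
    stop("island scanning is per-chromosome; got multiple chromosomes")
  keep <- !is.na(windows$value)
  if (sum(keep) < 20)
    stop("need at least 20 windows with values")
  w <- windows[keep, ]
  mid <- (w$start + w$end) / 2
  obs <- kernelSmooth(mid, w$value, bandwidth)
  set.seed(seed)
  n <- nrow(w)
  K <- stats::dnorm(outer(mid, mid, "-") / bandwidth)
  K <- K / rowSums(K)
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- w$value[sample.int(n)]
  threshold <- max(K %*% perm)
  above <- obs > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  isl <- which(runs$values)
  islands <- data.frame(
    chrom = rep(w$chrom[1], length(isl)),
    start = w$start[starts[isl]], end = w$end[ends[isl]],
    peak = vapply(isl, function(k)
      max(obs[starts[k]:ends[k]]), numeric(1)))
  list(threshold = threshold, islands = islands,
       smoothed = data.frame(chrom = w$chrom, mid = mid, observed = obs),
       n_perm = n_perm, seed = seed)
}
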