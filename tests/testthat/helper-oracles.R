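## Shared fixtures and independent oracles. The oracles are deliberately
## written as slow per-site scalar arithmetic / exhaustive enumeration,
## a different code path from the package's vectorised implementations.

makeGm <- function(gt, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                   dp = NULL, gq = NULL, sample_data = NULL) {
  gt <- as.matrix(gt)
  if (is.null(chrom)) chrom <- rep("1", nrow(gt))
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 100L
  StrainGenotypes(gt, chrom, pos, ref = ref, alt = alt, dp = dp, gq = gq,
                  sample_data = sample_data)
}

## expand a dosage vector into its multiset of alleles (0/1), dropping NA
allelesOf <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2L - x))))
}

## Weir & Cockerham (1984) theta at one site, longhand from the paper's
## two-population formulas (r = 2)
oracleWcSite <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  if (n1 < 2 || n2 < 2) return(NULL)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- (n1 + n2) / r
  CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / (r * nbar^2)
  nc <- nbar * (1 - CV2)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

## weighted Fst by ratio of summed components over all sites
oracleWcWeighted <- function(gtA, gtB) {
  num <- den <- 0
  for (s in seq_len(nrow(gtA))) {
    comp <- oracleWcSite(gtA[s, ], gtB[s, ])
    if (is.null(comp)) next
    tot <- comp$a + comp$b + comp$c
    if (is.na(tot) || tot == 0) next
    num <- num + comp$a
    den <- den + tot
  }
  num / den
}

## pi by exhaustive enumeration of allele pairs within each site
oraclePi <- function(gt) {
  diffs <- comps <- 0
  for (s in seq_len(nrow(gt))) {
    al <- allelesOf(gt[s, ])
    m <- length(al)
    if (m < 2) next
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      comps <- comps + 1
      if (al[i] != al[j]) diffs <- diffs + 1
    }
  }
  diffs / comps
}

## Dxy by exhaustive enumeration of cross-population allele pairs
oracleDxy <- function(gtA, gtB) {
  diffs <- comps <- 0
  for (s in seq_len(nrow(gtA))) {
    aA <- allelesOf(gtA[s, ]); aB <- allelesOf(gtB[s, ])
    for (x in aA) for (y in aB) {
      comps <- comps + 1
      if (x != y) diffs <- diffs + 1
    }
  }
  if (comps == 0) NA_real_ else diffs / comps
}

## Tajima's D from first principles for a set of sites sharing one
## sample size (no missing data)
oracleTajimaD <- function(gt) {
  n <- 2 * ncol(gt)
  counts <- rowSums(gt)
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pihat <- 0
  for (s in which(seg)) {
    al <- allelesOf(gt[s, ])
    k <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (al[i] != al[j]) k <- k + 1
    pihat <- pihat + k / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracleR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy^2 / (sxx * syy)
}

## omega by brute-force nested enumeration of split points and extents
oracleOmega <- function(gt, pos, minwin, maxwin) {
  W <- nrow(gt)
  r2 <- matrix(0, W, W)
  for (i in seq_len(W)) for (j in seq_len(W)) {
    v <- oracleR2(gt[i, ], gt[j, ])
    r2[i, j] <- if (is.na(v)) 0 else v
  }
  best <- NULL
  for (l in 2:(W - 2)) for (a in 1:(l - 1)) for (b in (l + 2):W) {
    nL <- l - a + 1; nR <- b - l
    if (nL < 2 || nR < 2) next
    if (pos[l] - pos[a] > maxwin || pos[b] - pos[l + 1] > maxwin) next
    if (pos[b] - pos[a] < minwin) next
    SL <- SR <- SB <- 0
    for (i in a:l) for (j in a:l) if (i < j) SL <- SL + r2[i, j]
    for (i in (l + 1):b) for (j in (l + 1):b) if (i < j) SR <- SR + r2[i, j]
    for (i in a:l) for (j in (l + 1):b) SB <- SB + r2[i, j]
    num <- (SL + SR) / (choose(nL, 2) + choose(nR, 2))
    om <- if (SB == 0) Inf else num / (SB / (nL * nR))
    if (is.null(best) || om > best) best <- om
  }
  best
}

## small random dosage matrix with optional missingness
randomGm <- function(n_site, n_sample, miss = 0, seed = 1) {
  set.seed(seed)
  gt <- matrix(sample(0:2, n_site * n_sample, TRUE,
                      prob = c(0.45, 0.35, 0.2)), n_site)
  if (miss > 0) gt[runif(length(gt)) < miss] <- NA_integer_
  gt
}
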