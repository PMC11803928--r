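test_that("Weir-Cockerham Fst matches its defining cases and the longhand formulas", {
  ## fixed difference: theta = 1 at the site
  gA <- matrix(0L, 1, 10); gB <- matrix(2L, 1, 10)
  gm <- makeGm(cbind(gA, gB) * 1L)
  f <- wcFst(gm, 1:10, 11:20)
  expect_equal(f$sites$theta, 1)
  ## identical genotype counts in both groups: theta <= 0
  g <- c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
  f2 <- wcFst(makeGm(matrix(c(g, g), 1)), 1:10, 11:20)
  expect_lte(f2$sites$theta, 0)
  ## the spec'd worked example against longhand 1984 arithmetic
  gA3 <- c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
  gB3 <- c(rep(0L, 8), rep(1L, 2))
  f3 <- wcFst(makeGm(matrix(c(gA3, gB3), 1)), 1:10, 11:20)
  o <- oracleWcSite(gA3, gB3)
  expect_equal(f3$sites$theta, o$theta, tolerance = 1e-12)
  expect_equal(f3$sites$a, o$a, tolerance = 1e-12)
})

test_that("per-site theta and weighted Fst agree with the oracle on random matrices", {
  for (seed in 1:4) {
    gt <- randomGm(25, 12, miss = if (seed %% 2) 0.15 else 0, seed = seed)
    gm <- makeGm(gt)
    f <- wcFst(gm, 1:6, 7:12)
    expect_equal(f$global, oracleWcWeighted(gt[, 1:6], gt[, 7:12]),
                 tolerance = 1e-10)
    for (s in c(1, 13, 25)) {
      o <- oracleWcSite(gt[s, 1:6], gt[s, 7:12])
      if (is.null(o) || (o$a + o$b + o$c) == 0) next
      expect_equal(f$sites$theta[s], o$theta, tolerance = 1e-10)
    }
  }
})

test_that("weighted Fst is a ratio of sums: window-associative", {
  gt <- randomGm(60, 10, miss = 0.1, seed = 5)
  gm <- makeGm(gt, pos = seq_len(60) * 400L)  # spans several 10 kb windows
  f <- wcFst(gm, 1:5, 6:10, window_bp = 10000)
  w <- f$windows[!is.na(f$windows$value), ]
  ## reconstruct the global ratio from per-window numerators
  usable <- !is.na(f$sites$theta)
  tot <- f$sites$a + f$sites$b + f$sites$c
  num <- sum(f$sites$a[usable & tot != 0])
  den <- sum(tot[usable & tot != 0])
  expect_equal(f$global, num / den, tolerance = 1e-12)
  ## and each window is itself the ratio over its own sites
  wi <- (siteInfo(gm)$pos - 1) %/% 10000
  for (k in unique(wi)) {
    sel <- wi == k & usable & tot != 0
    if (!any(sel)) next
    expect_equal(w$value[w$start == k * 10000],
                 sum(f$sites$a[sel]) / sum(tot[sel]), tolerance = 1e-12)
  }
})

test_that("pi follows the explicit-denominator convention", {
  ## monomorphic window: pi = 0
  p0 <- piWindowed(makeGm(matrix(0L, 5, 4)), window_bp = 1000)
  expect_equal(p0$value, 0)
  ## one site, allele counts 2/2 (two het diploids, m=4): pi = 2/3
  p1 <- piWindowed(makeGm(matrix(c(1L, 1L), 1)), window_bp = 1000)
  expect_equal(p1$value, 2 / 3)
  ## plus 999 invariant genotyped sites: window pi = 4/6000
  gt <- rbind(c(1L, 1L), matrix(0L, 999, 2))
  p2 <- piWindowed(makeGm(gt, pos = seq_len(1000)), window_bp = 5000)
  expect_equal(p2$value, 4 / 6000)
  expect_equal(p2$n_sites, 1000)
  ## empty window between sites -> missing value
  gx <- makeGm(matrix(c(0L, 1L), 2, 2), pos = c(100L, 9000L))
  px <- piWindowed(gx, window_bp = 1000)
  expect_true(all(is.na(px$value[2:8])))
})

test_that("pi equals exhaustive pair enumeration on small matrices", {
  for (seed in 1:3) {
    gt <- randomGm(15, 6, miss = 0.2 * (seed == 3), seed = seed + 30)
    pw <- piWindowed(makeGm(gt), window_bp = 10000)  # one window
    expect_equal(pw$value[1], oraclePi(gt), tolerance = 1e-12)
  }
})

test_that("Dxy matches enumeration, is symmetric, and collapses to pooled pi", {
  ## fixed difference -> 1; the 10/16 example (c1A=1/4, c1B=3/4)
  gA <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  gB <- matrix(c(2L, 2L, 1L, 2L), 2, 2, byrow = TRUE)
  gm <- makeGm(cbind(gA, gB))
  d <- dxyWindowed(gm, 1:2, 3:4, window_bp = 1000)
  expect_equal(d$value, oracleDxy(gA, gB))
  d1 <- dxyWindowed(gm[1, ], 1:2, 3:4, window_bp = 1000)
  expect_equal(d1$value, 1)
  d2 <- dxyWindowed(gm[2, ], 1:2, 3:4, window_bp = 1000)
  expect_equal(d2$value, 0.625)  # diffs 1*1 + 3*3 = 10 over 16
  ## symmetry and random-matrix agreement
  for (seed in 4:6) {
    gt <- randomGm(12, 8, miss = 0.1 * (seed == 5), seed = seed)
    gmr <- makeGm(gt)
    ab <- dxyWindowed(gmr, 1:4, 5:8, window_bp = 10000,
                      site_missing_max = 1)$value[1]
    ba <- dxyWindowed(gmr, 5:8, 1:4, window_bp = 10000,
                      site_missing_max = 1)$value[1]
    expect_equal(ab, oracleDxy(gt[, 1:4], gt[, 5:8]), tolerance = 1e-12)
    expect_equal(ab, ba)
    expect_true(ab >= 0 && ab <= 1)
  }
  ## equal allele frequencies, no missing: Dxy = pi of the pooled sample
  ## (identical haplotype pools, here via duplicated groups)
  gt <- randomGm(10, 4, seed = 9)
  both <- cbind(gt, gt)
  gmp <- makeGm(both)
  dv <- dxyWindowed(gmp, 1:4, 5:8, window_bp = 10000)$value[1]
  ## pooled pi over the doubled sample differs only through the
  ## m(m-1)/2 vs mA*mB denominators; compare to the allele-frequency form
  ac_p <- rowSums(gt) / 8
  expect_equal(dv, sum(2 * ac_p * (1 - ac_p) * 16) / (10 * 16),
               tolerance = 1e-12)
})

test_that("the >20% missing rule removes sites from Dxy", {
  gt <- rbind(c(0L, 0L, 2L, 2L),          # complete, fixed difference
              c(0L, NA, 2L, 2L))          # 25% missing -> excluded
  d <- dxyWindowed(makeGm(gt), 1:2, 3:4, window_bp = 1000,
                   site_missing_max = 0.2)
  expect_equal(d$n_sites, 1)
  expect_equal(d$value, 1)
})

test_that("Tajima's D reproduces the n=4 worked example and the oracle", {
  ## 2 diploids = 4 haplotypes; derived counts {1, 2}
  gt <- rbind(c(1L, 0L), c(1L, 1L))
  td <- tajimasDWindowed(makeGm(gt), window_bp = 1000)
  expect_equal(td$value, oracleTajimaD(gt), tolerance = 1e-12)
  expect_equal(td$value, 0.59158, tolerance = 1e-4)
  ## no segregating site -> missing
  t0 <- tajimasDWindowed(makeGm(matrix(0L, 4, 4)), window_bp = 1000)
  expect_true(is.na(t0$value))
  ## random small matrices, no missing data
  for (seed in 7:9) {
    gt <- randomGm(20, 5, seed = seed)
    td <- tajimasDWindowed(makeGm(gt), window_bp = 10000)
    expect_equal(td$value[1], oracleTajimaD(gt), tolerance = 1e-10)
  }
})

test_that("r2 matches direct Pearson arithmetic and handles degeneracy", {
  expect_equal(pairR2(c(0, 1, 2, 2), c(0, 1, 1, 2)), 4 / 5.5,
               tolerance = 1e-12)
  ## duplicated site -> r2 = 1
  expect_equal(pairR2(c(0, 1, 2), c(0, 1, 2)), 1)
  ## monomorphic member -> NA
  expect_true(is.na(pairR2(c(1, 1, 1), c(0, 1, 2))))
  for (seed in 1:3) {
    x <- sample(0:2, 8, TRUE); y <- sample(0:2, 8, TRUE)
    expect_equal(pairR2(x, y), oracleR2(x, y), tolerance = 1e-12)
  }
})

test_that("LD decay bins pairs by distance with the +/-50 bp tolerance", {
  ## sites at 0/100/151 bp offsets: (1,2) at 100 in-bin, (1,3) at 151 out
  gt <- rbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 1L, 2L), c(2L, 1L, 0L, 1L))
  gm <- makeGm(gt, pos = c(1000L, 1100L, 1151L))
  ld <- ldDecay(gm, distances = 100, tol = 50)
  expect_equal(ld$n_pairs, 2L)   # (1,2) d=100 and (2,3) d=51
  ## duplicated site at distance 100 gives r2 = 1
  gm2 <- makeGm(rbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 2L, 2L)),
                pos = c(500L, 600L))
  ld2 <- ldDecay(gm2, distances = 100)
  expect_equal(ld2$mean_r2, 1)
  ## independent sites: bin means near E[r2] ~ 1/n
  cfg <- simConfig(n_samples_per_group = 40, n_sites_per_chrom = 500,
                   chrom_lengths = c(rep(5e5, 30), 1e6),
                   fst_autosome = 0, fst_z = 0, fst_subpop = 0,
                   hybrid_fraction = 0, missing_rate = 0, seed = 8)
  sim <- simulateCohort(cfg, chroms = 1, degrade = FALSE)
  ld3 <- ldDecay(sim$genotypes, distances = c(1000, 10000), tol = 500)
  expect_gt(min(ld3$n_pairs), 50)
  expect_lt(max(ld3$mean_r2), 3 / 80)  # well under 3x the 1/n scale
})
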