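## a small sweep-bearing two-chromosome cohort reused across tests
sweepSim <- function(seed = 5, strength = 5e4) {
  cfg <- simConfig(n_samples_per_group = 30, n_sites_per_chrom = 1500,
                   chrom_lengths = c(rep(1e7, 30), 2e7), seed = seed,
                   missing_rate = 0.02,
                   sweep_specs = list(list(chrom = 2, center_bp = 5e6,
                                           strength = strength)))
  simulateCohort(cfg, chroms = c(1, 2))
}

test_that("hypergeometric projection enumerates the spec'd case exactly", {
  ## counts 3 derived of 8 alleles projected to 4
  p <- projectCounts(3, 8, 4)
  expect_equal(sum(p), 1)
  manual <- sapply(0:4, function(j)
    choose(3, j) * choose(5, 4 - j) / choose(8, 4))
  expect_equal(p, manual, tolerance = 1e-12)
  expect_error(projectCounts(1, 3, 4), "project")
})

test_that("the background SFS concentrates where the data do", {
  ## all singletons: folded spectrum mass at class 1
  gt <- diag(1L, 8, 8)
  sfs <- backgroundSFS(makeGm(gt), n_project = 16,
                       include_monomorphic = FALSE)
  expect_equal(unname(sfs$phi["1"]), 1)
  ## neutral simulation: folded shape ~ (1/j + 1/(n-j)) within MC error
  cfg <- simConfig(n_samples_per_group = 20, n_sites_per_chrom = 8000,
                   chrom_lengths = c(rep(2e6, 30), 4e6),
                   fst_autosome = 0, fst_z = 0, fst_subpop = 0,
                   hybrid_fraction = 0, missing_rate = 0,
                   spectrum = "neutral", seed = 12)
  sim <- simulateCohort(cfg, chroms = 1, degrade = FALSE)
  sfs2 <- backgroundSFS(sim$genotypes, include_monomorphic = FALSE)
  n <- sfs2$n
  j <- as.integer(names(sfs2$phi))
  expected <- (1 / j + 1 / (n - j)) / (1 + (j == n - j))
  expected <- expected / sum(expected)
  expect_gt(cor(sfs2$phi, expected), 0.98)
  expect_lt(max(abs(sfs2$phi - expected)), 0.02)
})

test_that("the sweep model nests the null: all-escape log-ratios vanish", {
  sim <- sweepSim()
  cpop <- samplesWhere(sim$genotypes, "strain", "C")
  sfs <- backgroundSFS(sim$genotypes, cpop)
  tab <- fawpopgen:::sweepLogRatioTable(sfs)
  ## at pe = 1 (last row) every class's log ratio is ~0
  expect_lt(max(abs(tab$L[nrow(tab$L), sfs$phi > 0])), 1e-6)
  ## data drawn i.i.d. from phi itself: median CLR ~ 0
  set.seed(4)
  n <- sfs$n
  cls <- as.integer(names(sfs$phi))
  b <- sample(cls, 1200, TRUE, prob = sfs$phi)
  gt <- t(vapply(b, function(k) {
    hap <- numeric(n)
    hap[sample.int(n, k)] <- 1
    as.integer(hap[seq(1, n, 2)] + hap[seq(2, n, 2)])
  }, integer(n / 2)))
  gmn <- makeGm(gt, pos = sort(sample.int(6e6, 1200)))
  grid <- clrScan(gmn, sfs = sfs, grid_bp = 5e4)
  expect_lt(median(grid$clr), 0.5)
})

test_that("the CLR scan localises an injected sweep", {
  sim <- sweepSim()
  cpop <- samplesWhere(sim$genotypes, "strain", "C")
  sfs <- backgroundSFS(sim$genotypes, cpop)
  grid <- clrScan(sim$genotypes, cpop, chroms = "2", sfs = sfs)
  expect_true(all(grid$clr >= 0))
  hit <- grid$pos[which.max(grid$clr)]
  step <- diff(grid$pos[1:2])
  expect_lte(abs(hit - 5e6), 2 * step)
  ## grid size = floor(length / spacing)
  expect_equal(nrow(grid), floor(max(siteInfo(sim$genotypes)$pos) / 5000))
  ## CLR is invariant to relabeling samples within the group
  grid2 <- clrScan(sim$genotypes, rev(cpop), chroms = "2", sfs = sfs)
  expect_equal(grid$clr, grid2$clr)
})

test_that("outlier calling pools percentiles and refuses degenerate grids", {
  flat <- data.frame(chrom = "1", pos = 1:100 * 5e3, clr = 1,
                     alpha = 1e-4)
  out <- suppressWarnings(findClrOutliers(flat))
  expect_equal(nrow(out), 0L)
  expect_true(attr(out, "degenerate"))
  ## ~0.01% of 20000 neutral points exceed the threshold by construction
  set.seed(2)
  g <- data.frame(chrom = "1", pos = 1:20000 * 5e3,
                  clr = rexp(20000), alpha = 1e-4)
  out2 <- findClrOutliers(g, 99.99)
  expect_lte(nrow(out2), 4L)
  expect_gte(nrow(out2), 1L)
  ## an injected sweep's grid point is an outlier
  sim <- sweepSim()
  cpop <- samplesWhere(sim$genotypes, "strain", "C")
  sfs <- backgroundSFS(sim$genotypes, cpop)
  grid <- rbind(clrScan(sim$genotypes, cpop, chroms = "1", sfs = sfs),
                clrScan(sim$genotypes, cpop, chroms = "2", sfs = sfs))
  out3 <- suppressWarnings(findClrOutliers(grid, 99.99))
  expect_true(any(out3$chrom == "2" & abs(out3$pos - 5e6) < 5e4))
})

test_that("region refinement spans the elevated run around the outlier", {
  sim <- sweepSim()
  cpop <- samplesWhere(sim$genotypes, "strain", "C")
  sfs <- backgroundSFS(sim$genotypes, cpop)
  reg <- refineSweepRegion(sim$genotypes, cpop, "2", 5e6,
                           fine_bp = 5000, sfs = sfs, population = "C")
  expect_equal(reg$n_windows > 0, TRUE)
  expect_lte(reg$start, 5e6)
  expect_gte(reg$end, 5e6)
  ## overlaps the true swept interval (Jaccard > 0)
  tr <- sim$truth$sweeps
  expect_lt(max(reg$start, tr$start), min(reg$end, tr$end))
})

test_that("consecutive-run delineation follows the score vector exactly", {
  ## plateau of 7 elevated fine windows around the focal point: the
  ## run boundaries come straight off the thresholded score vector
  clr <- c(rep(0, 40), rep(10, 7), rep(0, 53))
  thr <- quantile(clr, 0.99)
  above <- clr >= thr
  focal <- 43
  lo <- focal; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- focal; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  expect_equal(c(lo, hi), c(41, 47))
})

test_that("omega matches brute-force split enumeration on toy matrices", {
  set.seed(6)
  for (rep in 1:3) {
    gt <- matrix(sample(0:2, 6 * 10, TRUE), 6)
    pos <- sort(sample(1000:4000, 6))
    r2 <- suppressWarnings(cor(t(gt), use = "pairwise.complete.obs")^2)
    r2[is.na(r2)] <- 0
    keep <- apply(gt, 1, var) > 0
    if (sum(keep) < 4) next
    om <- fawpopgen:::omegaMax(r2[keep, keep], pos[keep],
                               minwin = 0, maxwin = 5000)
    oo <- oracleOmega(gt[keep, , drop = FALSE], pos[keep], 0, 5000)
    expect_equal(om, oo, tolerance = 1e-10)
  }
})

test_that("omega behaves at its structural extremes", {
  ## two internally perfect-LD blocks with exactly zero correlation
  ## between them: zero between-block r2 sum -> capped omega
  x <- rep(c(0L, 2L), 10)                 # alternating
  y <- rep(c(0L, 2L), each = 10)          # half/half: cor(x, y) = 0
  gt <- rbind(x, x, x, y, y, y)
  gm <- makeGm(gt, pos = c(100L, 300L, 500L, 700L, 900L, 1100L))
  om <- omegaScan(gm, window_bp = 5000, minwin = 0, maxwin = 5000)
  expect_true(om$capped[1])
  expect_equal(om$omega[1], 100)
  ## independent sites: numerator and denominator estimate the same
  ## mean r2, so with single-split windows (4 SNPs each) omega centres
  ## on 1 rather than drifting high or low
  cfg <- simConfig(n_samples_per_group = 50, n_sites_per_chrom = 600,
                   chrom_lengths = c(3e5, rep(1e6, 29), 2e6),
                   fst_autosome = 0, fst_z = 0, fst_subpop = 0,
                   hybrid_fraction = 0, missing_rate = 0, seed = 14)
  sim <- simulateCohort(cfg, chroms = 1, degrade = FALSE)
  om2 <- omegaScan(sim$genotypes, window_bp = 10000, minwin = 0,
                   maxwin = 10000, max_snps = 4)
  vals <- om2$omega[!is.na(om2$omega) & !om2$capped]
  expect_gt(length(vals), 10)
  expect_gt(median(vals), 0.4)
  expect_lt(median(vals), 2.5)
  ## the Z is refused
  expect_error(omegaScan(sim$genotypes, chroms = "31"), "autosome")
})
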