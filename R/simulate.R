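#' Create a simulation configuration
#'
#' Defaults describe the study system: two strains at genome-wide
#' Balding-Nichols differentiation F = 0.086 on the autosomes and
#' F = 0.671 on the Z (chromosome 31), C-strain flyway sub-structure at
#' F = 0.047, a small F1-like hybrid fraction, four fixed-difference
#' diagnostic markers on the Z, and per-genotype DP/GQ noise.
#'
#' @param n_samples_per_group diploid samples per strain (default 100)
#' @param chrom_lengths bp lengths of chromosomes 1..31 (31 = Z)
#' @param n_sites_per_chrom sites per chromosome
#' @param fst_autosome,fst_z,fst_subpop Balding-Nichols F parameters
#' @param hybrid_fraction F1 hybrids added, as a fraction of the two-strain
#'   total
#' @param n_subpops_c C-strain subpopulations (flyways)
#' @param n_markers diagnostic markers forced to fixed differences on the Z
#' @param missing_rate,depth_mean,gq_mean,gq_sd genotype noise model
#' @param spectrum "uniform" or "neutral" ancestral frequency model
#' @param sweep_specs list of `list(chrom, center_bp, strength)` entries
#' @param seed integer seed; fully determines the cohort
#' @return A validated [SimConfig-class] object.
#' @export
simConfig <- function(n_samples_per_group = 100,
                      chrom_lengths = c(rep(12.5e6, 30), 21.8e6),
                      n_sites_per_chrom = 2000,
                      fst_autosome = 0.086, fst_z = 0.671,
                      fst_subpop = 0.047, hybrid_fraction = 0.02,
                      n_subpops_c = 3, n_markers = 4,
                      missing_rate = 0.05, depth_mean = 100,
                      gq_mean = 60, gq_sd = 15,
                      spectrum = c("uniform", "neutral"),
                      sweep_specs = list(), seed = 1L) {
  new("SimConfig",
      n_samples_per_group = n_samples_per_group,
      chrom_lengths = chrom_lengths,
      n_sites_per_chrom = n_sites_per_chrom,
      fst_autosome = fst_autosome, fst_z = fst_z, fst_subpop = fst_subpop,
      hybrid_fraction = hybrid_fraction, n_subpops_c = n_subpops_c,
      n_markers = n_markers, missing_rate = missing_rate,
      depth_mean = depth_mean, gq_mean = gq_mean, gq_sd = gq_sd,
      spectrum = match.arg(spectrum), sweep_specs = sweep_specs,
      seed = seed)
}

## Balding-Nichols draw of a daughter frequency around p with parameter F
bnDraw <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a two-strain cohort
#'
#' Draws per-site ancestral frequencies, differentiates the two strains
#' under the Balding-Nichols model (Z-linked F on chromosome 31, autosomal
#' F elsewhere), adds C-strain subpopulation structure, fixes the
#' diagnostic markers to alternative alleles, samples diploid genotypes
#' binomially, forms hybrids from one haplotype per strain, applies
#' DP/GQ/missingness degradation and injects any configured sweeps.
#'
#' @param config a [SimConfig-class] object
#' @param chroms optional subset of chromosomes (indices into 1..31) to
#'   simulate; defaults to all 31
#' @param degrade apply the DP/GQ/missingness noise model (default TRUE)
#' @return `list(genotypes = StrainGenotypes, truth = list(...))`. The
#'   truth table records each sample's true strain and subpopulation, each
#'   site's ancestral and per-group frequencies, the diagnostic marker
#'   sites and any injected sweep intervals.
#' @export
simulateCohort <- function(config, chroms = NULL, degrade = TRUE) {
  validObject(config)
  if (config@n_sites_per_chrom < 1 || config@n_samples_per_group < 1)
    stop("refusing to simulate zero sites or zero samples")
  if (is.null(chroms)) chroms <- seq_along(config@chrom_lengths)
  set.seed(config@seed)

  n_per <- as.integer(config@n_samples_per_group)
  n_hyb <- round(config@hybrid_fraction * 2 * n_per)
  subpops <- paste0("C.flyway", seq_len(max(1L, as.integer(config@n_subpops_c))))
  samples <- data.frame(
    sample = c(sprintf("C%03d", seq_len(n_per)),
               sprintf("R%03d", seq_len(n_per)),
               if (n_hyb > 0) sprintf("H%03d", seq_len(n_hyb))),
    strain = c(rep("C", n_per), rep("R", n_per), rep("hybrid", n_hyb)),
    subpop = c(rep_len(subpops, n_per), rep("R.pool", n_per),
               rep("hybrid", n_hyb)),
    stringsAsFactors = FALSE)

  n_tot <- nrow(samples)
  c_idx <- which(samples$strain == "C")
  r_idx <- which(samples$strain == "R")
  h_idx <- which(samples$strain == "hybrid")

  gt_list <- list(); site_list <- list(); marker_rows <- list()
  for (ch in chroms) {
    len <- config@chrom_lengths[ch]
    n_site <- as.integer(config@n_sites_per_chrom)
    pos <- sort(sample.int(len, n_site))
    F <- if (ch == 31L) config@fst_z else config@fst_autosome

    neutral_exact <- config@spectrum == "neutral" && F == 0 &&
      config@fst_subpop == 0
    if (neutral_exact) {
      ## per-site minor count j with P(j) proportional to 1/j, alleles
      ## assigned to random haplotypes: E[pi] = E[S]/a1 exactly
      nh <- 2L * n_tot
      j <- sample(seq_len(nh - 1L), n_site, replace = TRUE,
                  prob = 1 / seq_len(nh - 1L))
      gt <- matrix(0L, n_site, n_tot)
      for (s in seq_len(n_site)) {
        hap <- sample.int(nh, j[s])
        gt[s, ] <- tabulate((hap - 1L) %/% 2L + 1L, nbins = n_tot)
      }
      p_anc <- j / nh; pC <- p_anc; pR <- p_anc
    } else {
      p_anc <- if (config@spectrum == "neutral") {
        ## ancestral frequencies with the standard-neutral 1/p density,
        ## truncated away from loss/fixation in the sample
        eps <- 1 / (4 * n_tot)
        exp(stats::runif(n_site, log(eps), log(1 - eps)))
      } else stats::runif(n_site, 0.05, 0.95)
      pC <- bnDraw(p_anc, F)
      pR <- bnDraw(p_anc, F)
      ## C-strain flyway sub-structure around the strain frequency
      pCs <- lapply(subpops, function(s) bnDraw(pC, config@fst_subpop))
      names(pCs) <- subpops

      gt <- matrix(0L, n_site, n_tot)
      for (i in c_idx)
        gt[, i] <- stats::rbinom(n_site, 2L, pCs[[samples$subpop[i]]])
      for (i in r_idx)
        gt[, i] <- stats::rbinom(n_site, 2L, pR)
      ## F1 hybrids: one haplotype from each strain's frequency draw
      for (i in h_idx)
        gt[, i] <- stats::rbinom(n_site, 1L, pC) + stats::rbinom(n_site, 1L, pR)
    }

    ## diagnostic markers: fixed differences on the Z
    if (ch == 31L && config@n_markers > 0) {
      mk <- round(seq(0.2, 0.8, length.out = config@n_markers) * n_site)
      mk <- pmin(pmax(mk, 1L), n_site)
      gt[mk, c_idx] <- 0L
      gt[mk, r_idx] <- 2L
      if (length(h_idx)) gt[mk, h_idx] <- 1L
      pC[mk] <- 0; pR[mk] <- 1
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        chrom = as.character(ch), pos = pos[mk],
        name = c("Tpi", paste0("SNP", seq_len(max(0, config@n_markers - 1))))[
          seq_along(mk)],
        stringsAsFactors = FALSE)
    }

    alle <- t(replicate(n_site, sample(c("A", "C", "G", "T"), 2L)))
    gt_list[[as.character(ch)]] <- gt
    site_list[[as.character(ch)]] <- data.frame(
      chrom = as.character(ch), pos = pos,
      ref = alle[, 1], alt = alle[, 2],
      p_anc = p_anc, p_C = pC, p_R = pR, stringsAsFactors = FALSE)
  }

  sites <- do.call(rbind, site_list)
  gt <- do.call(rbind, gt_list)
  colnames(gt) <- samples$sample
  gm <- StrainGenotypes(gt, sites$chrom, sites$pos, sites$ref, sites$alt,
                        sample_data = samples[, c("strain", "subpop")])
  truth <- list(
    samples = samples,
    sites = sites,
    markers = if (length(marker_rows)) do.call(rbind, marker_rows)
              else data.frame(chrom = character(), pos = integer(),
                              name = character()),
    sweeps = data.frame(chrom = character(), center_bp = numeric(),
                        start = numeric(), end = numeric(),
                        strength = numeric()))

  for (sw in config@sweep_specs) {
    res <- injectSweep(gm, truth, sw$chrom, sw$center_bp, sw$strength,
                       seed = config@seed + 97L)
    gm <- res$genotypes; truth <- res$truth
  }
  if (degrade)
    gm <- degradeGenotypes(gm, config@missing_rate, config@depth_mean,
                           config@gq_mean, seed = config@seed + 13L,
                           gq_sd = config@gq_sd)
  list(genotypes = gm, truth = truth)
}

#' Inject a hard selective sweep
#'
#' For each site at distance d from `center_bp` on `chrom`, with
#' probability exp(-d/strength) the site's minor allele (within the target
#' group) is removed, leaving the group monomorphic there — a diversity
#' trough widest at the sweep center. The swept interval
#' `[center - 3*strength, center + 3*strength]` is recorded in the truth
#' table.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param truth truth list from [simulateCohort()]
#' @param chrom chromosome name (character or integer)
#' @param center_bp sweep center
#' @param strength decay scale in bp; must be > 0 (0 is refused; the limit
#'   of no altered site is a strength of ~0+)
#' @param seed RNG seed
#' @param samples target group; defaults to the true C-strain samples
#' @return `list(genotypes=, truth=)` with the sweep applied and recorded.
#' @export
injectSweep <- function(gm, truth, chrom, center_bp, strength, seed = 1L,
                        samples = NULL) {
  if (strength <= 0) stop("sweep strength must be positive")
  chrom <- as.character(chrom)
  if (!chrom %in% chromOf(gm)) stop("chromosome ", chrom, " not present")
  idx_chr <- which(chromOf(gm) == chrom)
  if (is.null(samples))
    samples <- truth$samples$sample[truth$samples$strain == "C"]
  cols <- resolveSamples(gm, samples)
  set.seed(seed)
  d <- abs(posOf(gm)[idx_chr] - center_bp)
  hit <- stats::runif(length(d)) < exp(-d / strength)
  gt <- dosages(gm)
  for (s in idx_chr[hit]) {
    g <- gt[s, cols]
    f <- mean(g, na.rm = TRUE) / 2
    gt[s, cols] <- if (is.nan(f) || f < 0.5) 0L else 2L
  }
  assays(gm)$GT <- gt
  truth$sweeps <- rbind(truth$sweeps, data.frame(
    chrom = chrom, center_bp = center_bp,
    start = max(0, center_bp - 3 * strength),
    end = center_bp + 3 * strength, strength = strength))
  list(genotypes = gm, truth = truth)
}

#' Apply genotype-level noise (missingness, DP, GQ)
#'
#' Masks genotypes i.i.d. at `missing_rate`, draws per-genotype depths
#' DP ~ Poisson(depth_mean) and genotype qualities GQ from a normal
#' distribution clamped to [0, 99].
#'
#' @param gm a [StrainGenotypes-class] object
#' @param missing_rate genotype missingness probability in [0,1]
#' @param depth_mean mean sequencing depth (reads)
#' @param gq_mean,gq_sd mean/sd of the phred genotype quality
#' @param seed RNG seed
#' @return the degraded [StrainGenotypes-class] with DP and GQ assays.
#' @export
degradeGenotypes <- function(gm, missing_rate = 0.05, depth_mean = 100,
                             gq_mean = 60, seed = 1L, gq_sd = 15) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  gt <- dosages(gm)
  n <- length(gt)
  if (missing_rate > 0)
    gt[stats::runif(n) < missing_rate] <- NA_integer_
  dp <- matrix(stats::rpois(n, depth_mean), nrow(gt))
  gq <- matrix(pmin(99, pmax(0, round(stats::rnorm(n, gq_mean, gq_sd)))),
               nrow(gt))
  dimnames(dp) <- dimnames(gq) <- dimnames(gt)
  assays(gm) <- list(GT = gt, DP = dp, GQ = gq)
  gm
}

#' Diagnostic marker panel from a simulation truth table
#'
#' Formats the simulated fixed-difference marker sites as the panel table
#' the strain caller consumes (chrom, pos, C allele, R allele, name). In
#' the simulator the C strain always carries the REF allele at markers.
#'
#' @param gm the simulated [StrainGenotypes-class]
#' @param truth the matching truth list
#' @return data.frame with columns chrom, pos, C_allele, R_allele, name.
#' @export
markerPanel <- function(gm, truth) {
  mk <- truth$markers
  key <- paste(chromOf(gm), posOf(gm))
  idx <- match(paste(mk$chrom, mk$pos), key)
  data.frame(chrom = mk$chrom, pos = mk$pos,
             C_allele = mcols(rowRanges(gm))$REF[idx],
             R_allele = mcols(rowRanges(gm))$ALT[idx],
             name = mk$name, stringsAsFactors = FALSE)
}
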