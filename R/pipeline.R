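#' Run the full two-strain analysis pipeline from a config
#'
#' Orchestrates simulate -> filter -> strain-call -> stats -> islands ->
#' sweeps -> pca from a single declarative YAML config (path or list).
#' Present sections are run in that fixed order; each stage writes its
#' tabular outputs (TSV; VCF for the simulated cohort) into the output
#' directory and appends a manifest entry with the stage name, its
#' parameters and the md5 hashes of its outputs, so a rerun with the
#' same config and seeds reproduces identical files. Any stage failure
#' halts the run with a stage-named error.
#'
#' Config sections (all optional except one data source):
#' \describe{
#'   \item{simulate}{arguments of [simConfig()]; `seed` required}
#'   \item{input_vcf}{path to an existing VCF (alternative to simulate)}
#'   \item{filter}{`min_depth`, `min_gq`, `max_missing`, `maf`}
#'   \item{strain_call}{uses the simulated marker panel}
#'   \item{stats}{`window_fst`, `window_pi`, `window_d`}
#'   \item{islands}{`chrom`, `n_perm`, `bandwidth`, `seed`}
#'   \item{sweeps}{`population` ("C"/"R"), `grid_bp`, `fine_bp`,
#'     `outlier_pct`, `region_pct`, omega `minwin`/`maxwin`}
#'   \item{pca}{`k`, `dataset`}
#'   \item{output_dir}{where outputs and the manifest land}
#' }
#'
#' @param config list or path to a YAML file
#' @return data.frame manifest (one row per stage output), invisibly
#'   also written to `manifest.tsv`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir %||% stop("config needs an output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, params, files) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      params = paste(names(params), unlist(params), sep = "=",
                     collapse = ";"),
      output = basename(files),
      md5 = unname(tools::md5sum(files)))
  }
  wtsv <- function(d, name) {
    f <- file.path(out_dir, name)
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gm <- NULL; truth <- NULL; panel <- NULL
  if (!is.null(config$simulate)) {
    run("simulate", {
      sc <- do.call(simConfig, config$simulate)
      sim <- simulateCohort(sc)
      gm <- sim$genotypes; truth <- sim$truth
      vcf <- file.path(out_dir, "cohort.vcf.gz")
      writeGenotypeVcf(gm, vcf)
      f1 <- wtsv(truth$samples, "truth_samples.tsv")
      f2 <- wtsv(truth$sites, "truth_sites.tsv")
      panel <- markerPanel(gm, truth)
      f3 <- wtsv(panel, "marker_panel.tsv")
      note("simulate", config$simulate, c(vcf, f1, f2, f3))
    })
  } else if (!is.null(config$input_vcf)) {
    run("read", { gm <- readGenotypeVcf(config$input_vcf) })
  } else stop("config needs a 'simulate' section or an 'input_vcf'")

  full <- gm   # unfiltered-maf set kept for the sweep scans
  if (!is.null(config$filter)) {
    run("filter", {
      p <- config$filter
      gm <- filterSiteQuality(gm, p$min_depth %||% 6, p$min_gq %||% 10,
                               p$max_missing %||% 0.5)
      gm <- restrictChromosomes(gm)
      full <- gm
      gm <- filterBiallelicMaf(gm, p$maf %||% 0.01)
      f <- wtsv(metadata(gm)$filter_log, "filter_log.tsv")
      note("filter", p, f)
    })
  }

  calls <- NULL
  if (!is.null(config$strain_call)) {
    run("strain-call", {
      if (is.null(panel)) stop("no marker panel available")
      calls <- callStrains(full, panel)
      f1 <- wtsv(calls, "strain_calls.tsv")
      grp <- setNames(colData(gm)$subpop, colnames(gm))
      comp <- aggregateComposition(calls, grp)
      f2 <- wtsv(comp, "strain_composition.tsv")
      note("strain-call", list(panel_markers = nrow(panel)), c(f1, f2))
    })
  }

  strainOf <- function(lab) {
    if (!is.null(calls)) calls$sample[calls$label == lab]
    else samplesWhere(gm, "strain", lab)
  }

  if (!is.null(config$stats)) {
    run("stats", {
      p <- config$stats
      cs <- strainOf("C"); rs <- strainOf("R")
      fst <- wcFst(gm, cs, rs, window_bp = p$window_fst %||% 10000)
      f1 <- wtsv(fst$windows, "fst_windows.tsv")
      f2 <- wtsv(rbind(piWindowed(gm, cs, p$window_pi %||% 5000),
                       piWindowed(gm, rs, p$window_pi %||% 5000)),
                 "pi_windows.tsv")
      f3 <- wtsv(tajimasDWindowed(gm, NULL, p$window_d %||% 5000),
                 "tajimas_d_windows.tsv")
      f4 <- wtsv(ldDecay(gm), "ld_decay.tsv")
      note("stats", p, c(f1, f2, f3, f4))
    })
  }

  if (!is.null(config$islands)) {
    run("islands", {
      p <- config$islands
      ch <- as.character(p$chrom %||% "31")
      dxy <- dxyWindowed(gm, strainOf("C"), strainOf("R"),
                         window_bp = p$window %||% 10000)
      isl <- islandScan(dxy[dxy$chrom == ch, ],
                        n_perm = p$n_perm %||% 10000,
                        bandwidth = p$bandwidth %||% 50000,
                        seed = p$seed %||% 1L)
      f1 <- wtsv(isl$islands, "islands.tsv")
      f2 <- wtsv(data.frame(threshold = isl$threshold,
                            n_perm = isl$n_perm, seed = isl$seed),
                 "island_threshold.tsv")
      note("islands", p, c(f1, f2))
    })
  }

  if (!is.null(config$sweeps)) {
    run("sweeps", {
      p <- config$sweeps
      pop <- strainOf(p$population %||% "C")
      sfs <- backgroundSFS(full, pop)
      grid <- clrScan(full, pop, grid_bp = p$grid_bp %||% 5000, sfs = sfs)
      f1 <- wtsv(grid, "clr_grid.tsv")
      outl <- suppressWarnings(
        findClrOutliers(grid, p$outlier_pct %||% 99.99))
      regions <- if (nrow(outl) > 0) do.call(rbind, lapply(
        seq_len(nrow(outl)), function(i)
          refineSweepRegion(full, pop, outl$chrom[i], outl$pos[i],
                            fine_bp = p$fine_bp %||% 1000,
                            region_percentile = p$region_pct %||% 99,
                            sfs = sfs,
                            population = p$population %||% "C")))
      else data.frame()
      f2 <- wtsv(regions, "sweep_regions.tsv")
      om <- omegaScan(full, pop, minwin = p$minwin %||% 500,
                      maxwin = p$maxwin %||% 2500)
      f3 <- wtsv(om, "omega_windows.tsv")
      note("sweeps", p, c(f1, f2, f3))
    })
  }

  if (!is.null(config$pca)) {
    run("pca", {
      p <- config$pca
      pc <- genotypePca(gm, k = p$k %||% 10,
                        dataset = p$dataset %||% "autosomes")
      f1 <- wtsv(data.frame(sample = rownames(pc$coords), pc$coords),
                 "pca_coords.tsv")
      f2 <- wtsv(data.frame(component = seq_along(pc$eigenvalues),
                            eigenvalue = pc$eigenvalues,
                            pct_variance = pc$pct_variance),
                 "pca_eigen.tsv")
      note("pca", p, c(f1, f2))
    })
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
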