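#' Construct a StrainGenotypes object
#'
#' @param gt integer matrix of diploid dosages (sites x samples), values
#'   0/1/2 or NA.
#' @param chrom chromosome of each site (character; "1".."31" for the
#'   placed chromosomes, "31" being the Z).
#' @param pos 1-based position of each site.
#' @param ref,alt reference and alternate alleles (alt may contain commas
#'   for multi-allelic records, which are kept but flagged).
#' @param dp,gq optional per-genotype depth and genotype-quality matrices.
#' @param sample_data optional `DataFrame`/data.frame of per-sample
#'   metadata (strain, flyway, ...), one row per column of `gt`.
#' @return A [StrainGenotypes-class] object.
#' @export
StrainGenotypes <- function(gt, chrom, pos, ref = NULL, alt = NULL,
                            dp = NULL, gq = NULL, sample_data = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  n_site <- nrow(gt)
  chrom <- as.character(chrom)
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("T", n_site)
  multi <- grepl(",", alt, fixed = TRUE)
  rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                REF = as.character(ref), ALT = as.character(alt),
                multiallelic = multi)
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("S%03d", seq_len(ncol(gt)))
  assays <- list(GT = gt)
  if (!is.null(dp)) { dp <- as.matrix(dp); dimnames(dp) <- dimnames(gt); assays$DP <- dp }
  if (!is.null(gq)) { gq <- as.matrix(gq); dimnames(gq) <- dimnames(gt); assays$GQ <- gq }
  cd <- if (is.null(sample_data)) DataFrame(row.names = colnames(gt))
        else DataFrame(sample_data, row.names = colnames(gt))
  se <- SummarizedExperiment(assays = assays, rowRanges = rr, colData = cd)
  new("StrainGenotypes", se)
}

#' Accessors for StrainGenotypes assays and site information
#'
#' `dosages()` returns the sites-x-samples dosage matrix, `depthMatrix()`
#' and `gqMatrix()` the per-genotype DP/GQ annotations (or NULL), and
#' `siteInfo()` a data.frame of per-site chromosome, position, alleles,
#' missing fraction and global minor-allele frequency.
#'
#' @param x a [StrainGenotypes-class] object
#' @return see Description.
#' @export
dosages <- function(x) assay(x, "GT")

#' @rdname dosages
#' @export
depthMatrix <- function(x) if ("DP" %in% assayNames(x)) assay(x, "DP") else NULL

#' @rdname dosages
#' @export
gqMatrix <- function(x) if ("GQ" %in% assayNames(x)) assay(x, "GQ") else NULL

#' @rdname dosages
#' @export
siteInfo <- function(x) {
  gt <- dosages(x)
  n_obs <- rowSums(!is.na(gt))
  af <- ifelse(n_obs > 0, rowSums(gt, na.rm = TRUE) / (2 * n_obs), NA_real_)
  data.frame(
    chrom = as.character(seqnames(rowRanges(x))),
    pos = start(rowRanges(x)),
    ref = mcols(rowRanges(x))$REF,
    alt = mcols(rowRanges(x))$ALT,
    multiallelic = mcols(rowRanges(x))$multiallelic,
    missing_frac = 1 - n_obs / ncol(gt),
    maf = pmin(af, 1 - af),
    row.names = NULL
  )
}

chromOf <- function(x) as.character(seqnames(rowRanges(x)))
posOf <- function(x) start(rowRanges(x))

#' Resolve a sample specification to column indices
#'
#' Samples can be given as sample names, integer indices, a logical mask,
#' or the name of a `colData` column paired with a value via
#' `samplesWhere()`.
#' @noRd
resolveSamples <- function(x, samples) {
  if (is.null(samples)) return(seq_len(ncol(x)))
  if (is.logical(samples)) return(which(samples))
  if (is.numeric(samples)) return(as.integer(samples))
  idx <- match(samples, colnames(x))
  if (anyNA(idx))
    stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
  idx
}

#' Select sample names by a colData column value
#'
#' @param x a [StrainGenotypes-class] object
#' @param column name of a `colData(x)` column
#' @param value value(s) to match
#' @return character vector of sample names.
#' @export
samplesWhere <- function(x, column, value) {
  cd <- colData(x)
  if (!column %in% colnames(cd)) stop("no colData column '", column, "'")
  colnames(x)[cd[[column]] %in% value]
}

setMethod("show", "StrainGenotypes", function(object) {
  si <- rowRanges(object)
  chr <- unique(as.character(seqnames(si)))
  gt <- dosages(object)
  miss <- mean(is.na(gt))
  cat("StrainGenotypes:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  chromosomes:", if (length(chr) > 6)
    paste(c(utils::head(chr, 5), "...", utils::tail(chr, 1)), collapse = " ")
    else paste(chr, collapse = " "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "),
      sprintf("| missing: %.1f%%\n", 100 * miss))
  if (ncol(colData(object)) > 0)
    cat("  sample metadata:", paste(colnames(colData(object)), collapse = ", "), "\n")
  invisible(object)
})

## allele counts of one sample subset at each site:
## returns list(m = observed allele number, c1 = ALT allele count)
alleleCounts <- function(gt, idx) {
  sub <- gt[, idx, drop = FALSE]
  n_obs <- rowSums(!is.na(sub))
  list(m = 2 * n_obs, c1 = rowSums(sub, na.rm = TRUE))
}

## half-open genome windows [start, end) of fixed width anchored at 0
windowIndex <- function(pos, window_bp) (pos - 1L) %/% as.integer(window_bp)

windowFrame <- function(chrom, widx, window_bp) {
  data.frame(chrom = chrom, start = widx * window_bp,
             end = (widx + 1) * window_bp)
}

## round half up to nearest integer (printed-percentage convention)
roundHalfUp <- function(x) floor(x + 0.5)
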