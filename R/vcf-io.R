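#' Read a VCF into a StrainGenotypes object
#'
#' Parses a VCF 4.x file (plain or gzipped) with vcfR and converts the GT
#' field to diploid dosages (count of non-reference alleles; any missing
#' allele gives a missing dosage). Multi-allelic records are retained but
#' flagged in the site table. FORMAT/DP and FORMAT/GQ are carried along
#' when present.
#'
#' @param path VCF file path
#' @return a [StrainGenotypes-class] object.
#' @importClassesFrom vcfR vcfR
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_site <- nrow(v@gt) %||% 0L
  if (nrow(fix) == 0L || ncol(v@gt) < 2L) {
    return(StrainGenotypes(matrix(integer(), 0,
                                  max(0L, ncol(v@gt) - 1L),
                                  dimnames = list(NULL, colnames(v@gt)[-1])),
                           chrom = character(), pos = integer(),
                           ref = character(), alt = character()))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed VCF record at data line ", bad, ": non-numeric POS")
  }
  chrom <- fix[, "CHROM"]
  same <- chrom[-1] == chrom[-length(chrom)]
  if (length(pos) > 1 && any(same & diff(pos) <= 0))
    stop("input VCF is not sorted by position within chromosomes")

  gt_str <- vcfR::extract.gt(v, element = "GT")
  d <- gtToDosage(gt_str)
  dp <- gq <- NULL
  fmt_fields <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DP" %in% fmt_fields)
    dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  if ("GQ" %in% fmt_fields)
    gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  StrainGenotypes(d, chrom = chrom, pos = pos,
                  ref = fix[, "REF"], alt = fix[, "ALT"], dp = dp, gq = gq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## GT strings -> dosage via a lookup over the observed unique codes
gtToDosage <- function(gt_str) {
  u <- unique(as.vector(gt_str))
  val <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(chartr("|", "/", s), "/", fixed = TRUE)[[1]]
    if (any(al == ".") || length(al) == 0) return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  d <- matrix(val[match(as.vector(gt_str), u)], nrow(gt_str),
              dimnames = dimnames(gt_str))
  d
}

#' Write a StrainGenotypes object as VCF 4.2
#'
#' Emits one ALT allele per record with FORMAT `GT:DP:GQ` (DP/GQ columns
#' are included only when present). Output is gzip-compressed
#' (`.vcf.gz`), the form the reader and common tooling accept.
#'
#' @param gm a [StrainGenotypes-class] object
#' @param path output path (conventionally ending in .vcf.gz)
#' @return the path, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  gt <- dosages(gm)
  dp <- depthMatrix(gm); gq <- gqMatrix(gm)
  n_site <- nrow(gt)
  meta <- c("##fileformat=VCFv4.2",
            "##source=fawpopgen",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dpgq <- !is.null(dp) && !is.null(gq)
  if (has_dpgq)
    meta <- c(meta,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  fix <- cbind(CHROM = chromOf(gm), POS = as.character(posOf(gm)),
               ID = rep(".", n_site), REF = mcols(rowRanges(gm))$REF,
               ALT = mcols(rowRanges(gm))$ALT, QUAL = rep(".", n_site),
               FILTER = rep("PASS", n_site), INFO = rep(".", n_site))
  code <- c("0/0", "0/1", "1/1")
  gt_chr <- matrix("./.", n_site, ncol(gt))
  ok <- !is.na(gt)
  gt_chr[ok] <- code[gt[ok] + 1L]
  if (has_dpgq) {
    body <- matrix(paste(gt_chr, ifelse(is.na(dp), ".", dp),
                         ifelse(is.na(gq), ".", gq), sep = ":"),
                   n_site, ncol(gt))
    fmt <- "GT:DP:GQ"
  } else {
    body <- gt_chr
    fmt <- "GT"
  }
  colnames(body) <- colnames(gt)
  v <- new("vcfR", meta = meta, fix = fix,
           gt = cbind(FORMAT = rep(fmt, n_site), body))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
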