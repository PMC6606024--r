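#' Write genotypes as VCF
#'
#' Minimal VCFv4.2 text writer for simulated genotype matrices (phased GT
#' field, contigs from the genome map, 1-based positions).  Reading is done
#' with [read_genotypes()] (VariantAnnotation), and write/read round trips
#' are part of the test suite.
#'
#' @param hap1,hap2 per-homolog allele matrices (individuals x sites, 0/1).
#'   `hap2 = NULL` writes unphased genotypes from `hap1` interpreted as
#'   0/1/2 counts.
#' @param sites data.frame with `chrom`, `pos` (1-based).
#' @param map a [make_genome_map()] for contig headers.
#' @param path output file.
#' @param ids sample names.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(hap1, hap2, sites, map, path,
                               ids = paste0("ind", seq_len(nrow(hap1)))) {
  n <- nrow(hap1)
  stopifnot(length(ids) == n, nrow(sites) == ncol(hap1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedscan",
    sprintf("##contig=<ID=%s,length=%d>", map$chrom, as.integer(map$bp)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  gt <- if (is.null(hap2)) {
    m <- matrix(c("0/0", "0/1", "1/1")[hap1 + 1L], nrow = n)
    m
  } else {
    matrix(paste0(hap1, "|", hap2), nrow = n)
  }
  body <- apply(cbind(sites$chrom, sites$pos, ".", "A", "T", ".", "PASS", ".",
                      "GT", t(gt)), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a founder panel as a phased VCF
#'
#' @param panel a [make_founder_panel()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_founder_vcf <- function(panel, path) {
  n <- panel$n_founders
  h1 <- do.call(cbind, lapply(panel$hap, function(H) H[seq(1, 2 * n, 2), , drop = FALSE]))
  h2 <- do.call(cbind, lapply(panel$hap, function(H) H[seq(2, 2 * n, 2), , drop = FALSE]))
  sites <- data.frame(
    chrom = rep(panel$map$chrom, lengths(panel$sites)),
    pos = unlist(panel$sites, use.names = FALSE) + 1,
    stringsAsFactors = FALSE)
  write_genotype_vcf(h1, h2, sites, panel$map, path,
                     ids = paste0("founder", seq_len(n)))
}

#' Read a VCF into an alternate-allele count matrix
#'
#' Biallelic SNP records only; other records are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional sample subset.
#' @return list with `geno` (samples x sites matrix of 0/1/2, NA for
#'   missing), `sites` (data.frame chrom / pos, 1-based), and `n_skipped`.
#' @export
read_genotypes <- function(path, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!is.null(samples)) {
    hit <- intersect(samples, colnames(vcf))
    if (!length(hit)) stop("no samples matched")
    vcf <- vcf[, hit]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref_ok <- BiocGenerics::width(rr$REF) == 1L
  alt <- rr$ALT
  alt_ok <- S4Vectors::elementNROWS(alt) == 1L &
    vapply(seq_along(alt), function(i)
      alt_ok_one(alt[[i]]), TRUE)
  keep <- ref_ok & alt_ok
  n_skipped <- sum(!keep)
  vcf <- vcf[keep, ]
  rr <- rr[keep, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  lut <- c("0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2,
           "0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  g <- matrix(unname(lut[gt]), nrow = nrow(gt))
  geno <- t(g)
  rownames(geno) <- colnames(vcf)
  list(geno = geno,
       sites = data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                          pos = BiocGenerics::start(rr),
                          stringsAsFactors = FALSE),
       n_skipped = n_skipped)
}

alt_ok_one <- function(a) {
  s <- as.character(a)
  length(s) == 1 && nchar(s) == 1 && s %in% c("A", "C", "G", "T")
}
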