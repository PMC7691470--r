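#' Diploid genotype matrix
#'
#' Container for diploid biallelic SNP genotypes. Calls are coded as the count
#' of the minor allele: 0 (homozygous major), 1 (heterozygous), 2 (homozygous
#' minor), `NA` (missing). SNP metadata carries the chromosome, 1-based
#' position and the two allele labels per SNP.
#'
#' @param calls integer matrix, samples x SNPs, values 0/1/2/NA.
#' @param chrom character vector of chromosome labels, one per SNP.
#' @param pos integer vector of 1-based positions, one per SNP.
#' @param alleles data.frame with columns `major` and `minor` (single
#'   nucleotide characters), one row per SNP.
#' @param sample_ids,snp_ids optional label vectors; taken from `dimnames(calls)`
#'   when missing.
#'
#' @return an object of class `genotype_matrix`: a list with elements `calls`,
#'   `chrom`, `pos`, `alleles`, `sample_ids`, `snp_ids`.
#' @export
genotype_matrix <- function(calls, chrom, pos, alleles,
                            sample_ids = rownames(calls),
                            snp_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  m <- ncol(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  stopifnot(
    length(chrom) == m, length(pos) == m, nrow(alleles) == m,
    all(c("major", "minor") %in% names(alleles)),
    all(is.na(calls) | (calls >= 0L & calls <= 2L))
  )
  rownames(calls) <- sample_ids
  colnames(calls) <- snp_ids
  structure(
    list(
      calls = calls,
      chrom = as.character(chrom),
      pos = as.integer(pos),
      alleles = data.frame(major = as.character(alleles$major),
                           minor = as.character(alleles$minor),
                           stringsAsFactors = FALSE),
      sample_ids = as.character(sample_ids),
      snp_ids = as.character(snp_ids)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs on",
      length(unique(x$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples,snps index vectors (integer, logical or character labels);
#'   `NULL` keeps everything.
#' @return a `genotype_matrix` restricted to the requested samples and SNPs.
#' @export
gm_subset <- function(gm, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else samples
  if (is.character(si)) si <- match(si, gm$sample_ids)
  vi <- if (is.null(snps)) seq_along(gm$snp_ids) else snps
  if (is.character(vi)) vi <- match(vi, gm$snp_ids)
  genotype_matrix(
    gm$calls[si, vi, drop = FALSE],
    chrom = gm$chrom[vi], pos = gm$pos[vi],
    alleles = gm$alleles[vi, , drop = FALSE],
    sample_ids = gm$sample_ids[si], snp_ids = gm$snp_ids[vi]
  )
}

# genotype call as an unordered allele pair, e.g. c("A","T"); NULL if missing
gm_allele_pair <- function(gm, i, j) {
  g <- gm$calls[i, j]
  if (is.na(g)) return(NULL)
  maj <- gm$alleles$major[j]
  mnr <- gm$alleles$minor[j]
  switch(as.character(g),
         "0" = c(maj, maj),
         "1" = sort(c(maj, mnr)),
         "2" = c(mnr, mnr))
}

#' Write genotypes to a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT and (when read depths are supplied)
#' AD fields. Kept as uncompressed text so outputs diff cleanly and round-trip
#' through standard VCF readers.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param depths optional list with integer matrices `ref` and `alt`
#'   (samples x SNPs) of allele read counts.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path, depths = NULL) {
  n <- length(gm$sample_ids); m <- length(gm$snp_ids)
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=yhapnet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  fmt <- "GT"
  if (!is.null(depths)) {
    header <- c(header,
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
    fmt <- "GT:AD"
  }
  for (ctg in unique(gm$chrom)) {
    header <- c(header, sprintf("##contig=<ID=%s>", ctg))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", gm$sample_ids),
                            collapse = "\t"))
  body <- character(m)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    cell <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    if (!is.null(depths)) {
      ad <- paste(depths$ref[, j], depths$alt[, j], sep = ",")
      ad[is.na(depths$ref[, j])] <- "."
      cell <- paste(cell, ad, sep = ":")
    }
    body[j] <- paste(c(gm$chrom[j], gm$pos[j], gm$snp_ids[j],
                       gm$alleles$major[j], gm$alleles$minor[j],
                       ".", "PASS", ".", fmt, cell), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a biallelic SNP VCF via \pkg{vcfR} into a [genotype_matrix()]. The
#' REF allele is stored as the major allele label and ALT as the minor label;
#' minor-allele frequency used by the filters is computed from the calls, not
#' from the labels.
#'
#' @param path VCF file (plain text or gzipped).
#' @return list with elements `gm` (a `genotype_matrix`) and `depths`
#'   (list of `ref`/`alt` matrices, or `NULL` when AD is absent).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L)) {
    stop("only biallelic SNPs are supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  calls <- t(apply(gt, 1, code))          # SNP x sample
  colnames(calls) <- colnames(gt)
  gm <- genotype_matrix(
    t(calls),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    alleles = data.frame(major = fix[, "REF"], minor = fix[, "ALT"]),
    sample_ids = colnames(gt),
    snp_ids = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
  )
  depths <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split2 <- function(k) {
      as.integer(vapply(strsplit(ad, ",", fixed = TRUE),
                        function(p) if (length(p) >= k) p[k] else NA_character_,
                        character(1)))
    }
    ref <- matrix(split2(1), nrow = nrow(ad))
    alt <- matrix(split2(2), nrow = nrow(ad))
    depths <- list(ref = t(ref), alt = t(alt))
    dimnames(depths$ref) <- dimnames(depths$alt) <-
      list(gm$sample_ids, gm$snp_ids)
  }
  list(gm = gm, depths = depths)
}
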