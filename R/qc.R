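#' Per-SNP missingness and minor allele frequency
#'
#' Missingness is the fraction of all samples with a missing call; the minor
#' allele frequency is `min(p, 1 - p)` of the allele frequency among
#' non-missing calls. SNPs with no non-missing calls get `maf = NA` and
#' automatically fail [filter_snps()].
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame: snp_id, chrom, pos, n_called, missing_fraction, maf.
#' @export
snp_stats <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  minor_count <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_called > 0, minor_count / (2 * n_called), NA_real_)
  data.frame(
    snp_id = gm$snp_ids,
    chrom = gm$chrom,
    pos = gm$pos,
    n_called = n_called,
    missing_fraction = 1 - n_called / n,
    maf = pmin(p, 1 - p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Retains SNPs with `missing_fraction <= max_missing` and `maf >= min_maf`
#' (removal uses strict inequalities: a SNP at exactly 10% missing or exactly
#' the MAF floor is kept). SNP order is preserved. Filtering is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param stats result of [snp_stats()] aligned to `gm`; recomputed if `NULL`.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return the filtered `genotype_matrix`.
#' @export
filter_snps <- function(gm, stats = NULL, max_missing = 0.10, min_maf = 0.01) {
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1) {
    stop("max_missing and min_maf must lie in [0, 1]")
  }
  if (is.null(stats)) stats <- snp_stats(gm)
  if (!identical(stats$snp_id, gm$snp_ids)) {
    stop("stats are not aligned to the genotype matrix")
  }
  keep <- !is.na(stats$maf) &
    stats$missing_fraction <= max_missing &
    stats$maf >= min_maf
  gm_subset(gm, snps = which(keep))
}

#' Collapsed-paralog statistics from heterozygote read ratios
#'
#' For each SNP, `H` is the proportion of genotyped samples called
#' heterozygous, and `D` is the read-ratio deviation z-score over heterozygous
#' samples: with summed reads `N_A` (major) and `N_B` (minor),
#' `D = (N_A - N_B) / sqrt(N_A + N_B)`. A true single-copy locus gives
#' balanced heterozygote reads (`D ~ N(0,1)`) and moderate `H`; a collapsed
#' duplicate inflates both. A SNP is flagged when `H > max_H` or
#' `|D| > max_absD`. SNPs with no heterozygotes have undefined `D` and are
#' never flagged on `D`.
#'
#' @param gm a [genotype_matrix()].
#' @param depths list of `ref`/`alt` allele read count matrices (samples x
#'   SNPs) aligned to `gm`.
#' @param max_H heterozygosity ceiling (default 0.55).
#' @param max_absD read-ratio deviation ceiling (default 7).
#' @return data.frame: snp_id, H, D, n_het, paralog_flag.
#' @export
hdplot_stats <- function(gm, depths, max_H = 0.55, max_absD = 7) {
  calls <- gm$calls
  het <- !is.na(calls) & calls == 1L
  n_het <- colSums(het)
  n_genotyped <- colSums(!is.na(calls))
  H <- ifelse(n_genotyped > 0, n_het / n_genotyped, 0)
  NA_reads <- colSums(depths$ref * het, na.rm = TRUE)
  NB_reads <- colSums(depths$alt * het, na.rm = TRUE)
  tot <- NA_reads + NB_reads
  D <- ifelse(n_het > 0 & tot > 0, (NA_reads - NB_reads) / sqrt(tot), NA_real_)
  data.frame(
    snp_id = gm$snp_ids,
    H = H,
    D = D,
    n_het = n_het,
    paralog_flag = H > max_H | (!is.na(D) & abs(D) > max_absD),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Restrict a genotype matrix to one chromosome
#'
#' Returns the SNPs on the named chromosome sorted by position. An empty
#' result is a warning, not an error.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom_name chromosome label.
#' @return a `genotype_matrix` with only that chromosome's SNPs, sorted.
#' @export
subset_chromosome <- function(gm, chrom_name) {
  idx <- which(gm$chrom == chrom_name)
  if (!length(idx)) {
    warning("no SNPs on chromosome ", chrom_name)
  }
  idx <- idx[order(gm$pos[idx])]
  gm_subset(gm, snps = idx)
}
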