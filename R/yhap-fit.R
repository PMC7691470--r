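#' Discover Y-chromosome haplogroups from diploid SNP genotypes
#'
#' The central fitting function. Starting from diploid biallelic genotypes on
#' a sex chromosome, it (1) filters SNPs on missingness, minor allele
#' frequency and, when read depths are given, collapsed-paralog signal;
#' (2) estimates all pairwise linkage disequilibrium (two-locus EM composite
#' r-squared) and extracts long-range high-LD SNP sets as connected components
#' of the LD graph; (3) phases the union of block SNPs into two haplotypes per
#' individual by partition-ligation EM; (4) clusters the haplotypes with
#' Ward's criterion, classifies clusters as X- or Y-type from carrier sex,
#' names the Y-type clusters as male haplogroups; and (5) extracts diagnostic
#' SNPs with fixed allele-frequency differences from the X pool and assembles
#' them into an assignment panel.
#'
#' @param gm a [genotype_matrix()].
#' @param samples data.frame with sample_id, phenotypic_sex (and optionally
#'   genetic_sex, population) for the samples in `gm`.
#' @param depths optional `ref`/`alt` read-count matrices for paralog
#'   filtering.
#' @param chrom sex chromosome label to analyse; required when `gm` spans
#'   several chromosomes.
#' @param max_missing,min_maf SNP filters (defaults 0.10 and 0.01).
#' @param max_H,max_absD paralog filter ceilings (defaults 0.55 and 7).
#' @param r2_min LD edge threshold (default 0.3, inclusive).
#' @param min_snps,min_span block filters (defaults 5 SNPs, 1 Mb).
#' @param k clusters for the haplotype clustering (`"auto"` = silhouette).
#' @param male_frac_min male fraction calling a cluster Y-type (default 0.8).
#' @param fixed_threshold diagnostic frequency-difference floor (default 0.95).
#' @param window,top_k phasing controls, see [em_phase()].
#' @param ld_method `"em"` or `"dosage"`, see [pairwise_r2()].
#' @param sex_from which sex label classifies clusters: `"phenotypic_sex"`
#'   (default) or `"genetic_sex"`.
#' @param seed seed for the phasing EM initialisation.
#' @return an object of class `yhap` with components `blocks`, `phased`,
#'   `labels`, `classes`, `groups`, `diagnostics`, `panel`,
#'   `pairing_violations`, `snp_stats`, `gm_union`, and the parameters used.
#'   Methods: [print.yhap()], [summary.yhap()], [plot.yhap()],
#'   [predict.yhap()].
#' @export
yhap_discover <- function(gm, samples, depths = NULL, chrom = NULL,
                          max_missing = 0.10, min_maf = 0.01,
                          max_H = 0.55, max_absD = 7,
                          r2_min = 0.3, min_snps = 5, min_span = 1e6,
                          k = "auto", male_frac_min = 0.8,
                          fixed_threshold = 0.95,
                          window = 6, top_k = 50,
                          ld_method = c("em", "dosage"),
                          sex_from = c("phenotypic_sex", "genetic_sex"),
                          seed = 1L) {
  ld_method <- match.arg(ld_method)
  sex_from <- match.arg(sex_from)
  cl <- match.call()

  if (is.null(chrom)) {
    chroms <- unique(gm$chrom)
    if (length(chroms) > 1) {
      stop("gm spans several chromosomes; pass the sex chromosome as `chrom`")
    }
    chrom <- chroms
  }
  gm_chr <- subset_chromosome(gm, chrom)
  stats0 <- snp_stats(gm_chr)
  gm_f <- filter_snps(gm_chr, stats0, max_missing = max_missing,
                      min_maf = min_maf)
  hd <- NULL
  if (!is.null(depths)) {
    dsub <- list(ref = depths$ref[, gm_f$snp_ids, drop = FALSE],
                 alt = depths$alt[, gm_f$snp_ids, drop = FALSE])
    hd <- hdplot_stats(gm_f, dsub, max_H = max_H, max_absD = max_absD)
    gm_f <- gm_subset(gm_f, snps = which(!hd$paralog_flag))
  }
  n_after_filter <- length(gm_f$snp_ids)

  graph <- build_ld_graph(gm_f, r2_min = r2_min, method = ld_method)
  blocks <- extract_blocks(graph, min_snps = min_snps, min_span = min_span)
  if (!length(blocks)) {
    stop("no high-LD blocks found (", n_after_filter,
         " SNPs after filtering); nothing to phase")
  }
  union_ids <- attr(blocks, "union_snps")
  union_idx <- match(union_ids, gm_f$snp_ids)
  union_idx <- union_idx[order(gm_f$pos[union_idx])]
  gm_union <- gm_subset(gm_f, snps = union_idx)

  phased <- em_phase(gm_union, window = window, top_k = top_k, seed = seed)
  hm <- haplotype_matrix(phased)
  labels <- cluster_haplotypes(hm, k = k)
  carrier <- attr(hm, "sample_id")
  sex <- samples[[sex_from]][match(carrier, samples$sample_id)]
  classes <- classify_sex_specific(labels, sex,
                                   male_frac_min = male_frac_min)
  groups <- name_haplogroups(labels, classes, chrom_label = chrom,
                             hm = hm, pos = gm_union$pos)
  group_names <- groups$name[match(labels, groups$cluster)]
  y_groups <- groups$name[groups$chrom_class == "Y"]
  x_groups <- groups$name[groups$chrom_class == "X"]
  diagnostics <- diagnostic_snps(hm, group_names, y_groups, x_groups,
                                 pos = gm_union$pos,
                                 alleles = gm_union$alleles,
                                 fixed_threshold = fixed_threshold)
  panel <- if (nrow(diagnostics)) build_panel(diagnostics) else NULL
  hap_class <- groups$chrom_class[match(labels, groups$cluster)]
  violations <- pairing_violations(carrier, hap_class)

  structure(
    list(call = cl, chrom = chrom,
         n_snps_input = length(gm_chr$snp_ids),
         n_snps_filtered = n_after_filter,
         snp_stats = stats0, hdplot = hd,
         graph = graph, blocks = blocks,
         gm_union = gm_union, phased = phased,
         hm = hm, labels = labels,
         classes = classes, groups = groups,
         group_names = group_names,
         y_groups = y_groups, x_groups = x_groups,
         diagnostics = diagnostics, panel = panel,
         pairing_violations = violations,
         samples = samples,
         params = list(max_missing = max_missing, min_maf = min_maf,
                       max_H = max_H, max_absD = max_absD, r2_min = r2_min,
                       min_snps = min_snps, min_span = min_span, k = k,
                       male_frac_min = male_frac_min,
                       fixed_threshold = fixed_threshold, window = window,
                       top_k = top_k, seed = seed, ld_method = ld_method,
                       sex_from = sex_from)),
    class = "yhap")
}

#' @export
print.yhap <- function(x, ...) {
  cat("Y-haplogroup discovery fit (", x$chrom, ")\n", sep = "")
  cat(sprintf("  SNPs: %d input, %d after filters, %d in %d high-LD block(s)\n",
              x$n_snps_input, x$n_snps_filtered,
              length(x$gm_union$snp_ids), length(x$blocks)))
  cat(sprintf("  haplotypes: %d phased into %d clusters (%d Y-type, %d X-type)\n",
              nrow(x$hm), attr(x$labels, "k"),
              sum(x$groups$chrom_class == "Y"),
              sum(x$groups$chrom_class == "X")))
  if (length(x$y_groups)) {
    cat("  Y haplogroups:", paste(x$y_groups, collapse = ", "), "\n")
    cat(sprintf("  diagnostic SNPs: %d entries over %d SNPs\n",
                nrow(x$diagnostics), length(unique(x$diagnostics$snp_id))))
  }
  if (length(x$pairing_violations)) {
    cat("  pairing violations:", length(x$pairing_violations), "individuals\n")
  }
  invisible(x)
}

#' Summarise a Y-haplogroup fit
#'
#' @param object a `yhap` fit.
#' @param ... unused.
#' @return list of class `summary.yhap`: block table (with the percentage of
#'   filtered SNPs captured), the sex-by-group composition, the region-by-group
#'   composition when regions are available, and diagnostic SNP counts per
#'   haplogroup.
#' @export
summary.yhap <- function(object, ...) {
  blocks <- ld_block_summary(object$blocks, object$n_snps_filtered)
  comp <- merge(object$classes, object$groups[, c("cluster", "name")],
                by = "cluster")
  comp <- comp[order(comp$chrom_class, -comp$n_male - comp$n_female), ]
  region_tab <- NULL
  if ("region" %in% names(object$samples)) {
    carrier <- attr(object$hm, "sample_id")
    region <- object$samples$region[match(carrier, object$samples$sample_id)]
    region_tab <- table(group = object$group_names, region = region)
  }
  diag_counts <- if (nrow(object$diagnostics)) {
    as.data.frame(table(haplogroup = object$diagnostics$haplogroup),
                  responseName = "n_diagnostic")
  } else NULL
  structure(list(blocks = blocks,
                 percent_of_snps = attr(blocks, "percent_of_snps"),
                 composition = comp, region_table = region_tab,
                 diag_counts = diag_counts,
                 pairing_violations = object$pairing_violations),
            class = "summary.yhap")
}

#' @export
print.summary.yhap <- function(x, ...) {
  cat("High-LD blocks (", sprintf("%.1f", x$percent_of_snps),
      "% of filtered SNPs):\n", sep = "")
  print(x$blocks, row.names = FALSE)
  cat("\nHaplotype-cluster composition by carrier sex:\n")
  print(x$composition, row.names = FALSE)
  if (!is.null(x$diag_counts)) {
    cat("\nDiagnostic SNPs per haplogroup:\n")
    print(x$diag_counts, row.names = FALSE)
  }
  cat("\nPairing violations:", length(x$pairing_violations), "\n")
  invisible(x)
}

#' Assign new samples to discovered haplogroups
#'
#' `method = "genotype"` compares observed genotypes over the panel SNPs with
#' each haplogroup's expected genotypes ([assign_by_genotype()]);
#' `method = "cluster"` phases the queries jointly with the reference samples
#' and clusters ([assign_by_clustering()]).
#'
#' @param object a `yhap` fit.
#' @param newdata a [genotype_matrix()] with the query samples.
#' @param method `"genotype"` (default) or `"cluster"`.
#' @param ... passed on to the assignment function.
#' @return a `hap_assignment` data.frame.
#' @export
predict.yhap <- function(object, newdata,
                         method = c("genotype", "cluster"), ...) {
  method <- match.arg(method)
  if (is.null(object$panel)) stop("fit has no diagnostic panel")
  if (method == "genotype") {
    return(assign_by_genotype(newdata, object$panel, ...))
  }
  hm <- object$hm
  carrier <- attr(hm, "sample_id")
  ref_samples <- unique(carrier)
  gn <- object$group_names
  ref_labels <- data.frame(
    sample_id = ref_samples,
    hap1_group = gn[match(ref_samples, carrier)],
    hap2_group = gn[length(carrier) + 1 -
                      match(ref_samples, rev(carrier))],
    stringsAsFactors = FALSE)
  # restrict the reference to the panel SNPs actually available in the query
  assign_by_clustering(newdata, object$gm_union, ref_labels,
                       y_groups = object$y_groups, ...)
}

#' Plot a haplotype raster
#'
#' Draws each phased haplotype as a row, SNPs in genome order as columns,
#' major allele light and minor allele dark, rows ordered by the Ward
#' dendrogram and annotated with their group. The numeric content of the
#' figure is [allele_frequency_profile()].
#'
#' @param x a `yhap` fit.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.yhap <- function(x, ...) {
  hc <- attr(x$labels, "hclust")
  ord <- hc$order
  hm <- x$hm[ord, , drop = FALSE]
  z <- t(hm)
  z[is.na(z)] <- 0.5
  old <- graphics::par(mar = c(4, 4, 2, 6))
  on.exit(graphics::par(old))
  graphics::image(x = x$gm_union$pos, y = seq_len(nrow(hm)), z = z,
                  col = c("#FFD92F", "#D95F02"),
                  breaks = c(-0.1, 0.75, 1.1),
                  xlab = paste("position on", x$chrom, "(bp)"),
                  ylab = "phased haplotypes", ...)
  groups <- x$group_names[ord]
  gcol <- grDevices::rainbow(length(unique(groups)))
  names(gcol) <- unique(groups)
  graphics::mtext(side = 4, at = seq_along(groups), text = "",
                  col = gcol[groups], line = 0.5, cex = 0.2)
  boundaries <- which(diff(as.integer(factor(groups))) != 0)
  graphics::abline(h = boundaries + 0.5, col = "grey40", lwd = 0.5)
  graphics::axis(4, at = tapply(seq_along(groups), groups, stats::median),
                 labels = names(tapply(seq_along(groups), groups, stats::median)),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  invisible(x)
}
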