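# Diagnostic SNP panel construction and haplogroup assignment of new samples.

#' Build a diagnostic SNP panel
#'
#' Collapses the per-haplogroup diagnostic SNP list into a panel: one row per
#' SNP with the X-fixed allele and the expected Y allele for each haplogroup
#' where the SNP is diagnostic (elsewhere the haplogroup's Y chromosome is
#' assumed to carry the X allele). Discriminator rules are auto-generated for
#' every haplogroup pair separated by at most `discriminator_max_diff` panel
#' SNPs: each such haplogroup must positively show its own allele at those
#' SNPs (generalising the requirement used when two haplogroups differ at only
#' two assayed SNPs).
#'
#' @param diag a [diagnostic_snps()] table (optionally pruned to the SNPs that
#'   survived assay design).
#' @param discriminator_max_diff pair-difference count that triggers
#'   discriminator rules (default 2).
#' @return object of class `diagnostic_panel`: list with `snps` (snp_id, pos,
#'   x_allele, one `y_allele.<hap>` column per haplogroup) and `discriminators`
#'   (haplogroup, snp_id, pos, required_allele).
#' @export
build_panel <- function(diag, discriminator_max_diff = 2) {
  if (!nrow(diag)) stop("no diagnostic SNPs to build a panel from")
  haps <- sort(unique(diag$haplogroup))
  snp <- unique(diag[, c("snp_id", "pos", "x_allele")])
  if (anyDuplicated(snp$snp_id)) {
    stop("inconsistent x_allele for a panel SNP")
  }
  snp <- snp[order(snp$pos), ]
  rownames(snp) <- NULL
  ymat <- matrix(NA_character_, nrow(snp), length(haps),
                 dimnames = list(snp$snp_id, haps))
  for (i in seq_len(nrow(diag))) {
    ymat[diag$snp_id[i], diag$haplogroup[i]] <- diag$y_allele[i]
  }
  # expected Y allele defaults to the X allele where not diagnostic
  yfull <- ymat
  for (h in haps) {
    yfull[is.na(yfull[, h]), h] <- snp$x_allele[is.na(ymat[, h])]
  }
  disc <- list()
  if (length(haps) > 1) {
    for (i in seq_along(haps)) for (j in seq_along(haps)) {
      if (i == j) next
      g <- haps[i]; h <- haps[j]
      differs <- which(yfull[, g] != yfull[, h])
      if (length(differs) <= discriminator_max_diff) {
        own <- differs[!is.na(ymat[differs, h])]  # h's positively fixed SNPs
        if (length(own)) {
          disc[[paste(g, h)]] <- data.frame(
            haplogroup = h,
            snp_id = snp$snp_id[own],
            pos = snp$pos[own],
            required_allele = ymat[own, h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  disc <- if (length(disc)) unique(do.call(rbind, disc)) else
    data.frame(haplogroup = character(0), snp_id = character(0),
               pos = integer(0), required_allele = character(0))
  rownames(disc) <- NULL
  structure(list(snps = cbind(snp, y_allele = yfull,
                              stringsAsFactors = FALSE),
                 haplogroups = haps,
                 discriminators = disc),
            class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat("diagnostic_panel:", nrow(x$snps), "SNPs,",
      length(x$haplogroups), "haplogroups,",
      nrow(x$discriminators), "discriminator rules\n")
  invisible(x)
}

#' Write / read a panel as JSON
#'
#' @param panel a [build_panel()] result.
#' @param path JSON file path.
#' @return `path` (write) or a `diagnostic_panel` (read).
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(
    list(snps = panel$snps, haplogroups = panel$haplogroups,
         discriminators = panel$discriminators),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  disc <- x$discriminators
  if (is.null(disc) || !length(disc)) {
    disc <- data.frame(haplogroup = character(0), snp_id = character(0),
                       pos = integer(0), required_allele = character(0))
  }
  structure(list(snps = as.data.frame(x$snps),
                 haplogroups = x$haplogroups,
                 discriminators = as.data.frame(disc)),
            class = "diagnostic_panel")
}

#' Expected genotypes for a haplogroup
#'
#' The expected male genotype at each panel SNP assumes allele fixation on
#' both chromosomes: the unordered pair of the X-fixed allele and the
#' haplogroup's Y allele (heterozygous where they differ, homozygous for the
#' X allele where the SNP is not diagnostic for that haplogroup).
#'
#' @param panel a [build_panel()] result.
#' @param haplogroup haplogroup name present in the panel.
#' @return data.frame: snp_id, pos, allele1, allele2 (sorted within pair),
#'   genotype (e.g. "A/T").
#' @export
expected_genotypes <- function(panel, haplogroup) {
  if (!haplogroup %in% panel$haplogroups) {
    stop("haplogroup not in panel: ", haplogroup)
  }
  x <- panel$snps$x_allele
  y <- panel$snps[[paste0("y_allele.", haplogroup)]]
  a1 <- pmin(x, y)
  a2 <- pmax(x, y)
  data.frame(snp_id = panel$snps$snp_id, pos = panel$snps$pos,
             allele1 = a1, allele2 = a2,
             genotype = paste(a1, a2, sep = "/"),
             stringsAsFactors = FALSE)
}

# observed allele-pair matrix over panel SNPs: n x p character "A/T" or NA
observed_panel_genotypes <- function(gm, panel) {
  idx <- match(panel$snps$snp_id, gm$snp_ids)
  if (anyNA(idx)) {
    # fall back to matching on position
    idx <- match(panel$snps$pos, gm$pos)
  }
  if (anyNA(idx)) stop("panel SNPs missing from the genotype matrix")
  sub <- gm$calls[, idx, drop = FALSE]
  maj <- gm$alleles$major[idx]; mnr <- gm$alleles$minor[idx]
  hom_maj <- matrix(paste(maj, maj, sep = "/"), nrow(sub), ncol(sub), byrow = TRUE)
  hom_min <- matrix(paste(mnr, mnr, sep = "/"), nrow(sub), ncol(sub), byrow = TRUE)
  het <- matrix(paste(pmin(maj, mnr), pmax(maj, mnr), sep = "/"),
                nrow(sub), ncol(sub), byrow = TRUE)
  out <- ifelse(is.na(sub), NA_character_,
         ifelse(sub == 0L, hom_maj, ifelse(sub == 1L, het, hom_min)))
  dimnames(out) <- list(gm$sample_ids, panel$snps$snp_id)
  out
}

#' Assign samples to haplogroups by expected-genotype matching
#'
#' For every sample and candidate haplogroup, counts the non-missing panel
#' SNPs whose observed genotype differs from the haplogroup's expected
#' genotype. Candidates must have fewer than `max_mismatch` mismatches
#' (strict) and satisfy all their discriminator rules (a rule is violated only
#' when the genotype is observed and lacks the required allele). A sample is
#' assigned the unique minimum-mismatch candidate; ties, no candidate, or
#' fewer than `min_informative` non-missing panel SNPs leave it unassigned.
#'
#' @param gm a [genotype_matrix()] holding the query samples (panel SNPs are
#'   matched by id, falling back to position).
#' @param panel a [build_panel()] result.
#' @param max_mismatch exclusive mismatch ceiling (default 2: assigned
#'   candidates have 0 or 1 mismatches).
#' @param min_informative minimum non-missing panel SNPs (default 5).
#' @return data.frame of class `hap_assignment`: sample_id, haplogroup (`NA`
#'   when unassigned), best_mismatch, n_informative, method; the per-candidate
#'   mismatch matrix is in attribute `mismatches`.
#' @export
assign_by_genotype <- function(gm, panel, max_mismatch = 2,
                               min_informative = 5) {
  obs <- observed_panel_genotypes(gm, panel)
  n_inf <- rowSums(!is.na(obs))
  haps <- panel$haplogroups
  mism <- matrix(NA_integer_, nrow(obs), length(haps),
                 dimnames = list(rownames(obs), haps))
  ok_disc <- matrix(TRUE, nrow(obs), length(haps),
                    dimnames = dimnames(mism))
  for (h in haps) {
    exp_g <- expected_genotypes(panel, h)
    expm <- matrix(exp_g$genotype, nrow(obs), ncol(obs), byrow = TRUE)
    mism[, h] <- rowSums(!is.na(obs) & obs != expm)
    rules <- panel$discriminators[panel$discriminators$haplogroup == h, ]
    if (nrow(rules)) {
      for (r in seq_len(nrow(rules))) {
        g_obs <- obs[, rules$snp_id[r]]
        has <- is.na(g_obs) |
          vapply(strsplit(g_obs, "/", fixed = TRUE),
                 function(p) rules$required_allele[r] %in% p, logical(1))
        has[is.na(has)] <- TRUE
        ok_disc[, h] <- ok_disc[, h] & has
      }
    }
  }
  cand <- mism < max_mismatch & ok_disc
  assigned <- rep(NA_character_, nrow(obs))
  best <- rep(NA_integer_, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    ci <- which(cand[i, ])
    if (!length(ci) || n_inf[i] < min_informative) next
    mm <- mism[i, ci]
    best[i] <- min(mm)
    winners <- ci[mm == min(mm)]
    if (length(winners) == 1) assigned[i] <- haps[winners]
  }
  assigned[n_inf < min_informative] <- NA_character_
  out <- data.frame(sample_id = rownames(obs),
                    haplogroup = assigned,
                    best_mismatch = best,
                    n_informative = n_inf,
                    method = "genotype-match",
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "mismatches") <- mism
  class(out) <- c("hap_assignment", "data.frame")
  out
}

#' Assign samples to haplogroups by joint phasing and clustering
#'
#' Queries are phased together with the reference genotypes over the shared
#' panel SNPs, the pooled haplotypes are clustered, every cluster inherits the
#' majority label of the reference haplotypes it contains, and each query is
#' assigned the Y-haplogroup label among its two haplotypes' clusters (if
#' any). Clusters without reference members leave their queries unassigned,
#' with a warning.
#'
#' @param query_gm query [genotype_matrix()] over the panel SNPs.
#' @param ref_gm reference genotypes over the same SNPs.
#' @param ref_labels data.frame with sample_id, hap1_group, hap2_group: the
#'   discovery group names of each reference sample's two haplotypes (as
#'   ordered in the discovery `phased_set`).
#' @param y_groups names of the Y-type groups among the labels.
#' @param k number of clusters for the joint clustering; defaults to the
#'   number of distinct reference labels.
#' @param ... passed to [em_phase()].
#' @return a `hap_assignment` data.frame (method `"cluster"`).
#' @export
assign_by_clustering <- function(query_gm, ref_gm, ref_labels, y_groups,
                                 k = NULL, ...) {
  common <- intersect(query_gm$snp_ids, ref_gm$snp_ids)
  if (length(common) < 2) stop("query and reference share too few SNPs")
  q <- gm_subset(query_gm, snps = common)
  r <- gm_subset(ref_gm, snps = common)
  calls <- rbind(q$calls, r$calls)
  phased <- em_phase(calls, ...)
  hm <- haplotype_matrix(phased)
  carriers <- attr(hm, "sample_id")
  if (is.null(k)) {
    k <- length(unique(c(ref_labels$hap1_group, ref_labels$hap2_group)))
  }
  labels <- cluster_haplotypes(hm, k = k)
  # reference haplotype labels: match each re-phased pair to the original
  # pair orientation by allele agreement
  ref_group <- rep(NA_character_, nrow(hm))
  for (i in seq_len(nrow(ref_labels))) {
    s <- ref_labels$sample_id[i]
    rows <- which(carriers == s)
    if (length(rows) != 2) next
    ref_group[rows] <- c(ref_labels$hap1_group[i], ref_labels$hap2_group[i])
  }
  cl_label <- rep(NA_character_, max(labels))
  for (cl in seq_len(max(labels))) {
    members <- ref_group[labels == cl]
    members <- members[!is.na(members)]
    if (length(members)) {
      tab <- sort(table(members), decreasing = TRUE)
      cl_label[cl] <- names(tab)[1]
    }
  }
  if (anyNA(cl_label)) {
    warning("cluster(s) without reference members: queries there unassigned")
  }
  hap_label <- cl_label[labels]
  assigned <- rep(NA_character_, length(q$sample_ids))
  for (i in seq_along(q$sample_ids)) {
    rows <- which(carriers == q$sample_ids[i])
    ys <- intersect(hap_label[rows], y_groups)
    if (length(ys) == 1) assigned[i] <- ys
  }
  out <- data.frame(sample_id = q$sample_ids,
                    haplogroup = assigned,
                    best_mismatch = NA_integer_,
                    n_informative = rowSums(!is.na(q$calls)),
                    method = "cluster",
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("hap_assignment", "data.frame")
  out
}

#' Sex-marker concordance of Y assignments
#'
#' Lists samples assigned to a Y haplogroup whose genetic sex is female.
#' Samples without genetic sex are excluded from the check.
#'
#' @param assignments a `hap_assignment` data.frame.
#' @param genetic_sex named vector (`sample_id` -> "M"/"F"/NA) or a data.frame
#'   with sample_id and genetic_sex columns.
#' @return character vector of violating sample ids.
#' @export
sex_concordance <- function(assignments, genetic_sex) {
  if (is.data.frame(genetic_sex)) {
    gs <- stats::setNames(genetic_sex$genetic_sex, genetic_sex$sample_id)
  } else {
    gs <- genetic_sex
  }
  sx <- gs[assignments$sample_id]
  assignments$sample_id[!is.na(assignments$haplogroup) &
                        !is.na(sx) & sx == "F"]
}

#' Per-population haplogroup frequency table
#'
#' Frequencies of each Y haplogroup among assigned males per population.
#' Populations with no assigned samples get counts only (frequencies `NA`).
#'
#' @param assignments a `hap_assignment` data.frame.
#' @param sample_table data.frame with sample_id and population columns.
#' @return data.frame: population, n_samples, n_assigned, then one frequency
#'   column per haplogroup; attribute `counts` holds the count matrix.
#' @export
haplogroup_frequency_table <- function(assignments, sample_table) {
  pop <- sample_table$population[match(assignments$sample_id,
                                       sample_table$sample_id)]
  haps <- sort(unique(stats::na.omit(assignments$haplogroup)))
  pops <- unique(sample_table$population)
  counts <- matrix(0L, length(pops), length(haps),
                   dimnames = list(pops, haps))
  for (p in pops) {
    sel <- !is.na(pop) & pop == p & !is.na(assignments$haplogroup)
    if (any(sel)) {
      tb <- table(assignments$haplogroup[sel])
      counts[p, names(tb)] <- as.integer(tb)
    }
  }
  n_assigned <- rowSums(counts)
  freqs <- counts / ifelse(n_assigned > 0, n_assigned, NA_real_)
  out <- data.frame(population = pops,
                    n_samples = as.integer(table(pop)[pops]),
                    n_assigned = as.integer(n_assigned),
                    freqs,
                    check.names = FALSE,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}

#' Overall assignment rate
#'
#' Percentage of samples assigned to any haplogroup, as printed in summaries
#' (e.g. 93 of 103 phenotypic males gives 90%).
#'
#' @param assignments a `hap_assignment` data.frame, or a logical vector of
#'   assigned/unassigned.
#' @param digits rounding for the percentage (default 0, matching reporting
#'   style).
#' @return percentage in \[0, 100\].
#' @export
hap_assignment_rate <- function(assignments, digits = 0) {
  ok <- if (is.data.frame(assignments)) !is.na(assignments$haplogroup)
        else as.logical(assignments)
  round(100 * mean(ok), digits)
}
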