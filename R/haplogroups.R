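# Haplogroup discovery: cluster phased haplotypes, classify clusters as X- or
# Y-type from carrier sex, name them, and extract diagnostic SNPs.

#' Cluster haplotypes with Ward's criterion
#'
#' Agglomerative clustering of 0/1 allele vectors under the Ward criterion
#' (minimum within-cluster sum-of-squares increase). Distances are squared
#' Euclidean distances over the allele codes, so merge heights equal the SS
#' increase of each merge; unknown sites are mean-imputed per SNP for the
#' distance computation only. With `k = "auto"` the cut maximising the mean
#' silhouette width over `k_range` is chosen (ties go to the smaller k).
#'
#' @param x a `phased_set` from [em_phase()] or a haplotypes x SNPs 0/1 matrix
#'   (`NA` = unknown).
#' @param k number of clusters, or `"auto"`.
#' @param k_range candidate k values for the silhouette search (default 2:10).
#' @return integer vector of cluster labels, one per haplotype, with
#'   attributes `hclust` (the dendrogram), `k`, `silhouette` (mean widths per
#'   candidate k when `k = "auto"`) and `sample_id` (carrier of each
#'   haplotype, when available).
#' @export
cluster_haplotypes <- function(x, k = "auto", k_range = 2:10) {
  hm <- if (inherits(x, "phased_set")) haplotype_matrix(x) else as.matrix(x)
  n <- nrow(hm)
  if (!identical(k, "auto") && k > n) {
    stop("k exceeds the number of haplotypes")
  }
  X <- hm
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    X[is.na(X[, j]), j] <- mu
  }
  d <- stats::dist(X)
  hc <- stats::hclust(d^2, method = "ward.D")
  sil <- NULL
  if (identical(k, "auto")) {
    k_range <- k_range[k_range < n & k_range >= 2]
    sil <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
    }, numeric(1))
    k <- k_range[which.max(sil)]
    names(sil) <- k_range
  }
  labels <- stats::cutree(hc, k)
  attr(labels, "hclust") <- hc
  attr(labels, "k") <- as.integer(k)
  attr(labels, "silhouette") <- sil
  attr(labels, "sample_id") <- attr(hm, "sample_id")
  labels
}

#' Classify clusters as X- or Y-type from carrier sex
#'
#' A haplotype cluster on an undifferentiated sex chromosome is called Y-type
#' when its haplotypes come predominantly from males: with `n_male` and
#' `n_female` sexed carriers, the cluster is `Y` if
#' `n_male / (n_male + n_female) >= male_frac_min`, `X` otherwise, and
#' `undetermined` when it has no sexed carriers. Unknown-sex carriers are
#' excluded from the fraction. The default threshold 0.8 sits below typical
#' observed male compositions of true Y clusters to tolerate visual-sexing
#' error.
#'
#' @param labels cluster labels per haplotype (from [cluster_haplotypes()]).
#' @param sexes carrier sex per haplotype: `"M"`, `"F"` or `NA`/other for
#'   unknown.
#' @param male_frac_min male-fraction threshold for a Y call (default 0.8).
#' @return data.frame: cluster, n_female, n_male, n_unknown, male_fraction,
#'   chrom_class.
#' @export
classify_sex_specific <- function(labels, sexes, male_frac_min = 0.8) {
  stopifnot(length(labels) == length(sexes))
  sx <- ifelse(sexes %in% c("M", "F"), sexes, NA_character_)
  cl <- sort(unique(labels))
  out <- data.frame(
    cluster = cl,
    n_female = vapply(cl, function(k) sum(labels == k & sx == "F", na.rm = TRUE), numeric(1)),
    n_male = vapply(cl, function(k) sum(labels == k & sx == "M", na.rm = TRUE), numeric(1)),
    n_unknown = vapply(cl, function(k) sum(labels == k & is.na(sx)), numeric(1)))
  sexed <- out$n_female + out$n_male
  out$male_fraction <- ifelse(sexed > 0, out$n_male / sexed, NA_real_)
  out$chrom_class <- ifelse(sexed == 0, "undetermined",
                     ifelse(out$male_fraction >= male_frac_min, "Y", "X"))
  out
}

#' Name haplogroups
#'
#' Y-type clusters are named `<chrom_label>-MH<i>` ("male haplogroup") with
#' the index assigned in decreasing order of carrier count; ties are broken by
#' the leftmost position at which the cluster consensus carries the minor
#' allele. X clusters are labelled `<chrom_label>-X` (suffixed by size rank if
#' several), undetermined clusters `<chrom_label>-U<i>`.
#'
#' @param labels cluster labels per haplotype.
#' @param classes classification table from [classify_sex_specific()].
#' @param chrom_label chromosome label used as the name prefix.
#' @param hm haplotype matrix (needed only for tie-breaking; optional).
#' @param pos SNP positions aligned to `hm` columns (optional).
#' @return data.frame: cluster, chrom_class, name, n_haplotypes.
#' @export
name_haplogroups <- function(labels, classes, chrom_label = "chr",
                             hm = NULL, pos = NULL) {
  size <- vapply(classes$cluster, function(k) sum(labels == k), numeric(1))
  leftmost <- rep(Inf, nrow(classes))
  if (!is.null(hm) && !is.null(pos)) {
    for (i in seq_len(nrow(classes))) {
      cons <- colMeans(hm[labels == classes$cluster[i], , drop = FALSE],
                       na.rm = TRUE)
      hit <- which(!is.nan(cons) & cons >= 0.5)
      if (length(hit)) leftmost[i] <- min(pos[hit])
    }
  }
  out <- data.frame(cluster = classes$cluster,
                    chrom_class = classes$chrom_class,
                    name = NA_character_,
                    n_haplotypes = size)
  for (cls in c("Y", "X", "undetermined")) {
    idx <- which(out$chrom_class == cls)
    if (!length(idx)) next
    idx <- idx[order(-size[idx], leftmost[idx], out$cluster[idx])]
    out$name[idx] <- switch(cls,
      Y = sprintf("%s-MH%d", chrom_label, seq_along(idx)),
      X = if (length(idx) == 1) sprintf("%s-X", chrom_label)
          else sprintf("%s-X%d", chrom_label, seq_along(idx)),
      undetermined = sprintf("%s-U%d", chrom_label, seq_along(idx)))
  }
  out
}

#' Per-group minor-allele frequency profile
#'
#' Frequency of the minor allele at every SNP within each haplotype group
#' (unknown sites ignored) - the numeric content of a logo-style allele
#' frequency plot. Major and minor frequencies sum to 1 at every SNP.
#'
#' @param hm haplotypes x SNPs 0/1 matrix.
#' @param groups group name per haplotype.
#' @return matrix groups x SNPs of minor-allele frequencies.
#' @export
allele_frequency_profile <- function(hm, groups) {
  gs <- sort(unique(groups))
  out <- t(vapply(gs, function(g) {
    colMeans(hm[groups == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(hm))))
  rownames(out) <- gs
  colnames(out) <- colnames(hm)
  out
}

#' Diagnostic SNPs: fixed differences between Y haplogroups and the X pool
#'
#' A SNP is diagnostic for a Y haplogroup when the absolute difference between
#' its minor-allele frequency in that haplogroup and in the pooled X-type
#' haplotypes is at least `fixed_threshold` ("fixed or nearly fixed"). SNPs
#' diagnostic for several haplogroups are emitted once per haplogroup, so
#' shared diagnostics are visible in the output.
#'
#' @param hm haplotypes x SNPs 0/1 matrix.
#' @param group_names haplogroup name per haplotype (from [name_haplogroups()]
#'   mapped over cluster labels).
#' @param y_groups names of the Y-type groups.
#' @param x_groups names of the X-type groups (pooled into one X frequency).
#' @param pos SNP positions aligned to `hm` columns.
#' @param alleles data.frame of `major`/`minor` labels aligned to columns.
#' @param fixed_threshold minimum frequency difference (default 0.95).
#' @return data.frame: snp_id, pos, haplogroup, x_allele, y_allele, freq_x,
#'   freq_hap, freq_diff.
#' @export
diagnostic_snps <- function(hm, group_names, y_groups, x_groups,
                            pos, alleles, fixed_threshold = 0.95) {
  x_rows <- group_names %in% x_groups
  freq_x <- colMeans(hm[x_rows, , drop = FALSE], na.rm = TRUE)
  snp_ids <- colnames(hm)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(hm)))
  out <- list()
  for (g in y_groups) {
    freq_g <- colMeans(hm[group_names == g, , drop = FALSE], na.rm = TRUE)
    diff <- abs(freq_g - freq_x)
    hit <- which(!is.nan(diff) & diff >= fixed_threshold)
    if (!length(hit)) next
    out[[g]] <- data.frame(
      snp_id = snp_ids[hit],
      pos = pos[hit],
      haplogroup = g,
      x_allele = ifelse(freq_x[hit] >= 0.5,
                        alleles$minor[hit], alleles$major[hit]),
      y_allele = ifelse(freq_g[hit] >= 0.5,
                        alleles$minor[hit], alleles$major[hit]),
      freq_x = unname(freq_x[hit]),
      freq_hap = unname(freq_g[hit]),
      freq_diff = unname(diff[hit]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(snp_id = character(0), pos = integer(0),
                      haplogroup = character(0), x_allele = character(0),
                      y_allele = character(0), freq_x = numeric(0),
                      freq_hap = numeric(0), freq_diff = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$haplogroup, res$pos), ]
}

#' Check the X/Y pairing invariant
#'
#' Every individual contributing a haplotype to a Y-type group should carry
#' its second haplotype in an X-type group (a diploid male has one X and one
#' Y). Returns the individuals violating this, i.e. those with two Y-type
#' haplotypes or a Y-type haplotype paired with an undetermined one.
#'
#' @param sample_ids carrier sample id per haplotype.
#' @param group_class chrom_class ("X"/"Y"/"undetermined") per haplotype.
#' @return character vector of violating sample ids (empty when the invariant
#'   holds).
#' @export
pairing_violations <- function(sample_ids, group_class) {
  bad <- character(0)
  for (s in unique(sample_ids[group_class == "Y"])) {
    partner <- group_class[sample_ids == s]
    if (sum(partner == "Y") > 1 || any(partner == "undetermined")) {
      bad <- c(bad, s)
    }
  }
  bad
}

# plain Rand index between two partitions
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  (tot + 2 * sij - si - sj) / tot
}
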