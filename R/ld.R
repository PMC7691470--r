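# Two-locus composite linkage disequilibrium from unphased genotypes.
#
# Haplotype frequencies for a SNP pair are estimated by EM on the 3x3 table of
# minor-allele dosages: every cell except the double heterozygote determines
# its two haplotypes; the double heterozygotes are split between cis and trans
# configurations at each E-step. Allele frequencies are preserved by the EM,
# so r2 = D^2 / (pA(1-pA) pB(1-pB)) with D = p11 - pA pB.

# counts: 3x3 matrix, rows = dosage at A (0,1,2), cols = dosage at B
ld_em_full <- function(counts, tol = 1e-10, max_iter = 100L) {
  n <- counts
  N <- sum(n)
  c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  c01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2]
  c00 <- 2 * n[1, 1] + n[2, 1] + n[1, 2]
  ndh <- n[2, 2]
  pA <- (c11 + c10 + ndh) / (2 * N)
  pB <- (c11 + c01 + ndh) / (2 * N)
  if (N == 0 || pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(list(r2 = NA_real_, D = NA_real_,
                freqs = c(p11 = NA, p10 = NA, p01 = NA, p00 = NA),
                loglik = NA_real_, trace = numeric(0), iterations = 0L))
  }
  # independence start
  p11 <- pA * pB; p10 <- pA * (1 - pB); p01 <- (1 - pA) * pB
  p00 <- (1 - pA) * (1 - pB)
  loglik <- function(p11, p10, p01, p00) {
    probs <- c(p00^2, 2 * p00 * p01, p01^2,
               2 * p00 * p10, 2 * (p11 * p00 + p10 * p01), 2 * p01 * p11,
               p10^2, 2 * p10 * p11, p11^2)
    cnt <- as.vector(t(n))  # row-major: (0,0),(0,1),(0,2),(1,0),(1,1),...
    keep <- cnt > 0
    sum(cnt[keep] * log(probs[keep]))
  }
  trace <- loglik(p11, p10, p01, p00)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- p11 * p00 + p10 * p01
    w <- if (denom > 0) p11 * p00 / denom else 0.5
    p11_new <- (c11 + w * ndh) / (2 * N)
    p00_new <- (c00 + w * ndh) / (2 * N)
    p10_new <- (c10 + (1 - w) * ndh) / (2 * N)
    p01_new <- (c01 + (1 - w) * ndh) / (2 * N)
    delta <- max(abs(c(p11_new - p11, p10_new - p10,
                       p01_new - p01, p00_new - p00)))
    p11 <- p11_new; p10 <- p10_new; p01 <- p01_new; p00 <- p00_new
    trace <- c(trace, loglik(p11, p10, p01, p00))
    if (delta < tol || it >= max_iter) break
  }
  D <- p11 - pA * pB
  list(r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)), D = D,
       freqs = c(p11 = p11, p10 = p10, p01 = p01, p00 = p00),
       loglik = trace[length(trace)], trace = trace, iterations = it)
}

#' Pairwise r-squared between two SNPs
#'
#' Composite linkage disequilibrium from unphased diploid genotypes: haplotype
#' frequencies are estimated by two-locus EM over the 3x3 dosage table
#' (double-heterozygote phase unknown, independence start, tolerance 1e-10, at
#' most 100 iterations), then `r2 = D^2 / (pA(1-pA) pB(1-pB))`. Samples
#' missing at either SNP are excluded. Returns `NA` when either SNP is
#' monomorphic among the jointly genotyped samples.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_i,snp_j SNP labels or column indices.
#' @param method `"em"` (default) or `"dosage"` (squared Pearson correlation
#'   of minor-allele dosages, a fast approximation).
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
pairwise_r2 <- function(gm, snp_i, snp_j, method = c("em", "dosage")) {
  method <- match.arg(method)
  i <- if (is.character(snp_i)) match(snp_i, gm$snp_ids) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, gm$snp_ids) else snp_j
  a <- gm$calls[, i]; b <- gm$calls[, j]
  ok <- !is.na(a) & !is.na(b)
  if (method == "dosage") {
    if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) return(NA_real_)
    return(stats::cor(a[ok], b[ok])^2)
  }
  # same code path as the all-pairs computation, so graph construction and
  # scalar queries agree exactly
  ld_r2_matrix(gm_subset(gm, snps = c(i, j)))[1, 2]
}

#' All-pairs r-squared matrix
#'
#' Vectorised form of [pairwise_r2()]: the nine dosage-pair count matrices are
#' obtained by indicator cross-products and the EM update runs simultaneously
#' on every pair. Monomorphic pairs get `NA`. The diagonal is `NA`.
#'
#' @inheritParams pairwise_r2
#' @param tol,max_iter EM stopping rule.
#' @return symmetric m x m matrix of r-squared values.
#' @export
ld_r2_matrix <- function(gm, method = c("em", "dosage"),
                         tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  calls <- gm$calls
  m <- ncol(calls)
  if (method == "dosage") {
    r <- suppressWarnings(stats::cor(calls, use = "pairwise.complete.obs"))
    r2 <- r^2
    diag(r2) <- NA_real_
    return(r2)
  }
  I0 <- (!is.na(calls) & calls == 0L) + 0
  I1 <- (!is.na(calls) & calls == 1L) + 0
  I2 <- (!is.na(calls) & calls == 2L) + 0
  n00 <- crossprod(I0, I0); n01 <- crossprod(I0, I1); n02 <- crossprod(I0, I2)
  n10 <- crossprod(I1, I0); n11 <- crossprod(I1, I1); n12 <- crossprod(I1, I2)
  n20 <- crossprod(I2, I0); n21 <- crossprod(I2, I1); n22 <- crossprod(I2, I2)
  N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  c11 <- 2 * n22 + n21 + n12
  c10 <- 2 * n20 + n21 + n10
  c01 <- 2 * n02 + n12 + n01
  c00 <- 2 * n00 + n10 + n01
  pA <- (c11 + c10 + n11) / (2 * N)
  pB <- (c11 + c01 + n11) / (2 * N)
  valid <- N > 0 & pA > 0 & pA < 1 & pB > 0 & pB < 1
  p11 <- pA * pB; p10 <- pA * (1 - pB); p01 <- (1 - pA) * pB
  p00 <- (1 - pA) * (1 - pB)
  for (it in seq_len(max_iter)) {
    denom <- p11 * p00 + p10 * p01
    w <- ifelse(denom > 0, p11 * p00 / denom, 0.5)
    p11n <- (c11 + w * n11) / (2 * N)
    p00n <- (c00 + w * n11) / (2 * N)
    p10n <- (c10 + (1 - w) * n11) / (2 * N)
    p01n <- (c01 + (1 - w) * n11) / (2 * N)
    delta <- max(abs(p11n - p11)[valid], abs(p10n - p10)[valid],
                 abs(p01n - p01)[valid], abs(p00n - p00)[valid], 0)
    p11 <- p11n; p10 <- p10n; p01 <- p01n; p00 <- p00n
    if (delta < tol) break
  }
  D <- p11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  r2[!valid] <- NA_real_
  diag(r2) <- NA_real_
  dimnames(r2) <- list(gm$snp_ids, gm$snp_ids)
  r2
}

#' Build the linkage-disequilibrium graph over SNPs
#'
#' Nodes are all SNPs of the matrix; an undirected edge joins two SNPs when
#' their r-squared is at least `r2_min` (inclusive threshold). All pairs
#' within the matrix are computed, so callers normally pass a single
#' chromosome (see [subset_chromosome()]).
#'
#' @inheritParams pairwise_r2
#' @param r2_min edge threshold in \[0, 1\] (default 0.3).
#' @return an \pkg{igraph} graph whose vertices carry `name`, `chrom` and
#'   `pos` attributes and whose edges carry `r2` weights.
#' @export
build_ld_graph <- function(gm, r2_min = 0.3, method = c("em", "dosage")) {
  if (!is.numeric(r2_min) || r2_min < 0 || r2_min > 1) {
    stop("r2_min must lie in [0, 1]")
  }
  r2 <- ld_r2_matrix(gm, method = method)
  adj <- !is.na(r2) & r2 >= r2_min
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(gm$snp_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = gm$snp_ids)
  g <- igraph::set_vertex_attr(g, "chrom", value = gm$chrom)
  g <- igraph::set_vertex_attr(g, "pos", value = gm$pos)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx), r2 = r2[idx])
  }
  g
}

#' Extract long-range high-LD blocks from the LD graph
#'
#' Connected components of the LD graph are filtered to those with at least
#' `min_snps` SNPs spanning at least `min_span` bp. Blocks are ordered by
#' their leftmost position. The union of the retained blocks' SNPs is what
#' gets phased downstream.
#'
#' @param graph LD graph from [build_ld_graph()].
#' @param min_snps minimum SNPs per block (default 5).
#' @param min_span minimum spanned bp (default 1e6).
#' @return object of class `ld_blocks`: a list of blocks (each with `snp_ids`,
#'   `n_snps`, `start`, `end`, `span_bp`) with the union SNP set in attribute
#'   `union_snps`.
#' @export
extract_blocks <- function(graph, min_snps = 5, min_span = 1e6) {
  comp <- igraph::components(graph)
  pos <- igraph::vertex_attr(graph, "pos")
  nm <- igraph::vertex_attr(graph, "name")
  blocks <- list()
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) < min_snps) next
    span <- max(pos[members]) - min(pos[members])
    if (span < min_span) next
    members <- members[order(pos[members])]
    blocks[[length(blocks) + 1L]] <- list(
      snp_ids = nm[members],
      n_snps = length(members),
      start = min(pos[members]),
      end = max(pos[members]),
      span_bp = span)
  }
  if (length(blocks)) {
    blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "start"))]
  }
  structure(blocks,
            class = "ld_blocks",
            union_snps = unique(unlist(lapply(blocks, `[[`, "snp_ids"))))
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat("ld_blocks:", length(x), "block(s),",
      length(attr(x, "union_snps")), "SNPs in total\n")
  if (length(x)) print(ld_block_summary(x))
  invisible(x)
}

#' Summarise LD blocks
#'
#' One row per block (id, SNP count, bounds, span). When the total number of
#' SNPs that entered the network analysis is supplied, the percentage of SNPs
#' captured by the blocks is attached as attribute `percent_of_snps`.
#'
#' @param blocks an `ld_blocks` object (or list of blocks).
#' @param n_snps_total optional total SNP count after filtering.
#' @return data.frame with columns block_id, n_snps, start, end, span_bp.
#' @export
ld_block_summary <- function(blocks, n_snps_total = NULL) {
  df <- data.frame(
    block_id = seq_along(blocks),
    n_snps = vapply(blocks, `[[`, numeric(1), "n_snps"),
    start = vapply(blocks, `[[`, numeric(1), "start"),
    end = vapply(blocks, `[[`, numeric(1), "end"),
    span_bp = vapply(blocks, `[[`, numeric(1), "span_bp"))
  if (!is.null(n_snps_total)) {
    attr(df, "percent_of_snps") <- 100 * sum(df$n_snps) / n_snps_total
  }
  df
}
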