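# Shared fixtures and independent oracles for the test suite.

# quick genotype_matrix from a calls matrix (defaults: one chromosome,
# positions 1 Mb apart, alleles A/C)
mk_gm <- function(calls, chrom = "chr1", pos = NULL, alleles = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  if (is.null(alleles)) {
    alleles <- data.frame(major = rep("A", m), minor = rep("C", m))
  }
  genotype_matrix(calls, chrom = rep(chrom, length.out = m), pos = pos,
                  alleles = alleles)
}

# reduced-size simulation sharing the default planted structure
tiny_sim_config <- function(...) {
  sim_config(samples_per_pop = 60, n_snps = 120, ...)
}

# ---- independent oracles ------------------------------------------------

# exhaustive EM for haplotype pool frequencies over ALL 2^m haplotypes,
# written independently of the package's partition-ligation code: plain
# loops, uniform start, no pool truncation.
brute_em_phase <- function(calls, iters = 2000, tol = 1e-12) {
  m <- ncol(calls)
  H <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  K <- nrow(H)
  hs <- apply(H, 1, paste, collapse = "")
  p <- rep(1 / K, K)
  n <- nrow(calls)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- calls[i, ]
    ok <- matrix(FALSE, K, K)
    for (a in 1:K) for (b in 1:K) {
      s <- H[a, ] + H[b, ]
      ok[a, b] <- all(is.na(g) | s == g)
    }
    pairs[[i]] <- which(ok, arr.ind = TRUE)
  }
  for (it in seq_len(iters)) {
    p_new <- rep(0, K)
    for (i in seq_len(n)) {
      pb <- p[pairs[[i]][, 1]] * p[pairs[[i]][, 2]]
      w <- pb / sum(pb)
      for (r in seq_len(nrow(pairs[[i]]))) {
        p_new[pairs[[i]][r, 1]] <- p_new[pairs[[i]][r, 1]] + w[r] / 2
        p_new[pairs[[i]][r, 2]] <- p_new[pairs[[i]][r, 2]] + w[r] / 2
      }
    }
    p_new <- p_new / n
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  stats::setNames(p, hs)
}

# maximum-likelihood r2 by exhaustive grid search over the cis-haplotype
# frequency (allele frequencies fixed at their sample values, which the EM
# preserves); step 1e-4 over the feasible range.
grid_ml_r2 <- function(counts, step = 1e-4) {
  n <- counts
  N <- sum(n)
  pA <- (2 * (n[3, 1] + n[3, 2] + n[3, 3]) + n[2, 1] + n[2, 2] + n[2, 3]) / (2 * N)
  pB <- (2 * (n[1, 3] + n[2, 3] + n[3, 3]) + n[1, 2] + n[2, 2] + n[3, 2]) / (2 * N)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(p11) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    if (min(p10, p01, p00) < -1e-12) return(-Inf)
    p10 <- max(p10, 0); p01 <- max(p01, 0); p00 <- max(p00, 0)
    probs <- matrix(c(
      p00^2, 2 * p00 * p01, p01^2,
      2 * p00 * p10, 2 * (p11 * p00 + p10 * p01), 2 * p01 * p11,
      p10^2, 2 * p10 * p11, p11^2), 3, 3, byrow = TRUE)
    keep <- n > 0
    if (any(probs[keep] <= 0)) return(-Inf)
    sum(n[keep] * log(probs[keep]))
  }, numeric(1))
  p11 <- grid[which.max(ll)]
  D <- p11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# dosage 3x3 table for two genotype vectors
dosage_table <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[ok], levels = 0:2), factor(b[ok], levels = 0:2))
  matrix(as.numeric(tab), 3, 3)
}

# naive Ward agglomeration computing true within-cluster SS increases from
# scratch at every step (no Lance-Williams shortcut); heights are 2 * delta-SS
# to match hclust(d^2, "ward.D") conventions.
naive_ward <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  merge_ids <- -seq_len(n)      # hclust convention: negatives = singletons
  merges <- matrix(0, n - 1, 2)
  heights <- numeric(n - 1)
  delta_ss <- function(A, B) {
    ca <- colMeans(X[A, , drop = FALSE]); cb <- colMeans(X[B, , drop = FALSE])
    (length(A) * length(B)) / (length(A) + length(B)) * sum((ca - cb)^2)
  }
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- delta_ss(clusters[[i]], clusters[[j]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(j, i) }
    }
    merges[s, ] <- sort(c(merge_ids[best[1]], merge_ids[best[2]]))
    heights[s] <- 2 * best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    merge_ids[best[1]] <- s
    clusters[[best[2]]] <- NULL
    merge_ids <- merge_ids[-best[2]]
  }
  list(merge = merges, height = heights)
}

# truth label per haplotype instance of a discovery fit: "X" or the planted
# haplogroup name, derived from the truth table (error-free construction:
# a male's Y haplotype carries the minor allele at his haplogroup's
# diagnostic SNPs)
truth_hap_labels <- function(fit, sim) {
  carrier <- attr(fit$hm, "sample_id")
  tr <- sim$truth$samples
  ts <- sim$truth$snps[match(fit$gm_union$snp_ids, sim$truth$snps$snp_id), ]
  true_sex <- tr$true_sex[match(carrier, tr$sample_id)]
  true_hap <- tr$true_hap[match(carrier, tr$sample_id)]
  out <- rep("X", nrow(fit$hm))
  for (i in which(true_sex == "M")) {
    tmpl <- as.integer(mapply(grepl,
      paste0("(^|,)", true_hap[i], "($|,)"), ts$hap_set))
    match_y <- sum(fit$hm[i, ] == tmpl, na.rm = TRUE)
    match_x <- sum(fit$hm[i, ] == 0L, na.rm = TRUE)
    if (match_y >= match_x) out[i] <- true_hap[i]
  }
  out
}
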