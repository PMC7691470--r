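# Haplotype phasing by partition-ligation EM.
#
# The SNP set is split into consecutive windows; within each window haplotype
# pool frequencies are estimated by EM (each individual's genotype likelihood
# sums over all compatible ordered haplotype pairs; missing sites are
# marginalised). Adjacent segments are then ligated: candidate joint
# haplotypes are the cross-products of the retained pools, truncated to the
# top_k highest initial frequencies, augmented with forced-compatible pairs
# for any individual left without a compatible pair, and refined by EM. The
# final pool spans all SNPs and each individual is assigned its most probable
# compatible pair.

# hap pool utilities ---------------------------------------------------------

hap_strings <- function(H) apply(H, 1, paste, collapse = "")

# all 2^w haplotypes over w SNPs (w capped by the window size)
enumerate_haps <- function(w) {
  stopifnot(w <= 12)
  H <- as.matrix(expand.grid(rep(list(0:1), w), KEEP.OUT.ATTRS = FALSE))
  H <- H[, rev(seq_len(w)), drop = FALSE]  # lexicographic order
  dimnames(H) <- NULL
  H[order(hap_strings(H)), , drop = FALSE]
}

# forced-compatible pair for one genotype vector (het sites split 0|1,
# missing sites set to 0 on both haplotypes)
forced_pair <- function(g) {
  h1 <- ifelse(is.na(g), 0L, ifelse(g == 2L, 1L, 0L))
  h2 <- ifelse(is.na(g), 0L, ifelse(g >= 1L, 1L, 0L))
  rbind(h1, h2)
}

# compatibility of every (ordered) pool pair with every genotype pattern.
# G: P x w patterns (0/1/2/NA); H: K x w pool. Returns list(pat, a, b).
compatible_pairs <- function(G, H) {
  K <- nrow(H); P <- nrow(G); w <- ncol(G)
  a_idx <- rep(seq_len(K), each = K)
  b_idx <- rep(seq_len(K), times = K)
  PS <- H[a_idx, , drop = FALSE] + H[b_idx, , drop = FALSE]  # K^2 x w dosages
  matches <- matrix(0L, P, K * K)
  for (v in 0:2) {
    Gv <- (!is.na(G) & G == v) + 0
    PSv <- (PS == v) + 0
    matches <- matches + Gv %*% t(PSv)
  }
  nonmiss <- rowSums(!is.na(G))
  ok <- matches == nonmiss
  idx <- which(ok, arr.ind = TRUE)
  list(pat = idx[, 1], a = a_idx[idx[, 2]], b = b_idx[idx[, 2]])
}

# EM over a fixed haplotype pool.
# G: P x w unique genotype patterns, cnt: pattern multiplicities.
pool_em <- function(G, cnt, H, p_init, tol, max_iter) {
  cp <- compatible_pairs(G, H)
  if (!length(cp$pat)) stop("no compatible haplotype pair for some genotypes")
  covered <- sort(unique(cp$pat))
  if (length(covered) < nrow(G)) {
    stop("pool does not cover all genotype patterns")
  }
  K <- nrow(H)
  N2 <- 2 * sum(cnt)
  p <- p_init / sum(p_init)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    pr <- p[cp$a] * p[cp$b]
    norm <- rowsum(pr, cp$pat)[, 1]            # per-pattern likelihood
    norm_safe <- pmax(norm, .Machine$double.xmin)
    wgt <- cnt[cp$pat] * pr / norm_safe[cp$pat]
    p_new <- (rowsum_vec(wgt, cp$a, K) + rowsum_vec(wgt, cp$b, K)) / N2
    ll <- sum(cnt * log(norm_safe))
    trace <- c(trace, ll)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  pr <- p[cp$a] * p[cp$b]
  norm <- pmax(rowsum(pr, cp$pat)[, 1], .Machine$double.xmin)
  list(p = p, loglik = sum(cnt * log(norm)), trace = trace, cp = cp)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# unique genotype patterns over a column range
genotype_patterns <- function(calls) {
  key <- apply(calls, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  u <- !duplicated(key)
  list(G = calls[u, , drop = FALSE],
       cnt = as.vector(table(key)[key[u]]),
       map = match(key, key[u]))
}

#' Phase genotypes into haplotypes by partition-ligation EM
#'
#' Estimates a pool of haplotypes with frequencies over the given SNPs and
#' assigns every individual its most probable compatible ordered haplotype
#' pair. Designed for SNP sets dominated by a small number of long conserved
#' haplotypes (for example a sex chromosome with non-recombining Y lineages);
#' it is not a general-purpose chromosome-scale phaser.
#'
#' @param gm a [genotype_matrix()] restricted to the SNPs to phase (typically
#'   the union of high-LD block SNPs), or a plain 0/1/2/NA matrix.
#' @param window maximum SNPs per EM window (default 6).
#' @param top_k haplotypes retained per ligation step (default 50).
#' @param tol EM convergence tolerance on frequency change (default 1e-6).
#' @param max_iter maximum EM iterations per stage (default 200).
#' @param seed integer seed controlling the symmetry-breaking jitter of the
#'   initial frequencies.
#' @return object of class `phased_set`:
#'   \describe{
#'     \item{h1, h2}{samples x SNPs matrices of allele codes (0 major,
#'       1 minor, `NA` at an individual's missing sites); `h1` is the
#'       lexicographically smaller haplotype of each pair}
#'     \item{pool}{data.frame of distinct haplotypes and EM frequencies}
#'     \item{loglik}{final model log-likelihood}
#'     \item{loglik_trace}{log-likelihood per iteration of the final EM}
#'     \item{flagged}{ids of individuals missing at every SNP (returned
#'       all-`NA`)}
#'   }
#' @export
em_phase <- function(gm, window = 6, top_k = 50, tol = 1e-6,
                     max_iter = 200, seed = 1L) {
  calls <- if (inherits(gm, "genotype_matrix")) gm$calls else as.matrix(gm)
  snp_ids <- colnames(calls)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(calls)))
  sample_ids <- rownames(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  m <- ncol(calls); n <- nrow(calls)
  if (m < 2 || n < 2) stop("phasing needs at least 2 SNPs and 2 individuals")
  set.seed(seed)

  all_missing <- rowSums(!is.na(calls)) == 0
  work <- calls[!all_missing, , drop = FALSE]
  if (nrow(work) < 1) stop("all individuals are missing at every SNP")

  # ---- window stage ----
  starts <- seq(1, m, by = window)
  segs <- lapply(starts, function(s) s:min(s + window - 1, m))
  pools <- vector("list", length(segs))
  freqs <- vector("list", length(segs))
  for (k in seq_along(segs)) {
    cols <- segs[[k]]
    H <- enumerate_haps(length(cols))
    pat <- genotype_patterns(work[, cols, drop = FALSE])
    p0 <- rep(1 / nrow(H), nrow(H)) + stats::runif(nrow(H), 0, 1e-3)
    fit <- pool_em(pat$G, pat$cnt, H, p0, tol, max_iter)
    keep <- order(fit$p, decreasing = TRUE)[seq_len(min(top_k, nrow(H)))]
    keep <- keep[fit$p[keep] > 0]
    pools[[k]] <- H[keep, , drop = FALSE]
    freqs[[k]] <- fit$p[keep] / sum(fit$p[keep])
  }

  # ---- ligation, left to right ----
  segA <- segs[[1]]; HA <- pools[[1]]; pA <- freqs[[1]]
  fit <- NULL
  for (k in seq_along(segs)[-1]) {
    segB <- segs[[k]]; HB <- pools[[k]]; pB <- freqs[[k]]
    cols <- c(segA, segB)
    ai <- rep(seq_len(nrow(HA)), each = nrow(HB))
    bi <- rep(seq_len(nrow(HB)), times = nrow(HA))
    Hj <- cbind(HA[ai, , drop = FALSE], HB[bi, , drop = FALSE])
    pj <- pA[ai] * pB[bi]
    ord <- order(pj, decreasing = TRUE)[seq_len(min(top_k, length(pj)))]
    Hj <- Hj[ord, , drop = FALSE]; pj <- pj[ord]
    pat <- genotype_patterns(work[, cols, drop = FALSE])
    # augment with forced pairs so every individual keeps a compatible pair
    cp <- compatible_pairs(pat$G, Hj)
    uncovered <- setdiff(seq_len(nrow(pat$G)), unique(cp$pat))
    for (i in uncovered) {
      fp <- forced_pair(pat$G[i, ])
      new <- fp[!(hap_strings(fp) %in% hap_strings(Hj)), , drop = FALSE]
      if (nrow(new)) {
        Hj <- rbind(Hj, new)
        pj <- c(pj, rep(1e-4, nrow(new)))
      }
    }
    dup <- duplicated(hap_strings(Hj))
    Hj <- Hj[!dup, , drop = FALSE]; pj <- pj[!dup]
    fit <- pool_em(pat$G, pat$cnt, Hj, pj / sum(pj), tol, max_iter)
    segA <- cols; HA <- Hj; pA <- fit$p
  }
  if (is.null(fit)) {  # single window: rerun to expose trace/cp on full set
    pat <- genotype_patterns(work)
    fit <- pool_em(pat$G, pat$cnt, HA, pA, tol, max_iter)
    pA <- fit$p
  } else {
    pat <- genotype_patterns(work)
  }

  # ---- assignment: most probable compatible pair per pattern ----
  H <- HA; p <- pA
  hs <- hap_strings(H)
  cp <- fit$cp
  pr <- p[cp$a] * p[cp$b]
  pair_key <- ifelse(hs[cp$a] <= hs[cp$b],
                     paste(hs[cp$a], hs[cp$b]),
                     paste(hs[cp$b], hs[cp$a]))
  best_a <- integer(nrow(pat$G)); best_b <- integer(nrow(pat$G))
  for (i in seq_len(nrow(pat$G))) {
    sel <- which(cp$pat == i)
    top <- sel[pr[sel] >= max(pr[sel]) * (1 - 1e-9)]
    pick <- top[order(pair_key[top])][1]           # deterministic tie-break
    a <- cp$a[pick]; b <- cp$b[pick]
    if (hs[a] <= hs[b]) { best_a[i] <- a; best_b[i] <- b }
    else { best_a[i] <- b; best_b[i] <- a }
  }

  h1 <- matrix(NA_integer_, n, m, dimnames = list(sample_ids, snp_ids))
  h2 <- h1
  wi <- which(!all_missing)
  h1[wi, ] <- H[best_a[pat$map], , drop = FALSE]
  h2[wi, ] <- H[best_b[pat$map], , drop = FALSE]
  # missing sites stay unknown in the output haplotypes
  h1[is.na(calls)] <- NA_integer_
  h2[is.na(calls)] <- NA_integer_

  used <- p > 1e-9
  pool <- data.frame(haplotype = hs[used], frequency = p[used],
                     stringsAsFactors = FALSE)
  pool <- pool[order(-pool$frequency, pool$haplotype), ]
  rownames(pool) <- NULL

  structure(
    list(h1 = h1, h2 = h2, pool = pool,
         loglik = fit$loglik, loglik_trace = fit$trace,
         flagged = sample_ids[all_missing],
         snp_ids = snp_ids, sample_ids = sample_ids),
    class = "phased_set")
}

#' @export
print.phased_set <- function(x, ...) {
  cat("phased_set:", length(x$sample_ids), "individuals x",
      length(x$snp_ids), "SNPs;",
      nrow(x$pool), "haplotypes in pool; loglik",
      sprintf("%.2f", x$loglik), "\n")
  if (length(x$flagged)) {
    cat("  flagged (all-missing):", length(x$flagged), "individuals\n")
  }
  invisible(x)
}

#' Haplotype matrix of a phased set
#'
#' Stacks each individual's two haplotypes into a `(2n) x m` matrix of 0/1
#' allele codes (`NA` = unknown). Row names are `<sample_id>.1` / `.2`;
#' all-missing individuals are dropped.
#'
#' @param phased a [em_phase()] result.
#' @return integer matrix with a `sample_id` attribute mapping rows to samples.
#' @export
haplotype_matrix <- function(phased) {
  keep <- setdiff(phased$sample_ids, phased$flagged)
  ki <- match(keep, phased$sample_ids)
  hm <- rbind(phased$h1[ki, , drop = FALSE], phased$h2[ki, , drop = FALSE])
  ord <- order(rep(seq_along(ki), 2), rep(1:2, each = length(ki)))
  hm <- hm[ord, , drop = FALSE]
  rownames(hm) <- paste(rep(keep, each = 2), 1:2, sep = ".")
  attr(hm, "sample_id") <- rep(keep, each = 2)
  hm
}

#' Write phased haplotypes to TSV
#'
#' @param phased a [em_phase()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotypes_tsv <- function(phased, path) {
  hm <- haplotype_matrix(phased)
  df <- data.frame(
    sample_id = attr(hm, "sample_id"),
    haplotype_index = rep(1:2, length.out = nrow(hm)),
    ifelse(is.na(hm), ".", hm),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- phased$snp_ids
  write_tsv(df, path)
  invisible(path)
}
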