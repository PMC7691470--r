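test_that("identical genotype columns give r2 = 1", {
  col <- c(0, 0, 0, 2, 2, 0, 2, 0, 0, 2)   # hom-only: phase unambiguous
  gm <- mk_gm(cbind(col, col))
  expect_equal(pairwise_r2(gm, 1, 2), 1, tolerance = 1e-12)
  col2 <- c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2)  # with double heterozygotes
  gm2 <- mk_gm(cbind(col2, col2))
  expect_equal(pairwise_r2(gm2, 1, 2), 1, tolerance = 1e-6)
})

test_that("EM equals direct haplotype counting when no double heterozygotes", {
  # hand-built 20-sample dosage table with an empty double-het cell
  counts <- matrix(c(6, 3, 1,
                     4, 0, 2,
                     1, 1, 2), 3, 3, byrow = TRUE)
  calls <- cbind(rep(0:2, rowSums(counts)),
                 unlist(lapply(1:3, function(i) rep(0:2, counts[i, ]))))
  gm <- mk_gm(calls)
  # closed form: every haplotype is countable directly
  c11 <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  c10 <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1]
  c01 <- 2 * counts[1, 3] + counts[2, 3] + counts[1, 2]
  N2 <- 2 * sum(counts)
  pA <- (c11 + c10) / N2
  pB <- (c11 + c01) / N2
  D <- c11 / N2 - pA * pB
  r2_direct <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(pairwise_r2(gm, 1, 2), r2_direct, tolerance = 1e-12)
})

test_that("independent SNPs at equilibrium have near-zero r2", {
  set.seed(101)
  n <- 10000
  gm <- mk_gm(cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4)))
  expect_lt(pairwise_r2(gm, 1, 2), 0.01)
})

test_that("r2 is symmetric and invariant to allele label swaps", {
  set.seed(102)
  for (rep in 1:5) {
    a <- rbinom(40, 2, runif(1, 0.2, 0.8))
    b <- ifelse(runif(40) < 0.7, a, rbinom(40, 2, 0.5))
    if (var(a) == 0 || var(b) == 0) next
    gm <- mk_gm(cbind(a, b))
    r12 <- pairwise_r2(gm, 1, 2)
    expect_equal(r12, pairwise_r2(gm, 2, 1))
    gm_swap <- mk_gm(cbind(2 - a, b))     # relabel major/minor at SNP 1
    expect_equal(pairwise_r2(gm_swap, 1, 2), r12, tolerance = 1e-9)
  }
})

test_that("EM log-likelihood never decreases", {
  set.seed(103)
  for (rep in 1:10) {
    a <- rbinom(30, 2, runif(1, 0.1, 0.9))
    b <- ifelse(runif(30) < 0.5, a, rbinom(30, 2, runif(1, 0.1, 0.9)))
    res <- yhapnet:::ld_em_full(dosage_table(a, b))
    if (length(res$trace) > 1) {
      expect_true(all(diff(res$trace) >= -1e-9))
    }
  }
})

test_that("EM r2 matches exhaustive-grid maximum likelihood", {
  set.seed(104)
  done <- 0
  while (done < 8) {
    n <- sample(20:50, 1)
    pa <- runif(1, 0.15, 0.85)
    hap1 <- rbinom(n, 1, pa); hap2 <- rbinom(n, 1, pa)
    flip <- runif(1, 0, 0.5)
    b1 <- ifelse(runif(n) < flip, 1 - hap1, hap1)
    b2 <- ifelse(runif(n) < flip, 1 - hap2, hap2)
    a <- hap1 + hap2; b <- b1 + b2
    if (var(a) == 0 || var(b) == 0) next
    counts <- dosage_table(a, b)
    r2_em <- yhapnet:::ld_em_full(counts)$r2
    expect_lt(abs(r2_em - grid_ml_r2(counts)), 1e-3)   # grid step limits this
    done <- done + 1
  }
})

test_that("the vectorised all-pairs r2 agrees with the scalar EM", {
  set.seed(105)
  calls <- matrix(rbinom(200, 2, 0.4), 40, 5)
  calls[sample(200, 10)] <- NA
  gm <- mk_gm(calls)
  R <- ld_r2_matrix(gm)
  for (i in 1:4) for (j in (i + 1):5) {
    full <- yhapnet:::ld_em_full(dosage_table(calls[, i], calls[, j]))$r2
    expect_equal(R[i, j], full, tolerance = 1e-6)
  }
  expect_equal(R, t(R))
})

test_that("the graph edge threshold is inclusive", {
  set.seed(106)
  a <- rbinom(60, 2, 0.5)
  b <- ifelse(runif(60) < 0.8, a, rbinom(60, 2, 0.5))
  gm <- mk_gm(cbind(a, b))
  r2v <- pairwise_r2(gm, 1, 2)
  g_at <- build_ld_graph(gm, r2_min = r2v)
  expect_equal(igraph::ecount(g_at), 1)       # edge at exactly the threshold
  g_above <- build_ld_graph(gm, r2_min = min(1, r2v + 1e-9))
  expect_equal(igraph::ecount(g_above), 0)
  expect_error(build_ld_graph(gm, r2_min = 1.5), "\\[0, 1\\]")
})

test_that("a planted perfect-LD block forms a clique", {
  # 6 SNPs carried together on one haplotype: half the samples het at all
  calls <- rbind(matrix(1L, 10, 6), matrix(0L, 10, 6))
  gm <- mk_gm(calls)
  g <- build_ld_graph(gm, r2_min = 0.3)
  expect_equal(igraph::ecount(g), choose(6, 2))
})

test_that("block extraction enforces SNP count and span", {
  mk_graph <- function(n, span) {
    g <- igraph::make_full_graph(n)
    igraph::set_vertex_attr(g, "pos", value = round(seq(1, span, length.out = n))) |>
      igraph::set_vertex_attr("name", value = paste0("s", 1:n))
  }
  expect_length(extract_blocks(mk_graph(4, 2e6)), 0)   # too few SNPs
  expect_length(extract_blocks(mk_graph(8, 5e5)), 0)   # too short
  b <- extract_blocks(mk_graph(8, 2e6))
  expect_length(b, 1)
  expect_equal(b[[1]]$n_snps, 8)
  expect_equal(b[[1]]$span_bp, 2e6 - 1)
  # empty graph
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(extract_blocks(g0), 0)
})

test_that("planted blocks are recovered exactly from simulated data", {
  sim <- simulate_ychap(sim_config(samples_per_pop = 100, n_snps = 200,
                                   seed = 37L))
  gm <- filter_snps(subset_chromosome(sim$gm, "Ots17"))
  hd <- hdplot_stats(gm, list(ref = sim$depths$ref[, gm$snp_ids],
                              alt = sim$depths$alt[, gm$snp_ids]))
  gm <- gm_subset(gm, snps = which(!hd$paralog_flag))
  blocks <- extract_blocks(build_ld_graph(gm))
  ts <- sim$truth$snps
  planted <- split(ts$snp_id[ts$diagnostic], ts$block[ts$diagnostic])
  expect_length(blocks, length(planted))
  for (i in seq_along(blocks)) {
    expect_setequal(blocks[[i]]$snp_ids, planted[[i]])
  }
  # spans echo the planted megabase-scale structure
  spans <- vapply(blocks, `[[`, numeric(1), "span_bp")
  expect_true(all(spans >= 4e6 & spans <= 10e6))
})
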