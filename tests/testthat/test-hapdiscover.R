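test_that("separable haplotype families split perfectly at k = 2", {
  hm <- rbind(matrix(0L, 6, 8), matrix(1L, 5, 8))
  labels <- cluster_haplotypes(hm, k = 2)
  expect_equal(length(unique(labels[1:6])), 1)
  expect_equal(length(unique(labels[7:11])), 1)
  expect_false(labels[1] == labels[7])
  expect_error(cluster_haplotypes(hm, k = 20), "exceeds")
})

test_that("Ward merges match a naive sum-of-squares agglomeration", {
  set.seed(301)
  for (rep in 1:4) {
    # continuous profiles keep all pairwise SS increases distinct
    X <- matrix(round(runif(7 * 6), 3), 7, 6)
    labels <- cluster_haplotypes(X, k = 2)
    hc <- attr(labels, "hclust")
    oracle <- naive_ward(X)
    expect_equal(hc$height, oracle$height, tolerance = 1e-9)
    expect_equal(t(apply(hc$merge, 1, sort)),
                 t(apply(oracle$merge, 1, sort)))
  }
})

test_that("clustering is invariant under haplotype order permutation", {
  set.seed(302)
  hm <- rbind(matrix(rbinom(40, 1, 0.1), 5, 8),
              matrix(rbinom(40, 1, 0.9), 5, 8))
  l1 <- cluster_haplotypes(hm, k = 2)
  perm <- sample(nrow(hm))
  l2 <- cluster_haplotypes(hm[perm, ], k = 2)
  expect_equal(yhapnet:::rand_index(l1[perm], l2), 1)
})

test_that("sex composition drives the X/Y call", {
  labels <- rep(1:3, c(22, 282, 4))
  sexes <- c(rep("M", 21), "F",                     # cluster 1: 21 M / 1 F
             rep("M", 114), rep("F", 168),          # cluster 2: mostly F
             rep(NA, 4))                            # cluster 3: unsexed
  cls <- classify_sex_specific(labels, sexes)
  expect_equal(cls$male_fraction[1], 21 / 22)
  expect_equal(cls$chrom_class[1], "Y")
  expect_equal(cls$male_fraction[2], 114 / 282, tolerance = 1e-12)
  expect_equal(cls$chrom_class[2], "X")
  expect_equal(cls$chrom_class[3], "undetermined")
  # unknown-sex carriers are excluded from the fraction
  cls2 <- classify_sex_specific(c(1, 1, 1), c("M", NA, NA))
  expect_equal(cls2$male_fraction, 1)
})

test_that("haplogroups are named by decreasing size with positional ties", {
  labels <- rep(1:5, c(200, 150, 80, 60, 300))
  sexes <- c(rep("M", 490), rep("F", 300))
  cls <- classify_sex_specific(labels, sexes)
  nm <- name_haplogroups(labels, cls, chrom_label = "Ots17")
  expect_equal(nm$name[nm$cluster == 1], "Ots17-MH1")
  expect_equal(nm$name[nm$cluster == 2], "Ots17-MH2")
  expect_equal(nm$name[nm$cluster == 3], "Ots17-MH3")
  expect_equal(nm$name[nm$cluster == 4], "Ots17-MH4")
  expect_equal(nm$name[nm$cluster == 5], "Ots17-X")

  # equal sizes: the cluster whose minor-consensus starts further left wins
  labels2 <- rep(1:3, c(10, 10, 30))
  sexes2 <- c(rep("M", 20), rep("F", 30))
  hm <- rbind(cbind(matrix(0L, 10, 2), matrix(1L, 10, 2)),
              cbind(matrix(1L, 10, 2), matrix(0L, 10, 2)),
              matrix(0L, 30, 4))
  cls2 <- classify_sex_specific(labels2, sexes2)
  nm2 <- name_haplogroups(labels2, cls2, "Ots17", hm = hm,
                          pos = c(1e6, 2e6, 3e6, 4e6))
  expect_equal(nm2$name[nm2$cluster == 2], "Ots17-MH1")  # leftmost minor
  expect_equal(nm2$name[nm2$cluster == 1], "Ots17-MH2")

  # no Y clusters: only the X label is emitted
  cls3 <- classify_sex_specific(rep(1, 4), rep("F", 4))
  nm3 <- name_haplogroups(rep(1, 4), cls3, "Ots17")
  expect_equal(nm3$name, "Ots17-X")
})

test_that("allele frequency profiles are normalised per SNP", {
  hm <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 0, 0))
  prof <- allele_frequency_profile(hm, rep("G1", 3))
  expect_equal(unname(prof["G1", ]), c(1, 0, 1 / 3))
  # identical haplotypes: all frequencies 0 or 1
  prof2 <- allele_frequency_profile(rbind(c(1, 0), c(1, 0)), rep("G", 2))
  expect_true(all(prof2 %in% c(0, 1)))
  # major + minor frequency sums to 1 by construction
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("diagnostic SNPs require a near-fixed frequency difference", {
  # group G1 fixed minor at SNPs 1-2; X carries 6% minor at SNP 2
  hm <- rbind(matrix(c(1, 1, 0), 10, 3, byrow = TRUE),         # G1
              cbind(rep(0, 50), rep(c(1, 0), c(3, 47)), rep(0, 50)))  # X
  colnames(hm) <- paste0("snp", 1:3)
  groups <- rep(c("G1", "X"), c(10, 50))
  d <- diagnostic_snps(hm, groups, y_groups = "G1", x_groups = "X",
                       pos = c(1e6, 2e6, 3e6),
                       alleles = data.frame(major = rep("A", 3),
                                            minor = rep("T", 3)),
                       fixed_threshold = 0.95)
  expect_equal(d$snp_id, "snp1")        # 1.0 vs 0.0 -> diagnostic
  expect_equal(d$x_allele, "A")
  expect_equal(d$y_allele, "T")
  expect_equal(d$freq_diff, 1)
  # SNP 2: diff 0.94 < 0.95 -> not diagnostic
  expect_false("snp2" %in% d$snp_id)
})

test_that("discovery on simulated data recovers the planted structure", {
  sim <- simulate_ychap(sim_config(samples_per_pop = 100, n_snps = 200,
                                   seed = 43L))
  fit <- yhap_discover(sim$gm, sim$samples, depths = sim$depths,
                       chrom = "Ots17", seed = 11L)
  # one X pool + the four planted Y haplogroups
  expect_equal(sum(fit$groups$chrom_class == "Y"), 4)
  truth <- truth_hap_labels(fit, sim)
  ri <- yhapnet:::rand_index(as.integer(factor(truth)),
                             as.integer(fit$labels))
  expect_gte(ri, 0.95)
  # diagnostics match the planted diagnostic sets per haplogroup
  ts <- sim$truth$snps
  tab <- table(fit$group_names, truth)
  for (g in fit$y_groups) {
    planted_name <- colnames(tab)[which.max(tab[g, ])]
    planted <- ts$snp_id[grepl(paste0("(^|,)", planted_name, "($|,)"),
                               ts$hap_set)]
    found <- fit$diagnostics$snp_id[fit$diagnostics$haplogroup == g]
    precision <- mean(found %in% planted)
    recall <- mean(planted %in% found)
    expect_gte(precision, 0.9)
    expect_gte(recall, 0.9)
  }
})

test_that("Y carriers have their partner haplotype in an X group", {
  sim <- simulate_ychap(sim_config(samples_per_pop = 75, n_snps = 120,
                                   genotyping_error_rate = 0,
                                   missing_rate = 0, missexing_rate = 0,
                                   paralog_fraction = 0, seed = 47L))
  fit <- yhap_discover(sim$gm, sim$samples, depths = sim$depths,
                       chrom = "Ots17", seed = 13L)
  expect_length(fit$pairing_violations, 0)
  # a planted violation is caught
  viol <- pairing_violations(c("s1", "s1", "s2", "s2"),
                             c("Y", "Y", "Y", "X"))
  expect_equal(viol, "s1")
})
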