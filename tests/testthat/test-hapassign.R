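# hand-built panel: two haplogroups, three diagnostic SNPs each
mk_test_panel <- function() {
  diag <- data.frame(
    snp_id = paste0("s", 1:6),
    pos = 1:6 * 1e6,
    haplogroup = rep(c("MH1", "MH2"), each = 3),
    x_allele = "A",
    y_allele = "T",
    freq_x = 0, freq_hap = 1, freq_diff = 1,
    stringsAsFactors = FALSE)
  build_panel(diag)
}

# genotype matrix over the panel SNPs from dosage rows (0 = A/A hom-major)
mk_panel_gm <- function(rows) {
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(rows)
  genotype_matrix(calls, chrom = rep("c1", 6), pos = 1:6 * 1e6,
                  alleles = data.frame(major = rep("A", 6),
                                       minor = rep("T", 6)),
                  sample_ids = names(rows), snp_ids = paste0("s", 1:6))
}

test_that("expected genotypes assume X/Y fixation", {
  panel <- mk_test_panel()
  eg <- expected_genotypes(panel, "MH1")
  expect_equal(eg$genotype, c("A/T", "A/T", "A/T", "A/A", "A/A", "A/A"))
  eg2 <- expected_genotypes(panel, "MH2")
  expect_equal(eg2$genotype, c("A/A", "A/A", "A/A", "A/T", "A/T", "A/T"))
  expect_error(expected_genotypes(panel, "MH9"), "not in panel")
})

test_that("expected genotypes reproduce error-free simulated males", {
  sim <- simulate_ychap(tiny_sim_config(genotyping_error_rate = 0,
                                        missing_rate = 0,
                                        paralog_fraction = 0,
                                        missexing_rate = 0, seed = 53L))
  fit <- yhap_discover(sim$gm, sim$samples, depths = sim$depths,
                       chrom = "Ots17", seed = 3L)
  obs <- yhapnet:::observed_panel_genotypes(
    gm_subset(sim$gm, snps = fit$panel$snps$snp_id), fit$panel)
  truth <- truth_hap_labels(fit, sim)
  carrier <- attr(fit$hm, "sample_id")
  # one carrier per discovered group, via the truth mapping
  tab <- table(fit$group_names, truth)
  for (g in fit$y_groups) {
    s <- carrier[fit$group_names == g][1]
    eg <- expected_genotypes(fit$panel, g)
    expect_equal(unname(obs[s, ]), eg$genotype)
  }
})

test_that("assignment needs < 2 mismatches, unique minimum, discriminators", {
  panel <- mk_test_panel()
  g <- mk_panel_gm(list(
    perfect1 = c(1, 1, 1, 0, 0, 0),        # 0 mismatches to MH1
    one_mm   = c(1, 1, 0, 0, 0, 0),        # 1 mismatch to MH1
    two_mm   = c(1, 0, 0, 0, 0, 0),        # 2 mismatches to MH1 -> out
    tie      = c(1, 1, 1, 1, 1, 1),        # 3 vs 3: tie -> unassigned
    sparse   = c(1, 1, NA, NA, NA, NA),    # < 5 informative -> unassigned
    female   = c(0, 0, 0, 0, 0, 0)))       # >= 3 mismatches everywhere
  asn <- assign_by_genotype(g, panel)
  expect_equal(asn$haplogroup[asn$sample_id == "perfect1"], "MH1")
  expect_equal(asn$haplogroup[asn$sample_id == "one_mm"], "MH1")
  expect_true(is.na(asn$haplogroup[asn$sample_id == "two_mm"]))
  expect_true(is.na(asn$haplogroup[asn$sample_id == "tie"]))
  expect_true(is.na(asn$haplogroup[asn$sample_id == "sparse"]))
  expect_true(is.na(asn$haplogroup[asn$sample_id == "female"]))
  mm <- attr(asn, "mismatches")
  expect_equal(unname(mm["two_mm", "MH1"]), 2)
  expect_equal(unname(mm["female", "MH1"]), 3)
})

test_that("discriminator rules block candidates lacking their alleles", {
  # MH1 and MH2 differ at only two SNPs: rules are auto-generated
  diag <- data.frame(
    snp_id = paste0("s", 1:6), pos = 1:6 * 1e6,
    haplogroup = c("MH1", "MH1", "MH1", "MH1", "MH2", "MH2"),
    x_allele = "A", y_allele = "T",
    freq_x = 0, freq_hap = 1, freq_diff = 1, stringsAsFactors = FALSE)
  # make MH2 share MH1's first four diagnostics
  diag <- rbind(diag, transform(diag[1:4, ], haplogroup = "MH2"))
  panel <- build_panel(diag)
  # MH1 vs MH2 differ only at s5, s6 (MH2-only): discriminators exist
  expect_true(all(c("s5", "s6") %in% panel$discriminators$snp_id))
  expect_true("MH2" %in% panel$discriminators$haplogroup)
  g <- mk_panel_gm(list(
    mh2_ok   = c(1, 1, 1, 1, 1, 1),
    mh2_miss = c(1, 1, 1, 1, 0, 1)))  # lacks T at s5: fails MH2 rule
  asn <- assign_by_genotype(g, panel)
  expect_equal(asn$haplogroup[1], "MH2")
  # second sample: 1 mismatch to MH2 but the discriminator vetoes it,
  # and it has 1 mismatch to MH1 at s5? no: s5 reads A/A, MH1 expects A/A.
  # mismatches to MH1: s6 het = 1 mismatch -> assigned MH1
  expect_equal(asn$haplogroup[2], "MH1")
})

test_that("dropping a haplogroup's diagnostics unassigns its carriers", {
  sim <- simulate_ychap(tiny_sim_config(seed = 59L))
  fit <- yhap_discover(sim$gm, sim$samples, depths = sim$depths,
                       chrom = "Ots17", seed = 3L)
  g_drop <- fit$y_groups[1]
  pruned <- build_panel(fit$diagnostics[fit$diagnostics$haplogroup != g_drop, ])
  asn_full <- predict(fit, sim$gm)
  asn_pruned <- assign_by_genotype(sim$gm, pruned)
  carriers <- asn_full$sample_id[!is.na(asn_full$haplogroup) &
                                 asn_full$haplogroup == g_drop]
  got <- asn_pruned$haplogroup[match(carriers, asn_pruned$sample_id)]
  expect_true(all(is.na(got)))
})

test_that("genotype and clustering assignments agree on shared calls", {
  sim <- simulate_ychap(tiny_sim_config(seed = 61L))
  fit <- yhap_discover(sim$gm, sim$samples, depths = sim$depths,
                       chrom = "Ots17", seed = 3L)
  # hold out 60 samples as GT-seq-style queries
  set.seed(62)
  query_ids <- sample(sim$gm$sample_ids, 60)
  q_gm <- gm_subset(sim$gm, samples = query_ids)
  asn_g <- predict(fit, q_gm, method = "genotype")
  asn_c <- suppressWarnings(predict(fit, q_gm, method = "cluster", seed = 9L))
  both <- !is.na(asn_g$haplogroup) & !is.na(asn_c$haplogroup)
  expect_gt(sum(both), 10)
  expect_gte(mean(asn_g$haplogroup[both] == asn_c$haplogroup[both]), 0.95)
  # a query identical to a reference Y carrier gets that carrier's group
  ref_carrier <- attr(fit$hm, "sample_id")[match(fit$y_groups[1],
                                                 fit$group_names)]
  q1 <- gm_subset(sim$gm, samples = ref_carrier)
  expect_equal(predict(fit, q1)$haplogroup, fit$y_groups[1])
})

test_that("an all-missing query is unassigned", {
  panel <- mk_test_panel()
  g <- mk_panel_gm(list(empty = rep(NA, 6)))
  asn <- assign_by_genotype(g, panel)
  expect_true(is.na(asn$haplogroup))
  expect_equal(asn$n_informative, 0)
})

test_that("sex concordance flags planted female Y carriers", {
  asn <- structure(data.frame(sample_id = c("a", "b", "c", "d"),
                              haplogroup = c("MH1", NA, "MH2", "MH1"),
                              stringsAsFactors = FALSE),
                   class = c("hap_assignment", "data.frame"))
  gs <- c(a = "M", b = "F", c = "F", d = NA)
  expect_equal(sex_concordance(asn, gs), "c")  # d lacks genetic sex: excluded
})

test_that("frequency tables normalise per population", {
  asn <- structure(data.frame(
    sample_id = paste0("s", 1:8),
    haplogroup = c("MH1", "MH1", "MH1", "MH2", NA, NA, NA, NA),
    stringsAsFactors = FALSE), class = c("hap_assignment", "data.frame"))
  st <- data.frame(sample_id = paste0("s", 1:8),
                   population = rep(c("P1", "P2"), c(5, 3)))
  ft <- haplogroup_frequency_table(asn, st)
  expect_equal(ft$MH1[ft$population == "P1"], 0.75)
  expect_equal(ft$MH2[ft$population == "P1"], 0.25)
  expect_true(is.na(ft$MH1[ft$population == "P2"]))   # none assigned
  # published-style row: counts 47/47/2/4 give frequencies summing to 1
  asn2 <- structure(data.frame(
    sample_id = paste0("m", 1:100),
    haplogroup = rep(paste0("MH", 1:4), c(47, 47, 2, 4)),
    stringsAsFactors = FALSE), class = c("hap_assignment", "data.frame"))
  st2 <- data.frame(sample_id = paste0("m", 1:100), population = "Anvik")
  ft2 <- haplogroup_frequency_table(asn2, st2)
  expect_equal(unname(unlist(ft2[1, paste0("MH", 1:4)])),
               c(0.47, 0.47, 0.02, 0.04))
  expect_equal(sum(ft2[1, paste0("MH", 1:4)]), 1)
})
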