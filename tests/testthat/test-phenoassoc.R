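test_that("European age notation parses with the incubation year", {
  r <- parse_age_euro("1.3")
  expect_equal(r$freshwater_years, 1)
  expect_equal(r$ocean_years, 3)
  expect_equal(r$total_age_years, 5)
  expect_equal(parse_age_euro("0.1")$total_age_years, 2)
  v <- parse_age_euro(c("1.2", "2.4"))
  expect_equal(v$total_age_years, c(4, 7))
  expect_error(parse_age_euro("1x3"), "malformed")
  expect_error(parse_age_euro("5"), "malformed")
})

test_that("balanced two-factor ANOVA matches hand-computed sums of squares", {
  # 2 haplogroups x 2 populations x 3 replicates
  hap <- rep(rep(c("H1", "H2"), each = 3), 2)
  pop <- rep(c("P1", "P2"), each = 6)
  y <- c(10, 12, 11, 15, 16, 14, 13, 12, 14, 18, 17, 19)
  at <- anova_factor(y, hap, pop)
  # hand formulas: balanced design, so Type II equals the classical SS
  grand <- mean(y)
  ss_hap <- sum(tapply(y, hap, length) * (tapply(y, hap, mean) - grand)^2)
  ss_pop <- sum(tapply(y, pop, length) * (tapply(y, pop, mean) - grand)^2)
  cellm <- ave(y, interaction(hap, pop))
  fit_add <- lm(y ~ factor(hap) + factor(pop))
  ss_res <- sum(resid(fit_add)^2)
  expect_equal(at["haplogroup", "Sum.Sq"], ss_hap, tolerance = 1e-10)
  expect_equal(at["population", "Sum.Sq"], ss_pop, tolerance = 1e-10)
  expect_equal(at["Residuals", "Sum.Sq"], ss_res, tolerance = 1e-10)
  expect_equal(at["haplogroup", "F.value"],
               (ss_hap / 1) / (ss_res / 9), tolerance = 1e-10)
})

test_that("unbalanced Type II SS agree with the car oracle", {
  skip_if_not_installed("car")
  set.seed(401)
  n <- 80
  hap <- sample(c("H1", "H2", "H3"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  pop <- sample(c("P1", "P2"), n, TRUE, prob = c(0.7, 0.3))
  y <- rnorm(n) + (hap == "H2") * 0.8 + (pop == "P2") * 0.5
  at <- anova_factor(y, hap, pop)
  oracle <- car::Anova(lm(y ~ factor(hap) + factor(pop)), type = 2)
  expect_equal(at["haplogroup", "Sum.Sq"], oracle["factor(hap)", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(at["population", "Sum.Sq"], oracle["factor(pop)", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(at["haplogroup", "Pr..F."], oracle["factor(hap)", "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("total SS decomposes into model plus residual", {
  set.seed(402)
  y <- rnorm(60)
  hap <- sample(c("a", "b"), 60, TRUE)
  pop <- sample(c("p", "q"), 60, TRUE)
  at <- anova_factor(y, hap, pop)
  fit <- attr(at, "fit")
  ss_model <- sum((fitted(fit) - mean(y))^2)
  expect_equal(ss_model + at["Residuals", "Sum.Sq"],
               sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs are handled", {
  # constant response: zero between-group SS, F reported as 0
  at <- anova_factor(rep(5, 12), rep(c("a", "b"), 6), rep(c("p", "q"), each = 6))
  expect_equal(at["haplogroup", "F.value"], 0)
  expect_equal(at["population", "F.value"], 0)
  # single-level factor
  expect_error(anova_factor(rnorm(10), rep("a", 10), rep(c("p", "q"), 5)),
               "at least 2 levels")
  # haplogroup nested entirely within population levels
  expect_error(
    anova_factor(rnorm(8), rep(c("a", "b"), each = 4),
                 rep(c("p", "q"), each = 4)),
    "collinear|confounded")
})

test_that("Tukey letters reflect the significance pattern", {
  set.seed(403)
  # no differences: everyone shares "a"
  y0 <- rnorm(30)
  g <- rep(c("A", "B", "C"), 10)
  cld0 <- tukey_cld(y0, g)
  expect_true(all(cld0$letters == "a"))
  # all pairs hugely different: all distinct letters
  y1 <- rep(c(0, 50, 100), 10) + rnorm(30, 0, 0.5)
  cld1 <- tukey_cld(y1, g)
  expect_equal(length(unique(cld1$letters)), 3)
  # only the extreme pair differs: a / ab / b
  y2 <- rep(c(0, 1.1, 2.2), 10) + rnorm(30, 0, 1)
  cld2 <- tukey_cld(y2, g)
  sig <- cld2$significant
  if (sum(sig) == 2 && sig["A", "C"]) {    # planted pattern realised
    expect_equal(unname(cld2$letters[c("A", "B", "C")]), c("a", "ab", "b"))
  }
  # letter sharing must always reproduce the significance matrix
  for (cld in list(cld0, cld1, cld2)) {
    lv <- names(cld$letters)
    for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
      shares <- length(intersect(strsplit(cld$letters[i], "")[[1]],
                                 strsplit(cld$letters[j], "")[[1]])) > 0
      expect_equal(shares, !cld$significant[lv[i], lv[j]])
    }
  }
})

test_that("compact letter display encodes arbitrary significance relations", {
  set.seed(404)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (i in 2:k) for (j in 1:(i - 1)) {
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    }
    ltr <- yhapnet:::cld_insert_absorb(sig)
    for (i in 2:k) for (j in 1:(i - 1)) {
      shares <- length(intersect(strsplit(ltr[i], "")[[1]],
                                 strsplit(ltr[j], "")[[1]])) > 0
      expect_equal(shares, !sig[i, j])
    }
  }
})

test_that("groups with fewer than 2 observations are excluded with warning", {
  y <- c(rnorm(10), rnorm(10, 5), 3)
  g <- c(rep("A", 10), rep("B", 10), "C")
  expect_warning(cld <- tukey_cld(y, g), "fewer than 2")
  expect_setequal(names(cld$letters), c("A", "B"))
})

test_that("planted age-class mixtures are recovered within binomial error", {
  cfg <- sim_config(samples_per_pop = 100, n_snps = 60,
                    n_populations = 2, male_fraction = 1,
                    hap_freqs_per_pop = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                    n_y_haplogroups = 2,
                    y_block_spans = list(c(1e6, 6e6), c(8e6, 14e6)),
                    n_diagnostic_per_hap = 6,
                    pop_names = c("P1", "P2"), pop_regions = c("R", "R"),
                    length_mu_pop = c(800, 810), length_beta_hap = c(0, 40),
                    age_classes = c("1.3", "1.4"),
                    age_probs_per_hap = rbind(c(0.75, 0.25), c(0.5, 0.5)),
                    age_probs_female = c(0.6, 0.4),
                    seed = 67L)
  sim <- simulate_ychap(cfg)
  tr <- sim$truth$samples
  summ <- age_distribution_summary(tr$true_hap, sim$samples$age_euro,
                                   sim$samples$length_mm)
  counts <- summ$age_counts
  # counts conserved
  expect_equal(sum(counts), sum(!is.na(tr$true_hap)))
  for (h in 1:2) {
    n_h <- sum(counts[h, ])
    p_obs <- counts[h, "1.3"] / n_h
    p_true <- c(0.75, 0.5)[h]
    expect_lt(abs(p_obs - p_true), 3 * sqrt(p_true * (1 - p_true) / n_h))
  }
  # degenerate case: all fish in one cell
  s1 <- age_distribution_summary(rep("MH1", 10), rep("1.3", 10), rnorm(10, 800))
  expect_equal(unname(s1$age_counts["MH1", "1.3"]), 10)
})
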