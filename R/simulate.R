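#' Configuration for the synthetic genotype generator
#'
#' Builds and validates the configuration driving [simulate_ychap()]. The
#' defaults describe a study-scale dataset: 4 populations x 250 samples, 500
#' SNPs on a 25 Mb sex chromosome (10% of SNPs placed on an off-target
#' chromosome), four non-recombining Y haplogroups whose diagnostic SNPs fall
#' in three megabase-scale blocks, population-specific haplogroup frequencies,
#' 0.5% genotyping error, 2% missingness, 5% visual-sexing error, Poisson read
#' depth with collapsed-paralog artifacts at 10% of SNPs, and length/age
#' phenotypes with additive haplogroup effects.
#'
#' The default `diag_layout` plants the haplogroup/block structure typical of
#' partially shared Y lineages: MH1 has a private block; MH2 and MH3 share one
#' block (each with private SNPs plus a jointly fixed set, so their SNPs form a
#' single linkage-disequilibrium component); MH4 has a private block sharing no
#' diagnostics with the others.
#'
#' @param n_populations,samples_per_pop sampling design.
#' @param male_fraction proportion of samples that are (truly) male.
#' @param n_snps total SNP count, including off-target and paralogous SNPs.
#' @param chrom_name,chrom_length_bp sex chromosome label and length.
#' @param off_chrom_fraction fraction of SNPs placed on `off_chrom_name`.
#' @param off_chrom_name label of the off-target chromosome.
#' @param n_y_haplogroups number of planted Y haplogroups.
#' @param y_block_spans list of `c(start, end)` bp spans, one per block.
#' @param diag_layout data.frame with columns `block` (span index), `haps`
#'   (comma-separated haplogroup indices fixed for the minor allele) and
#'   `n_snps`. If `NULL` and `length(y_block_spans) == n_y_haplogroups`, one
#'   block per haplogroup with `n_diagnostic_per_hap` SNPs is used.
#' @param n_diagnostic_per_hap diagnostic SNPs per haplogroup for the simple
#'   one-block-per-haplogroup layout.
#' @param hap_freqs_per_pop matrix (populations x haplogroups) of Y-haplogroup
#'   frequencies among males; rows must sum to 1.
#' @param pop_names,pop_regions population labels and region labels.
#' @param x_maf_beta_params `c(alpha, beta)` of the Beta draw for X-pool
#'   minor-allele frequencies at non-diagnostic SNPs.
#' @param genotyping_error_rate,missing_rate,missexing_rate per-call genotype
#'   error, per-call missingness, and phenotypic sex-label flip probabilities.
#' @param mean_depth mean sequencing depth (reads) per sample x SNP.
#' @param paralog_fraction fraction of SNPs simulated as collapsed paralogs.
#' @param length_mu_pop mean male length (mm) per population.
#' @param length_beta_hap additive length effect (mm) per Y haplogroup.
#' @param length_sigma residual length SD (mm).
#' @param length_mu_female mean female length (mm), no haplogroup effect.
#' @param age_classes age-at-maturity classes in European notation
#'   ("freshwater.ocean").
#' @param age_probs_per_hap matrix (haplogroups x age classes) of class
#'   probabilities for males; rows sum to 1.
#' @param age_probs_female age-class probabilities for females.
#' @param seed integer seed; all randomness in [simulate_ychap()] flows from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4,
                       samples_per_pop = 250,
                       male_fraction = 0.5,
                       n_snps = 500,
                       chrom_name = "Ots17",
                       chrom_length_bp = 25e6,
                       off_chrom_fraction = 0.10,
                       off_chrom_name = "Ots01",
                       n_y_haplogroups = 4,
                       y_block_spans = list(c(600000L, 5100000L),
                                            c(4000000L, 13500000L),
                                            c(14000000L, 20000000L)),
                       diag_layout = NULL,
                       n_diagnostic_per_hap = 8,
                       hap_freqs_per_pop = rbind(
                         c(0.47, 0.47, 0.02, 0.04),
                         c(0.63, 0.09, 0.22, 0.06),
                         c(0.33, 0.11, 0.53, 0.03),
                         c(0.14, 0.14, 0.17, 0.55)),
                       pop_names = c("AnvikLike", "KogruklukLike",
                                     "AniakLike", "NeconsLike"),
                       pop_regions = c("Yukon River", "Western Alaska",
                                       "Western Alaska", "Western Alaska"),
                       x_maf_beta_params = c(0.8, 3),
                       genotyping_error_rate = 0.005,
                       missing_rate = 0.02,
                       missexing_rate = 0.05,
                       mean_depth = 24,
                       paralog_fraction = 0.10,
                       length_mu_pop = c(780, 800, 820, 810),
                       length_beta_hap = c(-40, 0, 10, 50),
                       length_sigma = 60,
                       length_mu_female = 820,
                       age_classes = c("1.2", "1.3", "1.4"),
                       age_probs_per_hap = rbind(
                         c(0.25, 0.60, 0.15),
                         c(0.10, 0.675, 0.225),
                         c(0.15, 0.55, 0.30),
                         c(0.10, 0.45, 0.45)),
                       age_probs_female = c(0.15, 0.55, 0.30),
                       seed = 1L) {
  if (is.null(diag_layout)) {
    if (length(y_block_spans) == n_y_haplogroups) {
      diag_layout <- data.frame(
        block = seq_len(n_y_haplogroups),
        haps = as.character(seq_len(n_y_haplogroups)),
        n_snps = n_diagnostic_per_hap)
    } else if (n_y_haplogroups == 4 && length(y_block_spans) == 3) {
      # default shared-lineage layout (3 blocks, 4 haplogroups)
      diag_layout <- data.frame(
        block = c(1L, 2L, 3L, 3L, 3L),
        haps = c("4", "1", "2", "2,3", "3"),
        n_snps = c(8L, 8L, 5L, 7L, 5L))
    } else {
      stop("diag_layout must be given when blocks do not map 1:1 to haplogroups")
    }
  }
  cfg <- as.list(environment())
  cfg$diag_layout <- diag_layout
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    rates <- c(male_fraction, off_chrom_fraction, genotyping_error_rate,
               missing_rate, missexing_rate, paralog_fraction)
    if (any(rates < 0 | rates > 1)) {
      stop("all rates and fractions must lie in [0, 1]")
    }
    hf <- as.matrix(hap_freqs_per_pop)
    if (nrow(hf) != n_populations || ncol(hf) != n_y_haplogroups) {
      stop("hap_freqs_per_pop must be n_populations x n_y_haplogroups")
    }
    if (any(abs(rowSums(hf) - 1) > 1e-9) || any(hf < 0)) {
      stop("hap_freqs_per_pop rows must be probability vectors summing to 1")
    }
    ap <- as.matrix(age_probs_per_hap)
    if (nrow(ap) != n_y_haplogroups || ncol(ap) != length(age_classes) ||
        any(abs(rowSums(ap) - 1) > 1e-9)) {
      stop("age_probs_per_hap must be n_y_haplogroups x length(age_classes), rows summing to 1")
    }
    if (abs(sum(age_probs_female) - 1) > 1e-9) {
      stop("age_probs_female must sum to 1")
    }
    for (sp in y_block_spans) {
      if (length(sp) != 2 || sp[1] < 1 || sp[2] > chrom_length_bp ||
          sp[1] >= sp[2]) {
        stop("each block span must lie within [1, chrom_length_bp]")
      }
    }
    if (any(cfg$diag_layout$block < 1 |
            cfg$diag_layout$block > length(y_block_spans))) {
      stop("diag_layout references an unknown block")
    }
    hap_sets <- lapply(strsplit(cfg$diag_layout$haps, ","), as.integer)
    if (any(unlist(hap_sets) < 1 | unlist(hap_sets) > n_y_haplogroups)) {
      stop("diag_layout references an unknown haplogroup")
    }
    if (length(length_mu_pop) != n_populations ||
        length(length_beta_hap) != n_y_haplogroups) {
      stop("phenotype effect vectors must match populations/haplogroups")
    }
    invisible(TRUE)
  })
}

#' Simulate a diploid SNP dataset with planted Y haplogroups
#'
#' Generates genotypes, allele read depths, sample metadata and a full truth
#' table. Males carry one X-pool haplotype and the fixed haplotype of their Y
#' haplogroup: the minor allele at every diagnostic SNP whose haplogroup set
#' contains theirs, X-pool draws elsewhere. Females carry two X-pool draws.
#' The X pool is fixed for the major allele at diagnostic SNPs and at linkage
#' equilibrium elsewhere (independent per-SNP draws). Collapsed paralogs are
#' emulated by summing reads from the target locus and a second locus fixed
#' heterozygous, producing elevated heterozygosity and skewed allele read
#' ratios; their calls are re-derived from the pooled reads. Genotyping errors,
#' missingness, visual-sexing error and length/age phenotypes are then applied.
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   \describe{
#'     \item{gm}{a [genotype_matrix()] of observed calls}
#'     \item{depths}{list of `ref`/`alt` read count matrices}
#'     \item{samples}{data.frame: sample_id, population, region,
#'       phenotypic_sex, genetic_sex, length_mm, age_euro}
#'     \item{truth}{list with `samples` (true_sex, true_hap, true X/Y
#'       haplotype matrices) and `snps` (diagnostic status, haplogroup set,
#'       paralog flag, block id, X-pool minor frequency)}
#'   }
#' @export
simulate_ychap <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_populations * cfg$samples_per_pop
  m <- cfg$n_snps
  n_off <- round(m * cfg$off_chrom_fraction)
  n_diag <- sum(cfg$diag_layout$n_snps)
  n_par <- round(m * cfg$paralog_fraction)
  n_bg_on <- m - n_off - n_diag
  if (n_bg_on < n_par) stop("too few background SNPs for the paralog fraction")

  ## ---- SNP map ----
  hap_sets <- lapply(strsplit(cfg$diag_layout$haps, ","), as.integer)
  diag_block <- rep(cfg$diag_layout$block, cfg$diag_layout$n_snps)
  diag_group <- rep(seq_len(nrow(cfg$diag_layout)), cfg$diag_layout$n_snps)
  diag_pos <- integer(n_diag)
  for (b in unique(diag_block)) {
    idx <- which(diag_block == b)
    sp <- cfg$y_block_spans[[b]]
    if (length(idx) == 1L) {
      diag_pos[idx] <- round(mean(sp))
    } else {
      # anchor the extremes so the realized span matches the planted span
      diag_pos[idx] <- sort(c(sp[1], sp[2],
                              round(runif(length(idx) - 2, sp[1], sp[2]))))
    }
  }
  bg_pos <- sample.int(cfg$chrom_length_bp, n_bg_on + n_off)
  pos <- c(diag_pos, bg_pos)
  chrom <- c(rep(cfg$chrom_name, n_diag + n_bg_on),
             rep(cfg$off_chrom_name, n_off))
  is_diag <- c(rep(TRUE, n_diag), rep(FALSE, n_bg_on + n_off))
  block_id <- c(diag_block, rep(NA_integer_, n_bg_on + n_off))
  group_id <- c(diag_group, rep(NA_integer_, n_bg_on + n_off))
  # paralogs only among on-target background SNPs
  paralog <- rep(FALSE, m)
  paralog[n_diag + sample.int(n_bg_on, n_par)] <- TRUE

  nuc <- c("A", "C", "G", "T")
  maj <- sample(nuc, m, replace = TRUE)
  mnr <- vapply(maj, function(a) sample(setdiff(nuc, a), 1), character(1))

  x_freq <- rbeta(m, cfg$x_maf_beta_params[1], cfg$x_maf_beta_params[2])
  x_freq[is_diag] <- 0

  ## ---- samples ----
  pop <- rep(seq_len(cfg$n_populations), each = cfg$samples_per_pop)
  true_male <- runif(n) < cfg$male_fraction
  hap <- rep(NA_integer_, n)
  hf <- as.matrix(cfg$hap_freqs_per_pop)
  for (p in seq_len(cfg$n_populations)) {
    sel <- which(pop == p & true_male)
    if (length(sel)) {
      hap[sel] <- sample.int(cfg$n_y_haplogroups, length(sel),
                             replace = TRUE, prob = hf[p, ])
    }
  }

  ## ---- haplotypes (0 = major, 1 = minor) ----
  draw_x <- function() {
    matrix(rbinom(n * m, 1L, rep(x_freq, each = n)), n, m)
  }
  hapA <- draw_x()                     # maternal X for everyone
  hapB <- draw_x()                     # paternal X (females) / Y base (males)
  y_template <- matrix(0L, cfg$n_y_haplogroups, m)
  for (g in seq_along(hap_sets)) {
    y_template[hap_sets[[g]], which(group_id == g)] <- 1L
  }
  males <- which(true_male)
  if (length(males)) {
    hapB[males, ] <- hapB[males, ] * rep(1L - is_diag, each = length(males))
    hapB[males, ] <- hapB[males, ] + y_template[hap[males], , drop = FALSE]
  }
  geno_true <- hapA + hapB

  ## ---- read depths ----
  depth <- matrix(rpois(n * m, cfg$mean_depth), n, m)
  alt <- matrix(0L, n, m)
  het <- geno_true == 1L
  alt[het] <- rbinom(sum(het), depth[het], 0.5)
  alt[geno_true == 2L] <- depth[geno_true == 2L]
  ref <- depth - alt
  calls <- geno_true
  par_idx <- which(paralog)
  if (length(par_idx)) {
    for (j in par_idx) {
      d2 <- rpois(n, cfg$mean_depth)        # shadow locus, fixed heterozygous
      alt2 <- rbinom(n, d2, 0.5)
      alt[, j] <- alt[, j] + alt2
      ref[, j] <- ref[, j] + (d2 - alt2)
      tot <- ref[, j] + alt[, j]
      calls[, j] <- ifelse(tot == 0L, NA_integer_,
                    ifelse(pmin(ref[, j], alt[, j]) >= 2L, 1L,
                    ifelse(alt[, j] > ref[, j], 2L, 0L)))
    }
  }

  ## ---- genotyping error and missingness ----
  if (cfg$genotyping_error_rate > 0) {
    err <- which(!is.na(calls) & matrix(runif(n * m) < cfg$genotyping_error_rate, n, m))
    if (length(err)) {
      shift <- sample.int(2L, length(err), replace = TRUE)
      calls[err] <- (calls[err] + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    calls[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA_integer_
  }

  ## ---- metadata and phenotypes ----
  sample_id <- sprintf("%s_%03d", cfg$pop_names[pop],
                       sequence(rep(cfg$samples_per_pop, cfg$n_populations)))
  genetic_sex <- ifelse(true_male, "M", "F")
  flip <- runif(n) < cfg$missexing_rate
  phenotypic_sex <- ifelse(flip, ifelse(true_male, "F", "M"), genetic_sex)
  length_mm <- ifelse(
    true_male,
    cfg$length_mu_pop[pop] + ifelse(is.na(hap), 0, cfg$length_beta_hap[hap]),
    cfg$length_mu_female) + rnorm(n, 0, cfg$length_sigma)
  age_euro <- character(n)
  for (i in seq_len(n)) {
    pr <- if (true_male[i]) cfg$age_probs_per_hap[hap[i], ] else cfg$age_probs_female
    age_euro[i] <- sample(cfg$age_classes, 1, prob = pr)
  }

  snp_ids <- sprintf("%s_%d", chrom, pos)
  # ensure unique ids even under positional collisions
  snp_ids <- make.unique(snp_ids, sep = "b")
  gm <- genotype_matrix(calls, chrom = chrom, pos = pos,
                        alleles = data.frame(major = maj, minor = mnr),
                        sample_ids = sample_id, snp_ids = snp_ids)
  dimnames(ref) <- dimnames(alt) <- list(sample_id, snp_ids)
  dimnames(hapA) <- dimnames(hapB) <- list(sample_id, snp_ids)

  hap_names <- paste0("MH", seq_len(cfg$n_y_haplogroups))
  truth_snps <- data.frame(
    snp_id = snp_ids, chrom = chrom, pos = pos,
    diagnostic = is_diag,
    hap_set = vapply(seq_len(m), function(j) {
      if (is.na(group_id[j])) "" else
        paste(hap_names[hap_sets[[group_id[j]]]], collapse = ",")
    }, character(1)),
    block = block_id, paralog = paralog, x_freq = x_freq,
    stringsAsFactors = FALSE)
  truth_samples <- data.frame(
    sample_id = sample_id,
    true_sex = genetic_sex,
    true_hap = ifelse(is.na(hap), NA_character_, hap_names[hap]),
    stringsAsFactors = FALSE)

  list(
    gm = gm,
    depths = list(ref = ref, alt = alt),
    samples = data.frame(
      sample_id = sample_id,
      population = cfg$pop_names[pop],
      region = cfg$pop_regions[pop],
      phenotypic_sex = phenotypic_sex,
      genetic_sex = genetic_sex,
      length_mm = round(length_mm, 1),
      age_euro = age_euro,
      stringsAsFactors = FALSE),
    truth = list(samples = truth_samples, snps = truth_snps,
                 hapA = hapA, hapB = hapB)
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the VCF (GT + AD), the sample metadata TSV and the two truth TSVs.
#'
#' @param sim result of [simulate_ychap()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    samples = file.path(dir, "samples.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_snps = file.path(dir, "truth_snps.tsv"))
  write_vcf_genotypes(sim$gm, paths["vcf"], depths = sim$depths)
  write_tsv(sim$samples, paths["samples"])
  write_tsv(sim$truth$samples, paths["truth_samples"])
  write_tsv(sim$truth$snps, paths["truth_snps"])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
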