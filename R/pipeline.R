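# End-to-end orchestration: simulate (or load) -> filter -> LD network ->
# phase -> discover -> panel -> assign -> associate, with a written report.

#' Build and validate a pipeline configuration
#'
#' Either supply `sim` (a [sim_config()] or a list of its arguments) to run on
#' simulated data, or `vcf` and `samples_tsv` paths for real inputs. Stage
#' thresholds mirror the arguments of [yhap_discover()] and
#' [assign_by_genotype()]. Thresholds are range-checked here so an invalid
#' configuration fails before any stage runs.
#'
#' @param ... configuration entries overriding the defaults; alternatively a
#'   single list or a path to a YAML file with the same entries.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args))) {
    if (is.character(args[[1]])) {
      args <- yaml::read_yaml(args[[1]])
    } else if (is.list(args[[1]])) {
      args <- args[[1]]
    }
  }
  cfg <- list(
    sim = NULL, vcf = NULL, samples_tsv = NULL,
    out_dir = NULL, chrom = NULL,
    max_missing = 0.10, min_maf = 0.01, max_H = 0.55, max_absD = 7,
    r2_min = 0.3, min_snps = 5, min_span = 1e6,
    k = "auto", male_frac_min = 0.8, fixed_threshold = 0.95,
    window = 6, top_k = 50,
    max_mismatch = 2, min_informative = 5,
    alpha = 0.05, seed = 1L,
    stages = c("discover", "assign", "associate"))
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(args)] <- args
  unit <- c("max_missing", "min_maf", "r2_min", "male_frac_min",
            "fixed_threshold", "alpha")
  for (nm in unit) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop("configuration error: ", nm, " must be a number in [0, 1]")
    }
  }
  pos <- c("max_H", "max_absD", "min_snps", "min_span", "window", "top_k",
           "max_mismatch", "min_informative")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("configuration error: ", nm, " must be non-negative")
    }
  }
  if (is.null(cfg$sim) && (is.null(cfg$vcf) || is.null(cfg$samples_tsv))) {
    stop("configuration error: need either `sim` or both `vcf` and `samples_tsv`")
  }
  if (!is.null(cfg$vcf) && !is.null(cfg$samples_tsv)) {
    for (f in c(cfg$vcf, cfg$samples_tsv)) {
      if (!file.exists(f)) stop("configuration error: file not found: ", f)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the discovery / assignment / association pipeline
#'
#' Executes the enabled stages in order and writes every stage output plus a
#' Markdown run report into `out_dir`. Rerunning with the same configuration
#' and seed reproduces byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()] (or arguments for it).
#' @param out_dir output directory; overrides the configuration entry.
#' @return list of class `pipeline_result` with the fit, assignments,
#'   association tables and file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  ## ---- inputs ----
  if (!is.null(config$sim)) {
    scfg <- if (inherits(config$sim, "sim_config")) config$sim
            else do.call(sim_config, config$sim)
    note("stage simulate: ", scfg$n_populations * scfg$samples_per_pop,
         " samples, ", scfg$n_snps, " SNPs, seed ", scfg$seed)
    sim <- simulate_ychap(scfg)
    gm <- sim$gm; depths <- sim$depths; samples <- sim$samples
    write_sim_dataset(sim, config$out_dir)
    if (is.null(config$chrom)) config$chrom <- scfg$chrom_name
  } else {
    note("stage load: ", config$vcf)
    inp <- read_vcf_genotypes(config$vcf)
    gm <- inp$gm; depths <- inp$depths
    samples <- utils::read.delim(config$samples_tsv, stringsAsFactors = FALSE)
    sim <- NULL
  }

  fit <- NULL; assignments <- NULL; freq_tab <- NULL
  assoc <- list()

  ## ---- discovery ----
  if ("discover" %in% config$stages) {
    note("stage discover: LD network + phasing + clustering")
    fit <- yhap_discover(
      gm, samples, depths = depths, chrom = config$chrom,
      max_missing = config$max_missing, min_maf = config$min_maf,
      max_H = config$max_H, max_absD = config$max_absD,
      r2_min = config$r2_min, min_snps = config$min_snps,
      min_span = config$min_span, k = config$k,
      male_frac_min = config$male_frac_min,
      fixed_threshold = config$fixed_threshold,
      window = config$window, top_k = config$top_k, seed = config$seed)
    write_tsv(fit$snp_stats, outfile("snp_stats.tsv"))
    if (!is.null(fit$hdplot)) write_tsv(fit$hdplot, outfile("hdplot.tsv"))
    write_tsv(ld_block_summary(fit$blocks), outfile("blocks.tsv"))
    write_haplotypes_tsv(fit$phased, outfile("haplotypes.tsv"))
    membership <- data.frame(
      haplotype = rownames(fit$hm),
      sample_id = attr(fit$hm, "sample_id"),
      cluster = as.integer(fit$labels),
      group = fit$group_names, stringsAsFactors = FALSE)
    write_tsv(membership, outfile("haplogroup_membership.tsv"))
    write_tsv(fit$classes, outfile("cluster_sex_composition.tsv"))
    write_tsv(fit$diagnostics, outfile("diagnostic_snps.tsv"))
    if (!is.null(fit$panel)) write_panel_json(fit$panel, outfile("panel.json"))
    note("  found ", length(fit$y_groups), " Y haplogroup(s) in ",
         length(fit$blocks), " block(s)")
  }

  ## ---- assignment ----
  if ("assign" %in% config$stages && !is.null(fit) && !is.null(fit$panel)) {
    note("stage assign: expected-genotype matching")
    assignments <- assign_by_genotype(
      gm, fit$panel,
      max_mismatch = config$max_mismatch,
      min_informative = config$min_informative)
    write_tsv(assignments, outfile("assignments.tsv"))
    freq_tab <- haplogroup_frequency_table(assignments, samples)
    write_tsv(freq_tab, outfile("haplogroup_frequencies.tsv"))
    if ("genetic_sex" %in% names(samples)) {
      viol <- sex_concordance(assignments, samples)
      writeLines(viol, outfile("sex_concordance_violations.txt"))
    }
  }

  ## ---- association ----
  if ("associate" %in% config$stages && !is.null(assignments)) {
    note("stage associate: ANOVA + Tukey")
    idx <- match(assignments$sample_id, samples$sample_id)
    dat <- data.frame(
      haplogroup = assignments$haplogroup,
      population = samples$population[idx],
      length_mm = samples$length_mm[idx],
      age_euro = samples$age_euro[idx],
      stringsAsFactors = FALSE)
    dat <- dat[!is.na(dat$haplogroup), ]
    assoc$anova_length <- tryCatch(
      anova_factor(dat$length_mm, dat$haplogroup, dat$population),
      error = function(e) {note("  length ANOVA skipped: ", conditionMessage(e)); NULL})
    if (!is.null(assoc$anova_length)) {
      write_tsv(cbind(term = rownames(assoc$anova_length),
                      as.data.frame(assoc$anova_length)),
                outfile("anova_length.tsv"))
      assoc$tukey_length <- tukey_cld(dat$length_mm, dat$haplogroup,
                                      covariate = dat$population,
                                      alpha = config$alpha)
      write_tsv(assoc$tukey_length$pairs, outfile("tukey_length.tsv"))
      write_tsv(data.frame(group = names(assoc$tukey_length$letters),
                           letters = unname(assoc$tukey_length$letters)),
                outfile("cld_length.tsv"))
    }
    if (!all(is.na(dat$age_euro))) {
      ages <- parse_age_euro(dat$age_euro)
      assoc$anova_age <- tryCatch(
        anova_factor(ages$total_age_years, dat$haplogroup, dat$population),
        error = function(e) {note("  age ANOVA skipped: ", conditionMessage(e)); NULL})
      if (!is.null(assoc$anova_age)) {
        write_tsv(cbind(term = rownames(assoc$anova_age),
                        as.data.frame(assoc$anova_age)),
                  outfile("anova_age.tsv"))
      }
      assoc$age_summary <- age_distribution_summary(
        dat$haplogroup, dat$age_euro, dat$length_mm)
      ac <- as.data.frame.matrix(assoc$age_summary$age_counts)
      write_tsv(cbind(haplogroup = rownames(ac), ac), outfile("age_counts.tsv"))
      if (!is.null(assoc$age_summary$size_at_age)) {
        write_tsv(assoc$age_summary$size_at_age, outfile("size_at_age.tsv"))
      }
    }
  }

  ## ---- report ----
  report <- pipeline_report(config, fit, assignments, freq_tab, assoc, samples)
  writeLines(report, outfile("report.md"))
  writeLines(log_lines, outfile("run.log"))

  invisible(structure(
    list(config = config, sim = sim, fit = fit,
         assignments = assignments, frequencies = freq_tab,
         association = assoc, out_dir = config$out_dir,
         report = report),
    class = "pipeline_result"))
}

pipeline_report <- function(config, fit, assignments, freq_tab, assoc,
                            samples) {
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(
        vapply(r, function(v) {
          if (is.na(v)) "NA"
          else if (is.numeric(v)) format(v, digits = 4)
          else as.character(v)
        }, character(1)), collapse = " | ")))
  }
  out <- c("# Y-haplogroup pipeline report", "",
           paste0("seed: ", config$seed))
  if (!is.null(fit)) {
    s <- summary(fit)
    out <- c(out, "", "## High-LD blocks",
             sprintf("%d block(s) capturing %d SNPs (%.1f%% of %d filtered SNPs)",
                     length(fit$blocks), length(fit$gm_union$snp_ids),
                     s$percent_of_snps, fit$n_snps_filtered),
             "", fmt_tab(s$blocks),
             "", "## Haplogroups (sex composition of carriers)",
             fmt_tab(s$composition))
    if (!is.null(fit$panel)) {
      out <- c(out, "",
               sprintf("Diagnostic panel: %d SNPs, %d discriminator rules",
                       nrow(fit$panel$snps), nrow(fit$panel$discriminators)))
    }
    out <- c(out, "",
             sprintf("Pairing violations: %d", length(fit$pairing_violations)))
  }
  if (!is.null(assignments)) {
    rate <- hap_assignment_rate(assignments)
    out <- c(out, "", "## Assignment",
             sprintf("%d of %d samples assigned (%d%%)",
                     sum(!is.na(assignments$haplogroup)),
                     nrow(assignments), rate))
    if (!is.null(freq_tab)) {
      out <- c(out, "", "### Haplogroup frequencies by population",
               fmt_tab(freq_tab))
    }
  }
  if (!is.null(assoc$anova_length)) {
    out <- c(out, "", "## Length ~ haplogroup + population (Type II ANOVA)",
             fmt_tab(cbind(term = rownames(assoc$anova_length),
                           as.data.frame(assoc$anova_length))))
    if (!is.null(assoc$tukey_length)) {
      out <- c(out, "", "Tukey compact letter display:",
               fmt_tab(data.frame(group = names(assoc$tukey_length$letters),
                                  letters = unname(assoc$tukey_length$letters))))
    }
  }
  if (!is.null(assoc$anova_age)) {
    out <- c(out, "", "## Total age ~ haplogroup + population (Type II ANOVA)",
             fmt_tab(cbind(term = rownames(assoc$anova_age),
                           as.data.frame(assoc$anova_age))))
  }
  out
}
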