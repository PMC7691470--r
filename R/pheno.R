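# Associations between haplogroups and size / age at maturity.

#' Parse European age notation
#'
#' Salmon ages in European notation are written "freshwater.ocean": the years
#' in fresh water after emergence, a dot, then the ocean years. Total age adds
#' the incubation year, so "1.3" is 1 + 3 + 1 = 5 years.
#'
#' @param text character vector of ages, each matching `digits.digits`.
#' @return data.frame: age (input), freshwater_years, ocean_years,
#'   total_age_years.
#' @export
parse_age_euro <- function(text) {
  text <- as.character(text)
  ok <- grepl("^[0-9]+\\.[0-9]+$", text)
  if (any(!ok & !is.na(text))) {
    stop("malformed European age notation: ",
         paste(utils::head(text[!ok & !is.na(text)], 3), collapse = ", "))
  }
  parts <- strsplit(text, ".", fixed = TRUE)
  fw <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  oc <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  data.frame(age = text,
             freshwater_years = fw,
             ocean_years = oc,
             total_age_years = fw + oc + 1L,
             stringsAsFactors = FALSE)
}

#' Two-factor ANOVA with Type II sums of squares
#'
#' Tests the association between a response (length or age) and haplogroup
#' with population of origin as covariate: the linear model
#' `response ~ haplogroup + population`. Because the design is generally
#' unbalanced, Type II sums of squares are used - each term's SS is the
#' reduction in residual SS when it is added last to the model containing the
#' other term.
#'
#' @param response numeric response per sample.
#' @param haplogroup factor (or coercible) of haplogroup labels.
#' @param population factor of population labels.
#' @return data.frame of class `anova_table`: rows haplogroup, population,
#'   Residuals with Df, Sum.Sq, Mean.Sq, F.value, Pr..F.. Attribute `fit`
#'   holds the full `lm` fit.
#' @export
anova_factor <- function(response, haplogroup, population) {
  keep <- !is.na(response) & !is.na(haplogroup) & !is.na(population)
  df <- data.frame(response = response[keep],
                   haplogroup = droplevels(factor(haplogroup[keep])),
                   population = droplevels(factor(population[keep])))
  for (term in c("haplogroup", "population")) {
    lv <- table(df[[term]])
    if (nlevels(df[[term]]) < 2) {
      stop("factor '", term, "' needs at least 2 levels with data")
    }
    if (any(lv < 2)) {
      warning("factor '", term, "' has level(s) with fewer than 2 observations")
    }
  }
  full <- stats::lm(response ~ haplogroup + population, data = df)
  if (any(is.na(stats::coef(full)))) {
    stop("collinear design: a haplogroup is confounded with population; ",
         "term not estimable")
  }
  no_hap <- stats::lm(response ~ population, data = df)
  no_pop <- stats::lm(response ~ haplogroup, data = df)
  rss <- function(f) sum(stats::residuals(f)^2)
  ss_hap <- rss(no_hap) - rss(full)
  ss_pop <- rss(no_pop) - rss(full)
  ss_res <- rss(full)
  df_hap <- nlevels(df$haplogroup) - 1L
  df_pop <- nlevels(df$population) - 1L
  df_res <- nrow(df) - 1L - df_hap - df_pop
  mse <- ss_res / df_res
  fval <- function(ss, d) {
    if (ss <= 1e-12) return(0)        # constant response: no variation to test
    (ss / d) / mse
  }
  f_hap <- fval(ss_hap, df_hap)
  f_pop <- fval(ss_pop, df_pop)
  out <- data.frame(
    Df = c(df_hap, df_pop, df_res),
    `Sum.Sq` = c(ss_hap, ss_pop, ss_res),
    `Mean.Sq` = c(ss_hap / df_hap, ss_pop / df_pop, mse),
    `F.value` = c(f_hap, f_pop, NA),
    `Pr..F.` = c(stats::pf(f_hap, df_hap, df_res, lower.tail = FALSE),
                 stats::pf(f_pop, df_pop, df_res, lower.tail = FALSE),
                 NA),
    row.names = c("haplogroup", "population", "Residuals"))
  attr(out, "fit") <- full
  attr(out, "n") <- nrow(df)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD with a compact letter display
#'
#' Pairwise comparisons of group means by Tukey's honestly-significant-
#' difference test (Tukey-Kramer for unbalanced groups), adjusted for the
#' covariate when given, summarised as a compact letter display: two groups
#' share a letter exactly when their adjusted p-value is at least `alpha`.
#' Letters are built by insert-and-absorb over the significance matrix.
#'
#' @param response numeric response.
#' @param groups group factor (haplogroups).
#' @param covariate optional factor adjusted for before the comparisons
#'   (population of origin).
#' @param alpha significance level (default 0.05).
#' @return list of class `tukey_cld`: `pairs` (data.frame of pairwise
#'   comparisons with adjusted p), `letters` (named character vector),
#'   `alpha`.
#' @export
tukey_cld <- function(response, groups, covariate = NULL, alpha = 0.05) {
  keep <- !is.na(response) & !is.na(groups)
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  g <- droplevels(factor(groups[keep]))
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    sel <- !(g %in% small)
    response <- response[keep][sel]
    g <- droplevels(g[sel])
    if (!is.null(covariate)) covariate <- covariate[keep][sel]
  } else {
    response <- response[keep]
    if (!is.null(covariate)) covariate <- covariate[keep]
  }
  if (nlevels(g) < 2) stop("need at least 2 groups with data")
  if (is.null(covariate)) {
    fit <- stats::aov(response ~ g)
  } else {
    fit <- stats::aov(response ~ factor(covariate) + g)
  }
  tk <- stats::TukeyHSD(fit, which = "g")$g
  lv <- levels(g)
  # TukeyHSD rows follow combn(levels, 2) order, named "<j>-<i>"; rebuild the
  # pairing from the level order (group names may themselves contain dashes)
  cmb <- utils::combn(lv, 2)
  stopifnot(identical(rownames(tk), paste(cmb[2, ], cmb[1, ], sep = "-")))
  pairs <- data.frame(
    group1 = cmb[2, ],
    group2 = cmb[1, ],
    comparison = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    row.names = NULL)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group1[i]; b <- pairs$group2[i]
    sig[a, b] <- sig[b, a] <- pairs$p_adj[i] < alpha
  }
  letters <- cld_insert_absorb(sig)
  structure(list(pairs = pairs, letters = letters, alpha = alpha,
                 significant = sig),
            class = "tukey_cld")
}

# insert-and-absorb compact letter display from a logical significance matrix
# (TRUE = the two groups differ). Guarantees: groups share a letter iff not
# significantly different.
cld_insert_absorb <- function(sig) {
  lv <- rownames(sig)
  cols <- list(rep(TRUE, length(lv)))  # letter columns: membership vectors
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        # duplicate the column, drop i from one copy and j from the other
        col_a <- col; col_a[i] <- FALSE
        col_b <- col; col_b[j] <- FALSE
        cols[[ci]] <- col_a
        cols[[length(cols) + 1]] <- col_b
      }
    }
    # absorb: remove columns whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[b]] > cols[[a]])) {
        keep[a] <- FALSE
      }
    }
    if (all(!keep)) keep[1] <- TRUE   # identical duplicates: keep one
    cols <- cols[keep]
    dup <- duplicated(vapply(cols, paste, character(1), collapse = ""))
    cols <- cols[!dup]
  }
  # order columns by first member for stable letter assignment
  first <- vapply(cols, function(cc) which(cc)[1], numeric(1))
  cols <- cols[order(first)]
  out <- vapply(seq_along(lv), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(out, lv)
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("Tukey HSD (alpha =", x$alpha, ")\n")
  print(data.frame(group = names(x$letters), letters = unname(x$letters)))
  invisible(x)
}

#' Age distribution and size-at-age by haplogroup
#'
#' Counts per (haplogroup, age class) and length summaries per cell, for aged
#' samples with a haplogroup assignment.
#'
#' @param haplogroup haplogroup per sample (`NA` = unassigned, dropped).
#' @param age_euro European-notation age strings.
#' @param length_mm optional lengths for the size-at-age table.
#' @return list: `age_counts` (haplogroup x age class matrix) and
#'   `size_at_age` (data.frame with n, mean, median, q25, q75 of length per
#'   cell; `NULL` without lengths).
#' @export
age_distribution_summary <- function(haplogroup, age_euro, length_mm = NULL) {
  keep <- !is.na(haplogroup) & !is.na(age_euro)
  hap <- haplogroup[keep]
  age <- age_euro[keep]
  len <- if (!is.null(length_mm)) length_mm[keep] else NULL
  counts <- table(haplogroup = hap, age = age)
  size <- NULL
  if (!is.null(len)) {
    cells <- unique(data.frame(hap, age, stringsAsFactors = FALSE))
    cells <- cells[order(cells$hap, cells$age), ]
    size <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- hap == cells$hap[i] & age == cells$age[i] & !is.na(len)
      q <- stats::quantile(len[sel], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(haplogroup = cells$hap[i], age = cells$age[i],
                 n = sum(sel), mean_length = mean(len[sel]),
                 q25 = q[1], median_length = q[2], q75 = q[3])
    }))
    rownames(size) <- NULL
  }
  list(age_counts = unclass(counts), size_at_age = size)
}
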