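## Cohort statistics: one-way ANOVA with Bonferroni post hoc pairwise tests,
## ordinary least-squares association, delta-delta-Ct fold changes, and the
## combined association report.

#' Group comparison by one-way ANOVA with Bonferroni post hoc tests
#'
#' Classical (equal-variance) one-way ANOVA across `k >= 2` groups, followed
#' by pairwise pooled-SD t tests whose p-values are multiplied by the number
#' of pairwise comparisons and capped at 1.
#'
#' @param values numeric outcome, one value per subject.
#' @param groups group labels (coerced to factor).
#' @return object of class `stat_result`: list with `method`, `statistic`
#'   (F), `df` (c(between, within)), `p_value`, `effect` (per-group n,
#'   mean, sd) and `posthoc` (data.frame of pairwise raw and
#'   Bonferroni-adjusted p).
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups) || anyNA(values) || anyNA(groups)) {
    stop_input("'values' and 'groups' must be equal length with no NA")
  }
  k <- nlevels(groups)
  if (k < 2L) stop_input("at least 2 groups required")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_input("insufficient data: group(s) with < 2 observations: ",
               paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  Fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  ## identical groups => zero between- and within-group variance; define F=0,p=1
  if (!is.finite(Fstat)) { Fstat <- 0; p <- 1 }

  effect <- data.frame(group = levels(groups),
                       n = as.integer(sizes),
                       mean = tapply(values, groups, mean),
                       sd = tapply(values, groups, sd),
                       row.names = NULL, stringsAsFactors = FALSE)

  ## pairwise t on the pooled ANOVA error term, Bonferroni over all pairs
  mse <- tab[["Mean Sq"]][2]
  df_w <- tab[["Df"]][2]
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    m1 <- effect$mean[effect$group == g1]; n1 <- effect$n[effect$group == g1]
    m2 <- effect$mean[effect$group == g2]; n2 <- effect$n[effect$group == g2]
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    tstat <- if (se > 0) (m1 - m2) / se else 0
    praw <- if (se > 0) 2 * pt(-abs(tstat), df_w) else 1
    data.frame(group1 = g1, group2 = g2, t = tstat, p = praw,
               adjusted_p = min(1, n_pairs * praw), stringsAsFactors = FALSE)
  }))
  structure(list(method = "one-way ANOVA + Bonferroni post hoc",
                 statistic = Fstat, df = c(between = tab[["Df"]][1], within = df_w),
                 p_value = p, effect = effect, posthoc = posthoc),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n  F(%d, %d) = %.4g, p = %.4g\n",
              x$method, x$df[1], x$df[2], x$statistic, x$p_value))
  for (i in seq_len(nrow(x$effect))) {
    cat(sprintf("  %-10s n = %2d, %.2f +- %.2f\n", x$effect$group[i],
                x$effect$n[i], x$effect$mean[i], x$effect$sd[i]))
  }
  invisible(x)
}

#' Ordinary least-squares association between two continuous parameters
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r` (Pearson), `r_squared`, `p`
#'   (t-test on the slope, n - 2 df) and `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop_input("'x' and 'y' must be the same length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_input("at least 3 complete observations required")
  if (var(x) == 0) stop_input("degenerate fit: 'x' is constant")
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  if (var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r = 0, r_squared = 0, p = 1, n = n))
  }
  r <- cor(x, y)
  ## slope SE from the residual variance directly (avoids summary.lm's
  ## perfect-fit warning when the points are exactly collinear)
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(-abs(b[2] / se), n - 2)
  list(slope = b[2], intercept = b[1], r = r, r_squared = r^2, p = p, n = n)
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' For each sample: `dCt = Ct_target - mean(Ct_refs)`, then
#' `ddCt = dCt - mean(dCt over calibrator samples)` and
#' `fold = 2^(-ddCt)`. The two reference genes are combined by the
#' arithmetic mean of their Ct values; the calibrator group has fold 1 by
#' construction (its mean log2 fold is 0).
#'
#' @param ct long data.frame with columns `animal_id`, `group`, `region`,
#'   `gene`, `ct` (one Ct per sample x gene).
#' @param target target gene symbol.
#' @param refs reference gene symbols (default HPRT and ACTB).
#' @param calibrator value of `group` used as calibrator (default
#'   `"Control"`).
#' @return data.frame with one row per sample: `animal_id`, `group`,
#'   `region`, `gene`, `dct`, `ddct`, `fold`.
#' @export
delta_delta_ct <- function(ct, target, refs = c("HPRT", "ACTB"),
                           calibrator = "Control") {
  stopifnot(is.data.frame(ct),
            all(c("animal_id", "group", "region", "gene", "ct") %in% names(ct)))
  samples <- unique(ct[c("animal_id", "group", "region")])
  key <- function(df) paste(df$animal_id, df$region, sep = "\r")
  get_ct <- function(gene) {
    sub <- ct[ct$gene == gene, ]
    ct_map <- setNames(sub$ct, key(sub))
    out <- ct_map[key(samples)]
    if (anyNA(out)) {
      miss <- samples[is.na(out), ]
      stop_input(sprintf("missing Ct for gene %s in sample(s): %s", gene,
                         paste(paste(miss$animal_id, miss$region, sep = "/"),
                               collapse = ", ")))
    }
    unname(out)
  }
  ct_t <- get_ct(target)
  ct_r <- rowMeans(vapply(refs, get_ct, numeric(nrow(samples))))
  dct <- ct_t - ct_r
  cal <- samples$group == calibrator
  if (!any(cal)) stop_input("no samples in calibrator group '", calibrator, "'")
  ddct <- dct - mean(dct[cal])
  out <- samples
  out$gene <- target
  out$dct <- dct
  out$ddct <- ddct
  out$fold <- 2^(-ddct)
  rownames(out) <- NULL
  out
}

#' Combined mismatch association report
#'
#' Runs the cohort-level statistics of the imaging study on a (simulated or
#' real) classified cohort: ANOVA group comparisons of EF, EDV and infarct
#' size at each timepoint; the MVO vs day-3 infarct-territory-uptake
#' regression; and the pooled month-1 segmental uptake vs contractility
#' regression.
#'
#' @param cohort a `sim_cohort` (or a list with compatible `animals` and
#'   `profiles` elements).
#' @param territory infarct [territory()] (default from the cohort config).
#' @param groups optional named character vector of group labels per
#'   `animal_id`; defaults to classifying day-3 profiles with
#'   [cohort_assign()].
#' @return object of class `mismatch_report`: list of `assignment`,
#'   `group_tests` (named list of [group_compare()] results),
#'   `mvo_uptake_fit` and `uptake_contractility_fit`.
#' @export
mismatch_association_suite <- function(cohort, territory = NULL, groups = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$animals), !is.null(cohort$profiles))
  territory <- territory %||% cohort$config$infarct_territory %||% lad_territory()
  day3 <- Filter(function(p) p$timepoint == "day3", cohort$profiles)
  month1 <- Filter(function(p) p$timepoint == "month1", cohort$profiles)
  if (!length(day3) || !length(month1)) {
    stop_input("cohort must contain both day-3 and month-1 profiles")
  }
  assignment <- cohort_assign(day3, cohort$config$thresholds %||% mismatch_thresholds())
  if (is.null(groups)) {
    groups <- setNames(assignment$table$group, assignment$table$animal_id)
  }
  an <- cohort$animals
  g <- groups[an$animal_id]

  outcomes <- c("ef_day3", "ef_month1", "edv_day3", "edv_month1",
                "infarct_day3", "infarct_month1")
  outcomes <- intersect(outcomes, names(an))
  group_tests <- lapply(setNames(outcomes, outcomes), function(v) {
    group_compare(an[[v]], g)
  })

  ## MVO vs mean day-3 infarct-territory uptake
  d3_by_id <- setNames(day3, vapply(day3, `[[`, character(1), "animal_id"))
  upt_d3 <- vapply(an$animal_id, function(id) {
    territory_summary(d3_by_id[[id]], territory)$mean_uptake
  }, numeric(1))
  mvo_fit <- linear_fit(an$mvo, upt_d3)

  ## pooled month-1 segmental uptake vs contractility
  upt <- unlist(lapply(month1, `[[`, "uptake_norm"))
  con <- unlist(lapply(month1, `[[`, "contractility"))
  uc_fit <- linear_fit(upt, con)

  structure(list(assignment = assignment, group_tests = group_tests,
                 mvo_uptake_fit = mvo_fit, uptake_contractility_fit = uc_fit,
                 territory = territory),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  print(x$assignment)
  for (nm in names(x$group_tests)) {
    gt <- x$group_tests[[nm]]
    eff <- gt$effect
    cat(sprintf("  %-15s %s  (F = %.3g, p = %.3g)\n", nm,
                paste(sprintf("%s %.1f +- %.1f", eff$group, eff$mean, eff$sd),
                      collapse = " vs "),
                gt$statistic, gt$p_value))
  }
  cat(sprintf("  MVO ~ day-3 territory uptake: slope %.3g, r = %.3f, p = %.3g\n",
              x$mvo_uptake_fit$slope, x$mvo_uptake_fit$r, x$mvo_uptake_fit$p))
  cat(sprintf("  month-1 uptake ~ contractility: slope %.3g, r = %.3f, p = %.3g\n",
              x$uptake_contractility_fit$slope, x$uptake_contractility_fit$r,
              x$uptake_contractility_fit$p))
  invisible(x)
}
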