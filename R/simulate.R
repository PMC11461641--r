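## Seeded synthetic-cohort generators.
##
## Everything is a pure function of (config, seed): the master seed fans out
## to named stage substreams (imaging, biomarkers, qPCR, bulk, nuclei) so a
## stage can be regenerated without rerunning the others.

## vectorised truncated-normal draw from a (mean, sd) config entry, with the
## latent parameters solved once per call
tn_draw <- function(n, entry, lower = 0, upper = 100) {
  rtnorm(n, entry$mean, entry$sd, lower, upper, moment_match = TRUE)
}

#' Simulate a Match/Mismatch imaging cohort
#'
#' Generates per-animal global CMR/lab parameters, angiographic grades,
#' day-3 and month-1 segmental profiles, circulating biomarker panels and a
#' tissue qPCR Ct table, with the group structure the mismatch analysis
#' assumes: Mismatch animals carry high day-3 FDG uptake co-located with
#' high transmurality in the infarct territory (so the rule-based classifier
#' recovers their label), a month-1 uptake defect, lower EF and larger
#' infarcts; Match animals share the scar but show low day-3 uptake.
#'
#' @param cfg a [cohort_config()].
#' @param n_rna_per_group animals per group in the qPCR/expression arm
#'   (default 3), plus the same number of healthy controls.
#' @return object of class `sim_cohort`: list with `animals` (data.frame of
#'   global parameters incl. latent `group_true`), `profiles` (list of
#'   [segment_profile()], day-3 and month-1 per animal), `biomarkers`
#'   (long data.frame), `qpcr` (long Ct data.frame) and `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), n_rna_per_group = 3L) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_match + cfg$n_mismatch
  ids <- sprintf("A%03d", seq_len(n))
  group <- c(rep("Match", cfg$n_match), rep("Mismatch", cfg$n_mismatch))

  ## --- global parameters ------------------------------------------------
  set.seed(derive_seed(cfg$seed, "globals"))
  per_group <- function(entry, lower = 0, upper = 100) {
    out <- numeric(n)
    for (g in c("Match", "Mismatch")) {
      idx <- which(group == g)
      if (length(idx)) out[idx] <- tn_draw(length(idx), entry[[g]], lower, upper)
    }
    out
  }
  animals <- data.frame(
    animal_id = ids, group_true = group,
    glucose = tn_draw(n, cfg$glucose, lower = 0, upper = Inf),
    ef_day3 = per_group(cfg$ef_day3),
    ef_month1 = per_group(cfg$ef_month1),
    edv_day3 = per_group(cfg$edv_day3, upper = Inf),
    edv_month1 = per_group(cfg$edv_month1, upper = Inf),
    infarct_day3 = per_group(cfg$infarct_day3),
    infarct_month1 = per_group(cfg$infarct_month1),
    mvo = tn_draw(n, cfg$mvo),
    stringsAsFactors = FALSE)
  p_t2 <- unlist(cfg$p_timi2[group])
  p_b2 <- unlist(cfg$p_blush2[group])
  animals$timi_flow <- ifelse(runif(n) < p_t2, 2L, 3L)
  animals$blush_grade <- ifelse(runif(n) < p_b2, 2L, 3L)

  ## --- segmental profiles ----------------------------------------------
  terr <- cfg$infarct_territory$segment_ids
  remote <- setdiff(1:17, terr)
  nt <- length(terr); nr <- length(remote)

  make_profiles <- function(stage, uptake_terr_entry) {
    set.seed(derive_seed(cfg$seed, stage))
    tp <- if (stage == "profiles_day3") "day3" else "month1"
    trans_t <- matrix(tn_draw(n * nt, cfg$transmurality_infarct), n, nt)
    trans_r <- matrix(tn_draw(n * nr, cfg$transmurality_remote), n, nr)
    upt_t <- matrix(0, n, nt)
    for (g in c("Match", "Mismatch")) {
      idx <- which(group == g)
      if (length(idx)) {
        upt_t[idx, ] <- matrix(tn_draw(length(idx) * nt, uptake_terr_entry[[g]]),
                               length(idx), nt)
      }
    }
    upt_r <- matrix(tn_draw(n * nr, cfg$uptake_remote), n, nr)
    ## hottest remote segment is the normalisation reference (reads 100%)
    for (i in seq_len(n)) upt_r[i, which.max(upt_r[i, ])] <- 100
    if (tp == "day3") {
      con_t <- matrix(tn_draw(n * nt, cfg$contractility_infarct_day3, -50, 100), n, nt)
      con_r <- matrix(tn_draw(n * nr, cfg$contractility_remote, -50, 100), n, nr)
    }
    lapply(seq_len(n), function(i) {
      trans <- numeric(17); upt <- numeric(17); con <- numeric(17)
      trans[terr] <- trans_t[i, ]; trans[remote] <- trans_r[i, ]
      upt[terr] <- upt_t[i, ]; upt[remote] <- upt_r[i, ]
      if (tp == "day3") {
        con[terr] <- con_t[i, ]; con[remote] <- con_r[i, ]
      } else {
        ## month-1: contractility couples linearly to uptake (inflammation
        ## resolved, FDG signal tracks viable, contracting tissue)
        m <- cfg$contractility_month1_model
        con <- m$intercept + m$slope * upt + rnorm(17, 0, m$sd)
        con <- pmin(pmax(con, -50), 100)
      }
      segment_profile(ids[i], tp, transmurality = trans, uptake_norm = upt,
                      contractility = con,
                      mvo_extent = if (tp == "day3") animals$mvo[i] else 0)
    })
  }
  profiles <- c(make_profiles("profiles_day3", cfg$uptake_day3_infarct),
                make_profiles("profiles_month1", cfg$uptake_infarct_month1))

  ## --- circulating biomarkers ------------------------------------------
  set.seed(derive_seed(cfg$seed, "biomarkers"))
  tps <- c("baseline", "post_ami_30min", "day3")
  biomarkers <- do.call(rbind, lapply(tps, function(tp) {
    data.frame(animal_id = ids, group = group, timepoint = tp,
               il6 = per_group_entry(cfg$il6[[tp]], group),
               il1b = per_group_entry(cfg$il1b[[tp]], group),
               stringsAsFactors = FALSE)
  }))
  rownames(biomarkers) <- NULL

  ## --- tissue qPCR Ct table (RNA arm + healthy controls) ----------------
  set.seed(derive_seed(cfg$seed, "qpcr"))
  qpcr <- simulate_qpcr(cfg, n_rna_per_group)

  structure(list(animals = animals, profiles = profiles,
                 biomarkers = biomarkers, qpcr = qpcr, config = cfg),
            class = "sim_cohort")
}

per_group_entry <- function(entry, group) {
  out <- numeric(length(group))
  for (g in c("Match", "Mismatch")) {
    idx <- which(group == g)
    if (length(idx)) out[idx] <- tn_draw(length(idx), entry[[g]], 0, Inf)
  }
  out
}

## long Ct table: RNA-arm animals (AMI + Border regions) plus controls
simulate_qpcr <- function(cfg, n_rna_per_group) {
  qp <- cfg$qpcr
  genes <- c(names(qp$target_ct_control), names(qp$ref_ct))
  rows <- list()
  add <- function(animal_id, group, region) {
    ct <- numeric(length(genes)); names(ct) <- genes
    for (g in names(qp$ref_ct)) {
      ct[g] <- tn_draw(1, qp$ref_ct[[g]], 10, 40)
    }
    for (g in names(qp$target_ct_control)) {
      base <- qp$target_ct_control[[g]]$mean
      eff <- if (region == "Control") 0 else qp$log2_effect[[g]][[region]][[group]]
      ## one extra log2 unit of expression = one cycle earlier
      ct[g] <- min(max(base - eff + rnorm(1, 0, qp$noise_sd), 10), 40)
    }
    data.frame(animal_id = animal_id, group = group, region = region,
               gene = genes, ct = unname(ct), stringsAsFactors = FALSE)
  }
  for (g in c("Match", "Mismatch")) {
    for (i in seq_len(n_rna_per_group)) {
      id <- sprintf("R%s%02d", substr(g, 1, 2), i)
      for (region in c("AMI", "Border")) rows[[length(rows) + 1L]] <- add(id, g, region)
    }
  }
  for (i in seq_len(n_rna_per_group)) {
    rows[[length(rows) + 1L]] <- add(sprintf("C%02d", i), "Control", "Control")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d animals (%d Match / %d Mismatch), seed %d\n",
              nrow(x$animals), sum(x$animals$group_true == "Match"),
              sum(x$animals$group_true == "Mismatch"), x$config$seed))
  cat(sprintf("  %d segment profiles, %d biomarker rows, %d qPCR rows\n",
              length(x$profiles), nrow(x$biomarkers), nrow(x$qpcr)))
  invisible(x)
}

#' Day-3 (or month-1) profiles of a simulated cohort
#'
#' @param cohort a `sim_cohort`.
#' @param timepoint `"day3"` or `"month1"`.
#' @return list of [segment_profile()]s.
#' @export
cohort_profiles <- function(cohort, timepoint = c("day3", "month1")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  timepoint <- match.arg(timepoint)
  Filter(function(p) p$timepoint == timepoint, cohort$profiles)
}

## shared gene universe: synthetic background + named markers + mito genes
build_gene_universe <- function(cfg, sigs) {
  bg <- sprintf("G%04d", seq_len(cfg$bulk$n_background_genes))
  named <- unique(c(unlist(sigs$sets, use.names = FALSE), "CD45", mito_gene_list()))
  overlap <- intersect(bg, named)
  if (length(overlap)) stop_input("signature genes overlap background ids: ",
                                  paste(head(overlap), collapse = ", "))
  c(bg, named)
}

#' Simulate bulk expression with additive immune-signature structure
#'
#' Negative-binomial gene-by-sample counts. Marker genes of immune cell type
#' `t` have their mean multiplied by `1 + effect(t, group, region)`, with the
#' largest effects for monocyte/macrophage signatures in Mismatch-AMI, so
#' signature scoring recovers the configured infiltration ordering.
#'
#' @param cfg a [cohort_config()].
#' @param arms data.frame with columns `group` and `region`, one row per
#'   arm; default: Match/Mismatch in AMI and Border plus Control in Remote.
#' @param n_per_arm samples per arm (default 3).
#' @param sigs a [signature_set()].
#' @return object of class `expr_matrix`.
#' @export
simulate_bulk_expression <- function(cfg = cohort_config(),
                                     arms = NULL, n_per_arm = 3L,
                                     sigs = default_signatures()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(sigs, "signature_set"))
  if (is.null(arms)) {
    arms <- rbind(expand.grid(group = c("Match", "Mismatch"),
                              region = c("AMI", "Border"),
                              stringsAsFactors = FALSE),
                  data.frame(group = "Control", region = "Remote"))
  }
  bk <- cfg$bulk
  genes <- build_gene_universe(cfg, sigs)
  set.seed(derive_seed(cfg$seed, "bulk-baseline"))
  mu0 <- rlnorm(length(genes), bk$baseline_meanlog, bk$baseline_sdlog)
  names(mu0) <- genes

  set.seed(derive_seed(cfg$seed, "bulk-counts"))
  n_s <- nrow(arms) * n_per_arm
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_s)),
    group = rep(arms$group, each = n_per_arm),
    region = rep(arms$region, each = n_per_arm),
    stringsAsFactors = FALSE)
  lib <- rlnorm(n_s, bk$libsize_meanlog, bk$libsize_sdlog)
  counts <- matrix(0L, length(genes), n_s, dimnames = list(genes, meta$sample_id))
  for (s in seq_len(n_s)) {
    eff <- rep(1, length(genes)); names(eff) <- genes
    gsc <- bk$group_scale[[meta$group[s]]] %||% 0
    rsc <- bk$region_scale[[meta$region[s]]] %||% 0
    for (type in names(sigs$sets)) {
      base <- bk$effect_ami_match[[type]] %||% 0
      g <- intersect(sigs$sets[[type]], genes)
      eff[g] <- eff[g] + base * gsc * rsc
    }
    mu <- mu0 * eff
    mu <- mu / sum(mu) * lib[s]
    counts[, s] <- rnbinom(length(genes), size = 1 / bk$dispersion, mu = mu)
  }
  expr_matrix(counts, meta)
}

#' Simulate a single-nucleus count matrix with latent structure
#'
#' Each nucleus draws a latent cell type from the configured
#' (region, group) proportions; marker genes of its own type are up-scaled
#' `marker_fold`-fold; the 13 mitochondrial genes receive counts matching a
#' Beta-distributed mito fraction (heavier tail in the AMI region); library
#' sizes are log-normal so detected-gene counts span the 200-gene QC
#' boundary; and hashtag-oligo counts follow a background/signal log-normal
#' mixture with the true sample identity latent.
#'
#' @param cfg a [cohort_config()].
#' @param region `"AMI"`, `"Border"` or `"Remote"`.
#' @param group `"Match"` or `"Mismatch"`.
#' @param n_cells number of nuclei (default from config).
#' @param sigs a [signature_set()]; types must match the configured
#'   proportions.
#' @return object of class `cell_matrix` with latent `type_true`,
#'   `tag_true` and `doublet` columns in `cell_meta` and a `hashtag_counts`
#'   matrix.
#' @export
simulate_nuclei <- function(cfg = cohort_config(),
                            region = c("Border", "AMI", "Remote"),
                            group = c("Match", "Mismatch"),
                            n_cells = NULL, sigs = default_signatures()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(sigs, "signature_set"))
  region <- match.arg(region); group <- match.arg(group)
  nc <- cfg$nuclei
  n_cells <- as.integer(n_cells %||% nc$n_cells)
  props <- nc$proportions[[region]][[group]]
  if (is.null(props)) stop_input("no proportions configured for ", region, "/", group)
  if (abs(sum(props) - 1) > 1e-6) stop_input("cell-type proportions must sum to 1")
  missing_types <- setdiff(names(props)[props > 0], names(sigs$sets))
  if (length(missing_types)) {
    stop_input("no signature for configured type(s): ",
               paste(missing_types, collapse = ", "))
  }

  genes <- build_gene_universe(cfg, sigs)
  mito <- mito_gene_list()
  nonmito <- setdiff(genes, mito)
  set.seed(derive_seed(cfg$seed, "nuclei-baseline"))
  mu0 <- rlnorm(length(genes), nc$baseline_meanlog, nc$baseline_sdlog)
  names(mu0) <- genes

  set.seed(derive_seed(cfg$seed, paste0("nuclei-", region, "-", group)))
  type <- sample(names(props), n_cells, replace = TRUE, prob = props)
  lib <- rlnorm(n_cells, nc$libsize_meanlog, nc$libsize_sdlog)
  mito_frac_target <- rbeta(n_cells, nc$mito_beta[[region]][["shape1"]],
                            nc$mito_beta[[region]][["shape2"]])
  mito_w <- rev(seq_along(mito)); mito_w <- mito_w / sum(mito_w)

  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, sprintf("%s_%s_C%04d",
                                                  substr(region, 1, 1),
                                                  substr(group, 1, 2),
                                                  seq_len(n_cells))))
  for (i in seq_len(n_cells)) {
    mu <- mu0[nonmito]
    mk <- intersect(sigs$sets[[type[i]]], nonmito)
    mu[mk] <- mu[mk] * nc$marker_fold
    mu <- mu / sum(mu) * lib[i]
    x <- rnbinom(length(mu), size = 1 / nc$dispersion, mu = mu)
    counts[nonmito, i] <- x
    tot <- sum(x)
    f <- mito_frac_target[i]
    m_tot <- round(f / (1 - f) * tot)
    if (m_tot > 0) counts[mito, i] <- as.integer(rmultinom(1, m_tot, mito_w))
  }

  ## hashtag-oligo counts (cells x tags)
  ht <- nc$hashtag
  tags <- sprintf("Tag%d", seq_len(ht$n_tags))
  tag_true <- sample(tags, n_cells, replace = TRUE)
  doublet <- runif(n_cells) < ht$doublet_rate
  second <- vapply(seq_len(n_cells), function(i) {
    if (!doublet[i]) NA_character_ else sample(setdiff(tags, tag_true[i]), 1)
  }, character(1))
  hashtag_counts <- matrix(
    round(rlnorm(n_cells * ht$n_tags, ht$background_meanlog, ht$background_sdlog)),
    n_cells, ht$n_tags, dimnames = list(colnames(counts), tags))
  for (i in seq_len(n_cells)) {
    pos <- c(tag_true[i], if (doublet[i]) second[i])
    hashtag_counts[i, pos] <- round(rlnorm(length(pos), ht$signal_meanlog,
                                           ht$signal_sdlog))
  }

  meta <- data.frame(cell_id = colnames(counts), region = region, group = group,
                     type_true = type, tag_true = tag_true, doublet = doublet,
                     stringsAsFactors = FALSE)
  cell_matrix(counts, meta, hashtag_counts = hashtag_counts)
}
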