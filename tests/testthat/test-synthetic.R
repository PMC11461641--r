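test_that("simulation is a pure function of (config, seed)", {
  cfg <- cohort_config(n_match = 6, n_mismatch = 4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # different seed changes the draws
  c2 <- simulate_cohort(cohort_config(n_match = 6, n_mismatch = 4, seed = 100))
  expect_false(identical(a$animals$ef_day3, c2$animals$ef_day3))

  bulk1 <- simulate_bulk_expression(cfg, n_per_arm = 2)
  bulk2 <- simulate_bulk_expression(cfg, n_per_arm = 2)
  expect_identical(bulk1$counts, bulk2$counts)

  n1 <- simulate_nuclei(cfg, "Border", "Match", n_cells = 100)
  n2 <- simulate_nuclei(cfg, "Border", "Match", n_cells = 100)
  expect_identical(n1$counts, n2$counts)
  expect_identical(n1$cell_meta$type_true, n2$cell_meta$type_true)
  expect_identical(n1$hashtag_counts, n2$hashtag_counts)
})

test_that("degenerate zero-variance config classifies every animal by construction", {
  cfg <- cohort_config(n_match = 5, n_mismatch = 5, seed = 5)
  zero_sd <- function(x) {
    if (is.list(x) && all(c("mean", "sd") %in% names(x))) { x$sd <- 0; x }
    else if (is.list(x)) lapply(x, zero_sd)
    else x
  }
  for (nm in c("ef_day3", "ef_month1", "infarct_day3", "infarct_month1",
               "uptake_infarct_month1", "glucose", "edv_day3", "edv_month1",
               "transmurality_infarct", "transmurality_remote",
               "uptake_day3_infarct", "uptake_remote", "contractility_remote",
               "contractility_infarct_day3", "mvo")) {
    cfg[[nm]] <- zero_sd(cfg[[nm]])
  }
  co <- simulate_cohort(cfg)
  expect_true(all(co$animals$glucose == 105))
  res <- cohort_assign(cohort_profiles(co, "day3"))
  got <- setNames(res$table$group, res$table$animal_id)
  expect_identical(unname(got[co$animals$animal_id]), co$animals$group_true)
})

test_that("simulated scalar means converge to configured values (3-SE check, scaled down)", {
  n <- 2000L
  cfg <- cohort_config(n_match = n, n_mismatch = n, seed = 31)
  co <- simulate_cohort(cfg)
  an <- co$animals
  check3se <- function(x, entry) {
    expect_lt(abs(mean(x) - entry$mean), 3 * entry$sd / sqrt(length(x)) + 1e-9)
  }
  check3se(an$ef_day3[an$group_true == "Mismatch"], cfg$ef_day3$Mismatch)
  check3se(an$ef_day3[an$group_true == "Match"], cfg$ef_day3$Match)
  check3se(an$infarct_day3[an$group_true == "Mismatch"], cfg$infarct_day3$Mismatch)
  check3se(an$glucose, cfg$glucose)
  # SDs are reproduced too (loose 5% band at this n)
  expect_equal(sd(an$ef_day3[an$group_true == "Match"]), cfg$ef_day3$Match$sd,
               tolerance = 0.05)
  expect_equal(sd(an$glucose), cfg$glucose$sd, tolerance = 0.05)
})

test_that("label recovery on the default generator reaches 95% (n = 200)", {
  cfg <- cohort_config(n_match = 147, n_mismatch = 53, seed = 17)
  co <- simulate_cohort(cfg)
  res <- cohort_assign(cohort_profiles(co, "day3"))
  got <- setNames(res$table$group, res$table$animal_id)
  acc <- mean(got[co$animals$animal_id] == co$animals$group_true)
  expect_gte(acc, 0.95)
})

test_that("truncated normal draws honour bounds and moment matching", {
  set.seed(301)
  x <- rtnorm(2e4, mean = 56, sd = 23.1, lower = 0, upper = 100)
  expect_true(all(x >= 0 & x <= 100))
  expect_equal(mean(x), 56, tolerance = 0.01)
  expect_equal(sd(x), 23.1, tolerance = 0.02)
  expect_identical(rtnorm(5, 10, 0, 0, 100), rep(10, 5))
  expect_error(rtnorm(5, 120, 5, 0, 100), "bounds")
})

test_that("null bulk config leaves signature scores exchangeable between groups", {
  cfg <- cohort_config(seed = 41)
  cfg$bulk$effect_ami_match[] <- 0
  sigs <- default_signatures()
  bulk <- simulate_bulk_expression(cfg, n_per_arm = 4, sigs = sigs)
  sc <- signature_score(bulk, sigs)
  is_mis <- bulk$sample_meta$group == "Mismatch" & bulk$sample_meta$region == "AMI"
  is_mat <- bulk$sample_meta$group == "Match" & bulk$sample_meta$region == "AMI"
  p <- wilcox.test(sc$score["Monocytes", is_mis],
                   sc$score["Monocytes", is_mat], exact = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("configured monocyte effect raises the Mismatch-AMI score in >= 95% of replicates", {
  sigs <- default_signatures()
  hits <- vapply(1:20, function(r) {
    cfg <- cohort_config(seed = 500 + r)
    bulk <- simulate_bulk_expression(
      cfg, arms = data.frame(group = c("Match", "Mismatch"),
                             region = c("AMI", "AMI")),
      n_per_arm = 10, sigs = sigs)
    sc <- signature_score(bulk, sigs)
    mis <- bulk$sample_meta$group == "Mismatch"
    mean(sc$score["Monocytes", mis]) > mean(sc$score["Monocytes", !mis])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("nuclei generator reproduces its configured latent structure", {
  cfg <- cohort_config(seed = 61)
  ami <- simulate_nuclei(cfg, "AMI", "Mismatch", n_cells = 600)
  rem <- simulate_nuclei(cfg, "Remote", "Mismatch", n_cells = 600)
  # AMI mito fractions are configured heavier than remote
  b_ami <- cfg$nuclei$mito_beta$AMI; b_rem <- cfg$nuclei$mito_beta$Remote
  expect_gt(b_ami[1] / sum(b_ami), b_rem[1] / sum(b_rem))
  expect_gt(mean(ami$cell_meta$mito_fraction), mean(rem$cell_meta$mito_fraction))
  # proportions recovered within Monte-Carlo error (4 SE, binomial)
  p_cm <- cfg$nuclei$proportions$AMI$Mismatch[["Cardiomyocytes"]]
  phat <- mean(ami$cell_meta$type_true == "Cardiomyocytes")
  expect_lt(abs(phat - p_cm), 4 * sqrt(p_cm * (1 - p_cm) / 600))
  # detected genes span the 200-gene QC boundary
  expect_gt(sum(ami$cell_meta$detected_genes < 200), 0)
  expect_gt(sum(ami$cell_meta$detected_genes >= 200), 0)
  # degenerate proportions: all cardiomyocytes
  cfg2 <- cohort_config(seed = 61)
  cfg2$nuclei$proportions$Remote$Match <-
    c(cfg2$nuclei$proportions$Remote$Match["Cardiomyocytes"] * 0 + 1)
  names(cfg2$nuclei$proportions$Remote$Match) <- "Cardiomyocytes"
  nuc <- simulate_nuclei(cfg2, "Remote", "Match", n_cells = 50)
  expect_true(all(nuc$cell_meta$type_true == "Cardiomyocytes"))
})

test_that("config validation rejects impossible inputs", {
  expect_error(cohort_config(n_match = 1, n_mismatch = 0), ">= 2")
  expect_error(cohort_config(glucose = list(mean = 105, sd = -1)), "negative sd")
  cfg <- cohort_config()
  cfg$nuclei$proportions$Border$Match[1] <-
    cfg$nuclei$proportions$Border$Match[1] + 0.2
  expect_error(petmismatch:::validate_cohort_config(cfg), "sum to 1")
  expect_error(cohort_config(bogus_entry = 1), "unknown config element")
})
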