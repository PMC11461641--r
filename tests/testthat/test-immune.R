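test_that("QC filter applies both rules inclusively at the boundaries", {
  genes <- c(sprintf("G%04d", 1:300), mito_gene_list())
  mk_cell <- function(n_detected, mito_frac) {
    x <- numeric(313)
    # n_detected nonmito genes with 1 count each, then mito counts on ND1
    stopifnot(n_detected <= 300)
    x[seq_len(n_detected)] <- 1
    m <- round(mito_frac / (1 - mito_frac) * n_detected)
    x[301] <- m  # ND1
    x
  }
  cells <- cbind(ok = mk_cell(200, 0),         # exactly 200 genes -> retained
                 low = mk_cell(199, 0),        # 199 genes -> removed
                 at20 = mk_cell(240, 0.20),    # exactly 20% mito -> retained
                 over20 = mk_cell(240, 0.25))  # > 20% -> removed
  rownames(cells) <- genes
  # the ND1 count adds one detected gene where mito > 0
  cm <- cell_matrix(cells, data.frame(cell_id = colnames(cells)))
  res <- qc_filter_nuclei(cm)
  expect_setequal(res$cells$cell_meta$cell_id, c("ok", "at20"))
  expect_equal(res$report$n_removed_low_genes, 1L)
  expect_equal(res$report$n_removed_high_mito, 1L)
  expect_equal(res$report$n_retained, 2L)
})

test_that("QC filter equals brute-force per-cell rule re-evaluation", {
  cm <- toy_cell_matrix(n_cells = 80, seed = 501)
  res <- qc_filter_nuclei(cm, min_genes = 250, max_mito = 0.05)
  mito <- intersect(mito_gene_list(), rownames(cm$counts))
  dense <- as.matrix(cm$counts)
  keep_oracle <- vapply(seq_len(ncol(dense)), function(i) {
    x <- dense[, i]
    detected <- sum(x > 0)
    mfrac <- sum(x[mito]) / sum(x)
    detected >= 250 && mfrac <= 0.05
  }, logical(1))
  expect_setequal(res$cells$cell_meta$cell_id,
                  colnames(dense)[keep_oracle])
  # also on a generated nuclei matrix with default rules
  nuc <- simulate_nuclei(cohort_config(seed = 77), "AMI", "Match", n_cells = 300)
  res2 <- qc_filter_nuclei(nuc)
  dense2 <- as.matrix(nuc$counts)
  mito2 <- intersect(mito_gene_list(), rownames(dense2))
  keep2 <- vapply(seq_len(ncol(dense2)), function(i) {
    x <- dense2[, i]
    sum(x > 0) >= 200 && sum(x[mito2]) / sum(x) <= 0.20
  }, logical(1))
  expect_identical(res2$cells$cell_meta$cell_id, colnames(dense2)[keep2])
  expect_error(qc_filter_nuclei(cell_matrix(
    matrix(0, 13, 0, dimnames = list(mito_gene_list(), NULL)),
    data.frame(cell_id = character(0)))), "empty")
})

test_that("hashtag demux recovers latent identities and applies the doublet rule", {
  set.seed(502)
  n <- 600; tags <- c("A", "B", "C")
  true <- sample(tags, n, replace = TRUE)
  counts <- matrix(round(rlnorm(n * 3, log(4), 0.6)), n, 3,
                   dimnames = list(sprintf("c%03d", 1:n), tags))
  for (i in seq_len(n)) counts[i, true[i]] <- round(rlnorm(1, log(250), 0.4))
  # spiked controls: all-zero cell and a two-tag cell
  counts[1, ] <- 0
  counts[2, c("A", "B")] <- c(300, 280); true[2] <- NA
  dm <- demux_hashtags(counts)
  expect_equal(dm$assignment$assignment[1], "negative")
  expect_equal(dm$assignment$assignment[2], "doublet")
  singlets <- which(!is.na(true))[-1]
  recovery <- mean(dm$assignment$assignment[singlets] == true[singlets])
  expect_gte(recovery, 0.98)
  # posterior matrix is aligned and in [0,1]
  expect_true(all(dm$posterior >= 0 & dm$posterior <= 1))
  expect_error(demux_hashtags(counts[, 1, drop = FALSE]), "2 tags")
  expect_error(demux_hashtags(counts[1:5, ]), "20 cells")
})

test_that("demux falls back to a 2-means threshold on degenerate tags", {
  set.seed(503)
  counts <- cbind(A = c(rep(0, 30), rep(500, 10)),
                  B = rep(0, 40))  # constant tag cannot be EM-fitted
  rownames(counts) <- sprintf("c%02d", 1:40)
  dm <- demux_hashtags(counts)
  expect_true(dm$fits$B$fallback)
  expect_equal(unname(dm$assignment$assignment[40]), "A")
  expect_equal(unname(dm$assignment$assignment[1]), "negative")
})

test_that("signature scores: constant signatures score flat, spikes dominate, decoys drop", {
  sigs <- signature_set(list(TypeA = sprintf("A%02d", 1:5),
                             TypeB = sprintf("B%02d", 1:5)))
  genes <- c(sigs$sets$TypeA, sigs$sets$TypeB, sprintf("BG%02d", 1:20))
  n_s <- 6
  set.seed(504)
  counts <- matrix(rpois(length(genes) * n_s, 60), length(genes), n_s,
                   dimnames = list(genes, sprintf("S%d", 1:n_s)))
  # constant signature at value v; equalise library sizes by padding the
  # last background gene so CPM is the same map in every sample
  counts[sigs$sets$TypeA, ] <- 40
  counts[length(genes), ] <- counts[length(genes), ] + max(colSums(counts)) - colSums(counts)
  em <- expr_matrix(counts, data.frame(sample_id = colnames(counts),
                                       group = "Match", region = "AMI"))
  sc <- signature_score(em, sigs)
  v_expected <- log1p(40 * 1e6 / colSums(counts)[[1]])
  expect_equal(unname(sc$score["TypeA", ]), rep(v_expected, n_s))
  expect_equal(unname(sc$relative["TypeA", ]), rep(0, n_s))

  # spike-in: one sample with all TypeB markers x10 has the max TypeB score
  counts2 <- matrix(rpois(length(genes) * n_s, 60), length(genes), n_s,
                    dimnames = list(genes, sprintf("S%d", 1:n_s)))
  counts2[sigs$sets$TypeB, 3] <- counts2[sigs$sets$TypeB, 3] * 10
  em2 <- expr_matrix(counts2, em$sample_meta)
  sc2 <- signature_score(em2, sigs)
  expect_equal(unname(which.max(sc2$score["TypeB", ])), 3L)
})

test_that("coherence filter excludes an anti-correlated decoy gene", {
  set.seed(505)
  n_s <- 10
  base <- seq(20, 200, length.out = n_s)  # strong shared profile
  sig_genes <- sprintf("S%02d", 1:5)
  counts <- t(vapply(sig_genes, function(g) round(base * runif(1, 0.8, 1.2)),
                     numeric(n_s)))
  decoy <- round(rev(base))  # anti-correlated
  bg <- matrix(rpois(20 * n_s, 50), 20, n_s)
  counts <- rbind(counts, DECOY = decoy, bg)
  rownames(counts) <- c(sig_genes, "DECOY", sprintf("BG%02d", 1:20))
  colnames(counts) <- sprintf("S%d", 1:n_s)
  # equalise library sizes so CPM keeps the constructed correlation structure
  counts[25, ] <- counts[25, ] + max(colSums(counts)) - colSums(counts)
  em <- expr_matrix(counts, data.frame(sample_id = colnames(counts),
                                       group = "Match", region = "AMI"))
  sigs <- signature_set(list(TypeX = c(sig_genes, "DECOY")))
  sc <- signature_score(em, sigs)
  expect_false("DECOY" %in% sc$surviving_genes$TypeX)
  expect_setequal(sc$surviving_genes$TypeX, sig_genes)
  expect_true(sc$scorable[["TypeX"]])
})

test_that("signature scores are invariant to per-sample library rescaling", {
  cfg <- cohort_config(seed = 81)
  sigs <- default_signatures()
  bulk <- simulate_bulk_expression(cfg, n_per_arm = 2, sigs = sigs)
  sc1 <- signature_score(bulk, sigs)
  scaled <- bulk$counts
  for (j in seq_len(ncol(scaled))) scaled[, j] <- scaled[, j] * (j + 1L)
  sc2 <- signature_score(expr_matrix(scaled, bulk$sample_meta), sigs)
  expect_equal(sc1$score, sc2$score, tolerance = 1e-12)
})

test_that("too-few surviving genes is reported as not scorable, not dropped", {
  sigs <- signature_set(list(Tiny = c("T01", "T02", "T03")))
  counts <- matrix(rpois(23 * 8, 30), 23, 8,
                   dimnames = list(c("T01", "T02", "T03", sprintf("BG%02d", 1:20)),
                                   sprintf("S%d", 1:8)))
  # one gene anti-coherent to the other two: the median profile follows the
  # majority, so only 2 of 3 genes survive the coherence filter
  counts["T01", ] <- seq(10, 150, length.out = 8)
  counts["T02", ] <- rev(seq(12, 160, length.out = 8))
  counts["T03", ] <- rev(seq(14, 170, length.out = 8))
  counts[23, ] <- counts[23, ] + max(colSums(counts)) - colSums(counts)
  em <- expr_matrix(counts, data.frame(sample_id = colnames(counts),
                                       group = "Match", region = "AMI"))
  sc <- signature_score(em, sigs)
  expect_false(sc$scorable[["Tiny"]])
  expect_true("Tiny" %in% rownames(sc$score))
  expect_true(all(is.na(sc$score["Tiny", ])))
  expect_error(signature_score(em, signature_set(list(Absent = c("Z1", "Z2", "Z3")))),
               ">= 3")
})

test_that("annotation labels cells by marker argmax with a tie margin", {
  sigs <- signature_set(list(TypeA = c("A1", "A2"), TypeB = c("B1", "B2")))
  counts <- cbind(onlyA = c(50, 60, 0, 0),
                  tie = c(30, 30, 30, 30),
                  onlyB = c(0, 0, 45, 55))
  rownames(counts) <- c("A1", "A2", "B1", "B2")
  cm <- cell_matrix(counts, data.frame(cell_id = colnames(counts)),
                    mito = "none-present")
  ann <- annotate_and_count(cm, sigs)
  expect_equal(unname(ann$labels["onlyA"]), "TypeA")
  expect_equal(unname(ann$labels["onlyB"]), "TypeB")
  expect_equal(unname(ann$labels["tie"]), "unassigned")
  tab <- ann$table
  expect_equal(sum(tab$count), 3L)
  expect_equal(tab$percent[tab$type == "TypeA"], 100 / 3)
})

test_that("annotation recovers latent labels at 90% macro-average on default nuclei", {
  cfg <- cohort_config(seed = 91)
  sigs <- default_signatures()
  nuc <- simulate_nuclei(cfg, "Border", "Mismatch", n_cells = 1200, sigs = sigs)
  qc <- qc_filter_nuclei(nuc)
  ann <- annotate_and_count(qc$cells, sigs)
  truth <- qc$cells$cell_meta$type_true
  per_type <- vapply(unique(truth), function(tp) {
    mean(ann$labels[truth == tp] == tp)
  }, numeric(1))
  expect_gte(mean(per_type), 0.90)
})

test_that("de_test handles all-zero genes and wires BH adjustment correctly", {
  set.seed(506)
  genes <- sprintf("G%03d", 1:40)
  counts <- matrix(rnbinom(40 * 60, mu = 20, size = 2), 40, 60,
                   dimnames = list(genes, sprintf("c%02d", 1:60)))
  counts["G001", ] <- 0                      # all-zero gene
  counts["G002", 31:60] <- counts["G002", 31:60] + 80  # strong true effect
  meta <- data.frame(cell_id = colnames(counts),
                     group = rep(c("Match", "Mismatch"), each = 30))
  cm <- cell_matrix(counts, meta, mito = "none-present")
  res <- de_test(cm, contrast = c("Mismatch", "Match"))
  z <- res[res$gene == "G001", ]
  expect_equal(z$p, 1)
  expect_equal(z$log2fc, 0)
  expect_true(res$significant[res$gene == "G002"])
  expect_gt(res$log2fc[res$gene == "G002"], 0)
  # hand-rolled BH oracle over the returned raw p-values
  p <- res$p
  n <- length(p)
  o <- order(p)
  bh <- numeric(n)
  bh[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(res$adjusted_p, pmin(1, bh))
  expect_error(de_test(cm, contrast = c("Mismatch", "Match"), min_cells = 40),
               "Mismatch vs Match")
})

test_that("de_test controls type-I error near nominal under the null", {
  set.seed(507)
  n_genes <- 1000; n_per_arm <- 50
  mu <- runif(n_genes, 5, 50)
  counts <- matrix(rnbinom(n_genes * 2 * n_per_arm, mu = mu, size = 2),
                   n_genes, 2 * n_per_arm,
                   dimnames = list(sprintf("G%04d", 1:n_genes),
                                   sprintf("c%03d", 1:(2 * n_per_arm))))
  meta <- data.frame(cell_id = colnames(counts),
                     group = rep(c("Match", "Mismatch"), each = n_per_arm))
  cm <- cell_matrix(counts, meta, mito = "none-present")
  res <- de_test(cm, contrast = c("Mismatch", "Match"))
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("ora_enrich matches exact hypergeometric enumeration (universe <= 25)", {
  hyper_tail <- function(q, m, N, K) {
    # combinatorial oracle: P(X >= q) by direct enumeration
    js <- q:min(m, K)
    sum(choose(m, js) * choose(N - m, K - js)) / choose(N, K)
  }
  set.seed(508)
  universe <- sprintf("g%02d", 1:20)
  for (i in 1:25) {
    pw <- sample(universe, sample(2:8, 1))
    deg <- sample(universe, sample(2:8, 1))
    res <- ora_enrich(deg, list(P = pw), universe)
    q <- length(intersect(pw, deg))
    expected <- if (q == 0) 1 else hyper_tail(q, length(pw), 20, length(deg))
    expect_equal(res$p, expected, tolerance = 1e-12)
  }
  # worked instance: universe 20, pathway 5, DEGs 5, overlap 3
  res <- ora_enrich(sprintf("g%02d", 1:5),
                    list(P = c("g01", "g02", "g03", "g19", "g20")), universe)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p, hyper_tail(3, 5, 20, 5), tolerance = 1e-12)
})

test_that("ora_enrich degenerate cases behave as defined", {
  universe <- sprintf("g%02d", 1:50)
  deg <- universe[1:5]
  res <- ora_enrich(deg, list(exact = deg, disjoint = universe[40:44]), universe)
  expect_equal(res$p[res$pathway == "disjoint"], 1)       # zero overlap
  expect_lt(res$p[res$pathway == "exact"], 1e-5)          # maximal enrichment
  expect_equal(res$pathway[1], "exact")                   # sorted by adjusted p
  expect_warning(out <- ora_enrich(character(0), list(P = deg), universe), "empty")
  expect_true(all(out$p == 1))
  expect_error(ora_enrich("not-in-universe", list(P = deg), universe), "universe")
})
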