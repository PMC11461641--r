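## Molecular stages: nuclei QC, hashtag demultiplexing, bulk signature
## scoring, marker-based annotation/counting, rank-based differential
## expression, and over-representation analysis.

#' QC-filter single nuclei
#'
#' Retains nuclei with at least `min_genes` detected genes AND a
#' mitochondrial fraction of at most `max_mito` (strictly more than
#' `max_mito` is removed, i.e. exactly 20% is retained). Both metrics are
#' recomputed from the counts.
#'
#' @param cells a [cell_matrix()].
#' @param min_genes minimum detected genes (inclusive; default 200).
#' @param max_mito maximum mitochondrial fraction (inclusive; default 0.20).
#' @param mito mitochondrial gene symbols.
#' @return list with `cells` (filtered [cell_matrix()]) and `report`
#'   (counts removed per criterion and retained).
#' @export
qc_filter_nuclei <- function(cells, min_genes = 200L, max_mito = 0.20,
                             mito = mito_gene_list()) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (ncol(cells$counts) == 0L) stop_input("empty cell matrix")
  if (!any(mito %in% rownames(cells$counts))) {
    stop_input("no mitochondrial genes present in the gene universe")
  }
  detected <- Matrix::colSums(cells$counts > 0)
  tot <- Matrix::colSums(cells$counts)
  msum <- Matrix::colSums(cells$counts[intersect(mito, rownames(cells$counts)), ,
                                       drop = FALSE])
  mfrac <- ifelse(tot > 0, msum / tot, 0)
  low_genes <- detected < min_genes
  high_mito <- mfrac > max_mito
  keep <- !low_genes & !high_mito
  report <- list(n_input = ncol(cells$counts),
                 n_removed_low_genes = sum(low_genes),
                 n_removed_high_mito = sum(high_mito),
                 n_removed = sum(!keep),
                 n_retained = sum(keep),
                 min_genes = min_genes, max_mito = max_mito)
  filtered <- cell_matrix(cells$counts[, keep, drop = FALSE],
                          cells$cell_meta[keep, , drop = FALSE],
                          hashtag_counts = if (is.null(cells$hashtag_counts)) NULL
                                           else cells$hashtag_counts[keep, , drop = FALSE],
                          mito = mito)
  list(cells = filtered, report = report)
}

## two-component univariate Gaussian-mixture EM; component 2 = higher mean
fit_gmm2 <- function(x, max_iter = 200L, tol = 1e-8) {
  n <- length(x)
  if (length(unique(x)) < 2L) {
    return(list(converged = FALSE, fallback = TRUE, threshold = max(x) + 1))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = sort(c(min(x), max(x))),
                                       iter.max = 50))
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  z0 <- (km$cluster == ord[2])
  sg <- c(max(sd(x[!z0]), 1e-3), max(sd(x[z0]), 1e-3))
  sg[is.na(sg)] <- max(sd(x), 1e-3)
  pi1 <- mean(z0)
  pi1 <- min(max(pi1, 0.01), 0.99)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- (1 - pi1) * dnorm(x, mu[1], sg[1])
    d2 <- pi1 * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot  # posterior of the signal component
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi1 <- min(max(mean(g), 1e-4), 1 - 1e-4)
    mu <- c(sum((1 - g) * x) / sum(1 - g), sum(g * x) / sum(g))
    sg <- c(sqrt(sum((1 - g) * (x - mu[1])^2) / sum(1 - g)),
            sqrt(sum(g * (x - mu[2])^2) / sum(g)))
    sg <- pmax(sg, 1e-3)
    if (mu[1] > mu[2]) {  # keep signal = higher mean
      mu <- rev(mu); sg <- rev(sg); pi1 <- 1 - pi1
    }
  }
  if (!converged) {
    ## fallback: hard threshold between the two means of a 2-means split
    return(list(converged = FALSE, fallback = TRUE,
                threshold = mean(mu), mu = mu, sigma = sg, pi_signal = pi1))
  }
  list(converged = TRUE, fallback = FALSE, mu = mu, sigma = sg,
       pi_signal = pi1, posterior = g)
}

#' Demultiplex hashtag-oligo counts
#'
#' For each tag, a two-component Gaussian mixture (background vs signal;
#' signal = higher mean) is fitted to `log1p` counts by
#' expectation-maximisation. A cell is positive for a tag when the signal
#' posterior exceeds 0.5; cells positive for exactly one tag are assigned to
#' it, cells with none are `negative`, cells with two or more are `doublet`.
#' If EM fails to converge for a tag, a hard threshold halfway between the
#' 2-means centres is used and flagged in the fit summary.
#'
#' @param tag_counts cells x tags nonnegative count matrix (at least 2 tags
#'   and 20 cells).
#' @return object of class `hashtag_demux`: list with `assignment`
#'   (data.frame `cell_id`, `assignment`, `n_positive`), `posterior`
#'   (cells x tags signal posteriors) and `fits` (per-tag fit summaries).
#' @export
demux_hashtags <- function(tag_counts) {
  tag_counts <- as.matrix(tag_counts)
  if (ncol(tag_counts) < 2L) stop_input("at least 2 tags required")
  if (nrow(tag_counts) < 20L) stop_input("at least 20 cells required")
  if (any(tag_counts < 0) || anyNA(tag_counts)) {
    stop_input("'tag_counts' must be nonnegative with no NA")
  }
  tags <- colnames(tag_counts) %||% sprintf("Tag%d", seq_len(ncol(tag_counts)))
  cells <- rownames(tag_counts) %||% sprintf("cell%d", seq_len(nrow(tag_counts)))
  posterior <- matrix(0, nrow(tag_counts), ncol(tag_counts),
                      dimnames = list(cells, tags))
  fits <- vector("list", length(tags)); names(fits) <- tags
  for (j in seq_along(tags)) {
    x <- log1p(tag_counts[, j])
    fit <- fit_gmm2(x)
    fits[[j]] <- fit[setdiff(names(fit), "posterior")]
    posterior[, j] <- if (fit$fallback) as.numeric(x > fit$threshold) else fit$posterior
  }
  pos <- posterior > 0.5
  npos <- rowSums(pos)
  assignment <- ifelse(npos == 0L, "negative",
                ifelse(npos >= 2L, "doublet",
                       tags[max.col(posterior, ties.method = "first")]))
  ## single-positive: take the (unique) positive tag, not the max posterior
  single <- which(npos == 1L)
  assignment[single] <- tags[apply(pos[single, , drop = FALSE], 1, which)]
  structure(list(assignment = data.frame(cell_id = cells,
                                         assignment = assignment,
                                         n_positive = as.integer(npos),
                                         stringsAsFactors = FALSE),
                 posterior = posterior, fits = fits),
            class = "hashtag_demux")
}

#' @export
print.hashtag_demux <- function(x, ...) {
  cat(sprintf("<hashtag_demux> %d cells, %d tags\n",
              nrow(x$posterior), ncol(x$posterior)))
  print(table(x$assignment$assignment))
  invisible(x)
}

#' Coherence-filtered immune signature scores for bulk samples
#'
#' Counts are normalised to counts per million and `log1p`-transformed.
#' Within each signature, genes whose Pearson correlation with the
#' signature's per-sample median profile falls below `min_cor` are dropped
#' (co-expression coherence filter); the raw score is the mean transformed
#' expression of the surviving genes, and the relative abundance is that
#' score standardised across samples within each cell type. Types with
#' fewer than 3 surviving genes are reported as not scorable (`NA` scores),
#' never silently dropped.
#'
#' @param bulk an [expr_matrix()].
#' @param sigs a [signature_set()]; each type needs >= 3 genes present in
#'   the matrix.
#' @param min_cor coherence cutoff (default 0.3).
#' @return object of class `signature_scores`: list with `score`
#'   (type x sample raw scores), `relative` (standardised scores),
#'   `surviving_genes` (per-type character vectors) and `scorable`
#'   (named logical).
#' @export
signature_score <- function(bulk, sigs, min_cor = 0.3) {
  stopifnot(inherits(bulk, "expr_matrix"), inherits(sigs, "signature_set"))
  expr <- log_cpm(bulk$counts)
  types <- names(sigs$sets)
  score <- matrix(NA_real_, length(types), ncol(expr),
                  dimnames = list(types, colnames(expr)))
  surviving <- setNames(vector("list", length(types)), types)
  for (type in types) {
    genes <- intersect(sigs$sets[[type]], rownames(expr))
    if (length(genes) < 3L) {
      stop_input(sprintf("signature '%s' has %d gene(s) present; >= 3 required",
                         type, length(genes)))
    }
    sub <- expr[genes, , drop = FALSE]
    med <- apply(sub, 2, median)
    keep <- vapply(genes, function(g) {
      r <- suppressWarnings(cor(sub[g, ], med))
      ## zero-variance gene or flat median profile: correlation undefined;
      ## treat as coherent rather than discard on an uninformative statistic
      is.na(r) || r >= min_cor
    }, logical(1))
    surviving[[type]] <- genes[keep]
    if (sum(keep) >= 3L) {
      score[type, ] <- colMeans(sub[genes[keep], , drop = FALSE])
    }
  }
  scorable <- rowSums(is.na(score)) == 0
  relative <- t(apply(score, 1, function(s) {
    if (anyNA(s)) return(rep(NA_real_, length(s)))
    sdev <- sd(s)
    if (sdev == 0) rep(0, length(s)) else (s - mean(s)) / sdev
  }))
  dimnames(relative) <- dimnames(score)
  structure(list(score = score, relative = relative,
                 surviving_genes = surviving, scorable = scorable,
                 min_cor = min_cor),
            class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %d types x %d samples (%d scorable)\n",
              nrow(x$score), ncol(x$score), sum(x$scorable)))
  invisible(x)
}

#' Marker-based cell-type annotation and counting
#'
#' Per cell, each type's score is the mean `log1p` counts-per-10k over its
#' marker genes; the argmax type is assigned when it beats the runner-up by
#' at least `margin` log-units, otherwise the cell is `unassigned`. The
#' count table mirrors the published layout: type x region x group with
#' absolute counts and percent of the region-group total.
#'
#' @param cells a QC-filtered [cell_matrix()].
#' @param sigs a [signature_set()].
#' @param margin assignment margin in log-units (default 0.25).
#' @return object of class `cell_annotation`: list with `labels` (per-cell
#'   character), `scores` (cells x types), and `table` (data.frame `type`,
#'   `region`, `group`, `count`, `percent`).
#' @export
annotate_and_count <- function(cells, sigs, margin = 0.25) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (!inherits(sigs, "signature_set")) stop_input("'sigs' must be a signature_set")
  expr <- log_norm_cells(cells$counts)
  types <- names(sigs$sets)
  scores <- vapply(types, function(type) {
    genes <- intersect(sigs$sets[[type]], rownames(expr))
    if (length(genes) == 0L) stop_input("no genes of signature '", type,
                                        "' present in the matrix")
    Matrix::colMeans(expr[genes, , drop = FALSE])
  }, numeric(ncol(expr)))
  scores <- matrix(scores, ncol = length(types),
                   dimnames = list(colnames(expr), types))
  labels <- apply(scores, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    if (s[o[1]] - s[o[2]] >= margin) types[o[1]] else "unassigned"
  })
  meta <- cells$cell_meta
  region <- meta$region %||% rep("all", nrow(meta))
  group <- meta$group %||% rep("all", nrow(meta))
  combos <- unique(data.frame(region = region, group = group,
                              stringsAsFactors = FALSE))
  tab <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    in_combo <- region == combos$region[i] & group == combos$group[i]
    total <- sum(in_combo)
    cnt <- vapply(c(types, "unassigned"),
                  function(tp) sum(labels[in_combo] == tp), numeric(1))
    data.frame(type = c(types, "unassigned"), region = combos$region[i],
               group = combos$group[i], count = as.integer(cnt),
               percent = 100 * cnt / total,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(labels = setNames(labels, colnames(expr)), scores = scores,
                 table = tab, margin = margin),
            class = "cell_annotation")
}

#' @export
print.cell_annotation <- function(x, ...) {
  cat(sprintf("<cell_annotation> %d cells, %d assigned (%.1f%%)\n",
              length(x$labels), sum(x$labels != "unassigned"),
              100 * mean(x$labels != "unassigned")))
  invisible(x)
}

#' Rank-based differential expression between two arms
#'
#' Per gene, a Wilcoxon rank-sum test on `log1p` counts-per-10k values plus
#' the log2 fold change of arm means with pseudocount 1; p-values are
#' Benjamini-Hochberg adjusted over all tested genes. Genes with all-zero
#' counts in both arms get `p = 1` and fold change 0.
#'
#' @param cells a [cell_matrix()].
#' @param group_col metadata column holding the contrast labels.
#' @param contrast length-2 character: `c(level_a, level_b)`; the fold
#'   change is a over b.
#' @param type,region optional filters on the matching metadata columns.
#' @param min_cells minimum cells per arm (default 10).
#' @param alpha adjusted-p cutoff defining the DEG set (default 0.05).
#' @return data.frame with `gene`, `log2fc`, `p`, `adjusted_p`,
#'   `significant`, sorted by `adjusted_p`; attribute `n_cells` holds the
#'   per-arm sizes.
#' @export
de_test <- function(cells, contrast = c("Mismatch", "Match"),
                    group_col = "group", type = NULL, region = NULL,
                    min_cells = 10L, alpha = 0.05) {
  stopifnot(inherits(cells, "cell_matrix"), length(contrast) == 2L)
  meta <- cells$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(type)) keep <- keep & meta$type_true %in% type
  if (!is.null(region)) keep <- keep & meta$region %in% region
  g <- meta[[group_col]]
  if (is.null(g)) stop_input("metadata column '", group_col, "' not found")
  in_a <- keep & g == contrast[1]
  in_b <- keep & g == contrast[2]
  if (sum(in_a) < min_cells || sum(in_b) < min_cells) {
    stop_input(sprintf("contrast %s vs %s: arm below %d cells (%d vs %d)",
                       contrast[1], contrast[2], min_cells, sum(in_a), sum(in_b)))
  }
  expr <- log_norm_cells(cells$counts[, in_a | in_b, drop = FALSE])
  arm <- factor(g[in_a | in_b], levels = contrast)
  raw <- cells$counts[, in_a | in_b, drop = FALSE]
  genes <- rownames(expr)
  p <- numeric(length(genes))
  l2fc <- numeric(length(genes))
  a_idx <- arm == contrast[1]
  expr <- as.matrix(expr)
  for (i in seq_along(genes)) {
    xa <- expr[i, a_idx]; xb <- expr[i, !a_idx]
    if (all(xa == 0) && all(xb == 0)) {
      p[i] <- 1; l2fc[i] <- 0
    } else {
      p[i] <- suppressWarnings(
        wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value)
      if (is.na(p[i])) p[i] <- 1
      l2fc[i] <- log2((mean(xa) + 1) / (mean(xb) + 1))
    }
  }
  adj <- p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, log2fc = l2fc, p = p, adjusted_p = adj,
                    significant = adj < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$p), ]
  rownames(out) <- NULL
  attr(out, "n_cells") <- c(sum(in_a), sum(in_b))
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the overlap between the DEG set and the pathway within the gene
#' universe, Benjamini-Hochberg adjusted across pathways.
#'
#' @param deg_genes character vector of differentially expressed genes
#'   (must be a subset of `universe`).
#' @param pathways nonempty named list of gene sets.
#' @param universe character vector of all testable genes.
#' @return data.frame with `pathway`, `size` (in-universe pathway size),
#'   `overlap`, `p`, `adjusted_p`, sorted by adjusted p.
#' @export
ora_enrich <- function(deg_genes, pathways, universe) {
  if (!is.list(pathways) || length(pathways) == 0L || is.null(names(pathways))) {
    stop_input("'pathways' must be a nonempty named list of gene sets")
  }
  universe <- unique(as.character(universe))
  deg_genes <- unique(as.character(deg_genes))
  extra <- setdiff(deg_genes, universe)
  if (length(extra)) {
    stop_input("DEG genes outside the universe: ", paste(head(extra), collapse = ", "))
  }
  if (length(deg_genes) == 0L) {
    warning("empty DEG set: all enrichment p-values are 1", call. = FALSE)
  }
  N <- length(universe); K <- length(deg_genes)
  out <- do.call(rbind, lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    m <- length(pw)
    q <- length(intersect(pw, deg_genes))
    p <- if (q == 0L) 1 else phyper(q - 1, m, N - m, K, lower.tail = FALSE)
    data.frame(pathway = nm, size = m, overlap = q, p = p,
               stringsAsFactors = FALSE)
  }))
  out$adjusted_p <- p.adjust(out$p, method = "BH")
  out <- out[order(out$adjusted_p, out$p), ]
  rownames(out) <- NULL
  out
}
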