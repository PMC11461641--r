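## Readers/writers for the package's delimited and Matrix Market formats.
## Convention: comma-separated UTF-8 with a header row, '.' decimal,
## percents stored on the 0-100 scale.

#' Write segment profiles as a delimited table
#'
#' One row per animal x timepoint with columns `animal_id`, `timepoint`,
#' `mvo`, and `seg01...seg17` blocks for transmurality, normalised uptake
#' and contractility.
#'
#' @param profiles list of [segment_profile()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(profiles, path) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  seg_cols <- function(prefix) sprintf("%s_seg%02d", prefix, 1:17)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "segment_profile"))
    vals <- c(p$transmurality, p$uptake_norm, p$contractility)
    df <- data.frame(animal_id = p$animal_id, timepoint = p$timepoint,
                     mvo = p$mvo_extent, stringsAsFactors = FALSE)
    df[c(seg_cols("transmurality"), seg_cols("uptake"), seg_cols("contractility"))] <-
      as.list(vals)
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read segment profiles from a delimited table
#'
#' Inverse of [write_segment_table()].
#'
#' @param path CSV path.
#' @return list of [segment_profile()]s.
#' @export
read_segment_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  seg_cols <- function(prefix) sprintf("%s_seg%02d", prefix, 1:17)
  need <- c("animal_id", "timepoint", "mvo", seg_cols("transmurality"),
            seg_cols("uptake"), seg_cols("contractility"))
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_input("segment table missing column(s): ",
                               paste(head(miss), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    segment_profile(
      animal_id = tab$animal_id[i], timepoint = tab$timepoint[i],
      transmurality = as.numeric(tab[i, seg_cols("transmurality")]),
      uptake_norm = as.numeric(tab[i, seg_cols("uptake")]),
      contractility = as.numeric(tab[i, seg_cols("contractility")]),
      mvo_extent = tab$mvo[i])
  })
}

#' Write a count matrix as Matrix Market triplets plus index files
#'
#' Writes `<stem>.mtx` (genes x cells/samples), `<stem>.genes.txt`,
#' `<stem>.cols.txt` and, if metadata is present, `<stem>.meta.csv`
#' (and `<stem>.hashtags.csv` for hashtag counts).
#'
#' @param x an [expr_matrix()] or [cell_matrix()].
#' @param stem output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_counts <- function(x, stem) {
  counts <- methods::as(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(counts, paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".cols.txt"))
  meta <- if (inherits(x, "expr_matrix")) x$sample_meta else x$cell_meta
  write.csv(meta, paste0(stem, ".meta.csv"), row.names = FALSE)
  if (inherits(x, "cell_matrix") && !is.null(x$hashtag_counts)) {
    write.csv(data.frame(cell_id = rownames(x$hashtag_counts),
                         x$hashtag_counts, check.names = FALSE),
              paste0(stem, ".hashtags.csv"), row.names = FALSE)
  }
  invisible(stem)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param stem path stem used when writing.
#' @param as `"cell_matrix"` or `"expr_matrix"`.
#' @return the reconstructed container.
#' @export
read_counts <- function(stem, as = c("cell_matrix", "expr_matrix")) {
  as <- match.arg(as)
  counts <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(paste0(stem, ".genes.txt"))
  colnames(counts) <- readLines(paste0(stem, ".cols.txt"))
  meta <- read.csv(paste0(stem, ".meta.csv"), stringsAsFactors = FALSE)
  if (as == "expr_matrix") {
    return(expr_matrix(as.matrix(counts), meta))
  }
  ht_path <- paste0(stem, ".hashtags.csv")
  ht <- NULL
  if (file.exists(ht_path)) {
    df <- read.csv(ht_path, check.names = FALSE, stringsAsFactors = FALSE)
    ht <- as.matrix(df[, -1, drop = FALSE])
    rownames(ht) <- df[[1]]
  }
  ## drop derived columns; cell_matrix() recomputes them
  meta$detected_genes <- NULL
  meta$mito_fraction <- NULL
  cell_matrix(counts, meta, hashtag_counts = ht)
}

#' Write a signature set as a two-column delimited file
#'
#' @param sigs a [signature_set()].
#' @param path output CSV path (columns `type`, `gene`).
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  tab <- do.call(rbind, lapply(names(sigs$sets), function(nm) {
    data.frame(type = nm, gene = sigs$sets[[nm]], stringsAsFactors = FALSE)
  }))
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a signature set from a two-column delimited file
#'
#' @param path CSV path with columns `type`, `gene`.
#' @param provenance provenance tag for the resulting set.
#' @return a [signature_set()].
#' @export
read_signatures <- function(path, provenance = path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("type", "gene") %in% names(tab))) {
    stop_input("signature file needs 'type' and 'gene' columns")
  }
  signature_set(split(tab$gene, factor(tab$type, levels = unique(tab$type))),
                provenance = provenance)
}

#' Write a cohort configuration as JSON
#'
#' @param cfg a [cohort_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  x <- unclass(cfg)
  x$infarct_territory <- list(name = cfg$infarct_territory$name,
                              segment_ids = cfg$infarct_territory$segment_ids)
  x$thresholds <- unclass(cfg$thresholds)
  ## jsonlite drops names of atomic vectors; store them as objects instead
  as_obj <- function(v) as.list(v)
  for (nm in c("effect_ami_match", "group_scale", "region_scale")) {
    x$bulk[[nm]] <- as_obj(x$bulk[[nm]])
  }
  x$nuclei$mito_beta <- lapply(x$nuclei$mito_beta, as_obj)
  x$nuclei$proportions <- lapply(x$nuclei$proportions,
                                 function(g) lapply(g, as_obj))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort configuration from JSON
#'
#' Unspecified elements fall back to the [cohort_config()] defaults; the
#' result is re-validated.
#'
#' @param path JSON path.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$infarct_territory)) {
    x$infarct_territory <- territory(x$infarct_territory$name,
                                     x$infarct_territory$segment_ids)
  }
  if (!is.null(x$thresholds)) {
    x$thresholds <- mismatch_thresholds(x$thresholds$transmurality_min,
                                        x$thresholds$uptake_min,
                                        x$thresholds$min_segments)
  }
  ## named numeric vectors round-trip as lists; restore the ones we use
  relist_num <- function(v) if (is.list(v)) unlist(v) else v
  if (!is.null(x$bulk)) {
    for (nm in c("effect_ami_match", "group_scale", "region_scale")) {
      x$bulk[[nm]] <- relist_num(x$bulk[[nm]])
    }
  }
  if (!is.null(x$nuclei)) {
    x$nuclei$mito_beta <- lapply(x$nuclei$mito_beta, relist_num)
    x$nuclei$proportions <- lapply(x$nuclei$proportions,
                                   function(g) lapply(g, relist_num))
  }
  base <- cohort_config(n_match = x$n_match %||% 22L,
                        n_mismatch = x$n_mismatch %||% 8L,
                        seed = x$seed %||% 1L)
  for (nm in setdiff(names(x), c("n_match", "n_mismatch", "seed"))) {
    if (nm %in% names(base)) base[[nm]] <- x[[nm]]
  }
  validate_cohort_config(base)
  structure(base, class = "cohort_config")
}
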