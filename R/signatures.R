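## Marker-gene signature sets and the mitochondrial gene list.

#' Mitochondrial gene symbols
#'
#' The 13 protein-coding mitochondrial genes used for the single-nucleus
#' mito-fraction QC metric.
#'
#' @return character vector of length 13.
#' @export
mito_gene_list <- function() {
  c("ND1", "ND2", "ND3", "ND4", "ND5", "ND6", "ND4L",
    "COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8")
}

#' Construct a signature set
#'
#' A named list mapping cell types to nonempty marker-gene vectors.
#'
#' @param sets named list of character vectors.
#' @param provenance free-text provenance tag.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(sets, provenance = "user") {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)) ||
      any(names(sets) == "") || anyDuplicated(names(sets))) {
    stop_input("'sets' must be a nonempty named list with unique names")
  }
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (!is.character(g) || length(g) == 0L || anyNA(g)) {
      stop_input(sprintf("signature '%s' must be a nonempty character vector", nm))
    }
    sets[[nm]] <- unique(g)
  }
  structure(list(sets = sets, provenance = provenance), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d cell types (%s)\n", length(x$sets), x$provenance))
  for (nm in names(x$sets)) {
    cat(sprintf("  %-18s %d genes\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

#' Default cell-type marker signatures
#'
#' Synthetic marker panels for the ten cell types the generator emulates.
#' Cardiomyocyte markers use canonical symbols (TNNI3, TNNT2, MYH7, ...);
#' macrophages carry CD68 and TNFa so the qPCR and expression stages share
#' identifiers; remaining panels use synthetic symbols (MON01..., NKC01...).
#'
#' @param n_markers synthetic markers per type (default 8).
#' @return a [signature_set()].
#' @export
default_signatures <- function(n_markers = 8L) {
  syn <- function(prefix) sprintf("%s%02d", prefix, seq_len(n_markers))
  sets <- list(
    Cardiomyocytes = c("TNNI3", "TNNT2", "MYH7", "RYR2", "ABLIM1", "ANKRD1",
                       "SLC8A1", "PDE4D"),
    Fibroblasts = syn("FIB"),
    `Endothelial cells` = syn("END"),
    Pericytes = syn("PER"),
    Monocytes = syn("MON"),
    Macrophages = c("CD68", "TNFa", syn("MAC")[seq_len(n_markers - 2L)]),
    `NK cells` = syn("NKC"),
    `B cells` = syn("BCL"),
    `T cells` = syn("TCL"),
    Neutrophils = syn("NEU"))
  signature_set(sets, provenance = "synthetic default panel")
}
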