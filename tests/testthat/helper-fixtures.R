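# Fixtures built in code: hand-specified profiles and small random ones.

# profile with given values in the infarct territory and low values elsewhere
make_profile <- function(id = "p1", timepoint = "day3",
                         terr = lad_territory()$segment_ids,
                         trans_terr = 0, upt_terr = 0,
                         trans_rest = 0, upt_rest = 50, mvo = 0) {
  trans <- rep(trans_rest, 17); trans[terr] <- trans_terr
  upt <- rep(upt_rest, 17); upt[terr] <- upt_terr
  upt[setdiff(1:17, terr)[1]] <- 100  # normalisation reference segment
  segment_profile(id, timepoint, transmurality = trans, uptake_norm = upt,
                  mvo_extent = mvo)
}

random_profile <- function(id = "r1", timepoint = "day3") {
  upt <- runif(17, 0, 100)
  upt[sample(17, 1)] <- 100
  segment_profile(id, timepoint,
                  transmurality = runif(17, 0, 100),
                  uptake_norm = upt,
                  contractility = runif(17, -50, 100),
                  mvo_extent = runif(1, 0, 30))
}

# tiny nuclei matrix with hand-controlled detected-gene and mito properties
toy_cell_matrix <- function(n_cells = 50, n_genes = 300, seed = 42) {
  set.seed(seed)
  genes <- c(sprintf("G%04d", seq_len(n_genes - 13)), mito_gene_list())
  counts <- matrix(rpois(n_genes * n_cells, lambda = 2), n_genes, n_cells,
                   dimnames = list(genes, sprintf("c%03d", seq_len(n_cells))))
  meta <- data.frame(cell_id = colnames(counts), region = "Border",
                     group = "Match", stringsAsFactors = FALSE)
  cell_matrix(counts, meta)
}
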