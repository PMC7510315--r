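# Hand-built 10-record cascade fixture.  Stage-by-stage trace:
#   input: 10
#   quality: removes 2 non-PASS + 1 indel in a poly-N run -> 7
#   population: removes 2 records at 1% population frequency -> 5
#   functional: removes 1 silent record -> 4
#   panel: removes 1 off-panel record -> 3
make_cascade_fixture <- function() {
  base <- tibble::tibble(
    sample_id = sprintf("T%03d", 1:10),
    chrom = "chr1",
    pos = 1000L + 1:10,
    ref = "A",
    alt = "C",
    filter_status = "PASS",
    alt_depth = 20L,
    alt_rate = 0.5,
    is_indel = FALSE,
    in_polyN_region = FALSE,
    pop_freq_1kg = NA_real_,
    pop_freq_esp = NA_real_,
    region_class = "exonic",
    consequence = "protein-changing",
    gene_symbol = "VHL"
  )
  base$filter_status[1:2] <- "LowQual"          # fail quality
  base$is_indel[3] <- TRUE                      # indel in poly-N run
  base$in_polyN_region[3] <- TRUE
  base$alt <- ifelse(base$is_indel, "AC", base$alt)
  base$pop_freq_1kg[4] <- 0.01                  # fail population
  base$pop_freq_esp[5] <- 0.01
  base$consequence[6] <- "silent"               # fail functional
  base$gene_symbol[7] <- "NOTCANCER"            # fail panel
  list(records = base, panel = c("VHL", "PBRM1", "SETD2"))
}

# Small named reference-profile matrix for deconvolution tests.
make_reference <- function(n_genes = 60, types = c("B", "CD4T", "CD8T",
                                                   "NK", "Mac", "Endo",
                                                   "CAF"),
                           seed = 42) {
  set.seed(seed)
  matrix(runif(n_genes * length(types), 0.5, 10), n_genes, length(types),
         dimnames = list(sprintf("g%03d", seq_len(n_genes)), types))
}

# Random fraction matrix with row sums <= max_total.
make_fractions <- function(n_samples, types, max_total = 0.95, seed = 43) {
  set.seed(seed)
  f <- matrix(runif(n_samples * length(types)), n_samples, length(types))
  f <- f / rowSums(f) * runif(n_samples, 0.4, max_total)
  dimnames(f) <- list(sprintf("S%03d", seq_len(n_samples)), types)
  f
}
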