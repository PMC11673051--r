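# Small fixture builders shared across test files.

# tiny panel from an explicit haplotype matrix
toy_panel <- function(mat, positions = NULL, contig_length = NULL, ...) {
  mat <- as.matrix(mat)
  if (is.null(positions)) positions <- seq_len(ncol(mat)) * 100L
  hap_panel(mat, positions, contig_length = contig_length, ...)
}

# popmap assigning the first n1 samples to pop "A" and the rest to "B"
toy_popmap <- function(panel, n1) {
  ids <- panel$sample_ids
  stats::setNames(c(rep("A", n1), rep("B", length(ids) - n1)), ids)
}

# moderate simulated cohort cached per (seed, extra args) within a test file
.sim_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cohort(seed = seed, ...)
  .sim_cache[[key]]
}

# small fast cohort for structural checks
small_cohort <- function(seed, ...) {
  cached_cohort(seed, seq_length = 1e6, mut_rate = 1.5e-3,
                sizes = c(xiangnan = 6, indicine = 6, taurine = 5,
                          banteng = 4, outgroup = 2), ...)
}
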