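# Shared fixture builders.  Everything is generated in code at test time.

# small default configuration for fast unit tests
tiny_config <- function(seed = 42, n_cpgs = 20, ...) {
  sim_config(seed = seed, n_brood_pairs = 4, brood_size_mean = 4,
             n_cpgs = n_cpgs, ...)
}

# the calibration-scale study conditions: 16 origin broods in 8
# cross-fostering pairs, ~64 nestlings, coverage ~30x
study_config <- function(seed, ...) {
  sim_config(seed = seed, n_brood_pairs = 8, brood_size_mean = 4,
             coverage_mean = 30, ...)
}

# hand-built 2x2-cell design with b broods per treatment arm, all crossed
manual_design <- function(n_per_cell = 8, n_broods = 4) {
  n <- 4 * n_per_cell
  data.frame(
    individual = sprintf("i%03d", seq_len(n)),
    sex = rep(c("F", "M"), each = 2 * n_per_cell),
    treatment = rep(rep(c("control", "testosterone"), each = n_per_cell), 2),
    brood_origin = sprintf("o%d", rep_len(seq_len(n_broods), n)),
    brood_rearing = sprintf("r%d", rep_len(seq_len(n_broods), n + 1)[-1]),
    stringsAsFactors = FALSE)
}

# small methylation matrix from explicit cell values
manual_matrix <- function(meth, cov, chrom = "chr1",
                          pos = seq_len(nrow(meth)) * 100L,
                          strand = "merged",
                          individuals = sprintf("i%03d", seq_len(ncol(meth)))) {
  methylation_matrix(
    data.frame(chrom = chrom, pos = pos, strand = strand,
               stringsAsFactors = FALSE),
    individuals, meth, cov)
}
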