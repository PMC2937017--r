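# fixture builders shared across the suite

toy_genome <- function() genome_build(c("chr1", "chr2"), c(100e6, 80e6))

# profile from a compact segment spec: list of c(start, end, n_probes,
# log2) per chromosome
make_profile <- function(sample, segs, chrom = "chr1", genome = NULL) {
  df <- as.data.frame(do.call(rbind, segs))
  names(df) <- c("start", "end", "n_probes", "log2")
  df$chrom <- rep_len(chrom, nrow(df))
  cn_profile(sample, df, genome = genome)
}

# a flat whole-genome profile with one segment per chromosome
flat_profile <- function(sample, genome = toy_genome(), log2 = 0) {
  cn_profile(sample, data.frame(chrom = genome$chrom, start = 0,
                                end = genome$length, n_probes = 1000,
                                log2 = log2), genome = genome)
}

# cohort where `k` of `n` samples carry a gain over [a, b) on chr1
cohort_with_gain <- function(n, k, a, b, log2 = 1.2,
                             genome = toy_genome()) {
  lapply(seq_len(n), function(i) {
    if (i <= k) {
      cn_profile(sprintf("S%02d", i), data.frame(
        chrom = c("chr1", "chr1", "chr1", "chr2"),
        start = c(0, a, b, 0),
        end = c(a, b, genome$length[1], genome$length[2]),
        n_probes = c(500, 100, 500, 800),
        log2 = c(0, log2, 0, 0)), genome = genome)
    } else {
      flat_profile(sprintf("S%02d", i), genome)
    }
  })
}

# minimal one-chromosome config for fast large-n simulation
mini_config <- function(n_tumours, region_specs = list(), seed = 1,
                        n_factors = 0, noise_sd = 0.05, n_normals = 0,
                        cnp_specs = NULL) {
  sim_config(genome_build("chr1", 100e6), n_tumours, n_normals,
             region_specs, n_factors = n_factors, cnp_specs = cnp_specs,
             noise_sd = noise_sd, probes_per_mb = 50,
             breakpoint_rate = 0.01, seed = seed)
}
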