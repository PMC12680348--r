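# Shared study conditions for the synthetic test classes.
#
# Both classes use the default 25-allele grid centred on an optimal allele of
# 13 repeat units and a realistic step law (90% single-step mutations, modest
# contraction bias). The baseline rates mirror the standard validation
# regimes: 1e-4 per generation for the high-mutation dinucleotide class and
# 1e-5 for the low-mutation class. All simulation-heavy tests run the 1/10
# rescaled demography, which preserves 4*N*mu and 2*N*s.

test_grid <- function() allele_grid(xopt = 13L)

high_mut_model <- function() mutation_model(1e-4, L = 0, rho = 0.9, beta = 0.25)
low_mut_model <- function() mutation_model(1e-5, L = 0, rho = 0.9, beta = 0.25)

TEST_SCALE <- 10
TEST_SAMPLE <- 1000L

# lookup tables are expensive; build each at most once per test run
.lut_cache <- new.env(parent = emptyenv())

cached_lookup <- function(which = c("high", "low")) {
  which <- match.arg(which)
  if (is.null(.lut_cache[[which]])) {
    mut <- if (which == "high") high_mut_model() else low_mut_model()
    set.seed(if (which == "high") 20101L else 20102L)
    .lut_cache[[which]] <- build_lookup_table(
      paste0(which, "_mut:13"), mut, default_demography(), test_grid(),
      sample_size = TEST_SAMPLE, reps_per_s = 50L, scale = TEST_SCALE
    )
  }
  .lut_cache[[which]]
}

# simulate a dataset of per-locus heterozygosities (and optionally keep the
# sampled frequency vectors); s_fun maps locus index -> selection coefficient
sim_class_data <- function(mut, s_fun, n_loci, sample_size = TEST_SAMPLE,
                           scale = TEST_SCALE, keep_freqs = FALSE) {
  prep <- strsel:::prepare_sim(mut, default_demography(), test_grid(), scale)
  freqs <- lapply(seq_len(n_loci), function(i) {
    end_sample(strsel:::run_trajectory(prep, min(s_fun(i), 1)), sample_size)
  })
  hets <- vapply(freqs, heterozygosity, numeric(1))
  if (keep_freqs) list(hets = hets, freqs = freqs) else list(hets = hets)
}

gamma_s_fun <- function(a, mean_s) {
  function(i) stats::rgamma(1, shape = a) * mean_s / a
}
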