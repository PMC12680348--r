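test_that("simulated trajectories are seed-deterministic and respect degenerate limits", {
  g <- test_grid()
  # no effective mutation + no selection: the optimal allele stays fixed
  quiet <- mutation_model(1e-8, rate_floor = 1e-9)
  tiny <- demographic_model(tibble::tibble(duration = 50, n_start = 50, rate = 0))
  set.seed(5)
  loc <- simulate_locus(quiet, 0, tiny, g, sample_size = 100)
  expect_equal(loc$freqs, init_freqs(g))
  # bit-identical under the same seed
  hm <- high_mut_model()
  set.seed(123)
  a <- simulate_locus(hm, 0.01, default_demography(), g, 1000, scale = TEST_SCALE)
  set.seed(123)
  b <- simulate_locus(hm, 0.01, default_demography(), g, 1000, scale = TEST_SCALE)
  expect_identical(a$freqs, b$freqs)
  expect_true(all(a$freqs >= 0))
  expect_equal(sum(a$freqs), 1)
})

test_that("end sampling is a plain multinomial with the right mean", {
  mono <- c(0, 1, 0)
  expect_equal(end_sample(mono, 50), mono)
  set.seed(2)
  draws <- replicate(50, end_sample(c(0.5, 0.5), 2))
  expect_true(all(draws[1, ] %in% c(0, 0.5, 1)))
  set.seed(3)
  reps <- replicate(10000, end_sample(c(0.3, 0.7), 100))
  se <- sqrt(0.3 * 0.7 / 100) / sqrt(10000)
  expect_lt(abs(mean(reps[1, ]) - 0.3), 3 * se)
})

test_that("selection coefficients round to one-significant-digit lookup keys", {
  expect_equal(round_s(0.00234), 0.002)
  expect_equal(round_s(8e-6), 0)
  expect_equal(round_s(0.049), 0.05)
  expect_equal(round_s(c(0, 1e-5, 0.9999)), c(0, 1e-5, 1))
  expect_error(round_s(-0.1), ">= 0")
  # every key on the ladder is its own fixed point
  ladder <- strsel:::lookup_s_grid()
  expect_equal(round_s(ladder), ladder)
})

test_that("lookup tables index replicates by rounded s and serve queries", {
  g <- test_grid()
  tiny <- demographic_model(tibble::tibble(duration = 30, n_start = 100, rate = 0))
  set.seed(9)
  lut <- build_lookup_table("AC:13", high_mut_model(), tiny, g,
                            sample_size = 100, s_grid = c(0, 0.001), reps_per_s = 2)
  expect_setequal(unique(lut$table$s_key), c(0, 0.001))
  expect_identical(nrow(lut$table), 4L)
  # queries resolve through round_s: 0.00234 -> served from an existing key
  set.seed(1)
  expect_length(strsel:::lookup_hets(lut, round_s(c(0.0013, 8e-6))), 2)
  expect_error(strsel:::lookup_hets(lut, 0.05), "does not cover")
  expect_error(build_lookup_table("AC:13", high_mut_model(), tiny, g,
                                  s_grid = numeric(0)), "non-empty")
  # TSV round trip preserves keys, heterozygosities and frequency vectors
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_table(lut, path)
  lut2 <- read_lookup_table(path)
  expect_equal(lut2$table$het, lut$table$het)
  expect_equal(lut2$table$freqs, lut$table$freqs)
  expect_equal(lut2$grid$xopt, g$xopt)
})

test_that("modal allele takes the argmax with ties toward the optimum then shorter", {
  g <- test_grid()
  expect_identical(modal_allele(init_freqs(g), g), 0L)
  p <- numeric(25); p[12] <- 0.4; p[13] <- 0.35; p[20] <- 0.25
  expect_identical(modal_allele(p, g), -1L)
  p2 <- numeric(25); p2[11] <- 0.5; p2[15] <- 0.5  # k = -2 vs +2
  expect_identical(modal_allele(p2, g), -2L)
  p3 <- numeric(25); p3[13] <- 0.5; p3[15] <- 0.5  # optimum wins ties
  expect_identical(modal_allele(p3, g), 0L)
})

test_that("heterozygosity responds to mutation rate, selection and bias as expected", {
  set.seed(31)
  n_rep <- 60
  mean_het <- function(mu0, s, beta = 0.25) {
    m <- mutation_model(mu0, L = 0, rho = 0.9, beta = beta)
    mean(sim_class_data(m, function(i) s, n_rep)$hets)
  }
  # heterozygosity rises with mutation rate under neutrality
  h_mu <- c(mean_het(1e-6, 0), mean_het(1e-5, 0), mean_het(1e-4, 0))
  expect_true(all(diff(h_mu) > 0))
  # and falls with selection strength at fixed mutation rate
  h_s <- c(mean_het(1e-4, 0), mean_het(1e-4, 1e-2), mean_het(1e-4, 1e-1))
  expect_true(all(diff(h_s) < 0))
  # directional bias pulls alleles toward the optimum: mean |k| shrinks
  set.seed(32)
  mean_absk <- function(beta) {
    m <- mutation_model(1e-4, L = 0, rho = 0.9, beta = beta)
    dat <- sim_class_data(m, function(i) 0, n_rep, keep_freqs = TRUE)
    mean(vapply(dat$freqs, function(p) sum(p * abs(test_grid()$offsets)), 1))
  }
  expect_lt(mean_absk(0.5), mean_absk(0))
})

test_that("modal-optimal agreement is high under strong selection and rises with s", {
  set.seed(41)
  d <- default_demography()
  frac <- vapply(c(0, 1e-3, 1e-1), function(s) {
    modal_match_fraction(high_mut_model(), s, d, test_grid(), n_loci = 60,
                         sample_size = TEST_SAMPLE, scale = TEST_SCALE)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gte(frac[3], 0.95)
  # nothing mutates -> the mode is always the optimum
  quiet <- mutation_model(1e-8, rate_floor = 1e-9)
  tiny <- demographic_model(tibble::tibble(duration = 20, n_start = 50, rate = 0))
  expect_identical(
    modal_match_fraction(quiet, 0, tiny, test_grid(), n_loci = 5, sample_size = 100),
    1
  )
})

test_that("genotyping-error injection flips calls to +/-1 neighbours at the stated rate", {
  g <- test_grid()
  # rate 0 reproduces a plain end sample under the same seed
  p <- c(rep(0, 10), 0.2, 0.2, 0.2, 0.2, 0.2, rep(0, 10))
  set.seed(55); plain <- end_sample(p, 500)
  set.seed(55); noerr <- inject_genotyping_errors(p, 500, error_model(0), g)
  expect_identical(noerr, plain)
  # rate 1 at the optimum: every call moves one unit away, about half each side
  set.seed(56)
  forced <- inject_genotyping_errors(init_freqs(g), 10000, error_model(1), g)
  expect_equal(forced[13], 0)
  expect_equal(forced[12] + forced[14], 1)
  expect_lt(abs(forced[12] - 0.5), 0.03)
  # expected flip count at the published 0.1% rate with N = 1068 alleles
  set.seed(57)
  flips <- replicate(2000, {
    out <- inject_genotyping_errors(init_freqs(g), 1068, error_model(0.001), g)
    1068 * (1 - out[13])
  })
  expect_lt(abs(mean(flips) - 1.068), 3 * sd(flips) / sqrt(length(flips)))
  # boundary calls move inward
  edge <- numeric(25); edge[25] <- 1
  set.seed(58)
  moved <- inject_genotyping_errors(edge, 1000, error_model(1), g)
  expect_equal(moved[24], 1)
})
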