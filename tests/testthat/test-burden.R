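class_rec <- function(...) {
  defaults <- list(class_key = "AC:13", n_loci = 1, mu_opt = 1e-3, rho = 1,
                   a = 0.6, b = 0.01 / 0.6, mean_s = 0.01, ks_score = 90)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("de novo STR class burden matches hand-computed cases and scales linearly", {
  # rho = 1 forces single-step mutations: burden = N*2*mu*(s*0.5)
  one <- str_denovo_burden(class_rec())
  expect_equal(one$burden, 1e-5)
  expect_equal(str_denovo_burden(class_rec(n_loci = 100, mu_opt = 1e-4))$burden, 1e-4)
  expect_equal(str_denovo_burden(class_rec(mean_s = 0))$burden, 0)
  # linear in N, mu and s
  base <- str_denovo_burden(class_rec(rho = 0.6))$burden
  expect_equal(str_denovo_burden(class_rec(rho = 0.6, n_loci = 7))$burden, 7 * base)
  expect_equal(str_denovo_burden(class_rec(rho = 0.6, mu_opt = 3e-3))$burden,
               3 * base, tolerance = 1e-9)
  expect_equal(str_denovo_burden(class_rec(rho = 0.6, mean_s = 0.03))$burden, 3 * base)
  # smaller rho means larger expected steps, hence more burden per mutation
  rhos <- c(0.9, 0.6, 0.3)
  burdens <- vapply(rhos, function(r) str_denovo_burden(class_rec(rho = r))$burden, 1)
  expect_true(all(diff(burdens) > 0))
  # the halved (allele-scale) variant
  expect_equal(str_denovo_burden(class_rec(), scaled = TRUE)$burden, 5e-6)
  # truncation beyond |step| = 20 is reported, not renormalised
  tr <- str_denovo_burden(class_rec(rho = 0.1))
  expect_equal(tr$truncation_deficit, 0.9^20)
  expect_lt(tr$burden_per_mutation,
            str_denovo_burden(class_rec(rho = 0.1), max_step = 2000)$burden_per_mutation)
})

test_that("genome-wide burden sums well-fitting classes and reports exclusions", {
  a <- class_rec(class_key = "AC:13")
  b <- class_rec(class_key = "AT:14", n_loci = 10, mu_opt = 1e-4)
  both <- dplyr::bind_rows(a, b)
  tot <- str_burden_total(both)
  expect_equal(tot$total_burden,
               str_denovo_burden(a)$burden + str_denovo_burden(b)$burden)
  expect_equal(tot$total_mutations, 2 * 1e-3 * 1 + 2 * 1e-4 * 10)
  # additivity over any partition
  expect_equal(tot$total_burden,
               str_burden_total(a)$total_burden + str_burden_total(b)$total_burden)
  # a poorly fitting class contributes zero and is counted as excluded
  bad <- dplyr::bind_rows(a, class_rec(class_key = "AG:15", ks_score = 40))
  tot_bad <- str_burden_total(bad)
  expect_equal(tot_bad$total_burden, str_denovo_burden(a)$burden)
  expect_identical(tot_bad$n_classes_excluded, 1L)
  expect_true(str_denovo_burden(bad)$excluded[2])
})

test_that("SNV burden bookkeeping reproduces the closed form", {
  rec <- tibble::tibble(label = c("nonsyn", "cnc"), mean_s = c(0.0066, 0.00056),
                        mutations_per_generation = c(0.56, 2.54))
  out <- snv_denovo_burden(rec)
  expect_equal(out$burden, c(0.0066 * 0.56, 0.00056 * 2.54))
  # mutations derived from target size and per-bp rate when not given
  out2 <- snv_denovo_burden(tibble::tibble(label = "x", mean_s = 0.001,
                                           target_size = 1e7, mu = 1.2e-8))
  expect_equal(out2$mutations_per_generation, 2 * 1e7 * 1.2e-8)
  expect_equal(snv_denovo_burden(tibble::tibble(label = "null", mean_s = 0,
                                                mutations_per_generation = 5))$burden, 0)
  expect_error(snv_denovo_burden(tibble::tibble(label = "y", mean_s = 1)), "target_size")
  # linear extrapolation in the fraction of sites under selection
  expect_equal(extrapolate_noncoding_burden(0.00571, 0.20, 0.30), 0.00571 * 1.5)
})

test_that("inherited-allele s draws weight by segregating frequency (worked example)", {
  pairs <- tibble::tibble(s = c(1e-4, 1e-3, 1e-2), freq = c(0.5, 0.2, 0.1))
  # the sampling weights are exactly freq / sum(freq) = 5/8, 1/4, 1/8
  expect_equal(pairs$freq / sum(pairs$freq), c(5 / 8, 1 / 4, 1 / 8))
  set.seed(301)
  draws <- replicate(16000, weighted_s_draw(pairs))
  expect_equal(mean(draws == 1e-4), 5 / 8, tolerance = 0.02)
  expect_equal(mean(draws == 1e-3), 1 / 4, tolerance = 0.03)
  expect_equal(mean(draws == 1e-2), 1 / 8, tolerance = 0.03)
  expect_identical(weighted_s_draw(pairs[0, ]), 0)
})

test_that("inherited burden applies the clamping and exclusion rules", {
  recs <- dplyr::bind_rows(
    class_rec(class_key = "good", ks_score = 90),
    class_rec(class_key = "poor", ks_score = 40)
  )
  sampler_fixed <- function(s) function(rec, offset) s
  run <- function(variants, s) {
    str_inherited_burden(variants, recs, s_sampler = sampler_fixed(s))
  }
  v <- function(key, off) tibble::tibble(class_key = key, offset = off)
  # optimal-allele variants carry no burden
  expect_equal(run(v("good", 0), 0.5)$total_burden, 0)
  # beyond the modelled grid (offset > 12): s forced to 0
  expect_equal(run(v("good", 15), 0.5)$total_burden, 0)
  # tiny reductions round down to 0
  tiny <- run(v("good", 1), 5e-6)
  expect_equal(tiny$total_burden, 0)
  expect_identical(tiny$n_zeroed, 1L)
  # reductions above 1 cap at 1
  expect_equal(run(v("good", 12), 0.2)$total_burden, 1)
  # poor-fit classes are excluded entirely
  poor <- run(v("poor", 5), 0.1)
  expect_equal(poor$total_burden, 0)
  expect_identical(poor$n_excluded_class, 1L)
  # sums across variants; the scaled variant halves each reduction
  mixed <- dplyr::bind_rows(v("good", 2), v("good", 3))
  expect_equal(run(mixed, 0.01)$total_burden, 0.02 + 0.03)
  expect_equal(str_inherited_burden(mixed, recs, scaled = TRUE,
                                    s_sampler = sampler_fixed(0.01))$total_burden,
               (0.02 + 0.03) / 2)
  expect_error(run(v("unknown", 1), 0.1), "unknown class")
})

test_that("simulation-backed inherited s sampling returns zero off-grid and a table on it", {
  g <- test_grid()
  rec <- class_rec()
  off_grid <- inherited_allele_s(rec, 15, high_mut_model(),
                                 default_demography(), g, n_draws = 5,
                                 scale = TEST_SCALE)
  expect_identical(off_grid$s, 0)
  expect_identical(nrow(off_grid$pairs), 0L)
  set.seed(311)
  on_grid <- inherited_allele_s(rec, 1, high_mut_model(),
                                default_demography(), g, n_draws = 30,
                                sample_size = 500, scale = TEST_SCALE)
  expect_true(on_grid$s >= 0)
  expect_true(all(on_grid$pairs$freq > 0))
})

test_that("new-mutation scoring is the signed offset difference times mean s", {
  expect_equal(score_mutation(0.001, 0, 3), 0.003)
  expect_equal(score_mutation(0.001, 3, 0), -0.003)
  expect_equal(score_mutation(0.001, 2, 2), 0)
  expect_error(score_mutation(0.001, -1, 2), ">= 0")
})
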