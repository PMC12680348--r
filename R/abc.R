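#' Prior on the gamma DFE parameters
#'
#' The shape `a` is uniform on `[a_low, a_high]` and the mean `a*b` is
#' lognormal: `log(mean)` is normal with mean `mean_log_center` and standard
#' deviation `mean_log_sd` (natural logs). The scale is recovered as
#' `b = mean / a`. Defaults centre the mean at 3e-4 with a spread factor of
#' 30, spanning the range of selective effects reported for SNVs.
#'
#' @param a_low,a_high Uniform bounds for the shape.
#' @param mean_log_center Mean of `log(a*b)`.
#' @param mean_log_sd Standard deviation of `log(a*b)`.
#' @return Object of class `gamma_prior`.
#' @export
gamma_prior <- function(a_low = 0, a_high = 1,
                        mean_log_center = log(3e-4),
                        mean_log_sd = log(30)) {
  stopifnot(a_low < a_high, mean_log_sd > 0)
  structure(
    list(a_low = a_low, a_high = a_high,
         mean_log_center = mean_log_center, mean_log_sd = mean_log_sd),
    class = "gamma_prior"
  )
}

#' Draw (a, b) pairs from the prior
#'
#' @param prior A [gamma_prior()].
#' @param n Number of draws.
#' @return Tibble with columns `a`, `b`, `mean_s` (= a*b).
#' @export
sample_prior <- function(prior, n = 1L) {
  a <- stats::runif(n, prior$a_low, prior$a_high)
  m <- stats::rlnorm(n, prior$mean_log_center, prior$mean_log_sd)
  tibble::tibble(a = a, b = m / a, mean_s = m)
}

#' ABC run configuration
#'
#' @param n_draws Number of prior draws `z` (default 50,000).
#' @param accept_fraction Fraction of draws accepted (default 0.01, the top
#'   1\% by distance).
#' @param subset_size Observed loci are subsampled to at most this many
#'   before inference (default 1,000).
#' @return Object of class `abc_config`.
#' @export
abc_config <- function(n_draws = 50000L, accept_fraction = 0.01,
                       subset_size = 1000L) {
  stopifnot(accept_fraction > 0, accept_fraction <= 1,
            n_draws * accept_fraction >= 1)
  structure(
    list(n_draws = as.integer(n_draws), accept_fraction = accept_fraction,
         subset_size = as.integer(subset_size)),
    class = "abc_config"
  )
}

# internal: number of accepted draws
n_accept <- function(cfg) as.integer(ceiling(cfg$n_draws * cfg$accept_fraction))

# internal: index of the lower-median element of x (ties/even sizes resolve
# to the lower of the two central order statistics)
lower_median_index <- function(x) {
  order(x)[ceiling(length(x) / 2)]
}

#' Jointly infer a gamma DFE for a set of STR loci
#'
#' The core ABC routine. For each of `z` draws: sample `(a, b)` from the
#' prior, draw one selection coefficient per locus from `Gamma(a, scale = b)`,
#' fetch a simulated heterozygosity for each from the class lookup table
#' (random replicate at the rounded-s key), and score the draw by
#' [het_distance()] between the sorted simulated and observed heterozygosity
#' vectors. The lowest `accept_fraction` of distances are accepted and the
#' accepted pair with the (lower) median `a*b` is reported as the point
#' estimate.
#'
#' @param obs Numeric vector of observed per-locus heterozygosities, or a
#'   one-row class tibble from [group_into_classes()] (its `hets` column is
#'   used).
#' @param table An `str_lookup` for the class (see [build_lookup_table()]).
#' @param prior A [gamma_prior()].
#' @param cfg An [abc_config()].
#' @return Object of class `dfe_posterior` with elements `accepted` (tibble
#'   of accepted `a`, `b`, `mean_s`, `distance`), `a`, `b`, `mean_s` (the
#'   point estimate), `n_loci`, `cfg`.
#' @export
infer_dfe <- function(obs, table, prior = gamma_prior(), cfg = abc_config()) {
  hets <- extract_hets(obs)
  if (length(hets) < 1) stop("need at least one observed locus", call. = FALSE)
  if (length(hets) > cfg$subset_size) hets <- sample(hets, cfg$subset_size)
  obs_sorted <- sort(hets)
  n_loci <- length(obs_sorted)

  draws <- sample_prior(prior, cfg$n_draws)
  dist <- vapply(seq_len(cfg$n_draws), function(i) {
    s <- pmin(stats::rgamma(n_loci, shape = draws$a[i]) * draws$b[i], 1)
    sim <- lookup_hets(table, round_s(s))
    mean(abs(obs_sorted - sort(sim)))
  }, numeric(1))

  k <- n_accept(cfg)
  acc_idx <- order(dist)[seq_len(k)]    # ties resolve by draw order (stable)
  accepted <- tibble::tibble(
    a = draws$a[acc_idx], b = draws$b[acc_idx],
    mean_s = draws$mean_s[acc_idx], distance = dist[acc_idx]
  )
  pt <- lower_median_index(accepted$mean_s)
  structure(
    list(accepted = accepted,
         a = accepted$a[pt], b = accepted$b[pt], mean_s = accepted$mean_s[pt],
         n_loci = n_loci, cfg = cfg,
         class_key = table$table$class_key[1]),
    class = "dfe_posterior"
  )
}

extract_hets <- function(obs) {
  if (is.data.frame(obs)) {
    stopifnot("hets" %in% names(obs), nrow(obs) == 1)
    as.numeric(obs$hets[[1]])
  } else {
    as.numeric(obs)
  }
}

#' @export
print.dfe_posterior <- function(x, ...) {
  cat("<dfe_posterior>", x$class_key, "- mean s =", format(x$mean_s, digits = 3),
      "(a =", format(x$a, digits = 3), ", b =", format(x$b, digits = 3),
      ");", nrow(x$accepted), "accepted of", x$cfg$n_draws, "draws\n")
  invisible(x)
}

#' @rdname infer_dfe
#' @param x A `dfe_posterior`.
#' @param ... Unused.
#' @export
tidy.dfe_posterior <- function(x, ...) x$accepted

#' @rdname infer_dfe
#' @export
glance.dfe_posterior <- function(x, ...) {
  tibble::tibble(
    class_key = x$class_key, a = x$a, b = x$b, mean_s = x$mean_s,
    n_loci = x$n_loci, n_draws = x$cfg$n_draws,
    n_accepted = nrow(x$accepted), min_distance = min(x$accepted$distance)
  )
}

#' Per-locus selection-coefficient inference
#'
#' The single-locus mode: ABC on one locus's heterozygosity. Each draw picks
#' an `s` uniformly from `s_prior` (by default the lookup key ladder) and a
#' random stored replicate at that key; the distance is the absolute
#' heterozygosity difference. Accepted draws and their median are returned.
#' Single-locus fits are confounded when variation is low (a low mutation
#' rate, strong selection, or both can all produce a near-monomorphic
#' locus), which is why the joint mode exists.
#'
#' @param obs_freqs Frequency vector for the locus (or a single
#'   heterozygosity value).
#' @param table An `str_lookup` for the locus's class.
#' @param s_prior Candidate selection coefficients (default: the table's key
#'   ladder).
#' @param cfg An [abc_config()].
#' @return Object of class `locus_posterior`: list with `accepted_s`,
#'   `median_s`, `het`.
#' @export
infer_locus_s <- function(obs_freqs, table, s_prior = NULL,
                          cfg = abc_config(n_draws = 10000L)) {
  h_obs <- if (length(obs_freqs) == 1) obs_freqs else heterozygosity(obs_freqs)
  if (is.null(s_prior)) s_prior <- sort(unique(table$table$s_key))
  s_draw <- sample(s_prior, cfg$n_draws, replace = TRUE)
  h_sim <- lookup_hets(table, round_s(s_draw))
  dist <- abs(h_obs - h_sim)
  k <- n_accept(cfg)
  acc <- order(dist)[seq_len(k)]
  accepted_s <- s_draw[acc]
  structure(
    list(accepted_s = accepted_s,
         median_s = stats::median(accepted_s),
         het = h_obs),
    class = "locus_posterior"
  )
}

#' @export
print.locus_posterior <- function(x, ...) {
  cat("<locus_posterior> het =", format(x$het, digits = 3),
      " median s =", format(x$median_s, digits = 3), "\n")
  invisible(x)
}

#' Select among candidate mutation models for putatively neutral loci
#'
#' Sets `s = 0` and pools ABC draws uniformly across the candidate models:
#' each draw picks a candidate at random, simulates a matched-size
#' heterozygosity set from that candidate's neutral pool, and is scored by
#' [het_distance()] against the observed set. The top `accept_fraction` of
#' the pooled draws are accepted; with the uniform prior over candidates the
#' per-candidate acceptance proportions approximate relative model
#' likelihoods.
#'
#' @param obs Observed heterozygosities (vector or one-row class tibble).
#' @param candidates Named list of [mutation_model()] objects.
#' @param demog A [demographic_model()].
#' @param grid An [allele_grid()].
#' @param cfg An [abc_config()] (defaults to 1,000 pooled draws).
#' @param sample_size End-sampling size for pool simulations.
#' @param n_pool Neutral loci simulated per candidate to form its pool.
#' @param pools Optional precomputed pools (named list of numeric vectors,
#'   as returned in the `pools` element) to reuse across runs.
#' @param scale Demographic rescaling factor.
#' @return Object of class `mutmodel_fit`: tibble `proportions` with one row
#'   per candidate, the `best` candidate name, and the `pools` used.
#' @export
select_mutation_model <- function(obs, candidates, demog, grid,
                                  cfg = abc_config(n_draws = 1000L,
                                                   accept_fraction = 0.01),
                                  sample_size = 1000L, n_pool = 200L,
                                  pools = NULL, scale = 1) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("model_", seq_along(candidates))
  }
  hets <- extract_hets(obs)
  if (length(hets) > cfg$subset_size) hets <- sample(hets, cfg$subset_size)
  obs_sorted <- sort(hets)
  n_loci <- length(obs_sorted)

  if (is.null(pools)) {
    pools <- purrr::map(candidates, function(m) {
      prep <- prepare_sim(m, demog, grid, scale)
      vapply(seq_len(n_pool), function(i) {
        heterozygosity(end_sample(run_trajectory(prep, 0), sample_size))
      }, numeric(1))
    })
  }

  cand_idx <- sample.int(length(candidates), cfg$n_draws, replace = TRUE)
  dist <- vapply(seq_len(cfg$n_draws), function(i) {
    sim <- sample(pools[[cand_idx[i]]], n_loci, replace = TRUE)
    mean(abs(obs_sorted - sort(sim)))
  }, numeric(1))

  k <- n_accept(cfg)
  acc <- cand_idx[order(dist)[seq_len(k)]]
  props <- tabulate(acc, nbins = length(candidates)) / k
  proportions <- tibble::tibble(
    candidate = names(candidates),
    acceptance_proportion = props
  )
  structure(
    list(proportions = proportions,
         best = names(candidates)[which.max(props)],
         pools = pools, n_accepted = k),
    class = "mutmodel_fit"
  )
}

#' @export
print.mutmodel_fit <- function(x, ...) {
  cat("<mutmodel_fit> best:", x$best, "\n")
  print(x$proportions)
  invisible(x)
}

#' @rdname select_mutation_model
#' @param x A `mutmodel_fit`.
#' @param ... Unused.
#' @export
tidy.mutmodel_fit <- function(x, ...) x$proportions

#' Kolmogorov-Smirnov goodness-of-fit score
#'
#' Post-hoc model check: for each of `n_rounds` rounds, simulate a dataset of
#' the same size as the observed one (optionally capped at `subsample_cap`
#' loci to equalise power across classes) under the fitted model -- either a
#' neutral mutation model (`s = 0`) or a mutation model plus gamma DFE -- and
#' run a two-sample, two-sided KS test against the observed heterozygosities.
#' The score is the number of rounds with p > 0.05 (0-100 for the default
#' 100 rounds); scores <= 50 flag a poorly fitting class, which downstream
#' burden calculations exclude.
#'
#' Every round simulates fresh trajectories. Reusing a finite lookup pool
#' here would miscalibrate the test: a 50-replicate pool differs from the
#' true heterozygosity distribution by about `1/sqrt(50)`, which is the same
#' order as the KS detection threshold at typical round sizes.
#'
#' @param mut A [mutation_model()].
#' @param obs Observed heterozygosities (vector or one-row class tibble).
#' @param dfe Optional `c(a =, b =)` gamma parameters; omitted means `s = 0`.
#' @param n_rounds Number of simulation rounds (default 100).
#' @param subsample_cap Optional per-round cap on the number of loci.
#' @param demog,grid,sample_size,scale Simulation context.
#' @return Integer score in `[0, n_rounds]`.
#' @export
ks_fit_score <- function(mut, obs, dfe = NULL, n_rounds = 100L,
                         subsample_cap = NULL,
                         demog = NULL, grid = NULL, sample_size = 1000L,
                         scale = 1) {
  hets <- extract_hets(obs)
  n <- length(hets)
  if (!is.null(subsample_cap)) n <- min(n, subsample_cap)
  prep <- prepare_sim(mut, demog, grid, scale)
  hits <- vapply(seq_len(n_rounds), function(r) {
    obs_r <- if (n < length(hets)) sample(hets, n) else hets
    s <- if (is.null(dfe)) rep(0, n) else
      pmin(stats::rgamma(n, shape = dfe[["a"]]) * dfe[["b"]], 1)
    sim <- vapply(s, function(si) {
      heterozygosity(end_sample(run_trajectory(prep, min(si, 1)), sample_size))
    }, numeric(1))
    suppressWarnings(stats::ks.test(obs_r, sim)$p.value) > 0.05
  }, logical(1))
  sum(hits)
}

#' Parameter-recovery validation of the joint DFE inference
#'
#' Simulates a ground-truth dataset (per-locus `s` drawn from
#' `Gamma(a, scale = b)`), then repeats the ABC inference `n_repeats` times
#' with `sims_per_repeat` draws each, reporting every repeat's point estimate
#' and the binned true-vs-inferred DFE mass.
#'
#' @param a,b True gamma parameters.
#' @param mut,demog,grid,sample_size,scale Simulation context for the class.
#' @param table An `str_lookup` for the class.
#' @param n_loci Loci in the ground-truth dataset.
#' @param n_repeats Number of independent ABC runs.
#' @param sims_per_repeat ABC draws per run.
#' @param prior A [gamma_prior()].
#' @param bin_breaks Bin edges for the DFE mass summary.
#' @return Object of class `recovery_report`: tibble `estimates` (one row
#'   per repeat), `mean_of_means`, `truth`, and `bins` (fractions of gamma
#'   draws per s bin for the truth and the mean estimate; each column sums
#'   to 1).
#' @export
validate_recovery <- function(a, b, mut, demog, grid, table,
                              n_loci = 1000L, n_repeats = 20L,
                              sims_per_repeat = 2000L,
                              sample_size = 1000L, scale = 1,
                              prior = gamma_prior(),
                              bin_breaks = c(0, 1e-4, 1e-3, 1e-2, 1)) {
  prep <- prepare_sim(mut, demog, grid, scale)
  s_true <- stats::rgamma(n_loci, shape = a) * b
  hets <- vapply(s_true, function(si) {
    heterozygosity(end_sample(run_trajectory(prep, min(si, 1)), sample_size))
  }, numeric(1))
  cfg <- abc_config(n_draws = sims_per_repeat, subset_size = n_loci)
  estimates <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    fit <- infer_dfe(hets, table, prior, cfg)
    tibble::tibble(repeat_id = r, a = fit$a, b = fit$b, mean_s = fit$mean_s)
  })
  bin_frac <- function(aa, bb) {
    draws <- stats::rgamma(1000L, shape = aa) * bb
    counts <- table(cut(pmin(draws, 1), breaks = bin_breaks,
                        include.lowest = TRUE, right = FALSE))
    as.numeric(counts) / sum(counts)
  }
  est <- estimates[lower_median_index(estimates$mean_s), ]
  structure(
    list(
      estimates = estimates,
      mean_of_means = mean(estimates$mean_s),
      truth = c(a = a, b = b, mean_s = a * b),
      bins = tibble::tibble(
        bin = levels(cut(0, bin_breaks, include.lowest = TRUE, right = FALSE)),
        truth = bin_frac(a, b),
        inferred = bin_frac(est$a, est$b)
      )
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> truth mean s =", format(x$truth[["mean_s"]], digits = 3),
      "-> mean of", nrow(x$estimates), "estimates =",
      format(x$mean_of_means, digits = 3), "\n")
  invisible(x)
}

#' @rdname validate_recovery
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) x$estimates

#' @rdname validate_recovery
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    true_mean_s = x$truth[["mean_s"]],
    mean_estimate = x$mean_of_means,
    median_estimate = stats::median(x$estimates$mean_s),
    n_repeats = nrow(x$estimates)
  )
}
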