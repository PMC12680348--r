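#' Simulate one STR locus forward in time
#'
#' Runs the full Wright-Fisher trajectory for one locus: starting from all
#' mass on the optimal allele, each generation applies mutation (transition
#' matrix product), deterministic diploid selection, and multinomial drift at
#' that generation's `2 * N`, across the whole demographic span. A final end
#' sampling step draws `sample_size` alleles to emulate a finite sequenced
#' sample.
#'
#' `scale` (lambda > 1) selects the rescaled fast mode: sizes and durations
#' are divided by lambda while mutation rates, growth rates and `s` are
#' multiplied by lambda, preserving `4*N*mu` and `2*N*s`. `s` is always given
#' on the unscaled (full-model) scale.
#'
#' @param mut A [mutation_model()].
#' @param s Selection coefficient (homozygote scale, unscaled).
#' @param demog A [demographic_model()] (unscaled).
#' @param grid An [allele_grid()].
#' @param sample_size Number of alleles drawn in the end sampling step.
#' @param scale Rescaling factor lambda (1 = full model).
#' @return Object of class `simulated_locus`: list with `freqs` (sampled
#'   frequency vector), `s`, `grid`, `sample_size`.
#' @examples
#' \donttest{
#' g <- allele_grid(xopt = 13)
#' m <- mutation_model(mu0 = 1e-4)
#' set.seed(1)
#' loc <- simulate_locus(m, s = 0.01, default_demography(), g,
#'                       sample_size = 1000, scale = 10)
#' heterozygosity(loc$freqs)
#' }
#' @export
simulate_locus <- function(mut, s, demog, grid, sample_size = 1000L,
                           scale = 1) {
  stopifnot(sample_size >= 2)
  if (!(s >= 0 && s <= 1)) stop("`s` must lie in [0, 1]", call. = FALSE)
  prep <- prepare_sim(mut, demog, grid, scale)
  freqs <- run_trajectory(prep, s)
  freqs <- end_sample(freqs, sample_size)
  structure(
    list(freqs = freqs, s = s, grid = grid, sample_size = as.integer(sample_size),
         scale = scale),
    class = "simulated_locus"
  )
}

# internal: precompute everything shared across loci of one class so batch
# simulation does not rebuild the matrix / size trajectory per locus
prepare_sim <- function(mut, demog, grid, scale = 1) {
  if (scale > 1) {
    mut <- scale_mutation_model(mut, scale)
    demog <- scale_demography(demog, scale)
  }
  list(
    tmat = mutation_matrix(mut, grid),
    sizes = size_trajectory(demog),
    grid = grid,
    scale = scale
  )
}

# internal: one trajectory from a prepared context; s on the unscaled scale
run_trajectory <- function(prep, s) {
  s_eff <- min(s * prep$scale, 1)
  w <- allele_fitness(s_eff, prep$grid)
  .wf_trajectory(init_freqs(prep$grid), prep$tmat, w, prep$sizes)
}

#' Finite-sample end sampling
#'
#' One multinomial draw of `n_alleles` alleles from the population
#' frequencies; returns count / `n_alleles` sample frequencies.
#'
#' @param freqs Frequency vector.
#' @param n_alleles Number of alleles in the sequenced sample (>= 2).
#' @return Frequency vector with denominator `n_alleles`.
#' @export
end_sample <- function(freqs, n_alleles) {
  stopifnot(n_alleles >= 2)
  n_alleles <- as.integer(n_alleles)
  as.numeric(stats::rmultinom(1L, n_alleles, freqs)) / n_alleles
}

#' Round a selection coefficient to its lookup key
#'
#' Lookup tables index simulations by `s` rounded to one significant digit;
#' values below `1e-5` round to 0. Two coefficients match if their keys are
#' equal.
#'
#' @param s Selection coefficient(s) (>= 0).
#' @return Rounded key(s).
#' @examples
#' round_s(c(0.00234, 8e-6, 0.049))
#' @export
round_s <- function(s) {
  if (any(s < 0)) stop("`s` must be >= 0", call. = FALSE)
  ifelse(s < 1e-5, 0, signif(s, 1))
}

# the full one-significant-digit key ladder covering the prior's support
lookup_s_grid <- function() {
  c(0, as.vector(outer(1:9, 10^(-5:-1))), 1)
}

#' Build an ABC lookup table for one STR class
#'
#' Simulates `reps_per_s` loci at every selection coefficient in `s_grid`
#' (each already a one-significant-digit key, see [round_s()]) and stores the
#' end-sampled frequency vector and heterozygosity of each replicate. During
#' ABC, a drawn `s` is served by a random replicate stored under its key.
#'
#' @param class_key Label for the class, e.g. `"AC:13"`.
#' @param mut A [mutation_model()].
#' @param demog A [demographic_model()].
#' @param grid An [allele_grid()].
#' @param sample_size End-sampling size.
#' @param s_grid Selection coefficients to tabulate (default: 0 plus every
#'   one-significant-digit value in `[1e-5, 1]`).
#' @param reps_per_s Replicates per key (default 50).
#' @param scale Demographic rescaling factor passed to [simulate_locus()].
#' @return Object of class `str_lookup`; its `$table` is a tibble with
#'   columns `class_key`, `s_key`, `rep`, `het`, `freqs` (list column).
#' @export
build_lookup_table <- function(class_key, mut, demog, grid,
                               sample_size = 1000L,
                               s_grid = lookup_s_grid(),
                               reps_per_s = 50L, scale = 1) {
  if (length(s_grid) == 0) stop("`s_grid` must be non-empty", call. = FALSE)
  if (any(s_grid < 0 | s_grid > 1)) {
    stop("`s_grid` values must lie in [0, 1]", call. = FALSE)
  }
  keys <- round_s(s_grid)
  prep <- prepare_sim(mut, demog, grid, scale)
  rows <- purrr::map(seq_along(keys), function(i) {
    freqs <- purrr::map(seq_len(reps_per_s), function(r) {
      end_sample(run_trajectory(prep, keys[i]), sample_size)
    })
    tibble::tibble(
      class_key = class_key,
      s_key = keys[i],
      rep = seq_len(reps_per_s),
      het = purrr::map_dbl(freqs, heterozygosity),
      freqs = freqs
    )
  })
  new_str_lookup(dplyr::bind_rows(rows), grid)
}

new_str_lookup <- function(table, grid) {
  structure(
    list(
      table = table,
      grid = grid,
      het_by_key = split(table$het, format_s_key(table$s_key))
    ),
    class = "str_lookup"
  )
}

# stable string form of an s key, used as the list index
format_s_key <- function(s) formatC(s, format = "g", digits = 6)

#' @export
print.str_lookup <- function(x, ...) {
  cat("<str_lookup>", x$table$class_key[1], "-",
      length(unique(x$table$s_key)), "s keys x",
      max(x$table$rep), "replicates\n")
  invisible(x)
}

# internal: random simulated heterozygosity for each (rounded) s, vectorised
lookup_hets <- function(table, s_keys) {
  idx <- match(format_s_key(s_keys), names(table$het_by_key))
  if (anyNA(idx)) {
    missing <- unique(s_keys[is.na(idx)])
    stop("lookup table does not cover s key(s): ",
         paste(format(missing), collapse = ", "), call. = FALSE)
  }
  pools <- table$het_by_key
  sizes <- lengths(pools)[idx]
  picks <- ceiling(stats::runif(length(idx)) * sizes)
  vapply(seq_along(idx), function(i) pools[[idx[i]]][picks[i]], numeric(1))
}

#' Serialize / read a lookup table
#'
#' Tables are written as plain TSV (one row per replicate) with the frequency
#' vector comma-joined, so they are portable and diffable.
#'
#' @param x An `str_lookup`.
#' @param path Output path.
#' @return `write_lookup_table()` returns `path` invisibly;
#'   `read_lookup_table()` returns an `str_lookup`.
#' @export
write_lookup_table <- function(x, path) {
  out <- dplyr::mutate(
    x$table,
    freqs = purrr::map_chr(.data$freqs, ~ paste(format(.x, digits = 12), collapse = ","))
  )
  out$grid_xopt <- x$grid$xopt
  out$grid_n <- x$grid$n
  out$grid_unit <- x$grid$repeat_unit_len
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  grid <- allele_grid(xopt = raw$grid_xopt[1], n = raw$grid_n[1],
                      repeat_unit_len = raw$grid_unit[1])
  tab <- tibble::tibble(
    class_key = raw$class_key,
    s_key = raw$s_key,
    rep = raw$rep,
    het = raw$het,
    freqs = purrr::map(strsplit(raw$freqs, ","), as.numeric)
  )
  new_str_lookup(tab, grid)
}

#' Modal allele of a frequency vector
#'
#' Returns the offset with maximal frequency. Ties are broken toward the
#' smallest `|k|`, then toward the negative (shorter) allele.
#'
#' @param freqs Frequency vector on `grid`.
#' @param grid An [allele_grid()].
#' @return Integer offset.
#' @export
modal_allele <- function(freqs, grid) {
  check_freqs(freqs, grid)
  top <- which(freqs == max(freqs))
  offs <- grid$offsets[top]
  offs[order(abs(offs), offs)][1]
}

#' Fraction of simulated loci whose modal allele is the optimum
#'
#' Simulates `n_loci` loci and reports the fraction for which the modal
#' allele of the sampled frequencies equals the optimal allele (`k = 0`).
#' Under at least moderately strong selection this fraction is near 1, which
#' underpins using the population modal allele as the assumed optimum.
#'
#' @inheritParams simulate_locus
#' @param n_loci Number of loci to simulate.
#' @return Fraction in `[0, 1]`.
#' @export
modal_match_fraction <- function(mut, s, demog, grid, n_loci = 200L,
                                 sample_size = 1000L, scale = 1) {
  stopifnot(n_loci >= 1)
  prep <- prepare_sim(mut, demog, grid, scale)
  hits <- vapply(seq_len(n_loci), function(i) {
    freqs <- end_sample(run_trajectory(prep, s), sample_size)
    modal_allele(freqs, grid) == 0L
  }, logical(1))
  mean(hits)
}

#' Genotyping-error model
#'
#' Each observed allele call is independently wrong with probability
#' `per_allele_error_rate`; an erroneous call is one repeat unit larger or
#' shorter than the truth with equal probability (boundary alleles move
#' inward).
#'
#' @param per_allele_error_rate Error probability per observed allele.
#' @return Object of class `error_model`.
#' @export
error_model <- function(per_allele_error_rate = 0.001) {
  stopifnot(per_allele_error_rate >= 0, per_allele_error_rate <= 1)
  structure(list(rate = per_allele_error_rate), class = "error_model")
}

#' Inject genotyping errors into sampled allele frequencies
#'
#' Materialises `n_alleles` calls from `freqs`, flips each call with the
#' error model's probability to a +/-1-repeat neighbour, and returns the
#' recomputed sample frequencies.
#'
#' @param freqs Frequency vector (typically an [end_sample()] output).
#' @param n_alleles Number of allele calls to materialise.
#' @param err An [error_model()].
#' @param grid An [allele_grid()].
#' @return Frequency vector with denominator `n_alleles`.
#' @export
inject_genotyping_errors <- function(freqs, n_alleles, err, grid) {
  check_freqs(freqs, grid)
  n_alleles <- as.integer(n_alleles)
  counts <- as.numeric(stats::rmultinom(1L, n_alleles, freqs))
  calls <- rep.int(seq_len(grid$n), counts)
  flip <- stats::runif(n_alleles) < err$rate
  if (any(flip)) {
    dir <- ifelse(stats::runif(sum(flip)) < 0.5, -1L, 1L)
    moved <- calls[flip] + dir
    moved[moved < 1L] <- 2L          # boundary calls move inward
    moved[moved > grid$n] <- grid$n - 1L
    calls[flip] <- moved
  }
  tabulate(calls, nbins = grid$n) / n_alleles
}
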