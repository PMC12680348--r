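#' Allele fitness under linear selection around the optimum
#'
#' Fitness of the allele at offset `k` is `w(k) = 1 - s * |k|`, floored at 0.
#' `s` is on the homozygote scale: an individual's fitness is the average of
#' its two allele fitnesses, so a homozygote for an allele one unit from the
#' optimum loses `s` and a heterozygote loses `s / 2`.
#'
#' @param s Selection coefficient in `[0, 1]`.
#' @param grid An [allele_grid()].
#' @return Numeric vector of allele fitness values over the grid.
#' @export
allele_fitness <- function(s, grid) {
  if (!(s >= 0 && s <= 1)) stop("`s` must lie in [0, 1]", call. = FALSE)
  pmax(1 - s * abs(grid$offsets), 0)
}

#' One generation of deterministic selection
#'
#' Standard diploid random-mating update with additive (allele-averaged)
#' fitness: allele `i` is reweighted by its marginal fitness
#' `(w_i + wbar) / 2` where `wbar` is the population mean fitness, then the
#' vector is renormalised. With `s = 0` the input is returned unchanged.
#'
#' @param freqs Frequency vector on `grid`.
#' @param s Selection coefficient in `[0, 1]`.
#' @param grid An [allele_grid()].
#' @return Updated frequency vector.
#' @export
apply_selection <- function(freqs, s, grid) {
  check_freqs(freqs, grid)
  if (s == 0) return(freqs)
  w <- allele_fitness(s, grid)
  wbar <- sum(freqs * w)
  if (wbar <= 0) stop("degenerate fitness: population mean fitness is <= 0",
                      call. = FALSE)
  out <- freqs * (w + wbar) / (2 * wbar)
  out / sum(out)
}

#' One generation of multinomial genetic drift
#'
#' Draws `2 * n_eff` alleles from the input frequencies and returns the
#' resulting sample frequencies. The expectation over replicates equals the
#' input vector.
#'
#' @param freqs Frequency vector.
#' @param n_eff Diploid effective population size (>= 1).
#' @return Frequency vector of multinomial counts / (2 * n_eff).
#' @export
apply_drift <- function(freqs, n_eff) {
  stopifnot(n_eff >= 1)
  size <- 2L * as.integer(round(n_eff))
  as.numeric(stats::rmultinom(1L, size, freqs)) / size
}
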