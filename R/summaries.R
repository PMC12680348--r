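#' Heterozygosity of a locus
#'
#' `h = 1 - sum(p^2)`: the probability that two alleles drawn at random
#' differ. 0 for a fixed locus; approaches 1 for highly variable STRs.
#'
#' @param freqs Frequency vector (must sum to 1).
#' @return Heterozygosity in `[0, 1)`.
#' @examples
#' heterozygosity(c(0.5, 0.5))
#' @export
heterozygosity <- function(freqs) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("`freqs` must be non-negative and sum to 1", call. = FALSE)
  }
  1 - sum(freqs^2)
}

#' ABC distance between two heterozygosity distributions
#'
#' Both vectors are sorted ascending and the distance is the mean absolute
#' difference of the sorted values (an L1 distance between empirical
#' quantiles). If the sets differ in size the larger is subsampled without
#' replacement to the smaller before sorting.
#'
#' @param obs,sim Numeric vectors of per-locus heterozygosities.
#' @return Non-negative distance; 0 iff the sorted vectors coincide.
#' @examples
#' het_distance(c(0.1, 0.2, 0.3), c(0.4, 0.1, 0.2))
#' @export
het_distance <- function(obs, sim) {
  if (length(obs) != length(sim)) {
    n <- min(length(obs), length(sim))
    if (n < 1) stop("both sets must be non-empty", call. = FALSE)
    if (length(obs) > n) obs <- sample(obs, n)
    if (length(sim) > n) sim <- sample(sim, n)
  }
  mean(abs(sort(obs) - sort(sim)))
}

#' Locus-count-weighted empirical CDF of selection coefficients
#'
#' Pools gamma draws across fitted classes, weighting each class by its locus
#' count: for each fit, `n_loci * n_draws_per_locus` values are drawn from
#' `Gamma(shape = a, scale = b)` (classes fitted as strictly neutral
#' contribute zeros), and the empirical CDF of the pooled draws is returned.
#'
#' @param fits A data frame with columns `class_key`, `a`, `b`, `n_loci`.
#' @param n_draws_per_locus Gamma draws per locus (default 1).
#' @return A tibble with columns `s` (sorted pooled draws) and `cdf`.
#' @export
weighted_dfe_cdf <- function(fits, n_draws_per_locus = 1L) {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c("class_key", "a", "b", "n_loci") %in% names(fits)),
            all(fits$n_loci >= 1))
  draws <- purrr::pmap(fits, function(class_key, a, b, n_loci, ...) {
    n <- n_loci * n_draws_per_locus
    if (a == 0 || b == 0) rep(0, n) else stats::rgamma(n, shape = a, scale = b)
  })
  s <- sort(unlist(draws, use.names = FALSE))
  tibble::tibble(s = s, cdf = seq_along(s) / length(s))
}
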