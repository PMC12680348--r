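#' Multi-epoch demographic model
#'
#' A demographic model is an ordered table of epochs running from the distant
#' past to the present. Each epoch has a duration (generations), a starting
#' diploid effective size, and a continuous exponential growth rate (0 for
#' constant-size epochs): within a growth epoch
#' `N(t) = n_start * exp(rate * elapsed)`, evaluated at integer generations
#' and rounded to the nearest integer >= 1.
#'
#' The first (ancestral) epoch is treated as extending indefinitely into the
#' past, so [population_size()] can be queried at any time at or before the
#' model span.
#'
#' @param epochs A data frame with columns `duration` (generations),
#'   `n_start` (diploid size at the epoch start) and `rate` (per-generation
#'   exponential growth rate).
#' @param name Optional label.
#' @return Object of class `demographic_model`.
#' @seealso [default_demography()] for the built-in European model.
#' @export
demographic_model <- function(epochs, name = "custom") {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("duration", "n_start", "rate") %in% names(epochs)))
  if (any(epochs$duration < 1) || any(epochs$duration != round(epochs$duration))) {
    stop("epoch durations must be positive integers", call. = FALSE)
  }
  if (any(epochs$n_start < 1)) stop("epoch sizes must be >= 1", call. = FALSE)
  structure(
    list(epochs = epochs, span = sum(epochs$duration), name = name),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>", x$name, "-", nrow(x$epochs), "epochs,",
      x$span, "generations\n")
  print(x$epochs)
  invisible(x)
}

#' Built-in European demographic model
#'
#' The default demographic history: an ancestral population of 7,310 diploids
#' for a 50,000-generation burn-in; expansion to 14,474 at 5,920 generations
#' before present; an out-of-Africa bottleneck to 1,861 at 2,040 generations;
#' a European/Asian divergence to 1,032 at 920 generations; exponential growth
#' at rate 0.00307 from 920 to 205 generations before present, then at 0.0195
#' to the present.
#'
#' @return A `demographic_model` spanning 55,920 generations.
#' @examples
#' d <- default_demography()
#' population_size(d, 2040)  # 1861
#' @export
default_demography <- function() {
  n_growth1 <- 1032 * exp(0.00307 * (920 - 205))
  demographic_model(
    tibble::tibble(
      duration = c(50000, 5920 - 2040, 2040 - 920, 920 - 205, 205),
      n_start  = c(7310, 14474, 1861, 1032, n_growth1),
      rate     = c(0, 0, 0, 0.00307, 0.0195)
    ),
    name = "European"
  )
}

#' Effective population size at a time before present
#'
#' @param demog A [demographic_model()].
#' @param generations_before_present Non-negative time(s); 0 is the present.
#'   Times before the model span fall in the open-ended ancestral epoch.
#' @return Integer diploid size(s) (>= 1).
#' @export
population_size <- function(demog, generations_before_present) {
  t <- generations_before_present
  if (any(t < 0)) stop("time before present must be >= 0", call. = FALSE)
  ep <- demog$epochs
  starts_ago <- demog$span - c(0, cumsum(ep$duration)[-nrow(ep)])
  ends_ago <- demog$span - cumsum(ep$duration)
  vapply(t, function(ti) {
    j <- if (ti >= starts_ago[1]) 1L else which(ti > ends_ago & ti <= starts_ago)[1]
    if (is.na(j)) j <- nrow(ep)  # the present (t = 0) belongs to the last epoch
    elapsed <- max(starts_ago[j] - ti, 0)
    max(1L, as.integer(round(ep$n_start[j] * exp(ep$rate[j] * elapsed))))
  }, integer(1))
}

# internal: diploid size for every simulated generation, ordered past ->
# present (element 1 is the oldest generation of the span)
size_trajectory <- function(demog) {
  population_size(demog, seq.int(demog$span - 1L, 0L))
}

#' Rescale a demographic model for fast simulation
#'
#' Standard population-genetic rescaling by a factor `lambda`: sizes and
#' epoch durations are divided by `lambda` and growth rates multiplied by
#' `lambda`. Used together with [scale_mutation_model()] and a selection
#' coefficient multiplied by `lambda`, this preserves the population-scaled
#' parameters `4*N*mu` and `2*N*s`, so scaled runs emulate full-span dynamics
#' at a fraction of the cost.
#'
#' @param demog A [demographic_model()].
#' @param lambda Scaling factor (> 1 shrinks the model).
#' @return A `demographic_model`.
#' @export
scale_demography <- function(demog, lambda = 10) {
  stopifnot(lambda >= 1)
  ep <- demog$epochs
  demographic_model(
    tibble::tibble(
      duration = pmax(1, round(ep$duration / lambda)),
      n_start = pmax(1, ep$n_start / lambda),
      rate = ep$rate * lambda
    ),
    name = paste0(demog$name, "/", lambda)
  )
}

#' @rdname scale_demography
#' @param model A [mutation_model()]; `mu0` and both clamp bounds are
#'   multiplied by `lambda` (capped at 1).
#' @export
scale_mutation_model <- function(model, lambda = 10) {
  mutation_model(
    mu0 = min(model$mu0 * lambda, 1),
    L = model$L, rho = model$rho, beta = model$beta, ref_len = model$ref_len,
    rate_floor = model$rate_floor * lambda,
    rate_cap = min(model$rate_cap * lambda, 1)
  )
}
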