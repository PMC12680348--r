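#' Generalized stepwise mutation model with length-dependent rate
#'
#' STR mutation is modelled per generation: an allele of length `x` repeat
#' units mutates with probability `mu(x)` where
#' `log10 mu(x) = log10(mu0) + L * (x - ref_len)`, clamped into
#' `[rate_floor, rate_cap]`. Step sizes (repeat units gained or lost) follow a
#' geometric distribution with parameter `rho`; the direction is biased toward
#' the optimal allele with strength `beta` (long alleles preferentially
#' contract, short alleles expand).
#'
#' With `ref_len = NULL` the reference length defaults to the optimal allele
#' of whichever grid the model is applied to, making `mu0` the mutation rate
#' of the optimal allele.
#'
#' @param mu0 Per-generation mutation rate at the reference length.
#' @param L Slope of log10 mutation rate per added repeat unit.
#' @param rho Geometric step-size parameter in (0, 1]; `rho = 1` means all
#'   mutations are single steps.
#' @param beta Directional length constraint (>= 0); 0 means unbiased.
#' @param ref_len Allele length (repeat units) at which `mu0` applies, or
#'   `NULL` to anchor at the grid optimum.
#' @param rate_floor,rate_cap Clamp bounds for the per-allele rate.
#' @return Object of class `mutation_model`.
#' @examples
#' m <- mutation_model(mu0 = 1e-4, L = 0.05, rho = 0.9, beta = 0.25)
#' @export
mutation_model <- function(mu0, L = 0, rho = 0.9, beta = 0, ref_len = NULL,
                           rate_floor = 1e-8, rate_cap = 1e-3) {
  stopifnot(rate_floor > 0, rate_floor < rate_cap, rate_cap <= 1)
  if (!(mu0 > 0 && mu0 <= rate_cap)) {
    stop("`mu0` must lie in (0, rate_cap]", call. = FALSE)
  }
  if (!(rho > 0 && rho <= 1)) stop("`rho` must lie in (0, 1]", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  structure(
    list(mu0 = mu0, L = L, rho = rho, beta = beta,
         ref_len = if (is.null(ref_len)) NULL else as.integer(ref_len),
         rate_floor = rate_floor, rate_cap = rate_cap),
    class = "mutation_model"
  )
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation_model> mu0 =", format(x$mu0), " L =", x$L, " rho =", x$rho,
      " beta =", x$beta,
      if (is.null(x$ref_len)) " ref_len = xopt" else paste(" ref_len =", x$ref_len),
      "\n")
  invisible(x)
}

#' Per-allele mutation rate
#'
#' Evaluates the length-dependent rate
#' `10^(log10(mu0) + L * ((xopt + k) - ref_len))` for the allele at grid
#' offset `k`, clamped into `[rate_floor, rate_cap]`. Vectorised over `k`.
#'
#' @param model A [mutation_model()].
#' @param k Integer offset(s) from the optimal allele.
#' @param xopt Optimal allele length in repeat units.
#' @return Mutation probability per generation, same length as `k`.
#' @examples
#' m <- mutation_model(mu0 = 1e-5, L = 0.05)
#' mutation_rate(m, k = 0, xopt = 13)   # exactly mu0
#' mutation_rate(m, k = 10, xopt = 13)  # 10^-4.5
#' @export
mutation_rate <- function(model, k, xopt) {
  x <- xopt + k
  if (any(x < 1)) {
    stop("invalid grid: allele length ", min(x), " is not positive",
         call. = FALSE)
  }
  ref <- if (is.null(model$ref_len)) xopt else model$ref_len
  mu <- 10^(log10(model$mu0) + model$L * (x - ref))
  pmin(pmax(mu, model$rate_floor), model$rate_cap)
}

#' Mutation direction probabilities
#'
#' For an allele at offset `k` from the optimum the probability that a
#' mutation expands the allele is `(1 - beta * rho * k) / 2` and that it
#' contracts is `(1 + beta * rho * k) / 2`, clamped to `[0, 1]` and
#' renormalised. At the optimum both equal 1/2; below the optimum (`k < 0`)
#' expansion is favoured.
#'
#' @param beta Directional length constraint (>= 0).
#' @param rho Geometric step-size parameter.
#' @param k Integer offset from the optimal allele.
#' @return Named numeric vector `c(expand = ..., contract = ...)`.
#' @examples
#' step_direction_probs(0.3, 0.9, 2)
#' @export
step_direction_probs <- function(beta, rho, k) {
  stopifnot(beta >= 0, rho > 0, rho <= 1)
  p_expand <- (1 - beta * rho * k) / 2
  p_contract <- (1 + beta * rho * k) / 2
  p_expand <- min(max(p_expand, 0), 1)
  p_contract <- min(max(p_contract, 0), 1)
  tot <- p_expand + p_contract
  c(expand = p_expand / tot, contract = p_contract / tot)
}

#' Per-generation mutation transition matrix
#'
#' Builds the `n x n` row-stochastic matrix `T` where `T[i, j]` is the
#' probability that an allele at offset `k_i` is at offset `k_j` after one
#' generation of mutation. The diagonal carries `1 - mu(k_i)`; off-diagonal
#' mass splits between expansion and contraction by [step_direction_probs()]
#' and over step sizes `d` by the geometric law `rho * (1 - rho)^(d - 1)`.
#' Step mass that would leave the grid accumulates on the boundary allele, so
#' every row sums to exactly 1.
#'
#' @param model A [mutation_model()].
#' @param grid An [allele_grid()].
#' @return `n x n` numeric matrix.
#' @export
mutation_matrix <- function(model, grid) {
  n <- grid$n
  offs <- grid$offsets
  mu <- mutation_rate(model, offs, grid$xopt)
  tmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dirs <- step_direction_probs(model$beta, model$rho, offs[i])
    n_up <- n - i     # steps available toward longer alleles
    n_dn <- i - 1L    # steps available toward shorter alleles
    # geometric step mass; the boundary allele absorbs the tail
    if (n_up > 0) {
      d <- seq_len(n_up)
      gm <- model$rho * (1 - model$rho)^(d - 1)
      gm[n_up] <- gm[n_up] + (1 - model$rho)^n_up
      tmat[i, i + d] <- mu[i] * dirs[["expand"]] * gm
    } else {
      tmat[i, i] <- tmat[i, i] + mu[i] * dirs[["expand"]]
    }
    if (n_dn > 0) {
      d <- seq_len(n_dn)
      gm <- model$rho * (1 - model$rho)^(d - 1)
      gm[n_dn] <- gm[n_dn] + (1 - model$rho)^n_dn
      tmat[i, i - d] <- mu[i] * dirs[["contract"]] * gm
    } else {
      tmat[i, i] <- tmat[i, i] + mu[i] * dirs[["contract"]]
    }
    tmat[i, i] <- tmat[i, i] + 1 - mu[i]
  }
  tmat
}
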