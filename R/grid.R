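#' Allele grid for an STR class
#'
#' The simulator models a fixed window of `n` allele lengths centred on the
#' optimal allele `xopt`. Alleles are indexed by their integer offset
#' `k = x - xopt` (repeat units), so the grid spans `k = -(n-1)/2 ... +(n-1)/2`.
#'
#' All allele lengths on the grid must be at least one repeat unit, so `xopt`
#' must be at least `(n - 1) / 2 + 1`. Classes with shorter optimal alleles
#' need a narrower grid.
#'
#' @param xopt Optimal allele length in repeat units.
#' @param n Number of modelled alleles (odd, >= 3). Default 25.
#' @param repeat_unit_len Length of the repeat motif in bp (2, 3 or 4).
#' @return An object of class `allele_grid` with fields `n`, `offsets`,
#'   `xopt` and `repeat_unit_len`.
#' @examples
#' g <- allele_grid(xopt = 13)
#' range(g$offsets)
#' @export
allele_grid <- function(xopt, n = 25L, repeat_unit_len = 2L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L || n %% 2L == 0L) {
    stop("`n` must be an odd integer >= 3", call. = FALSE)
  }
  if (!repeat_unit_len %in% 2:4) {
    stop("`repeat_unit_len` must be 2, 3 or 4", call. = FALSE)
  }
  half <- (n - 1L) %/% 2L
  xopt <- as.integer(xopt)
  if (is.na(xopt) || xopt - half < 1L) {
    stop("invalid grid: allele lengths must be >= 1 repeat unit ",
         "(need xopt >= ", half + 1L, " for n = ", n, ")", call. = FALSE)
  }
  structure(
    list(n = n, offsets = seq.int(-half, half), xopt = xopt,
         repeat_unit_len = as.integer(repeat_unit_len)),
    class = "allele_grid"
  )
}

#' @export
print.allele_grid <- function(x, ...) {
  cat("<allele_grid> n =", x$n, " offsets", min(x$offsets), "..", max(x$offsets),
      " xopt =", x$xopt, " unit =", x$repeat_unit_len, "bp\n")
  invisible(x)
}

#' Build a frequency vector on a grid
#'
#' A frequency vector holds one probability per grid allele, ordered by offset.
#' `init_freqs()` returns the initial state of every simulation: all mass on
#' the optimal allele (`k = 0`).
#'
#' @param grid An [allele_grid()].
#' @return Numeric vector of length `grid$n` summing to 1.
#' @export
init_freqs <- function(grid) {
  p <- numeric(grid$n)
  p[grid$offsets == 0L] <- 1
  p
}

# internal: validate a frequency vector against a grid
check_freqs <- function(p, grid, tol = 1e-9) {
  if (length(p) != grid$n) {
    stop("frequency vector length ", length(p), " does not match grid n = ",
         grid$n, call. = FALSE)
  }
  if (any(p < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}
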