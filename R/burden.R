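#' STR class records for burden calculation
#'
#' A class record summarises one STR class (repeat unit / optimal allele):
#' its locus count, optimal-allele mutation rate, step-size parameter, fitted
#' gamma DFE and KS goodness-of-fit score. `read_str_classes()` reads a TSV
#' with columns `class_key`, `n_loci`, `mu_opt`, `rho`, `a`, `b`, `mean_s`,
#' `ks_score`.
#'
#' @param path Path to the class-record TSV.
#' @return Tibble of class records.
#' @export
read_str_classes <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("class_key", "n_loci", "mu_opt", "rho", "mean_s", "ks_score")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    stop("class-record table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(rec$ks_score < 0 | rec$ks_score > 100)) {
    stop("ks_score must lie in [0, 100]", call. = FALSE)
  }
  tibble::as_tibble(rec)
}

# expected per-mutation burden factor: sum over step sizes i in +/-[1, max]
# of P(step = i) * 0.5 * |i|, with |i| ~ Geometric(rho) truncated at max
# (truncation mass is dropped, not renormalised) and direction 1/2 each.
step_burden_factor <- function(rho, max_step = 20L) {
  d <- seq_len(max_step)
  sum(rho * (1 - rho)^(d - 1) * 0.5 * d)
}

#' Expected de novo mutation burden of STR classes
#'
#' For each class `c` the expected per-generation fitness burden is
#' `N_c * 2 * mu_c * sum_i P(mutation_i) * s_c * 0.5 * |i|` over step sizes
#' `i` in -20..20 (i != 0), where `P(mutation_i)` is the symmetric truncated
#' geometric step law with parameter `rho`, `s_c` the class mean selection
#' coefficient, and the 0.5 converts the homozygote-scale `s` to the effect
#' of a single allele copy. Classes with `ks_score <= 50` are flagged
#' excluded and contribute zero.
#'
#' @param records Tibble of class records (see [read_str_classes()]).
#' @param max_step Largest step size summed (default 20).
#' @param scaled If `TRUE`, burdens are divided by 2 so `s` refers to a
#'   single allele, comparable to SNV conventions.
#' @return The input tibble with added columns `expected_mutations`
#'   (`2 * mu_c * N_c`), `burden_per_mutation`, `burden`, `excluded`,
#'   `truncation_deficit` (geometric mass beyond `max_step`).
#' @export
str_denovo_burden <- function(records, max_step = 20L, scaled = FALSE) {
  records <- tibble::as_tibble(records)
  factor <- vapply(records$rho, step_burden_factor, numeric(1),
                   max_step = max_step)
  per_mut <- records$mean_s * factor * (if (scaled) 0.5 else 1)
  excluded <- records$ks_score <= 50
  dplyr::mutate(
    records,
    expected_mutations = 2 * .data$mu_opt * .data$n_loci,
    burden_per_mutation = per_mut,
    burden = ifelse(excluded, 0, .data$expected_mutations * per_mut),
    excluded = excluded,
    truncation_deficit = (1 - .data$rho)^max_step
  )
}

#' Genome-wide de novo STR burden
#'
#' Sums class burdens over all well-fitting classes (`ks_score > 50`) and
#' reports the totals.
#'
#' @inheritParams str_denovo_burden
#' @return One-row tibble with `total_burden`, `total_mutations` (summed
#'   over included classes), `burden_per_mutation` (their ratio),
#'   `n_classes_included`, `n_classes_excluded`.
#' @export
str_burden_total <- function(records, max_step = 20L, scaled = FALSE) {
  per_class <- str_denovo_burden(records, max_step = max_step, scaled = scaled)
  inc <- dplyr::filter(per_class, !.data$excluded)
  tibble::tibble(
    total_burden = sum(inc$burden),
    total_mutations = sum(inc$expected_mutations),
    burden_per_mutation = sum(inc$burden) / sum(inc$expected_mutations),
    n_classes_included = nrow(inc),
    n_classes_excluded = sum(per_class$excluded)
  )
}

#' De novo SNV burden
#'
#' Closed-form per-generation burden for a SNV category:
#' `Burden = 2 * L * mu * s`, i.e. the expected number of new mutations per
#' diploid genome (`2 * L * mu`) times the mean heterozygote selection
#' coefficient. Rows may give `mutations_per_generation` directly or
#' `target_size` and `mu`.
#'
#' @param records Tibble with columns `label`, `mean_s`, and either
#'   `mutations_per_generation` or both `target_size` and `mu`.
#' @return The input tibble with `mutations_per_generation` filled in and a
#'   `burden` column.
#' @examples
#' snv_denovo_burden(tibble::tibble(
#'   label = "nonsynonymous", mean_s = 0.0066,
#'   mutations_per_generation = 0.56
#' ))
#' @export
snv_denovo_burden <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"mutations_per_generation" %in% names(records)) {
    records$mutations_per_generation <- NA_real_
  }
  fill <- is.na(records$mutations_per_generation)
  if (any(fill)) {
    if (!all(c("target_size", "mu") %in% names(records))) {
      stop("need `mutations_per_generation` or both `target_size` and `mu`",
           call. = FALSE)
    }
    records$mutations_per_generation[fill] <-
      2 * records$target_size[fill] * records$mu[fill]
  }
  dplyr::mutate(records,
                burden = .data$mutations_per_generation * .data$mean_s)
}

#' Linear extrapolation of a noncoding SNV burden
#'
#' The burden of noncoding mutations scales linearly with the assumed
#' fraction of noncoding sites under selection (target size enters the
#' burden formula linearly), so a burden computed at one fraction converts
#' to another by simple proportion.
#'
#' @param burden Burden at `from_fraction`.
#' @param from_fraction,to_fraction Fractions of noncoding sites assumed
#'   under selection.
#' @return Extrapolated burden.
#' @export
extrapolate_noncoding_burden <- function(burden, from_fraction, to_fraction) {
  stopifnot(from_fraction > 0, to_fraction > 0)
  burden * to_fraction / from_fraction
}

#' Draw a selection coefficient weighted by segregating-allele frequency
#'
#' Given a table of `(s, frequency)` pairs recorded from simulations in which
#' the observed allele segregated, draws one `s` with probability
#' proportional to the recorded frequency. With the table
#' `{(1e-4, 0.5), (1e-3, 0.2), (1e-2, 0.1)}` the draw probabilities are
#' 5/8, 1/4 and 1/8.
#'
#' @param pairs Data frame with columns `s` and `freq`.
#' @return One sampled `s` (0 if the table is empty).
#' @export
weighted_s_draw <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0 || sum(pairs$freq) == 0) return(0)
  pairs$s[sample.int(nrow(pairs), 1L, prob = pairs$freq / sum(pairs$freq))]
}

#' Frequency-weighted posterior s for an inherited STR allele
#'
#' Inherited variants are biased toward the neutral part of the DFE: a
#' strongly selected allele far from the optimum would rarely segregate. To
#' account for this, `n_draws` selection coefficients are drawn from the
#' class DFE; for each, allele frequencies are simulated and, whenever the
#' observed allele (at `offset` repeat units from the optimum) segregates,
#' the pair `(s, allele frequency)` is recorded. One `s` is then drawn from
#' the recorded table with probability proportional to frequency
#' ([weighted_s_draw()]). Returns 0 if the allele never segregates or if
#' `offset` exceeds the modelled grid (more than 12 repeat units with the
#' default 25-allele grid).
#'
#' @param class_rec One-row tibble with `a`, `b` (gamma DFE) for the class.
#' @param offset `|allele - optimal allele|` in repeat units (>= 0).
#' @param mut,demog,grid,sample_size,scale Simulation context for the class.
#' @param n_draws DFE draws (default 1,000).
#' @return List with `s` (the sampled coefficient) and `pairs` (the recorded
#'   table).
#' @export
inherited_allele_s <- function(class_rec, offset, mut, demog, grid,
                               n_draws = 1000L, sample_size = 1000L,
                               scale = 1) {
  stopifnot(offset >= 0)
  half <- (grid$n - 1) / 2
  if (offset == 0 || offset > half) {
    return(list(s = 0, pairs = tibble::tibble(s = numeric(), freq = numeric())))
  }
  prep <- prepare_sim(mut, demog, grid, scale)
  s_draws <- stats::rgamma(n_draws, shape = class_rec$a) * class_rec$b
  cell <- which(grid$offsets == offset)
  rec <- purrr::map_dfr(s_draws, function(si) {
    freqs <- end_sample(run_trajectory(prep, min(si, 1)), sample_size)
    if (freqs[cell] > 0) tibble::tibble(s = si, freq = freqs[cell]) else NULL
  })
  list(s = weighted_s_draw(rec), pairs = rec)
}

#' Total inherited STR burden of a genome
#'
#' Sums per-variant fitness reductions `offset * s` over a genome's STR
#' variants, with `s` sampled by the frequency-weighted procedure of
#' [inherited_allele_s()]. Reductions below `1e-5` are rounded to 0 and
#' reductions above 1 are capped at 1; variants in classes with
#' `ks_score <= 50` are excluded; offsets beyond the grid contribute 0.
#'
#' @param variants Tibble with columns `class_key` and `offset`
#'   (`|allele - optimal|`, repeat units).
#' @param records Class records with `class_key`, `a`, `b`, `ks_score`,
#'   plus the mutation-model columns `mu_opt` and `rho` used for simulation.
#' @param demog,grid,sample_size,scale Simulation context.
#' @param n_draws DFE draws per variant.
#' @param scaled If `TRUE`, reductions are halved for SNV comparability.
#' @param s_sampler Optional function `(class_rec, offset) -> s` replacing
#'   the simulation-backed sampler (used to plug in precomputed tables).
#' @return One-row tibble with `total_burden`, `n_variants`,
#'   `n_excluded_class`, `n_zeroed`.
#' @export
str_inherited_burden <- function(variants, records, demog = NULL, grid = NULL,
                                 n_draws = 1000L, sample_size = 1000L,
                                 scale = 1, scaled = FALSE,
                                 s_sampler = NULL) {
  variants <- tibble::as_tibble(variants)
  records <- tibble::as_tibble(records)
  unmapped <- setdiff(variants$class_key, records$class_key)
  if (length(unmapped)) {
    stop("variants map to unknown class(es): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  half <- if (is.null(grid)) 12 else (grid$n - 1) / 2
  n_excluded <- 0L
  n_zeroed <- 0L
  reductions <- purrr::pmap_dbl(variants, function(class_key, offset, ...) {
    rec <- records[records$class_key == class_key, ]
    if (rec$ks_score <= 50) {
      n_excluded <<- n_excluded + 1L
      return(0)
    }
    if (offset == 0 || offset > half) return(0)
    s <- if (!is.null(s_sampler)) {
      s_sampler(rec, offset)
    } else {
      mut <- mutation_model(mu0 = rec$mu_opt, rho = rec$rho)
      inherited_allele_s(rec, offset, mut, demog, grid,
                         n_draws = n_draws, sample_size = sample_size,
                         scale = scale)$s
    }
    red <- offset * s
    if (red < 1e-5) { n_zeroed <<- n_zeroed + 1L; red <- 0 }
    if (red > 1) red <- 1
    red
  })
  if (scaled) reductions <- reductions / 2
  tibble::tibble(
    total_burden = sum(reductions),
    n_variants = nrow(variants),
    n_excluded_class = n_excluded,
    n_zeroed = n_zeroed
  )
}

#' Fitness change of a new (noninherited) STR mutation
#'
#' Scores alleles by `|allele - optimal| * s` with the class mean selection
#' coefficient and returns the child-minus-parent difference: positive values
#' mean the new allele is more deleterious than the parental one.
#'
#' @param mean_s Class mean selection coefficient.
#' @param parent_offset,child_offset `|allele - optimal|` for the parental
#'   and new allele (repeat units, >= 0).
#' @return Fitness difference.
#' @examples
#' score_mutation(0.001, parent_offset = 0, child_offset = 3)
#' @export
score_mutation <- function(mean_s, parent_offset, child_offset) {
  stopifnot(parent_offset >= 0, child_offset >= 0)
  (child_offset - parent_offset) * mean_s
}
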