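#' Read a per-locus allele-frequency table
#'
#' The native format is a TSV with header columns `locus_id`, `chrom`,
#' `pos`, `repeat_unit`, `ref_len_units`, `call_rate`, `counts`, where
#' `counts` encodes per-allele-length observed counts as
#' `"len:count,len:count,..."` (lengths in repeat units). Coordinates are
#' 1-based metadata only.
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per locus; `counts` is a list column of named
#'   numeric vectors (names = allele lengths in repeat units), plus a
#'   computed `n_alleles` column (total observed count).
#' @export
read_freq_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           locus_id = readr::col_character(),
                           chrom = readr::col_character(),
                           pos = readr::col_double(),
                           repeat_unit = readr::col_character(),
                           ref_len_units = readr::col_integer(),
                           call_rate = readr::col_double(),
                           counts = readr::col_character()
                         ))
  needed <- c("locus_id", "repeat_unit", "ref_len_units", "call_rate", "counts")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("frequency table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts <- purrr::imap(raw$counts, function(str, i) {
    parts <- strsplit(str, ",", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) {
      stop("line ", i + 1, ": malformed counts entry '", str, "'", call. = FALSE)
    }
    lens <- as.numeric(vapply(kv, `[`, "", 1))
    cnt <- as.numeric(vapply(kv, `[`, "", 2))
    if (anyNA(lens) || anyNA(cnt) || any(cnt < 0)) {
      stop("line ", i + 1, ": counts must be non-negative numbers", call. = FALSE)
    }
    if (sum(cnt) <= 0) {
      stop("line ", i + 1, ": locus has zero total allele count", call. = FALSE)
    }
    stats::setNames(cnt, lens)
  })
  unit_len <- nchar(raw$repeat_unit)
  if (any(!unit_len %in% 2:4)) {
    stop("line(s) ", paste(which(!unit_len %in% 2:4) + 1, collapse = ", "),
         ": repeat unit length must be 2-4 bp", call. = FALSE)
  }
  if (any(raw$call_rate < 0 | raw$call_rate > 1)) {
    stop("call_rate must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  out$counts <- counts
  out$n_alleles <- purrr::map_dbl(counts, sum)
  out
}

#' @rdname read_freq_table
#' @param records Tibble as returned by `read_freq_table()`.
#' @export
write_freq_table <- function(records, path) {
  out <- dplyr::select(records, dplyr::any_of(
    c("locus_id", "chrom", "pos", "repeat_unit", "ref_len_units",
      "call_rate", "counts")
  ))
  out$counts <- purrr::map_chr(records$counts, function(ct) {
    paste(paste0(names(ct), ":", format(ct, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read per-allele counts from a minimal STR VCF
#'
#' Reads the small VCF dialect emitted by STR genotypers: one record per
#' locus with the repeat unit in `INFO/RU`, allele counts in `INFO/AC`
#' (alternate alleles) and the total in `INFO/AN`. REF/ALT sequence lengths
#' are converted from bp to repeat units and must divide evenly by the unit
#' length; records violating this (or lacking `RU`) are skipped with a
#' warning. Allele lengths that collide after conversion have their counts
#' merged.
#'
#' @param path Path to an uncompressed VCF.
#' @param call_rate Call rate to assign (the dialect does not carry one).
#' @return Tibble in the same shape as [read_freq_table()].
#' @export
read_vcf_counts <- function(path, call_rate = 1) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  rows <- purrr::imap(body, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      warning("skipping malformed VCF record at data line ", i)
      return(NULL)
    }
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    val <- function(k) if (k %in% keys) kv[[match(k, keys)]][2] else NA_character_
    ru <- val("RU")
    if (is.na(ru)) {
      warning("skipping record at data line ", i, ": no RU INFO key")
      return(NULL)
    }
    unit <- nchar(ru)
    alts <- if (f[5] %in% c(".", "")) character() else
      strsplit(f[5], ",", fixed = TRUE)[[1]]
    lens_bp <- c(nchar(f[4]), nchar(alts))
    if (any(lens_bp %% unit != 0)) {
      warning("skipping record at data line ", i,
              ": allele length not a whole number of repeat units")
      return(NULL)
    }
    lens <- lens_bp / unit
    an <- as.numeric(val("AN"))
    ac <- if (length(alts)) as.numeric(strsplit(val("AC"), ",")[[1]]) else numeric()
    counts <- c(an - sum(ac), ac)
    agg <- tapply(counts, lens, sum)
    tibble::tibble(
      locus_id = if (f[3] != ".") f[3] else paste0(f[1], ":", f[2]),
      chrom = f[1], pos = as.numeric(f[2]),
      repeat_unit = ru,
      ref_len_units = as.integer(lens[1]),
      call_rate = call_rate,
      counts = list(stats::setNames(as.numeric(agg), names(agg))),
      n_alleles = an
    )
  })
  dplyr::bind_rows(rows)
}

#' Filter loci by reference length and call rate
#'
#' Drops loci whose reference allele is shorter than the per-unit-class
#' threshold (defaults: 11 units for dinucleotides, 5 for trinucleotides,
#' 7 for tetranucleotides -- shorter repeats are typically not polymorphic)
#' or whose call rate is below `min_call_rate`.
#'
#' @param records Locus tibble from [read_freq_table()].
#' @param min_call_rate Minimum fraction of genotyped samples (default 0.8).
#' @param min_len_units Named vector of per-unit-length thresholds.
#' @return List with `kept` (filtered tibble) and `report` (tibble of drop
#'   counts per reason).
#' @export
filter_loci <- function(records, min_call_rate = 0.8,
                        min_len_units = c("2" = 11, "3" = 5, "4" = 7)) {
  unit_len <- as.character(nchar(records$repeat_unit))
  thresh <- unname(min_len_units[unit_len])
  too_short <- records$ref_len_units < thresh
  low_call <- records$call_rate < min_call_rate
  list(
    kept = records[!too_short & !low_call, , drop = FALSE],
    report = tibble::tibble(
      reason = c("reference_too_short", "call_rate_below_minimum"),
      n_dropped = c(sum(too_short), sum(low_call & !too_short))
    )
  )
}

#' Canonical form of a repeat motif
#'
#' Maps a motif to the lexicographically smallest string among all rotations
#' of itself and of its reverse complement, so that e.g. `"TG"`, `"GT"` and
#' `"CA"` all canonicalise to `"AC"`.
#'
#' @param unit Character vector of motifs (A/C/G/T).
#' @return Canonical motif(s).
#' @examples
#' canonical_motif(c("TG", "AAT", "GATC"))
#' @export
canonical_motif <- function(unit) {
  one <- function(u) {
    chars <- strsplit(toupper(u), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")[rev(chars)]
    rots <- function(x) {
      n <- length(x)
      vapply(seq_len(n), function(i) {
        paste(x[c(seq.int(i, n), seq_len(i - 1L))], collapse = "")
      }, "")
    }
    min(c(rots(chars), rots(unname(comp))))
  }
  vapply(unit, one, "", USE.NAMES = FALSE)
}

#' Group loci into STR classes
#'
#' A class is the set of loci sharing a canonical repeat unit and modal
#' (assumed optimal) allele. The modal allele of each locus is taken from
#' its counts (ties broken toward the shorter allele) and per-locus
#' heterozygosities are computed from the count proportions.
#'
#' @param records Filtered locus tibble.
#' @return Tibble with one row per class: `repeat_unit` (canonical),
#'   `opt_allele`, `class_key`, `n_loci`, and list columns `hets`,
#'   `locus_ids`.
#' @export
group_into_classes <- function(records) {
  records <- tibble::as_tibble(records)
  modal <- purrr::map_dbl(records$counts, function(ct) {
    lens <- as.numeric(names(ct))
    top <- lens[ct == max(ct)]
    min(top)  # tie toward the shorter allele
  })
  hets <- purrr::map_dbl(records$counts, function(ct) {
    heterozygosity(ct / sum(ct))
  })
  grouped <- tibble::tibble(
    repeat_unit = canonical_motif(records$repeat_unit),
    opt_allele = modal,
    locus_id = records$locus_id,
    het = hets
  )
  out <- dplyr::summarise(
    dplyr::group_by(grouped, .data$repeat_unit, .data$opt_allele),
    n_loci = dplyr::n(),
    hets = list(.data$het),
    locus_ids = list(.data$locus_id),
    .groups = "drop"
  )
  dplyr::mutate(out,
                class_key = paste0(.data$repeat_unit, ":", .data$opt_allele),
                .after = "opt_allele")
}

#' Specification for a synthetic allele-frequency dataset
#'
#' Bundles everything needed to generate a reproducible synthetic dataset by
#' running the simulator under known truth: the class, the true DFE (gamma
#' parameters or a constant `s`), the mutation model, demography, sample
#' size, optional genotyping-error model and seed.
#'
#' @param class_key Class label, e.g. `"AC:13"`.
#' @param n_loci Number of loci.
#' @param mut A [mutation_model()].
#' @param grid An [allele_grid()].
#' @param truth Either `c(a =, b =)` for gamma-distributed `s` or
#'   `c(s = ...)` for a constant.
#' @param demog A [demographic_model()] (default European).
#' @param sample_size End-sampling allele count.
#' @param err Optional [error_model()].
#' @param scale Demographic rescaling factor.
#' @param seed Integer seed; the dataset is byte-identical given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_key, n_loci, mut, grid, truth,
                           demog = default_demography(),
                           sample_size = 1000L, err = NULL, scale = 1,
                           seed = 1L) {
  stopifnot(n_loci >= 1)
  if (!(all(c("a", "b") %in% names(truth)) || "s" %in% names(truth))) {
    stop("`truth` must be c(a=, b=) or c(s=)", call. = FALSE)
  }
  structure(
    list(class_key = class_key, n_loci = as.integer(n_loci), mut = mut,
         grid = grid, truth = truth, demog = demog,
         sample_size = as.integer(sample_size), err = err, scale = scale,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic allele-frequency dataset with known truth
#'
#' Simulates `n_loci` loci under the spec (per-locus `s` drawn from the
#' truth), optionally injects genotyping errors, and returns the dataset in
#' the native frequency-table shape together with a truth sidecar recording
#' every simulated `s`. When `path` is given, writes `<path>.tsv` (the
#' table), `<path>_truth.tsv` (locus id, true s) and `<path>_spec.yaml`
#' (the resolved spec), byte-identical under the same seed.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional output path stem.
#' @return List with `records` (locus tibble), `truth` (tibble of
#'   `locus_id`, `s_true`) and `paths` (written files, if any).
#' @export
generate_synthetic_dataset <- function(spec, path = NULL) {
  set.seed(spec$seed)
  prep <- prepare_sim(spec$mut, spec$demog, spec$grid, spec$scale)
  s_true <- if ("s" %in% names(spec$truth)) {
    rep(unname(spec$truth[["s"]]), spec$n_loci)
  } else {
    stats::rgamma(spec$n_loci, shape = spec$truth[["a"]]) * spec$truth[["b"]]
  }
  grid <- spec$grid
  records <- purrr::map_dfr(seq_len(spec$n_loci), function(i) {
    freqs <- end_sample(run_trajectory(prep, min(s_true[i], 1)),
                        spec$sample_size)
    if (!is.null(spec$err)) {
      freqs <- inject_genotyping_errors(freqs, spec$sample_size, spec$err, grid)
    }
    cnt <- round(freqs * spec$sample_size)
    keep <- cnt > 0
    lens <- grid$xopt + grid$offsets[keep]
    tibble::tibble(
      locus_id = sprintf("synth_%05d", i),
      chrom = "chrS", pos = i * 1000,
      repeat_unit = sub(":.*$", "", spec$class_key),
      ref_len_units = grid$xopt,
      call_rate = 1,
      counts = list(stats::setNames(as.numeric(cnt[keep]), lens)),
      n_alleles = sum(cnt)
    )
  })
  truth <- tibble::tibble(locus_id = records$locus_id, s_true = s_true)
  paths <- NULL
  if (!is.null(path)) {
    paths <- c(table = paste0(path, ".tsv"),
               truth = paste0(path, "_truth.tsv"),
               spec = paste0(path, "_spec.yaml"))
    write_freq_table(records, paths[["table"]])
    readr::write_tsv(truth, paths[["truth"]])
    yaml::write_yaml(
      list(class_key = spec$class_key, n_loci = spec$n_loci,
           truth = as.list(spec$truth),
           mutation_model = spec$mut[c("mu0", "L", "rho", "beta")],
           demography = spec$demog$name, sample_size = spec$sample_size,
           error_rate = if (is.null(spec$err)) 0 else spec$err$rate,
           scale = spec$scale, seed = spec$seed),
      paths[["spec"]]
    )
  }
  list(records = records, truth = truth, paths = paths)
}
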