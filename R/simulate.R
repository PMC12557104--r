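# Count-level cohort simulation: a synthetic stand-in for a reference NIPT
# cohort of euploid pregnancies, with GC-tilted chromosome proportions, a
# truncated total-read-count distribution, a fetal-fraction floor, and a
# small Y-chromosome read-misassignment background in female-fetus samples.

#' Simulator configuration for synthetic negative cohorts
#'
#' Collects every tunable of [simulate_negative_cohort()] with defaults that
#' emulate a low-coverage cfDNA screening cohort: roughly 3.3 million unique
#' reads per sample (truncated below at 2 million), GC content uniform on
#' 39.5–43\%, fetal fraction at least 4\% with a lognormal body, chromosome
#' read-count expectations proportional to hg19 chromosome lengths weighted
#' by maternal/fetal copy number, a per-chromosome exponential GC tilt, and a
#' linear-in-TRC Y-misassignment background for female fetuses.
#'
#' @param n_samples Number of samples to simulate.
#' @param male_fraction Expected fraction of male (XY) fetuses.
#' @param trc_mean,trc_sd,trc_min Total-read-count distribution: normal with
#'   this mean and sd, truncated below at `trc_min` reads.
#' @param ff_meanlog,ff_sdlog,ff_min,ff_max Fetal-fraction distribution:
#'   lognormal with these log-scale parameters, truncated to
#'   `[ff_min, ff_max]`.
#' @param gc_min,gc_max Per-sample GC content, uniform on this interval.
#' @param base_proportions Baseline chromosome proportion vector (sums to 1);
#'   defaults to hg19 chromosome-length fractions. Copy-number weighting by
#'   fetal sex and fetal fraction is applied on top of it.
#' @param gc_kappa Named per-chromosome GC-sensitivity coefficients: the
#'   expected proportion of chromosome c is multiplied by
#'   `exp(gc_kappa[c] * (gc - gc_ref))` and renormalized. The default tilts
#'   chr13 down with GC (`-3`), reproducing the strong GC/count coupling that
#'   makes chromosome-13 screening hard for a plain z score.
#' @param gc_ref GC content at which the tilt is neutral.
#' @param y_misassign_intercept,y_misassign_slope,y_misassign_sd Background
#'   of reads erroneously assigned to chrY in samples with no true fetal Y:
#'   `max(0, round(intercept + slope * TRC + Normal(0, sd)))` reads.
#' @return An object of class `simulator_config` (a validated list).
#' @export
simulator_config <- function(n_samples = 1000,
                             male_fraction = 0.5,
                             trc_mean = 3.3e6,
                             trc_sd = 0.4e6,
                             trc_min = 2e6,
                             ff_meanlog = log(0.10),
                             ff_sdlog = 0.35,
                             ff_min = 0.04,
                             ff_max = 0.30,
                             gc_min = 0.395,
                             gc_max = 0.43,
                             base_proportions = NULL,
                             gc_kappa = NULL,
                             gc_ref = 0.4125,
                             y_misassign_intercept = 50,
                             y_misassign_slope = 2e-4,
                             y_misassign_sd = 10) {
  if (is.null(base_proportions)) {
    base_proportions <- hg19_lengths / sum(hg19_lengths)
  }
  if (!identical(sort(names(base_proportions)), sort(chromosome_names())) ||
      abs(sum(base_proportions) - 1) > 1e-8 || any(base_proportions <= 0)) {
    abort("`base_proportions` must be positive, named by the 24 chromosomes, and sum to 1.")
  }
  base_proportions <- base_proportions[chromosome_names()]
  if (is.null(gc_kappa)) {
    gc_kappa <- setNames(rep(0, 24), chromosome_names())
    gc_kappa["chr13"] <- -3
  }
  if (!all(chromosome_names() %in% names(gc_kappa))) {
    abort("`gc_kappa` must name all 24 chromosomes.")
  }
  gc_kappa <- gc_kappa[chromosome_names()]
  stopifnot(
    n_samples >= 1, male_fraction >= 0, male_fraction <= 1,
    trc_sd >= 0, trc_min > 0, trc_mean > 0,
    ff_sdlog >= 0, ff_min >= 0, ff_max < 1, ff_min < ff_max,
    gc_min > 0, gc_max < 1, gc_min < gc_max,
    y_misassign_sd >= 0
  )
  structure(
    list(
      n_samples = as.integer(n_samples), male_fraction = male_fraction,
      trc_mean = trc_mean, trc_sd = trc_sd, trc_min = trc_min,
      ff_meanlog = ff_meanlog, ff_sdlog = ff_sdlog,
      ff_min = ff_min, ff_max = ff_max,
      gc_min = gc_min, gc_max = gc_max,
      base_proportions = base_proportions,
      gc_kappa = gc_kappa, gc_ref = gc_ref,
      y_misassign_intercept = y_misassign_intercept,
      y_misassign_slope = y_misassign_slope,
      y_misassign_sd = y_misassign_sd
    ),
    class = "simulator_config"
  )
}

#' @exportS3Method base::print
print.simulator_config <- function(x, ...) {
  cat(sprintf(
    "<simulator_config> n = %d, TRC ~ N(%.3g, %.3g) >= %.3g, FF in [%.3g, %.3g], GC in [%.3g, %.3g]\n",
    x$n_samples, x$trc_mean, x$trc_sd, x$trc_min, x$ff_min, x$ff_max,
    x$gc_min, x$gc_max))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- rlnorm(n, meanlog, sdlog)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# Expected chromosome proportions for one sample: maternal (XX) and fetal
# genomes weighted (1 - ff, ff) by copy number, then GC-tilted and
# renormalized. chrY expectation is zero for female fetuses (misassignment
# background is added separately).
expected_proportions <- function(config, fetal_sex, ff, gc) {
  p <- config$base_proportions
  copies_mat <- setNames(c(rep(2, 22), 2, 0), chromosome_names())
  copies_fet <- if (fetal_sex == "XY") {
    setNames(c(rep(2, 22), 1, 1), chromosome_names())
  } else {
    setNames(c(rep(2, 22), 2, 0), chromosome_names())
  }
  w_mat <- p * copies_mat; w_mat <- w_mat / sum(w_mat)
  w_fet <- p * copies_fet; w_fet <- w_fet / sum(w_fet)
  w <- (1 - ff) * w_mat + ff * w_fet
  w <- w * exp(config$gc_kappa * (gc - config$gc_ref))
  w / sum(w)
}

#' Simulate a synthetic negative (euploid) NIPT cohort
#'
#' Draws `n_samples` count-level samples. For each sample: fetal sex is
#' Bernoulli(`male_fraction`); TRC, FF and GC are drawn from the configured
#' truncated distributions; a Y-misassignment background count is drawn as
#' `max(0, round(intercept + slope * TRC + noise))`; and the remaining reads
#' are distributed over the chromosomes by a multinomial draw from the
#' sample's GC-tilted, sex- and FF-weighted expected proportions. Male
#' fetuses contribute true chrY reads through the multinomial (their
#' expectation grows with FF and TRC); female-fetus chrY counts are pure
#' misassignment background.
#'
#' @param config A [simulator_config()].
#' @param seed Integer seed; identical seed and config give an identical
#'   cohort.
#' @return Tibble with one row per sample and columns `sample_id`,
#'   `fetal_sex`, `ff`, `gc`, `chr1`..`chr22`, `chrX`, `chrY`, `label`
#'   (`NEG_XX` or `NEG_XY`). Row sums of the count columns equal the drawn
#'   TRC exactly.
#' @export
simulate_negative_cohort <- function(config = simulator_config(), seed = NULL) {
  if (!inherits(config, "simulator_config")) {
    abort("`config` must be a simulator_config object.")
  }
  local_seed(seed)
  n <- config$n_samples
  fetal_sex <- ifelse(runif(n) < config$male_fraction, "XY", "XX")
  trc <- round(rtrunc_norm(n, config$trc_mean, config$trc_sd, config$trc_min))
  ff <- rtrunc_lnorm(n, config$ff_meanlog, config$ff_sdlog,
                     config$ff_min, config$ff_max)
  gc <- runif(n, config$gc_min, config$gc_max)

  y_bg <- pmax(0, round(config$y_misassign_intercept +
                          config$y_misassign_slope * trc +
                          rnorm(n, 0, config$y_misassign_sd)))
  y_bg <- pmin(y_bg, trc)

  # Per-sample expected proportions (n x 24), chrY excluded for females.
  p <- config$base_proportions
  w_mat <- p * c(rep(2, 22), 2, 0); w_mat <- w_mat / sum(w_mat)
  w_xy <- p * c(rep(2, 22), 1, 1); w_xy <- w_xy / sum(w_xy)
  w_xx <- w_mat
  w_fet <- matrix(w_xx, n, 24, byrow = TRUE)
  n_xy <- sum(fetal_sex == "XY")
  if (n_xy > 0) {
    w_fet[fetal_sex == "XY", ] <- matrix(w_xy, n_xy, 24, byrow = TRUE)
  }
  probs <- (1 - ff) * matrix(w_mat, n, 24, byrow = TRUE) + ff * w_fet
  probs <- probs * exp(outer(gc - config$gc_ref, config$gc_kappa))
  probs <- probs / rowSums(probs)
  colnames(probs) <- chromosome_names()

  # Multinomial draw via sequential binomial thinning, vectorized over
  # samples; the last category absorbs the remainder so totals are exact.
  size <- trc - y_bg
  counts <- matrix(0L, n, 24, dimnames = list(NULL, chromosome_names()))
  remaining <- size
  prem <- rep(1, n)
  for (j in seq_len(23)) {
    pj <- pmin(1, pmax(0, probs[, j] / prem))
    x <- rbinom(n, remaining, pj)
    counts[, j] <- x
    remaining <- remaining - x
    prem <- prem - probs[, j]
  }
  counts[, 24] <- remaining
  counts[, "chrY"] <- counts[, "chrY"] + y_bg

  out <- tibble(
    sample_id = sprintf("sim%06d", seq_len(n)),
    fetal_sex = fetal_sex,
    ff = ff,
    gc = gc
  )
  out <- dplyr::bind_cols(out, as_tibble(counts))
  out$label <- ifelse(fetal_sex == "XY", "NEG_XY", "NEG_XX")
  out
}

#' Simulate a cfDNA-like fixture FASTQ set
#'
#' Emits `n_reads` reads whose lengths follow a two-component cfDNA fragment
#' size mixture: a maternal component and a shorter fetal component, weighted
#' `(1 - ff, ff)`. Sequences are substrings of a random background genome
#' generated at the requested GC rate, so the emitted reads have realistic
#' base composition without any alignment semantics.
#'
#' @param n_reads Number of reads.
#' @param ff Fetal fraction in `[0, 1)`; the fetal mixture weight.
#' @param fetal_sex `"XX"` or `"XY"` (metadata only).
#' @param length_model List with `maternal_mode`, `maternal_sd`, `fetal_mode`,
#'   `fetal_sd`, `min_len`, `max_len` (bp). Defaults: maternal 166 +/- 9,
#'   fetal 143 +/- 8, support 100–220 bp.
#' @param gc_rate GC rate of the background genome.
#' @param id_prefix Prefix of the read ids; pass distinct prefixes to keep
#'   sets nonoverlapping for [merge_fastq_sets()].
#' @param seed Integer seed.
#' @return A [fastq_set()].
#' @export
simulate_fixture_fastq <- function(n_reads, ff, fetal_sex = c("XX", "XY"),
                                   length_model = list(), gc_rate = 0.41,
                                   id_prefix = "read", seed = NULL) {
  fetal_sex <- arg_match(fetal_sex)
  if (n_reads < 1) abort("`n_reads` must be positive.")
  check_ff(ff)
  lm0 <- list(maternal_mode = 166, maternal_sd = 9,
              fetal_mode = 143, fetal_sd = 8,
              min_len = 100, max_len = 220)
  lm0[names(length_model)] <- length_model
  local_seed(seed)

  fetal <- runif(n_reads) < ff
  len <- ifelse(fetal,
                rnorm(n_reads, lm0$fetal_mode, lm0$fetal_sd),
                rnorm(n_reads, lm0$maternal_mode, lm0$maternal_sd))
  len <- pmin(lm0$max_len, pmax(lm0$min_len, round(len)))

  genome_len <- max(1e6, 10 * lm0$max_len)
  genome <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE,
                         prob = c((1 - gc_rate) / 2, gc_rate / 2,
                                  gc_rate / 2, (1 - gc_rate) / 2)),
                  collapse = "")
  start <- floor(runif(n_reads, 1, genome_len - lm0$max_len))
  seqs <- substring(genome, start, start + len - 1)
  qual <- strrep("I", len)

  fastq_set(
    tibble(id = sprintf("%s_%07d", id_prefix, seq_len(n_reads)),
           sequence = seqs, quality = qual),
    ff = ff, fetal_sex = fetal_sex
  )
}

#' Apply cohort inclusion filters
#'
#' Retains samples that meet the reference-cohort inclusion criteria: at
#' least 2 million unique reads, GC content between 39.5\% and 43\%
#' (inclusive), and a fetal fraction of 4\% or higher (inclusive). Order is
#' preserved and the operation is idempotent.
#'
#' @param cohort Cohort tibble (see [simulate_negative_cohort()]).
#' @param min_trc Minimum total read count.
#' @param gc_range Closed GC interval, as fractions.
#' @param min_ff Minimum fetal fraction.
#' @return The filtered cohort tibble (possibly empty).
#' @export
apply_inclusion_filters <- function(cohort, min_trc = 2e6,
                                    gc_range = c(0.395, 0.43),
                                    min_ff = 0.04) {
  check_cohort(cohort)
  trc <- total_read_count(cohort)
  keep <- trc >= min_trc &
    cohort$gc >= gc_range[1] & cohort$gc <= gc_range[2] &
    cohort$ff >= min_ff
  cohort[keep, , drop = FALSE]
}

# Cohort I/O --------------------------------------------------------------

#' Read and write cohort tables
#'
#' Cohorts are stored as plain TSV with columns `sample_id`, `fetal_sex`,
#' `ff`, `gc`, `chr1`..`chr22`, `chrX`, `chrY`, `label`.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_tsv(path, show_col_types = FALSE)
  check_cohort(cohort)
  cohort
}
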