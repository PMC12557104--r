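# Shared fixture builders; everything is generated in code at test time.

small_sim_config <- function(n = 200, ...) {
  simulator_config(n_samples = n, ...)
}

# A tiny deterministic cohort for arithmetic-level tests: counts are exact
# round numbers so equation oracles can be evaluated by hand.
toy_cohort <- function(n = 4, fetal_sex = rep(c("XX", "XY"), length.out = n),
                       ff = seq(0.05, 0.2, length.out = n),
                       gc = rep(0.41, n)) {
  counts <- matrix(100000L, n, 24,
                   dimnames = list(NULL, chromosome_names()))
  counts[, "chrY"] <- ifelse(fetal_sex == "XY", 9000L, 500L)
  counts[, "chrX"] <- 200000L
  out <- tibble::tibble(
    sample_id = sprintf("toy%02d", seq_len(n)),
    fetal_sex = fetal_sex, ff = ff, gc = gc
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out$label <- ifelse(fetal_sex == "XY", "NEG_XY", "NEG_XX")
  out
}

# Small FASTQ sets with controllable ids for merge tests.
tiny_fastq <- function(n, prefix, ff = 0.05, fetal_sex = "XX", seed = 1,
                       len = NULL) {
  withr::with_seed(seed, {
    lens <- if (is.null(len)) sample(100:200, n, replace = TRUE) else rep(len, n)
    tibble::tibble(
      id = sprintf("%s_%05d", prefix, seq_len(n)),
      sequence = vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
      }, character(1)),
      quality = strrep("I", lens)
    )
  }) |>
    fastq_set(ff = ff, fetal_sex = fetal_sex)
}
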