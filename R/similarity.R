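# Fragment-length similarity study: compares cfDNA-like fixture read sets
# against merged-and-subsampled synthetic sets at matched fetal fractions.

#' Fragment-length similarity of fixture vs merged synthetic read sets
#'
#' For each fetal-fraction level, generates `n_sets` fixture FASTQ sets and
#' `n_sets` synthetic sets — each synthetic set merges two or three
#' nonoverlapping donor sets whose fetal fractions straddle the level
#' symmetrically (so the read-count-weighted mean equals the level exactly)
#' and subsamples the pool back to `n_reads` — then correlates the mean
#' fragment-length frequency distribution of the fixture group with that of
#' the synthetic group.
#'
#' @param ff_levels Fetal-fraction levels to study.
#' @param n_sets Sets per group per level.
#' @param n_reads Reads per set.
#' @param ff_spread Half-width of the donor fetal-fraction spread.
#' @param seed Integer seed.
#' @return Tibble with one row per level: `ff`, `correlation` (percent,
#'   from [length_distribution_correlation()]), `n_sets`, `n_reads`.
#' @export
merge_similarity_study <- function(ff_levels = c(0.05, 0.10, 0.15),
                                   n_sets = 20, n_reads = 1e5,
                                   ff_spread = 0.02, seed = NULL) {
  stopifnot(n_sets >= 1, n_reads >= 1, ff_spread >= 0)
  check_ff(ff_levels)
  local_seed(seed)

  mean_distribution <- function(dists) {
    support <- sort(unique(unlist(purrr::map(dists, "length"))))
    freqs <- purrr::map(dists, function(d) {
      f <- setNames(numeric(length(support)), support)
      f[as.character(d$length)] <- d$frequency
      f
    })
    tibble(length = support,
           frequency = Reduce(`+`, freqs) / length(freqs))
  }

  purrr::map(ff_levels, function(level) {
    fixture <- purrr::map(seq_len(n_sets), function(i) {
      length_distribution(simulate_fixture_fastq(
        n_reads, level, "XX", id_prefix = sprintf("fix%02d", i),
        seed = sample.int(.Machine$integer.max, 1)))
    })
    synthetic <- purrr::map(seq_len(n_sets), function(i) {
      k <- sample(2:3, 1)
      ffs <- if (k == 2) {
        c(level - ff_spread, level + ff_spread)
      } else {
        c(level - ff_spread, level, level + ff_spread)
      }
      ffs <- pmax(0, ffs)
      donors <- purrr::imap(ffs, function(f, j) {
        simulate_fixture_fastq(n_reads, f, "XX",
                               id_prefix = sprintf("don%02d_%d", i, j),
                               seed = sample.int(.Machine$integer.max, 1))
      })
      merged <- merge_fastq_sets(donors, target_reads = n_reads,
                                 seed = sample.int(.Machine$integer.max, 1))
      length_distribution(merged)
    })
    tibble(
      ff = level,
      correlation = length_distribution_correlation(
        mean_distribution(fixture), mean_distribution(synthetic)),
      n_sets = n_sets, n_reads = n_reads
    )
  }) |>
    dplyr::bind_rows()
}
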