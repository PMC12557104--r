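# FASTQ-level synthetic-negative generation: merge nonoverlapping read sets,
# shuffle, subsample to a target depth, and propagate the fetal fraction by
# its read-count-weighted mean.

#' Construct a FASTQ read set with sample metadata
#'
#' A `fastq_set` bundles the reads of one cfDNA sequencing run (as a tibble
#' with columns `id`, `sequence`, `quality`) with the metadata the merge
#' pathway needs: the read count, the fetal fraction (FF) and the fetal sex.
#' FF is stored at full floating precision; it is never rounded before the
#' weighted-mean arithmetic of [merged_ff()].
#'
#' @param reads Tibble or data frame with character columns `id`, `sequence`
#'   and `quality`. Sequence and quality must be equal-length strings per
#'   read, and sequences use the alphabet A, C, G, T, N.
#' @param ff Fetal fraction in `[0, 1)`.
#' @param fetal_sex `"XX"` or `"XY"`.
#' @return An object of class `fastq_set`.
#' @seealso [merge_fastq_sets()], [read_fastq()], [simulate_fixture_fastq()]
#' @export
fastq_set <- function(reads, ff, fetal_sex = c("XX", "XY")) {
  fetal_sex <- arg_match(fetal_sex)
  reads <- as_tibble(reads)
  required <- c("id", "sequence", "quality")
  if (!all(required %in% names(reads))) {
    abort("`reads` must have columns id, sequence and quality.")
  }
  reads <- reads[required]
  if (nrow(reads) > 0) {
    if (anyDuplicated(reads$id)) {
      abort("Read ids within a fastq_set must be unique.")
    }
    if (!all(nchar(reads$sequence) == nchar(reads$quality))) {
      abort("Each read's sequence and quality strings must have equal length.")
    }
    if (any(stringr::str_detect(reads$sequence, "[^ACGTN]"))) {
      abort("Sequences may only contain A, C, G, T and N.")
    }
  }
  check_ff(ff)
  if (length(ff) != 1) abort("`ff` must be a single fetal fraction.")
  structure(
    list(reads = reads, read_count = nrow(reads), ff = as.numeric(ff),
         fetal_sex = fetal_sex),
    class = "fastq_set"
  )
}

#' @exportS3Method base::print
print.fastq_set <- function(x, ...) {
  cat(sprintf("<fastq_set> %d reads, FF = %.6g, fetal sex %s\n",
              x$read_count, x$ff, x$fetal_sex))
  invisible(x)
}

#' @rdname fastq_set
#' @param x Object to test.
#' @export
is_fastq_set <- function(x) inherits(x, "fastq_set")

#' Read and write FASTQ files with sample metadata
#'
#' Strict 4-line FASTQ records (no line wrapping, Phred+33 qualities), parsed
#' and emitted through Biostrings. Metadata (fetal fraction, fetal sex) is not
#' part of the FASTQ format and travels in a sidecar manifest; see
#' [write_fastq_manifest()].
#'
#' @param path File path of the FASTQ file.
#' @param ff,fetal_sex Metadata attached to the returned set.
#' @return `read_fastq()` returns a [fastq_set()]; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path, ff, fetal_sex = c("XX", "XY")) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  reads <- tibble(
    id = names(seqs),
    sequence = unname(as.character(seqs)),
    quality = unname(as.character(S4Vectors::mcols(seqs)$qualities))
  )
  fastq_set(reads, ff = ff, fetal_sex = fetal_sex)
}

#' @rdname read_fastq
#' @param x A [fastq_set()].
#' @export
write_fastq <- function(x, path) {
  stopifnot(is_fastq_set(x))
  seqs <- Biostrings::DNAStringSet(x$reads$sequence)
  names(seqs) <- x$reads$id
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(x$reads$quality)
  )
  invisible(path)
}

#' Write a cohort manifest for a collection of FASTQ sets
#'
#' Writes each set to `<dir>/<id>.fastq` and a TSV manifest with columns
#' `path`, `read_count`, `ff`, `fetal_sex` — the metadata contract of the
#' merge pathway.
#'
#' @param sets Named list of [fastq_set()] objects; names become file stems.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest, invisibly; also written to `<dir>/manifest.tsv`.
#' @export
write_fastq_manifest <- function(sets, dir) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- purrr::imap(sets, function(s, nm) {
    p <- file.path(dir, paste0(nm, ".fastq"))
    write_fastq(s, p)
    tibble(path = p, read_count = s$read_count, ff = s$ff,
           fetal_sex = s$fetal_sex)
  })
  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' @rdname write_fastq_manifest
#' @param manifest Path to a manifest TSV written by [write_fastq_manifest()].
#' @export
read_fastq_manifest <- function(manifest) {
  tab <- readr::read_tsv(manifest, show_col_types = FALSE)
  purrr::pmap(tab, function(path, read_count, ff, fetal_sex, ...) {
    s <- read_fastq(path, ff = ff, fetal_sex = fetal_sex)
    if (s$read_count != read_count) {
      abort(sprintf("Manifest read_count (%d) disagrees with %s (%d reads).",
                    read_count, path, s$read_count))
    }
    s
  })
}

# Fetal-fraction arithmetic ----------------------------------------------

#' Fetal fraction of a merged read pool
#'
#' When read sets are pooled, the fetal fraction of the pool is the
#' read-count-weighted mean of the component fetal fractions:
#' \deqn{FF_{pool} = \frac{\sum_i M_i \cdot FF_i}{\sum_i M_i}}
#' where \eqn{M_i} is the number of reads contributed by component \eqn{i}.
#' The value is exact — no rounding is applied — and the weighted mean is
#' associative, so merging merged pools gives the same answer as merging
#' their components directly.
#'
#' @param components Data frame with columns `read_count` (positive integers)
#'   and `ff` (fetal fractions in `[0, 1)`); one row per component file.
#' @return The pooled fetal fraction as a single number.
#' @export
#' @examples
#' merged_ff(data.frame(read_count = c(1e6, 3e6), ff = c(0.04, 0.08)))
merged_ff <- function(components) {
  if (!is.data.frame(components) ||
      !all(c("read_count", "ff") %in% names(components))) {
    abort("`components` must be a data frame with columns read_count and ff.")
  }
  if (nrow(components) == 0) {
    abort("At least one component is required to form a merged fetal fraction.")
  }
  m <- components$read_count
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("All component read counts must be positive.")
  }
  check_ff(components$ff)
  sum(m * components$ff) / sum(m)
}

# Merge and subsample ----------------------------------------------------

#' Merge nonoverlapping FASTQ sets and subsample to a target depth
#'
#' Pools the reads of two or more nonoverlapping read sets (disjoint read
#' ids) of the same fetal sex, shuffles the pool with a seeded RNG, and keeps
#' exactly `target_reads` reads — sampling without replacement, so every
#' output read is one of the input reads. The output fetal fraction is the
#' weighted mean of the inputs ([merged_ff()]); the fragment-length
#' distribution of the pool is preserved up to subsampling noise.
#'
#' @param inputs List of at least two [fastq_set()] objects with pairwise
#'   disjoint read ids and identical `fetal_sex`.
#' @param target_reads Number of reads to keep; at most the pooled total.
#' @param seed Integer seed controlling the shuffle/subsample. Identical
#'   seeds and inputs give byte-identical output.
#' @return A [fastq_set()] with exactly `target_reads` reads.
#' @export
merge_fastq_sets <- function(inputs, target_reads, seed = NULL) {
  if (!is.list(inputs) || length(inputs) < 2 ||
      !all(vapply(inputs, is_fastq_set, logical(1)))) {
    abort("`inputs` must be a list of two or more fastq_set objects.")
  }
  sexes <- vapply(inputs, function(s) s$fetal_sex, character(1))
  if (length(unique(sexes)) != 1) {
    abort("All inputs must share the same fetal sex.")
  }
  pool <- dplyr::bind_rows(purrr::map(inputs, "reads"))
  if (anyDuplicated(pool$id)) {
    abort("Input sets overlap: read ids must be pairwise disjoint.")
  }
  total <- nrow(pool)
  target_reads <- as.integer(target_reads)
  if (target_reads < 1 || target_reads > total) {
    abort(sprintf("`target_reads` must be in [1, %d] (pooled total).", total))
  }
  local_seed(seed)
  keep <- sample.int(total, total, replace = FALSE)[seq_len(target_reads)]
  out <- pool[keep, ]
  ff <- merged_ff(tibble(
    read_count = vapply(inputs, function(s) s$read_count, numeric(1)),
    ff = vapply(inputs, function(s) s$ff, numeric(1))
  ))
  fastq_set(out, ff = ff, fetal_sex = sexes[[1]])
}

# Fragment-length distributions ------------------------------------------

#' Fragment-length frequency distribution of a read set
#'
#' Tabulates read lengths into relative frequencies. cfDNA fragment sizes are
#' bimodal (a maternal mode near 166 bp and a shorter fetal mode), so the
#' shape of this distribution varies with the fetal fraction and is the basis
#' of the real-vs-synthetic similarity check.
#'
#' @param x A [fastq_set()] or a numeric vector of fragment lengths (bp).
#' @return Tibble with columns `length` (strictly increasing) and `frequency`
#'   (non-negative, summing to 1).
#' @export
length_distribution <- function(x) {
  lengths <- if (is_fastq_set(x)) nchar(x$reads$sequence) else x
  if (length(lengths) == 0) abort("Cannot tabulate an empty read set.")
  tab <- table(lengths)
  tibble(
    length = as.integer(names(tab)),
    frequency = as.numeric(tab) / length(lengths)
  )
}

#' Correlation between two fragment-length distributions (percent)
#'
#' Aligns two fragment-length frequency distributions on the union of their
#' supports (absent lengths contribute frequency 0) and returns the
#' product-moment correlation of the two frequency vectors, expressed in
#' percent. This is the similarity statistic used to compare real and merged
#' synthetic read sets; values above 99.9 indicate near-identical fragment
#' size profiles.
#'
#' @param a,b Length-distribution tibbles as returned by
#'   [length_distribution()], or objects coercible via that function.
#' @return Correlation coefficient times 100 (so in `[-100, 100]`).
#' @export
length_distribution_correlation <- function(a, b) {
  a <- as_length_distribution(a)
  b <- as_length_distribution(b)
  support <- sort(union(a$length, b$length))
  fa <- setNames(numeric(length(support)), support)
  fb <- fa
  fa[as.character(a$length)] <- a$frequency
  fb[as.character(b$length)] <- b$frequency
  if (sd(fa) == 0 || sd(fb) == 0) {
    abort("Correlation is undefined for a zero-variance frequency vector.")
  }
  100 * cor(fa, fb)
}

as_length_distribution <- function(x) {
  if (is_fastq_set(x) || is.numeric(x)) x <- length_distribution(x)
  if (!is.data.frame(x) || !all(c("length", "frequency") %in% names(x))) {
    abort("Expected a length-distribution tibble with columns length, frequency.")
  }
  if (any(x$frequency < 0) || abs(sum(x$frequency) - 1) > 1e-8) {
    abort("Frequencies must be non-negative and sum to 1.")
  }
  if (is.unsorted(x$length, strictly = TRUE)) {
    x <- dplyr::arrange(x, .data$length)
  }
  x
}

#' GC content of a read set
#'
#' Computed from the emitted sequences themselves, not from metadata: after a
#' merge the GC content of the output is recomputed from its actual reads, so
#' the value always matches the file a downstream model would see.
#'
#' @param x A [fastq_set()].
#' @return Fraction of G+C bases among all non-N bases.
#' @export
gc_content <- function(x) {
  stopifnot(is_fastq_set(x))
  gc <- sum(stringr::str_count(x$reads$sequence, "[GC]"))
  acgt <- sum(stringr::str_count(x$reads$sequence, "[ACGT]"))
  if (acgt == 0) abort("No called bases; GC content undefined.")
  gc / acgt
}
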