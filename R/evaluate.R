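# Prevalence-stratified evaluation: build evaluation sets whose positive
# counts reflect a condition's population prevalence inflated by an
# upscaling factor, score them with both classifiers, and compare
# sensitivity and PPV across upscales. As the upscale falls toward 1x the
# evaluation set approaches the real class balance, which is where PPV
# differences between methods become visible.

#' Build a prevalence-stratified evaluation set
#'
#' Draws `n_neg` negatives from a held-out pool and adds
#' `n_pos = round(n_neg * prevalence * upscale)` positives produced by
#' `pos_generator`, then shuffles. The negative pool must be disjoint from
#' everything used in training; positives are synthesized from fresh
#' negatives by the generator.
#'
#' @param neg_pool Tibble of held-out negative samples (at least `n_neg`).
#' @param pos_generator Function `(n, seed)` returning `n` positive samples
#'   of the evaluated condition.
#' @param prevalence Condition prevalence as a fraction (e.g. `8.27e-4` for
#'   8.27 per 10,000).
#' @param upscale Prevalence upscaling factor (1 reproduces the population
#'   rate).
#' @param n_neg Number of negatives in the set.
#' @param seed Integer seed for negative sampling, positive generation and
#'   the final shuffle.
#' @return Shuffled cohort tibble of `n_neg + n_pos` rows.
#' @export
build_prevalence_eval_set <- function(neg_pool, pos_generator, prevalence,
                                      upscale, n_neg, seed = NULL) {
  check_cohort(neg_pool)
  check_negative(neg_pool)
  stopifnot(prevalence > 0, prevalence < 1, upscale >= 1, n_neg > 0)
  if (nrow(neg_pool) < n_neg) {
    abort("Negative pool is smaller than `n_neg`.")
  }
  n_pos <- as.integer(round(n_neg * prevalence * upscale))
  if (n_pos == 0) {
    abort("Requested prevalence/upscale yields zero positives; evaluation undefined.")
  }
  local_seed(seed)
  negs <- neg_pool[sample.int(nrow(neg_pool), n_neg), , drop = FALSE]
  pos <- pos_generator(n_pos, sample.int(.Machine$integer.max, 1))
  check_cohort(pos)
  out <- dplyr::bind_rows(negs, pos)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Confusion counts, sensitivity and PPV
#'
#' @param predicted Logical vector of positive calls.
#' @param truth Logical vector of true positive status, same length.
#' @return One-row tibble with `TP`, `FP`, `TN`, `FN`, `sensitivity` and
#'   `ppv` in percent. When a ratio is undefined (no true positives, or no
#'   positive calls) the corresponding metric is `NA`, never a silent 0.
#' @export
evaluate_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  tibble(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}

#' Per-class one-vs-rest metrics for multiclass predictions
#'
#' @param predicted Character vector of predicted class labels.
#' @param truth Character vector of true class labels, same length.
#' @return Tibble with one row per class present in `truth`, with the same
#'   columns as [evaluate_metrics()] plus `class`.
#' @export
evaluate_per_class <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  classes <- sort(unique(truth))
  purrr::map(classes, function(cl) {
    dplyr::bind_cols(tibble(class = cl),
                     evaluate_metrics(predicted == cl, truth == cl))
  }) |>
    dplyr::bind_rows()
}

# Experiment configuration ---------------------------------------------------

#' Configuration of the full comparison experiment
#'
#' Bundles every knob of [run_comparison_experiment()]. The default
#' prevalences are the population rates used for evaluation — 0.55, 1.07
#' and 8.27 per 10,000 for T13, T18 and T21 — and the default upscale grid
#' is 1, 5, 10, 20, 40. Defaults are desk-scale: 20,000 training samples
#' per class and 50,000 evaluation negatives per trisomy, 35,000/9,000 per
#' sex-karyotype class.
#'
#' @param sim A [simulator_config()] describing the negative cohort
#'   (its `n_samples` is overridden per stage).
#' @param n_train_per_class,n_eval_neg ACA training size per class and
#'   evaluation negative count.
#' @param prevalence Named vector of condition prevalences.
#' @param upscales Integer vector of upscaling factors.
#' @param sca_train_per_class,sca_eval_per_class SCA training/evaluation
#'   sizes per class.
#' @param z_threshold z-score decision threshold.
#' @param outlier_k Robust z threshold of [remove_outliers()].
#' @param lambda Ridge penalty of the logistic models.
#' @param baseline Normalization baseline in reads.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = simulator_config(),
                              n_train_per_class = 20000,
                              n_eval_neg = 50000,
                              prevalence = c(T13 = 0.55e-4, T18 = 1.07e-4,
                                             T21 = 8.27e-4),
                              upscales = c(1, 5, 10, 20, 40),
                              sca_train_per_class = 35000,
                              sca_eval_per_class = 9000,
                              z_threshold = 3,
                              outlier_k = 4,
                              lambda = 1e-4,
                              baseline = 3e6) {
  stopifnot(inherits(sim, "simulator_config"),
            all(prevalence > 0), all(prevalence < 1),
            all(upscales >= 1), n_train_per_class > 0, n_eval_neg > 0,
            sca_train_per_class > 0, sca_eval_per_class > 0)
  if (is.null(names(prevalence)) ||
      !all(names(prevalence) %in% c("T13", "T18", "T21"))) {
    abort("`prevalence` must be named with conditions T13/T18/T21.")
  }
  structure(
    list(sim = sim, n_train_per_class = n_train_per_class,
         n_eval_neg = n_eval_neg, prevalence = prevalence,
         upscales = upscales, sca_train_per_class = sca_train_per_class,
         sca_eval_per_class = sca_eval_per_class, z_threshold = z_threshold,
         outlier_k = outlier_k, lambda = lambda, baseline = baseline),
    class = "experiment_config"
  )
}

sim_with <- function(config, n, male_fraction = NULL) {
  sim <- config$sim
  sim$n_samples <- as.integer(n)
  if (!is.null(male_fraction)) sim$male_fraction <- male_fraction
  class(sim) <- "simulator_config"
  sim
}

condition_target <- function(condition) {
  paste0("chr", sub("T", "", condition))
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% .Machine$integer.max
}

# The full experiment ---------------------------------------------------------

#' Run the logistic-regression vs z-score comparison experiment
#'
#' End to end, per trisomy condition: simulate training negatives; derive
#' trisomy positives from an equal number of fresh negatives; normalize,
#' remove outliers and train the binary logistic model; build a z-score
#' reference from the training negatives; simulate a held-out negative
#' evaluation pool (reused across upscales, as in a fixed screening cohort);
#' and at every upscale add freshly synthesized positives, score both
#' methods and record confusion counts. For the sex karyotypes: simulate
#' male and female cohorts, fit the two chrY regressions, synthesize the
#' four aneuploidy classes, train the multinomial model and evaluate
#' per-class sensitivity and PPV on held-out samples.
#'
#' @param config An [experiment_config()].
#' @param seed Integer master seed; every stage derives its own stream from
#'   it, so identical seed and config give an identical report.
#' @param aca,sca Set either to `FALSE` to skip that arm.
#' @return An object of class `eval_report`: a list with tibbles `aca`
#'   (columns `method`, `condition`, `upscale`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `ppv`) and `sca` (per-class metrics for the multiclass
#'   model), plus the config.
#' @export
run_comparison_experiment <- function(config = experiment_config(), seed = 1,
                                      aca = TRUE, sca = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  aca_rows <- list()
  sca_tab <- NULL

  if (aca) {
    for (ci in seq_along(config$prevalence)) {
      condition <- names(config$prevalence)[ci]
      target <- condition_target(condition)
      s0 <- derive_seed(seed, 10 * ci)

      n_tr <- config$n_train_per_class
      train_neg <- simulate_negative_cohort(sim_with(config, n_tr),
                                            seed = derive_seed(s0, 1))
      train_neg$sample_id <- paste0("trn_", train_neg$sample_id)
      pos_src <- simulate_negative_cohort(sim_with(config, n_tr),
                                          seed = derive_seed(s0, 2))
      pos_src$sample_id <- paste0("trp_", pos_src$sample_id)
      train_pos <- synthesize_trisomy(pos_src, target)
      train <- normalize_counts(dplyr::bind_rows(train_neg, train_pos),
                                config$baseline)
      train <- remove_outliers(train,
                               features = aca_feature_names(target),
                               k = config$outlier_k)
      model <- train_aca_classifier(train, target, lambda = config$lambda)
      zref <- zscore_reference(
        dplyr::filter(train, .data$label %in% negative_labels()),
        target, threshold = config$z_threshold)

      # Evaluation negatives are outlier-filtered before use, like the
      # training set; simulate a surplus so the pool stays >= n_eval_neg.
      eval_pool <- simulate_negative_cohort(
        sim_with(config, ceiling(1.05 * config$n_eval_neg)),
        seed = derive_seed(s0, 3))
      eval_pool$sample_id <- paste0("ev_", eval_pool$sample_id)
      eval_pool <- normalize_counts(eval_pool, config$baseline) |>
        remove_outliers(features = aca_feature_names(target),
                        k = config$outlier_k)
      eval_pool <- eval_pool[seq_len(min(nrow(eval_pool), config$n_eval_neg)), ]
      # held-out design: no training sample may reappear in evaluation
      stopifnot(length(intersect(train$sample_id, eval_pool$sample_id)) == 0)
      pos_gen <- function(n, gen_seed) {
        src <- simulate_negative_cohort(sim_with(config, n), seed = gen_seed)
        src$sample_id <- paste0("pos_", src$sample_id)
        synthesize_trisomy(src, target)
      }
      for (ui in seq_along(config$upscales)) {
        up <- config$upscales[ui]
        eval_set <- build_prevalence_eval_set(
          eval_pool, pos_gen, prevalence = config$prevalence[[ci]],
          upscale = up, n_neg = config$n_eval_neg,
          seed = derive_seed(s0, 100 + ui))
        eval_norm <- normalize_counts(eval_set, config$baseline)
        truth <- eval_norm$label == condition
        lr <- evaluate_metrics(predict(model, eval_norm)$.pred, truth)
        zs <- evaluate_metrics(zscore_classify(eval_norm, zref)$.pred, truth)
        aca_rows[[length(aca_rows) + 1]] <- dplyr::bind_rows(
          dplyr::bind_cols(tibble(method = "lr", condition = condition,
                                  upscale = up), lr),
          dplyr::bind_cols(tibble(method = "zscore", condition = condition,
                                  upscale = up), zs)
        )
      }
    }
  }

  if (sca) {
    s0 <- derive_seed(seed, 900)
    train <- synthesize_sca_cohort(config, config$sca_train_per_class,
                                   seed = derive_seed(s0, 1))
    train <- remove_outliers(train, features = sca_feature_names(),
                             k = config$outlier_k)
    model <- train_sca_classifier(train, lambda = config$lambda)
    eval_set <- synthesize_sca_cohort(config, config$sca_eval_per_class,
                                      seed = derive_seed(s0, 2))
    pred <- predict(model, eval_set)$.pred
    sca_tab <- evaluate_per_class(pred, eval_set$label)
    sca_tab <- dplyr::bind_cols(tibble(method = "lr"), sca_tab)
  }

  structure(
    list(aca = if (aca) dplyr::bind_rows(aca_rows) else NULL,
         sca = sca_tab, config = config),
    class = "eval_report"
  )
}

# Simulate, synthesize and normalize one balanced six-class SCA cohort.
synthesize_sca_cohort <- function(config, n_per_class, seed) {
  male_cfg <- sim_with(config, n_per_class, male_fraction = 1)
  female_cfg <- sim_with(config, n_per_class, male_fraction = 0)
  neg_xy <- simulate_negative_cohort(male_cfg, seed = derive_seed(seed, 1))
  neg_xy$sample_id <- paste0("c1_", neg_xy$sample_id)
  neg_xx <- simulate_negative_cohort(female_cfg, seed = derive_seed(seed, 2))
  neg_xx$sample_id <- paste0("c2_", neg_xx$sample_id)
  y_mis <- fit_y_misassignment(neg_xx)
  y_cnt <- fit_y_count_model(neg_xy)
  fresh <- function(cfg, k) {
    x <- simulate_negative_cohort(cfg, seed = derive_seed(seed, k))
    x$sample_id <- paste0("c", k, "_", x$sample_id)
    x
  }
  cohort <- dplyr::bind_rows(
    neg_xy, neg_xx,
    synthesize_xo(fresh(male_cfg, 3), y_mis, seed = derive_seed(seed, 13)),
    synthesize_xyy(fresh(male_cfg, 4), y_mis, seed = derive_seed(seed, 14)),
    synthesize_xxx(fresh(female_cfg, 5)),
    synthesize_xxy(fresh(female_cfg, 6), y_cnt, seed = derive_seed(seed, 16))
  )
  normalize_counts(cohort, config$baseline)
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  if (!is.null(x$aca)) {
    cat("ACA (method x condition x upscale):\n")
    print(as.data.frame(x$aca), row.names = FALSE)
  }
  if (!is.null(x$sca)) {
    cat("SCA (per class):\n")
    print(as.data.frame(x$sca), row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Binds the ACA and SCA blocks into one long table (columns absent from a
#' block are `NA`) and writes it as TSV.
#'
#' @param report An `eval_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  tab <- dplyr::bind_rows(
    if (!is.null(report$aca)) dplyr::mutate(report$aca, block = "ACA"),
    if (!is.null(report$sca)) dplyr::mutate(report$sca, block = "SCA")
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Plot an evaluation report
#'
#' Sensitivity and PPV against the prevalence upscale, one panel per trisomy
#' condition and metric, with one line per method. A flat line at 100 means
#' the method is unaffected by the class balance of the evaluation set.
#'
#' @param object An `eval_report` with an ACA block.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$aca)) abort("Report has no ACA block to plot.")
  long <- tidyr::pivot_longer(object$aca, c("sensitivity", "ppv"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$upscale, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = sort(unique(long$upscale))) +
    ggplot2::facet_grid(metric ~ condition) +
    ggplot2::labs(x = "prevalence upscale", y = "percent", colour = NULL) +
    ggplot2::theme_minimal()
}
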