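# Feature construction and classifiers: normalization of per-chromosome
# counts to a fixed read-depth baseline, robust outlier removal, binary
# logistic regression per autosomal trisomy, multinomial logistic regression
# over the six sex-karyotype classes, and the z-score baseline.

#' Normalize chromosome counts to a fixed read-depth baseline
#'
#' Scales every chromosome count by `baseline / TRC` and rounds, so each
#' sample's total read count lands within rounding slack (at most 24 reads,
#' one per chromosome) of the baseline. Classifiers are trained on
#' baseline-normalized counts so they respond to chromosome-share shifts,
#' not sequencing depth.
#'
#' @param samples Cohort tibble.
#' @param baseline Target total read count; default 3,000,000.
#' @return The cohort with rescaled integer counts.
#' @export
normalize_counts <- function(samples, baseline = 3e6) {
  check_cohort(samples)
  trc <- total_read_count(samples)
  if (any(trc == 0)) abort("Cannot normalize a sample with zero total reads.")
  scale <- baseline / trc
  out <- samples
  for (chr in chromosome_names()) {
    out[[chr]] <- round_counts(samples[[chr]] * scale)
  }
  out
}

#' Remove statistical outliers per label group
#'
#' Flags a sample as an outlier when its robust z-score — the absolute
#' deviation from the within-label median, scaled by 1.4826 times the MAD —
#' exceeds `k` on any of the listed features. Features with zero MAD in a
#' group (for example, all-identical counts) contribute no outliers. The
#' rule is deliberately conservative: on a clean unimodal cohort, well under
#' 1\% of samples are removed at the default `k = 4`.
#'
#' @param dataset Cohort tibble with a `label` column; every label group
#'   must contain at least `min_group` samples.
#' @param features Character vector of feature columns to screen; defaults
#'   to all 24 chromosome counts plus `gc` and `ff`.
#' @param k Robust z-score threshold.
#' @param min_group Minimum group size.
#' @return The dataset with outliers removed, order preserved.
#' @export
remove_outliers <- function(dataset, features = NULL, k = 4, min_group = 10) {
  check_cohort(dataset)
  if (!"label" %in% names(dataset)) abort("`dataset` must have a label column.")
  features <- features %||% c(chromosome_names(), "gc", "ff")
  missing_feat <- setdiff(features, names(dataset))
  if (length(missing_feat) > 0) {
    abort(paste0("Unknown feature columns: ", paste(missing_feat, collapse = ", ")))
  }
  sizes <- table(dataset$label)
  if (any(sizes < min_group)) {
    abort(sprintf("Every label group needs at least %d samples.", min_group))
  }
  keep <- rep(TRUE, nrow(dataset))
  for (lab in names(sizes)) {
    idx <- which(dataset$label == lab)
    for (f in features) {
      x <- dataset[[f]][idx]
      m <- median(x)
      s <- mad(x)
      if (s > 0) keep[idx[abs(x - m) / s > k]] <- FALSE
    }
  }
  dataset[keep, , drop = FALSE]
}

# Internal: standardized design matrices -----------------------------------

aca_feature_names <- function(target) c(target, "gc", "ff")

sca_feature_names <- function() c("chrX", "chrY", "gc", "ff")

feature_matrix <- function(samples, features) {
  x <- as.matrix(as.data.frame(samples[features]))
  storage.mode(x) <- "double"
  x
}

standardize <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, sd)
  scale[scale == 0] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# Logistic-regression classifiers ------------------------------------------

#' Train a binary trisomy classifier
#'
#' Fits an L2-regularized (ridge) logistic regression distinguishing a
#' target trisomy from negatives, on three features: the normalized target
#' chromosome count, GC content and fetal fraction. Features are
#' standardized with training-set mean and sd; the regularization is weak
#' (`lambda`) and exists only to stabilize the fit when the classes are
#' (near-)separable. The fit is deterministic for fixed training data.
#'
#' @param train Normalized cohort tibble ([normalize_counts()]) containing
#'   both negative samples and the matching trisomy class.
#' @param target `"chr13"`, `"chr18"` or `"chr21"`.
#' @param lambda Ridge penalty.
#' @return An object of class `aca_classifier`: feature names, scaler
#'   parameters, weights and intercept, the trisomy label, and the
#'   normalization baseline.
#' @export
train_aca_classifier <- function(train, target = c("chr13", "chr18", "chr21"),
                                 lambda = 1e-4) {
  target <- arg_match(target)
  check_cohort(train)
  pos_label <- paste0("T", sub("chr", "", target))
  is_pos <- train$label == pos_label
  is_neg <- train$label %in% negative_labels()
  if (!any(is_pos) || !any(is_neg)) {
    abort(sprintf("Training data must contain both negatives and %s samples.",
                  pos_label))
  }
  train <- train[is_pos | is_neg, , drop = FALSE]
  features <- aca_feature_names(target)
  std <- standardize(feature_matrix(train, features))
  y <- as.integer(train$label == pos_label)
  fit <- glmnet::glmnet(std$x, y, family = "binomial", alpha = 0,
                        lambda = ridge_path(lambda), standardize = FALSE,
                        maxit = 1e6)
  beta <- as.numeric(coef(fit, s = lambda))
  structure(
    list(
      kind = "ACA", target = target, pos_label = pos_label,
      classes = c("negative", pos_label),
      features = features,
      center = std$center, scale = std$scale,
      intercept = beta[1], weights = setNames(beta[-1], features),
      lambda = lambda, baseline = 3e6, n_train = nrow(train),
      version = 1L
    ),
    class = "aca_classifier"
  )
}

ridge_path <- function(lambda) {
  # warm-start the ridge fit from heavy regularization down to the target;
  # cold starts at a near-zero lambda can diverge on separable data
  sort(unique(c(10^seq(2, log10(max(lambda, 1e-8)), length.out = 25), lambda)),
       decreasing = TRUE)
}

#' @exportS3Method base::print
print.aca_classifier <- function(x, ...) {
  cat(sprintf("<aca_classifier> %s vs negative, %d training samples\n",
              x$pos_label, x$n_train))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict with a trisomy classifier
#'
#' @param object An [train_aca_classifier()] model.
#' @param newdata Normalized cohort tibble.
#' @param ... Unused.
#' @return Tibble with `.prob` (probability of the trisomy) and `.pred`
#'   (logical; positive when `.prob > 0.5`).
#' @export
predict.aca_classifier <- function(object, newdata, ...) {
  check_cohort(newdata)
  x <- standardize(feature_matrix(newdata, object$features),
                   object$center, object$scale)$x
  eta <- object$intercept + drop(x %*% object$weights)
  prob <- stats::plogis(eta)
  tibble(.prob = prob, .pred = prob > 0.5)
}

#' Train the six-class sex-karyotype classifier
#'
#' Fits a weakly ridge-regularized multinomial logistic regression over the
#' classes `NEG_XX`, `NEG_XY`, `XO`, `XXX`, `XXY`, `XYY` on four features:
#' the normalized chrX and chrY counts, GC content and fetal fraction. All
#' six classes must be present in the training data; predictions are always
#' one of the six (ties broken by fixed class order).
#'
#' @param train Normalized cohort tibble containing all six classes.
#' @param lambda Ridge penalty.
#' @return An object of class `sca_classifier`.
#' @export
train_sca_classifier <- function(train, lambda = 1e-4) {
  check_cohort(train)
  classes <- sca_classes()
  missing_cls <- setdiff(classes, unique(train$label))
  if (length(missing_cls) > 0) {
    abort(paste0("Training data is missing classes: ",
                 paste(missing_cls, collapse = ", ")))
  }
  train <- train[train$label %in% classes, , drop = FALSE]
  features <- sca_feature_names()
  std <- standardize(feature_matrix(train, features))
  y <- factor(train$label, levels = classes)
  fit <- glmnet::glmnet(std$x, y, family = "multinomial", alpha = 0,
                        lambda = ridge_path(lambda), standardize = FALSE,
                        maxit = 1e6)
  cf <- coef(fit, s = lambda)
  intercepts <- vapply(classes, function(cl) as.numeric(cf[[cl]][1]),
                       numeric(1))
  weights <- vapply(classes, function(cl) as.numeric(cf[[cl]][-1]),
                    numeric(length(features)))
  rownames(weights) <- features
  structure(
    list(
      kind = "SCA", classes = classes, features = features,
      center = std$center, scale = std$scale,
      intercepts = intercepts, weights = weights,
      lambda = lambda, baseline = 3e6, n_train = nrow(train),
      version = 1L
    ),
    class = "sca_classifier"
  )
}

#' @exportS3Method base::print
print.sca_classifier <- function(x, ...) {
  cat(sprintf("<sca_classifier> classes %s, %d training samples\n",
              paste(x$classes, collapse = "/"), x$n_train))
  invisible(x)
}

#' Predict with the sex-karyotype classifier
#'
#' @param object A [train_sca_classifier()] model.
#' @param newdata Normalized cohort tibble.
#' @param ... Unused.
#' @return Tibble with `.pred` (one of the six classes; argmax probability,
#'   ties broken by class order) and one `.prob_<class>` column per class.
#' @export
predict.sca_classifier <- function(object, newdata, ...) {
  check_cohort(newdata)
  x <- standardize(feature_matrix(newdata, object$features),
                   object$center, object$scale)$x
  eta <- sweep(x %*% object$weights, 2, object$intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  prob <- exp(eta) / rowSums(exp(eta))
  pred <- object$classes[max.col(prob, ties.method = "first")]
  out <- tibble(.pred = pred)
  prob <- as_tibble(prob)
  names(prob) <- paste0(".prob_", object$classes)
  dplyr::bind_cols(out, prob)
}

# z-score baseline ---------------------------------------------------------

#' Build a z-score reference for one target chromosome
#'
#' Records the mean and standard deviation of the normalized target
#' chromosome count over a reference set of negative samples. No GC
#' correction is applied; the statistic is the plain normalized count, which
#' is exactly what makes the z score vulnerable to GC-driven count shifts.
#'
#' @param negatives Normalized negative cohort tibble.
#' @param target `"chr13"`, `"chr18"` or `"chr21"`.
#' @param threshold Decision threshold on the z score (default 3).
#' @return An object of class `zscore_reference`.
#' @export
zscore_reference <- function(negatives, target = c("chr13", "chr18", "chr21"),
                             threshold = 3) {
  target <- arg_match(target)
  check_cohort(negatives)
  check_negative(negatives)
  x <- negatives[[target]]
  ref_sd <- sd(x)
  if (!is.finite(ref_sd) || ref_sd <= 0) {
    abort("Reference standard deviation must be positive.")
  }
  structure(
    list(target = target, mean = mean(x), sd = ref_sd,
         threshold = threshold, n_ref = length(x)),
    class = "zscore_reference"
  )
}

#' @exportS3Method base::print
print.zscore_reference <- function(x, ...) {
  cat(sprintf("<zscore_reference> %s: mean %.1f, sd %.1f, threshold %g (n = %d)\n",
              x$target, x$mean, x$sd, x$threshold, x$n_ref))
  invisible(x)
}

#' Classify samples by z score
#'
#' Computes `z = (normalized target count - mean) / sd` against a
#' [zscore_reference()] and calls a sample positive when `z` strictly
#' exceeds the threshold. Samples must be normalized with the same baseline
#' as the reference.
#'
#' @param samples Normalized cohort tibble.
#' @param ref A [zscore_reference()].
#' @return Tibble with `.z` and `.pred` (logical positive call).
#' @export
zscore_classify <- function(samples, ref) {
  stopifnot(inherits(ref, "zscore_reference"))
  check_cohort(samples)
  if (ref$sd <= 0) abort("Reference standard deviation must be positive.")
  z <- (samples[[ref$target]] - ref$mean) / ref$sd
  tibble(.z = z, .pred = z > ref$threshold)
}

# Serialization ------------------------------------------------------------

#' Serialize and restore classifiers
#'
#' Classifiers are written as versioned JSON files carrying feature names,
#' scaler parameters (training mean/sd per feature) and weights, so a model
#' trained in one process can score samples in another with no refitting.
#'
#' @param model An `aca_classifier` or `sca_classifier`.
#' @param path JSON file path.
#' @return `write_classifier()` returns `path` invisibly; `read_classifier()`
#'   the restored model.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, c("aca_classifier", "sca_classifier")))
  payload <- unclass(model)
  payload$class <- class(model)[1]
  if (!is.null(payload$weights) && is.matrix(payload$weights)) {
    payload$weights <- as.data.frame(payload$weights)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$class
  payload$class <- NULL
  if (cls == "sca_classifier") {
    payload$weights <- as.matrix(payload$weights)
    payload$intercepts <- unlist(payload$intercepts)
  } else {
    payload$weights <- unlist(payload$weights)
  }
  payload$center <- unlist(payload$center)
  payload$scale <- unlist(payload$scale)
  structure(payload, class = cls)
}

# Broom-style methods -------------------------------------------------------

#' Tidy a fitted classifier
#'
#' @param x An `aca_classifier` or `sca_classifier`.
#' @param ... Unused.
#' @return `tidy()`: one row per (class,) term with the standardized-scale
#'   weight; `glance()`: a one-row fit summary.
#' @export
tidy.aca_classifier <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$weights)),
         estimate = c(x$intercept, unname(x$weights)))
}

#' @rdname tidy.aca_classifier
#' @export
tidy.sca_classifier <- function(x, ...) {
  out <- purrr::map(x$classes, function(cl) {
    tibble(class = cl,
           term = c("(Intercept)", rownames(x$weights)),
           estimate = c(x$intercepts[[cl]], x$weights[, cl]))
  })
  dplyr::bind_rows(out)
}

#' @rdname tidy.aca_classifier
#' @export
glance.aca_classifier <- function(x, ...) {
  tibble(kind = x$kind, target = x$target, n_train = x$n_train,
         lambda = x$lambda, baseline = x$baseline)
}

#' @rdname tidy.aca_classifier
#' @export
glance.sca_classifier <- function(x, ...) {
  tibble(kind = x$kind, n_classes = length(x$classes), n_train = x$n_train,
         lambda = x$lambda, baseline = x$baseline)
}
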