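# Synthetic positives from synthetic negatives. Trisomies and XXX add half a
# fetal-fraction's worth of target-chromosome reads; the sex-chromosome
# aneuploidies involving chrY go through two regressions fitted on negative
# samples: the misassignment background (chrY reads in female-fetus samples,
# linear in TRC) and the true male chrY count (linear in TRC and FF).
# Residuals of each fit are resampled from a normal distribution with the
# fitted residual mean and sd when synthesizing, so synthetic positives carry
# the same dispersion as the negatives the fit came from.

round_counts <- function(x) {
  # base round() is round-half-to-even, which keeps integer count synthesis
  # deterministic and unbiased
  as.integer(round(x))
}

new_y_model <- function(cls, fit, n_fit) {
  r <- resid(fit)
  structure(
    list(
      beta = coef(fit),
      # noiseless designs are a supported case; silence the perfect-fit note
      se = suppressWarnings(sqrt(diag(stats::vcov(fit)))),
      residual_mean = mean(r),
      residual_sd = if (length(r) > 1) sd(r) else 0,
      n_fit = n_fit,
      df_residual = fit$df.residual
    ),
    class = c(cls, "y_model")
  )
}

#' Fit the Y-chromosome read-misassignment regression
#'
#' Female fetuses carry no Y chromosome, yet a small number of reads is
#' always assigned to chrY by misalignment, and this background grows
#' roughly linearly with the total read count. This fits, on female-fetus
#' negatives only, the ordinary least-squares model
#' \deqn{CyRC = \beta_0 + \beta_1 \cdot TRC + \varepsilon}
#' and records the residual mean and standard deviation for later residual
#' resampling in [synthesize_xo()] and [synthesize_xyy()].
#'
#' @param females Cohort tibble of female-fetus (`XX`) negative samples; at
#'   least 3 rows with non-constant TRC.
#' @return An object of class `y_misassignment_model` with elements `beta`
#'   (intercept and TRC slope), `se`, `residual_mean`, `residual_sd`,
#'   `n_fit`.
#' @seealso [fit_y_count_model()], [tidy.y_model()]
#' @export
fit_y_misassignment <- function(females) {
  check_cohort(females)
  check_sex(females, "XX")
  check_negative(females)
  if (nrow(females) < 3) abort("Need at least 3 female-fetus samples.")
  trc <- total_read_count(females)
  if (sd(trc) == 0) abort("Degenerate design: TRC is constant.")
  fit <- lm(females$chrY ~ trc)
  model <- new_y_model("y_misassignment_model", fit, nrow(females))
  names(model$beta) <- names(model$se) <- c("beta0", "beta1")
  model
}

#' Fit the male Y-chromosome read-count regression
#'
#' On male-fetus negatives, the chrY read count is modelled as linear in
#' both the total read count and the fetal fraction:
#' \deqn{CYRC = \beta_0 + \beta_1 \cdot TRC + \beta_2 \cdot FF + \varepsilon}
#' Because the chrY count is tiny relative to TRC, the TRC and FF of a
#' female-fetus sample can stand in as proxy covariates when predicting the
#' chrY count an XXY fetus would produce ([synthesize_xxy()]).
#'
#' @param males Cohort tibble of male-fetus (`XY`) negative samples; at
#'   least 4 rows with a non-degenerate (TRC, FF) design.
#' @return An object of class `y_count_model` with elements `beta`
#'   (`beta0`, `beta1` for TRC, `beta2` for FF), `se`, `residual_mean`,
#'   `residual_sd`, `n_fit`.
#' @export
fit_y_count_model <- function(males) {
  check_cohort(males)
  check_sex(males, "XY")
  check_negative(males)
  if (nrow(males) < 4) abort("Need at least 4 male-fetus samples.")
  trc <- total_read_count(males)
  ff <- males$ff
  x <- cbind(trc, ff)
  if (qr(cbind(1, x))$rank < 3) {
    abort("Degenerate design: TRC and FF are constant or collinear.")
  }
  fit <- lm(males$chrY ~ trc + ff)
  model <- new_y_model("y_count_model", fit, nrow(males))
  names(model$beta) <- names(model$se) <- c("beta0", "beta1", "beta2")
  model
}

#' @exportS3Method base::print
print.y_model <- function(x, ...) {
  cat(sprintf("<%s> fitted on %d samples\n", class(x)[1], x$n_fit))
  print(round(x$beta, 6))
  cat(sprintf("residual mean %.4g, sd %.4g\n", x$residual_mean,
              x$residual_sd))
  invisible(x)
}

predict_y <- function(model, trc, ff = NULL, resample = TRUE) {
  mu <- if (inherits(model, "y_count_model")) {
    model$beta[["beta0"]] + model$beta[["beta1"]] * trc +
      model$beta[["beta2"]] * ff
  } else {
    model$beta[["beta0"]] + model$beta[["beta1"]] * trc
  }
  if (resample) {
    mu <- mu + rnorm(length(trc), model$residual_mean, model$residual_sd)
  }
  mu
}

# Model serialization -----------------------------------------------------

#' Serialize and restore fitted Y-chromosome regressions
#'
#' Models are written as small JSON key-value files (coefficients, standard
#' errors, residual mean/sd, fit size) so synthesis pipelines can be split
#' across processes.
#'
#' @param model A `y_misassignment_model` or `y_count_model`.
#' @param path JSON file path.
#' @return `write_y_model()` returns `path` invisibly; `read_y_model()`
#'   returns the restored model.
#' @export
write_y_model <- function(model, path) {
  stopifnot(inherits(model, "y_model"))
  payload <- list(
    class = class(model)[1],
    beta = as.list(model$beta),
    se = as.list(model$se),
    residual_mean = model$residual_mean,
    residual_sd = model$residual_sd,
    n_fit = model$n_fit,
    df_residual = model$df_residual
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_y_model
#' @export
read_y_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      beta = unlist(payload$beta),
      se = unlist(payload$se),
      residual_mean = payload$residual_mean,
      residual_sd = payload$residual_sd,
      n_fit = payload$n_fit,
      df_residual = payload$df_residual
    ),
    class = c(payload$class, "y_model")
  )
}

# Synthesis operations ----------------------------------------------------

#' Synthesize autosomal trisomy positives
#'
#' A trisomic fetus carries three copies of the target chromosome instead of
#' two, so the fetal contribution to that chromosome's reads rises by half:
#' \deqn{T_iRC = C_iRC + C_iRC \cdot FF / 2.}
#' Only the target chromosome's count and the label change; FF, GC and every
#' other chromosome are left untouched.
#'
#' @param samples Negative cohort tibble (labels `NEG_XX`/`NEG_XY`).
#' @param target `"chr13"`, `"chr18"` or `"chr21"`.
#' @return The cohort with the target count inflated (rounded half-to-even)
#'   and label set to `T13`/`T18`/`T21`.
#' @export
synthesize_trisomy <- function(samples, target = c("chr13", "chr18", "chr21")) {
  target <- arg_match(target)
  check_cohort(samples)
  check_negative(samples)
  out <- samples
  out[[target]] <- round_counts(samples[[target]] +
                                  samples[[target]] * samples$ff / 2)
  out$label <- paste0("T", sub("chr", "", target))
  out
}

#' Synthesize triple-X (XXX) positives from female-fetus negatives
#'
#' Identical arithmetic to a trisomy, applied to chrX of a female fetus:
#' \deqn{C_{XXX}RC = C_{XX}RC + C_{XX}RC \cdot FF / 2.}
#'
#' @param samples Female-fetus (`XX`) negative cohort tibble.
#' @return The cohort with chrX inflated and label `XXX`.
#' @export
synthesize_xxx <- function(samples) {
  check_cohort(samples)
  check_negative(samples)
  check_sex(samples, "XX")
  out <- samples
  out$chrX <- round_counts(samples$chrX + samples$chrX * samples$ff / 2)
  out$label <- "XXX"
  out
}

#' Synthesize monosomy-X (XO) positives from male-fetus negatives
#'
#' An XO fetus has one X and no Y — the same X dosage as a male fetus, but
#' with the true fetal chrY reads removed. Algebraically the male sample's
#' chrY count is replaced by a misassignment background predicted from the
#' female-fitted regression, with a residual resampled from its fitted
#' normal distribution:
#' \deqn{chrY := \max(0, round(\beta_0 + \beta_1 TRC + \varepsilon)).}
#' chrX and all autosomes are unchanged.
#'
#' @param samples Male-fetus (`XY`) negative cohort tibble.
#' @param model A [fit_y_misassignment()] model.
#' @param seed Integer seed for residual sampling.
#' @return The cohort with chrY replaced by background and label `XO`.
#' @export
synthesize_xo <- function(samples, model, seed = NULL) {
  check_cohort(samples)
  check_negative(samples)
  check_sex(samples, "XY")
  stopifnot(inherits(model, "y_misassignment_model"))
  local_seed(seed)
  trc <- total_read_count(samples)
  out <- samples
  out$chrY <- pmax(0L, round_counts(predict_y(model, trc)))
  out$label <- "XO"
  out
}

#' Synthesize XYY positives from male-fetus negatives
#'
#' An XYY fetus carries two Y chromosomes, so the true fetal chrY signal —
#' the observed male chrY count minus the misassignment background —
#' doubles:
#' \deqn{chrY := round(2 \cdot C_YRC - CyRC)}
#' where the background `CyRC` is sampled from the female-fitted regression
#' and clipped to `[0, C_YRC]` (the background can be neither negative nor
#' larger than the observed count). chrX and all autosomes are unchanged.
#'
#' @inheritParams synthesize_xo
#' @return The cohort with chrY doubled net of background and label `XYY`.
#' @export
synthesize_xyy <- function(samples, model, seed = NULL) {
  check_cohort(samples)
  check_negative(samples)
  check_sex(samples, "XY")
  stopifnot(inherits(model, "y_misassignment_model"))
  local_seed(seed)
  trc <- total_read_count(samples)
  cy <- pmin(pmax(predict_y(model, trc), 0), samples$chrY)
  out <- samples
  out$chrY <- round_counts(2 * samples$chrY - cy)
  out$label <- "XYY"
  out
}

#' Synthesize Klinefelter (XXY) positives from female-fetus negatives
#'
#' An XXY fetus has two X chromosomes — the same X dosage as a female fetus
#' — plus one Y. The chrY count is predicted from the male-fitted regression
#' using the female sample's TRC and FF as proxy covariates (valid because
#' chrY reads are a negligible share of TRC), with a resampled residual:
#' \deqn{chrY := \max(0, round(\beta_0 + \beta_1 TRC + \beta_2 FF +
#'   \varepsilon)).}
#' chrX is left at the female value.
#'
#' @param samples Female-fetus (`XX`) negative cohort tibble.
#' @param model A [fit_y_count_model()] model.
#' @param seed Integer seed for residual sampling.
#' @return The cohort with a male-like chrY count added and label `XXY`.
#' @export
synthesize_xxy <- function(samples, model, seed = NULL) {
  check_cohort(samples)
  check_negative(samples)
  check_sex(samples, "XX")
  stopifnot(inherits(model, "y_count_model"))
  local_seed(seed)
  trc <- total_read_count(samples)
  out <- samples
  out$chrY <- pmax(0L, round_counts(predict_y(model, trc, samples$ff)))
  out$label <- "XXY"
  out
}

# Broom-style methods ------------------------------------------------------

#' Tidy a fitted Y-chromosome regression
#'
#' @param x A `y_misassignment_model` or `y_count_model`.
#' @param ... Unused.
#' @return `tidy()` gives one row per coefficient with `term`, `estimate`,
#'   `std.error`; `glance()` gives a one-row summary with `n_fit`,
#'   `residual_mean`, `residual_sd`.
#' @export
tidy.y_model <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(x$se))
}

#' @rdname tidy.y_model
#' @export
glance.y_model <- function(x, ...) {
  tibble(n_fit = x$n_fit, residual_mean = x$residual_mean,
         residual_sd = x$residual_sd, df_residual = x$df_residual)
}
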