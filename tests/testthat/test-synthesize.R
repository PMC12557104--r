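# Positive synthesis: read-count equations, chrY regressions, residual
# resampling, and the preservation invariants (only the documented
# chromosome, the label and TRC may change).

# Noise-free female cohort with chrY = 50 + 2e-4 * TRC exactly: chrY is
# chosen first and chr1 back-solved so the linear relation holds at integer
# counts.
exact_female_cohort <- function(y = c(550L, 650L, 750L, 850L, 950L)) {
  n <- length(y)
  trc <- 5000 * (y - 50)
  co <- toy_cohort(n, fetal_sex = rep("XX", n), ff = rep(0.1, n))
  co$chrY <- y
  co$chr1 <- as.integer(trc - (total_read_count(co) - co$chr1))
  stopifnot(all(total_read_count(co) == trc))
  co
}

test_that("trisomy synthesis implements the target-chromosome equation", {
  co <- toy_cohort(1, fetal_sex = "XX", ff = 0.10)
  out <- synthesize_trisomy(co, "chr21")
  expect_identical(out$chr21, 105000L)  # 100000 + 100000 * 0.10 / 2
  expect_identical(out$label, "T21")
  for (chr in setdiff(chromosome_names(), "chr21")) {
    expect_identical(out[[chr]], co[[chr]])
  }
  expect_identical(out$ff, co$ff)
  expect_identical(out$gc, co$gc)

  # zero fetal fraction leaves counts untouched
  co0 <- toy_cohort(1, ff = 0)
  out0 <- synthesize_trisomy(co0, "chr13")
  expect_identical(out0$chr13, co0$chr13)
})

test_that("XXX synthesis inflates chrX of female fetuses only", {
  co <- toy_cohort(1, fetal_sex = "XX", ff = 0.08)
  out <- synthesize_xxx(co)
  expect_identical(out$chrX, 208000L)  # 200000 + 200000 * 0.08 / 2
  expect_identical(out$label, "XXX")
  expect_identical(out$chr1, co$chr1)
  expect_error(synthesize_xxx(toy_cohort(1, fetal_sex = "XY")), "XX")
})

test_that("synthesis requires negative-labelled input of the right sex", {
  pos <- synthesize_trisomy(toy_cohort(2), "chr21")
  expect_error(synthesize_trisomy(pos, "chr21"), "negative label")
  expect_error(synthesize_xo(toy_cohort(1, fetal_sex = "XX"),
                             fit_y_misassignment(exact_female_cohort())),
               "XY")
  expect_error(synthesize_xxy(toy_cohort(1, fetal_sex = "XY"),
                              structure(list(), class = c("y_count_model",
                                                          "y_model"))),
               "XX")
})

test_that("equation outputs match an independently coded arithmetic oracle", {
  withr::with_seed(42, {
    n <- 1000
    co <- toy_cohort(n,
                     fetal_sex = sample(c("XX", "XY"), n, replace = TRUE),
                     ff = runif(n, 0.04, 0.3),
                     gc = runif(n, 0.395, 0.43))
    for (chr in chromosome_names()) {
      co[[chr]] <- sample.int(200000L, n)
    }
    co$label <- ifelse(co$fetal_sex == "XY", "NEG_XY", "NEG_XX")

    # trisomy / XXX oracle: independent arithmetic, scalar loop
    for (target in c("chr13", "chr18", "chr21")) {
      got <- synthesize_trisomy(co, target)[[target]]
      want <- vapply(seq_len(n), function(i) {
        c0 <- co[[target]][i]
        as.integer(round(c0 * (1 + co$ff[i] / 2)))
      }, integer(1))
      expect_identical(got, want)
    }
    f <- co[co$fetal_sex == "XX", ]
    expect_identical(
      synthesize_xxx(f)$chrX,
      vapply(seq_len(nrow(f)), function(i) {
        as.integer(round(f$chrX[i] * (1 + f$ff[i] / 2)))
      }, integer(1))
    )

    # XO / XYY / XXY with a zero-noise model: closed-form oracle
    mis <- fit_y_misassignment(exact_female_cohort())
    expect_equal(mis$residual_sd, 0, tolerance = 1e-8)
    m <- co[co$fetal_sex == "XY", ]
    trc_m <- rowSums(as.matrix(m[chromosome_names()]))
    xo <- synthesize_xo(m, mis, seed = 1)
    expect_identical(
      xo$chrY,
      vapply(seq_len(nrow(m)), function(i) {
        max(0L, as.integer(round(50 + 2e-4 * trc_m[i])))
      }, integer(1))
    )
    expect_identical(xo$chrX, m$chrX)

    xyy <- synthesize_xyy(m, mis, seed = 2)
    expect_identical(
      xyy$chrY,
      vapply(seq_len(nrow(m)), function(i) {
        cy <- min(max(50 + 2e-4 * trc_m[i], 0), m$chrY[i])
        as.integer(round(2 * m$chrY[i] - cy))
      }, integer(1))
    )
    expect_identical(xyy$chrX, m$chrX)

    # plant chrY = 100 + 1e-4 * TRC + 50000 * ff self-consistently (chrY is
    # itself part of TRC), then expect near-exact coefficient recovery
    males_fit <- m
    males_fit$chrY <- 0L
    s <- rowSums(as.matrix(males_fit[chromosome_names()]))
    males_fit$chrY <- as.integer(round(
      (100 + 1e-4 * s + 50000 * m$ff) / (1 - 1e-4)))
    ycm <- fit_y_count_model(males_fit)
    expect_equal(unname(ycm$beta), c(100, 1e-4, 50000), tolerance = 1e-2)
    expect_lt(ycm$residual_sd, 1)

    # XXY oracle with an exactly specified zero-noise model
    exact_ycm <- structure(
      list(beta = c(beta0 = 100, beta1 = 1e-4, beta2 = 50000),
           se = c(beta0 = 0, beta1 = 0, beta2 = 0),
           residual_mean = 0, residual_sd = 0, n_fit = 0L,
           df_residual = 0L),
      class = c("y_count_model", "y_model"))
    trc_f <- rowSums(as.matrix(f[chromosome_names()]))
    xxy <- synthesize_xxy(f, exact_ycm, seed = 3)
    expect_identical(
      xxy$chrY,
      vapply(seq_len(nrow(f)), function(i) {
        max(0L, as.integer(round(100 + 1e-4 * trc_f[i] + 50000 * f$ff[i])))
      }, integer(1))
    )
    expect_identical(xxy$chrX, f$chrX)
  })
})

test_that("XYY arithmetic and clipping follow the stated rules", {
  m <- toy_cohort(1, fetal_sex = "XY")   # chrY = 9000
  # constant background 500 reads: 2 * 9000 - 500 = 17500
  flat <- fit_y_misassignment(local({
    co <- exact_female_cohort()
    co$chrY <- 500L
    co
  }))
  expect_equal(unname(flat$beta), c(500, 0), tolerance = 1e-9)
  expect_identical(synthesize_xyy(m, flat, seed = 1)$chrY, 17500L)

  # background >= observed chrY: all observed Y is misassignment, count
  # unchanged
  big <- flat; big$beta[["beta0"]] <- 20000
  expect_identical(synthesize_xyy(m, big, seed = 1)$chrY, m$chrY)

  # zero-background model drives XO chrY to zero
  zero <- flat; zero$beta[["beta0"]] <- 0
  expect_identical(synthesize_xo(m, zero, seed = 1)$chrY, 0L)
})

test_that("noise-free regressions recover planted coefficients exactly", {
  mis <- fit_y_misassignment(exact_female_cohort())
  expect_equal(unname(mis$beta), c(50, 2e-4), tolerance = 1e-9)
  expect_equal(mis$residual_sd, 0, tolerance = 1e-8)
  expect_error(fit_y_misassignment(exact_female_cohort(rep(550L, 5))),
               "constant")
})

test_that("noisy regressions recover parameters within their 95% CIs", {
  cfg <- small_sim_config(n = 200, male_fraction = 0,
                          y_misassign_slope = 2e-4, y_misassign_sd = 10)
  co <- simulate_negative_cohort(cfg, seed = 31)
  mis <- fit_y_misassignment(co)
  expect_lt(abs(mis$beta[["beta1"]] - 2e-4), 1.96 * mis$se[["beta1"]])
  # residual sd concentrates near the generating value (rounding of counts
  # adds a little variance on top of the planted sd)
  expect_lt(abs(mis$residual_sd - 10) / 10, 0.3)

  males <- simulate_negative_cohort(small_sim_config(n = 200,
                                                     male_fraction = 1),
                                    seed = 32)
  ycm <- fit_y_count_model(males)
  # the generator's true FF coefficient is the fetal chrY genome share times
  # the mean TRC; check the fit brackets it
  expect_gt(ycm$beta[["beta2"]], 0)
  expect_lt(abs(ycm$beta[["beta2"]] - 0.00993 * 3.3e6),
            3 * ycm$se[["beta2"]])
})

test_that("adding FF to the male chrY model never hurts the fit", {
  males <- simulate_negative_cohort(small_sim_config(n = 150,
                                                     male_fraction = 1),
                                    seed = 33)
  trc <- total_read_count(males)
  full <- lm(males$chrY ~ trc + males$ff)
  reduced <- lm(males$chrY ~ trc)
  expect_lte(sum(resid(full)^2), sum(resid(reduced)^2))
})

test_that("trisomy target counts increase strictly with fetal fraction", {
  ffs <- seq(0.04, 0.28, by = 0.04)
  co <- toy_cohort(length(ffs), fetal_sex = rep("XX", length(ffs)), ff = ffs)
  out <- synthesize_trisomy(co, "chr18")
  expect_true(all(diff(out$chr18) > 0))
})

test_that("XO synthesis reproduces the female misassignment distribution", {
  females <- simulate_negative_cohort(
    small_sim_config(n = 1000, male_fraction = 0), seed = 41)
  males <- simulate_negative_cohort(
    small_sim_config(n = 1000, male_fraction = 1), seed = 42)
  mis <- fit_y_misassignment(females)
  xo <- synthesize_xo(males, mis, seed = 43)
  refit <- lm(xo$chrY ~ total_read_count(xo))
  expect_lt(abs(coef(refit)[2] - mis$beta[["beta1"]]),
            3 * summary(refit)$coefficients[2, 2])
  expect_lt(abs(sd(resid(refit)) - mis$residual_sd) / mis$residual_sd, 0.25)
})

test_that("residual sampling is seed-deterministic", {
  males <- simulate_negative_cohort(small_sim_config(n = 50,
                                                     male_fraction = 1),
                                    seed = 51)
  mis <- fit_y_misassignment(
    simulate_negative_cohort(small_sim_config(n = 50, male_fraction = 0),
                             seed = 52))
  expect_identical(synthesize_xo(males, mis, seed = 7),
                   synthesize_xo(males, mis, seed = 7))
  expect_false(identical(synthesize_xo(males, mis, seed = 7)$chrY,
                         synthesize_xo(males, mis, seed = 8)$chrY))
})

test_that("fitted chrY models round-trip through JSON", {
  mis <- fit_y_misassignment(exact_female_cohort())
  path <- withr::local_tempfile(fileext = ".json")
  write_y_model(mis, path)
  back <- read_y_model(path)
  expect_s3_class(back, "y_misassignment_model")
  expect_equal(back$beta, mis$beta)
  expect_equal(back$residual_sd, mis$residual_sd)
  expect_equal(tidy(back), tidy(mis))
})
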