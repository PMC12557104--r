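# Normalization, outlier removal, the two logistic classifiers and the
# z-score baseline.

test_that("normalization scales counts to the baseline within rounding slack", {
  co <- toy_cohort(1)  # TRC = 2,409,000 (XX row)
  norm <- normalize_counts(co)
  expect_lte(abs(total_read_count(norm) - 3e6), 24)

  # a sample already at baseline is untouched
  at_base <- co
  for (chr in chromosome_names()) at_base[[chr]] <- 125000L
  expect_identical(normalize_counts(at_base)[chromosome_names()],
                   at_base[chromosome_names()])

  # doubling the depth halves every count (to rounding)
  double <- at_base
  for (chr in chromosome_names()) double[[chr]] <- 250000L
  halved <- normalize_counts(double)
  expect_true(all(abs(as.numeric(halved[1, chromosome_names()]) - 125000) <= 1))

  # chromosome proportions preserved to 1/baseline
  p_before <- as.numeric(co[1, chromosome_names()]) / total_read_count(co)
  p_after <- as.numeric(norm[1, chromosome_names()]) / total_read_count(norm)
  expect_true(all(abs(p_before - p_after) <= 1 / 3e6 + 1e-9))

  zero <- co
  for (chr in chromosome_names()) zero[[chr]] <- 0L
  expect_error(normalize_counts(zero), "zero total reads")
})

test_that("normalization is idempotent at the baseline", {
  co <- simulate_negative_cohort(small_sim_config(n = 20), seed = 1)
  once <- normalize_counts(co)
  twice <- normalize_counts(once)
  for (chr in chromosome_names()) {
    expect_true(all(abs(twice[[chr]] - once[[chr]]) <= 1))
  }
})

test_that("outlier removal flags planted outliers and nothing else", {
  co <- simulate_negative_cohort(small_sim_config(n = 300), seed = 2)
  norm <- normalize_counts(co)
  planted <- norm
  med <- median(planted$chr21)
  s <- mad(planted$chr21)
  planted$chr21[7] <- as.integer(med + 10 * s)
  kept <- remove_outliers(planted, features = c("chr21"))
  expect_false(planted$sample_id[7] %in% kept$sample_id)
  expect_identical(nrow(kept), nrow(planted) - 1L)

  # all-identical feature: zero dispersion means no outliers
  flat <- planted
  flat$chr21 <- 100000L
  expect_identical(nrow(remove_outliers(flat, features = c("chr21"))),
                   nrow(flat))
})

test_that("outlier removal is conservative on clean cohorts", {
  co <- simulate_negative_cohort(small_sim_config(n = 10000), seed = 3)
  norm <- normalize_counts(co)
  kept <- remove_outliers(norm, features = c("chr13", "chr18", "chr21",
                                             "gc", "ff"))
  expect_gt(nrow(kept) / nrow(norm), 0.99)
  expect_error(remove_outliers(norm[1:5, ]), "at least 10")
})

make_aca_train <- function(n = 2000, seed = 4) {
  neg <- simulate_negative_cohort(small_sim_config(n = n), seed = seed)
  src <- simulate_negative_cohort(small_sim_config(n = n), seed = seed + 1)
  src$sample_id <- paste0("p_", src$sample_id)
  normalize_counts(dplyr::bind_rows(neg, synthesize_trisomy(src, "chr21")))
}

test_that("the binary trisomy classifier learns the expected geometry", {
  train <- make_aca_train()
  model <- train_aca_classifier(train, "chr21")
  expect_gt(model$weights[["chr21"]], 0)

  # probability is nondecreasing in the target count, gc and ff held fixed
  grid <- train[rep(1, 50), ]
  grid$chr21 <- as.integer(seq(40000, 60000, length.out = 50))
  probs <- predict(model, grid)$.prob
  expect_true(all(diff(probs) >= 0))

  # training on one class only is an error
  expect_error(
    train_aca_classifier(dplyr::filter(train, label != "T21"), "chr21"),
    "both negatives")

  # retraining on the same data reproduces identical weights
  again <- train_aca_classifier(train, "chr21")
  expect_identical(model$weights, again$weights)
})

test_that("the multiclass model is closed over the six karyotype classes", {
  # well-separated toy clusters, one per class
  mk <- function(label, x, y, n = 40) {
    co <- toy_cohort(n, fetal_sex = rep("XX", n), ff = seq(0.05, 0.2,
                                                           length.out = n))
    co$chrX <- as.integer(x + seq_len(n))
    co$chrY <- as.integer(y + seq_len(n))
    co$label <- label
    co
  }
  train <- dplyr::bind_rows(
    mk("NEG_XX", 150000, 500), mk("NEG_XY", 145000, 3000),
    mk("XO", 145000, 500), mk("XXX", 160000, 500),
    mk("XXY", 150000, 3000), mk("XYY", 145000, 6000)
  )
  model <- train_sca_classifier(train)
  pred <- predict(model, train)
  expect_true(all(pred$.pred %in% c("NEG_XX", "NEG_XY", "XO", "XXX",
                                    "XXY", "XYY")))
  expect_identical(pred$.pred, train$label)

  expect_error(train_sca_classifier(dplyr::filter(train, label != "XO")),
               "missing classes")
})

test_that("z-score classification thresholds strictly at z > 3", {
  neg <- simulate_negative_cohort(small_sim_config(n = 500), seed = 6)
  norm <- normalize_counts(neg)
  ref <- zscore_reference(norm, "chr21")
  probe <- norm[rep(1, 3), ]
  probe$chr21 <- as.integer(round(ref$mean + c(0, 2.99, 3.01) * ref$sd))
  res <- zscore_classify(probe, ref)
  expect_equal(res$.z[1], 0, tolerance = 1e-2)
  expect_identical(res$.pred, c(FALSE, FALSE, TRUE))

  flat <- norm
  flat$chr21 <- 100000L
  expect_error(zscore_reference(flat, "chr21"), "positive")
})

test_that("LR and z-score agree on extreme samples", {
  train <- make_aca_train()
  model <- train_aca_classifier(train, "chr21")
  negs <- dplyr::filter(train, label != "T21")
  ref <- zscore_reference(negs, "chr21")
  extreme <- negs[1:5, ]
  extreme$chr21 <- as.integer(round(ref$mean + 12 * ref$sd))
  expect_true(all(predict(model, extreme)$.pred))
  expect_true(all(zscore_classify(extreme, ref)$.pred))
})

test_that("classifiers round-trip through JSON with identical predictions", {
  train <- make_aca_train(n = 800, seed = 8)
  model <- train_aca_classifier(train, "chr21")
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(predict(back, train), predict(model, train))

  sca_train <- niptsynth:::synthesize_sca_cohort(
    experiment_config(sca_train_per_class = 300, sca_eval_per_class = 100),
    300, seed = 9)
  sca <- train_sca_classifier(sca_train)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_classifier(sca, path2)
  back2 <- read_classifier(path2)
  expect_equal(predict(back2, sca_train), predict(sca, sca_train))
})

test_that("tidy and glance summarise fitted classifiers", {
  train <- make_aca_train(n = 600, seed = 10)
  model <- train_aca_classifier(train, "chr21")
  td <- tidy(model)
  expect_identical(td$term, c("(Intercept)", "chr21", "gc", "ff"))
  gl <- glance(model)
  expect_identical(gl$target, "chr21")
})
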