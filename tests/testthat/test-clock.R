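test_that("splits are stratified, disjoint, covering and deterministic", {
  gen <- generate_dataset(synthetic_config(seed = 2))
  ds <- gen$dataset
  sp <- split_cohort(ds, "control", split_spec(2 / 3, seed = 9))
  ids_tr <- sp$train$samples$sample_id
  ids_te <- sp$test$samples$sample_id
  ctrl_ids <- ds$samples$sample_id[ds$samples$group == "control"]
  expect_length(intersect(ids_tr, ids_te), 0)
  expect_setequal(c(ids_tr, ids_te), ctrl_ids)
  # per-age rounding toward training: ceiling(2/3 * n)
  for (a in c(30, 60, 90, 120, 150)) {
    n_a <- sum(ds$samples$group == "control" & ds$samples$age_days == a)
    expect_equal(sum(sp$train$samples$age_days == a), ceiling(2 / 3 * n_a))
  }
  sp2 <- split_cohort(ds, "control", split_spec(2 / 3, seed = 9))
  expect_identical(sp2$train$samples$sample_id, ids_tr)

  # exact division at fraction 0.5
  coh <- make_cohort(n_per_age = 4, ages = c(30, 60), seed = 4)
  h <- split_cohort(coh, "control", split_spec(0.5, seed = 1))
  expect_equal(sum(h$train$samples$age_days == 30), 2)
  expect_equal(sum(h$test$samples$age_days == 30), 2)
})

test_that("an age stratum with one sample goes wholly to training, with a warning", {
  x <- matrix(runif(7 * 3, 50, 60), 7, 3)
  meta <- data.frame(sample_id = paste0("s", 1:7), group = "control",
                     age_days = c(30, 30, 30, 60, 60, 60, 90))
  ds <- proteomic_dataset(x, meta)
  expect_warning(sp <- split_cohort(ds, "control", split_spec(0.5, seed = 2)),
                 "stratum 90")
  expect_true("s7" %in% sp$train$samples$sample_id)
})

test_that("gamma1 = 0 reproduces the ridge closed form on standardized features", {
  set.seed(11)
  n <- 8; p <- 3
  X <- matrix(runif(n * p, 40, 80), n, p)
  ages <- c(31, 45, 58, 77, 92, 110, 128, 143)
  ds <- proteomic_dataset(X, data.frame(sample_id = paste0("s", 1:n),
                                        group = "control", age_days = ages))
  g2 <- 3.7
  m <- fit_clock(ds, gamma1_grid = 0, gamma2_grid = g2, cv_folds = 5, seed = 1)
  Xs <- standardize_like_fit(X)
  beta_oracle <- solve(crossprod(Xs) + g2 * diag(p),
                       crossprod(Xs, ages - mean(ages)))
  expect_lt(max(abs(unname(m$beta) - as.numeric(beta_oracle))), 1e-6)
  expect_equal(m$intercept, mean(ages), tolerance = 1e-8)
})

test_that("gamma2 = 0 soft-thresholds least squares on an orthonormal design", {
  set.seed(12)
  n <- 12; p <- 4
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M))
  X <- Q * sqrt(n - 1) + 10  # column shifts vanish under centering
  ages <- c(33, 41, 52, 60, 74, 83, 95, 104, 118, 127, 139, 148)
  ds <- proteomic_dataset(X, data.frame(sample_id = paste0("s", 1:n),
                                        group = "control", age_days = ages))
  g1 <- 40
  m <- fit_clock(ds, gamma1_grid = g1, gamma2_grid = 0, cv_folds = 4, seed = 1)
  Xs <- standardize_like_fit(X)          # equals Q * sqrt(n-1); X's Xs = (n-1) I
  cc <- n - 1
  b_ls <- crossprod(Xs, ages - mean(ages)) / cc
  beta_oracle <- sign(b_ls) * pmax(abs(b_ls) - g1 / (2 * cc), 0)
  expect_lt(max(abs(unname(m$beta) - as.numeric(beta_oracle))), 1e-6)
})

test_that("a noiseless cohort is fitted perfectly, selecting clock features", {
  cfg <- synthetic_config(n_features = 30, n_shared_clock_features = 10,
                          n_divergent_clock_features = 0, noise_sd = 1e-6,
                          seed = 8)
  gen <- generate_dataset(cfg)
  train <- subset_group(gen$dataset, "control")
  m <- fit_clock(train, gamma1_grid = c(0.01, 0.1), gamma2_grid = 0.01,
                 cv_folds = 3, seed = 2)
  expect_gt(m$training_r2, 1 - 1e-6)
  # substantive weight sits only on the true clock features (tiny numerical
  # residues on noise features are below the solver tolerance)
  big <- names(m$beta)[abs(m$beta) > 1e-4 * max(abs(m$beta))]
  expect_true(all(big %in% gen$truth$shared_features))
})

test_that("predictions are internally consistent with the stored model", {
  coh <- make_cohort(seed = 21)
  m <- fit_clock(coh, gamma1_grid = c(1, 10), gamma2_grid = 1,
                 cv_folds = 3, seed = 5)
  pr <- predict_ages(m, coh)
  expect_equal(r_squared(pr), m$training_r2)
  expect_equal(pr$residual, pr$predicted_age - pr$actual_age)

  # all-zero coefficients predict the intercept everywhere
  m0 <- m
  m0$beta[] <- 0
  pr0 <- predict_ages(m0, coh)
  expect_true(all(pr0$predicted_age == m0$intercept))

  # a missing model feature is a named validation error
  sub <- coh
  sub$intensities <- sub$intensities[, -1]
  sub$feature_ids <- sub$feature_ids[-1]
  expect_error(predict_ages(m, sub), m$feature_ids[1])
})

test_that("r_squared is Pearson-squared with its documented edge cases", {
  pr <- function(a, p) data.frame(actual_age = a, predicted_age = p)
  expect_equal(r_squared(pr(c(30, 60, 90), c(30, 60, 90))), 1)
  expect_equal(r_squared(pr(c(30, 60, 90), 2 * c(30, 60, 90) + 7)), 1)
  # hand-computed: Pearson correlation 0.5, squared
  expect_equal(r_squared(pr(c(30, 60, 90), c(30, 90, 60))), 0.25)
  expect_warning(r0 <- r_squared(pr(c(30, 60, 90), c(50, 50, 50))), "constant")
  expect_equal(r0, 0)
  expect_error(r_squared(pr(c(60, 60, 60), c(30, 60, 90))), "actual ages equal")
  expect_error(r_squared(pr(c(30, 60), c(30, 60))), "at least 3")
  # coefficient-of-determination variant can fall below zero under miscalibration
  expect_lt(r_squared(pr(c(30, 60, 90), c(90, 120, 30)), method = "cod"), 0)
})

test_that("the fitted loss beats the null and least-squares reference points", {
  set.seed(31)
  n <- 20; p <- 5
  X <- matrix(runif(n * p, 10, 50), n, p)
  ages <- rep(c(30, 60, 90, 120), each = 5)
  ds <- proteomic_dataset(X, data.frame(sample_id = paste0("s", 1:n),
                                        group = "control", age_days = ages))
  g1 <- 15; g2 <- 2
  m <- fit_clock(ds, gamma1_grid = g1, gamma2_grid = g2, cv_folds = 4, seed = 1)
  Xs <- standardize_like_fit(X)
  loss_fit <- en_loss(unname(m$beta), m$intercept, Xs, ages, g1, g2)
  loss_null <- en_loss(rep(0, p), mean(ages), Xs, ages, g1, g2)
  b_ols <- solve(crossprod(Xs), crossprod(Xs, ages - mean(ages)))
  loss_ols <- en_loss(as.numeric(b_ols), mean(ages), Xs, ages, g1, g2)
  expect_lte(loss_fit, loss_null + 1e-8)
  expect_lte(loss_fit, loss_ols + 1e-8)
})

test_that("sparsity is non-increasing along a gamma1 ladder", {
  coh <- make_cohort(n_per_age = 5, n_features = 20, n_clock = 8, seed = 13)
  ladder <- c(0.5, 5, 50, 500, 5000)
  nnz <- vapply(ladder, function(g1) {
    # heavy penalties can zero every coefficient (constant-prediction warning)
    m <- suppressWarnings(fit_clock(coh, gamma1_grid = g1, gamma2_grid = 0.1,
                                    cv_folds = 3, seed = 1))
    sum(m$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("constant features are dropped with a warning and the fit proceeds", {
  coh <- make_cohort(seed = 17)
  coh$intensities[, 2] <- 42
  expect_warning(m <- fit_clock(coh, gamma1_grid = 1, gamma2_grid = 0.1,
                                cv_folds = 3, seed = 1),
                 "constant feature")
  expect_false(coh$feature_ids[2] %in% m$feature_ids)
  expect_s3_class(predict_ages(m, coh), "data.frame")
})

test_that("model files round-trip exactly", {
  coh <- make_cohort(seed = 19)
  m <- fit_clock(coh, gamma1_grid = c(1, 10), gamma2_grid = c(0, 1),
                 cv_folds = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_identical(unname(back$beta), unname(m$beta))
  expect_identical(back$intercept, m$intercept)
  expect_identical(unname(back$center), unname(m$center))
  expect_identical(unname(back$scale), unname(m$scale))
  expect_identical(back$gamma1, m$gamma1)
  expect_identical(back$label, m$label)
  expect_identical(predict_ages(back, coh), predict_ages(m, coh))
})

test_that("degenerate cohorts are rejected", {
  x <- matrix(runif(12, 1, 2), 4, 3)
  meta <- data.frame(sample_id = paste0("s", 1:4), group = "control",
                     age_days = rep(60, 4))
  ds <- proteomic_dataset(x, meta)
  expect_error(fit_clock(ds, gamma1_grid = 1, gamma2_grid = 0, cv_folds = 2),
               "single sampling age")
  expect_error(fit_clock(make_tiny_dataset(), gamma1_grid = numeric(),
                         gamma2_grid = 1, cv_folds = 2), "nonempty")
})
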