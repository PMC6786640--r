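test_that("clock distance is the absolute age residual", {
  coh <- make_cohort(seed = 23)
  m <- fit_clock(coh, gamma1_grid = 1, gamma2_grid = 0.1, cv_folds = 3, seed = 1)
  pr <- predict_ages(m, coh)
  d <- clock_distance(m, coh)
  expect_equal(unname(d), abs(pr$residual))
  expect_true(all(d >= 0))
  # signed and squared variants
  expect_equal(unname(clock_distance(m, coh, "signed")), pr$residual)
  expect_equal(unname(clock_distance(m, coh, "squared")), pr$residual^2)

  # a sample predicted exactly at its age has distance 0; arithmetic case
  m0 <- m
  m0$beta[] <- 0
  m0$intercept <- 75
  one <- coh[which(coh$samples$age_days == 60)[1]]
  expect_equal(unname(clock_distance(m0, one)), 15)
  m0$intercept <- 60
  expect_equal(unname(clock_distance(m0, one)), 0)
})

test_that("distances ignore features the model does not use", {
  coh <- make_cohort(seed = 24)
  m <- fit_clock(coh, gamma1_grid = 1, gamma2_grid = 0.1, cv_folds = 3, seed = 1)
  wide <- coh
  wide$intensities <- cbind(coh$intensities, extra = 7)
  wide$feature_ids <- c(coh$feature_ids, "extra")
  expect_equal(clock_distance(m, wide), clock_distance(m, coh))
})

test_that("delta_pr is the distance difference and is antisymmetric in the clocks", {
  gen <- generate_dataset(synthetic_config(n_features = 40, seed = 31,
                                           n_shared_clock_features = 3,
                                           n_divergent_clock_features = 12))
  ds <- gen$dataset
  mn <- fit_clock(subset_group(ds, "control"), gamma1_grid = c(1, 10),
                  gamma2_grid = 1, cv_folds = 3, seed = 1, label = "normal_clock")
  mt <- fit_clock(subset_group(ds, "exposed"), gamma1_grid = c(1, 10),
                  gamma2_grid = 1, cv_folds = 3, seed = 2, label = "tumor_clock")
  pts <- deviation_points(ds, mn, mt)
  expect_equal(pts$delta_pr, pts$d_normal - pts$d_tumor)
  swapped <- deviation_points(ds, mt, mn)
  expect_equal(swapped$delta_pr, -pts$delta_pr)
  # equidistant sample scores zero: same model on both axes
  same <- deviation_points(ds, mn, mn)
  expect_true(all(same$delta_pr == 0))
})

test_that("rank AUC matches its documented conventions", {
  expect_equal(rank_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rank_auc(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.5)
  # brute-force over the 4 positive-negative pairs: 3 concordant, 1 discordant
  expect_equal(rank_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(rank_auc(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("rank AUC equals exhaustive pair counting on random small instances", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    n_pos <- sample(seq_len(n - 1), 1)
    pos <- seq_len(n) <= n_pos
    # integer scores force frequent ties
    s <- sample(1:4, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    expect_equal(rank_auc(s, pos), auc_brute(s, pos))
  }
})

test_that("the per-timepoint evaluation pools 120/150 and skips one-class strata", {
  pts <- data.frame(
    sample_id = paste0("s", 1:12),
    d_normal = 0, d_tumor = 0,
    delta_pr = c(1, 2, -1, -2, 5, 6, -5, -6, 3, 4, -3, -4),
    age_days = c(30, 30, 30, 30, 60, 60, 60, 60, 120, 120, 150, 150),
    group = rep(c("exposed", "exposed", "control", "control"), 3),
    tumor_status = "unknown"
  )
  tab <- evaluate_2d_predictor(pts)
  expect_setequal(tab$stratum, c("30", "60", "120/150"))
  pooled <- tab[tab$stratum == "120/150", ]
  expect_equal(pooled$n_positive, 2)
  expect_equal(pooled$n_negative, 2)
  expect_equal(pooled$auc, 1)

  solo <- pts
  solo$group[solo$age_days == 30] <- "exposed"
  expect_warning(tab2 <- evaluate_2d_predictor(solo), "single class")
  expect_false("30" %in% tab2$stratum)
})

test_that("the optional logistic scorer runs on the 2D coordinates", {
  set.seed(5)
  pts <- data.frame(
    sample_id = paste0("s", 1:40),
    d_normal = c(runif(20, 5, 15), runif(20, 0, 5)),
    d_tumor = c(runif(20, 0, 5), runif(20, 5, 15)),
    age_days = rep(c(30, 60), 20),
    group = rep(c("exposed", "control"), each = 20),
    tumor_status = "unknown"
  )
  pts$delta_pr <- pts$d_normal - pts$d_tumor
  tab <- suppressWarnings(evaluate_2d_predictor(pts, scorer = "logistic"))
  expect_true(all(tab$auc > 0.9))
})

test_that("null data yields chance-level AUC on held-out samples", {
  # held-out scoring: in-sample scoring would favour each clock on its own
  # training cohort and bias the AUC above 0.5 even under the null
  aucs <- vapply(1:8, function(s) {
    cfg <- synthetic_config(n_features = 40, n_shared_clock_features = 4,
                            n_divergent_clock_features = 8, seed = s)
    ds <- generate_null_dataset(cfg)
    spc <- split_cohort(ds, "control", split_spec(seed = s))
    spe <- split_cohort(ds, "exposed", split_spec(seed = s + 25))
    mn <- fit_clock(spc$train, gamma1_grid = c(1, 100),
                    gamma2_grid = 1, cv_folds = 3, seed = s)
    mt <- fit_clock(spe$train, gamma1_grid = c(1, 100),
                    gamma2_grid = 1, cv_folds = 3, seed = s + 50)
    held_out <- ds[c(spc$test$samples$sample_id, spe$test$samples$sample_id)]
    pts <- deviation_points(held_out, mn, mt)
    rank_auc(pts$delta_pr, pts$group == "exposed")
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})
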