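#' Configure a full pipeline run
#'
#' One global seed fans out deterministically to stage-specific seeds
#' (generator, both cohort splits, both clocks' cross-validation folds, the
#' permutation stream), so any stage can be rerun in isolation and an
#' identical configuration yields byte-identical output tables.
#'
#' @param input Path to a dataset file readable with `layout`, or `NULL` to
#'   generate a synthetic cohort from `synthetic`.
#' @param layout A [layout_config()] for `input`.
#' @param synthetic A [synthetic_config()]; its own seed is overridden by a
#'   seed derived from `seed`.
#' @param seed Global integer seed.
#' @param train_fraction Training fraction for both cohort splits.
#' @param gamma1_grid,gamma2_grid,cv_folds Clock-fitting settings (see
#'   [fit_clock()]).
#' @param n_perm Permutations for the global FDR (default 200; the full
#'   design value is 1000).
#' @param entropy_bins Bins for [entropy_profile()].
#' @param test_ages Ages for [per_feature_tests()].
#' @param output_dir Directory for the report tables and provenance file, or
#'   `NULL` to skip writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, layout = layout_config(),
                       synthetic = synthetic_config(),
                       seed = 1L, train_fraction = 2 / 3,
                       gamma1_grid = 10^seq(-1, 3),
                       gamma2_grid = c(0, 1, 10),
                       cv_folds = 5L, n_perm = 200L,
                       entropy_bins = 6L, test_ages = c(30, 150),
                       output_dir = NULL) {
  structure(
    list(input = input, layout = layout, synthetic = synthetic,
         seed = as.integer(seed), train_fraction = train_fraction,
         gamma1_grid = gamma1_grid, gamma2_grid = gamma2_grid,
         cv_folds = as.integer(cv_folds), n_perm = as.integer(n_perm),
         entropy_bins = as.integer(entropy_bins), test_ages = test_ages,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the complete clock analysis end to end
#'
#' Executes: load or generate the cohort; split both cohorts 2/3-1/3; fit the
#' normal and tumor clocks; assemble the R-squared matrix (own-train,
#' own-test, cross-applied); compute per-sample deviation points and the
#' per-timepoint AUC table; estimate the global permutation FDR; compute both
#' clocks' entropy profiles and their contrast; and build the feature
#' comparison report. All tables plus a provenance file are written to
#' `config$output_dir` when set.
#'
#' A stage failure marks the report `partial = TRUE` and preserves the
#' completed stages; the error messages are collected in `$errors`.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` with elements `dataset`,
#'   `r2_matrix`, `priors`, `clocks`, `deviations`, `auc_table`,
#'   `permutation`, `entropy` (profiles + contrast), `features`,
#'   `provenance`, `partial`, `errors`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(partial = FALSE, errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$partial <<- TRUE
      report$errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  seed <- config$seed
  ds <- stage("data", {
    if (!is.null(config$input)) {
      read_dataset(config$input, config$layout)
    } else {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(seed, 10L)
      generate_dataset(cfg)$dataset
    }
  })
  if (is.null(ds)) {
    report$partial <- TRUE
    return(structure(report, class = "run_report"))
  }
  report$dataset <- ds
  report$priors <- stage("priors", class_priors(ds))

  splits <- stage("split", list(
    control = split_cohort(ds, "control",
                           split_spec(config$train_fraction, derive_seed(seed, 20L))),
    exposed = split_cohort(ds, "exposed",
                           split_spec(config$train_fraction, derive_seed(seed, 21L)))
  ))
  clocks <- stage("fit", list(
    normal = fit_clock(splits$control$train, config$gamma1_grid,
                       config$gamma2_grid, config$cv_folds,
                       seed = derive_seed(seed, 30L), label = "normal_clock"),
    tumor = fit_clock(splits$exposed$train, config$gamma1_grid,
                      config$gamma2_grid, config$cv_folds,
                      seed = derive_seed(seed, 31L), label = "tumor_clock")
  ))
  report$clocks <- clocks

  if (!is.null(clocks)) {
    report$r2_matrix <- stage("r2_matrix", {
      m <- matrix(NA_real_, 2L, 3L,
                  dimnames = list(c("normal_clock", "tumor_clock"),
                                  c("own_train", "own_test", "cross_group")))
      m["normal_clock", "own_train"] <- clocks$normal$training_r2
      m["normal_clock", "own_test"] <-
        r_squared(predict_ages(clocks$normal, splits$control$test))
      m["normal_clock", "cross_group"] <-
        r_squared(predict_ages(clocks$normal, subset_group(ds, "exposed")))
      m["tumor_clock", "own_train"] <- clocks$tumor$training_r2
      m["tumor_clock", "own_test"] <-
        r_squared(predict_ages(clocks$tumor, splits$exposed$test))
      m["tumor_clock", "cross_group"] <-
        r_squared(predict_ages(clocks$tumor, subset_group(ds, "control")))
      m
    })
    report$deviations <- stage("deviation",
                               deviation_points(ds, clocks$normal, clocks$tumor))
    if (!is.null(report$deviations)) {
      report$auc_table <- stage("auc", evaluate_2d_predictor(report$deviations))
    }
    report$entropy <- stage("entropy", {
      pn <- entropy_profile(clock_residuals(clocks$normal, ds),
                            config$entropy_bins, "normal_clock")
      pt <- entropy_profile(clock_residuals(clocks$tumor, ds),
                            config$entropy_bins, "tumor_clock")
      list(normal_clock = pn, tumor_clock = pt,
           contrast = entropy_contrast(pn, pt))
    })
    report$features <- stage("features", list(
      coefficients = compare_clocks(clocks$normal, clocks$tumor),
      tests = per_feature_tests(ds, config$test_ages)
    ))
  }
  report$permutation <- stage("fdr", permutation_fdr(
    ds, n_perm = config$n_perm, seed = derive_seed(seed, 40L),
    train_fraction = config$train_fraction,
    gamma1_grid = config$gamma1_grid, gamma2_grid = config$gamma2_grid,
    cv_folds = config$cv_folds))

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("proteoclock")),
    seed = seed,
    stage_seeds = list(generator = derive_seed(seed, 10L),
                       split_control = derive_seed(seed, 20L),
                       split_exposed = derive_seed(seed, 21L),
                       cv_normal = derive_seed(seed, 30L),
                       cv_tumor = derive_seed(seed, 31L),
                       permutation = derive_seed(seed, 40L)),
    train_fraction = config$train_fraction,
    gamma1_grid = config$gamma1_grid, gamma2_grid = config$gamma2_grid,
    cv_folds = config$cv_folds, n_perm = config$n_perm,
    entropy_bins = config$entropy_bins, test_ages = config$test_ages,
    input = if (is.null(config$input)) "synthetic" else config$input,
    penalty_convention = if (!is.null(clocks)) clocks$normal$convention else NA
  )
  report <- structure(report, class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# write all report tables (plain CSV) plus a machine-readable provenance file
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name, rn = FALSE) {
    utils::write.csv(x, file.path(dir, name), row.names = rn)
  }
  if (!is.null(report$r2_matrix)) w(report$r2_matrix, "r2_matrix.csv", rn = TRUE)
  if (!is.null(report$priors)) {
    w(data.frame(p_normal = report$priors$p_normal,
                 p_tumor = report$priors$p_tumor,
                 n_control = report$priors$n_control,
                 n_case = report$priors$n_case), "class_priors.csv")
  }
  if (!is.null(report$deviations)) w(report$deviations, "deviations.csv")
  if (!is.null(report$auc_table)) w(report$auc_table, "auc_by_age.csv")
  if (!is.null(report$permutation)) {
    p <- report$permutation
    w(data.frame(observed_diff = p$observed_diff, fdr = p$fdr,
                 n_perm = p$n_perm), "fdr.csv")
    w(data.frame(null_diff = p$null_diffs), "null_diffs.csv")
  }
  if (!is.null(report$entropy)) {
    w(rbind(report$entropy$normal_clock$entries,
            report$entropy$tumor_clock$entries), "entropy_profiles.csv")
    w(report$entropy$contrast, "entropy_contrast.csv")
  }
  if (!is.null(report$features)) {
    w(report$features$coefficients, "feature_coefficients.csv")
    w(report$features$tests, "feature_tests.csv")
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("proteoclock run report",
      if (isTRUE(x$partial)) "(PARTIAL)" else "", "\n")
  if (!is.null(x$r2_matrix)) {
    cat("\nR^2 matrix:\n"); print(round(x$r2_matrix, 3))
  }
  if (!is.null(x$auc_table)) {
    cat("\nPer-timepoint AUC of delta_pr:\n"); print(x$auc_table)
  }
  if (!is.null(x$permutation)) {
    cat("\n"); print(x$permutation)
  }
  if (length(x$errors)) {
    cat("\nfailed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
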