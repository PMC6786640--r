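#' Specify a train/test split
#'
#' @param train_fraction Fraction of each cohort assigned to training,
#'   in (0, 1); default 2/3 as in the clock development design.
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split one cohort into training and testing sets
#'
#' Randomly splits the samples of the named group, stratified by sampling age:
#' each age stratum contributes approximately `train_fraction` of its samples
#' to training, with rounding toward training (`ceiling`). Stratification is
#' used because with a 5-level age grid and small cells an unstratified split
#' can lose an age level entirely. Strata with fewer than 2 samples are
#' assigned wholly to training with a warning.
#'
#' @param ds A [proteomic_dataset()].
#' @param group `"control"` or `"exposed"`.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`, both `proteomic_dataset`s,
#'   disjoint and jointly covering the cohort.
#' @export
split_cohort <- function(ds, group, spec = split_spec()) {
  stopifnot(inherits(ds, "proteomic_dataset"), inherits(spec, "split_spec"))
  group <- match.arg(group, c("control", "exposed"))
  idx <- which(ds$samples$group == group)
  if (length(idx) < 6L) stop("cohort '", group, "' has fewer than 6 samples")
  train_idx <- with_seed(spec$seed, {
    out <- integer()
    for (a in sort(unique(ds$samples$age_days[idx]))) {
      ii <- idx[ds$samples$age_days[idx] == a]
      if (length(ii) < 2L) {
        warning("age stratum ", a, " has < 2 samples; assigned wholly to training")
        out <- c(out, ii)
      } else {
        n_tr <- ceiling(spec$train_fraction * length(ii))
        out <- c(out, sample(ii, n_tr))
      }
    }
    sort(out)
  })
  list(train = ds[train_idx], test = ds[sort(setdiff(idx, train_idx))])
}

# ---- elastic-net core ----------------------------------------------------
#
# The clock loss, on standardized features X and ages Y, is
#     L(beta) = |Y - X beta|^2 + gamma1 |beta|_1 + gamma2 |beta|_2^2
# with an unpenalized intercept. glmnet minimizes
#     (1/(2n)) |y - b0 - X b|^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# and, for gaussian responses, its penalty effectively scales with the
# population sd of y. We therefore standardize y to unit population sd
# ourselves, in which case the mapping is exact:
#     lambda = gamma1 / (2 n s_y) + gamma2 / n
#     alpha  = (gamma1 / (2 n s_y)) / lambda,    s_y = sqrt(mean((y - ybar)^2))
# and coefficients back-transform as beta = s_y * beta_tilde. This convention
# (recorded in model provenance as "rss + gamma1*L1 + gamma2*L2sq") makes the
# gamma1 = 0 solution equal the ridge closed form (X'X + gamma2 I)^-1 X'y.
en_fit <- function(X, y, gamma1, gamma2, n_lambda = 25L, thresh = 1e-15) {
  n <- nrow(X)
  ybar <- mean(y)
  sy <- sqrt(mean((y - ybar)^2))
  if (sy == 0) stop("degenerate response: all ages equal")
  yt <- (y - ybar) / sy
  lam <- gamma1 / (2 * n * sy) + gamma2 / n
  alpha <- if (lam == 0) 1 else (gamma1 / (2 * n * sy)) / lam
  lseq <- if (lam > 0) {
    exp(seq(log(lam * 200), log(lam), length.out = n_lambda))
  } else {
    c(0.5, 0.1, 0)
  }
  fit <- glmnet::glmnet(X, yt, alpha = alpha, lambda = lseq,
                        standardize = FALSE, thresh = thresh, maxit = 1e7)
  co <- as.numeric(stats::coef(fit, s = lam))
  list(beta = co[-1L] * sy, intercept = co[1L] * sy + ybar)
}

# age-stratified fold assignment, deterministic given the current RNG state
stratified_folds <- function(ages, k) {
  fold <- integer(length(ages))
  for (a in unique(ages)) {
    ii <- which(ages == a)
    fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
  }
  fold
}

#' Fit an elastic-net proteomic age clock
#'
#' Regresses sampling age on peak intensities under the elastic-net loss
#' `|Y - X beta|^2 + gamma1 |beta|_1 + gamma2 |beta|_2^2` with an unpenalized
#' intercept. Features are standardized to zero mean and unit (sample, n-1)
#' standard deviation on the training data; the standardization travels with
#' the model so cross-application to the other cohort is well defined.
#' `(gamma1, gamma2)` are chosen from the supplied grids by k-fold
#' cross-validation (folds stratified by age) minimizing mean squared
#' prediction error; ties go to the earliest grid point in
#' `expand.grid(gamma1_grid, gamma2_grid)` order. Constant features are
#' dropped with a warning.
#'
#' @param train A [proteomic_dataset()] of the training cohort (at least
#'   `cv_folds` samples and two distinct ages).
#' @param gamma1_grid,gamma2_grid Nonempty grids of nonnegative penalty
#'   weights (L1 and squared-L2 respectively).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param label `"normal_clock"` (control cohort) or `"tumor_clock"`
#'   (exposed cohort); provenance only.
#' @param log1p If `TRUE`, apply `log(1 + x)` to intensities before
#'   standardization (recorded in the model, applied again at prediction).
#' @return An object of class `clock_model`: coefficients `beta` (on the
#'   standardized scale), `intercept` (days), the selected `gamma1`/`gamma2`,
#'   `feature_ids` of retained features, standardization `center`/`scale`,
#'   `training_sample_ids`, `training_r2`, `label`, the penalty `convention`
#'   string and the cross-validation table `cv_table`.
#' @seealso [predict_ages()], [r_squared()], [split_cohort()]
#' @export
fit_clock <- function(train,
                      gamma1_grid = 10^seq(-1, 3),
                      gamma2_grid = c(0, 1, 10),
                      cv_folds = 5L,
                      seed = 1L,
                      label = c("normal_clock", "tumor_clock"),
                      log1p = FALSE) {
  stopifnot(inherits(train, "proteomic_dataset"))
  label <- match.arg(label)
  if (length(gamma1_grid) == 0L || length(gamma2_grid) == 0L) {
    stop("penalty grids must be nonempty")
  }
  if (any(gamma1_grid < 0) || any(gamma2_grid < 0)) {
    stop("penalty weights must be >= 0")
  }
  y <- as.numeric(train$samples$age_days)
  if (length(unique(y)) < 2L) stop("degenerate response: single sampling age")
  if (length(y) < cv_folds) stop("fewer samples than cv_folds")

  X <- train$intensities
  if (isTRUE(log1p)) X <- log1p(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s): ",
            paste(utils::head(train$feature_ids[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  }
  feature_ids <- train$feature_ids[keep]
  ctr <- ctr[keep]; scl <- scl[keep]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr), 2L, scl, `/`)

  grid <- expand.grid(gamma1 = gamma1_grid, gamma2 = gamma2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > 1L) {
    fold <- with_seed(seed, stratified_folds(y, cv_folds))
    cv_err <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        if (sum(tr) < 2L || sum(!tr) == 0L) return(NA_real_)
        m <- en_fit(Xs[tr, , drop = FALSE], y[tr],
                    grid$gamma1[g], grid$gamma2[g],
                    n_lambda = 12L, thresh = 1e-8)
        mean((y[!tr] - (m$intercept +
                          Xs[!tr, , drop = FALSE] %*% m$beta))^2)
      }, numeric(1L))
      mean(errs, na.rm = TRUE)
    }, numeric(1L))
    best <- which.min(cv_err)
    grid$cv_mse <- cv_err
  } else {
    best <- 1L
    grid$cv_mse <- NA_real_
  }
  g1 <- grid$gamma1[best]; g2 <- grid$gamma2[best]

  m <- en_fit(Xs, y, g1, g2)
  model <- structure(
    list(beta = stats::setNames(m$beta, feature_ids),
         intercept = m$intercept,
         gamma1 = g1, gamma2 = g2,
         feature_ids = feature_ids,
         center = stats::setNames(ctr, feature_ids),
         scale = stats::setNames(scl, feature_ids),
         training_sample_ids = train$samples$sample_id,
         training_r2 = NA_real_,
         label = label, log1p = isTRUE(log1p),
         convention = "rss + gamma1*L1 + gamma2*L2sq; X standardized (n-1 sd); y internally scaled to unit population sd",
         cv_table = grid),
    class = "clock_model"
  )
  model$training_r2 <- r_squared(predict_ages(model, train))
  model
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model '%s': %d features (%d nonzero), gamma1 = %g, gamma2 = %g\n",
              x$label, length(x$beta), sum(x$beta != 0), x$gamma1, x$gamma2))
  cat(sprintf("  intercept %.2f days, training R^2 = %.3f (n = %d)\n",
              x$intercept, x$training_r2, length(x$training_sample_ids)))
  invisible(x)
}

#' Predict sampling ages with a fitted clock
#'
#' Applies the model's stored training standardization (and `log1p`
#' preprocessing, if used at training) to the dataset's intensities and
#' returns one prediction per sample. The dataset's features must be a
#' superset of the model's retained features.
#'
#' @param model A [fit_clock()] model.
#' @param ds A [proteomic_dataset()] (any group; this is how clocks are
#'   cross-applied).
#' @return Data frame of class `clock_predictions` with columns `sample_id`,
#'   `actual_age`, `predicted_age` and `residual` (`predicted - actual`,
#'   days).
#' @export
predict_ages <- function(model, ds) {
  stopifnot(inherits(model, "clock_model"), inherits(ds, "proteomic_dataset"))
  missing <- setdiff(model$feature_ids, ds$feature_ids)
  if (length(missing)) {
    stop("dataset lacks model feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  X <- ds$intensities[, model$feature_ids, drop = FALSE]
  if (model$log1p) X <- log1p(X)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  pred <- as.numeric(model$intercept + Xs %*% model$beta)
  out <- data.frame(
    sample_id = ds$samples$sample_id,
    actual_age = as.numeric(ds$samples$age_days),
    predicted_age = pred,
    residual = pred - as.numeric(ds$samples$age_days),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clock_predictions", "data.frame")
  out
}

#' Goodness of fit of clock predictions
#'
#' By default the squared Pearson correlation between predicted and actual
#' ages, which stays in `[0, 1]` even for a miscalibrated cross-applied clock;
#' the coefficient of determination (`1 - SS_res / SS_tot`, which can be
#' negative under miscalibration) is available via `method = "cod"`.
#'
#' @param predictions A [predict_ages()] result (>= 3 rows, actual ages not
#'   all equal).
#' @param method `"pearson"` (default) or `"cod"`.
#' @return A single numeric value. Constant predictions yield 0 with a
#'   warning under `"pearson"`.
#' @export
r_squared <- function(predictions, method = c("pearson", "cod")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(predictions),
            all(c("actual_age", "predicted_age") %in% names(predictions)))
  if (nrow(predictions) < 3L) stop("need at least 3 predictions")
  a <- predictions$actual_age
  p <- predictions$predicted_age
  if (stats::sd(a) == 0) stop("all actual ages equal; R^2 undefined")
  if (method == "cod") {
    return(1 - sum((a - p)^2) / sum((a - mean(a))^2))
  }
  if (stats::sd(p) == 0) {
    warning("constant predictions; returning R^2 = 0")
    return(0)
  }
  stats::cor(a, p)^2
}

#' Serialize a clock model to a portable text file
#'
#' JSON with full-precision numbers; [read_clock_model()] round-trips the
#' model exactly.
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- unclass(model)
  obj$cv_table <- NULL  # provenance detail, not needed to apply the model
  # encode doubles as %.17g strings so the round trip is bit-exact
  enc <- function(v) sprintf("%.17g", v)
  obj$beta <- enc(obj$beta)
  obj$intercept <- enc(obj$intercept)
  obj$center <- enc(obj$center)
  obj$scale <- enc(obj$scale)
  obj$gamma1 <- enc(obj$gamma1)
  obj$gamma2 <- enc(obj$gamma2)
  obj$training_r2 <- enc(obj$training_r2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a clock model written by [write_clock_model()]
#'
#' @param path Path to the model file.
#' @return A `clock_model`.
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) as.numeric(v)
  model <- structure(
    list(beta = stats::setNames(num(obj$beta), obj$feature_ids),
         intercept = num(obj$intercept),
         gamma1 = num(obj$gamma1), gamma2 = num(obj$gamma2),
         feature_ids = obj$feature_ids,
         center = stats::setNames(num(obj$center), obj$feature_ids),
         scale = stats::setNames(num(obj$scale), obj$feature_ids),
         training_sample_ids = obj$training_sample_ids,
         training_r2 = num(obj$training_r2),
         label = obj$label, log1p = isTRUE(obj$log1p),
         convention = obj$convention,
         cv_table = NULL),
    class = "clock_model"
  )
  model
}
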