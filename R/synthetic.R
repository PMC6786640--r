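#' Per-timepoint cohort counts of the study design
#'
#' The cross-sectional sampling design emulated by the generator: control and
#' ENU-exposed (case) rats drawn at 30, 60, 90, 120 and 150 days of age,
#' 60 control and 64 case samples in total (124 rats, one CSF draw each).
#'
#' @return Data frame with columns `group`, `age_days`, `n`.
#' @export
#' @examples
#' tab <- table1_counts()
#' sum(tab$n)                       # 124
#' sum(tab$n[tab$group == "exposed"])  # 64
table1_counts <- function() {
  data.frame(
    group = rep(c("control", "exposed"), each = 5L),
    age_days = rep(c(30L, 60L, 90L, 120L, 150L), 2L),
    n = c(11L, 16L, 23L, 5L, 5L, 13L, 16L, 22L, 6L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Default group x age variance-inflation schedule
#'
#' Multipliers applied to the noise variance per (group, age) cell. The
#' default inflates the exposed group most strongly at day 60 with a return
#' to baseline at day 90 and renewed inflation at 120/150, which makes the
#' entropy of the exposed group's clock residuals peak at day 60 and reach a
#' local minimum at day 90 — the qualitative kinetics the pipeline is designed
#' to detect. Controls are never inflated by default.
#'
#' @param ages Integer ages of the schedule.
#' @param exposed Multipliers for the exposed group at `ages`.
#' @return Data frame with columns `group`, `age_days`, `multiplier`.
#' @export
default_variance_inflation <- function(ages = c(30L, 60L, 90L, 120L, 150L),
                                       exposed = c(2, 5, 1, 3, 3)) {
  stopifnot(length(ages) == length(exposed))
  data.frame(
    group = rep(c("control", "exposed"), each = length(ages)),
    age_days = rep(as.integer(ages), 2L),
    multiplier = c(rep(1, length(ages)), exposed),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic cohort generator
#'
#' Defines a two-group cross-sectional proteomic cohort with the statistical
#' structure the clock analysis assumes:
#' \itemize{
#'   \item a subset of "clock" features whose mean intensity is linear in age
#'     (`baseline + slope * age_days`), the simplest structure consistent with
#'     a linear age clock;
#'   \item *shared* clock features with one slope used by both groups, and
#'     *divergent* clock features whose slopes are drawn independently per
#'     group — these make each group's clock accurate within-group but
#'     degraded when cross-applied, and separate the groups from the first
#'     sampling age onward;
#'   \item a per-(group, age) variance-inflation schedule producing
#'     group-specific entropy kinetics;
#'   \item all remaining features are age-independent noise around their
#'     baseline.
#' }
#' Negative draws are truncated at zero so intensities stay nonnegative; a
#' log-normal noise option is available behind `log_normal = TRUE`.
#'
#' All distributional choices are synthetic stand-ins: the source study gives
#' no generative description of its CSF intensities.
#'
#' @param counts Data frame `(group, age_days, n)` of cell sizes; defaults to
#'   [table1_counts()].
#' @param n_features Total number of m/Z features (default 247).
#' @param n_shared_clock_features Number of age-trending features with a slope
#'   common to both groups (default 5).
#' @param n_divergent_clock_features Number of age-trending features whose
#'   slope is drawn independently in each group (default 35).
#' @param slope_scale Standard deviation of the per-feature slopes, intensity
#'   units per day (default 0.35).
#' @param noise_sd Baseline noise standard deviation, intensity units
#'   (default 10).
#' @param baseline_range Interval from which per-feature baselines are drawn
#'   uniformly (default `c(200, 600)`).
#' @param variance_inflation Data frame `(group, age_days, multiplier)` of
#'   noise-variance multipliers (all `>= 1`); defaults to
#'   [default_variance_inflation()]. Cells absent from the table get
#'   multiplier 1.
#' @param log_normal If `TRUE`, use multiplicative log-normal noise instead of
#'   additive Gaussian noise (off by default).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()], [generate_null_dataset()]
#' @export
synthetic_config <- function(counts = table1_counts(),
                             n_features = 247L,
                             n_shared_clock_features = 5L,
                             n_divergent_clock_features = 35L,
                             slope_scale = 0.35,
                             noise_sd = 10,
                             baseline_range = c(200, 600),
                             variance_inflation = default_variance_inflation(),
                             log_normal = FALSE,
                             seed = 1L) {
  cfg <- structure(
    list(counts = counts, n_features = as.integer(n_features),
         n_shared_clock_features = as.integer(n_shared_clock_features),
         n_divergent_clock_features = as.integer(n_divergent_clock_features),
         slope_scale = slope_scale, noise_sd = noise_sd,
         baseline_range = baseline_range,
         variance_inflation = variance_inflation,
         log_normal = isTRUE(log_normal), seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  problems <- character()
  cnt <- cfg$counts
  if (!is.data.frame(cnt) || !all(c("group", "age_days", "n") %in% names(cnt))) {
    problems <- c(problems, "counts must be a data frame with group, age_days, n")
  } else {
    if (any(cnt$n < 0)) problems <- c(problems, "counts must be >= 0")
    for (g in c("control", "exposed")) {
      ages_g <- unique(cnt$age_days[cnt$group == g & cnt$n > 0])
      if (length(ages_g) < 2L) {
        problems <- c(problems,
                      sprintf("group '%s' needs nonzero counts at >= 2 distinct ages", g))
      }
    }
  }
  n_clock <- cfg$n_shared_clock_features + cfg$n_divergent_clock_features
  if (n_clock > cfg$n_features) {
    problems <- c(problems, "shared + divergent clock features exceed n_features")
  }
  if (cfg$n_shared_clock_features < 0L || cfg$n_divergent_clock_features < 0L) {
    problems <- c(problems, "clock feature counts must be >= 0")
  }
  if (!(cfg$slope_scale > 0)) problems <- c(problems, "slope_scale must be > 0")
  if (!(cfg$noise_sd > 0)) problems <- c(problems, "noise_sd must be > 0")
  if (length(cfg$baseline_range) != 2L || any(cfg$baseline_range < 0) ||
      diff(cfg$baseline_range) < 0) {
    problems <- c(problems, "baseline_range must be a nonnegative interval")
  }
  vi <- cfg$variance_inflation
  if (!is.data.frame(vi) || !all(c("group", "age_days", "multiplier") %in% names(vi))) {
    problems <- c(problems,
                  "variance_inflation must be a data frame with group, age_days, multiplier")
  } else if (any(vi$multiplier < 1)) {
    problems <- c(problems, "variance_inflation multipliers must be >= 1")
  }
  if (length(problems)) {
    stop("invalid synthetic_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

# evaluate RNG-dependent code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic fan-out of one global seed into stage-specific seeds (< 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629) + 1L
}

#' Generate a synthetic two-group proteomic cohort
#'
#' Draws a cohort from a [synthetic_config()]: per-feature baselines, slopes
#' for the shared and divergent clock features, and per-sample noise with the
#' configured variance-inflation schedule. Mean trends are anchored at birth
#' (`baseline + slope * age_days`), so groups with divergent slopes already
#' differ in expectation at the first sampling age — the property that makes
#' presymptomatic (day-30) classification possible downstream.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{dataset}{a validated [proteomic_dataset()];}
#'     \item{truth}{a `ground_truth` list: `shared_features`,
#'       `divergent_features`, `slopes` (per feature and group), `baselines`,
#'       and `mean_signal`, the noiseless per-sample mean matrix.}
#'   }
#' @export
#' @examples
#' gen <- generate_dataset(synthetic_config(seed = 42))
#' dim(gen$dataset)          # 124 x 247
#' length(gen$truth$divergent_features)
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_impl(config, null_model = FALSE))
}

#' Generate an exchangeable null cohort
#'
#' As [generate_dataset()], but group labels carry no signal: every clock
#' feature uses one slope for both groups and a single (the control group's)
#' variance schedule applies to everyone, so the two groups are statistically
#' exchangeable by construction. Labels are assigned by count only. Used to
#' calibrate the permutation false-discovery procedure.
#'
#' @param config A [synthetic_config()].
#' @return A validated [proteomic_dataset()].
#' @export
generate_null_dataset <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_impl(config, null_model = TRUE))$dataset
}

generate_impl <- function(cfg, null_model) {
  p <- cfg$n_features
  n_sh <- cfg$n_shared_clock_features
  n_dv <- cfg$n_divergent_clock_features
  feature_ids <- sprintf("mz%03d", seq_len(p))

  baselines <- stats::runif(p, cfg$baseline_range[1L], cfg$baseline_range[2L])
  clock_idx <- sample.int(p, n_sh + n_dv)
  shared_idx <- clock_idx[seq_len(n_sh)]
  divergent_idx <- clock_idx[n_sh + seq_len(n_dv)]

  s_ctrl <- s_exp <- rep(0, p)
  sh_slopes <- stats::rnorm(n_sh, 0, cfg$slope_scale)
  s_ctrl[shared_idx] <- s_exp[shared_idx] <- sh_slopes
  s_ctrl[divergent_idx] <- stats::rnorm(n_dv, 0, cfg$slope_scale)
  s_exp[divergent_idx] <- if (null_model) s_ctrl[divergent_idx]
                          else stats::rnorm(n_dv, 0, cfg$slope_scale)

  cnt <- cfg$counts
  cnt <- cnt[cnt$n > 0, , drop = FALSE]
  cnt <- cnt[order(cnt$group, cnt$age_days), , drop = FALSE]

  vi_lookup <- function(group, age) {
    vi <- cfg$variance_inflation
    if (null_model) group <- "control"
    hit <- vi$multiplier[vi$group == group & vi$age_days == age]
    if (length(hit)) hit[1L] else 1
  }

  blocks <- vector("list", nrow(cnt))
  means <- vector("list", nrow(cnt))
  meta <- vector("list", nrow(cnt))
  for (k in seq_len(nrow(cnt))) {
    g <- cnt$group[k]; a <- cnt$age_days[k]; nn <- cnt$n[k]
    sl <- if (g == "control") s_ctrl else s_exp
    mu <- matrix(baselines + sl * a, nn, p, byrow = TRUE)
    sdk <- cfg$noise_sd * sqrt(vi_lookup(g, a))
    if (cfg$log_normal) {
      cv <- sdk / pmax(mu, 1e-8)
      x <- mu * exp(matrix(stats::rnorm(nn * p), nn, p) * cv -
                      cv^2 / 2)
    } else {
      x <- mu + matrix(stats::rnorm(nn * p, 0, sdk), nn, p)
    }
    x[x < 0] <- 0
    blocks[[k]] <- x
    means[[k]] <- mu
    status <- if (g == "exposed") {
      if (a >= 120) "tumor" else if (a >= 60) "microtumor" else "none"
    } else "none"
    ids <- sprintf("%s_d%03d_%02d", substr(g, 1L, 4L), a, seq_len(nn))
    meta[[k]] <- data.frame(sample_id = ids, rat_id = ids, group = g,
                            age_days = a, tumor_status = status,
                            stringsAsFactors = FALSE)
  }
  x <- do.call(rbind, blocks)
  mu <- do.call(rbind, means)
  samples <- do.call(rbind, meta)
  ds <- proteomic_dataset(x, samples, feature_ids = feature_ids)
  rownames(mu) <- samples$sample_id
  colnames(mu) <- feature_ids
  truth <- structure(
    list(shared_features = feature_ids[shared_idx],
         divergent_features = feature_ids[divergent_idx],
         slopes = data.frame(feature_id = feature_ids,
                             slope_control = s_ctrl, slope_exposed = s_exp,
                             stringsAsFactors = FALSE),
         baselines = stats::setNames(baselines, feature_ids),
         mean_signal = mu),
    class = "ground_truth"
  )
  list(dataset = ds, truth = truth)
}
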