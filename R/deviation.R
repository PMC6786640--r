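#' Distance of samples to a clock's regression line
#'
#' The deviation of a sample from a clock is the magnitude of its age
#' residual: `|predicted_age - actual_age|` in days, i.e. the vertical
#' distance to the identity line in the predicted-vs-actual plane at the
#' sample's known age. Signed and squared variants are available; the
#' absolute residual is the default used by the deviation score.
#'
#' @param model A [fit_clock()] model.
#' @param ds A [proteomic_dataset()] (may be a single-sample view obtained
#'   with `ds[i]`).
#' @param type `"absolute"` (default), `"signed"` or `"squared"`.
#' @return Named numeric vector of distances (days; days^2 for
#'   `"squared"`), one per sample.
#' @export
clock_distance <- function(model, ds, type = c("absolute", "signed", "squared")) {
  type <- match.arg(type)
  if (anyNA(ds$samples$age_days)) stop("sample(s) with unknown age")
  pr <- predict_ages(model, ds)
  d <- switch(type,
              absolute = abs(pr$residual),
              signed = pr$residual,
              squared = pr$residual^2)
  stats::setNames(d, pr$sample_id)
}

#' Per-sample deviation coordinates and the delta-Pr score
#'
#' For every sample, computes the distance to the normal clock and to the
#' tumor clock and the classification score
#' `delta_pr = d_normal - d_tumor`. The score is the Bayesian-posterior
#' surrogate `Pr(x | tumor) - Pr(x | normal)`: a sample close to the tumor
#' clock's regression line and far from the normal clock's is tumor-like
#' (large positive `delta_pr`). Class priors are deliberately omitted from
#' the score (they are nearly equal in the emulated design; see
#' [class_priors()]).
#'
#' @param ds A [proteomic_dataset()].
#' @param normal,tumor `clock_model`s fitted to the control and exposed
#'   cohorts.
#' @param type Distance type passed to [clock_distance()].
#' @return Data frame of class `deviation_points` with columns `sample_id`,
#'   `d_normal`, `d_tumor`, `delta_pr`, `age_days`, `group`, `tumor_status`.
#' @export
deviation_points <- function(ds, normal, tumor, type = "absolute") {
  dn <- clock_distance(normal, ds, type)
  dt <- clock_distance(tumor, ds, type)
  out <- data.frame(
    sample_id = ds$samples$sample_id,
    d_normal = as.numeric(dn),
    d_tumor = as.numeric(dt),
    delta_pr = as.numeric(dn) - as.numeric(dt),
    age_days = ds$samples$age_days,
    group = ds$samples$group,
    tumor_status = ds$samples$tumor_status,
    stringsAsFactors = FALSE
  )
  class(out) <- c("deviation_points", "data.frame")
  out
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' Area under the ROC curve of `scores` for separating positives from
#' negatives, computed from mid-ranks so that ties receive half credit:
#' `AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)` where `R_pos` is
#' the rank sum of the positive scores. Equals exhaustive pair counting
#' (concordant + 0.5 * tied) / (n_pos * n_neg).
#'
#' @param scores Numeric scores; larger means more positive-like.
#' @param positive Logical vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' rank_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop("need both positive and negative samples")
  r <- rank(scores)  # mid-ranks: half credit for ties
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate the two-dimensional presymptomatic predictor per timepoint
#'
#' Within each age stratum, computes the AUC of the deviation score for
#' separating exposed (tumor-destined; positive class) from control samples.
#' Days 120 and 150 are pooled by default, matching the evaluation design in
#' which all exposed animals carry overt tumors past day 120. The default
#' scorer is the scalar `delta_pr = d_normal - d_tumor`; `scorer =
#' "logistic"` instead scores with the linear predictor of an (in-sample)
#' logistic regression of group on the two distances.
#'
#' @param points A [deviation_points()] data frame.
#' @param pool Named list of age vectors to pool into one stratum
#'   (default `list("120/150" = c(120, 150))`).
#' @param scorer `"delta_pr"` (default) or `"logistic"`.
#' @return Data frame with columns `stratum`, `auc`, `n_positive`,
#'   `n_negative`. Single-class strata are skipped with a warning.
#' @export
evaluate_2d_predictor <- function(points,
                                  pool = list("120/150" = c(120, 150)),
                                  scorer = c("delta_pr", "logistic")) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(points, "data.frame"),
            all(c("delta_pr", "age_days", "group") %in% names(points)))
  score <- if (scorer == "delta_pr") {
    points$delta_pr
  } else {
    fit <- stats::glm(I(group == "exposed") ~ d_normal + d_tumor,
                      family = stats::binomial(), data = points)
    as.numeric(stats::predict(fit, type = "link"))
  }
  pooled_ages <- unlist(pool)
  strata <- c(as.list(sort(setdiff(unique(points$age_days), pooled_ages))), pool)
  names(strata) <- vapply(seq_along(strata), function(i) {
    if (!is.null(names(strata)[i]) && nzchar(names(strata)[i])) names(strata)[i]
    else as.character(strata[[i]])
  }, character(1L))
  rows <- lapply(names(strata), function(nm) {
    sel <- points$age_days %in% strata[[nm]]
    if (!any(sel)) return(NULL)
    pos <- points$group[sel] == "exposed"
    if (all(pos) || !any(pos)) {
      warning("stratum ", nm, " has a single class; skipped")
      return(NULL)
    }
    data.frame(stratum = nm, auc = rank_auc(score[sel], pos),
               n_positive = sum(pos), n_negative = sum(!pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
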