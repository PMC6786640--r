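#' Align and compare the coefficients of the two clocks
#'
#' Joins the two clocks' coefficient vectors over the union of their feature
#' universes and flags features selected (nonzero coefficient) in exactly one
#' clock — the clock-specific analyte peaks. A feature absent from one
#' model's universe (e.g. dropped as constant in that cohort) gets `NA`
#' there.
#'
#' @param normal,tumor `clock_model`s sharing (at least partially) a feature
#'   universe; disjoint universes are an error.
#' @return Data frame with columns `feature_id`, `beta_normal`,
#'   `beta_tumor`, `selected_normal`, `selected_tumor`, `clock_specific`.
#' @export
compare_clocks <- function(normal, tumor) {
  stopifnot(inherits(normal, "clock_model"), inherits(tumor, "clock_model"))
  if (length(intersect(normal$feature_ids, tumor$feature_ids)) == 0L) {
    stop("models have disjoint feature universes")
  }
  ids <- union(normal$feature_ids, tumor$feature_ids)
  bn <- normal$beta[match(ids, names(normal$beta))]
  bt <- tumor$beta[match(ids, names(tumor$beta))]
  sn <- !is.na(bn) & bn != 0
  st <- !is.na(bt) & bt != 0
  data.frame(feature_id = ids,
             beta_normal = as.numeric(bn),
             beta_tumor = as.numeric(bt),
             selected_normal = sn, selected_tumor = st,
             clock_specific = xor(sn, st),
             stringsAsFactors = FALSE)
}

#' Per-feature group-difference tests at chosen ages
#'
#' For each requested sampling age, tests every feature for a control vs
#' exposed intensity difference (two-sided), with Benjamini-Hochberg
#' adjustment across features within each age — 247 simultaneous tests
#' demand multiplicity control. The default is the Wilcoxon rank-sum test
#' (robust for skewed intensities); Welch's t-test is available.
#'
#' @param ds A [proteomic_dataset()].
#' @param ages Ages (days) at which to test (default `c(30, 150)`, the first
#'   and last sampling points). Ages with fewer than 3 samples in either
#'   group are skipped with a warning.
#' @param method `"rank_sum"` (default) or `"t_test"`.
#' @return Data frame with columns `feature_id`, `age_days`, `p_value`,
#'   `q_value` (BH within age).
#' @export
per_feature_tests <- function(ds, ages = c(30, 150),
                              method = c("rank_sum", "t_test")) {
  method <- match.arg(method)
  validate_dataset(ds)
  rows <- lapply(ages, function(a) {
    sel <- ds$samples$age_days == a
    ctrl <- sel & ds$samples$group == "control"
    expo <- sel & ds$samples$group == "exposed"
    if (sum(ctrl) < 3L || sum(expo) < 3L) {
      warning("age ", a, " has < 3 samples in a group; skipped")
      return(NULL)
    }
    p <- vapply(seq_along(ds$feature_ids), function(j) {
      x <- ds$intensities[ctrl, j]
      y <- ds$intensities[expo, j]
      if (method == "rank_sum") {
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      } else {
        stats::t.test(x, y)$p.value
      }
    }, numeric(1L))
    data.frame(feature_id = ds$feature_ids, age_days = a,
               p_value = p, q_value = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
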