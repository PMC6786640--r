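#' Clock residuals joined with sample metadata
#'
#' Convenience accessor producing the per-sample "predictive metric"
#' deviations entering the entropy analysis: the clock residuals
#' (`predicted - actual` age) of every sample, with group and age attached.
#'
#' @param model A [fit_clock()] model.
#' @param ds A [proteomic_dataset()].
#' @return Data frame with columns `sample_id`, `group`, `age_days`,
#'   `residual`.
#' @export
clock_residuals <- function(model, ds) {
  pr <- predict_ages(model, ds)
  data.frame(sample_id = pr$sample_id,
             group = ds$samples$group,
             age_days = ds$samples$age_days,
             residual = pr$residual,
             stringsAsFactors = FALSE)
}

#' Shannon entropy of a count vector, in bits
#'
#' `-sum(p_k log2 p_k)` over occupied bins with `p_k = count_k / n`.
#'
#' @param counts Nonnegative counts (at least one positive).
#' @return Entropy in bits, in `[0, log2(length(counts))]`.
#' @export
#' @examples
#' shannon_entropy(c(2, 2, 2, 2))  # 2 bits
#' shannon_entropy(c(3, 1))        # ~0.811 bits
shannon_entropy <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Entropy kinetics of a clock's residuals per group and age
#'
#' Quantifies the longitudinal dispersion ("deviation kinetics") of one
#' clock's predictive metric: residuals are binned on a single equal-width
#' grid spanning the pooled residual range (shared edges make cells
#' comparable), and each (group, age) cell's Shannon entropy is computed from
#' its bin occupancy. Entropies are bounded by `log2(n_bins)`; a cell whose
#' residuals are all equal has entropy 0. Cells with fewer than 5 samples are
#' flagged low-confidence rather than suppressed; cells below `min_cell`
#' samples are omitted with a warning.
#'
#' This estimator is a reconstruction: it is a deliberately simple, bounded,
#' comparable-across-cells summary of residual dispersion, not a reproduction
#' of any previously published network-entropy method.
#'
#' @param residuals A [clock_residuals()] data frame (columns `group`,
#'   `age_days`, `residual`).
#' @param n_bins Number of equal-width bins (default 6, `>= 2`).
#' @param clock_label Label recorded with each entry.
#' @param min_cell Minimum samples per (group, age) cell (default 2).
#' @return An object of class `entropy_profile`: `entries` (data frame with
#'   `clock_label`, `group`, `age_days`, `n_samples`, `entropy_bits`,
#'   `low_confidence`), `bin_edges`, `n_bins`.
#' @export
entropy_profile <- function(residuals, n_bins = 6L, clock_label = "clock",
                            min_cell = 2L) {
  stopifnot(is.data.frame(residuals),
            all(c("group", "age_days", "residual") %in% names(residuals)),
            n_bins >= 2L)
  r <- residuals$residual
  rng <- range(r)
  zero_range <- diff(rng) == 0
  edges <- if (zero_range) {
    seq(rng[1L] - 0.5, rng[2L] + 0.5, length.out = n_bins + 1L)
  } else {
    seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  cells <- unique(residuals[, c("group", "age_days")])
  cells <- cells[order(cells$group, cells$age_days), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    sel <- residuals$group == cells$group[k] &
      residuals$age_days == cells$age_days[k]
    n <- sum(sel)
    if (n < min_cell) {
      warning(sprintf("cell (%s, %s) has %d sample(s); omitted",
                      cells$group[k], cells$age_days[k], n))
      return(NULL)
    }
    cnt <- tabulate(findInterval(r[sel], edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    data.frame(clock_label = clock_label,
               group = cells$group[k], age_days = cells$age_days[k],
               n_samples = n, entropy_bits = shannon_entropy(cnt),
               low_confidence = n < 5L,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  structure(list(entries = entries, bin_edges = edges,
                 n_bins = as.integer(n_bins)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile (%d bins, edges %.2f..%.2f):\n",
              x$n_bins, x$bin_edges[1L], x$bin_edges[length(x$bin_edges)]))
  print(x$entries)
  invisible(x)
}

#' Contrast entropy kinetics between the two clocks
#'
#' Per age, reports the exposed-minus-control entropy under each clock and
#' flags the expected sign pattern: each group should be *tighter* (lower
#' entropy) under its own clock, i.e. positive contrast under the normal
#' clock and negative under the tumor clock.
#'
#' @param profile_normal_clock,profile_tumor_clock [entropy_profile()]s
#'   computed from the normal and tumor clocks on the same samples; they must
#'   cover the same (group, age) cells.
#' @return Data frame with columns `age_days`, `contrast_normal_clock`,
#'   `contrast_tumor_clock`, `own_group_tighter`.
#' @export
entropy_contrast <- function(profile_normal_clock, profile_tumor_clock) {
  stopifnot(inherits(profile_normal_clock, "entropy_profile"),
            inherits(profile_tumor_clock, "entropy_profile"))
  en <- profile_normal_clock$entries
  et <- profile_tumor_clock$entries
  key <- function(e) paste(e$group, e$age_days)
  if (!setequal(key(en), key(et))) {
    stop("profiles cover different (group, age) cells")
  }
  ages <- sort(unique(en$age_days))
  pull <- function(e, g, a) e$entropy_bits[e$group == g & e$age_days == a]
  rows <- lapply(ages, function(a) {
    cn <- pull(en, "exposed", a) - pull(en, "control", a)
    ct <- pull(et, "exposed", a) - pull(et, "control", a)
    if (!length(cn) || !length(ct)) return(NULL)
    data.frame(age_days = a,
               contrast_normal_clock = cn,
               contrast_tumor_clock = ct,
               own_group_tighter = cn > 0 & ct < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
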