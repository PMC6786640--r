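#' Construct a proteomic dataset
#'
#' The universal input of the pipeline: a samples x features matrix of
#' nonnegative peak intensities together with per-sample metadata. Samples are
#' treated as cross-sectional and independent (one CSF draw per rat);
#' `rat_id` is retained for provenance only.
#'
#' @param intensities Numeric matrix, `n_samples x n_features`, nonnegative and
#'   finite. Column names, when present, seed `feature_ids`.
#' @param samples Data frame with one row per intensity row. Required columns:
#'   `sample_id` (unique), `group` (levels `"control"`/`"exposed"`),
#'   `age_days` (positive integers, days since birth). Optional: `rat_id`
#'   (defaults to `sample_id`) and `tumor_status` (one of `"none"`,
#'   `"microtumor"`, `"tumor"`, `"unknown"`; defaults to `"unknown"`).
#' @param feature_ids Character vector of unique feature labels (anonymous m/Z
#'   peaks); defaults to the column names of `intensities`.
#'
#' @return An object of class `proteomic_dataset`: a list with elements
#'   `intensities`, `samples` and `feature_ids`.
#' @seealso [read_dataset()], [write_dataset()], [class_priors()],
#'   [generate_dataset()]
#' @export
#' @examples
#' x <- matrix(runif(12, 10, 20), 4, 3)
#' meta <- data.frame(
#'   sample_id = paste0("s", 1:4),
#'   group = c("control", "control", "exposed", "exposed"),
#'   age_days = c(30, 60, 30, 60)
#' )
#' ds <- proteomic_dataset(x, meta, feature_ids = c("mz1", "mz2", "mz3"))
#' ds
proteomic_dataset <- function(intensities, samples, feature_ids = colnames(intensities)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0("f", seq_len(ncol(intensities)))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$rat_id)) samples$rat_id <- samples$sample_id
  if (is.null(samples$tumor_status)) samples$tumor_status <- "unknown"
  samples$sample_id <- as.character(samples$sample_id)
  samples$rat_id <- as.character(samples$rat_id)
  samples$group <- as.character(samples$group)
  samples$tumor_status <- as.character(samples$tumor_status)
  samples <- samples[, c("sample_id", "rat_id", "group", "age_days", "tumor_status")]
  rownames(samples) <- NULL
  colnames(intensities) <- as.character(feature_ids)
  rownames(intensities) <- samples$sample_id
  ds <- structure(
    list(intensities = intensities, samples = samples,
         feature_ids = as.character(feature_ids)),
    class = "proteomic_dataset"
  )
  validate_dataset(ds)
  ds
}

# construction without invariant checks, for internal subsetting
new_proteomic_dataset <- function(intensities, samples, feature_ids) {
  structure(
    list(intensities = intensities, samples = samples, feature_ids = feature_ids),
    class = "proteomic_dataset"
  )
}

#' Validate a proteomic dataset
#'
#' Checks the dataset invariants: no missing or non-finite intensities, no
#' negative intensities, unique sample and feature identifiers, positive
#' integer ages, at least 2 samples and 1 feature, and recognized group and
#' tumor-status levels.
#'
#' @param ds A [proteomic_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "proteomic_dataset"))
  x <- ds$intensities
  s <- ds$samples
  if (nrow(x) < 2L) stop("dataset must contain at least 2 samples")
  if (ncol(x) < 1L) stop("dataset must contain at least 1 feature")
  if (nrow(s) != nrow(x)) stop("metadata rows do not match intensity rows")
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite intensity at sample '%s', feature '%s'",
                 s$sample_id[bad[1L]], ds$feature_ids[bad[2L]]))
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative intensity at sample '%s', feature '%s'",
                 s$sample_id[bad[1L]], ds$feature_ids[bad[2L]]))
  }
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id: ", s$sample_id[duplicated(s$sample_id)][1L])
  }
  if (anyDuplicated(ds$feature_ids)) {
    stop("duplicate feature_id: ", ds$feature_ids[duplicated(ds$feature_ids)][1L])
  }
  if (!all(s$group %in% c("control", "exposed"))) {
    stop("group must be 'control' or 'exposed'; found: ",
         paste(unique(setdiff(s$group, c("control", "exposed"))), collapse = ", "))
  }
  age <- s$age_days
  if (anyNA(age) || any(age <= 0) || any(age != round(age))) {
    stop("age_days must be positive integers (days since birth)")
  }
  if (!all(s$tumor_status %in% c("none", "microtumor", "tumor", "unknown"))) {
    stop("tumor_status must be one of none/microtumor/tumor/unknown")
  }
  invisible(ds)
}

#' @export
print.proteomic_dataset <- function(x, ...) {
  cat(sprintf("proteomic_dataset: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$samples$group, x$samples$age_days)
  cat("group x age_days cross-tabulation:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.proteomic_dataset <- function(x) dim(x$intensities)

#' Subset a proteomic dataset by samples
#'
#' `ds[i]` keeps the samples selected by `i` (indices, logical mask, or
#' sample ids). Used throughout the pipeline for cohort filtering and
#' train/test splitting; invariants on minimum sample count are not re-checked
#' so single-sample views are permitted.
#'
#' @param x A [proteomic_dataset()].
#' @param i Sample selector.
#' @return A `proteomic_dataset` containing the selected samples.
#' @export
`[.proteomic_dataset` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  s <- x$samples[i, , drop = FALSE]
  rownames(s) <- NULL
  new_proteomic_dataset(x$intensities[i, , drop = FALSE], s, x$feature_ids)
}

#' Extract the samples of one group
#'
#' @param ds A [proteomic_dataset()].
#' @param group `"control"` or `"exposed"`.
#' @return A `proteomic_dataset` restricted to the group.
#' @export
subset_group <- function(ds, group) {
  group <- match.arg(group, c("control", "exposed"))
  ds[ds$samples$group == group]
}

#' Describe the on-disk layout of a dataset file
#'
#' The default dialect is a UTF-8 delimited text file with a header row,
#' samples as rows, metadata columns first and one column per feature.
#' A `layout_config` remaps column names, the field separator and the
#' orientation, so exports of differently shaped supplementary tables
#' (e.g. a spreadsheet sheet saved as CSV with samples as columns) can be
#' ingested without editing the file.
#'
#' @param sample_id,rat_id,group,age_days,tumor_status Names of the metadata
#'   columns in the file. `rat_id` and `tumor_status` may be `NA` (absent).
#' @param samples `"rows"` (default) if each file row is a sample, or
#'   `"columns"` if each file column is a sample (first column then holds the
#'   feature ids and metadata field names).
#' @param sep Field separator (default comma).
#' @param control_labels,exposed_labels Group labels in the file normalized to
#'   `"control"` / `"exposed"` (case-insensitive).
#' @return An object of class `layout_config`.
#' @export
layout_config <- function(sample_id = "sample_id", rat_id = "rat_id",
                          group = "group", age_days = "age_days",
                          tumor_status = "tumor_status",
                          samples = c("rows", "columns"), sep = ",",
                          control_labels = c("control", "normal", "ctrl", "saline"),
                          exposed_labels = c("exposed", "case", "enu", "tumor")) {
  structure(
    list(sample_id = sample_id, rat_id = rat_id, group = group,
         age_days = age_days, tumor_status = tumor_status,
         samples = match.arg(samples), sep = sep,
         control_labels = tolower(control_labels),
         exposed_labels = tolower(exposed_labels)),
    class = "layout_config"
  )
}

#' Read a proteomic dataset from a delimited text file
#'
#' Parses a delimited table into a validated [proteomic_dataset()]. The layout
#' (metadata column names, orientation, separator, group label vocabulary) is
#' configurable through [layout_config()]; spreadsheet supplementary tables
#' should be exported sheet-by-sheet to CSV and read with a matching layout.
#'
#' @param path Path to the file.
#' @param layout A [layout_config()].
#' @return A validated [proteomic_dataset()].
#' @export
read_dataset <- function(path, layout = layout_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = layout$sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           quote = "\"", comment.char = "")
  if (layout$samples == "columns") {
    keys <- raw[[1L]]
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    raw <- as.data.frame(t(vals), stringsAsFactors = FALSE)
    names(raw) <- keys
    raw <- cbind(stats::setNames(data.frame(colnames(vals),
                                            stringsAsFactors = FALSE),
                                 layout$sample_id),
                 raw)
  }
  need <- c(sample_id = layout$sample_id, group = layout$group,
            age_days = layout$age_days)
  for (role in names(need)) {
    if (!need[[role]] %in% names(raw)) {
      stop(sprintf("configuration error: metadata column '%s' (%s) not found",
                   need[[role]], role))
    }
  }
  meta_cols <- unlist(need)
  if (!is.na(layout$rat_id) && layout$rat_id %in% names(raw)) {
    meta_cols <- c(meta_cols, layout$rat_id)
  }
  if (!is.na(layout$tumor_status) && layout$tumor_status %in% names(raw)) {
    meta_cols <- c(meta_cols, layout$tumor_status)
  }
  feat_cols <- setdiff(names(raw), meta_cols)
  if (length(feat_cols) == 0L) stop("no feature columns found")

  x <- matrix(NA_real_, nrow(raw), length(feat_cols),
              dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(raw[[feat_cols[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf(
        "parse error: non-numeric or missing intensity '%s' at row %d, column '%s'",
        raw[[feat_cols[j]]][i], i, feat_cols[j]))
    }
    x[, j] <- v
  }

  grp <- tolower(trimws(raw[[layout$group]]))
  group <- ifelse(grp %in% layout$control_labels, "control",
                  ifelse(grp %in% layout$exposed_labels, "exposed", NA))
  if (anyNA(group)) {
    stop("unrecognized group label(s): ",
         paste(unique(raw[[layout$group]][is.na(group)]), collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(raw[[layout$age_days]]))
  if (anyNA(age)) {
    stop("parse error: non-numeric age_days at row ", which(is.na(age))[1L])
  }
  samples <- data.frame(
    sample_id = raw[[layout$sample_id]],
    group = group, age_days = age,
    stringsAsFactors = FALSE
  )
  if (!is.na(layout$rat_id) && layout$rat_id %in% names(raw)) {
    samples$rat_id <- raw[[layout$rat_id]]
  }
  if (!is.na(layout$tumor_status) && layout$tumor_status %in% names(raw)) {
    samples$tumor_status <- raw[[layout$tumor_status]]
  }
  proteomic_dataset(x, samples, feature_ids = feat_cols)
}

#' Write a proteomic dataset to a comma-separated file
#'
#' Emits the default on-disk dialect read by [read_dataset()]: header row,
#' samples as rows, metadata columns (`sample_id`, `rat_id`, `group`,
#' `age_days`, `tumor_status`) then one column per feature. Intensities are
#' written with 17 significant digits so that a write/read round trip is exact.
#'
#' @param ds A valid [proteomic_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  s <- ds$samples
  num <- apply(ds$intensities, 2L, function(col) sprintf("%.17g", col))
  out <- cbind(as.matrix(s), num)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(c(colnames(s), ds$feature_ids), collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Empirical class priors of the two groups
#'
#' The prior probabilities entering the Bayesian derivation of the deviation
#' score: `p_normal = n_control / n_total` and `p_tumor = n_case / n_total`.
#' With the study's cohort counts (60 control, 64 case) these are
#' approximately 0.48 and 0.52. The deviation score itself deliberately omits
#' them (see [deviation_points()]).
#'
#' @param ds A [proteomic_dataset()] containing both groups.
#' @return A list of class `class_priors` with elements `p_normal`,
#'   `p_tumor`, `n_control`, `n_case`.
#' @export
#' @examples
#' gen <- generate_dataset(synthetic_config(seed = 1))
#' class_priors(gen$dataset)
class_priors <- function(ds) {
  stopifnot(inherits(ds, "proteomic_dataset"))
  n_control <- sum(ds$samples$group == "control")
  n_case <- sum(ds$samples$group == "exposed")
  if (n_control == 0L) stop("no control samples in dataset")
  if (n_case == 0L) stop("no exposed samples in dataset")
  structure(
    list(p_normal = n_control / (n_control + n_case),
         p_tumor = n_case / (n_control + n_case),
         n_control = n_control, n_case = n_case),
    class = "class_priors"
  )
}

#' @export
print.class_priors <- function(x, ...) {
  cat(sprintf("class priors: Pr(normal) = %d/%d = %.2f, Pr(tumor) = %d/%d = %.2f\n",
              x$n_control, x$n_control + x$n_case, x$p_normal,
              x$n_case, x$n_control + x$n_case, x$p_tumor))
  invisible(x)
}
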