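# Missing-value removal, outlier removal, class-balancing undersampling.
# Pipeline order is fixed: drop_missing -> remove_outliers -> undersample
# (labels are joined before preprocessing so dropped rows cannot
# unbalance the final classes).

dataset_feature_cols <- function(dataset) {
  setdiff(names(dataset), "label")
}

#' Drop rows with missing feature values
#'
#' @param dataset data.frame (feature columns, optional `label` column).
#' @param feature_cols columns checked for missingness (default: all
#'   non-label columns).
#' @return list with `dataset` (rows in original order) and `report`
#'   (`rows_in`, `rows_dropped_missing`, `rows_out`).
#' @export
drop_missing <- function(dataset, feature_cols = dataset_feature_cols(dataset)) {
  keep <- stats::complete.cases(dataset[feature_cols])
  if (!any(keep))
    stop_dd("all %d rows contain missing values", nrow(dataset),
            class = "deceptrf_empty_dataset")
  list(dataset = dataset[keep, , drop = FALSE],
       report = list(rows_in = nrow(dataset),
                     rows_dropped_missing = sum(!keep),
                     rows_out = sum(keep)))
}

#' Remove outlier rows by per-feature quartile fences
#'
#' `tukey` (default) drops rows with any feature outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; `literal_quartile` drops rows outside
#' `[Q1, Q3]` (the much more aggressive literal rule, which removes about
#' half the rows per feature and is retained only for fidelity
#' experiments). Quantiles are computed per feature over the whole
#' dataset.
#'
#' @param dataset data.frame.
#' @param mode `"tukey"` or `"literal_quartile"`.
#' @param feature_cols columns the fences apply to; defaults to all
#'   non-label columns except the integer event-count columns (see
#'   [count_feature_names()]).
#' @return list with `dataset` and `report` (counts and the mode used).
#' @export
remove_outliers <- function(dataset, mode = c("tukey", "literal_quartile"),
                            feature_cols = setdiff(dataset_feature_cols(dataset),
                                                   count_feature_names())) {
  mode <- match.arg(mode)
  if (nrow(dataset) < 4)
    stop_dd("remove_outliers needs at least 4 rows, got %d", nrow(dataset),
            class = "deceptrf_argument_error")
  keep <- rep(TRUE, nrow(dataset))
  for (cn in feature_cols) {
    x <- dataset[[cn]]
    q1 <- q_linear(x, 0.25); q3 <- q_linear(x, 0.75)
    if (mode == "tukey") {
      iqr <- q3 - q1
      lo <- q1 - 1.5 * iqr; hi <- q3 + 1.5 * iqr
    } else {
      lo <- q1; hi <- q3
    }
    keep <- keep & !is.na(x) & x >= lo & x <= hi
  }
  if (!any(keep))
    stop_dd("outlier removal (%s) dropped every row", mode,
            class = "deceptrf_empty_dataset")
  list(dataset = dataset[keep, , drop = FALSE],
       report = list(rows_in = nrow(dataset),
                     rows_dropped_outlier = sum(!keep),
                     rows_out = sum(keep), mode = mode))
}

#' Undersample the majority class
#'
#' Randomly subsamples the majority class without replacement to the
#' minority-class count, reproducibly under `seed`; the minority class is
#' untouched. Output rows keep their original order.
#'
#' @param dataset data.frame with a 0/1 `label` column.
#' @param seed integer seed for the row selection.
#' @return list with `dataset` and `report` (class counts before/after,
#'   seed).
#' @export
undersample <- function(dataset, seed = 1L) {
  if (!"label" %in% names(dataset))
    stop_dd("undersample needs a 'label' column", class = "deceptrf_argument_error")
  pos <- which(dataset$label == 1L)
  neg <- which(dataset$label == 0L)
  if (length(pos) == 0 || length(neg) == 0)
    stop_dd("undersample: one class is absent (%d positives, %d negatives)",
            length(pos), length(neg), class = "deceptrf_class_missing")
  m <- min(length(pos), length(neg))
  keep <- withr::with_seed(seed, {
    if (length(pos) > m) pos <- sample(pos, m)
    if (length(neg) > m) neg <- sample(neg, m)
    sort(c(pos, neg))
  })
  list(dataset = dataset[keep, , drop = FALSE],
       report = list(positives_before = sum(dataset$label == 1L),
                     negatives_before = sum(dataset$label == 0L),
                     positives_after = m, negatives_after = m,
                     seed = seed))
}

#' Run the full preprocessing pipeline
#'
#' `drop_missing` then `remove_outliers` then `undersample`, returning the
#' processed dataset and a combined report.
#'
#' The quartile fences are applied to the raw per-frame geometric features
#' only (measurement outliers, e.g. tracking glitches): derived
#' rolling-variance columns are strongly right-skewed and event counts are
#' small integers, so fences on them would discard large swaths of valid
#' frames — including precisely the deception-window frames the derived
#' features exist to flag.
#'
#' @param dataset labeled feature table (from [label_dataset()]).
#' @param outlier_mode see [remove_outliers()].
#' @param seed undersampling seed.
#' @param outlier_cols columns the fences apply to (default: the static
#'   geometric features present in the dataset).
#' @return list with `dataset` and `report`.
#' @export
preprocess_dataset <- function(dataset, outlier_mode = "tukey", seed = 1L,
                               outlier_cols = intersect(static_feature_names(),
                                                        names(dataset))) {
  s1 <- drop_missing(dataset)
  s2 <- remove_outliers(s1$dataset, mode = outlier_mode,
                        feature_cols = outlier_cols)
  s3 <- undersample(s2$dataset, seed = seed)
  list(dataset = s3$dataset,
       report = list(rows_in = s1$report$rows_in,
                     rows_dropped_missing = s1$report$rows_dropped_missing,
                     rows_dropped_outlier = s2$report$rows_dropped_outlier,
                     outlier_mode = s2$report$mode,
                     positives_before = s3$report$positives_before,
                     negatives_before = s3$report$negatives_before,
                     positives_after = s3$report$positives_after,
                     negatives_after = s3$report$negatives_after,
                     rows_out = nrow(s3$dataset),
                     seed = seed))
}
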