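#' Score one subject's imputations against hidden truth
#'
#' Metrics pooled over all of the subject's hidden cells across regions:
#' `rmse = sqrt(mean((truth - imputed)^2))`; `correlation` is the pooled
#' Pearson correlation; `auc` is the area under the ROC curve using the
#' truth binarized at 0.5 (>= 0.5 is the positive class) as labels and the
#' raw imputed values as scores. A one-class truth leaves `auc` as `NA`; a
#' constant imputation leaves `correlation` as `NA`.
#'
#' @param truth Numeric vector of hidden true values.
#' @param imputed Numeric vector of imputed values (same cells).
#' @return Named list `rmse`, `correlation`, `auc`, `n_points`.
#' @export
score_subject <- function(truth, imputed) {
  stopifnot(length(truth) == length(imputed))
  ok <- !is.na(truth) & !is.na(imputed)
  truth <- truth[ok]; imputed <- imputed[ok]
  n <- length(truth)
  if (n == 0)
    return(list(rmse = NA_real_, correlation = NA_real_, auc = NA_real_,
                n_points = 0L))
  rmse <- sqrt(mean((truth - imputed)^2))
  correlation <- if (n >= 2 && stats::sd(truth) > 0 && stats::sd(imputed) > 0)
    stats::cor(truth, imputed) else NA_real_
  labels <- truth >= 0.5
  auc <- if (length(unique(labels)) == 2)
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = imputed,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  else NA_real_
  list(rmse = rmse, correlation = correlation, auc = auc, n_points = n)
}

#' Paired t-test comparing two methods on a per-subject metric
#'
#' Subjects are matched across methods (the same subjects are scored under
#' every method), so a paired two-sided t-test is used by default. A
#' zero-variance difference vector makes the test degenerate; the result is
#' then flagged, with `t = 0, p = 1` when the methods agree exactly.
#'
#' @param scores Data frame with columns `subject`, `method`, `metric`,
#'   `value` (long format, as produced by [benchmark_imputation()]).
#' @param metric Metric name to compare.
#' @param method_a,method_b The two method labels.
#' @param paired Use a paired test (default) or Welch's unpaired.
#' @return List `t_statistic`, `p_value`, `degenerate`, `mean_diff`.
#' @export
compare_methods <- function(scores, metric, method_a, method_b,
                            paired = TRUE) {
  a <- scores[scores$method == method_a & scores$metric == metric, ]
  b <- scores[scores$method == method_b & scores$metric == metric, ]
  a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
  if (!identical(a$subject, b$subject))
    stop("methods were not scored on the same subjects")
  ok <- !is.na(a$value) & !is.na(b$value)
  if (sum(ok) < 2) stop("need >= 2 subjects with scores for both methods")
  x <- a$value[ok]; y <- b$value[ok]
  if (paired && stats::sd(x - y) <= 1e-12 * (abs(mean(x - y)) + 1)) {
    d <- mean(x - y)
    return(list(t_statistic = if (abs(d) <= 1e-12) 0 else sign(d) * Inf,
                p_value = if (abs(d) <= 1e-12) 1 else 0,
                degenerate = TRUE, mean_diff = d))
  }
  tt <- stats::t.test(x, y, paired = paired)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE, mean_diff = mean(x - y))
}

run_method <- function(dataset, method, config, seed, knn_k, n_boot,
                       artificial_frac) {
  switch(method,
         regional = suppressWarnings(impute_regional(dataset, config, seed)),
         subject = suppressWarnings(impute_subject(dataset, config, seed)),
         stacked = suppressWarnings(impute_stacked(
           dataset, config, n_boot = n_boot,
           artificial_frac = artificial_frac, seed = seed)),
         average = impute_baseline(dataset, "average"),
         knn = impute_baseline(dataset, "knn", k = knn_k),
         stop("unknown method: ", method))
}

#' Benchmark imputation methods against hidden truth
#'
#' Runs each requested imputer on the masked dataset and scores every
#' subject's hidden cells pooled across regions. One failing method does
#' not abort the others.
#'
#' @param masked Either a `sim_truth` from [simulate_mrm()] or a list
#'   `list(dataset =, hidden =)` as returned by [inject_missing()].
#' @param truth For a `sim_truth` input: score against the noise-free
#'   cluster-mean values (`"clean"`, the default -- the imputation target
#'   is the underlying methylation level, and correlation against the
#'   noisy draws is bounded away from 1 by the noise itself) or against
#'   the deleted noisy observations (`"noisy"`). Ignored for
#'   [inject_missing()] input, where the measured value is the only truth
#'   available.
#' @param methods Subset of `c("regional", "subject", "stacked", "average",
#'   "knn")`.
#' @param config [mrm_control()] list (plus optional `rbf_centers`,
#'   `rbf_scale`, `K_max`, `lambda_grid`).
#' @param seed Integer seed.
#' @param knn_k Neighbours for the KNN baseline.
#' @param n_boot,artificial_frac Stacking settings (only used when
#'   `"stacked"` is requested).
#' @return Long-format data frame `subject`, `method`, `metric`, `value`,
#'   `n_points` (one row per subject x method x metric).
#' @export
benchmark_imputation <- function(masked,
                                 methods = c("regional", "average", "knn"),
                                 config = mrm_control(), seed = 1,
                                 knn_k = 10, n_boot = 10,
                                 artificial_frac = 0.1,
                                 truth = c("clean", "noisy")) {
  if (inherits(masked, "sim_truth")) {
    dataset <- masked$dataset
    hidden <- sim_hidden_table(masked, match.arg(truth))
  } else {
    dataset <- masked$dataset
    hidden <- masked$hidden
  }
  subj <- subject_ids(dataset)
  rows <- list()
  for (method in methods) {
    res <- tryCatch(
      run_method(dataset, method, config, seed, knn_k, n_boot,
                 artificial_frac),
      error = function(e) {
        warning("method ", method, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    for (s in subj) {
      hs <- hidden[hidden$subject == s, ]
      imp <- vapply(seq_len(nrow(hs)), function(i) {
        r <- res$dataset$regions[[hs$region_id[i]]]
        r$values[match(s, r$subject_ids),
                 match(hs$position[i], r$positions)]
      }, numeric(1))
      sc <- score_subject(hs$truth, imp)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, method = method,
        metric = c("rmse", "correlation", "auc"),
        value = c(sc$rmse, sc$correlation, sc$auc),
        n_points = sc$n_points)
    }
  }
  do.call(rbind, rows)
}

# hidden-truth table of a sim_truth: every masked cell, with the truth
# taken from the noise-free cluster means ("clean") or the deleted noisy
# draws ("noisy")
sim_hidden_table <- function(st, truth = "clean") {
  src <- if (truth == "clean") st$full_values else st$noisy_values
  out <- list()
  for (rid in names(st$dataset$regions)) {
    r <- st$dataset$regions[[rid]]
    idx <- which(!r$mask, arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[rid]] <- data.frame(
      region_id = rid, subject = r$subject_ids[idx[, 1]],
      position = r$positions[idx[, 2]],
      truth = src[[rid]][idx])
  }
  do.call(rbind, out)
}
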