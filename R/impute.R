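#' Non-negative least squares for stacking two predictors
#'
#' Solves `min_beta || y - X beta ||^2  s.t. beta >= 0` for a small number
#' of columns by exact enumeration of active sets (every subset of columns
#' is tried clamped to zero; the feasible solution with the lowest residual
#' wins, earlier-enumerated subsets breaking exact ties). With two columns
#' this is the stacking problem combining the regional and subject
#' predictions; printed strict positivity constraints are implemented as
#' `>= 0` (the open set has no attained minimum in degenerate cases) and
#' exact zeros are reported as such.
#'
#' @param X Numeric matrix (n x p, p small).
#' @param y Numeric response.
#' @return List: `beta` (length p, >= 0), `sse`.
#' @export
nnls_fit <- function(X, y) {
  X <- as.matrix(X); p <- ncol(X)
  stopifnot(p >= 1, nrow(X) == length(y))
  best <- list(beta = rep(0, p), sse = sum(y^2))
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  # larger active sets first; within a size, lower column indices first, so
  # exact ties resolve deterministically toward the first predictor
  subsets <- subsets[order(-lengths(subsets))]
  for (active in subsets) {
    Xa <- X[, active, drop = FALSE]
    b <- tryCatch(solve(crossprod(Xa), crossprod(Xa, y)),
                  error = function(e) NULL)
    if (is.null(b) || any(b < 0)) next
    beta <- rep(0, p); beta[active] <- drop(b)
    sse <- sum((y - drop(X %*% beta))^2)
    if (sse < best$sse - 1e-12) best <- list(beta = beta, sse = sse)
  }
  best
}

# units for the regional model: one per subject with >= 1 observed point
region_units <- function(r) {
  xs <- scale_positions(r$positions, r$start, r$end)
  units <- list(); unit_subject <- integer(0)
  for (n in seq_len(nrow(r$values))) {
    obs <- which(r$mask[n, ])
    if (length(obs) >= 1) {
      units[[length(units) + 1]] <- list(x = xs[obs], y = r$values[n, obs])
      unit_subject <- c(unit_subject, n)
    }
  }
  list(units = units, unit_subject = unit_subject, xs = xs)
}

empty_result <- function(dataset) {
  src <- lapply(dataset$regions, function(r) {
    s <- matrix("missing", nrow(r$values), ncol(r$values))
    s[r$mask] <- "observed"
    s
  })
  list(dataset = dataset, source = src,
       regional_values = NULL, subject_values = NULL, fits = list(),
       flags = character(0))
}

#' Regional mixture-model imputation
#'
#' Fits one mixture of RBF regressions per region, clustering the subjects'
#' observed profiles ([mrm_select()] chooses K and lambda), then imputes
#' each subject's missing positions from its assigned component curve.
#' Regions with fewer than 2 subjects having >= 2 observed points are
#' skipped with a warning (cells left missing). Subjects with no observed
#' point in a region receive the population mean curve (flagged).
#'
#' @param dataset A [methylation_dataset()].
#' @param config Control list from [mrm_control()]; entries `rbf_centers`,
#'   `rbf_scale`, `K_max`, `lambda_grid` may be added to override defaults.
#' @param seed Integer seed.
#' @return An `imputation_result`: `dataset` (filled), `source` (per-cell
#'   tags), `fits` (per-region fit summaries), `flags`.
#' @export
impute_regional <- function(dataset, config = mrm_control(), seed = 1) {
  basis <- rbf_basis(config$rbf_centers %||% 50, config$rbf_scale %||% 10)
  res <- empty_result(dataset)
  for (rid in names(dataset$regions)) {
    r <- dataset$regions[[rid]]
    ru <- region_units(r)
    n_usable <- sum(vapply(ru$units, function(u) length(u$x) >= 2, logical(1)))
    if (n_usable < 2) {
      warning("region ", rid, " skipped: fewer than 2 subjects with >= 2 ",
              "observed points")
      next
    }
    fit <- mrm_select(ru$units, basis, K_max = config$K_max,
                      lambda_grid = config$lambda_grid, seed = seed,
                      control = config)
    for (n in seq_len(nrow(r$values))) {
      miss <- which(!r$mask[n, ])
      if (!length(miss)) next
      ui <- match(n, ru$unit_subject)
      vals <- mrm_impute_unit(fit, ui, ru$xs[miss], config$assignment,
                              config$clip)
      if (is.na(ui))
        res$flags <- c(res$flags, paste0(rid, ":", r$subject_ids[n],
                                         ":no_observed_data"))
      r$values[n, miss] <- vals
      res$source[[rid]][n, miss] <- "regional"
    }
    res$dataset$regions[[rid]] <- r
    res$fits[[rid]] <- list(K = fit$K, lambda = fit$lambda, icl = fit$icl,
                            n_iter = fit$n_iter, converged = fit$converged)
  }
  class(res) <- "imputation_result"
  res
}

#' Subject-level mixture-model imputation
#'
#' For each subject, the units are that subject's regions (each region's
#' positions scaled to \[-1, 1\] independently so profiles are comparable);
#' the mixture clusters regions and each region's missing positions are
#' imputed from its assigned component curve. Subjects with fewer than 2
#' regions having >= 2 observed points are left unimputed and flagged
#' (callers fall back to the regional model).
#'
#' @inheritParams impute_regional
#' @return An `imputation_result`.
#' @export
impute_subject <- function(dataset, config = mrm_control(), seed = 1) {
  basis <- rbf_basis(config$rbf_centers %||% 50, config$rbf_scale %||% 10)
  res <- empty_result(dataset)
  rids <- names(dataset$regions)
  xs_list <- lapply(dataset$regions, function(r)
    scale_positions(r$positions, r$start, r$end))
  for (n in seq_len(n_subjects(dataset))) {
    units <- list(); unit_region <- character(0)
    for (rid in rids) {
      r <- dataset$regions[[rid]]
      obs <- which(r$mask[n, ])
      if (length(obs) >= 2) {
        units[[length(units) + 1]] <-
          list(x = xs_list[[rid]][obs], y = r$values[n, obs])
        unit_region <- c(unit_region, rid)
      }
    }
    if (length(units) < 2) {
      res$flags <- c(res$flags,
                     paste0(subject_ids(dataset)[n], ":too_few_regions"))
      next
    }
    fit <- mrm_select(units, basis, K_max = config$K_max,
                      lambda_grid = config$lambda_grid, seed = seed,
                      control = config)
    for (rid in rids) {
      r <- res$dataset$regions[[rid]]
      miss <- which(!r$mask[n, ])
      if (!length(miss)) next
      ui <- match(rid, unit_region)
      vals <- mrm_impute_unit(fit, ui, xs_list[[rid]][miss],
                              config$assignment, config$clip)
      r$values[n, miss] <- vals
      res$source[[rid]][n, miss] <- "subject"
      res$dataset$regions[[rid]] <- r
    }
    res$fits[[subject_ids(dataset)[n]]] <-
      list(K = fit$K, lambda = fit$lambda, icl = fit$icl,
           n_iter = fit$n_iter, converged = fit$converged)
  }
  class(res) <- "imputation_result"
  res
}

# mask an artificial fraction of OBSERVED cells (disjoint from true missing)
mask_artificial <- function(dataset, frac) {
  hidden <- list()
  for (rid in names(dataset$regions)) {
    r <- dataset$regions[[rid]]
    for (n in seq_len(nrow(r$values))) {
      obs <- which(r$mask[n, ])
      n_hide <- min(floor(frac * length(obs)), max(0L, length(obs) - 2L))
      if (n_hide < 1) next
      hide <- sample(obs, n_hide)
      hidden[[length(hidden) + 1]] <- data.frame(
        region_id = rid, subject = n, col = hide, truth = r$values[n, hide])
      r$mask[n, hide] <- FALSE
      r$values[n, hide] <- NA_real_
    }
    dataset$regions[[rid]] <- r
  }
  list(dataset = dataset, hidden = do.call(rbind, hidden))
}

lookup_cells <- function(result, hidden) {
  vapply(seq_len(nrow(hidden)), function(i)
    result$dataset$regions[[hidden$region_id[i]]]$values[hidden$subject[i],
                                                         hidden$col[i]],
    numeric(1))
}

#' Fit non-negative stacking weights by bootstrap
#'
#' Each bootstrap replicate hides `artificial_frac` of the observed cells
#' (never overlapping truly missing cells), runs both the regional and the
#' subject model on the reduced data, and solves the non-negative
#' least-squares problem regressing the hidden truths on the two
#' predictions (no intercept). The reported weights are the means over
#' `n_boot` replicates.
#'
#' @inheritParams impute_regional
#' @param n_boot Bootstrap replicates (reference setting 100).
#' @param artificial_frac Fraction of observed cells hidden per replicate.
#' @return A `stacking_weights` object: `beta_r`, `beta_s`, `n_boot`,
#'   `per_boot` (n_boot x 2 matrix).
#' @export
fit_stacking <- function(dataset, config = mrm_control(), n_boot = 100,
                         artificial_frac = 0.1, seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  per_boot <- matrix(NA_real_, n_boot, 2,
                     dimnames = list(NULL, c("beta_r", "beta_s")))
  for (b in seq_len(n_boot)) {
    art <- with_seed(seed + b - 1, mask_artificial(dataset, artificial_frac))
    reg <- suppressWarnings(impute_regional(art$dataset, config, seed))
    sub <- suppressWarnings(impute_subject(art$dataset, config, seed))
    yr <- lookup_cells(reg, art$hidden)
    ys <- lookup_cells(sub, art$hidden)
    ok <- !is.na(yr) & !is.na(ys)
    if (sum(ok) < 2) next
    per_boot[b, ] <- nnls_fit(cbind(yr[ok], ys[ok]), art$hidden$truth[ok])$beta
  }
  ok <- stats::complete.cases(per_boot)
  if (!any(ok)) stop("stacking failed on every bootstrap replicate")
  structure(list(beta_r = mean(per_boot[ok, 1]),
                 beta_s = mean(per_boot[ok, 2]),
                 n_boot = n_boot, per_boot = per_boot),
            class = "stacking_weights")
}

#' @export
print.stacking_weights <- function(x, ...) {
  cat(sprintf("<stacking_weights> beta_r=%.3f beta_s=%.3f (%d bootstraps)\n",
              x$beta_r, x$beta_s, x$n_boot))
  invisible(x)
}

#' Stacked imputation (regional + subject models)
#'
#' Runs both component models, learns non-negative stacking weights by
#' [fit_stacking()] (or uses supplied `weights`), and fills each missing
#' cell with `clip(beta_r * yhat_regional + beta_s * yhat_subject)`. Cells
#' where only the regional prediction exists (e.g. a subject with too few
#' regions for the subject model) keep the regional value.
#'
#' @inheritParams fit_stacking
#' @param weights Optional pre-fitted `stacking_weights`.
#' @return An `imputation_result` with `regional_values` and
#'   `subject_values` holding the component predictions and `weights` the
#'   stacking weights used.
#' @export
impute_stacked <- function(dataset, config = mrm_control(), n_boot = 100,
                           artificial_frac = 0.1, seed = 1, weights = NULL) {
  if (is.null(weights))
    weights <- fit_stacking(dataset, config, n_boot, artificial_frac, seed)
  reg <- suppressWarnings(impute_regional(dataset, config, seed))
  sub <- suppressWarnings(impute_subject(dataset, config, seed))
  res <- reg
  res$weights <- weights
  res$regional_values <- lapply(reg$dataset$regions, function(r) r$values)
  res$subject_values <- lapply(sub$dataset$regions, function(r) r$values)
  for (rid in names(dataset$regions)) {
    r0 <- dataset$regions[[rid]]
    miss <- which(!r0$mask, arr.ind = TRUE)
    if (!nrow(miss)) next
    vr <- reg$dataset$regions[[rid]]$values[miss]
    vs <- sub$dataset$regions[[rid]]$values[miss]
    stacked <- ifelse(is.na(vs) | is.na(vr), vr,
                      clip01(weights$beta_r * vr + weights$beta_s * vs))
    res$dataset$regions[[rid]]$values[miss] <- stacked
    res$source[[rid]][miss] <-
      ifelse(is.na(vs) & !is.na(vr), "regional",
             ifelse(is.na(vr), "missing", "stacked"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
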