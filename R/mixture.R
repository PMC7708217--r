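#' Control parameters for mixture-regression fitting
#'
#' @param em_tol Relative change of the penalized log-likelihood below which
#'   EM stops.
#' @param em_max_iter Maximum EM iterations.
#' @param restarts Number of EM restarts (seeds `seed .. seed+restarts-1`);
#'   the restart with the best penalized log-likelihood is kept.
#' @param cv_restarts,cv_max_iter Cheaper settings used for the fold fits
#'   inside lambda cross-validation (fold fits only rank lambda values, they
#'   are not the final estimates).
#' @param ridge Tiny ridge added to every weighted Gram matrix so the
#'   coordinate-descent M-step is well-posed when a cluster sees fewer CpGs
#'   than basis functions.
#' @param assignment `"hard"` (argmax responsibility, the default) or
#'   `"soft"` (responsibility-weighted mixture) imputation.
#' @param clip Clip imputed values into \[0, 1\].
#' @param n_folds Folds for lambda cross-validation.
#' @param init_ridge Ridge used only for the per-unit least-squares
#'   coefficients that seed k-means++ initialization.
#' @return Named list of control values.
#' @export
mrm_control <- function(em_tol = 1e-6, em_max_iter = 200, restarts = 5,
                        cv_restarts = 2, cv_max_iter = 60, ridge = 1e-8,
                        assignment = c("hard", "soft"), clip = TRUE,
                        n_folds = 10, init_ridge = 1e-3) {
  list(em_tol = em_tol, em_max_iter = em_max_iter, restarts = restarts,
       cv_restarts = cv_restarts, cv_max_iter = cv_max_iter, ridge = ridge,
       assignment = match.arg(assignment), clip = clip, n_folds = n_folds,
       init_ridge = init_ridge)
}

# k-means++ seeded clustering of rows of X into K groups; falls back to a
# random assignment when kmeans cannot run (e.g. duplicate rows).
kmeanspp_assign <- function(X, K) {
  n <- nrow(X)
  if (K == 1) return(rep(1L, n))
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (k in 2:K) {
    if (sum(d2) <= 0) centers[k] <- sample.int(n, 1)
    else centers[k] <- sample.int(n, 1, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums((X - matrix(X[centers[k], ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  cl <- tryCatch(
    stats::kmeans(X, centers = X[centers, , drop = FALSE],
                  iter.max = 25)$cluster,
    error = function(e) sample.int(K, n, replace = TRUE))
  cl
}

unit_coefs <- function(units, basis, control) {
  t(vapply(units, function(u)
    rbf_fit(u$x, u$y, basis, ridge = control$init_ridge)$weights,
    numeric(basis$J)))
}

init_responsibilities <- function(units, basis, K, control, coefs = NULL) {
  if (is.null(coefs)) coefs <- unit_coefs(units, basis, control)
  cl <- kmeanspp_assign(coefs, K)
  z <- matrix(0, length(units), K)
  z[cbind(seq_along(units), cl)] <- 1
  # keep every requested cluster alive at the first M-step
  empty <- setdiff(seq_len(K), unique(cl))
  for (k in empty) z[sample.int(length(units), 1), ] <- {
    row <- numeric(K); row[k] <- 1; row
  }
  z
}

stack_units <- function(units) {
  list(H_x = unlist(lapply(units, function(u) u$x)),
       y = unlist(lapply(units, function(u) u$y)),
       unit = rep(seq_along(units) - 1L,
                  vapply(units, function(u) length(u$x), integer(1))))
}

#' Fit a penalized mixture of RBF regressions by EM
#'
#' Each unit (a subject's profile within a region, or one region of a
#' subject) is a set of (scaled position, methylation) pairs. Units are
#' assumed to arise from one of `K` latent regression components with
#' mixing proportions `pi_k`; component curves are linear combinations of
#' the RBF basis and share a Gaussian noise variance. The log-likelihood is
#' penalized by `lambda * sum_k pi_k * ||w_k||_1`, which shrinks component
#' coefficients when observed CpGs are scarce relative to the basis size.
#' The M-step solves each component's responsibility-weighted lasso problem
#' by exact coordinate descent.
#'
#' @param units List of `list(x =, y =)` observed profiles, `x` scaled to
#'   \[-1, 1\].
#' @param basis An [rbf_basis()].
#' @param K Number of mixture components (>= 1). Components whose total
#'   responsibility vanishes are dropped during fitting.
#' @param lambda Non-negative lasso penalty.
#' @param seed Integer seed for initialization restarts.
#' @param control See [mrm_control()].
#' @param z_init Optional responsibility matrix (units x K) to start from;
#'   when given, a single EM run is performed with no restarts (used for
#'   warm starts along the cross-validation lambda path).
#' @return An object of class `mrm_fit`: `K`, `pi`, `weights` (J x K),
#'   `sigma2`, `responsibilities` (units x K), `lambda`, `loglik`
#'   (penalized), `loglik_raw`, `icl`, `entropy`, `converged`, `n_iter`,
#'   `n_dropped`, `n_obs`, `basis`.
#' @export
mrm_fit <- function(units, basis, K, lambda = 0, seed = 1,
                    control = mrm_control(), z_init = NULL) {
  stopifnot(K >= 1, lambda >= 0, length(units) >= 1)
  if (any(vapply(units, function(u) length(u$x), integer(1)) < 1))
    stop("every unit needs at least one observed point")
  if (K > length(units)) {
    warning("K reduced to the number of units (", length(units), ")")
    K <- length(units)
  }
  st <- stack_units(units)
  H <- rbf_design(st$H_x, basis)
  if (!is.null(z_init)) {
    best <- cpp_em_fit(H, st$y, st$unit, length(units), z_init, lambda,
                       control$ridge, control$em_max_iter, control$em_tol)
  } else {
    # short-run/long-run strategy: every restart gets a short EM budget,
    # the best penalized log-likelihood is then run to full convergence
    coefs <- if (K > 1) unit_coefs(units, basis, control) else NULL
    short_iter <- min(50L, control$em_max_iter)
    best <- NULL
    for (r in seq_len(control$restarts)) {
      z0 <- with_seed(seed + r - 1,
                      init_responsibilities(units, basis, K, control, coefs))
      res <- cpp_em_fit(H, st$y, st$unit, length(units), z0, lambda,
                        control$ridge,
                        if (control$restarts > 1) short_iter
                        else control$em_max_iter,
                        control$em_tol)
      if (is.null(best) || res$loglik_pen > best$loglik_pen) best <- res
    }
    if (control$restarts > 1 && !best$converged)
      best <- cpp_em_fit(H, st$y, st$unit, length(units), best$z, lambda,
                         control$ridge, control$em_max_iter, control$em_tol)
  }
  fit <- structure(
    list(K = best$K, pi = drop(best$pi), weights = best$W,
         sigma2 = best$sigma2, responsibilities = best$z, lambda = lambda,
         loglik = best$loglik_pen, loglik_raw = best$loglik,
         entropy = best$entropy, converged = best$converged,
         n_iter = best$n_iter, n_dropped = best$n_dropped,
         n_obs = best$n_obs, trace = best$trace, basis = basis, seed = seed),
    class = "mrm_fit")
  fit$icl <- mrm_icl(fit)
  fit
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf(paste0("<mrm_fit> K=%d | pi=(%s) | sigma2=%.4g | lambda=%.3g",
                     " | loglik=%.2f | ICL=%.2f | %s in %d iter\n"),
              x$K, paste(sprintf("%.2f", x$pi), collapse = ", "), x$sigma2,
              x$lambda, x$loglik,
              x$icl, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' Integrated completed likelihood of a mixture fit
#'
#' `ICL = -2 loglik + p log(n_obs) + 2 * entropy`, where `n_obs` is the
#' total number of observed points and `entropy` is the responsibility
#' entropy `-sum z log z` (0 for hard assignments, so ICL then equals BIC).
#' Computed from the unpenalized log-likelihood; lower is better.
#'
#' Following the convention for l1-penalized mixture regressions, the
#' parameter count `p` is the number of *nonzero* component coefficients
#' plus `K - 1` mixing proportions plus 1 noise variance; at `lambda = 0`
#' every coefficient is nonzero and `p` reduces to the naive
#' `K*J + K - 1 + 1`. Counting all `K*J` coefficients regardless of the
#' penalty makes ICL collapse to `K = 1` whenever observed CpGs are scarce,
#' because each extra cluster is billed `J log(n_obs)` even when the lasso
#' has zeroed most of its coefficients.
#'
#' @param fit An [mrm_fit()].
#' @return Scalar ICL.
#' @export
mrm_icl <- function(fit) {
  p <- sum(abs(fit$weights) > 0) + fit$K - 1 + 1
  -2 * fit$loglik_raw + p * log(fit$n_obs) + 2 * fit$entropy
}

# predict one unit's curve at scaled coordinates
mrm_predict_unit <- function(fit, unit_index, x_new,
                             assignment = "hard", clip = TRUE) {
  Hn <- rbf_design(x_new, fit$basis)
  z <- fit$responsibilities[unit_index, ]
  p <- if (assignment == "hard") drop(Hn %*% fit$weights[, which.max(z)])
       else drop(Hn %*% fit$weights %*% z)
  if (clip) p <- clip01(p)
  p
}

#' Impute a unit's missing positions from a mixture fit
#'
#' Default `"hard"` assignment predicts from the component with the highest
#' responsibility (ties broken by the lowest component index); `"soft"`
#' returns the responsibility-weighted mixture of component curves.
#'
#' @param fit An [mrm_fit()].
#' @param unit_index Index of the unit among those the fit was trained on,
#'   or `NA` for a unit with no observed data, which is imputed by the
#'   mixing-proportion-weighted population mean curve (low confidence,
#'   flagged by attribute `low_confidence`).
#' @param x_missing Scaled coordinates to impute.
#' @param assignment `"hard"` or `"soft"`; defaults to the control default.
#' @param clip Clip into \[0, 1\].
#' @return Numeric vector of imputed values.
#' @export
mrm_impute_unit <- function(fit, unit_index, x_missing,
                            assignment = c("hard", "soft"), clip = TRUE) {
  assignment <- match.arg(assignment)
  if (length(x_missing) == 0) return(numeric(0))
  if (is.na(unit_index)) {
    p <- drop(rbf_design(x_missing, fit$basis) %*% fit$weights %*% fit$pi)
    if (clip) p <- clip01(p)
    attr(p, "low_confidence") <- TRUE
    return(p)
  }
  mrm_predict_unit(fit, unit_index, x_missing, assignment, clip)
}

#' Select the number of components and the lasso penalty
#'
#' For each `K` in `1..K_max`, `lambda` is chosen by cross-validation:
#' observed points are partitioned into folds within each unit (every unit
#' keeps points in every training fold), the model is refitted without the
#' held-out points, and held-out points are scored by squared prediction
#' error. `K` is then chosen by the lowest [mrm_icl()] among the per-K
#' refits at their selected `lambda` (ties favour smaller `K`; ties in the
#' CV error favour smaller `lambda`).
#'
#' @param units,basis,seed,control As in [mrm_fit()].
#' @param K_max Maximum components; default `min(10, max(2, floor(N/5)))`
#'   with `N` the number of units (at least ~5 expected units per
#'   component).
#' @param lambda_grid Penalty grid; default 8 values log-spaced over
#'   `[1e-4, 1] * sd(y)`.
#' @return The winning `mrm_fit`, with attributes `cv_table` (K, lambda,
#'   cv_mse) and `icl_table` (K, lambda, icl).
#' @export
mrm_select <- function(units, basis, K_max = NULL, lambda_grid = NULL,
                       seed = 1, control = mrm_control()) {
  N <- length(units)
  if (is.null(K_max)) K_max <- min(10L, max(2L, floor(N / 5)))
  K_max <- min(K_max, N)
  if (is.null(lambda_grid)) {
    sdy <- stats::sd(unlist(lapply(units, function(u) u$y)))
    if (!is.finite(sdy) || sdy <= 0) sdy <- 1
    lambda_grid <- 10^seq(-4, 0, length.out = 8) * sdy
  }
  folds <- with_seed(seed, lapply(units, function(u) {
    p <- length(u$x)
    if (p < 2) return(rep(NA_integer_, p)) # always kept in training
    sample(rep_len(seq_len(control$n_folds), p))
  }))
  cv_control <- control
  cv_control$restarts <- control$cv_restarts
  cv_control$em_max_iter <- control$cv_max_iter

  cv_rows <- list(); icl_rows <- list(); fits <- list()
  for (K in seq_len(K_max)) {
    fold_mse <- cv_lambda_path(units, basis, K, lambda_grid, folds, seed,
                               cv_control)
    cv_mse <- rowMeans(fold_mse)
    ok <- which(is.finite(cv_mse))
    if (!length(ok)) next
    # one-standard-error rule: the largest lambda whose CV error is within
    # one SE of the minimum (sparsest model of comparable predictive power)
    i_min <- ok[which.min(cv_mse[ok])]
    se_min <- stats::sd(fold_mse[i_min, ]) / sqrt(ncol(fold_mse))
    if (!is.finite(se_min)) se_min <- 0
    within <- ok[cv_mse[ok] <= cv_mse[i_min] + se_min]
    lam_best <- max(lambda_grid[within])
    fit <- tryCatch(mrm_fit(units, basis, K, lam_best, seed, control),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cv_rows[[K]] <- data.frame(K = K, lambda = lambda_grid, cv_mse = cv_mse)
    icl_rows[[K]] <- data.frame(K = K, lambda = lam_best, icl = fit$icl)
    fits[[K]] <- fit
  }
  if (!length(Filter(Negate(is.null), fits)))
    stop("model selection failed: no candidate fit succeeded")
  icl_tab <- do.call(rbind, Filter(Negate(is.null), icl_rows))
  winner <- fits[[icl_tab$K[which.min(icl_tab$icl)]]]
  attr(winner, "cv_table") <- do.call(rbind, Filter(Negate(is.null), cv_rows))
  attr(winner, "icl_table") <- icl_tab
  winner
}

# Held-out squared error for every lambda at one K, fold by fold; returns
# an n_lambda x n_folds matrix of per-fold MSEs (Inf where a fit failed).
# Within a fold the grid is traversed from the largest lambda down, each fit
# warm-started from the previous one's responsibilities; only the first fit
# of a fold pays for multiple initializations.
cv_lambda_path <- function(units, basis, K, lambda_grid, folds, seed,
                           control) {
  n_folds <- max(unlist(folds), na.rm = TRUE)
  ord <- order(lambda_grid, decreasing = TRUE)
  se <- n_se <- matrix(0, length(lambda_grid), n_folds)
  failed <- matrix(FALSE, length(lambda_grid), n_folds)
  for (f in seq_len(n_folds)) {
    train <- vector("list", length(units)); ho <- vector("list", length(units))
    for (i in seq_along(units)) {
      out <- which(!is.na(folds[[i]]) & folds[[i]] == f)
      keep <- setdiff(seq_along(units[[i]]$x), out)
      train[[i]] <- list(x = units[[i]]$x[keep], y = units[[i]]$y[keep])
      ho[[i]] <- list(x = units[[i]]$x[out], y = units[[i]]$y[out])
    }
    usable <- vapply(train, function(u) length(u$x) > 0, logical(1))
    tu <- train[usable]
    Keff <- min(K, length(tu))
    st <- stack_units(tu)
    H <- rbf_design(st$H_x, basis)
    coefs <- if (Keff > 1) unit_coefs(tu, basis, control) else NULL
    z_prev <- NULL
    idx_map <- cumsum(usable)
    for (li in ord) {
      lam <- lambda_grid[li]
      res <- NULL
      if (!is.null(z_prev)) {
        res <- tryCatch(
          cpp_em_fit(H, st$y, st$unit, length(tu), z_prev, lam,
                     control$ridge, control$em_max_iter, control$em_tol),
          error = function(e) NULL)
      } else {
        for (r in seq_len(control$restarts)) {
          z0 <- with_seed(seed + r - 1,
                          init_responsibilities(tu, basis, Keff, control,
                                                coefs))
          cand <- tryCatch(
            cpp_em_fit(H, st$y, st$unit, length(tu), z0, lam,
                       control$ridge, control$em_max_iter, control$em_tol),
            error = function(e) NULL)
          if (!is.null(cand) &&
              (is.null(res) || cand$loglik_pen > res$loglik_pen)) res <- cand
        }
      }
      if (is.null(res)) { failed[li, f] <- TRUE; next }
      z_prev <- res$z
      for (i in which(usable)) {
        if (!length(ho[[i]]$x)) next
        zrow <- res$z[idx_map[i], ]
        Hn <- rbf_design(ho[[i]]$x, basis)
        pred <- if (control$assignment == "hard")
          drop(Hn %*% res$W[, which.max(zrow)])
        else drop(Hn %*% res$W %*% zrow)
        if (control$clip) pred <- clip01(pred)
        se[li, f] <- se[li, f] + sum((pred - ho[[i]]$y)^2)
        n_se[li, f] <- n_se[li, f] + length(pred)
      }
    }
  }
  ifelse(failed | n_se == 0, Inf, se / pmax(n_se, 1))
}
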