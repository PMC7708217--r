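#' Map genomic coordinates into the model's [-1, 1] interval
#'
#' Affine map sending `start` to -1 and `end` to +1; CpG order is preserved.
#'
#' @param positions Genomic coordinates within `[start, end]`.
#' @param start,end Region bounds, `start < end`.
#' @return Numeric vector of scaled coordinates in \[-1, 1\].
#' @export
scale_positions <- function(positions, start, end) {
  if (end <= start) stop("degenerate region: start must be < end")
  if (any(positions < start | positions > end))
    stop("positions must lie within [start, end]")
  2 * (positions - start) / (end - start) - 1
}

#' Radial basis function system over [-1, 1]
#'
#' Gaussian bumps `h_j(x) = exp(-scale * (x - mu_j)^2)` with `n_centers`
#' centers equally spaced over \[-1, 1\]. Defaults (50 centers, scale 10)
#' give bumps with sd ~0.22 on the scaled axis, a localized but overlapping
#' basis for 50-CpG regions.
#'
#' @param n_centers Number of centers J (>= 1).
#' @param scale Positive rate inside the exponential. (Conventions differ on
#'   the sign: a "scale of -10" with the exponent written `exp(gamma r^2)`
#'   is the same basis; only the positive-rate form is localized.)
#' @return An object of class `rbf_basis` with fields `centers`, `scale`, `J`.
#' @export
rbf_basis <- function(n_centers = 50, scale = 10) {
  stopifnot(n_centers >= 1, scale > 0)
  centers <- if (n_centers == 1) 0 else seq(-1, 1, length.out = n_centers)
  structure(list(centers = centers, scale = scale, J = as.integer(n_centers)),
            class = "rbf_basis")
}

#' @export
print.rbf_basis <- function(x, ...) {
  cat(sprintf("<rbf_basis> %d centers on [-1, 1], scale %.3g\n", x$J, x$scale))
  invisible(x)
}

#' RBF design matrix
#'
#' @param x Scaled coordinates in \[-1, 1\].
#' @param basis An [rbf_basis()].
#' @return `length(x)` x `J` matrix with entries
#'   `exp(-scale * (x_i - mu_j)^2)`, all in (0, 1\].
#' @export
rbf_design <- function(x, basis) {
  stopifnot(inherits(basis, "rbf_basis"))
  exp(-basis$scale * outer(x, basis$centers, `-`)^2)
}

#' Least-squares fit of a single methylation profile
#'
#' Solves the (optionally ridge-stabilized) normal equation
#' `(H'H + ridge I) w = H'y`. With more centers than observed CpGs the plain
#' normal equation is rank-deficient; the tiny default ridge keeps the solve
#' well-posed without noticeably biasing the fit.
#'
#' @param x Scaled coordinates of observed CpGs.
#' @param y Observed methylation levels.
#' @param basis An [rbf_basis()].
#' @param ridge Non-negative ridge term; `0` requests the exact normal
#'   equation and signals a `mrm_rank_deficient` error if singular.
#' @return An object of class `rbf_fit` with `weights`, `basis`,
#'   `residual_sse`.
#' @export
rbf_fit <- function(x, y, basis, ridge = 1e-8) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  H <- rbf_design(x, basis)
  A <- crossprod(H)
  if (ridge > 0) diag(A) <- diag(A) + ridge
  w <- tryCatch(solve(A, crossprod(H, y)),
                error = function(e)
                  stop(structure(class = c("mrm_rank_deficient", "error",
                                           "condition"),
                                 list(message = paste0(
                                   "normal equation is rank-deficient; ",
                                   "retry with ridge > 0"),
                                   call = sys.call(-1)))))
  w <- drop(w)
  structure(list(weights = w, basis = basis,
                 residual_sse = sum((y - drop(H %*% w))^2)),
            class = "rbf_fit")
}

#' Predict methylation levels from a fitted RBF profile
#'
#' @param object An [rbf_fit()].
#' @param x_new Scaled coordinates.
#' @param clip Clip predictions into \[0, 1\] (methylation is a proportion;
#'   the linear model itself is unconstrained). Default `TRUE`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rbf_fit <- function(object, x_new, clip = TRUE, ...) {
  p <- drop(rbf_design(x_new, object$basis) %*% object$weights)
  if (clip) p <- clip01(p)
  p
}
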