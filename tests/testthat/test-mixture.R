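test_that("single-component fit with no penalty is the pooled normal equation", {
  b <- rbf_basis(8, 6)
  withr::with_seed(5, {
    units <- lapply(1:4, function(i) {
      x <- sort(runif(12, -1, 1))
      list(x = x, y = runif(12))
    })
  })
  f <- mrm_fit(units, b, K = 1, lambda = 0, seed = 1)
  pooled <- rbf_fit(unlist(lapply(units, `[[`, "x")),
                    unlist(lapply(units, `[[`, "y")), b, ridge = 1e-8)
  expect_equal(drop(f$weights), pooled$weights, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f$pi, 1)
})

test_that("EM separates well-separated flat profiles exactly", {
  units <- flat_units()
  f <- mrm_fit(units, rbf_basis(10, 10), K = 2, lambda = 0.001, seed = 1)
  hard <- apply(f$responsibilities, 1, which.max)
  truth <- rep(1:2, each = 10)
  expect_equal(mclust::adjustedRandIndex(hard, truth), 1)
  expect_equal(sum(f$pi), 1, tolerance = 1e-10)
  expect_true(all(f$pi >= 0))
  expect_equal(rowSums(f$responsibilities), rep(1, 20), tolerance = 1e-10)
  expect_gt(f$sigma2, 0)
})

test_that("the penalized objective is monotone non-decreasing across EM iterations", {
  withr::with_seed(21, {
    for (case in 1:4) {
      K <- sample(2:4, 1)
      units <- lapply(seq_len(10 + 2 * case), function(i) {
        x <- sort(runif(sample(5:20, 1), -1, 1))
        list(x = x, y = runif(length(x)))
      })
      f <- mrm_fit(units, rbf_basis(12, 10), K = K, lambda = 0.05,
                   seed = case, control = mrm_control(restarts = 1))
      tr <- f$trace
      expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)),
                  label = sprintf("monotone trace, case %d", case))
      expect_gte(tr[length(tr)], tr[1] - 1e-8)
    }
  })
})

test_that("loglik, ICL and imputations are invariant to component relabelling", {
  units <- flat_units(sd = 0.05)
  f <- mrm_fit(units, rbf_basis(10, 10), K = 2, lambda = 0.01, seed = 1)
  perm <- f
  perm$weights <- f$weights[, 2:1]
  perm$pi <- f$pi[2:1]
  perm$responsibilities <- f$responsibilities[, 2:1]
  expect_equal(mrm_icl(perm), mrm_icl(f))
  x_new <- c(-0.5, 0.2, 0.9)
  for (u in c(1, 5, 15))
    expect_equal(mrm_impute_unit(perm, u, x_new),
                 mrm_impute_unit(f, u, x_new))
})

test_that("a huge penalty drives all component coefficients to zero", {
  units <- flat_units(sd = 0.05)
  f <- mrm_fit(units, rbf_basis(10, 10), K = 2, lambda = 1e6, seed = 1)
  expect_equal(max(abs(f$weights)), 0)
})

test_that("ICL instantiates as BIC plus twice the assignment entropy", {
  units <- flat_units(sd = 0.01)
  f <- mrm_fit(units, rbf_basis(6, 5), K = 2, lambda = 0.001, seed = 1)
  # separation is extreme: responsibilities are numerically hard
  expect_lt(f$entropy, 1e-6)
  p <- sum(abs(f$weights) > 0) + f$K - 1 + 1
  bic <- -2 * f$loglik_raw + p * log(f$n_obs)
  expect_equal(f$icl, bic, tolerance = 1e-4)
  # K = 1 at lambda = 0: dense weights, p = J + 1
  f1 <- mrm_fit(units[1:10], rbf_basis(6, 5), K = 1, lambda = 0, seed = 1)
  expect_equal(f1$icl,
               -2 * f1$loglik_raw + (6 + 1) * log(f1$n_obs) + 2 * f1$entropy,
               tolerance = 1e-8)
})

test_that("mixing proportions and assignments are recovered at N = 200", {
  st <- simulate_mrm(sim_config(n_regions = 1, n_cpg = 50, n_subjects = 200,
                                cluster_props = c(0.1, 0.2, 0.3, 0.4),
                                noise_sd = 0.1, missing_rate = 0, seed = 7))
  r <- st$dataset$regions[[1]]
  xs <- scale_positions(r$positions, r$start, r$end)
  units <- lapply(1:200, function(n) list(x = xs, y = r$values[n, ]))
  sdy <- sd(r$values)
  f <- mrm_fit(units, rbf_basis(50, 10), K = 4, lambda = 0.1 * sdy, seed = 1)
  expect_lt(max(abs(sort(f$pi) - c(0.1, 0.2, 0.3, 0.4))), 0.05)
  hard <- apply(f$responsibilities, 1, which.max)
  expect_gte(mclust::adjustedRandIndex(hard, st$labels[[1]]), 0.9)
})

test_that("noise-free single-cluster data needs no shrinkage under CV", {
  b <- rbf_basis(5, 4)
  w0 <- c(0.4, 0.1, 0.6, 0.3, 0.5)
  units <- lapply(1:8, function(i) {
    x <- seq(-1, 1, length.out = 12)
    list(x = x, y = drop(rbf_design(x, b) %*% w0))
  })
  fit <- mrm_select(units, b, K_max = 1, lambda_grid = c(1e-4, 0.1, 1),
                    seed = 1)
  cv <- attr(fit, "cv_table")
  expect_equal(cv$cv_mse[which.min(cv$lambda)], min(cv$cv_mse),
               tolerance = 1e-10)
})

test_that("model selection picks enough components on clustered data", {
  st <- simulate_mrm(sim_config(n_regions = 1, n_cpg = 50, n_subjects = 40,
                                cluster_props = c(0.25, 0.25, 0.25, 0.25),
                                noise_sd = 0.1, missing_rate = 0.2, seed = 3))
  r <- st$dataset$regions[[1]]
  xs <- scale_positions(r$positions, r$start, r$end)
  units <- lapply(1:40, function(n) {
    obs <- which(r$mask[n, ])
    list(x = xs[obs], y = r$values[n, obs])
  })
  fit <- mrm_select(units, rbf_basis(50, 10), K_max = 8, seed = 1)
  expect_gte(fit$K, 3)
  hard <- apply(fit$responsibilities, 1, which.max)
  expect_gte(mclust::adjustedRandIndex(hard, st$labels[[1]]), 0.85)
})

test_that("unit imputation clips, honours assignments and handles empty units", {
  units <- flat_units(sd = 0.05)
  f <- mrm_fit(units, rbf_basis(10, 10), K = 2, lambda = 0.01, seed = 1)
  x_new <- seq(-1, 1, length.out = 7)
  v_hard <- mrm_impute_unit(f, 1, x_new)
  v_soft <- mrm_impute_unit(f, 1, x_new, assignment = "soft")
  expect_true(all(v_hard >= 0 & v_hard <= 1))
  expect_true(all(v_soft >= 0 & v_soft <= 1))
  # group 1 sits near 0.1, group 2 near 0.9
  expect_lt(max(abs(v_hard - 0.1)), 0.1)
  expect_lt(max(abs(mrm_impute_unit(f, 15, x_new) - 0.9)), 0.1)
  # a unit with no observed data gets the population mean curve, flagged
  v_pop <- mrm_impute_unit(f, NA, x_new)
  expect_true(isTRUE(attr(v_pop, "low_confidence")))
  pop_curve <- drop(rbf_design(x_new, f$basis) %*% f$weights %*% f$pi)
  expect_equal(as.numeric(v_pop), pmin(1, pmax(0, pop_curve)),
               tolerance = 1e-12)
  expect_length(mrm_impute_unit(f, 1, numeric(0)), 0)
})

test_that("K exceeding the unit count is reduced with a warning", {
  units <- flat_units(n_per = 2)
  expect_warning(f <- mrm_fit(units, rbf_basis(6, 5), K = 10, lambda = 0.01,
                              seed = 1), "reduced")
  expect_lte(f$K, 4)
})
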