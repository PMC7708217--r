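test_that("non-negative least squares matches an active-set oracle", {
  withr::with_seed(14, {
    for (rep in 1:100) {
      n <- sample(5:40, 1)
      X <- cbind(runif(n), runif(n))
      beta_true <- c(runif(1, -0.5, 1.5), runif(1, -0.5, 1.5))
      y <- drop(X %*% beta_true) + rnorm(n, 0, 0.05)
      ours <- nnls_fit(X, y)
      oracle <- pracma::lsqnonneg(X, y)
      expect_true(all(ours$beta >= 0))
      expect_equal(ours$beta, oracle$x, tolerance = 1e-7,
                   ignore_attr = TRUE)
      expect_equal(ours$sse, oracle$resid.norm, tolerance = 1e-7)
    }
  })
})

test_that("NNLS recognises a perfect first predictor and collinearity", {
  withr::with_seed(15, {
    y <- runif(200)
    X <- cbind(y, runif(200)) # first column is the truth itself
  })
  fit <- nnls_fit(X, y)
  expect_lt(abs(fit$beta[1] - 1), 0.05)
  expect_lt(fit$beta[2], 0.05)
  # collinear predictors: combined weight equals the optimal single scalar
  Xc <- cbind(y * 0.5, y * 0.5)
  fitc <- nnls_fit(Xc, y)
  expect_equal(sum(fitc$beta) * 0.5, 1, tolerance = 1e-8)
  expect_true(all(fitc$beta >= 0))
})

test_that("a fully observed dataset passes through regional imputation", {
  st <- simulate_mrm(sim_config(n_regions = 2, n_cpg = 15, n_subjects = 6,
                                noise_sd = 0.1, missing_rate = 0, seed = 3))
  res <- impute_regional(st$dataset, mrm_control(), seed = 1)
  for (rid in names(st$dataset$regions)) {
    expect_equal(res$dataset$regions[[rid]]$values,
                 st$dataset$regions[[rid]]$values)
    expect_true(all(res$source[[rid]] == "observed"))
  }
})

test_that("regional imputation recovers two-cluster structure accurately", {
  st <- simulate_mrm(sim_config(n_regions = 1, n_cpg = 50, n_subjects = 20,
                                cluster_props = c(0.5, 0.5), noise_sd = 0.1,
                                missing_rate = 0.2, seed = 6))
  res <- impute_regional(st$dataset, mrm_control(), seed = 1)
  hid <- methylMRM:::sim_hidden_table(st, "clean")
  expect_gte(mean_subject_correlation(res, hid), 0.9)
  # observed cells are never modified
  r0 <- st$dataset$regions[[1]]
  expect_equal(res$dataset$regions[[1]]$values[r0$mask], r0$values[r0$mask])
  expect_true(all(res$dataset$regions[[1]]$values >= 0 &
                    res$dataset$regions[[1]]$values <= 1))
})

test_that("regions too sparse for the regional model are skipped", {
  vals <- matrix(c(0.1, NA, NA, 0.2, NA, NA), 2, 3) # 1 usable subject
  ds <- methylation_dataset(list(
    region_matrix("chr1", c(1, 11, 21), vals, region_id = "thin")))
  expect_warning(res <- impute_regional(ds, mrm_control(), seed = 1),
                 "skipped")
  expect_true(anyNA(res$dataset$regions[["thin"]]$values))
})

test_that("the subject model recovers a shared cross-region curve", {
  # every region of a subject follows the same curve: the subject model can
  # pool regions to fill heavy per-region missingness
  withr::with_seed(44, {
    b <- rbf_basis(12, 10)
    xs <- seq(-1, 1, length.out = 30)
    H <- rbf_design(xs, b)
    regions <- lapply(1:6, function(m) {
      vals <- t(vapply(1:4, function(n) {
        curve <- methylMRM:::rescale_curve(drop(H %*% sin(n + 1:12)))
        pmin(1, pmax(0, curve + rnorm(30, 0, 0.1)))
      }, numeric(30)))
      mask <- matrix(TRUE, 4, 30)
      for (n in 1:4) mask[n, sample(30, 12)] <- FALSE
      vals[!mask] <- NA
      region_matrix("chr1", seq(1, by = 10, length.out = 30) + m * 1000,
                    vals, mask = mask, region_id = paste0("m", m))
    })
    ds <- methylation_dataset(regions)
  })
  res <- impute_subject(ds, mrm_control(), seed = 1)
  cors <- vapply(1:4, function(n) {
    curve <- methylMRM:::rescale_curve(drop(rbf_design(
      seq(-1, 1, length.out = 30), rbf_basis(12, 10)) %*% sin(n + 1:12)))
    imp <- unlist(lapply(res$dataset$regions, function(r) {
      miss <- which(!ds$regions[[r$region_id]]$mask[n, ])
      r$values[n, miss]
    }))
    tr <- unlist(lapply(res$dataset$regions, function(r) {
      curve[which(!ds$regions[[r$region_id]]$mask[n, ])]
    }))
    cor(tr, imp)
  }, numeric(1))
  expect_gte(mean(cors), 0.9)
})

test_that("subjects with too few usable regions are flagged, not imputed", {
  vals1 <- rbind(c(0.1, 0.2, 0.3, 0.4), c(NA, 0.5, NA, NA))
  vals2 <- rbind(c(0.5, 0.6, 0.7, 0.8), c(NA, NA, NA, 0.2))
  ds <- methylation_dataset(list(
    region_matrix("chr1", c(1, 11, 21, 31), vals1, region_id = "a"),
    region_matrix("chr1", c(101, 111, 121, 131), vals2, region_id = "b")))
  res <- impute_subject(ds, mrm_control(), seed = 1)
  expect_true(any(grepl("too_few_regions", res$flags)))
  expect_true(anyNA(res$dataset$regions[["a"]]$values[2, ]))
})

test_that("stacking weights are non-negative bootstrap means", {
  st <- simulate_mrm(sim_config(n_regions = 3, n_cpg = 20, n_subjects = 8,
                                noise_sd = 0.15, missing_rate = 0.2,
                                seed = 9))
  w <- fit_stacking(st$dataset, mrm_control(), n_boot = 3,
                    artificial_frac = 0.15, seed = 2)
  expect_gte(w$beta_r, 0)
  expect_gte(w$beta_s, 0)
  ok <- complete.cases(w$per_boot)
  expect_equal(w$beta_r, mean(w$per_boot[ok, 1]))
  expect_equal(w$beta_s, mean(w$per_boot[ok, 2]))
  expect_error(fit_stacking(st$dataset, n_boot = 0), "n_boot")
})

test_that("stacked imputation blends the two models and stays in range", {
  st <- simulate_mrm(sim_config(n_regions = 3, n_cpg = 20, n_subjects = 8,
                                noise_sd = 0.15, missing_rate = 0.3,
                                seed = 10))
  w <- structure(list(beta_r = 1, beta_s = 0, n_boot = 1,
                      per_boot = matrix(c(1, 0), 1)),
                 class = "stacking_weights")
  res <- impute_stacked(st$dataset, mrm_control(), seed = 2, weights = w)
  reg <- impute_regional(st$dataset, mrm_control(), seed = 2)
  for (rid in names(st$dataset$regions))
    expect_equal(res$dataset$regions[[rid]]$values,
                 reg$dataset$regions[[rid]]$values, tolerance = 1e-12)
  # a genuine blend keeps values in [0, 1] and preserves observed cells
  w2 <- structure(list(beta_r = 0.6, beta_s = 0.6, n_boot = 1,
                       per_boot = matrix(c(0.6, 0.6), 1)),
                  class = "stacking_weights")
  res2 <- impute_stacked(st$dataset, mrm_control(), seed = 2, weights = w2)
  for (rid in names(st$dataset$regions)) {
    r0 <- st$dataset$regions[[rid]]
    expect_equal(res2$dataset$regions[[rid]]$values[r0$mask],
                 r0$values[r0$mask])
    expect_true(all(res2$dataset$regions[[rid]]$values >= 0 &
                      res2$dataset$regions[[rid]]$values <= 1))
  }
})
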