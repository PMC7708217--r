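#' Simulation settings for the mixture-model methylation generator
#'
#' Defaults reproduce the generator's reference conditions: 100 independent
#' regions of 50 CpGs, four latent clusters with proportions
#' (0.1, 0.2, 0.3, 0.4), Gaussian noise added to the methylation
#' probabilities, and a fixed fraction of cells masked per subject.
#'
#' @param n_regions Number of regions M.
#' @param n_cpg CpGs per region I.
#' @param n_subjects Subjects N.
#' @param cluster_props Mixing proportions (sum to 1).
#' @param noise_sd Standard deviation of the Gaussian noise on the
#'   probability scale.
#' @param missing_rate Fraction of cells masked per subject per region
#'   (exact count `floor(rate * I)`, without replacement).
#' @param rbf_centers,rbf_scale Basis used both to generate and (by default)
#'   to fit.
#' @param seed Integer seed; the full simulation is a deterministic function
#'   of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 100, n_cpg = 50, n_subjects = 20,
                       cluster_props = c(0.1, 0.2, 0.3, 0.4),
                       noise_sd = 0.2, missing_rate = 0.2,
                       rbf_centers = 50, rbf_scale = 10, seed = 1) {
  stopifnot(abs(sum(cluster_props) - 1) < 1e-8, all(cluster_props >= 0),
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  structure(list(n_regions = n_regions, n_cpg = n_cpg,
                 n_subjects = n_subjects, cluster_props = cluster_props,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 rbf_centers = rbf_centers, rbf_scale = rbf_scale,
                 seed = seed), class = "sim_config")
}

# rescale a curve into [lo, hi]; a flat curve maps to its midpoint
rescale_curve <- function(v, lo = 0.05, hi = 0.95) {
  rng <- range(v)
  if (diff(rng) < 1e-12) return(rep((lo + hi) / 2, length(v)))
  lo + (v - rng[1]) / diff(rng) * (hi - lo)
}

#' Simulate methylation data from the mixture of RBF regressions
#'
#' Per region: K cluster coefficient vectors are drawn i.i.d. standard
#' normal; cluster mean curves are the RBF expansions on `n_cpg` equally
#' spaced positions, affinely rescaled into \[0.05, 0.95\] so each is a
#' valid probability profile; subjects are assigned to clusters from
#' `Multinomial(cluster_props)` independently per region; cell-level
#' Gaussian noise is added and values are clipped to \[0, 1\]; finally
#' `floor(missing_rate * n_cpg)` cells per subject are masked uniformly at
#' random.
#'
#' CpGs are placed 10 bp apart; regions are laid out end to end on a
#' synthetic chromosome `chrS`.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `dataset` (masked [methylation_dataset()]),
#'   `full_values` / `noisy_values` (per-region matrices before masking),
#'   `labels` (per-region true cluster assignment of each subject),
#'   `cluster_curves` (per-region K x I mean curves), `config`,
#'   `n_clipped` (cells clipped after noise).
#' @export
simulate_mrm <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    basis <- rbf_basis(config$rbf_centers, config$rbf_scale)
    K <- length(config$cluster_props)
    I <- config$n_cpg; N <- config$n_subjects
    xs <- seq(-1, 1, length.out = I)
    H <- rbf_design(xs, basis)
    n_mask <- floor(config$missing_rate * I)
    regions <- vector("list", config$n_regions)
    full <- noisy <- curves <- labels <- vector("list", config$n_regions)
    n_clipped <- 0L
    for (m in seq_len(config$n_regions)) {
      W <- matrix(rnorm(basis$J * K), basis$J, K)
      cc <- t(apply(H %*% W, 2, rescale_curve)) # K x I
      lab <- sample.int(K, N, replace = TRUE, prob = config$cluster_props)
      mu <- cc[lab, , drop = FALSE]
      noise <- matrix(rnorm(N * I, sd = config$noise_sd), N, I)
      raw <- mu + noise
      n_clipped <- n_clipped + sum(raw < 0 | raw > 1)
      vals <- clip01(raw)
      mask <- matrix(TRUE, N, I)
      for (n in seq_len(N))
        if (n_mask > 0) mask[n, sample.int(I, n_mask)] <- FALSE
      start <- (m - 1) * (I * 10 + 100) + 1
      pos <- start + (seq_len(I) - 1) * 10
      masked_vals <- vals; masked_vals[!mask] <- NA_real_
      regions[[m]] <- region_matrix(
        chrom = "chrS", positions = pos, values = masked_vals, mask = mask,
        region_id = sprintf("region%03d", m))
      full[[m]] <- cc[lab, , drop = FALSE]
      noisy[[m]] <- vals
      curves[[m]] <- cc
      labels[[m]] <- lab
    }
    ds <- methylation_dataset(regions, provenance = "simulate_mrm")
    names(full) <- names(noisy) <- names(curves) <- names(labels) <-
      names(ds$regions)
    structure(list(dataset = ds, full_values = full, noisy_values = noisy,
                   cluster_curves = curves, labels = labels, config = config,
                   n_clipped = n_clipped), class = "sim_truth")
  })
}

#' Simulate data violating the mixture assumption (smooth shared profiles)
#'
#' A misspecification fixture: every subject in a region follows one random
#' smooth mean curve (a cubic spline through a few uniform control points)
#' plus beta-distributed subject-level deviation, i.e. there is no cluster
#' structure. Useful for checking behaviour when the mixture model's
#' assumptions do not hold.
#'
#' @param config A [sim_config()]; `cluster_props` is ignored,
#'   `noise_sd` controls the beta concentration (smaller = tighter).
#' @return A `sim_truth` (labels all 1, one cluster curve per region).
#' @export
simulate_smooth <- function(config = sim_config()) {
  with_seed(config$seed, {
    I <- config$n_cpg; N <- config$n_subjects
    xs <- seq(-1, 1, length.out = I)
    n_mask <- floor(config$missing_rate * I)
    regions <- vector("list", config$n_regions)
    full <- noisy <- curves <- labels <- vector("list", config$n_regions)
    for (m in seq_len(config$n_regions)) {
      knots <- seq(-1, 1, length.out = 6)
      mean_curve <- rescale_curve(
        stats::spline(knots, runif(6), xout = xs)$y, 0.1, 0.9)
      conc <- max(1 / max(config$noise_sd, 1e-3)^2, 2)
      vals <- t(vapply(seq_len(N), function(n)
        stats::rbeta(I, mean_curve * conc, (1 - mean_curve) * conc),
        numeric(I)))
      mask <- matrix(TRUE, N, I)
      for (n in seq_len(N))
        if (n_mask > 0) mask[n, sample.int(I, n_mask)] <- FALSE
      start <- (m - 1) * (I * 10 + 100) + 1
      pos <- start + (seq_len(I) - 1) * 10
      masked_vals <- vals; masked_vals[!mask] <- NA_real_
      regions[[m]] <- region_matrix(
        chrom = "chrS", positions = pos, values = masked_vals, mask = mask,
        region_id = sprintf("region%03d", m))
      full[[m]] <- matrix(mean_curve, N, I, byrow = TRUE)
      noisy[[m]] <- vals
      curves[[m]] <- matrix(mean_curve, 1, I)
      labels[[m]] <- rep(1L, N)
    }
    ds <- methylation_dataset(regions, provenance = "simulate_smooth")
    names(full) <- names(noisy) <- names(curves) <- names(labels) <-
      names(ds$regions)
    structure(list(dataset = ds, full_values = full, noisy_values = noisy,
                   cluster_curves = curves, labels = labels, config = config,
                   n_clipped = 0L), class = "sim_truth")
  })
}

#' Hide a fraction of observed cells as an evaluation hold-out
#'
#' Per subject per region, `floor(rate * n_observed)` observed cells are
#' hidden without replacement; the hidden truths are returned so imputation
#' accuracy can be scored. If hiding would leave fewer than 2 observed
#' points for a subject in a region, fewer cells are hidden there (with a
#' warning).
#'
#' @param dataset A [methylation_dataset()].
#' @param rate Fraction in (0, 1) of observed cells to hide.
#' @param seed Integer seed.
#' @return List: `dataset` (masked copy) and `hidden`, a data frame with
#'   columns `region_id`, `subject`, `position`, `truth`.
#' @export
inject_missing <- function(dataset, rate, seed = 1) {
  stopifnot(rate > 0, rate < 1)
  with_seed(seed, {
    hidden <- list()
    reduced <- FALSE
    for (rid in names(dataset$regions)) {
      r <- dataset$regions[[rid]]
      for (n in seq_len(nrow(r$values))) {
        obs <- which(r$mask[n, ])
        n_hide <- floor(rate * length(obs))
        if (length(obs) - n_hide < 2) {
          n_hide <- max(0L, length(obs) - 2L)
          reduced <- TRUE
        }
        if (n_hide == 0) next
        hide <- sample(obs, n_hide)
        hidden[[length(hidden) + 1]] <- data.frame(
          region_id = rid, subject = r$subject_ids[n],
          position = r$positions[hide], truth = r$values[n, hide])
        r$mask[n, hide] <- FALSE
        r$values[n, hide] <- NA_real_
      }
      dataset$regions[[rid]] <- r
    }
    if (reduced)
      warning("hiding reduced in some subject-regions to keep >= 2 observed points")
    list(dataset = dataset,
         hidden = do.call(rbind, hidden))
  })
}
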