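#' Distance-weighted nearest-neighbour imputation
#'
#' For each missing cell, the closest observed upstream and downstream CpGs
#' of the same subject are combined with weights inversely proportional to
#' genomic distance: `(v_u/d_u + v_d/d_d) / (1/d_u + 1/d_d)`. A single-sided
#' neighbour is copied as-is. A subject with no observed CpG in the region
#' falls back to the mean of all observed values in the region (flagged by
#' attribute `fallback_cells`).
#'
#' @param region A [region_matrix()].
#' @return The region with missing cells filled (mask unchanged, so callers
#'   can still tell imputed from observed cells).
#' @export
impute_neighbor_average <- function(region) {
  r <- region
  grand_mean <- mean(r$values[r$mask])
  fallback <- 0L
  for (n in seq_len(nrow(r$values))) {
    obs <- which(r$mask[n, ])
    miss <- which(!r$mask[n, ])
    if (!length(miss)) next
    if (!length(obs)) {
      r$values[n, miss] <- grand_mean
      fallback <- fallback + length(miss)
      next
    }
    for (i in miss) {
      up <- obs[obs < i]; down <- obs[obs > i]
      if (length(up) && length(down)) {
        iu <- up[length(up)]; id <- down[1]
        du <- r$positions[i] - r$positions[iu]
        dd <- r$positions[id] - r$positions[i]
        r$values[n, i] <- (r$values[n, iu] / du + r$values[n, id] / dd) /
          (1 / du + 1 / dd)
      } else if (length(up)) {
        r$values[n, i] <- r$values[n, up[length(up)]]
      } else {
        r$values[n, i] <- r$values[n, down[1]]
      }
    }
  }
  if (fallback > 0) attr(r, "fallback_cells") <- fallback
  r
}

#' K-nearest-neighbour imputation over CpG rows
#'
#' The region is oriented CpGs x subjects. For a CpG row with missing
#' entries, Euclidean distances to every other CpG row are computed over
#' the subject columns where the target row is observed (only co-observed
#' columns contribute); the `k` closest rows are its neighbours, and each
#' missing entry is the mean of the neighbours' observed entries in that
#' column. If every neighbour is missing in a column, the target CpG's own
#' row mean (its mean over observed subjects) is used; if the target row
#' has no observed entry at all, the regional mean fills in.
#'
#' @param region A [region_matrix()].
#' @param k Number of neighbours (default 10; reduced with a warning when
#'   fewer rows are available).
#' @return The region with missing cells filled (mask unchanged).
#' @export
impute_knn <- function(region, k = 10) {
  stopifnot(k >= 1)
  r <- region
  X <- t(r$values)      # CpGs x subjects
  M <- t(r$mask)
  I <- nrow(X)
  if (k > I - 1) {
    warning("k reduced to ", I - 1, " (available CpG rows)")
    k <- I - 1
  }
  grand_mean <- mean(X[M])
  filled <- X
  for (i in seq_len(I)) {
    miss_cols <- which(!M[i, ])
    if (!length(miss_cols)) next
    obs_cols <- which(M[i, ])
    row_mean <- if (length(obs_cols)) mean(X[i, obs_cols]) else grand_mean
    if (!length(obs_cols)) {
      filled[i, miss_cols] <- grand_mean
      next
    }
    d <- rep(Inf, I)
    for (s in seq_len(I)) {
      if (s == i) next
      co <- obs_cols[M[s, obs_cols]]
      if (length(co))
        d[s] <- sqrt(sum((X[i, co] - X[s, co])^2))
    }
    nbr <- order(d)[seq_len(k)]
    nbr <- nbr[is.finite(d[nbr])]
    for (cc in miss_cols) {
      v <- X[nbr, cc][M[nbr, cc]]
      filled[i, cc] <- if (length(v)) mean(v) else row_mean
    }
  }
  r$values <- t(filled)
  r
}

# run a baseline over every region of a dataset
impute_baseline <- function(dataset, method = c("average", "knn"), k = 10) {
  method <- match.arg(method)
  res <- empty_result(dataset)
  for (rid in names(dataset$regions)) {
    r <- dataset$regions[[rid]]
    filled <- if (method == "average") impute_neighbor_average(r)
              else impute_knn(r, k)
    res$source[[rid]][!r$mask] <- method
    res$dataset$regions[[rid]] <- filled
  }
  class(res) <- "imputation_result"
  res
}
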