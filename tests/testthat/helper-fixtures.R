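# Shared fixtures, built in code at test time.

# write a matrix TSV + positions TSV pair; returns the two paths
write_toy_matrix <- function(values, positions, region_id = "r1",
                             chrom = "chr1",
                             dir = withr::local_tempdir(
                               .local_envir = parent.frame()),
                             na_string = "NA") {
  mat_path <- file.path(dir, "matrix.tsv")
  pos_path <- file.path(dir, "positions.tsv")
  out <- t(values) # CpGs x subjects
  colnames(out) <- paste0("S", seq_len(nrow(values)))
  write.table(out, mat_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_string)
  write.table(data.frame(region_id = region_id, chrom = chrom,
                         pos = positions),
              pos_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat_path, positions = pos_path)
}

# two well-separated groups of flat profiles
flat_units <- function(n_per = 10, n_points = 15, levels = c(0.1, 0.9),
                       sd = 0.01, seed = 42) {
  withr::with_seed(seed, {
    x <- seq(-1, 1, length.out = n_points)
    c(lapply(seq_len(n_per), function(i)
        list(x = x, y = pmin(1, pmax(0, rnorm(n_points, levels[1], sd))))),
      lapply(seq_len(n_per), function(i)
        list(x = x, y = pmin(1, pmax(0, rnorm(n_points, levels[2], sd))))))
  })
}

# exhaustive KNN imputation oracle, row-by-row over a CpG x subject matrix
knn_oracle <- function(X, M, k) {
  I <- nrow(X)
  out <- X
  for (i in seq_len(I)) {
    miss <- which(!M[i, ])
    if (!length(miss)) next
    obs <- which(M[i, ])
    row_mean <- if (length(obs)) mean(X[i, obs]) else mean(X[M])
    if (!length(obs)) { out[i, miss] <- mean(X[M]); next }
    d <- rep(Inf, I)
    for (s in seq_len(I)) {
      if (s == i) next
      co <- obs[M[s, obs]]
      if (length(co)) d[s] <- sqrt(sum((X[i, co] - X[s, co])^2))
    }
    nbr <- order(d)[seq_len(min(k, I - 1))]
    nbr <- nbr[is.finite(d[nbr])]
    for (cc in miss) {
      v <- X[nbr, cc][M[nbr, cc]]
      out[i, cc] <- if (length(v)) mean(v) else row_mean
    }
  }
  out
}

# Mann-Whitney AUC with midranks (independent of pROC)
auc_oracle <- function(labels, scores) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

mean_subject_correlation <- function(result, hidden) {
  subj <- unique(hidden$subject)
  mean(vapply(subj, function(s) {
    hs <- hidden[hidden$subject == s, ]
    imp <- vapply(seq_len(nrow(hs)), function(i) {
      r <- result$dataset$regions[[hs$region_id[i]]]
      r$values[match(s, r$subject_ids), match(hs$position[i], r$positions)]
    }, numeric(1))
    cor(hs$truth, imp)
  }, numeric(1)))
}
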