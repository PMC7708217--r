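#' Correlation-based clustering of adjacent CpG sites into regions
#'
#' Bottom-up agglomeration in the style of adjacent-site clustering
#' (Aclust): at each step the adjacent pair of regions with the highest
#' similarity is merged, where similarity is the average pairwise Pearson
#' correlation between all sites of the two regions, subject to the facing
#' sites being closer than `max_dist` bp and similarity exceeding
#' `min_corr`; sites wedged between merged endpoints are absorbed. Only
#' adjacent regions merge; iteration stops at a fixed point. Ties in
#' similarity go to the leftmost pair. Constant (zero-variance) sites get
#' correlation 0 with every other site.
#'
#' @param region A [region_matrix()] spanning one chromosome.
#' @param max_dist Maximum distance in bp between the facing CpGs of two
#'   regions (default 3000).
#' @param min_corr Minimum average correlation required to merge
#'   (default 0.3).
#' @return Data frame `region_id`, `chrom`, `start`, `end`, `n_sites`, with
#'   attribute `site_region` giving each input site's region index.
#' @export
cluster_adjacent <- function(region, max_dist = 3000, min_corr = 0.3) {
  validate_region_matrix(region)
  if (nrow(region$values) < 2)
    stop("adjacent clustering needs >= 2 subjects")
  S <- ncol(region$values)
  vals <- region$values
  vals[!region$mask] <- NA
  cm <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  groups <- as.list(seq_len(S)) # contiguous index runs
  repeat {
    if (length(groups) < 2) break
    n_g <- length(groups)
    sims <- rep(-Inf, n_g - 1)
    for (i in seq_len(n_g - 1)) {
      left <- groups[[i]]; right <- groups[[i + 1]]
      gap <- region$positions[right[1]] - region$positions[left[length(left)]]
      if (gap >= max_dist) next
      sims[i] <- mean(cm[left, right])
    }
    i_best <- which.max(sims) # ties -> leftmost
    if (!is.finite(sims[i_best]) || sims[i_best] <= min_corr) break
    groups[[i_best]] <- c(groups[[i_best]], groups[[i_best + 1]])
    groups[[i_best + 1]] <- NULL
  }
  site_region <- integer(S)
  for (g in seq_along(groups)) site_region[groups[[g]]] <- g
  out <- data.frame(
    region_id = sprintf("%s_r%03d", region$chrom, seq_along(groups)),
    chrom = region$chrom,
    start = vapply(groups, function(g) region$positions[g[1]], numeric(1)),
    end = vapply(groups, function(g) region$positions[g[length(g)]],
                 numeric(1)),
    n_sites = lengths(groups))
  attr(out, "site_region") <- site_region
  out
}

#' Split a region's CpGs into fixed-size consecutive windows
#'
#' Non-overlapping blocks of `window` consecutive CpGs; a trailing
#' remainder shorter than `window` is dropped with a warning.
#'
#' @param region A [region_matrix()].
#' @param window CpGs per window (default 50).
#' @return Data frame `region_id`, `chrom`, `start`, `end`, `n_sites` with
#'   attribute `site_window` (0 = dropped remainder).
#' @export
sliding_windows <- function(region, window = 50) {
  S <- length(region$positions)
  if (S < window) stop("need at least ", window, " CpGs")
  n_win <- S %/% window
  if (S %% window > 0)
    warning("trailing remainder of ", S %% window, " CpGs dropped")
  site_window <- integer(S)
  out <- data.frame(region_id = sprintf("%s_w%03d", region$chrom,
                                        seq_len(n_win)),
                    chrom = region$chrom, start = NA_real_, end = NA_real_,
                    n_sites = window)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * window + 1):(w * window)
    site_window[idx] <- w
    out$start[w] <- region$positions[idx[1]]
    out$end[w] <- region$positions[idx[window]]
  }
  attr(out, "site_window") <- site_window
  out
}

#' Prune a promoter region to the CpGs nearest the TSS
#'
#' Keeps the `flank_cpgs` CpGs immediately upstream (coordinate < TSS) and
#' the `flank_cpgs` immediately downstream (coordinate >= TSS); fewer are
#' kept if unavailable, flagged by attribute `short_flank`.
#'
#' @param region A [region_matrix()].
#' @param tss TSS coordinate, inside `[start, end]`.
#' @param flank_cpgs CpGs kept on each side (default 25).
#' @return A pruned [region_matrix()].
#' @export
prune_promoter <- function(region, tss, flank_cpgs = 25) {
  if (tss < region$start || tss > region$end)
    stop("tss lies outside the region")
  up <- which(region$positions < tss)
  down <- which(region$positions >= tss)
  keep <- sort(c(tail(up, flank_cpgs), head(down, flank_cpgs)))
  out <- region_matrix(chrom = region$chrom,
                       positions = region$positions[keep],
                       values = region$values[, keep, drop = FALSE],
                       mask = region$mask[, keep, drop = FALSE],
                       subject_ids = region$subject_ids,
                       region_id = region$region_id)
  if (length(up) < flank_cpgs || length(down) < flank_cpgs)
    attr(out, "short_flank") <- TRUE
  out
}

#' Filter a region on data availability, variance, skewness and runs
#'
#' A region is kept for imputation only if more than `min_subjects`
#' subjects have data in it, the pooled observed values have variance above
#' `min_var` and adjusted Fisher-Pearson skewness above `min_skew`, and the
#' across-subject mean profile, dichotomized at its median, has fewer than
#' `max_runs` runs. The runs gate rejects spatially random (alternating)
#' profiles while keeping block-like patterns the mixture model can fit.
#'
#' @param region A [region_matrix()].
#' @param min_subjects Subjects-with-data threshold (strictly more
#'   required; default 15).
#' @param min_var Pooled variance threshold (default 0.1).
#' @param min_skew Skewness threshold (default -1).
#' @param max_runs Runs threshold (strictly fewer required; default 15).
#' @return A `region_filter_report` list: `region_id`,
#'   `n_subjects_available`, `variance`, `skewness`, `n_runs`, `passed`,
#'   `failure_reasons`.
#' @export
filter_region <- function(region, min_subjects = 15, min_var = 0.1,
                          min_skew = -1, max_runs = 15) {
  obs <- region$values[region$mask]
  if (length(obs) == 0) {
    return(structure(list(region_id = region$region_id,
                          n_subjects_available = 0L, variance = NA_real_,
                          skewness = NA_real_, n_runs = NA_integer_,
                          passed = FALSE, failure_reasons = "no data"),
                     class = "region_filter_report"))
  }
  n_avail <- sum(rowSums(region$mask) > 0)
  v <- stats::var(obs)
  sk <- e1071::skewness(obs, type = 2)
  prof <- colMeans(ifelse(region$mask, region$values, NA), na.rm = TRUE)
  prof <- prof[is.finite(prof)]
  runs <- if (length(prof)) {
    side <- prof >= stats::median(prof)
    length(rle(side)$lengths)
  } else NA_integer_
  reasons <- character(0)
  if (!(n_avail > min_subjects))
    reasons <- c(reasons, sprintf("subjects (%d) not > %d", n_avail,
                                  min_subjects))
  if (!isTRUE(v > min_var))
    reasons <- c(reasons, sprintf("variance (%.4f) not > %.4f", v, min_var))
  if (!isTRUE(sk > min_skew))
    reasons <- c(reasons, sprintf("skewness (%.4f) not > %.4f", sk, min_skew))
  if (!isTRUE(runs < max_runs))
    reasons <- c(reasons, sprintf("runs (%d) not < %d", runs, max_runs))
  structure(list(region_id = region$region_id,
                 n_subjects_available = n_avail, variance = v,
                 skewness = sk, n_runs = runs,
                 passed = length(reasons) == 0,
                 failure_reasons = reasons),
            class = "region_filter_report")
}

#' @export
print.region_filter_report <- function(x, ...) {
  cat(sprintf("<region_filter_report> %s: %s\n", x$region_id,
              if (x$passed) "PASSED"
              else paste("FAILED -", paste(x$failure_reasons,
                                           collapse = "; "))))
  invisible(x)
}

#' Assign regions to promoters within a TSS flank
#'
#' A region is assigned to every gene whose `[tss - flank_bp, tss +
#' flank_bp]` window it overlaps (multi-mapping allowed).
#'
#' @param regions Data frame `region_id`, `chrom`, `start`, `end`.
#' @param tss_table Data frame `gene`, `chrom`, `tss` and optionally
#'   `strand` (missing strand assumed `+` with a warning).
#' @param flank_bp Promoter half-width (default 5000).
#' @return Data frame `region_id`, `gene`.
#' @export
map_to_promoters <- function(regions, tss_table, flank_bp = 5000) {
  if (is.null(tss_table$strand)) {
    warning("no strand column; assuming '+'")
    tss_table$strand <- "+"
  }
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  prom_gr <- GenomicRanges::GRanges(
    tss_table$chrom,
    IRanges::IRanges(pmax(1, tss_table$tss - flank_bp),
                     tss_table$tss + flank_bp))
  hits <- GenomicRanges::findOverlaps(reg_gr, prom_gr)
  data.frame(
    region_id = regions$region_id[S4Vectors::queryHits(hits)],
    gene = tss_table$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
}
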