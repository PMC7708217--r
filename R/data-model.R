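#' Regional methylation matrix
#'
#' The basic container of the package: the methylation levels of one genomic
#' region for a roster of subjects. Rows are subjects, columns are CpG sites
#' (in ascending genomic order); levels are beta values in \[0, 1\]. A logical
#' mask of the same shape marks which cells were actually measured.
#'
#' @param chrom Chromosome name.
#' @param positions Integer vector of CpG coordinates (1-based, strictly
#'   increasing).
#' @param values Numeric matrix, subjects x CpGs, entries in \[0, 1\] where
#'   observed (`NA` allowed at unobserved cells).
#' @param mask Logical matrix of the same shape; `TRUE` = observed. Defaults
#'   to `!is.na(values)`.
#' @param subject_ids Character vector of subject labels (rows of `values`).
#' @param region_id Region label.
#' @param start,end Region bounds (1-based inclusive); default to the range
#'   of `positions`.
#'
#' @return An object of class `region_matrix`.
#' @export
region_matrix <- function(chrom, positions, values, mask = NULL,
                          subject_ids = NULL, region_id = "region1",
                          start = NULL, end = NULL) {
  values <- as.matrix(values)
  positions <- as.numeric(positions)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(start)) start <- min(positions)
  if (is.null(end)) end <- max(positions)
  rm <- structure(
    list(chrom = as.character(chrom), start = start, end = end,
         positions = positions, values = values, mask = mask,
         subject_ids = as.character(subject_ids),
         region_id = as.character(region_id)),
    class = "region_matrix")
  validate_region_matrix(rm)
  rm
}

validate_region_matrix <- function(rm) {
  stopifnot(inherits(rm, "region_matrix"))
  if (length(rm$positions) != ncol(rm$values))
    stop("positions length (", length(rm$positions),
         ") must match number of value columns (", ncol(rm$values), ")")
  if (!all(dim(rm$mask) == dim(rm$values)))
    stop("mask and values must have identical shape")
  if (length(rm$subject_ids) != nrow(rm$values))
    stop("subject_ids must have one entry per row of values")
  if (length(rm$positions) > 1 && any(diff(rm$positions) <= 0))
    stop("positions must be strictly increasing in region ", rm$region_id)
  if (any(rm$positions < rm$start | rm$positions > rm$end))
    stop("positions must lie within [start, end] in region ", rm$region_id)
  obs <- rm$values[rm$mask]
  if (anyNA(obs))
    stop("observed cells (mask TRUE) may not be NA in region ", rm$region_id)
  bad <- which(obs < 0 | obs > 1)
  if (length(bad)) {
    cell <- which(rm$mask)[bad[1]]
    ij <- arrayInd(cell, dim(rm$values))
    stop("methylation value out of [0, 1] at subject ",
         rm$subject_ids[ij[1]], ", position ", rm$positions[ij[2]],
         " (value ", rm$values[cell], ") in region ", rm$region_id)
  }
  invisible(rm)
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("<region_matrix> %s %s:%d-%d | %d subjects x %d CpGs | %.1f%% observed\n",
              x$region_id, x$chrom, as.integer(x$start), as.integer(x$end),
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.region_matrix <- function(x) dim(x$values)

#' Collection of regional matrices sharing one subject roster
#'
#' @param regions List of [region_matrix()] objects with identical
#'   `subject_ids` (same order) and unique `region_id`s.
#' @param provenance Free-text description of the data source.
#'
#' @return An object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(regions, provenance = "unspecified") {
  stopifnot(length(regions) >= 1)
  lapply(regions, validate_region_matrix)
  ids <- vapply(regions, function(r) r$region_id, character(1))
  if (anyDuplicated(ids)) stop("region_ids must be unique")
  roster <- regions[[1]]$subject_ids
  for (r in regions)
    if (!identical(r$subject_ids, roster))
      stop("all regions must share one subject roster (region ",
           r$region_id, " differs)")
  names(regions) <- ids
  structure(list(regions = regions, provenance = provenance),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  n_cpg <- sum(vapply(x$regions, function(r) ncol(r$values), numeric(1)))
  cat(sprintf("<methylation_dataset> %d regions | %d subjects | %d CpGs | %s\n",
              length(x$regions), length(x$regions[[1]]$subject_ids),
              as.integer(n_cpg), x$provenance))
  invisible(x)
}

#' @export
length.methylation_dataset <- function(x) length(x$regions)

n_subjects <- function(ds) length(ds$regions[[1]]$subject_ids)
subject_ids <- function(ds) ds$regions[[1]]$subject_ids
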