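#' Read a CpG x subject methylation matrix with a positions file
#'
#' The matrix TSV has a header row of subject ids and one row per CpG;
#' missing cells are encoded as `NA` (case-insensitive) or an empty string.
#' The positions TSV maps each matrix row, in order, to a region label,
#' chromosome and 1-based coordinate (columns `region_id`, `chrom`, `pos`).
#'
#' @param path Matrix TSV path.
#' @param positions_path Positions TSV path.
#' @return A [methylation_dataset()] with one region per distinct
#'   `region_id` in the positions file.
#' @export
read_matrix_tsv <- function(path, positions_path) {
  mat <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", "na", "Na", "nA", ""),
                           check.names = FALSE, colClasses = "numeric")
  pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("region_id", "chrom", "pos")
  if (!all(need %in% names(pos)))
    stop("positions file must have columns region_id, chrom, pos")
  if (nrow(mat) != nrow(pos))
    stop("row count mismatch: matrix has ", nrow(mat), " CpGs but positions ",
         "file has ", nrow(pos))
  vals <- t(as.matrix(mat)) # subjects x CpGs
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("methylation value out of [0, 1] at subject '",
         rownames(vals)[bad[1, 1]], "', CpG row ", bad[1, 2],
         " (value ", vals[bad[1, , drop = FALSE]], ")")
  subj <- colnames(mat)
  regions <- lapply(unique(pos$region_id), function(rid) {
    sel <- which(pos$region_id == rid)
    ord <- sel[order(pos$pos[sel])]
    region_matrix(chrom = pos$chrom[ord[1]], positions = pos$pos[ord],
                  values = vals[, ord, drop = FALSE], subject_ids = subj,
                  region_id = as.character(rid))
  })
  methylation_dataset(regions, provenance = paste0("matrix_tsv:", path))
}

#' Read one bedGraph file per subject into a dataset
#'
#' Each file is 4-column bedGraph (`chrom  start0  end0  level`) with 0-based
#' half-open intervals; the CpG coordinate is taken as `start0 + 1`. Levels
#' on a percentage scale (maximum > 1) are divided by 100 per file unless
#' `percent` is set explicitly. The union of coordinates across subjects
#' defines the sites of each per-chromosome region; subjects lacking a site
#' are masked missing there.
#'
#' @param paths Character vector of bedGraph paths, one per subject.
#' @param subject_ids Subject labels; default file base names.
#' @param percent `NULL` (auto-detect per file), `TRUE` (always divide by
#'   100) or `FALSE` (never).
#' @return A [methylation_dataset()] with one region per chromosome.
#' @export
read_bedgraph_set <- function(paths, subject_ids = NULL, percent = NULL) {
  if (is.null(subject_ids))
    subject_ids <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
  recs <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[i])
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t|\\s+")
    nf <- lengths(fields)
    if (any(nf < 4))
      stop("malformed bedGraph line ", which(nf < 4)[1], " in ", paths[i])
    chrom <- vapply(fields, `[`, character(1), 1)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
    level <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4)))
    if (anyNA(start0) || anyNA(level))
      stop("malformed bedGraph line ",
           which(is.na(start0) | is.na(level))[1], " in ", paths[i])
    for (ch in unique(chrom)) {
      s <- start0[chrom == ch]
      if (is.unsorted(s, strictly = TRUE))
        stop("unsorted positions on ", ch, " near line ",
             which(chrom == ch)[which(diff(s) <= 0)[1] + 1], " in ", paths[i])
    }
    pct <- if (is.null(percent)) max(level) > 1 else isTRUE(percent)
    if (pct) level <- level / 100
    if (any(level < 0 | level > 1))
      stop("level out of range at line ", which(level < 0 | level > 1)[1],
           " in ", paths[i])
    data.frame(chrom = chrom, pos = start0 + 1, level = level)
  })
  chroms <- unique(unlist(lapply(recs, function(r) r$chrom)))
  regions <- lapply(chroms, function(ch) {
    pos_union <- sort(unique(unlist(
      lapply(recs, function(r) r$pos[r$chrom == ch]))))
    vals <- matrix(NA_real_, nrow = length(paths), ncol = length(pos_union))
    for (i in seq_along(recs)) {
      r <- recs[[i]][recs[[i]]$chrom == ch, ]
      vals[i, match(r$pos, pos_union)] <- r$level
    }
    region_matrix(chrom = ch, positions = pos_union, values = vals,
                  subject_ids = subject_ids, region_id = ch)
  })
  methylation_dataset(regions, provenance = "bedgraph_set")
}

#' Write an imputed (complete) dataset as matrix + positions TSV
#'
#' Round-trippable by [read_matrix_tsv()]. Values are written with enough
#' digits that originally observed cells survive a read-back unchanged.
#'
#' @param dataset A complete [methylation_dataset()] (no masked-and-unfilled
#'   cells, i.e. no `NA` values).
#' @param path Output matrix TSV path.
#' @param positions_path Output positions TSV path; default `path` with a
#'   `.positions.tsv` suffix.
#' @export
write_imputed <- function(dataset, path,
                          positions_path = paste0(path, ".positions.tsv")) {
  for (r in dataset$regions)
    if (anyNA(r$values))
      stop("dataset still has missing cells (region ", r$region_id,
           "); impute before writing")
  mats <- lapply(dataset$regions, function(r) t(r$values))
  big <- do.call(rbind, mats)
  colnames(big) <- subject_ids(dataset)
  out <- apply(big, 2, function(col) format(col, digits = 15, trim = TRUE,
                                            scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pos <- do.call(rbind, lapply(dataset$regions, function(r)
    data.frame(region_id = r$region_id, chrom = r$chrom, pos = r$positions)))
  utils::write.table(pos, positions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write region intervals as BED
#'
#' @param regions Data frame with columns `region_id`, `chrom`, `start`,
#'   `end` (1-based inclusive; converted to BED 0-based half-open).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end, name = regions$region_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a table of transcription start sites
#'
#' Accepts a 6-column BED (`chrom start0 end name score strand`; the TSS is
#' the strand-aware interval start) or a headered TSV with columns `gene`,
#' `chrom`, `tss` and optionally `strand`.
#'
#' @param path Input path.
#' @return Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\bgene\\b", first) && grepl("\\btss\\b", first)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (is.null(tab$strand)) {
      warning("no strand column; assuming '+'")
      tab$strand <- "+"
    }
    return(tab[, c("gene", "chrom", "tss", "strand")])
  }
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) {
    warning("BED has no strand column; assuming '+'")
    bed$V6 <- "+"
  }
  tss <- ifelse(bed$V6 == "-", bed$V3, bed$V2 + 1)
  data.frame(gene = bed$V4, chrom = bed$V1, tss = tss, strand = bed$V6,
             stringsAsFactors = FALSE)
}
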