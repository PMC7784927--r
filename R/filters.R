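# Marker/datapoint filtering of allele-count data. The thresholds mirror
# standard capture-seq quality control for polyploid ratio genotypes: a
# site-mean depth floor (default 60X), a per-datapoint depth floor (default
# 2X, avoiding imputation of shallow cells), missing-fraction caps, and a
# minor-allele-frequency floor estimated from the read ratios themselves.

#' Filtering thresholds
#'
#' @param min_site_mean_depth markers must average at least this depth over
#'   non-missing datapoints (default 60).
#' @param min_datapoint_depth datapoints below this depth are set missing
#'   (default 2).
#' @param max_missing maximum missing fraction tolerated, applied to markers
#'   and then to individuals (default 0.2).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param chrom_whitelist chromosomes to keep (`NULL` = all), e.g. the
#'   chromosome-anchored scaffolds of an assembly.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_site_mean_depth = 60,
                              min_datapoint_depth = 2,
                              max_missing = 0.2,
                              min_maf = 0.05,
                              chrom_whitelist = NULL) {
  stopifnot(min_site_mean_depth >= 0, min_datapoint_depth >= 0,
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(min_site_mean_depth = min_site_mean_depth,
                 min_datapoint_depth = min_datapoint_depth,
                 max_missing = max_missing,
                 min_maf = min_maf,
                 chrom_whitelist = chrom_whitelist),
            class = "filter_thresholds")
}

#' Apply marker and datapoint filters to a read-count matrix
#'
#' Filters are applied in a fixed, documented order: (1) chromosome
#' whitelist; (2) datapoints with depth below `min_datapoint_depth` are set
#' missing; (3) markers whose mean depth over non-missing datapoints falls
#' below `min_site_mean_depth` are dropped; (4) markers, then individuals,
#' with missing fraction above `max_missing` are dropped; (5) markers with
#' minor allele frequency below `min_maf` are dropped. Depth-based
#' missingness is counted before the missing-fraction caps so that shallow
#' datapoints never need imputation downstream.
#'
#' The allele frequency behind step 5 is, by default, the mean of
#' per-individual read ratios over non-missing datapoints (robust to depth
#' heterogeneity across individuals); `maf_method = "pooled"` instead pools
#' reads across individuals.
#'
#' @param rc a `read_counts` object.
#' @param map marker map covering all markers of `rc`.
#' @param th a [filter_thresholds()] object.
#' @param maf_method `"ratio_mean"` (default) or `"pooled"`.
#' @return list with `counts` (filtered `read_counts`) and `report` (a
#'   `filter_report`: per-step drop counts and remaining dimensions).
#' @export
apply_filters <- function(rc, map, th = filter_thresholds(),
                          maf_method = c("ratio_mean", "pooled")) {
  stopifnot(inherits(rc, "read_counts"), inherits(th, "filter_thresholds"))
  maf_method <- match.arg(maf_method)
  map <- validate_marker_map(map)
  if (!all(colnames(rc$AO) %in% map$marker_id)) {
    stop("markers absent from the map")
  }
  AO <- rc$AO; RO <- rc$RO
  report <- list(input_dim = dim(AO))

  # (1) chromosome whitelist
  if (!is.null(th$chrom_whitelist)) {
    chrom <- map$chrom[match(colnames(AO), map$marker_id)]
    keep <- chrom %in% th$chrom_whitelist
    report$chrom_dropped <- sum(!keep)
    AO <- AO[, keep, drop = FALSE]; RO <- RO[, keep, drop = FALSE]
  } else {
    report$chrom_dropped <- 0L
  }

  # (2) shallow datapoints set missing
  depth <- AO + RO
  shallow <- !is.na(depth) & depth < th$min_datapoint_depth
  report$datapoints_set_missing <- sum(shallow)
  AO[shallow] <- NA_integer_; RO[shallow] <- NA_integer_

  # (3) site-mean depth floor (over non-missing datapoints)
  depth <- AO + RO
  site_mean <- colMeans(depth, na.rm = TRUE)
  keep <- !is.nan(site_mean) & site_mean >= th$min_site_mean_depth
  report$low_depth_markers_dropped <- sum(!keep)
  AO <- AO[, keep, drop = FALSE]; RO <- RO[, keep, drop = FALSE]

  # (4) missing-fraction caps: markers first, then individuals
  miss_m <- colMeans(is.na(AO))
  keep <- miss_m <= th$max_missing
  report$high_missing_markers_dropped <- sum(!keep)
  AO <- AO[, keep, drop = FALSE]; RO <- RO[, keep, drop = FALSE]
  miss_i <- rowMeans(is.na(AO))
  keep_i <- miss_i <= th$max_missing
  report$high_missing_individuals_dropped <- sum(!keep_i)
  AO <- AO[keep_i, , drop = FALSE]; RO <- RO[keep_i, , drop = FALSE]

  # (5) minor-allele-frequency floor
  if (ncol(AO) > 0 && nrow(AO) > 0) {
    freq <- switch(maf_method,
                   ratio_mean = colMeans(AO / (AO + RO), na.rm = TRUE),
                   pooled = colSums(AO, na.rm = TRUE) /
                     colSums(AO + RO, na.rm = TRUE))
    maf <- pmin(freq, 1 - freq)
    keep <- !is.nan(maf) & maf >= th$min_maf
    report$low_maf_markers_dropped <- sum(!keep)
    AO <- AO[, keep, drop = FALSE]; RO <- RO[, keep, drop = FALSE]
  } else {
    report$low_maf_markers_dropped <- 0L
  }

  report$output_dim <- dim(AO)
  report$residual_missing <- sum(is.na(AO))
  class(report) <- "filter_report"
  if (ncol(AO) == 0) {
    stop("all markers filtered out (",
         paste(names(report), vapply(report, paste, "", collapse = "x"),
               sep = "=", collapse = "; "), ")")
  }
  list(counts = read_count_matrix(AO, RO), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  cat("  input:                      ", x$input_dim[1], "x", x$input_dim[2], "\n")
  cat("  chromosome-dropped markers: ", x$chrom_dropped, "\n")
  cat("  shallow datapoints -> NA:   ", x$datapoints_set_missing, "\n")
  cat("  low site-mean-depth markers:", x$low_depth_markers_dropped, "\n")
  cat("  high-missing markers:       ", x$high_missing_markers_dropped, "\n")
  cat("  high-missing individuals:   ", x$high_missing_individuals_dropped, "\n")
  cat("  low-MAF markers:            ", x$low_maf_markers_dropped, "\n")
  cat("  output:                     ", x$output_dim[1], "x", x$output_dim[2],
      " (", x$residual_missing, "missing )\n")
  invisible(x)
}
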