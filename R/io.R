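# Read-count container and file I/O. Count tables use the deposited-data
# layout: individuals as rows, markers as columns, first column the
# individual id. A minimal VCF path (per-sample allele depths, biallelic
# records only) is provided as the alternative input.

#' Construct a read-count matrix pair
#'
#' The raw observable of the whole pipeline: per individual x marker counts
#' of reads carrying the alternative allele (`AO`) and the reference allele
#' (`RO`). Missing datapoints are `NA` in both matrices.
#'
#' @param AO,RO equally-shaped non-negative integer matrices with identical
#'   dimnames (rows = individuals, columns = markers).
#' @return a `read_counts` object (list with `AO` and `RO`).
#' @export
read_count_matrix <- function(AO, RO) {
  stopifnot(is.matrix(AO), is.matrix(RO))
  if (!all(dim(AO) == dim(RO))) stop("AO and RO shapes disagree")
  if (!identical(dimnames(AO), dimnames(RO))) {
    stop("AO and RO individual/marker ids disagree")
  }
  if (any(AO < 0, na.rm = TRUE) || any(RO < 0, na.rm = TRUE)) {
    stop("negative read counts")
  }
  if (!identical(is.na(AO), is.na(RO))) {
    stop("AO and RO must be missing at the same datapoints")
  }
  storage.mode(AO) <- "integer"
  storage.mode(RO) <- "integer"
  structure(list(AO = AO, RO = RO), class = "read_counts")
}

#' @export
dim.read_counts <- function(x) dim(x$AO)

#' @export
print.read_counts <- function(x, ...) {
  cat("read_counts:", nrow(x$AO), "individuals x", ncol(x$AO), "markers;",
      sum(is.na(x$AO)), "missing datapoint(s); mean depth",
      round(mean(x$AO + x$RO, na.rm = TRUE), 2), "\n")
  invisible(x)
}

#' Total sequencing depth per datapoint
#'
#' @param rc a `read_counts` object.
#' @return integer matrix `AO + RO` (NA where missing).
#' @export
rc_depth <- function(rc) rc$AO + rc$RO

#' Subset a read-count matrix
#'
#' @param rc a `read_counts` object.
#' @param individuals,markers row/column selectors (ids or indices; `NULL`
#'   keeps all).
#' @return a `read_counts` object.
#' @export
rc_subset <- function(rc, individuals = NULL, markers = NULL) {
  i <- individuals %||% seq_len(nrow(rc$AO))
  j <- markers %||% seq_len(ncol(rc$AO))
  read_count_matrix(rc$AO[i, j, drop = FALSE], rc$RO[i, j, drop = FALSE])
}

.read_count_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read allele counts from a TSV pair or a VCF
#'
#' TSV mode expects two tab-separated tables (alternative and reference
#' counts) with a header row of marker ids and the individual id in the
#' first column; ids must agree between the two files. VCF mode uses the
#' per-sample allele-depth (`AD`) field of biallelic records; multiallelic
#' records are skipped and counted, and records failing `QUAL >= qual_min`
#' or `MQ >= mq_min` (when those fields are present) are dropped — the
#' upstream mapping/variant-quality criteria that AO/RO tables are assumed
#' to have had applied already. Skip/drop counts are attached as the
#' `"vcf_report"` attribute.
#'
#' @param ao_path,ro_path paths of the alternative/reference count TSVs.
#' @param vcf_path alternatively, a VCF 4.x file with per-sample `AD`.
#' @param qual_min,mq_min site-quality thresholds applied in VCF mode.
#' @return a `read_counts` object.
#' @export
read_counts <- function(ao_path = NULL, ro_path = NULL, vcf_path = NULL,
                        qual_min = 10, mq_min = 20) {
  if (!is.null(vcf_path)) {
    return(.read_counts_vcf(vcf_path, qual_min, mq_min))
  }
  stopifnot(!is.null(ao_path), !is.null(ro_path))
  AO <- .read_count_tsv(ao_path)
  RO <- .read_count_tsv(ro_path)
  if (!identical(colnames(AO), colnames(RO))) {
    stop("marker ids differ between AO and RO files")
  }
  if (!identical(rownames(AO), rownames(RO))) {
    stop("individual ids differ between AO and RO files")
  }
  read_count_matrix(AO, RO)
}

.read_counts_vcf <- function(vcf_path, qual_min, mq_min) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  n_rec <- nrow(v@fix)
  bi <- vcfR::is.biallelic(v)
  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  qual_ok <- is.na(qual) | qual >= qual_min
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.]+).*", "\\1",
                                        v@fix[, "INFO"])))
  mq[!grepl("MQ=", v@fix[, "INFO"] %||% "")] <- NA
  mq_ok <- is.na(mq) | mq >= mq_min
  keep <- bi & qual_ok & mq_ok
  if (!any(keep)) stop("no biallelic records passing quality filters")
  v <- v[keep, ]
  ad <- vcfR::extract.gt(v, element = "AD")
  ro <- vcfR::masplit(ad, record = 1, sort = 0)
  ao <- vcfR::masplit(ad, record = 2, sort = 0)
  ids <- unname(v@fix[, "ID"])
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(v@fix[noid, "CHROM"], "_", v@fix[noid, "POS"])
  rownames(ao) <- rownames(ro) <- ids
  out <- read_count_matrix(t(ao), t(ro))
  attr(out, "vcf_report") <- list(
    n_records = n_rec,
    n_multiallelic_skipped = sum(!bi),
    n_quality_dropped = sum(bi & !(qual_ok & mq_ok)),
    n_used = sum(keep))
  out
}

#' Write allele counts as a TSV pair
#'
#' @param rc a `read_counts` object.
#' @param ao_path,ro_path output paths.
#' @return invisibly, the paths.
#' @export
write_counts <- function(rc, ao_path, ro_path) {
  stopifnot(inherits(rc, "read_counts"))
  w <- function(m, path) {
    data.table::fwrite(data.frame(individual_id = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t")
  }
  w(rc$AO, ao_path)
  w(rc$RO, ro_path)
  invisible(c(ao_path, ro_path))
}

#' Write allele counts as a minimal VCF
#'
#' One biallelic record per marker with a per-sample `AD` field
#' (`reference,alternative`), mainly for round-trip testing of the VCF
#' reader. REF/ALT bases are placeholders.
#'
#' @param rc a `read_counts` object.
#' @param map marker map supplying chromosome and position.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_counts_vcf <- function(rc, map, path) {
  stopifnot(inherits(rc, "read_counts"))
  map <- validate_marker_map(map)
  mk <- colnames(rc$AO)
  mi <- match(mk, map$marker_id)
  if (anyNA(mi)) stop("markers missing from the map")
  samples <- rownames(rc$AO)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(mk), function(j) {
    ad <- ifelse(is.na(rc$AO[, j]), ".,.",
                 paste0(rc$RO[, j], ",", rc$AO[, j]))
    paste(c(map$chrom[mi[j]], map$pos[mi[j]], mk[j], "A", "C", "100", "PASS",
            "MQ=60", "AD", ad), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a marker map from TSV
#'
#' @param path tab-separated file with columns `marker_id`, `chrom`, `pos`,
#'   `cM` and optionally `probe_id`.
#' @return a `marker_map` data frame.
#' @export
read_marker_map <- function(path) {
  validate_marker_map(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' Read phenotype records from TSV
#'
#' @param path tab-separated file with columns `individual_id`, `year`,
#'   `value` and optionally `trait`.
#' @return a data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("individual_id", "year", "value")
  if (!all(need %in% names(d))) {
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  }
  d
}
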