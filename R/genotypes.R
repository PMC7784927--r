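# Continuous (ratio) genotypes and phenotype adjustment. Instead of calling
# tetraploid dosage classes (0..4) — error-prone at realistic depths — each
# datapoint is parameterized directly by the fraction of reads carrying the
# alternative allele, #a / (#A + #a), a value in [0, 1] whose expectation is
# dosage/4 under unbiased allele sampling.

#' Continuous ratio genotypes from read counts
#'
#' `M[i, j] = AO[i, j] / (AO[i, j] + RO[i, j])`. Non-missing zero-depth
#' datapoints are an error (they cannot arise after [apply_filters()] with a
#' positive datapoint-depth floor). Missing datapoints are mean-imputed per
#' marker as a last resort — the mixed model requires a complete matrix —
#' and the imputed count is recorded in the `"n_imputed"` attribute; set
#' `impute_missing = FALSE` to error on missingness instead.
#'
#' @param rc a `read_counts` object.
#' @param impute_missing replace missing cells by their marker mean ratio
#'   (default `TRUE`).
#' @return numeric matrix `M` (individuals x markers) with entries in
#'   `[0, 1]`, attribute `n_imputed`.
#' @export
ratio_genotypes <- function(rc, impute_missing = TRUE) {
  stopifnot(inherits(rc, "read_counts"))
  depth <- rc$AO + rc$RO
  zero <- !is.na(depth) & depth == 0
  if (any(zero)) {
    w <- which(zero, arr.ind = TRUE)[1, ]
    stop("zero-depth datapoint at individual '", rownames(depth)[w[1]],
         "', marker '", colnames(depth)[w[2]], "'")
  }
  M <- rc$AO / depth
  n_imp <- 0L
  if (anyNA(M)) {
    if (!impute_missing) stop("missing datapoints present and impute_missing = FALSE")
    cm <- colMeans(M, na.rm = TRUE)
    if (any(is.nan(cm))) stop("marker(s) entirely missing; filter first")
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- cm[idx[, 2]]
    n_imp <- nrow(idx)
  }
  attr(M, "n_imputed") <- n_imp
  M
}

#' Least-squares adjusted means (LSMeans) of genotypes over seasons
#'
#' Ordinary least squares of `value ~ genotype + year` (both categorical,
#' fixed). The adjusted mean of genotype g is the model intercept plus its
#' genotype effect plus the unweighted mean of the year effects — the
#' classical two-way fixed-effects adjusted mean. On balanced data this
#' reduces to the simple per-genotype mean; with a single year it degenerates
#' to per-genotype means. Rank deficiency (e.g. a year observed for a single
#' genotype only) is an error.
#'
#' @param records data frame with columns `individual_id`, `year`, `value`,
#'   and optionally `trait` (multiple traits are adjusted independently).
#' @return for a single trait, a named vector of LSMeans; with a `trait`
#'   column of several traits, a long data frame `individual_id`, `trait`,
#'   `lsmean`.
#' @export
lsmeans_phenotypes <- function(records) {
  need <- c("individual_id", "year", "value")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  if ("trait" %in% names(records) &&
      length(unique(records$trait)) > 1) {
    traits <- unique(records$trait)
    out <- do.call(rbind, lapply(traits, function(tr) {
      ls <- .lsmeans_one(records[records$trait == tr, , drop = FALSE])
      data.frame(individual_id = names(ls), trait = tr, lsmean = unname(ls),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  .lsmeans_one(records)
}

.lsmeans_one <- function(d) {
  if (!all(is.finite(d$value))) stop("non-finite phenotype values")
  geno <- factor(d$individual_id)
  yearf <- factor(d$year)
  if (nlevels(geno) < 2) stop("need at least 2 genotypes")
  if (nlevels(yearf) == 1) {
    ls <- tapply(d$value, geno, mean)
    return(stats::setNames(as.vector(ls), levels(geno)))
  }
  fit <- stats::lm(value ~ geno + yearf,
                   data = data.frame(value = d$value, geno = geno,
                                     yearf = yearf))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: a year is confounded with genotype")
  }
  gl <- levels(geno); yl <- levels(yearf)
  geno_eff <- c(0, unname(cf[paste0("geno", gl[-1])]))
  year_eff <- c(0, unname(cf[paste0("yearf", yl[-1])]))
  stats::setNames(unname(cf[1]) + geno_eff + mean(year_eff), gl)
}
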