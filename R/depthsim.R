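# Sequencing-depth downsampling. A high-coverage count matrix is resampled
# to a lower target coverage: new per-datapoint totals are drawn from a
# Poisson with the scenario mean, truncated below at the datapoint-depth
# floor, and the allele split at the new total is binomial with the input
# read ratio as success probability — the resampling model consistent with
# the ratio parameterization of the genotypes.

#' Downsample a read-count matrix to a target mean depth
#'
#' New totals `n'` are drawn fresh per datapoint from
#' Poisson(`target_depth`) conditioned on `n' >= min_depth` — not thinned
#' from the observed depth, because the scenario specifies the new depth
#' distribution directly. New alternative counts are
#' Binomial(`n'`, `AO/(AO+RO)`); marker positions and individuals are
#' unchanged. `method = "hypergeometric"` instead subsamples reads without
#' replacement from the observed pool (totals capped at the observed depth),
#' for sensitivity checks at targets below the input depth.
#'
#' @param rc a `read_counts` object with no zero-depth datapoints (missing
#'   cells are propagated as missing).
#' @param target_depth scenario mean depth (> 0), e.g. 2, 6, 12, 24, 48.
#' @param min_depth minimum retained depth (default 2).
#' @param seed optional integer seed.
#' @param method `"poisson"` (default) or `"hypergeometric"`.
#' @return a `read_counts` object at the new depth.
#' @export
downsample <- function(rc, target_depth, min_depth = 2, seed = NULL,
                       method = c("poisson", "hypergeometric")) {
  stopifnot(inherits(rc, "read_counts"), target_depth > 0, min_depth >= 0)
  method <- match.arg(method)
  depth <- rc$AO + rc$RO
  if (any(depth == 0, na.rm = TRUE)) {
    stop("input contains zero-depth datapoints; filter first")
  }
  .seed(seed)
  ok <- !is.na(depth)
  N <- sum(ok)
  n2 <- rtruncpois(N, target_depth, min_depth)
  AO2 <- rc$AO; RO2 <- rc$RO  # keeps NA pattern and dimnames
  if (method == "poisson") {
    p <- rc$AO[ok] / depth[ok]
    ao <- stats::rbinom(N, n2, p)
  } else {
    n2 <- pmin(n2, depth[ok])
    ao <- suppressWarnings(
      stats::rhyper(N, m = rc$AO[ok], n = rc$RO[ok], k = n2))
  }
  AO2[ok] <- ao
  RO2[ok] <- n2 - ao
  read_count_matrix(AO2, RO2)
}

#' Independent downsampling replicates over several depth targets
#'
#' @param rc a `read_counts` object.
#' @param targets vector of scenario mean depths.
#' @param n_reps independent replicates per target (default 5).
#' @param master_seed integer; per-replicate seeds are derived
#'   deterministically as `derive_seed(master_seed, target, rep)`.
#' @param min_depth minimum retained depth (default 2).
#' @return nested list: `out[[as.character(target)]][[rep]]`, each a
#'   `read_counts` object.
#' @export
replicate_downsample <- function(rc, targets, n_reps = 5, master_seed = 1,
                                 min_depth = 2) {
  stopifnot(length(targets) >= 1, n_reps >= 1)
  out <- lapply(targets, function(tg) {
    lapply(seq_len(n_reps), function(r) {
      downsample(rc, tg, min_depth = min_depth,
                 seed = derive_seed(master_seed, "downsample", tg, r))
    })
  })
  names(out) <- as.character(targets)
  out
}
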