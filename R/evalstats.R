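# Scoring and summary statistics: predictive ability (Pearson correlation
# of predictions with adjusted phenotypes in the held-out set), mean squared
# error, one-way Tukey HSD with a compact letter display, variance explained
# by relationship-matrix principal components, and the sequencing-budget
# arithmetic that turns a depth decision into samples-per-flow-cell.

#' Predictive ability (Pearson correlation)
#'
#' @param pred,obs equal-length numeric vectors (length >= 3) of predictions
#'   and observed (adjusted) phenotypes; zero variance in either is an
#'   error, not `NA`.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
predictive_ability <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(pred)) || !all(is.finite(obs))) stop("non-finite values")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("zero variance in predictions or observations")
  }
  stats::cor(pred, obs)
}

#' Mean squared error of predictions
#'
#' Average squared difference between predicted and observed values;
#' `standardized = TRUE` divides by the sample variance of the observations
#' (unitless standardized MSE).
#'
#' @param pred,obs equal-length numeric vectors.
#' @param standardized divide by `var(obs)` (default `FALSE`).
#' @return non-negative scalar.
#' @export
mse <- function(pred, obs, standardized = FALSE) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 1) stop("empty input")
  out <- mean((pred - obs)^2)
  if (standardized) {
    v <- stats::var(obs)
    if (!isTRUE(v > 0)) stop("zero variance in observations")
    out <- out / v
  }
  out
}

# Insert-and-absorb assembly of a compact letter display from a logical
# significance relation on 1..k (ordered by descending mean). Every
# significant pair ends up sharing no letter; every non-significant pair
# keeps at least one common letter.
.cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  absorb <- function(cols) {
    cols <- unique(lapply(cols, sort))
    cols <- cols[lengths(cols) > 0]
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            length(cols[[a]]) < length(cols[[b]]) &&
            all(cols[[a]] %in% cols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    cols[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!sig[i, j]) next
      hit <- which(vapply(cols, function(s) all(c(i, j) %in% s), TRUE))
      if (!length(hit)) next
      new_cols <- cols[-hit]
      for (h in hit) {
        s <- cols[[h]]
        new_cols <- c(new_cols, list(setdiff(s, i)), list(setdiff(s, j)))
      }
      cols <- absorb(new_cols)
    }
  }
  cols[order(vapply(cols, min, 0L))]
}

#' Tukey HSD compact letter display over factor levels
#'
#' One-way ANOVA across the levels (replicate-level values within each
#' level supply the pooled within-level variance), all pairwise comparisons
#' by the studentized-range (Tukey-Kramer) statistic, and a compact letter
#' display assembled by insert-and-absorb. Letters are assigned in
#' descending order of level means, so `"a"` marks the highest mean and
#' levels sharing a letter are not significantly different at `alpha`.
#'
#' @param value numeric vector of replicate-level observations (e.g.
#'   predictive abilities).
#' @param level factor/vector of the same length giving each observation's
#'   level; at least 2 levels with at least 2 replicates each.
#' @param alpha familywise significance level (default 0.05).
#' @return a `tukey_cld` data frame (`level`, `n`, `mean`, `letters`,
#'   descending mean order) with attributes `alpha`, `p_matrix`,
#'   `ms_error`, `df_error`.
#' @export
tukey_cld <- function(value, level, alpha = 0.05) {
  stopifnot(length(value) == length(level), alpha > 0, alpha < 1)
  if (!all(is.finite(value))) stop("non-finite values")
  lf <- factor(level)
  k <- nlevels(lf)
  if (k < 2) stop("need at least 2 levels")
  vs <- split(value, lf)
  n_i <- lengths(vs)
  if (any(n_i < 2)) {
    stop("level(s) with a single replicate: ",
         paste(names(vs)[n_i < 2], collapse = ", "))
  }
  means <- vapply(vs, mean, 0)
  N <- sum(n_i)
  dfe <- N - k
  ms <- sum(vapply(vs, function(v) sum((v - mean(v))^2), 0)) / dfe
  ord <- order(-means)
  labs <- names(vs)[ord]
  mo <- unname(means[ord])
  no <- unname(n_i[ord])
  pmat <- matrix(1, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d <- abs(mo[i] - mo[j])
      p <- if (ms <= 0) {
        if (d > 0) 0 else 1
      } else {
        stats::ptukey(d / sqrt(ms / 2 * (1 / no[i] + 1 / no[j])),
                      nmeans = k, df = dfe, lower.tail = FALSE)
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  cols <- .cld_insert_absorb(pmat < alpha)
  letts <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(s) i %in% s, TRUE))],
          collapse = "")
  }, "")
  out <- data.frame(level = labs, n = no, mean = mo, letters = letts,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "p_matrix") <- pmat
  attr(out, "ms_error") <- ms
  attr(out, "df_error") <- dfe
  class(out) <- c("tukey_cld", "data.frame")
  out
}

#' Do two levels of a compact letter display share a letter?
#'
#' @param cld a [tukey_cld()] result.
#' @param a,b level labels.
#' @return logical: `TRUE` when not significantly different.
#' @export
cld_shares_letter <- function(cld, a, b) {
  la <- cld$letters[match(as.character(a), cld$level)]
  lb <- cld$letters[match(as.character(b), cld$level)]
  if (is.na(la) || is.na(lb)) stop("level not found in the display")
  any(strsplit(la, "")[[1]] %in% strsplit(lb, "")[[1]])
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("Tukey HSD compact letter display (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Percentage of variance explained by leading principal components
#'
#' Eigendecomposition of a (symmetric) relationship matrix; returns
#' `100 * lambda_j / sum(max(lambda_i, 0))` for the top `k` components
#' (negative eigenvalues are clipped to zero in the denominator).
#'
#' @param G symmetric matrix.
#' @param k number of leading components (default 1).
#' @return numeric vector of percentages, decreasing.
#' @export
pc_variance_explained <- function(G, k = 1) {
  stopifnot(is.matrix(G), k >= 1, k <= nrow(G))
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  pos <- pmax(ev, 0)
  if (sum(pos) <= 0) stop("matrix has no positive eigenvalue")
  100 * pos[seq_len(k)] / sum(pos)
}

#' Sequencing-budget arithmetic
#'
#' Data needed per sample is `genome_gb * depth`; the number of samples that
#' can be multiplexed per flow-cell run is `flowcell_gb` divided by that,
#' rounded to the nearest integer by default (e.g. a 0.6 Gb genome at 12X
#' needs 7.2 Gb per sample, so a 3000 Gb flow cell carries 417 samples; at
#' 60X, 36 Gb and 83 samples).
#'
#' @param genome_gb genome size in Gb (default 0.6).
#' @param depth target average sequencing depth (X).
#' @param flowcell_gb flow-cell output in Gb (default 3000).
#' @param rounding `"nearest"` (default), `"floor"` or `"ceiling"`.
#' @return list with `gb_per_sample` and `samples_per_run`.
#' @export
sequencing_budget <- function(genome_gb = 0.6, depth, flowcell_gb = 3000,
                              rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!(genome_gb > 0 && depth > 0 && flowcell_gb > 0)) {
    stop("all inputs must be positive")
  }
  gb <- genome_gb * depth
  spr <- switch(rounding,
                nearest = round(flowcell_gb / gb),
                floor = floor(flowcell_gb / gb),
                ceiling = ceiling(flowcell_gb / gb))
  list(gb_per_sample = gb, samples_per_run = as.integer(spr))
}
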