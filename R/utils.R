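`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and context labels
#'
#' Every stochastic step of the package takes an explicit seed. Grid runners
#' derive one seed per (scenario, replicate, ...) cell from a single master
#' seed and a set of context labels, by hashing the labels into a 31-bit
#' integer. The mapping is deterministic and independent of R's RNG state.
#'
#' @param master integer master seed.
#' @param ... context labels (coerced to character) identifying the cell.
#' @return an integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "depth", 6, 2)
#' @export
derive_seed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), paste, "", collapse = "_")),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# set.seed only when a seed is supplied; NULL means "continue the RNG stream"
.seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Effective sample size of an MCMC draw sequence
#'
#' Crude spectral estimate: n / (1 + 2 * sum of positive initial-sequence
#' autocorrelations). Used for chain diagnostics only.
#'
#' @param x numeric vector of (thinned) posterior draws.
#' @return effective sample size (numeric scalar).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(100L, n - 2L), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}
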