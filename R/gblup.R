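# G-BLUP on continuous ratio genotypes. The genomic relationship matrix is
# G = ZZ'/h, where Z is the column-centered ratio matrix M and
# h = sum_i s_i^2 is the summed sample variance of the centered marker
# vectors — the "ratio" relationship of tetraploid read-fraction genotypes.
# The mixed model y = mu + g + e, g ~ MVN(0, G sigma_a^2),
# e ~ MVN(0, I sigma_e^2), is fit by Gibbs sampling with scaled-inverse-
# chi-square priors on both variances; a closed-form BLUP solver at fixed
# variance components serves as the deterministic oracle.

#' Genomic relationship matrix from ratio genotypes
#'
#' `G = ZZ'/h` with `Z` the column-centered ratio matrix and
#' `h = sum(s_i^2)`, `s_i^2` the sample variance (divisor `n - 1`) of the
#' i-th centered marker vector. With this divisor the identities
#' `rowSums(G) = 0` and `trace(G) = n - 1` hold exactly for any complete
#' `M`; monomorphic markers contribute zero and are tolerated (an all-
#' monomorphic matrix, `h = 0`, is an error). `G` is invariant to rescaling
#' the spread of all marker columns by a common constant.
#'
#' @param M complete numeric matrix of ratio genotypes (individuals x
#'   markers), entries in `[0, 1]`, rownames = individual ids.
#' @return an n x n symmetric matrix with attributes `h` (scale factor) and
#'   `m` (marker count).
#' @export
build_g <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2, ncol(M) >= 1)
  if (anyNA(M)) stop("M must be complete (impute or filter first)")
  Z <- sweep(M, 2, colMeans(M))
  h <- sum(colSums(Z^2)) / (nrow(M) - 1)
  if (h <= 0) stop("all markers monomorphic (h = 0)")
  G <- tcrossprod(Z) / h
  rownames(G) <- colnames(G) <- rownames(M)
  attr(G, "h") <- h
  attr(G, "m") <- ncol(M)
  G
}

#' Gibbs chain settings
#'
#' Reference-analysis defaults: 35,000 iterations, 5,000 burn-in, thinning
#' of five. Desk-scale runs use shorter chains (see [reduced_chains()]).
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations.
#' @param thin thinning interval.
#' @return a `chain_control` list.
#' @export
chain_control <- function(n_iter = 35000, burn_in = 5000, thin = 5) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)),
            class = "chain_control")
}

#' Shortened chain settings for desk-scale grids
#'
#' @param n_iter,burn_in,thin see [chain_control()].
#' @return a `chain_control` list.
#' @export
reduced_chains <- function(n_iter = 2000, burn_in = 500, thin = 5) {
  chain_control(n_iter, burn_in, thin)
}

# Eigen-decompose G once and pre-rotate so every Gibbs update is diagonal:
# with G = U D U' (rank k), write g = W alpha, W = U D^(1/2), alpha ~
# N(0, sigma_a^2 I). For the training rows W_t, a second eigendecomposition
# W_t'W_t = V S V' gives T = W_t V with T'T = S diagonal, so the full
# conditional of beta = V'alpha factorizes coordinate-wise.
.g_factor <- function(G, train_idx) {
  tr <- sum(diag(G))
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * tr) {
    stop("G is not positive semi-definite (min eigenvalue ",
         signif(min(eg$values), 3), ")")
  }
  d <- pmax(eg$values, 0)
  keep <- d > 1e-12 * max(d)
  W_all <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d[keep]),
                                                     sum(keep))
  W <- W_all[train_idx, , drop = FALSE]
  ea <- eigen(crossprod(W), symmetric = TRUE)
  S <- pmax(ea$values, 0)
  list(TT = W %*% ea$vectors, WallV = W_all %*% ea$vectors, S = S)
}

#' Fit the G-BLUP mixed model by Gibbs sampling
#'
#' Samples the model `y = mu + g + e` on the training records with
#' `g ~ MVN(0, G sigma_a^2)` over *all* individuals in `G` (training and
#' candidates jointly, so candidate genetic values are posterior draws, not
#' a post-hoc projection), `e ~ MVN(0, I sigma_e^2)`, a flat prior on `mu`,
#' and scaled-inverse-chi-square priors on both variances with `df0` degrees
#' of freedom and scales set from the phenotypic variance split by `R2`
#' (the default-hyper-parameter convention of Bayesian whole-genome
#' regression software). Supplying `sigma2_a`/`sigma2_e` fixes that variance
#' (no update), which makes the posterior mean of `g` the classical BLUP —
#' the equivalence exploited by the test oracle.
#'
#' @param y named numeric vector of adjusted phenotypes (must cover
#'   `train_ids`).
#' @param G relationship matrix from [build_g()] (ids in rownames).
#' @param train_ids ids used as training records (default `names(y)`).
#' @param chains a [chain_control()].
#' @param df0 prior degrees of freedom (default 5).
#' @param R2 prior variance split assigned to the genetic term (default 0.5).
#' @param sigma2_a,sigma2_e optional fixed variance components.
#' @param seed optional integer seed.
#' @return a `gblup_fit`: posterior means `mu`, `g` (all individuals in
#'   `G`), `sigma2_a`, `sigma2_e`; stored-sample traces in `$samples`;
#'   effective sample sizes in `$diagnostics`.
#' @export
fit_gibbs <- function(y, G, train_ids = names(y), chains = chain_control(),
                      df0 = 5, R2 = 0.5, sigma2_a = NULL, sigma2_e = NULL,
                      seed = NULL) {
  stopifnot(inherits(chains, "chain_control"), df0 > 0, R2 > 0, R2 < 1)
  ids <- rownames(G)
  if (is.null(ids)) stop("G must carry individual ids as rownames")
  if (!all(train_ids %in% ids)) stop("train_ids absent from G")
  if (!all(train_ids %in% names(y))) stop("y missing for some train_ids")
  y <- y[train_ids]
  if (!all(is.finite(y))) stop("non-finite phenotypes")
  .seed(seed)
  n <- length(y)
  train_idx <- match(train_ids, ids)
  fac <- .g_factor(G, train_idx)
  TT <- fac$TT; S <- fac$S; k <- length(S)
  Ty <- drop(crossprod(TT, y))
  T1 <- drop(crossprod(TT, rep(1, n)))
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) vy <- 1e-8
  mdg <- mean(diag(G)[train_idx])
  Sa <- vy * R2 * (df0 + 2) / max(mdg, 1e-12)
  Se <- vy * (1 - R2) * (df0 + 2)
  fix_a <- !is.null(sigma2_a)
  fix_e <- !is.null(sigma2_e)
  s2a <- if (fix_a) sigma2_a else vy * R2 / max(mdg, 1e-12)
  s2e <- if (fix_e) sigma2_e else vy * (1 - R2)
  stopifnot(s2a > 0, s2e > 0)
  mu <- mean(y)
  beta <- numeric(k)
  n_store <- (chains$n_iter - chains$burn_in) %/% chains$thin
  beta_sum <- numeric(k)
  mu_s <- s2a_s <- s2e_s <- numeric(n_store)
  st <- 0L
  for (it in seq_len(chains$n_iter)) {
    prec <- S / s2e + 1 / s2a
    bmean <- (Ty - T1 * mu) / s2e / prec
    beta <- bmean + stats::rnorm(k) / sqrt(prec)
    gt <- drop(TT %*% beta)
    mu <- stats::rnorm(1, mean(y - gt), sqrt(s2e / n))
    if (!fix_a) s2a <- (sum(beta^2) + df0 * Sa) / stats::rchisq(1, k + df0)
    if (!fix_e) {
      r <- y - mu - gt
      s2e <- (sum(r^2) + df0 * Se) / stats::rchisq(1, n + df0)
    }
    if (it > chains$burn_in && (it - chains$burn_in) %% chains$thin == 0) {
      st <- st + 1L
      beta_sum <- beta_sum + beta
      mu_s[st] <- mu
      s2a_s[st] <- s2a
      s2e_s[st] <- s2e
    }
  }
  g_hat <- drop(fac$WallV %*% (beta_sum / n_store))
  names(g_hat) <- ids
  structure(list(
    mu = mean(mu_s),
    g = g_hat,
    sigma2_a = mean(s2a_s),
    sigma2_e = mean(s2e_s),
    samples = list(mu = mu_s, sigma2_a = s2a_s, sigma2_e = s2e_s),
    chains = chains,
    train_ids = train_ids,
    fixed = c(sigma2_a = fix_a, sigma2_e = fix_e),
    diagnostics = list(ess_mu = ess(mu_s),
                       ess_sigma2_a = ess(s2a_s),
                       ess_sigma2_e = ess(s2e_s)),
    method = "gibbs"),
    class = "gblup_fit")
}

#' Closed-form BLUP at fixed variance components
#'
#' Deterministic mixed-model solution at variance ratio
#' `lambda = sigma2_e / sigma2_a`: the intercept is the GLS mean under
#' `V = G_tt sigma2_a + I sigma2_e`, training genetic values solve
#' `(G_tt + lambda I) alpha = y - mu`, and candidate individuals are
#' predicted by the conditional expectation `G_ct alpha` implied by the
#' partitioned `G`. Serves as the exact oracle for [fit_gibbs()] run at the
#' same fixed variances.
#'
#' @param y named numeric vector of adjusted phenotypes.
#' @param G relationship matrix (ids in rownames).
#' @param train_ids training ids (default `names(y)`).
#' @param sigma2_a,sigma2_e positive variance components.
#' @return a `gblup_fit` with `mu` and `g` (all individuals in `G`).
#' @export
fit_closed_form <- function(y, G, train_ids = names(y), sigma2_a, sigma2_e) {
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  ids <- rownames(G)
  if (!all(train_ids %in% ids)) stop("train_ids absent from G")
  y <- y[train_ids]
  if (!all(is.finite(y))) stop("non-finite phenotypes")
  t_idx <- match(train_ids, ids)
  Gtt <- G[t_idx, t_idx, drop = FALSE]
  n <- length(y)
  V <- sigma2_a * Gtt + diag(sigma2_e, n)
  cv <- tryCatch(chol(V), error = function(e) stop("singular system: ", conditionMessage(e)))
  Vi1 <- backsolve(cv, forwardsolve(t(cv), rep(1, n)))
  Viy <- backsolve(cv, forwardsolve(t(cv), y))
  mu <- sum(Viy) / sum(Vi1)
  lambda <- sigma2_e / sigma2_a
  alpha <- solve(Gtt + diag(lambda, n), y - mu)
  g_hat <- drop(G[, t_idx, drop = FALSE] %*% alpha)
  names(g_hat) <- ids
  structure(list(mu = mu, g = g_hat, sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e, train_ids = train_ids,
                 method = "blup"),
            class = "gblup_fit")
}

#' Predicted values from a G-BLUP fit
#'
#' Returns `mu + g` (posterior means) for the requested individuals. Asking
#' for a training individual returns its fitted value (allowed, but
#' reported via a message).
#'
#' @param object a `gblup_fit`.
#' @param ids individuals to predict (default: all in the fit).
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.gblup_fit <- function(object, ids = NULL, ...) {
  ids <- ids %||% names(object$g)
  missing_ids <- setdiff(ids, names(object$g))
  if (length(missing_ids)) {
    stop("id(s) absent from the fitted G: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  overlap <- intersect(ids, object$train_ids)
  if (length(overlap)) {
    message(length(overlap), " requested id(s) were in the training set; ",
            "returning fitted values")
  }
  object$mu + object$g[ids]
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit (", x$method, "): ", length(x$g), " individuals, ",
      length(x$train_ids), " training records\n", sep = "")
  cat("  mu = ", signif(x$mu, 4), "; sigma2_a = ", signif(x$sigma2_a, 4),
      "; sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  invisible(x)
}
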