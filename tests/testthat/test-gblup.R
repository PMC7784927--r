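# Relationship matrix identities, closed-form BLUP, Gibbs sampler.

test_that("G = ZZ'/h reproduces the hand-computed 2x2 example", {
  M <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
  G <- build_g(M)
  # Z = (-0.5, 0.5), s2 = 0.5, h = 0.5 -> G = [[0.5, -0.5], [-0.5, 0.5]]
  expect_equal(unclass(G)[1:2, 1:2],
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(attr(G, "h"), 0.5)
})

test_that("G satisfies the centering identities for arbitrary complete M", {
  set.seed(23)
  for (n in c(5, 30)) {
    M <- matrix(runif(n * 40), n, 40,
                dimnames = list(sprintf("i%02d", 1:n), NULL))
    G <- build_g(M)
    expect_lt(max(abs(rowSums(G))), 1e-10)
    expect_lt(abs(sum(diag(G)) - (n - 1)), 1e-10)
    expect_lt(max(abs(G - t(G))), 1e-12)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("G is invariant to common rescaling of marker spread", {
  set.seed(29)
  M <- matrix(runif(200), 20, 10, dimnames = list(sprintf("i%02d", 1:20), NULL))
  G1 <- build_g(M)
  G2 <- build_g(0.5 + (M - 0.5) * 3)  # triple every column's spread
  expect_equal(unclass(G1), unclass(G2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # monomorphic columns tolerated; all-monomorphic errors
  expect_silent(build_g(cbind(M, const = 0.5)))
  expect_error(build_g(matrix(0.25, 5, 3,
                              dimnames = list(letters[1:5], NULL))),
               "monomorphic")
  Mna <- M; Mna[1, 1] <- NA
  expect_error(build_g(Mna), "complete")
})

test_that("closed-form BLUP matches the hand-solved 3-individual system", {
  M <- matrix(c(0, 0.5, 1), 3, 1, dimnames = list(c("a", "b", "c"), "m1"))
  G <- build_g(M)  # [[1,0,-1],[0,0,0],[-1,0,1]]
  f <- fit_closed_form(c(a = 1, b = 2, c = 3), G, sigma2_a = 1, sigma2_e = 1)
  # hand solution of the mixed-model equations at lambda = 1:
  # mu = 2, alpha = (-1/3, 0, 1/3), g = G alpha = (-2/3, 0, 2/3)
  expect_lt(abs(f$mu - 2), 1e-10)
  expect_lt(max(abs(f$g - c(a = -2 / 3, b = 0, c = 2 / 3))), 1e-10)
})

test_that("closed-form BLUP has the right shrinkage limits", {
  set.seed(31)
  M <- matrix(runif(20 * 50), 20, 50,
              dimnames = list(sprintf("i%02d", 1:20), NULL))
  G <- build_g(M)
  y <- setNames(rnorm(20), rownames(G))
  # lambda -> Inf: everything shrinks to zero
  f_inf <- fit_closed_form(y, G, sigma2_a = 1e-8, sigma2_e = 1)
  expect_lt(max(abs(f_inf$g)), 1e-5)
  # lambda -> 0 with nonsingular G_tt: training fits interpolate y - mu
  f0 <- fit_closed_form(y, G, sigma2_a = 1, sigma2_e = 1e-10)
  expect_lt(max(abs(f0$mu + f0$g[names(y)] - y)), 1e-3)
})

test_that("BLUP predicts held-out individuals via the G partition", {
  set.seed(37)
  M <- matrix(runif(30 * 80), 30, 80,
              dimnames = list(sprintf("i%02d", 1:30), NULL))
  G <- build_g(M)
  y <- setNames(rnorm(30), rownames(G))
  train <- rownames(G)[1:20]
  f <- fit_closed_form(y, G, train_ids = train, sigma2_a = 2, sigma2_e = 1)
  test <- rownames(G)[21:30]
  # conditional expectation: G_ct (G_tt + lambda I)^-1 (y_t - mu)
  lam <- 1 / 2
  alpha <- solve(G[train, train] + diag(lam, 20), y[train] - f$mu)
  expect_equal(unname(f$g[test]), unname(drop(G[test, train] %*% alpha)),
               tolerance = 1e-10)
  expect_equal(unname(predict(f, test)), unname(f$mu + f$g[test]))
  expect_error(predict(f, "nope"), "absent")
})

test_that("Gibbs posterior means agree with closed-form BLUP at fixed variances", {
  set.seed(41)
  n <- 30
  M <- matrix(runif(n * 100), n, 100,
              dimnames = list(sprintf("i%02d", 1:n), NULL))
  G <- build_g(M)
  g0 <- drop(chol(G + diag(1e-6, n)) %*% rnorm(n))  # correlated signal
  y <- setNames(g0 + rnorm(n, 0, 0.5), rownames(G))
  train <- rownames(G)[1:22]
  fg <- fit_gibbs(y, G, train_ids = train,
                  chains = chain_control(12000, 2000, 2),
                  sigma2_a = 1, sigma2_e = 0.25, seed = 42)
  fb <- fit_closed_form(y, G, train_ids = train, sigma2_a = 1,
                        sigma2_e = 0.25)
  expect_gt(cor(fg$g, fb$g), 0.99)
  expect_lt(abs(fg$mu - fb$mu), 0.1)
  # fixed variances are not updated
  expect_equal(fg$sigma2_a, 1)
  expect_equal(fg$sigma2_e, 0.25)
})

test_that("Gibbs with no signal collapses to the intercept", {
  set.seed(43)
  M <- matrix(runif(15 * 30), 15, 30,
              dimnames = list(sprintf("i%02d", 1:15), NULL))
  G <- build_g(M)
  y <- setNames(rep(7, 15), rownames(G))
  f <- fit_gibbs(y, G, chains = chain_control(2000, 500, 2), seed = 44)
  expect_lt(max(abs(f$g)), 0.05)
  expect_lt(abs(f$mu - 7), 0.05)
  expect_lt(f$sigma2_a, 1e-4)
  p <- suppressMessages(predict(f, rownames(G)))
  expect_lt(max(abs(p - 7)), 0.1)
})

test_that("Gibbs fit validates its inputs and reports diagnostics", {
  set.seed(47)
  M <- matrix(runif(10 * 20), 10, 20,
              dimnames = list(sprintf("i%02d", 1:10), NULL))
  G <- build_g(M)
  y <- setNames(rnorm(10), rownames(G))
  expect_error(fit_gibbs(y, G, train_ids = c("i01", "zz")), "absent")
  expect_error(fit_gibbs(c(y[-1], zz = 1), G), "absent|missing")
  bad <- G; bad[1, 2] <- bad[2, 1] <- -50
  expect_error(fit_gibbs(y, bad, chains = chain_control(100, 10, 1)),
               "positive semi-definite")
  f <- fit_gibbs(y, G, chains = chain_control(600, 100, 5), seed = 48)
  expect_identical(length(f$samples$sigma2_a), 100L)
  expect_true(all(unlist(f$diagnostics) > 0))
  expect_true(f$sigma2_a > 0 && f$sigma2_e > 0)
})

test_that("prediction accuracy increases with heritability", {
  accs <- sapply(c(0.2, 0.8), function(h2) {
    mean(sapply(1:5, function(r) {
      pop <- sim_study_population(
        preset = "demo", seed = derive_seed(100 * h2, r),
        n_markers = 300,
        cross_plan = make_cross_plan(sprintf("F%03d", 1:20), rep(25L, 10),
                                     seed = r),
        traits = list(t = trait_architecture(100, h2, "normal", name = "t")))
      M <- ratio_genotypes(pop$counts)
      G <- build_g(M)
      y <- lsmeans_phenotypes(pop$phenotypes[, c("individual_id", "year",
                                                 "value")])
      test <- make_test_sets(rownames(G), 50, 1, seed = r)[[1]]
      f <- fit_gibbs(y, G, train_ids = setdiff(rownames(G), test),
                     chains = chain_control(800, 200, 3),
                     seed = derive_seed(r, "fit"))
      cor(predict(f, test), pop$truth$t$g_true[test])
    }))
  })
  expect_gt(accs[2], accs[1])
})

test_that("full sibs share more relationship than non-sibs", {
  map <- make_marker_map(400, 4, seed = 53)
  f <- simulate_founders(4, map, seed = 54)
  plan <- data.frame(family_id = c("A", "B"),
                     parent1 = c("F001", "F003"), parent2 = c("F002", "F004"),
                     n_offspring = c(25L, 25L))
  cr <- simulate_crosses(f, plan, seed = 55)
  rc <- simulate_read_counts(cr$dosages, 60, 2, 0, seed = 56)
  G <- build_g(ratio_genotypes(rc))
  fam <- cr$pedigree$family_id
  same <- outer(fam, fam, "==") & upper.tri(G)
  diff <- !outer(fam, fam, "==") & upper.tri(G)
  expect_gt(mean(G[same]), mean(G[diff]))
})
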