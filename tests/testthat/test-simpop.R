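# Synthetic-population generator: founder allele frequencies and LD,
# tetrasomic gamete laws, cross dosages, trait heritability, read counts.

test_that("founder allele frequencies match the target and LD follows the chain", {
  map <- flat_map(paste0("m", 1:30))
  # 2500 founders = 10,000 haplotypes at a fixed frequency of 0.30
  f <- simulate_founders(2500, map, maf_range = c(0.3, 0.3), ld_rho = 0,
                         seed = 11)
  freq <- colMeans(f$H)
  expect_true(all(abs(freq - 0.30) < 0.02))
  # independence at rho = 0
  r_adj <- cor(f$H[, 10], f$H[, 11])
  expect_lt(abs(r_adj), 0.05)
  # strong chain: adjacent correlation exceeds 10-markers-apart correlation
  f9 <- simulate_founders(1000, map, maf_range = c(0.3, 0.3), ld_rho = 0.9,
                          seed = 12)
  expect_gt(cor(f9$H[, 10], f9$H[, 11]), cor(f9$H[, 5], f9$H[, 15]))
  expect_gt(cor(f9$H[, 10], f9$H[, 11]), 0.7)
})

test_that("founder simulation rejects bad inputs", {
  map <- flat_map(c("a", "b"))
  expect_error(simulate_founders(5, map, ld_rho = 1), "ld_rho")
  expect_error(simulate_founders(5, map, ld_rho = -0.1), "ld_rho")
  expect_error(simulate_founders(5, map, maf_range = c(0, 0.5)), "maf_range")
  expect_error(validate_marker_map(data.frame()), "columns|empty")
})

test_that("gamete allele counts follow the 2-of-4 sampling law", {
  map <- one_marker_map()
  # nulliplex: always 0; quadriplex: always 2
  set.seed(1)
  expect_true(all(replicate(50, sum(make_gamete(one_locus_parent(0), map))) == 0))
  expect_true(all(replicate(50, sum(make_gamete(one_locus_parent(4), map))) == 2))
  # simplex: carries the allele with probability 1/2
  draws <- replicate(4000, sum(make_gamete(one_locus_parent(1), map)))
  expect_true(all(draws %in% 0:1))
  expect_lt(abs(mean(draws) - 0.5), 0.03)
  # duplex: hypergeometric P(0,1,2) = (1/6, 4/6, 1/6)
  draws2 <- replicate(6000, sum(make_gamete(one_locus_parent(2), map)))
  p <- tabulate(draws2 + 1L, 3) / 6000
  expect_true(all(abs(p - c(1, 4, 1) / 6) < 0.025))
})

test_that("crosses produce the expected dosage distributions", {
  map <- one_marker_map()
  founders <- founder_haplotypes(
    list(one_locus_parent(0), one_locus_parent(4), one_locus_parent(2)),
    map, founder_ids = c("null", "quad", "dup"))
  plan <- data.frame(family_id = c("f1", "f2", "f3"),
                     parent1 = c("null", "quad", "dup"),
                     parent2 = c("null", "null", "dup"),
                     n_offspring = c(30L, 30L, 4000L))
  cr <- simulate_crosses(founders, plan, seed = 21)
  d1 <- cr$dosages[cr$pedigree$family_id == "f1", 1]
  d2 <- cr$dosages[cr$pedigree$family_id == "f2", 1]
  d3 <- cr$dosages[cr$pedigree$family_id == "f3", 1]
  expect_true(all(d1 == 0))           # nulliplex x nulliplex
  expect_true(all(d2 == 2))           # quadriplex x nulliplex: forced
  # duplex x duplex: mean 2, variance = 2 * Var(hypergeometric gamete) = 2/3
  expect_lt(abs(mean(d3) - 2), 0.05)
  expect_lt(abs(var(d3) - 2 / 3), 0.06)
  expect_error(
    simulate_crosses(founders, data.frame(family_id = "x", parent1 = "nope",
                                          parent2 = "null", n_offspring = 1L)),
    "unknown parent")
})

test_that("simulated phenotypes hit the target heritability", {
  map <- flat_map(paste0("m", 1:200))
  f <- simulate_founders(40, map, seed = 31)
  plan <- make_cross_plan(f$founder_ids, rep(50L, 20), seed = 31)
  cr <- simulate_crosses(f, plan, seed = 32)
  arch <- trait_architecture(100, 0.5, "normal", year_effects = c(0, 1))
  sim <- simulate_phenotypes(cr$dosages, arch, years = c(1, 2), seed = 33)
  d <- sim$phenotypes[sim$phenotypes$year == 1, ]
  g <- sim$truth$g_true[d$individual_id]
  # realized h2 within 0.05 of target at n = 1000
  expect_lt(abs(var(g) / var(d$value) - 0.5), 0.05)
  # law of total variance: year-corrected phenotype regresses on g with slope 1
  slope <- coef(lm(d$value ~ g))[2]
  expect_lt(abs(slope - 1), 0.1)
  # h2 = 1: across-year difference is exactly the year effect
  sim1 <- simulate_phenotypes(cr$dosages, trait_architecture(100, 1),
                              years = c(1, 2), seed = 34)
  w <- reshape(sim1$phenotypes, idvar = "individual_id", timevar = "year",
               direction = "wide")
  expect_equal(w$value.2 - w$value.1, rep(0.5, nrow(w)), tolerance = 1e-12)
  # degenerate: monomorphic dosages cannot support h2 > 0
  expect_error(
    simulate_phenotypes(matrix(2L, 50, 10), trait_architecture(5, 0.5)),
    "zero genetic variance")
})

test_that("read counts follow the truncated-Poisson/binomial model", {
  dos <- matrix(rep(c(0L, 2L, 4L), each = 2000), 2000, 3)
  dimnames(dos) <- list(sprintf("i%04d", 1:2000), c("d0", "d2", "d4"))
  rc <- simulate_read_counts(dos, mean_depth = 60, min_depth = 2,
                             error_rate = 0, seed = 41)
  expect_true(all(rc$AO[, "d0"] == 0))
  expect_true(all(rc$RO[, "d4"] == 0))
  ratio <- rc$AO[, "d2"] / (rc$AO[, "d2"] + rc$RO[, "d2"])
  expect_lt(abs(mean(ratio) - 0.5), 0.01)
  expect_true(all(rc_depth(rc) >= 2))
  # truncation semantics: resampled depths beat clamped ones above min_depth
  rc_low <- simulate_read_counts(dos, mean_depth = 1, min_depth = 2, seed = 42)
  expect_true(all(rc_depth(rc_low) >= 2))
  rc_cl <- simulate_read_counts(dos, mean_depth = 1, min_depth = 2, seed = 42,
                                truncation = "clamp")
  expect_gt(mean(rc_depth(rc_cl) == 2), 0.7)  # clamping piles mass at 2
  expect_error(simulate_read_counts(dos, 60, 2, error_rate = 0.5), "error_rate")
})

test_that("study cross plan reproduces the reference population layout", {
  plan <- study_cross_plan(seed = 51)
  expect_identical(nrow(plan), 117L)
  expect_identical(sum(plan$n_offspring), 1804L)
  expect_identical(length(unique(c(plan$parent1, plan$parent2))), 146L)
  big <- plan$n_offspring >= 10
  expect_identical(sum(big), 103L)
  expect_identical(sum(plan$n_offspring[big]), 1706L)
})

test_that("population bundle is coherent and writable", {
  pop <- sim_study_population(preset = "demo", seed = 61, n_markers = 240,
                              cross_plan = make_cross_plan(
                                sprintf("F%03d", 1:12), rep(10L, 6), seed = 1))
  expect_identical(dim(pop$dosages), c(60L, 240L))
  expect_true(all(pop$dosages %in% 0:4))
  expect_identical(rownames(pop$counts$AO), pop$pedigree$individual_id)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  expect_true(all(file.exists(file.path(dir, c("pedigree.tsv", "AO.tsv",
                                               "RO.tsv", "phenotypes.tsv",
                                               "marker_map.tsv")))))
  rc <- read_counts(file.path(dir, "AO.tsv"), file.path(dir, "RO.tsv"))
  expect_identical(rc$AO, pop$counts$AO)
})
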