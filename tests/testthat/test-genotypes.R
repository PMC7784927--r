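# Allele-count input, filtering, ratio genotypes, LSMeans adjustment.

test_that("TSV count pairs round-trip and mismatches are rejected", {
  rc <- toy_counts()
  a <- withr::local_tempfile(); r <- withr::local_tempfile()
  write_counts(rc, a, r)
  rc2 <- read_counts(a, r)
  expect_identical(rc2$AO, rc$AO)
  expect_identical(rc2$RO, rc$RO)
  # a marker present in AO but absent from RO is an error
  ro_bad <- data.table::fread(r, data.table = FALSE)
  ro_bad$m3 <- NULL
  r2 <- withr::local_tempfile()
  data.table::fwrite(ro_bad, r2, sep = "\t")
  expect_error(read_counts(a, r2), "marker ids differ")
})

test_that("VCF allele depths map to AO/RO and filters act at parse", {
  # one sample, one biallelic site, allele depths (9, 3) -> RO 9, AO 3
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\tsnp1\tA\tC\t99\tPASS\tMQ=60\tAD\t9,3",
    "1\t200\tsnp2\tA\tC,G\t99\tPASS\tMQ=60\tAD\t4,3,2",   # multiallelic: skipped
    "1\t300\tsnp3\tA\tC\t5\tPASS\tMQ=60\tAD\t5,5",        # QUAL < 10: dropped
    "1\t400\tsnp4\tA\tC\t99\tPASS\tMQ=10\tAD\t6,6"        # MQ < 20: dropped
  ), vcf)
  rc <- read_counts(vcf_path = vcf)
  expect_identical(colnames(rc$AO), "snp1")
  expect_identical(unname(rc$AO[1, 1]), 3L)
  expect_identical(unname(rc$RO[1, 1]), 9L)
  rep <- attr(rc, "vcf_report")
  expect_identical(rep$n_multiallelic_skipped, 1L)
  expect_identical(rep$n_quality_dropped, 2L)
  # round trip through the writer
  map <- flat_map("snp1")
  out <- withr::local_tempfile(fileext = ".vcf")
  write_counts_vcf(rc, map, out)
  rc2 <- read_counts(vcf_path = out)
  expect_identical(rc2$AO, rc$AO)
  expect_identical(rc2$RO, rc$RO)
})

test_that("filters drop markers in the documented order with counts", {
  # m1: low site-mean depth; m2: healthy; m3: near-fixed ratio (MAF < 0.05)
  rc <- toy_counts()
  map <- flat_map(colnames(rc$AO))
  th <- filter_thresholds(min_site_mean_depth = 60, min_datapoint_depth = 2,
                          max_missing = 0.5, min_maf = 0.05)
  out <- apply_filters(rc, map, th)
  rep <- out$report
  # m1 depths: 12, 7, 7, 2 -> site mean 7 < 60 -> dropped at step 3
  # m2 depths: 60..65 -> site mean >= 60 -> kept
  # m3 depths: 61, 60, 62, 62 -> kept by depth, mean ratio ~ 0.966 -> MAF drop
  expect_identical(colnames(out$counts$AO), "m2")
  expect_identical(rep$low_depth_markers_dropped, 1L)
  expect_identical(rep$low_maf_markers_dropped, 1L)
  # hand check of the MAF that removed m3
  ratio3 <- rc$AO[, 3] / (rc$AO[, 3] + rc$RO[, 3])
  expect_lt(1 - mean(ratio3), 0.05)
})

test_that("no-op thresholds leave the data untouched and filtering is idempotent", {
  rc <- toy_counts()
  map <- flat_map(colnames(rc$AO))
  noop <- filter_thresholds(min_site_mean_depth = 0, min_datapoint_depth = 0,
                            max_missing = 1, min_maf = 0)
  out <- apply_filters(rc, map, noop)
  expect_identical(out$counts$AO, rc$AO)
  expect_identical(out$counts$RO, rc$RO)
  th <- filter_thresholds(min_site_mean_depth = 50, min_datapoint_depth = 2,
                          max_missing = 0.5, min_maf = 0.05)
  once <- apply_filters(rc, map, th)
  twice <- apply_filters(once$counts, map, th)
  expect_identical(twice$counts$AO, once$counts$AO)
  expect_identical(twice$counts$RO, once$counts$RO)
  # chromosome whitelist drops whole chromosomes
  th2 <- filter_thresholds(0, 0, 1, 0, chrom_whitelist = 2)
  expect_error(apply_filters(rc, map, th2), "all markers filtered out")
})

test_that("ratio genotypes implement #a/(#A + #a) with guards", {
  AO <- matrix(c(3L, 0L, 7L, 1L), 2, 2,
               dimnames = list(c("i1", "i2"), c("m1", "m2")))
  RO <- matrix(c(9L, 7L, 0L, 1L), 2, 2, dimnames = dimnames(AO))
  M <- ratio_genotypes(read_count_matrix(AO, RO))
  expect_equal(M, matrix(c(0.25, 0, 1, 0.5), 2, 2, dimnames = dimnames(AO)),
               ignore_attr = TRUE)
  # zero-depth cell names the culprit
  RO[2, 1] <- 0L
  AO[2, 1] <- 0L
  expect_error(ratio_genotypes(read_count_matrix(AO, RO)), "i2.*m1")
  # missing cells are mean-imputed and counted
  AO2 <- matrix(c(4L, NA, 2L, 6L), 2, 2, dimnames = dimnames(AO))
  RO2 <- matrix(c(4L, NA, 6L, 2L), 2, 2, dimnames = dimnames(AO))
  M2 <- ratio_genotypes(read_count_matrix(AO2, RO2))
  expect_identical(attr(M2, "n_imputed"), 1L)
  expect_equal(unname(M2[2, 1]), 0.5)  # imputed with the marker mean
  expect_error(ratio_genotypes(read_count_matrix(AO2, RO2),
                               impute_missing = FALSE), "missing")
})

test_that("ratio genotypes converge to dosage/4 as depth grows", {
  set.seed(71)
  dos <- matrix(sample(0:4, 600, replace = TRUE), 30, 20,
                dimnames = list(sprintf("i%02d", 1:30), sprintf("m%02d", 1:20)))
  # per-cell binomial sd at depth d is sqrt(p(1-p)/d) <= 0.5/sqrt(d); depth
  # 2000 makes the 0.05 bound a >3.5-sigma budget for the max over 600 cells
  rc <- simulate_read_counts(dos, mean_depth = 2000, min_depth = 2,
                             error_rate = 0, seed = 72)
  M <- ratio_genotypes(rc)
  expect_lt(max(abs(M - dos / 4)), 0.05)
  # at a moderate depth the typical deviation already shrinks as 1/sqrt(d)
  rc2 <- simulate_read_counts(dos, mean_depth = 500, min_depth = 2,
                              error_rate = 0, seed = 73)
  expect_lt(mean(abs(ratio_genotypes(rc2) - dos / 4)), 0.015)
})

test_that("LSMeans reproduce balanced means and the unbalanced normal equations", {
  rec <- data.frame(individual_id = rep(c("g1", "g2", "g3"), each = 2),
                    year = rep(c(1, 2), 3),
                    value = c(10, 12, 8, 9, 5, 9))
  # balanced: simple per-genotype means
  expect_equal(lsmeans_phenotypes(rec),
               c(g1 = 11, g2 = 8.5, g3 = 7))
  # drop g3's year-2 record: the year effect is estimated from the balanced
  # pairs, (12-10)/2 + (9-8)/2 = 1.5, and g3's adjusted mean is
  # 5 + 1.5/2 = 5.75 (hand solution of the 4-parameter least squares)
  rec2 <- rec[-6, ]
  ls <- lsmeans_phenotypes(rec2)
  expect_equal(ls, c(g1 = 11, g2 = 8.5, g3 = 5.75))
  # independent oracle: adjusted means from emmeans on the same OLS fit
  skip_if_not_installed("emmeans")
  em <- summary(emmeans::emmeans(
    stats::lm(value ~ individual_id + factor(year), rec2), "individual_id"))
  expect_equal(unname(ls), em$emmean, tolerance = 1e-10)
})

test_that("LSMeans degenerate cases behave", {
  # single year: genotype means
  rec <- data.frame(individual_id = c("a", "a", "b"), year = 1,
                    value = c(1, 3, 5))
  expect_equal(lsmeans_phenotypes(rec), c(a = 2, b = 5))
  # each genotype seen in exactly one year: genotype and year are confounded
  rec2 <- data.frame(individual_id = c("a", "a", "b"), year = c(1, 1, 2),
                     value = c(1, 2, 3))
  expect_error(lsmeans_phenotypes(rec2), "rank-deficient")
  # multiple traits adjust independently
  rec3 <- rbind(cbind(rec, trait = "t1"), cbind(rec, trait = "t2"))
  out <- lsmeans_phenotypes(rec3)
  expect_identical(nrow(out), 4L)
  expect_equal(out$lsmean[out$trait == "t1"], c(2, 5))
})
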