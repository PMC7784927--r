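# Shared fixtures, built in code at test time.

# single-marker map (one chromosome, zero genetic length -> no crossovers)
one_marker_map <- function() {
  validate_marker_map(data.frame(marker_id = "m1", chrom = 1L, pos = 100L,
                                 cM = 0, probe_id = "p1",
                                 stringsAsFactors = FALSE))
}

# tetraploid parent with a given number of alternative alleles at one locus
one_locus_parent <- function(dosage) {
  matrix(as.integer(seq_len(4) <= dosage), 4, 1)
}

# small read-count fixture with known depths and ratios
toy_counts <- function() {
  AO <- matrix(c(3L, 0L, 7L, 1L,
                 30L, 40L, 20L, 35L,
                 60L, 58L, 61L, 59L), 4, 3,
               dimnames = list(paste0("i", 1:4), paste0("m", 1:3)))
  RO <- matrix(c(9L, 7L, 0L, 1L,
                 30L, 21L, 39L, 30L,
                 1L, 2L, 1L, 3L), 4, 3,
               dimnames = list(paste0("i", 1:4), paste0("m", 1:3)))
  read_count_matrix(AO, RO)
}

# flat map covering arbitrary marker names on one chromosome
flat_map <- function(marker_ids, chrom = 1L) {
  validate_marker_map(data.frame(marker_id = marker_ids, chrom = chrom,
                                 pos = seq_along(marker_ids) * 100L,
                                 cM = seq_along(marker_ids) * 0.1,
                                 probe_id = paste0("p", chrom),
                                 stringsAsFactors = FALSE))
}

# analytic mean of Poisson(lambda) truncated at >= min_depth, enumerated pmf
truncpois_mean_enum <- function(lambda, min_depth, kmax = 200) {
  k <- 0:kmax
  pmf <- stats::dpois(k, lambda)
  pmf[k < min_depth] <- 0
  sum(k * pmf) / sum(pmf)
}

# brute-force pairwise Tukey-Kramer significance on replicate data: the
# independent oracle for the compact letter display
tukey_pairwise_oracle <- function(value, level, alpha = 0.05) {
  vs <- split(value, factor(level))
  k <- length(vs)
  n_i <- lengths(vs)
  means <- vapply(vs, mean, 0)
  dfe <- sum(n_i) - k
  ms <- sum(unlist(lapply(vs, function(v) (v - mean(v))^2))) / dfe
  sig <- matrix(FALSE, k, k, dimnames = list(names(vs), names(vs)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    q <- abs(means[i] - means[j]) /
      sqrt(ms / 2 * (1 / n_i[i] + 1 / n_i[j]))
    sig[i, j] <- sig[j, i] <-
      stats::ptukey(q, k, dfe, lower.tail = FALSE) < alpha
  }
  sig
}

# check that a letter display is consistent with a significance relation:
# sharing a letter <=> not significantly different
expect_valid_cld <- function(cld, sig) {
  for (a in cld$level) for (b in cld$level) {
    if (a == b) next
    expect_identical(cld_shares_letter(cld, a, b), !sig[a, b])
  }
}
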