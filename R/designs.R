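# Structured resampling designs: cumulative (nested) marker sets balanced
# across chromosomes, probe sets at fixed spacing with random starts, fixed
# test sets re-used across every factor, and random vs family-based
# cumulative training series.

#' Cumulative chromosome-balanced marker series
#'
#' For each replicate, a nested series of marker sets at the requested sizes:
#' every smaller set is contained in every larger one (cumulative sampling,
#' avoiding position bias between sizes), and at each size the per-chromosome
#' counts are balanced — `floor(size / n_chrom)` per chromosome with the
#' remainder assigned to randomly chosen chromosomes (kept consistent across
#' sizes so nesting and balance hold simultaneously). If a chromosome runs
#' out of markers its shortfall spills to chromosomes with room, with a
#' warning.
#'
#' @param map a marker map.
#' @param sizes target set sizes (e.g. 500, 1000, 2000, ...; a size equal to
#'   the total marker count returns the full set).
#' @param n_reps independent replicates (default 5).
#' @param seed integer; replicate seeds are derived from it.
#' @return list of length `n_reps`; each element a named list mapping
#'   `as.character(size)` to a character vector of marker ids.
#' @export
sample_marker_series <- function(map, sizes, n_reps = 5, seed = 1) {
  map <- validate_marker_map(map)
  sizes <- sort(unique(as.integer(sizes)))
  total <- nrow(map)
  if (max(sizes) > total) stop("requested size exceeds available markers")
  chroms <- sort(unique(map$chrom))
  C <- length(chroms)
  by_chrom <- split(map$marker_id, factor(map$chrom, levels = chroms))
  avail <- lengths(by_chrom)
  lapply(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, "marker_series", r))
    remaining <- by_chrom
    chosen <- lapply(by_chrom, function(x) character(0))
    cur <- integer(C)
    sets <- list()
    for (s in sizes) {
      if (s == total) {
        t_target <- as.integer(avail)
      } else {
        q <- s %/% C
        rr <- s - q * C
        over <- which(cur > q)
        if (length(over) > rr) stop("sizes too close to nest with balance")
        pool_extra <- setdiff(seq_len(C), over)
        extras <- c(over, if (rr > length(over))
          pool_extra[sample.int(length(pool_extra), rr - length(over))])
        t_target <- rep(q, C)
        t_target[extras] <- q + 1L
        deficit <- pmax(t_target - as.integer(avail), 0L)
        if (any(deficit > 0)) {
          warning("chromosome(s) exhausted at size ", s,
                  "; spilling ", sum(deficit), " marker(s)")
          t_target <- pmin(t_target, as.integer(avail))
          spill <- sum(deficit)
          while (spill > 0) {
            room <- which(as.integer(avail) - t_target > 0)
            if (!length(room)) stop("not enough markers to reach size ", s)
            pick <- room[which.min(t_target[room])]
            t_target[pick] <- t_target[pick] + 1L
            spill <- spill - 1L
          }
        }
      }
      stopifnot(all(t_target >= cur))
      add <- t_target - cur
      for (cc in which(add > 0)) {
        pick <- sample(remaining[[cc]], add[cc])
        chosen[[cc]] <- c(chosen[[cc]], pick)
        remaining[[cc]] <- setdiff(remaining[[cc]], pick)
      }
      cur <- t_target
      sets[[as.character(s)]] <- unlist(chosen, use.names = FALSE)
    }
    sets
  })
}

#' Probe series at fixed spacing with random starts
#'
#' For each replicate (random start) and each probe count, probes are
#' allocated to chromosomes proportionally to each chromosome's probe count
#' (largest-remainder rounding), then selected within each chromosome at a
#' fixed index stride `floor(available / quota)` along the position order,
#' beginning at a random offset in `[0, stride)`. One random start is drawn
#' per replicate per probe count. The induced marker set is the union of the
#' markers captured by the selected probes. Probe series are deliberately
#' not nested: fixed spacing at different densities selects different
#' positions.
#'
#' @param map a marker map with `probe_id`.
#' @param nprobes probe-count levels (e.g. 50, 100, 500, ...).
#' @param n_starts random starts = replicates (default 5).
#' @param seed integer; replicate seeds are derived from it.
#' @return list of length `n_starts`; each element a named list mapping
#'   `as.character(nprobe)` to `list(probes =, markers =)`.
#' @export
sample_probe_series <- function(map, nprobes, n_starts = 5, seed = 1) {
  map <- validate_marker_map(map)
  if (is.null(map$probe_id) || all(is.na(map$probe_id))) {
    stop("map has no probe information")
  }
  ptab <- unique(data.frame(chrom = map$chrom, probe_id = map$probe_id,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(ptab$probe_id)) stop("probe ids not unique across chromosomes")
  chroms <- sort(unique(ptab$chrom))
  by_chrom <- lapply(chroms, function(ch) {
    # probes in position order within the chromosome
    unique(map$probe_id[map$chrom == ch])
  })
  n_c <- lengths(by_chrom)
  N <- sum(n_c)
  nprobes <- sort(unique(as.integer(nprobes)))
  if (max(nprobes) > N) stop("nprobe exceeds the number of probes (", N, ")")
  lapply(seq_len(n_starts), function(r) {
    set.seed(derive_seed(seed, "probe_series", r))
    sets <- list()
    for (np in nprobes) {
      exact <- np * n_c / N
      q <- floor(exact)
      rem <- np - sum(q)
      if (rem > 0) {
        ord <- order(-(exact - q), stats::runif(length(q)))
        q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1
      }
      q <- pmin(q, n_c)
      sel <- character(0)
      for (i in seq_along(by_chrom)) {
        if (q[i] == 0) next
        stride <- n_c[i] %/% q[i]
        start <- sample.int(stride, 1) - 1L
        ranks <- start + stride * (seq_len(q[i]) - 1L)
        sel <- c(sel, by_chrom[[i]][ranks + 1L])
      }
      sets[[as.character(np)]] <- list(
        probes = sel,
        markers = map$marker_id[map$probe_id %in% sel])
    }
    sets
  })
}

#' Fixed test sets shared across all factors
#'
#' Simple random samples without replacement; one per replicate. The same
#' test set (by replicate index) is re-used for every factor of an analysis
#' grid, so factor comparisons are never confounded with validation-set
#' changes.
#'
#' @param ids candidate individual ids.
#' @param size test-set size (default 200).
#' @param n_reps replicates (default 5; a pseudo k-fold validation).
#' @param seed integer; replicate seeds are derived from it.
#' @return list of `n_reps` character vectors of length `size`.
#' @export
make_test_sets <- function(ids, size = 200, n_reps = 5, seed = 1) {
  if (size >= length(ids)) stop("test size must be smaller than the population")
  lapply(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, "test_set", r))
    sample(ids, size)
  })
}

#' Cumulative random training series
#'
#' Nested random subsets of the training pool at the requested sizes: the
#' pool is shuffled once and each size takes a prefix, so smaller sets are
#' contained in larger ones.
#'
#' @param pool candidate training ids (test individuals already excluded).
#' @param sizes training sizes (default the reference series 120, 240, 480,
#'   960, 1560).
#' @param seed optional integer seed.
#' @return named list mapping `as.character(size)` to id vectors.
#' @export
training_series_random <- function(pool, sizes = c(120, 240, 480, 960, 1560),
                                   seed = NULL) {
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) > length(pool)) stop("training size exceeds the pool")
  .seed(seed)
  shuffled <- sample(pool)
  out <- lapply(sizes, function(s) shuffled[seq_len(s)])
  names(out) <- as.character(sizes)
  out
}

#' Cumulative family-based training series
#'
#' Families smaller than `min_family_size` (in the full pedigree) are
#' excluded; from the remaining families, level `k` samples
#' `min(k, available)` individuals per family, cumulatively nested across
#' levels (each family's members are shuffled once and levels take growing
#' prefixes). Test individuals are removed from the sampling pool first.
#'
#' @param pedigree pedigree data frame (`individual_id`, `family_id`).
#' @param test_ids ids excluded from sampling (the fixed test set).
#' @param per_family per-family levels (default 1, 3, 6, 9, 12, 15).
#' @param min_family_size family-size floor for eligibility (default 10).
#' @param seed optional integer seed.
#' @return named list mapping `as.character(level)` to id vectors; attribute
#'   `n_families` gives the number of eligible families.
#' @export
training_series_by_family <- function(pedigree, test_ids = character(),
                                      per_family = c(1, 3, 6, 9, 12, 15),
                                      min_family_size = 10, seed = NULL) {
  stopifnot(all(c("individual_id", "family_id") %in% names(pedigree)))
  per_family <- sort(unique(as.integer(per_family)))
  fam_sizes <- table(pedigree$family_id)
  eligible <- names(fam_sizes)[fam_sizes >= min_family_size]
  if (!length(eligible)) stop("no family meets min_family_size")
  .seed(seed)
  pool <- pedigree[pedigree$family_id %in% eligible &
                     !(pedigree$individual_id %in% test_ids), , drop = FALSE]
  members <- lapply(split(pool$individual_id, pool$family_id), sample)
  out <- lapply(per_family, function(k) {
    unlist(lapply(members, function(mm) mm[seq_len(min(k, length(mm)))]),
           use.names = FALSE)
  })
  names(out) <- as.character(per_family)
  attr(out, "n_families") <- length(eligible)
  out
}
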