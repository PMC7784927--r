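# Synthetic autotetraploid breeding population: marker map, founder
# haplotypes, tetrasomic meiosis, biparental crosses, additive traits, and
# capture-seq style read counts. Meiosis uses the bivalent-pairing baseline
# (no double reduction, no preferential pairing), which keeps the per-locus
# gamete law closed form: drawing 2 of the 4 homologs uniformly at random.

#' Build a synthetic marker map
#'
#' Markers are spread (near-)evenly over chromosomes, placed at sorted uniform
#' base-pair positions, given proportional genetic-map (cM) positions, and
#' grouped into position-contiguous capture probes of `markers_per_probe`
#' markers each (emulating a capture-seq panel in which each probe yields a
#' handful of SNPs).
#'
#' @param n_markers total number of biallelic markers.
#' @param n_chrom number of chromosomes (default 12).
#' @param markers_per_probe markers captured per probe (default 18).
#' @param chrom_length_cM genetic length of each chromosome in centimorgans.
#' @param genome_bp physical genome size in base pairs (spread evenly over
#'   chromosomes; default 0.6 Gb).
#' @param seed optional integer seed.
#' @return a `marker_map` data frame with columns `marker_id`, `chrom`, `pos`,
#'   `cM`, `probe_id`.
#' @export
make_marker_map <- function(n_markers, n_chrom = 12, markers_per_probe = 18,
                            chrom_length_cM = 100, genome_bp = 6e8,
                            seed = NULL) {
  stopifnot(n_markers >= n_chrom, n_chrom >= 1, markers_per_probe >= 1,
            chrom_length_cM >= 0, genome_bp > n_markers)
  .seed(seed)
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  bp_per_chrom <- floor(genome_bp / n_chrom)
  rows <- lapply(seq_len(n_chrom), function(ch) {
    m <- per[ch]
    pos <- sort(sample.int(bp_per_chrom, m))
    data.frame(
      marker_id = sprintf("chr%02d_m%05d", ch, seq_len(m)),
      chrom = ch,
      pos = pos,
      cM = (pos / bp_per_chrom) * chrom_length_cM,
      probe_id = sprintf("chr%02d_probe%04d", ch,
                         ((seq_len(m) - 1L) %/% markers_per_probe) + 1L),
      stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  validate_marker_map(map)
}

#' Validate (and class) a marker map
#'
#' Checks the map invariants: unique marker ids, one chromosome per marker,
#' non-decreasing positions (bp and cM) within chromosomes, and
#' position-contiguous probe groups.
#'
#' @param map a data frame with columns `marker_id`, `chrom`, `pos`, `cM` and
#'   optionally `probe_id`.
#' @return the map, classed as `marker_map`.
#' @export
validate_marker_map <- function(map) {
  need <- c("marker_id", "chrom", "pos", "cM")
  if (!all(need %in% names(map))) {
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(map) == 0) stop("marker map is empty")
  if (anyDuplicated(map$marker_id)) stop("duplicated marker ids")
  if (any(map$pos < 0) || any(map$cM < 0)) stop("negative map positions")
  for (ch in unique(map$chrom)) {
    i <- map$chrom == ch
    if (is.unsorted(map$pos[i]) || is.unsorted(map$cM[i])) {
      stop("positions not sorted within chromosome ", ch)
    }
  }
  if (!is.null(map$probe_id) && !all(is.na(map$probe_id))) {
    # probe groups must be contiguous runs in position order
    runs <- rle(paste(map$chrom, map$probe_id))$values
    if (anyDuplicated(runs)) stop("probe groups are not contiguous in position")
  }
  class(map) <- unique(c("marker_map", class(map)))
  map
}

#' Simulate founder haplotypes
#'
#' Each founder carries 4 haplotypes (autotetraploid). Per-marker alternative
#' allele frequencies are drawn uniformly in `maf_range`. Along each
#' chromosome, haplotype alleles follow a first-order Markov chain:
#' `P(x_k = 1 | x_{k-1}) = p_k + ld_rho * (x_{k-1} - p_{k-1})` (clamped to
#' \[0, 1\]), so adjacent markers are in LD with correlation `ld_rho` when
#' frequencies are equal, decaying geometrically with distance in marker
#' index; chromosomes are independent. `ld_rho = 0` gives independent
#' markers.
#'
#' @param n_founders number of founders.
#' @param map a [make_marker_map()] marker map.
#' @param maf_range length-2 vector `(low, high)`, `0 < low <= high < 1`:
#'   range of the alternative-allele frequency.
#' @param ld_rho Markov-chain correlation parameter in `[0, 1)`.
#' @param seed optional integer seed.
#' @return a `founder_haps` object: list with `H` (a `4 * n_founders` x
#'   `n_markers` 0/1 integer matrix), `founder_ids`, `allele_freq`, `map`.
#' @export
simulate_founders <- function(n_founders, map, maf_range = c(0.1, 0.9),
                              ld_rho = 0.3, seed = NULL) {
  map <- validate_marker_map(map)
  stopifnot(n_founders >= 1, length(maf_range) == 2)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] < 1)) {
    stop("maf_range must satisfy 0 < low <= high < 1")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  .seed(seed)
  m <- nrow(map)
  nh <- 4L * n_founders
  p <- stats::runif(m, maf_range[1], maf_range[2])
  H <- matrix(0L, nh, m)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    H[, idx[1]] <- stats::rbinom(nh, 1L, p[idx[1]])
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        k <- idx[j]; km1 <- idx[j - 1]
        pr <- pmin(pmax(p[k] + ld_rho * (H[, km1] - p[km1]), 0), 1)
        H[, k] <- stats::rbinom(nh, 1L, pr)
      }
    }
  }
  founder_ids <- sprintf("F%03d", seq_len(n_founders))
  dimnames(H) <- list(paste0(rep(founder_ids, each = 4L), "_h", 1:4),
                      map$marker_id)
  structure(list(H = H, founder_ids = founder_ids, allele_freq = p, map = map),
            class = "founder_haps")
}

#' Assemble a founder set from explicit haplotypes
#'
#' Mostly useful for constructing parents of known dosage in tests and worked
#' examples (e.g. a duplex parent `(1, 1, 0, 0)` at one locus).
#'
#' @param haplotypes a list, one element per founder, each a 4 x n_markers
#'   0/1 matrix.
#' @param map a marker map covering the columns.
#' @param founder_ids optional founder names.
#' @return a `founder_haps` object.
#' @export
founder_haplotypes <- function(haplotypes, map, founder_ids = NULL) {
  map <- validate_marker_map(map)
  stopifnot(length(haplotypes) >= 1)
  for (h in haplotypes) {
    stopifnot(is.matrix(h), nrow(h) == 4, ncol(h) == nrow(map),
              all(h %in% c(0L, 1L)))
  }
  founder_ids <- founder_ids %||% sprintf("F%03d", seq_along(haplotypes))
  H <- do.call(rbind, haplotypes)
  storage.mode(H) <- "integer"
  dimnames(H) <- list(paste0(rep(founder_ids, each = 4L), "_h", 1:4),
                      map$marker_id)
  structure(list(H = H, founder_ids = founder_ids,
                 allele_freq = colMeans(H), map = map),
            class = "founder_haps")
}

#' Extract the 4 haplotypes of one founder
#'
#' @param founders a `founder_haps` object.
#' @param id founder id.
#' @return a 4 x n_markers 0/1 integer matrix.
#' @export
get_founder <- function(founders, id) {
  stopifnot(inherits(founders, "founder_haps"))
  i <- match(id, founders$founder_ids)
  if (is.na(i)) stop("unknown founder id: ", id)
  founders$H[(i - 1L) * 4L + 1:4, , drop = FALSE]
}

#' Simulate one gamete from a tetraploid parent
#'
#' Tetrasomic meiosis with random bivalent pairing: per chromosome the 4
#' homologs are partitioned at random into 2 bivalents; within each bivalent,
#' the crossover count is Poisson(map length in Morgans) with uniform cM
#' positions, and one recombinant chromatid is transmitted. The gamete is the
#' union of one chromatid per bivalent (2 homolog copies per chromosome).
#' Marginally at any single locus this transmits a uniform 2-of-4 draw of the
#' parental alleles (hypergeometric gamete law).
#'
#' @param parent a 4 x n_markers 0/1 matrix (see [get_founder()]).
#' @param map the marker map.
#' @param seed optional integer seed.
#' @return a 2 x n_markers 0/1 integer matrix.
#' @export
make_gamete <- function(parent, map, seed = NULL) {
  stopifnot(is.matrix(parent), nrow(parent) == 4, ncol(parent) == nrow(map))
  .seed(seed)
  g <- matrix(0L, 2L, ncol(parent))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cM[idx]
    len_m <- (max(cm) - min(cm)) / 100  # Morgans
    perm <- sample.int(4L)
    for (b in 1:2) {
      pair <- perm[c(2L * b - 1L, 2L * b)]
      ncx <- stats::rpois(1L, len_m)
      phase <- sample.int(2L, 1L)
      if (ncx == 0L) {
        seg <- integer(length(idx))
      } else {
        cx <- sort(stats::runif(ncx, min(cm), max(cm)))
        seg <- findInterval(cm, cx)
      }
      pick <- pair[(phase + seg - 1L) %% 2L + 1L]
      g[b, idx] <- parent[cbind(pick, idx)]
    }
  }
  g
}

#' Simulate biparental crosses
#'
#' Each offspring is the union of one gamete from each parent (4 homologs);
#' its dosage at a marker is the number of alternative alleles among the 4.
#'
#' @param founders a `founder_haps` object.
#' @param cross_plan data frame with columns `family_id`, `parent1`,
#'   `parent2`, `n_offspring` (see [make_cross_plan()]).
#' @param seed optional integer seed.
#' @param keep_haplotypes keep offspring haplotypes (memory-hungry; default
#'   `FALSE`).
#' @return list with `pedigree` (data frame: `individual_id`, `family_id`,
#'   `parent1_id`, `parent2_id`), `dosages` (n x m integer matrix, entries
#'   0..4) and optionally `haplotypes`.
#' @export
simulate_crosses <- function(founders, cross_plan, seed = NULL,
                             keep_haplotypes = FALSE) {
  stopifnot(inherits(founders, "founder_haps"))
  need <- c("family_id", "parent1", "parent2", "n_offspring")
  if (!all(need %in% names(cross_plan))) {
    stop("cross_plan needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(cross_plan$n_offspring >= 1))
  unknown <- setdiff(unique(c(cross_plan$parent1, cross_plan$parent2)),
                     founders$founder_ids)
  if (length(unknown)) stop("unknown parent id(s): ",
                            paste(unknown, collapse = ", "))
  .seed(seed)
  map <- founders$map
  total <- sum(cross_plan$n_offspring)
  m <- ncol(founders$H)
  D <- matrix(0L, total, m)
  ids <- character(total)
  fam <- character(total)
  p1v <- character(total)
  p2v <- character(total)
  haps <- if (keep_haplotypes) vector("list", total) else NULL
  row <- 0L
  for (f in seq_len(nrow(cross_plan))) {
    h1 <- get_founder(founders, cross_plan$parent1[f])
    h2 <- get_founder(founders, cross_plan$parent2[f])
    for (o in seq_len(cross_plan$n_offspring[f])) {
      row <- row + 1L
      off <- rbind(make_gamete(h1, map), make_gamete(h2, map))
      D[row, ] <- colSums(off)
      ids[row] <- sprintf("%s_i%03d", cross_plan$family_id[f], o)
      fam[row] <- cross_plan$family_id[f]
      p1v[row] <- cross_plan$parent1[f]
      p2v[row] <- cross_plan$parent2[f]
      if (keep_haplotypes) haps[[row]] <- off
    }
  }
  dimnames(D) <- list(ids, map$marker_id)
  ped <- data.frame(individual_id = ids, family_id = fam,
                    parent1_id = p1v, parent2_id = p2v,
                    stringsAsFactors = FALSE)
  out <- list(pedigree = ped, dosages = D)
  if (keep_haplotypes) {
    names(haps) <- ids
    out$haplotypes <- haps
  }
  out
}

#' Build a biparental cross plan
#'
#' Founders are shuffled and paired so that every founder is used when there
#' are at least `length(family_sizes)` pairs to form; additional crosses (when
#' more families than founder pairs are requested) re-use founders in new,
#' distinct pairings — emulating a breeding program in which parents
#' contribute to several crosses.
#'
#' @param founder_ids character vector of founder ids.
#' @param family_sizes integer vector, one entry per cross: offspring count.
#' @param seed optional integer seed.
#' @return data frame `family_id`, `parent1`, `parent2`, `n_offspring`.
#' @export
make_cross_plan <- function(founder_ids, family_sizes, seed = NULL) {
  stopifnot(length(founder_ids) >= 2, all(family_sizes >= 1))
  .seed(seed)
  n_cross <- length(family_sizes)
  perm <- sample(founder_ids)
  np <- length(perm) %/% 2L
  p1 <- character(0); p2 <- character(0)
  for (i in seq_len(min(np, n_cross))) {
    p1 <- c(p1, perm[2L * i - 1L]); p2 <- c(p2, perm[2L * i])
  }
  seen <- paste(pmin(p1, p2), pmax(p1, p2))
  while (length(p1) < n_cross) {
    cand <- sample(founder_ids, 2L)
    key <- paste(min(cand), max(cand))
    if (key %in% seen) next
    p1 <- c(p1, cand[1]); p2 <- c(p2, cand[2]); seen <- c(seen, key)
  }
  data.frame(family_id = sprintf("fam%03d", seq_len(n_cross)),
             parent1 = p1, parent2 = p2,
             n_offspring = as.integer(family_sizes),
             stringsAsFactors = FALSE)
}

#' Cross plan emulating the reference breeding population
#'
#' 117 biparental crosses of 146 parents totalling 1804 offspring: 103
#' families of >= 10 individuals (58 of 17 plus 45 of 16 = 1706 genotypes)
#' plus 14 small families of 7. Family-size detail beyond these reference
#' totals is not known; this allocation reproduces them exactly.
#'
#' @param seed optional integer seed.
#' @return a cross-plan data frame (see [make_cross_plan()]).
#' @export
study_cross_plan <- function(seed = NULL) {
  make_cross_plan(sprintf("F%03d", 1:146),
                  c(rep(17L, 58), rep(16L, 45), rep(7L, 14)),
                  seed = seed)
}

#' Pedigree implied by a cross plan (no genotypes)
#'
#' Expands a cross plan into one pedigree row per offspring. Useful for
#' design-only computations (e.g. family-based training series) that do not
#' need genotypes.
#'
#' @param cross_plan a cross-plan data frame.
#' @return pedigree data frame.
#' @export
make_pedigree <- function(cross_plan) {
  idx <- rep(seq_len(nrow(cross_plan)), cross_plan$n_offspring)
  o <- unlist(lapply(cross_plan$n_offspring, seq_len))
  data.frame(
    individual_id = sprintf("%s_i%03d", cross_plan$family_id[idx], o),
    family_id = cross_plan$family_id[idx],
    parent1_id = cross_plan$parent1[idx],
    parent2_id = cross_plan$parent2[idx],
    stringsAsFactors = FALSE)
}

#' Describe an additive trait architecture
#'
#' @param n_qtl number of causal markers (QTL), sampled uniformly among the
#'   simulated markers.
#' @param h2 narrow-sense heritability target of a single-season phenotype,
#'   in (0, 1].
#' @param effect_distribution `"normal"` (many small effects) or
#'   `"gamma-signed"` (a few large effects: Gamma(0.5, 1) magnitudes with
#'   random signs).
#' @param year_effects per-year fixed shifts (trait units; the first season is
#'   the reference).
#' @param mu overall mean.
#' @param name optional trait label.
#' @return a `trait_architecture` list.
#' @export
trait_architecture <- function(n_qtl, h2,
                               effect_distribution = c("normal", "gamma-signed"),
                               year_effects = c(0, 0.5), mu = 0, name = NULL) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(n_qtl >= 1, h2 > 0, h2 <= 1)
  structure(list(n_qtl = as.integer(n_qtl), h2 = h2,
                 effect_distribution = effect_distribution,
                 year_effects = year_effects, mu = mu,
                 name = name %||% sprintf("trait_q%d_h%02d", n_qtl,
                                          round(100 * h2))),
            class = "trait_architecture")
}

#' Trait presets of contrasting architecture
#'
#' Three unitless traits spanning the oligogenic-to-infinitesimal range,
#' emulating fruit-quality traits of differing genetic control and
#' heritability: `oligogenic` (50 QTL, h2 = 0.7, signed-gamma effects),
#' `polygenic` (500 QTL, h2 = 0.5) and `infinitesimal` (5000 QTL, h2 = 0.3).
#' QTL counts are capped at the available marker number.
#'
#' @param n_markers markers available in the map.
#' @return named list of [trait_architecture()] objects.
#' @export
trait_presets <- function(n_markers) {
  list(
    oligogenic = trait_architecture(min(50L, n_markers), 0.7, "gamma-signed",
                                    name = "oligogenic"),
    polygenic = trait_architecture(min(500L, n_markers), 0.5, "normal",
                                   name = "polygenic"),
    infinitesimal = trait_architecture(min(5000L, n_markers), 0.3, "normal",
                                       name = "infinitesimal"))
}

#' Simulate phenotypes and true genetic values
#'
#' QTL positions are sampled uniformly; effects are drawn from the
#' architecture's distribution; the true additive value `g` of an individual
#' is its dosage-weighted sum of QTL effects (centered). The residual
#' variance is set so that `Var(g) / (Var(g) + sigma_e^2)` equals the target
#' `h2` in the simulated population, and one record per individual and year
#' is generated as `mu + year_effect + g + e`, `e ~ N(0, sigma_e^2)` iid.
#'
#' @param dosages n x m dosage matrix (rownames = individual ids).
#' @param architecture a [trait_architecture()].
#' @param years vector of season labels (must match
#'   `length(architecture$year_effects)`).
#' @param seed optional integer seed.
#' @return list with `phenotypes` (data frame `individual_id`, `year`,
#'   `value`), `truth` (list `g_true` named vector, `qtl_effects` named
#'   vector), and `sigma_e2`.
#' @export
simulate_phenotypes <- function(dosages, architecture, years = c(2014, 2015),
                                seed = NULL) {
  stopifnot(inherits(architecture, "trait_architecture"),
            is.matrix(dosages),
            length(years) == length(architecture$year_effects))
  m <- ncol(dosages)
  if (architecture$n_qtl > m) stop("n_qtl exceeds the number of markers")
  .seed(seed)
  qtl <- sort(sample.int(m, architecture$n_qtl))
  eff <- switch(architecture$effect_distribution,
                normal = stats::rnorm(architecture$n_qtl),
                `gamma-signed` = stats::rgamma(architecture$n_qtl, 0.5, 1) *
                  sample(c(-1, 1), architecture$n_qtl, replace = TRUE))
  g <- drop(dosages[, qtl, drop = FALSE] %*% eff)
  g <- g - mean(g)
  vg <- stats::var(g)
  if (vg < 1e-12) stop("zero genetic variance: cannot reach h2 > 0")
  sigma_e2 <- if (architecture$h2 >= 1) 0 else vg * (1 - architecture$h2) / architecture$h2
  n <- nrow(dosages)
  ids <- rownames(dosages) %||% sprintf("ind%04d", seq_len(n))
  recs <- do.call(rbind, lapply(seq_along(years), function(t) {
    data.frame(individual_id = ids, year = years[t],
               value = architecture$mu + architecture$year_effects[t] + g +
                 stats::rnorm(n, 0, sqrt(sigma_e2)),
               stringsAsFactors = FALSE)
  }))
  names(g) <- ids
  names(eff) <- colnames(dosages)[qtl]
  list(phenotypes = recs,
       truth = list(g_true = g, qtl_effects = eff),
       sigma_e2 = sigma_e2)
}

# Truncated Poisson: X ~ Poisson(lambda) conditional on X >= min_depth,
# sampled by inverse-cdf restricted to the upper tail.
rtruncpois <- function(n, lambda, min_depth) {
  stopifnot(lambda > 0, min_depth >= 0)
  if (min_depth <= 0) return(stats::rpois(n, lambda))
  p0 <- stats::ppois(min_depth - 1, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

#' Simulate capture-seq read counts from dosages
#'
#' Total depth per datapoint is Poisson(`mean_depth`) conditioned on being at
#' least `min_depth` (truncated Poisson; set `truncation = "clamp"` to clamp
#' draws up to `min_depth` instead, for sensitivity checks). The
#' alternative-allele count is Binomial(depth, p) with
#' `p = (d/4)(1 - error_rate) + (1 - d/4) error_rate` for dosage `d`, folding
#' a symmetric per-read miscall rate into the allele sampling.
#'
#' @param dosages n x m integer dosage matrix (entries 0..4).
#' @param mean_depth Poisson mean of the total depth (> 0).
#' @param min_depth minimum retained depth (>= 0; default 2).
#' @param error_rate per-read miscall probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @param truncation `"resample"` (truncated Poisson, default) or `"clamp"`.
#' @return a [read_count_matrix()] with `AO` (alternative) and `RO`
#'   (reference) counts.
#' @export
simulate_read_counts <- function(dosages, mean_depth = 60, min_depth = 2,
                                 error_rate = 0.001, seed = NULL,
                                 truncation = c("resample", "clamp")) {
  truncation <- match.arg(truncation)
  stopifnot(is.matrix(dosages), mean_depth > 0, min_depth >= 0)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must lie in [0, 0.5)")
  }
  if (any(dosages < 0 | dosages > 4)) stop("dosages must lie in 0..4")
  .seed(seed)
  N <- length(dosages)
  depth <- switch(truncation,
                  resample = rtruncpois(N, mean_depth, min_depth),
                  clamp = pmax(stats::rpois(N, mean_depth), min_depth))
  p <- (dosages / 4) * (1 - error_rate) + (1 - dosages / 4) * error_rate
  AO <- matrix(stats::rbinom(N, depth, as.vector(p)),
               nrow(dosages), ncol(dosages), dimnames = dimnames(dosages))
  RO <- matrix(depth, nrow(dosages), ncol(dosages),
               dimnames = dimnames(dosages)) - AO
  read_count_matrix(AO, RO)
}

#' Simulate a complete study population
#'
#' One call producing everything the analysis factorial consumes: marker map,
#' founders, pedigree, dosages, phenotypes for each trait preset, true
#' genetic values, and benchmark-depth read counts.
#'
#' Presets: `"demo"` is the desk-scale default (40 families x 15 offspring =
#' 600 individuals, 3000 markers on 12 chromosomes, 18 markers per probe);
#' `"study"` matches the reference population layout (117 crosses of 146
#' parents, 1804 individuals, ~10k markers).
#'
#' @param preset `"demo"` or `"study"`; ignored when `cross_plan` is given.
#' @param seed integer master seed (all internal steps derive from it).
#' @param cross_plan optional explicit cross plan (founders are created to
#'   match its parents).
#' @param n_markers,n_chrom,markers_per_probe map layout.
#' @param traits named list of [trait_architecture()]s (default
#'   [trait_presets()]).
#' @param mean_depth,min_depth,error_rate read-count model (benchmark depth).
#' @param maf_range,ld_rho founder-haplotype model.
#' @param years season labels.
#' @return a `gp_population` list: `map`, `founders`, `pedigree`, `dosages`,
#'   `counts`, `phenotypes` (long, with `trait` column), `truth` (per trait),
#'   `architectures`, `mean_depth`.
#' @export
sim_study_population <- function(preset = c("demo", "study"), seed = 1,
                                 cross_plan = NULL,
                                 n_markers = NULL, n_chrom = 12,
                                 markers_per_probe = 18, traits = NULL,
                                 mean_depth = 60, min_depth = 2,
                                 error_rate = 0.001, maf_range = c(0.1, 0.9),
                                 ld_rho = 0.3, years = c(2014, 2015)) {
  preset <- match.arg(preset)
  if (is.null(cross_plan)) {
    cross_plan <- switch(preset,
      demo = make_cross_plan(sprintf("F%03d", 1:80), rep(15L, 40),
                             seed = derive_seed(seed, "plan")),
      study = study_cross_plan(seed = derive_seed(seed, "plan")))
  }
  n_markers <- n_markers %||% switch(preset, demo = 3000L, study = 10044L)
  founder_ids <- unique(c(cross_plan$parent1, cross_plan$parent2))
  map <- make_marker_map(n_markers, n_chrom = n_chrom,
                         markers_per_probe = markers_per_probe,
                         seed = derive_seed(seed, "map"))
  founders <- simulate_founders(length(founder_ids), map,
                                maf_range = maf_range, ld_rho = ld_rho,
                                seed = derive_seed(seed, "founders"))
  # relabel founders to the plan's parent ids
  founders$founder_ids <- founder_ids
  rownames(founders$H) <- paste0(rep(founder_ids, each = 4L), "_h", 1:4)
  cross <- simulate_crosses(founders, cross_plan,
                            seed = derive_seed(seed, "crosses"))
  traits <- traits %||% trait_presets(n_markers)
  ph <- list(); truth <- list()
  for (nm in names(traits)) {
    sim <- simulate_phenotypes(cross$dosages, traits[[nm]], years = years,
                               seed = derive_seed(seed, "trait", nm))
    sim$phenotypes$trait <- nm
    ph[[nm]] <- sim$phenotypes
    truth[[nm]] <- sim$truth
  }
  counts <- simulate_read_counts(cross$dosages, mean_depth = mean_depth,
                                 min_depth = min_depth,
                                 error_rate = error_rate,
                                 seed = derive_seed(seed, "counts"))
  structure(list(map = map, founders = founders, pedigree = cross$pedigree,
                 dosages = cross$dosages, counts = counts,
                 phenotypes = do.call(rbind, ph), truth = truth,
                 architectures = traits, mean_depth = mean_depth,
                 seed = seed),
            class = "gp_population")
}

#' @export
print.gp_population <- function(x, ...) {
  cat("gp_population:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "markers;", length(unique(x$pedigree$family_id)), "families;",
      length(x$truth), "trait(s); benchmark depth", x$mean_depth, "X\n")
  invisible(x)
}

#' Write a simulated population to tab-separated files
#'
#' Writes `pedigree.tsv`, `dosages.tsv`, `AO.tsv`, `RO.tsv`,
#' `phenotypes.tsv`, `true_values.tsv` and `marker_map.tsv` (count tables in
#' the individuals-as-rows layout used by [read_counts()]).
#'
#' @param pop a `gp_population`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "gp_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(d, f) data.table::fwrite(d, file.path(dir, f), sep = "\t")
  fw(pop$pedigree, "pedigree.tsv")
  fw(data.frame(individual_id = rownames(pop$dosages), pop$dosages,
                check.names = FALSE), "dosages.tsv")
  write_counts(pop$counts, file.path(dir, "AO.tsv"), file.path(dir, "RO.tsv"))
  fw(pop$phenotypes, "phenotypes.tsv")
  tv <- do.call(rbind, lapply(names(pop$truth), function(nm) {
    data.frame(individual_id = names(pop$truth[[nm]]$g_true), trait = nm,
               g_true = unname(pop$truth[[nm]]$g_true))
  }))
  fw(tv, "true_values.tsv")
  fw(as.data.frame(pop$map), "marker_map.tsv")
  invisible(dir)
}
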