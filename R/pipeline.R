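# Config-driven orchestration of the analysis factorial: marker density x
# probe density x sequencing depth x training design x replicate x trait.
# Per cell: subset markers, downsample depth, compute ratio genotypes,
# build G, fit G-BLUP, predict the replicate's fixed test set, and score.
# All seeds derive deterministically from one master seed; fixed test sets
# are shared across every factor within a replicate.

#' Declare a scenario grid
#'
#' Each non-`NULL` factor adds an experiment: `marker_sizes` (cumulative
#' marker-density series at `marker_depth`), `probe_counts` (crossed with
#' `probe_depths`), `depths` (depth series at `depth_marker_size` markers,
#' or the full set), `train_sizes` (random-composition training series) and
#' `family_levels` (per-family training series), both crossed with
#' `train_depths`. A depth of `NA` (or equal to the data's benchmark depth)
#' means the original counts are used unchanged.
#'
#' @param marker_sizes marker-density levels (`NULL` = skip).
#' @param marker_depth depth for the marker experiment (default `NA` =
#'   benchmark).
#' @param probe_counts probe-density levels.
#' @param probe_depths depths crossed with the probe experiment.
#' @param depths sequencing-depth levels.
#' @param depth_marker_size fixed marker count for the depth experiment
#'   (`NULL` = all markers).
#' @param train_sizes random training-population sizes.
#' @param family_levels individuals sampled per family.
#' @param train_depths depths crossed with both training experiments.
#' @param min_family_size family-eligibility floor (default 10).
#' @param n_reps replicates (default 5).
#' @param test_size fixed test-set size (default 200).
#' @return a `scenario_grid` data frame (`experiment`, `level`, `depth`,
#'   `composition`) with design attributes.
#' @export
scenario_grid <- function(marker_sizes = NULL, marker_depth = NA,
                          probe_counts = NULL,
                          probe_depths = c(2, 6, 12, 24, 48, 60),
                          depths = NULL, depth_marker_size = NULL,
                          train_sizes = NULL, family_levels = NULL,
                          train_depths = NA, min_family_size = 10,
                          n_reps = 5, test_size = 200) {
  rows <- list()
  add <- function(experiment, level, depth, composition = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      experiment = experiment, level = level, depth = depth,
      composition = composition, stringsAsFactors = FALSE)
  }
  for (s in marker_sizes) add("marker_density", s, marker_depth)
  for (np in probe_counts) for (d in probe_depths) add("probe_density", np, d)
  for (d in depths) add("depth", d, d)
  for (s in train_sizes) for (d in train_depths)
    add("training_random", s, d, "random")
  for (l in family_levels) for (d in train_depths)
    add("training_family", l, d, "by_family")
  if (!length(rows)) stop("empty grid: give at least one factor")
  g <- do.call(rbind, rows)
  attr(g, "n_reps") <- as.integer(n_reps)
  attr(g, "test_size") <- as.integer(test_size)
  attr(g, "depth_marker_size") <- depth_marker_size
  attr(g, "min_family_size") <- min_family_size
  class(g) <- c("scenario_grid", "data.frame")
  g
}

#' The reference study's full factorial
#'
#' The levels analyzed at full scale: marker sizes 500-60k, probe counts
#' 50-5000 crossed with six depths, depths 2/6/12/24/48/60X, random
#' training sizes 120-1560 and family levels 1-15 crossed with
#' 6/12/24/60X, 5 replicates, 200-individual test sets. Running it
#' requires the full-size dataset; [demo_grid()] is the desk-scale analog.
#'
#' @return a `scenario_grid`.
#' @export
study_grid <- function() {
  scenario_grid(
    marker_sizes = c(500, 1000, 2000, 3000, 5000, 10000, 20000, 40000, 60000),
    probe_counts = c(50, 100, 500, 1000, 2000, 3000, 5000),
    probe_depths = c(2, 6, 12, 24, 48, 60),
    depths = c(2, 6, 12, 24, 48, 60),
    train_sizes = c(120, 240, 480, 960, 1560),
    family_levels = c(1, 3, 6, 9, 12, 15),
    train_depths = c(6, 12, 24, 60),
    n_reps = 5, test_size = 200)
}

#' Desk-scale demonstration grid
#'
#' Scaled to the demo population (600 individuals, 3000 markers): marker
#' sizes 250-2000 plus the full set, depths 2/6/12/60X at 2000 markers,
#' probe counts crossed with 6X and 60X, and random/family training series
#' at the benchmark depth.
#'
#' @param n_markers marker count of the population (default 3000).
#' @param n_probes probe count of the population's map.
#' @return a `scenario_grid`.
#' @export
demo_grid <- function(n_markers = 3000, n_probes = 168) {
  scenario_grid(
    marker_sizes = c(250, 500, 1000, 2000, n_markers),
    depths = c(2, 6, 12, 60), depth_marker_size = 2000,
    probe_counts = c(10, 40, n_probes), probe_depths = c(6, 60),
    train_sizes = c(120, 240, 400),
    family_levels = c(1, 3, 6),
    train_depths = NA,
    n_reps = 5, test_size = 200)
}

#' Run a scenario grid over a population
#'
#' For every scenario x replicate x trait: resolve the marker set
#' (cumulative chromosome-balanced series for marker scenarios, stride-
#' sampled probe sets for probe scenarios), downsample the counts to the
#' scenario depth (original counts at the benchmark), compute ratio
#' genotypes, build `G = ZZ'/h` over all individuals, fit the Gibbs
#' G-BLUP on the training records, predict the replicate's fixed test set,
#' and record predictive ability, MSE and (when true genetic values are
#' available) accuracy against truth. Relationship matrices are cached
#' across cells that share a marker set, depth and replicate. Infeasible
#' cells (e.g. a training size exceeding the pool) are recorded as failed
#' rows and the run continues. With `results_path`, completed cells found
#' in the file are skipped on re-run and new rows are appended (resumable).
#'
#' @param pop a `gp_population` (or an equivalent list with `map`,
#'   `counts`, `phenotypes`, `pedigree`, optionally `truth`).
#' @param grid a [scenario_grid()].
#' @param traits trait names to evaluate (default: all in `pop`).
#' @param chains Gibbs settings (default [reduced_chains()]).
#' @param master_seed master seed; all cell seeds derive from it.
#' @param benchmark_depth depth of the original counts (default
#'   `pop$mean_depth`).
#' @param min_depth datapoint-depth floor used when downsampling.
#' @param results_path optional TSV path for resumable, incremental output.
#' @param verbose print one line per scenario.
#' @return a `grid_result` data frame, one row per cell.
#' @export
run_grid <- function(pop, grid, traits = NULL, chains = reduced_chains(),
                     master_seed = 1, benchmark_depth = NULL, min_depth = 2,
                     results_path = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  benchmark_depth <- benchmark_depth %||% pop$mean_depth %||% 60
  n_reps <- attr(grid, "n_reps")
  test_size <- attr(grid, "test_size")
  traits <- traits %||% unique(pop$phenotypes$trait) %||% "trait"
  ids <- rownames(pop$counts$AO)

  y_list <- lapply(traits, function(tr) {
    d <- pop$phenotypes
    if ("trait" %in% names(d)) d <- d[d$trait == tr, , drop = FALSE]
    lsmeans_phenotypes(d[, c("individual_id", "year", "value")])
  })
  names(y_list) <- traits

  test_sets <- make_test_sets(ids, test_size, n_reps,
                              seed = derive_seed(master_seed, "test_sets"))

  msizes <- unique(c(grid$level[grid$experiment == "marker_density"],
                     attr(grid, "depth_marker_size")))
  marker_series <- if (length(msizes)) {
    sample_marker_series(pop$map, msizes, n_reps,
                         seed = derive_seed(master_seed, "marker_series"))
  }
  probe_series <- if (any(grid$experiment == "probe_density")) {
    sample_probe_series(pop$map,
                        unique(grid$level[grid$experiment == "probe_density"]),
                        n_starts = n_reps,
                        seed = derive_seed(master_seed, "probe_series"))
  }
  rand_series <- fam_series <- vector("list", n_reps)
  rsz <- unique(grid$level[grid$experiment == "training_random"])
  flv <- unique(grid$level[grid$experiment == "training_family"])
  for (r in seq_len(n_reps)) {
    pool <- setdiff(ids, test_sets[[r]])
    if (length(rsz)) {
      feas <- rsz[rsz <= length(pool)]
      if (length(feas)) {
        rand_series[[r]] <- training_series_random(
          pool, feas, seed = derive_seed(master_seed, "train_random", r))
      }
    }
    if (length(flv)) {
      fam_series[[r]] <- tryCatch(
        training_series_by_family(pop$pedigree, test_sets[[r]], flv,
                                  min_family_size = attr(grid, "min_family_size"),
                                  seed = derive_seed(master_seed, "train_family", r)),
        error = function(e) NULL)
    }
  }

  done <- character(0)
  if (!is.null(results_path) && file.exists(results_path)) {
    prev <- utils::read.delim(results_path, stringsAsFactors = FALSE)
    done <- paste(prev$experiment, prev$level, prev$depth, prev$replicate,
                  prev$trait, sep = "||")
  }

  cache <- new.env(parent = emptyenv())
  get_g <- function(marker_key, marker_ids, depth, r) {
    key <- paste(marker_key, depth, r, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    rc <- rc_subset(pop$counts, markers = marker_ids)
    if (!is.na(depth) && depth < benchmark_depth) {
      rc <- downsample(rc, depth, min_depth = min_depth,
                       seed = derive_seed(master_seed, "downsample", key))
    }
    G <- build_g(ratio_genotypes(rc))
    cache[[key]] <- G
    G
  }

  out <- list()
  emit <- function(row) {
    out[[length(out) + 1]] <<- row
    if (!is.null(results_path)) {
      utils::write.table(row, results_path, sep = "\t", row.names = FALSE,
                         col.names = !file.exists(results_path),
                         append = file.exists(results_path), quote = FALSE)
    }
  }

  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    if (verbose) {
      cat(sprintf("[%s] level=%s depth=%s\n", sc$experiment, sc$level,
                  ifelse(is.na(sc$depth), "benchmark", sc$depth)))
    }
    for (r in seq_len(n_reps)) {
      test <- test_sets[[r]]
      for (tr in traits) {
        key <- paste(sc$experiment, sc$level, sc$depth, r, tr, sep = "||")
        if (key %in% done) next
        row <- tryCatch({
          mk <- switch(sc$experiment,
            marker_density = list(key = paste0("mk", sc$level, "_", r),
                                  ids = marker_series[[r]][[as.character(sc$level)]]),
            probe_density = list(key = paste0("pb", sc$level, "_", r),
                                 ids = probe_series[[r]][[as.character(sc$level)]]$markers),
            depth = if (!is.null(attr(grid, "depth_marker_size"))) {
              list(key = paste0("mk", attr(grid, "depth_marker_size"), "_", r),
                   ids = marker_series[[r]][[as.character(attr(grid, "depth_marker_size"))]])
            } else list(key = "full", ids = NULL),
            list(key = "full", ids = NULL))
          marker_ids <- mk$ids %||% colnames(pop$counts$AO)
          train <- switch(sc$experiment,
            training_random = {
              s <- rand_series[[r]][[as.character(sc$level)]]
              if (is.null(s)) stop("training size ", sc$level,
                                   " exceeds the pool")
              s
            },
            training_family = {
              s <- fam_series[[r]][[as.character(sc$level)]]
              if (is.null(s)) stop("no eligible families")
              s
            },
            setdiff(ids, test))
          G <- get_g(mk$key, marker_ids, sc$depth, r)
          y <- y_list[[tr]]
          fit <- fit_gibbs(y, G, train_ids = train, chains = chains,
                           seed = derive_seed(master_seed, "fit",
                                              sc$experiment, sc$level,
                                              sc$depth, r, tr))
          pred <- predict(fit, test)
          acc <- if (!is.null(pop$truth[[tr]])) {
            stats::cor(pred, pop$truth[[tr]]$g_true[test])
          } else NA_real_
          data.frame(experiment = sc$experiment, level = sc$level,
                     depth = sc$depth, composition = sc$composition,
                     replicate = r, trait = tr,
                     n_markers = length(marker_ids), n_train = length(train),
                     n_test = length(test),
                     predictive_ability = predictive_ability(pred, y[test]),
                     mse = mse(pred, y[test]),
                     accuracy = acc, status = "ok", note = "",
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(experiment = sc$experiment, level = sc$level,
                     depth = sc$depth, composition = sc$composition,
                     replicate = r, trait = tr,
                     n_markers = NA_integer_, n_train = NA_integer_,
                     n_test = length(test),
                     predictive_ability = NA_real_, mse = NA_real_,
                     accuracy = NA_real_, status = "failed",
                     note = conditionMessage(e), stringsAsFactors = FALSE)
        })
        emit(row)
      }
    }
  }
  if (!length(out)) {
    out <- list(data.frame(experiment = character(), level = numeric(),
                           depth = numeric(), composition = character(),
                           replicate = integer(), trait = character(),
                           n_markers = integer(), n_train = integer(),
                           n_test = integer(), predictive_ability = numeric(),
                           mse = numeric(), accuracy = numeric(),
                           status = character(), note = character(),
                           stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "test_sets") <- test_sets
  class(res) <- c("grid_result", "data.frame")
  res
}

#' Tukey letter displays per experiment and trait of a grid result
#'
#' Within each (experiment, trait), levels — crossed with depth where the
#' experiment is depth-crossed — are compared on replicate-level predictive
#' abilities; training experiments of both compositions are compared in one
#' display per trait (so composition differences carry letters too).
#'
#' @param res a [run_grid()] result.
#' @param alpha significance level (default 0.05).
#' @return named list of [tukey_cld()] tables, one per experiment x trait
#'   (training experiments combined).
#' @export
grid_tukey <- function(res, alpha = 0.05) {
  res <- res[res$status == "ok", , drop = FALSE]
  res$expgroup <- ifelse(res$experiment %in% c("training_random",
                                               "training_family"),
                         "training", res$experiment)
  out <- list()
  for (eg in unique(res$expgroup)) {
    for (tr in unique(res$trait)) {
      d <- res[res$expgroup == eg & res$trait == tr, , drop = FALSE]
      if (!nrow(d)) next
      lab <- d$level
      if (eg == "probe_density" || length(unique(d$depth[!is.na(d$depth)])) > 1) {
        lab <- paste0(d$level, "@", ifelse(is.na(d$depth), "bench", d$depth), "X")
      }
      if (eg == "training") {
        lab <- paste0(substr(d$composition, 1, 3), d$level,
                      ifelse(is.na(d$depth), "", paste0("@", d$depth, "X")))
      }
      tab <- table(lab)
      if (length(tab) < 2 || any(tab < 2)) next
      out[[paste(eg, tr, sep = ".")]] <- tukey_cld(d$predictive_ability,
                                                   lab, alpha = alpha)
    }
  }
  out
}

#' Run the full synthetic demonstration study
#'
#' Simulates the preset population, runs reduced versions of the four
#' experiments (marker density, probe density, sequencing depth, training
#' size/composition), computes Tukey letter displays and the sequencing-
#' budget table, and optionally writes everything (results TSV, Tukey TSVs,
#' report) to a directory.
#'
#' @param seed master seed.
#' @param dir optional output directory.
#' @param preset population preset (`"demo"` default; see
#'   [sim_study_population()]).
#' @param traits trait names to evaluate (default `"polygenic"`; add
#'   `"oligogenic"` / `"infinitesimal"` for the full contrast at extra
#'   compute cost).
#' @param chains Gibbs settings (default [reduced_chains()]).
#' @param n_reps replicates (default 5).
#' @param verbose print progress.
#' @return list with `pop`, `grid`, `results`, `tukey`, `budget`, invisibly.
#' @export
run_demo <- function(seed = 1, dir = NULL, preset = "demo",
                     traits = "polygenic",
                     chains = reduced_chains(), n_reps = 5, verbose = FALSE) {
  pop <- sim_study_population(preset = preset,
                              seed = derive_seed(seed, "pop"))
  n_probes <- length(unique(pop$map$probe_id))
  grid <- demo_grid(n_markers = nrow(pop$map), n_probes = n_probes)
  attr(grid, "n_reps") <- as.integer(n_reps)
  res <- run_grid(pop, grid, traits = traits, chains = chains,
                  master_seed = derive_seed(seed, "grid"), verbose = verbose)
  tk <- grid_tukey(res)
  budget <- do.call(rbind, lapply(c(2, 6, 12, 24, 48, 60), function(d) {
    b <- sequencing_budget(depth = d)
    data.frame(depth = d, gb_per_sample = b$gb_per_sample,
               samples_per_run = b$samples_per_run)
  }))
  out <- list(pop = pop, grid = grid, results = res, tukey = tk,
              budget = budget)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(res, file.path(dir, "results.tsv"), sep = "\t")
    for (nm in names(tk)) {
      data.table::fwrite(as.data.frame(tk[[nm]]),
                         file.path(dir, paste0("tukey_", nm, ".tsv")),
                         sep = "\t")
    }
    data.table::fwrite(budget, file.path(dir, "budget.tsv"), sep = "\t")
    writeLines(.demo_report(res, tk, budget), file.path(dir, "report.md"))
  }
  invisible(out)
}

.demo_report <- function(res, tk, budget) {
  sec <- function(exp_name, title) {
    d <- res[res$experiment %in% exp_name & res$status == "ok", , drop = FALSE]
    lines <- c(paste("##", title), "")
    if (!nrow(d)) return(c(lines, "(no successful cells)", ""))
    agg <- stats::aggregate(predictive_ability ~ trait + level + depth,
                            data = transform(d, depth = ifelse(is.na(depth),
                                                               -1, depth)),
                            FUN = mean)
    agg$depth <- ifelse(agg$depth < 0, "benchmark", agg$depth)
    c(lines, utils::capture.output(print(agg, row.names = FALSE)), "")
  }
  failed <- res[res$status == "failed", , drop = FALSE]
  c("# Synthetic demonstration study", "",
    sec("marker_density", "Marker density"),
    sec("probe_density", "Probe density"),
    sec("depth", "Sequencing depth"),
    sec(c("training_random", "training_family"),
        "Training population size and composition"),
    "## Sequencing budget", "",
    utils::capture.output(print(budget, row.names = FALSE)), "",
    if (nrow(failed)) {
      c("## Failed cells", "",
        utils::capture.output(print(failed[, c("experiment", "level", "depth",
                                               "replicate", "trait", "note")],
                                    row.names = FALSE)))
    } else "All cells completed.")
}
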