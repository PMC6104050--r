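# Scoring alignments against the known true mapping, the noise-sweep
# experiment harness, and rank-frequency summaries of sweep results.

#' Node correctness of an alignment
#'
#' Percentage of aligned pairs that agree with the true node mapping.
#'
#' @param alignment an [alignment] or named character vector.
#' @param truth named character vector (or [alignment]): true mapping with
#'   the same source node set.
#' @return percentage in `[0, 100]`.
#' @export
node_correctness <- function(alignment, truth) {
  f <- if (inherits(alignment, "alignment")) alignment$mapping else alignment
  tr <- if (inherits(truth, "alignment")) truth$mapping else truth
  if (!setequal(names(f), names(tr)))
    stop("alignment and truth must share the same source node set")
  100 * mean(f[names(tr)] == tr)
}

parse_scenario <- function(scenario) {
  parts <- strsplit(scenario, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L ||
      !parts[1L] %in% c("HomNC", "HetNC") ||
      !parts[2L] %in% c("HomEC", "HetEC"))
    stop("scenario must be one of HomNC-HomEC, HetNC-HomEC, ",
         "HomNC-HetEC, HetNC-HetEC")
  list(nc = if (parts[1L] == "HetNC") "het" else "hom",
       ec = if (parts[2L] == "HetEC") "hets3" else "homs3")
}

#' Sweep configuration
#'
#' Factors and budgets for [run_sweep()]. Defaults give a desk-scale version
#' of the synthetic noise-robustness experiment: both generators at
#' 300 nodes / 1,800 edges (same density as the full-scale 1,000 / 6,000
#' setting), 1, 2 and 4 balanced random colors, noise levels 0/25/50%,
#' seed-and-extend plus iteration-budgeted annealing, 3 replicates.
#'
#' @param models subset of `c("geo", "sf")`.
#' @param methods subset of `c("wave", "sana", "magna")`.
#' @param scenarios evaluation scenarios for colored runs (`k > 1`); with
#'   `k = 1` every scenario collapses to HomNC-HomEC, which is then run
#'   once. WAVE cannot optimize EC, so for WAVE only the NC half matters.
#' @param ks numbers of node colors.
#' @param noise_levels rewiring fractions.
#' @param replicates noisy instances per cell.
#' @param n,m network size.
#' @param seed master seed; all per-cell seeds derive from it.
#' @param alpha NC weight of the search objective.
#' @param sana_iters,magna_population,magna_generations search budgets.
#' @param reduction similarity reduction, `"pca"` or `"none"`.
#' @export
sweep_config <- function(models = c("geo", "sf"),
                         methods = c("wave", "sana"),
                         scenarios = "HetNC-HetEC",
                         ks = c(1L, 2L, 4L),
                         noise_levels = c(0, 0.25, 0.5),
                         replicates = 3L,
                         n = 300L, m = 1800L,
                         seed = 1L,
                         alpha = 0.5,
                         sana_iters = 4.5e7,
                         magna_population = 200L,
                         magna_generations = 100L,
                         reduction = "none") {
  structure(list(models = models, methods = methods, scenarios = scenarios,
                 ks = ks, noise_levels = noise_levels,
                 replicates = replicates, n = n, m = m, seed = seed,
                 alpha = alpha, sana_iters = sana_iters,
                 magna_population = magna_population,
                 magna_generations = magna_generations,
                 reduction = reduction),
            class = "sweep_config")
}

#' Run the noise-sweep experiment
#'
#' For every cell (model x k x noise x replicate): generate the original
#' network, color it with `k` balanced random colors, rewire `noise` of its
#' edges (keeping the identity true mapping), compute node similarities per
#' scenario, align with each method, and score node correctness. Fully
#' reproducible from the master seed.
#'
#' @param config a [sweep_config()].
#' @param progress print one line per completed cell.
#' @return data frame with columns model, method, scenario, k, noise,
#'   replicate, seed, node_correctness, objective, runtime.
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  seeds <- run_once(config$seed,
                    sample.int(.Machine$integer.max - 1L,
                               10000L + 10L * length(config$models) *
                                 length(config$noise_levels) *
                                 config$replicates * length(config$ks)))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  rows <- list()
  sig_cache <- new.env(parent = emptyenv())
  for (model in config$models) {
    base <- switch(model,
                   geo = generate_geo(config$n, config$m, next_seed()),
                   sf = generate_sf(config$n, config$m, next_seed()),
                   stop("unknown model: ", model))
    for (k in config$ks) {
      colored <- assign_colors_random(base, k, next_seed())
      scen_set <- if (k == 1L) "HomNC-HomEC" else unique(config$scenarios)
      for (noise in config$noise_levels) {
        for (rep_i in seq_len(config$replicates)) {
          noisy <- rewire_noise(colored, noise, next_seed())
          sims <- list()
          for (scen in scen_set) {
            sc <- parse_scenario(scen)
            if (is.null(sims[[sc$nc]])) {
              # original-network signatures are reused across noise cells
              ck <- paste(model, k, sc$nc)
              if (is.null(sig_cache[[ck]])) {
                sig_cache[[ck]] <- if (sc$nc == "hom") count_gdv(colored)
                  else count_ncgdv(colored, colors = color_set(colored))
              }
              sig_noisy <- if (sc$nc == "hom") count_gdv(noisy$network)
                else count_ncgdv(noisy$network, colors = color_set(colored))
              sims[[sc$nc]] <- build_similarity(
                sig_cache[[ck]], sig_noisy, reduction = config$reduction)
            }
            for (method in config$methods) {
              t0 <- proc.time()[["elapsed"]]
              al <- switch(method,
                wave = wave_align(colored, noisy$network, sims[[sc$nc]]),
                sana = sana_align(colored, noisy$network, sims[[sc$nc]],
                                  objective_config(config$alpha, sc$ec),
                                  iters = config$sana_iters,
                                  seed = next_seed()),
                magna = magna_align(colored, noisy$network, sims[[sc$nc]],
                                    objective_config(config$alpha, sc$ec),
                                    population = config$magna_population,
                                    generations = config$magna_generations,
                                    seed = next_seed()),
                stop("unknown method: ", method))
              rt <- proc.time()[["elapsed"]] - t0
              nc_pct <- node_correctness(al, noisy$mapping)
              rows[[length(rows) + 1L]] <- data.frame(
                model = model, method = method, scenario = scen, k = k,
                noise = noise, replicate = rep_i,
                seed = if (is.na(al$seed)) NA_integer_ else al$seed,
                node_correctness = nc_pct,
                objective = al$objective, runtime = rt,
                stringsAsFactors = FALSE)
              if (progress)
                message(sprintf(
                  "%s %s %s k=%d noise=%.2f rep=%d: NC %.1f%% (%.1fs)",
                  model, method, scen, k, noise, rep_i, nc_pct, rt))
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Rank-frequency summary of sweep results
#'
#' Within each case (every factor fixed except `group_by`, after averaging
#' node correctness over replicates), ranks the levels of `group_by` from
#' best (rank 1) to worst by mean node correctness; tied levels share the
#' best applicable rank. Returns the percentage of cases in which each level
#' attains each rank. Full-noise (100%) rows are excluded by default since
#' all alignments are expected to be random there.
#'
#' @param result data frame from [run_sweep()].
#' @param group_by factor column to rank: `"k"`, `"method"` or `"scenario"`.
#' @param exclude_full_noise drop `noise == 1` rows first (default TRUE).
#' @param best_scenario_per_k before ranking, keep only the best-scoring
#'   scenario within each (case, group level), mirroring best-of
#'   HetNC-HomEC/HetNC-HetEC reporting. Only sensible when `group_by`
#'   is not `"scenario"`.
#' @return data frame with columns level, rank, frequency (percent), cases.
#' @export
rank_summary <- function(result, group_by = "k",
                         exclude_full_noise = TRUE,
                         best_scenario_per_k = FALSE) {
  stopifnot(nrow(result) > 0, group_by %in% names(result))
  df <- result
  if (exclude_full_noise) df <- df[df$noise < 1, , drop = FALSE]
  factors <- intersect(c("model", "method", "scenario", "k", "noise"),
                       names(df))
  # average over replicates
  agg <- stats::aggregate(df["node_correctness"], df[factors], mean)
  if (best_scenario_per_k && "scenario" %in% factors &&
      group_by != "scenario") {
    keycols <- setdiff(factors, "scenario")
    key <- do.call(paste, agg[keycols])
    keep <- unlist(lapply(split(seq_len(nrow(agg)), key), function(idx) {
      idx[which.max(agg$node_correctness[idx])]
    }), use.names = FALSE)
    agg <- agg[keep, , drop = FALSE]
    factors <- keycols
  }
  case_cols <- setdiff(factors, group_by)
  case_key <- if (length(case_cols)) do.call(paste, agg[case_cols])
              else rep("all", nrow(agg))
  out <- list()
  for (cs in unique(case_key)) {
    sub <- agg[case_key == cs, , drop = FALSE]
    rk <- rank(-sub$node_correctness, ties.method = "min")
    out[[length(out) + 1L]] <- data.frame(
      level = as.character(sub[[group_by]]), rank = rk,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, out)
  n_cases <- length(unique(case_key))
  tab <- as.data.frame(table(level = long$level, rank = long$rank),
                       stringsAsFactors = FALSE)
  tab$frequency <- 100 * tab$Freq / n_cases
  tab$rank <- as.integer(tab$rank)
  tab$cases <- n_cases
  tab[order(tab$level, tab$rank), c("level", "rank", "frequency", "cases")]
}
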