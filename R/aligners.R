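# The three alignment strategies. All consume a cross-network similarity
# matrix (rows: G nodes, columns: H nodes, G the smaller network) and return
# an injective mapping total on V(G).
#
# wave_align: greedy seed-and-extend. magna_align: genetic search over
# injective mappings. sana_align: simulated annealing with incremental
# objective updates (C++ core).

check_sim <- function(g, h, sim) {
  if (!identical(rownames(sim), g$nodes) ||
      !identical(colnames(sim), h$nodes))
    stop("similarity matrix must cover all G x H pairs ",
         "(rownames = G nodes, colnames = H nodes)")
  sim
}

#' Seed-and-extend alignment (WAVE-style)
#'
#' Seeds the alignment with the highest-similarity cross-network pair, then
#' repeatedly commits the best candidate pair among (g, h) where g neighbors
#' an aligned source and h neighbors its image. A candidate's score is its
#' similarity plus one vote per already-aligned neighbor pair supporting it,
#' so edge conservation is optimized implicitly. Ties break lexicographically
#' on (G node, H node) order. If the frontier empties before all of V(G) is
#' aligned, a fresh seed is picked among unaligned pairs by best similarity.
#'
#' @param g,h [colored_network] objects with `|V(G)| <= |V(H)|`.
#' @param sim similarity matrix with `rownames = g$nodes`,
#'   `colnames = h$nodes`.
#' @return an [alignment] (method `"wave"`).
#' @export
wave_align <- function(g, h, sim) {
  ng <- length(g$nodes); nh <- length(h$nodes)
  if (ng > nh) stop("G must be the smaller network; swap the arguments")
  check_sim(g, h, sim)

  nbr_g <- vector("list", ng)
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1L]; b <- g$edges[e, 2L]
    nbr_g[[a]] <- c(nbr_g[[a]], b); nbr_g[[b]] <- c(nbr_g[[b]], a)
  }
  nbr_h <- vector("list", nh)
  for (e in seq_len(nrow(h$edges))) {
    a <- h$edges[e, 1L]; b <- h$edges[e, 2L]
    nbr_h[[a]] <- c(nbr_h[[a]], b); nbr_h[[b]] <- c(nbr_h[[b]], a)
  }

  votes <- matrix(0, ng, nh)
  cand <- matrix(-Inf, ng, nh)   # candidate pool scores (sim + votes)
  sim_live <- sim                # for (re)seeding; -Inf once aligned
  f <- rep(NA_integer_, ng)
  aligned_h <- logical(nh)

  pick <- function(m) {
    mx <- max(m)
    if (!is.finite(mx)) return(NULL)
    idx <- which(m == mx)
    rows <- (idx - 1L) %% ng + 1L
    cols <- (idx - 1L) %/% ng + 1L
    first <- order(rows, cols)[1L]  # lexicographic tie-break on node order
    c(rows[first], cols[first])
  }

  commit <- function(u, hu) {
    f[u] <<- hu
    aligned_h[hu] <<- TRUE
    sim_live[u, ] <<- -Inf
    sim_live[, hu] <<- -Inf
    cand[u, ] <<- -Inf
    cand[, hu] <<- -Inf
    gn <- nbr_g[[u]]; gn <- gn[is.na(f[gn])]
    hn <- nbr_h[[hu]]; hn <- hn[!aligned_h[hn]]
    if (length(gn) && length(hn)) {
      votes[gn, hn] <<- votes[gn, hn] + 1
      cand[gn, hn] <<- sim[gn, hn] + votes[gn, hn]
    }
  }

  for (step in seq_len(ng)) {
    p <- pick(cand)
    if (is.null(p)) p <- pick(sim_live)  # (re)seed by best similarity
    commit(p[1L], p[2L])
  }

  fm <- setNames(h$nodes[f], g$nodes)
  alignment(fm, method = "wave")
}

#' Simulated-annealing alignment (SANA-style)
#'
#' Starts from a seeded uniformly random injective mapping and explores
#' neighboring alignments: swaps (two sources exchange images) and, when
#' `|V(H)| > |V(G)|`, changes (one source re-images to an unused H node),
#' proposed 50/50 when both are legal. Improving moves are always accepted;
#' worsening moves with probability `exp(delta/T)` under a geometrically
#' decaying temperature calibrated so that about half of the initially
#' proposed worsening moves would be accepted and almost none near the end
#' of the budget. The objective `alpha * NC + (1-alpha) * EC` is updated
#' incrementally per move. The final-iteration alignment is returned.
#' Identical inputs, seed and iteration budget give identical output.
#'
#' @param g,h [colored_network] objects with `|V(G)| <= |V(H)|`.
#' @param sim similarity matrix (G x H).
#' @param objective an [objective_config()].
#' @param iters iteration budget (default `1e5`).
#' @param seconds optional wall-clock budget; when given, the iteration
#'   count is estimated from a short timed calibration run (output is then
#'   machine-dependent, unlike the iteration mode).
#' @param seed integer seed.
#' @return an [alignment] (method `"sana"`) with the final objective value.
#' @export
sana_align <- function(g, h, sim, objective = objective_config(),
                       iters = 1e5, seconds = NULL, seed = 1L) {
  ng <- length(g$nodes); nh <- length(h$nodes)
  if (ng > nh) stop("G must be the smaller network; swap the arguments")
  check_sim(g, h, sim)
  if (!is.null(seconds)) {
    t0 <- proc.time()[["elapsed"]]
    run_once(seed, sana_core(g, h, sim, objective, 2000, seed))
    rate <- 2000 / max(1e-6, proc.time()[["elapsed"]] - t0)
    iters <- max(2000, round(rate * seconds))
  }
  if (!is.numeric(iters) || iters < 1) stop("invalid iteration budget")
  res <- run_once(seed, sana_core(g, h, sim, objective, iters, seed))
  fm <- setNames(h$nodes[res$mapping + 1L], g$nodes)
  alignment(fm, method = "sana", seed = as.integer(seed),
            objective = res$objective)
}

sana_core <- function(g, h, sim, objective, iters, seed) {
  ng <- length(g$nodes); nh <- length(h$nodes)
  init <- sample.int(nh, ng)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sana_align_cpp(ng, nh, g$edges - 1L, h$edges - 1L, sim,
                 match(g$node_color, cols) - 1L,
                 match(h$node_color, cols) - 1L,
                 objective$alpha, objective$ec_measure == "hets3",
                 objective$weights, init - 1L, as.double(iters),
                 as.integer(seed))
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
run_once <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# full-recompute objective for an integer mapping (vectorized); shared by
# magna_align and the tests
mapping_objective <- function(f, g, h, sim, cfg, adj_h) {
  e <- g$edges
  ia <- f[e[, 1L]]; ib <- f[e[, 2L]]
  cons <- adj_h[cbind(ia, ib)]
  gcol <- g$node_color; hcol <- h$node_color
  m <- (gcol[e[, 1L]] == hcol[ia]) + (gcol[e[, 2L]] == hcol[ib])
  W <- if (cfg$ec_measure == "hets3") sum(cfg$weights[3L - m[cons]]) else sum(cons)
  C <- sum(cons)
  in_img <- logical(length(h$nodes)); in_img[f] <- TRUE
  ehin <- sum(in_img[h$edges[, 1L]] & in_img[h$edges[, 2L]])
  denom <- W + (nrow(e) - C) + (ehin - C)
  ec <- if (denom > 0) W / denom else 0
  nc <- mean(sim[cbind(seq_along(f), f)])
  cfg$alpha * nc + (1 - cfg$alpha) * ec
}

#' Genetic-search alignment (MAGNA-style)
#'
#' Evolves a population of injective mappings: fitness is the blended
#' NC/EC objective, the best alignment of each generation survives
#' unchanged (elitism), parents are drawn with probability proportional to
#' fitness, and a uniform-mask crossover combines two parents; positions
#' whose inherited images collide are repaired with random unused images.
#' The best alignment ever seen is returned. The defaults mirror the
#' published tool's suggested population of 15,000 and 2,000 generations;
#' desk-scale runs should lower both.
#'
#' @param g,h [colored_network] objects with `|V(G)| <= |V(H)|`.
#' @param sim similarity matrix (G x H).
#' @param objective an [objective_config()].
#' @param population population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param seed integer seed.
#' @return an [alignment] (method `"magna"`) with its objective value.
#' @export
magna_align <- function(g, h, sim, objective = objective_config(),
                        population = 15000L, generations = 2000L, seed = 1L) {
  ng <- length(g$nodes); nh <- length(h$nodes)
  if (ng > nh) stop("G must be the smaller network; swap the arguments")
  if (population < 2L) stop("population must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  check_sim(g, h, sim)
  adj_h <- matrix(FALSE, nh, nh)
  adj_h[h$edges] <- TRUE
  adj_h[h$edges[, c(2L, 1L), drop = FALSE]] <- TRUE

  run_once(seed, {
    pop <- replicate(population, sample.int(nh, ng), simplify = FALSE)
    fit <- vapply(pop, mapping_objective, 0, g, h, sim, objective, adj_h)
    best_f <- pop[[which.max(fit)]]
    best_v <- max(fit)
    for (gen in seq_len(generations)) {
      pr <- fit - min(fit)
      pr <- if (sum(pr) > 0) pr / sum(pr) else rep(1 / length(fit), length(fit))
      # guard against degenerate all-equal fitness
      pr <- pr + 1e-12
      pr <- pr / sum(pr)
      n_child <- population - 1L
      pa <- sample.int(population, n_child, replace = TRUE, prob = pr)
      pb <- sample.int(population, n_child, replace = TRUE, prob = pr)
      children <- vector("list", n_child)
      for (i in seq_len(n_child)) {
        mask <- stats::runif(ng) < 0.5
        ch <- ifelse(mask, pop[[pa[i]]], pop[[pb[i]]])
        dup <- duplicated(ch)
        if (any(dup)) {
          free <- setdiff(seq_len(nh), ch[!dup])
          ch[dup] <- free[sample.int(length(free), sum(dup))]
        }
        children[[i]] <- ch
      }
      pop <- c(list(best_f), children)
      fit <- vapply(pop, mapping_objective, 0, g, h, sim, objective, adj_h)
      if (max(fit) > best_v) {
        best_v <- max(fit)
        best_f <- pop[[which.max(fit)]]
      }
    }
    fm <- setNames(h$nodes[best_f], g$nodes)
    alignment(fm, method = "magna", seed = as.integer(seed),
              objective = best_v)
  })
}
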