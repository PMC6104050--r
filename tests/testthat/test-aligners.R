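test_that("wave recovers the identity when similarity forces it", {
  net <- random_colored_net(15, 0.35, k = 2, seed = 41)
  n <- length(net$nodes)
  sim <- matrix(0.2, n, n, dimnames = list(net$nodes, net$nodes))
  diag(sim) <- 1
  al <- wave_align(net, net, sim)
  expect_identical(unname(al$mapping), net$nodes)
  expect_equal(node_correctness(al, setNames(net$nodes, net$nodes)), 100)
})

test_that("wave handles a single-node network and validates orientation", {
  g1 <- colored_network(matrix(character(0), 0, 2), nodes = "a")
  h <- random_colored_net(5, 0.5, seed = 42)
  sim <- matrix(c(0.1, 0.9, 0.3, 0.2, 0.4), 1, 5,
                dimnames = list("a", h$nodes))
  al <- wave_align(g1, h, sim)
  expect_identical(unname(al$mapping), h$nodes[2L])
  expect_error(wave_align(h, g1, t(sim)), "smaller")
})

test_that("sana is deterministic for a fixed seed and budget", {
  g <- random_colored_net(12, 0.4, k = 2, seed = 51)
  h <- random_colored_net(15, 0.35, k = 2, seed = 52)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sim <- build_similarity(count_ncgdv(g, colors = cols),
                          count_ncgdv(h, colors = cols), reduction = "none")
  a1 <- sana_align(g, h, sim, iters = 2e4, seed = 7)
  a2 <- sana_align(g, h, sim, iters = 2e4, seed = 7)
  expect_identical(a1$mapping, a2$mapping)
  expect_identical(a1$objective, a2$objective)
  a3 <- sana_align(g, h, sim, iters = 2e4, seed = 8)
  expect_false(identical(a1$mapping, a3$mapping))
  expect_error(sana_align(g, h, sim, iters = 0), "budget")
})

test_that("sana's reported objective matches a from-scratch recomputation", {
  g <- random_colored_net(12, 0.4, k = 2, seed = 53)
  h <- random_colored_net(15, 0.35, k = 2, seed = 54)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sim <- build_similarity(count_ncgdv(g, colors = cols),
                          count_ncgdv(h, colors = cols), reduction = "none")
  for (ecm in c("hets3", "homs3")) {
    cfg <- objective_config(0.5, ecm)
    al <- sana_align(g, h, sim, cfg, iters = 3e4, seed = 11)
    st <- align_state(g, h, al, sim, cfg)
    expect_equal(al$objective, cgalign:::state_objective(st),
                 tolerance = 1e-9, info = ecm)
  }
})

test_that("equal-size networks use swap moves only (image set never changes)", {
  g <- random_colored_net(10, 0.4, seed = 55)
  h <- random_colored_net(10, 0.4, seed = 56)
  sim <- matrix(0.5, 10, 10, dimnames = list(g$nodes, h$nodes))
  al <- sana_align(g, h, sim, iters = 1e4, seed = 3)
  # a bijection: every H node is used exactly once
  expect_setequal(unname(al$mapping), h$nodes)
})

test_that("magna: identical parents reproduce themselves; elitism holds", {
  g <- random_colored_net(8, 0.45, k = 2, seed = 57)
  h <- random_colored_net(10, 0.4, k = 2, seed = 58)
  sim <- matrix(0.5, 8, 10, dimnames = list(g$nodes, h$nodes))
  cfg <- objective_config()

  # crossover of identical parents is that parent (repair never triggers)
  set.seed(1)
  pa <- sample.int(10, 8)
  mask <- runif(8) < 0.5
  ch <- ifelse(mask, pa, pa)
  expect_identical(ch, pa)

  # elitism: returned objective >= best of a fresh generation-1 population
  al <- magna_align(g, h, sim, cfg, population = 30, generations = 10,
                    seed = 5)
  adj_h <- matrix(FALSE, 10, 10)
  adj_h[h$edges] <- TRUE; adj_h[h$edges[, 2:1]] <- TRUE
  gen1 <- cgalign:::run_once(5, {
    pop <- replicate(30, sample.int(10, 8), simplify = FALSE)
    max(vapply(pop, cgalign:::mapping_objective, 0, g, h, sim, cfg, adj_h))
  })
  expect_gte(al$objective, gen1)
  # reported objective is a true recomputation
  st <- align_state(g, h, al, sim, cfg)
  expect_equal(al$objective, cgalign:::state_objective(st), tolerance = 1e-9)
  expect_error(magna_align(g, h, sim, cfg, population = 1), "population")
})

test_that("magna reaches near-optimal objective on an exhaustively solvable instance", {
  # n = 8 toy: brute force over all 8! bijections
  g <- random_colored_net(8, 0.4, k = 2, seed = 59)
  h <- random_colored_net(8, 0.45, k = 2, seed = 60)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sim <- build_similarity(count_ncgdv(g, colors = cols),
                          count_ncgdv(h, colors = cols), reduction = "none")
  cfg <- objective_config()
  adj_h <- matrix(FALSE, 8, 8)
  adj_h[h$edges] <- TRUE; adj_h[h$edges[, 2:1]] <- TRUE
  perms <- cgalign:::all_perms(8L)
  best <- max(apply(perms, 1L, cgalign:::mapping_objective,
                    g, h, sim, cfg, adj_h))
  al <- magna_align(g, h, sim, cfg, population = 200, generations = 100,
                    seed = 13)
  expect_gte(al$objective, 0.95 * best)
})

test_that("all aligners return injective mappings total on V(G)", {
  g <- random_colored_net(9, 0.4, k = 2, seed = 63)
  h <- random_colored_net(12, 0.35, k = 2, seed = 64)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sim <- build_similarity(count_ncgdv(g, colors = cols),
                          count_ncgdv(h, colors = cols), reduction = "none")
  for (al in list(wave_align(g, h, sim),
                  sana_align(g, h, sim, iters = 1e4, seed = 2),
                  magna_align(g, h, sim, population = 20, generations = 5,
                              seed = 2))) {
    expect_setequal(names(al$mapping), g$nodes)
    expect_false(anyDuplicated(al$mapping) > 0)
    expect_true(all(al$mapping %in% h$nodes))
  }
})
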