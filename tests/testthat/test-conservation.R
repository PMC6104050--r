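test_that("worked example: conserved/non-conserved tallies and S3 scores", {
  ex <- worked_example()
  cs <- classify_edges(ex$g, ex$h, ex$f)
  expect_equal(cs$n_conserved, 4L)
  expect_equal(cs$n_nonconserved, 2L)
  expect_equal(cs$weight_full, 1L)
  expect_equal(cs$weight_partial, 2L)
  expect_equal(cs$weight_least, 1L)
  expect_equal(cs$total_weight, 8 / 3)
  expect_equal(hom_s3(cs), 4 / 6)
  expect_equal(het_s3(cs), (8 / 3) / (8 / 3 + 2))
  expect_equal(round(hom_s3(cs), 2), 0.67)
  expect_equal(round(het_s3(cs), 2), 0.57)
})

test_that("self-alignment conserves everything; colors control the weights", {
  net <- random_colored_net(10, 0.4, k = 2, seed = 8)
  f <- setNames(net$nodes, net$nodes)
  cs <- classify_edges(net, net, f)
  expect_equal(cs$n_conserved, nrow(net$edges))
  expect_equal(cs$n_nonconserved, 0L)
  expect_equal(cs$weight_full, nrow(net$edges))
  expect_equal(hom_s3(cs), 1)
  expect_equal(het_s3(cs), 1)

  # recolor the copy so no node matches: all conserved edges least-conserved
  net2 <- net
  net2$node_color <- paste0(net$node_color, "x")
  cs2 <- classify_edges(net, net2, f)
  expect_equal(cs2$weight_least, nrow(net$edges))
  expect_equal(het_s3(cs2), 1 / 3 / (1 / 3))  # (c/3)/((c/3)+0) with m = 0
})

test_that("least-conserved closed form (c/3)/((c/3)+m) holds", {
  # G: path a-b-c-d; H: a-b, b-c, a-d (so c-d maps to a non-edge and
  # H edge a-d is non-conserved from the H side)
  g <- colored_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")),
                       node_color = c(a = "p", b = "p", c = "p", d = "p"))
  h <- colored_network(rbind(c("a", "b"), c("b", "c"), c("a", "d")),
                       node_color = c(a = "q", b = "q", c = "q", d = "q"))
  f <- setNames(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  cs <- classify_edges(g, h, f)
  ccount <- 2; m <- 2
  expect_equal(cs$n_conserved, ccount)
  expect_equal(cs$n_nonconserved, m)
  expect_equal(cs$weight_least, ccount)  # no color ever matches
  expect_equal(het_s3(cs), (ccount / 3) / ((ccount / 3) + m))
})

test_that("k = 1 reduces het_s3 to hom_s3 and het_s3 <= hom_s3 always", {
  for (seed in 1:5) {
    g <- random_colored_net(9, 0.4, k = 3, seed = seed)
    h <- random_colored_net(12, 0.35, k = 3, seed = seed + 50)
    f <- random_alignment(g, h, seed = seed)
    cs <- classify_edges(g, h, f)
    expect_lte(het_s3(cs), hom_s3(cs) + 1e-12)
    expect_true(hom_s3(cs) >= 0 && hom_s3(cs) <= 1)
    # all-one-color versions must coincide
    g1 <- g; g1$node_color <- rep("c", length(g$nodes))
    h1 <- h; h1$node_color <- rep("c", length(h$nodes))
    cs1 <- classify_edges(g1, h1, f)
    expect_equal(het_s3(cs1), hom_s3(cs1))
    expect_equal(hom_s3(cs1), hom_s3(cs))  # colors cannot change topology
  }
})

test_that("classify_edges validates the mapping", {
  ex <- worked_example()
  expect_error(classify_edges(ex$g, ex$h, c(a = "a", b = "a")),
               "injective")
  expect_error(classify_edges(ex$g, ex$h, c(a = "a", b = "b")),
               "total")
})

test_that("delta_objective equals full recomputation over random moves", {
  set.seed(99)
  g <- random_colored_net(12, 0.35, k = 2, seed = 61)
  h <- random_colored_net(16, 0.3, k = 2, seed = 62)
  cols <- sort(unique(c(g$node_color, h$node_color)))
  sim <- build_similarity(count_ncgdv(g, colors = cols),
                          count_ncgdv(h, colors = cols), reduction = "none")
  ng <- length(g$nodes); nh <- length(h$nodes)
  for (ecm in c("hets3", "homs3")) {
    cfg <- objective_config(0.5, ecm)
    st <- align_state(g, h, sample.int(nh, ng), sim, cfg)
    obj <- cgalign:::state_objective(st)
    n_moves <- 500L
    for (i in seq_len(n_moves)) {
      if (runif(1) < 0.5) {
        uv <- sample.int(ng, 2L)
        mv <- list(type = "swap", u = uv[1L], v = uv[2L])
      } else {
        mv <- list(type = "change", u = sample.int(ng, 1L),
                   h_new = sample(setdiff(seq_len(nh), st$f), 1L))
      }
      d <- delta_objective(st, mv)
      st2 <- attr(d, "state")
      obj2 <- cgalign:::state_objective(st2)
      expect_equal(obj + as.numeric(d), obj2, tolerance = 1e-9,
                   info = sprintf("%s move %d (%s)", ecm, i, mv$type))
      st <- st2
      obj <- obj2
    }
  }
})

test_that("swap then swap back is a net zero", {
  g <- random_colored_net(8, 0.4, k = 2, seed = 71)
  h <- random_colored_net(10, 0.4, k = 2, seed = 72)
  sim <- matrix(0.5, 8, 10, dimnames = list(g$nodes, h$nodes))
  st <- align_state(g, h, 1:8, sim, objective_config())
  mv <- list(type = "swap", u = 2L, v = 5L)
  d1 <- delta_objective(st, mv)
  d2 <- delta_objective(attr(d1, "state"), mv)
  expect_equal(as.numeric(d1) + as.numeric(d2), 0, tolerance = 1e-12)
})

test_that("illegal moves are rejected", {
  g <- random_colored_net(6, 0.5, seed = 81)
  h <- random_colored_net(8, 0.5, seed = 82)
  sim <- matrix(0.5, 6, 8, dimnames = list(g$nodes, h$nodes))
  st <- align_state(g, h, 1:6, sim, objective_config())
  expect_error(delta_objective(st, list(type = "swap", u = 2L, v = 2L)),
               "illegal")
  expect_error(delta_objective(st, list(type = "change", u = 1L, h_new = 3L)),
               "in use")
})
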