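test_that("catalog sizes match brute-force enumeration", {
  # graphlet counts 1/2/6/21 and orbit totals 1/4/15/73 for max sizes 2..5
  # were computed by the package's own exhaustive enumeration and are the
  # standard values for connected graphs on 2..5 nodes
  expect_error(build_catalog(1), "2..5")
  expect_error(build_catalog(6), "2..5")
  ct2 <- build_catalog(2)
  expect_equal(length(ct2$graphlets), 1L)
  expect_equal(ct2$n_orbits, 1L)
  ct3 <- build_catalog(3)
  expect_equal(length(ct3$graphlets), 3L)
  expect_equal(ct3$n_orbits, 4L)
  ct5 <- build_catalog(5)
  expect_equal(length(ct5$graphlets), 30L)
  expect_equal(ct5$n_orbits, 73L)
})

test_that("catalog orbits agree with igraph automorphism groups", {
  ct <- build_catalog(5)
  for (gl in ct$graphlets) {
    g <- igraph::make_empty_graph(gl$size, directed = FALSE)
    g <- igraph::add_edges(g, t(gl$edges))
    gens <- igraph::automorphism_group(g)
    # orbits from generators: union-find over generator images
    rep_ <- seq_len(gl$size)
    find <- function(x) { while (rep_[x] != x) x <- rep_[x]; x }
    for (p in gens) {
      p <- as.integer(p)
      for (v in seq_len(gl$size)) {
        a <- find(v); b <- find(p[v])
        if (a != b) rep_[max(a, b)] <- min(a, b)
      }
    }
    orb_igraph <- vapply(seq_len(gl$size), find, 0L)
    # same partition?
    expect_equal(length(unique(orb_igraph)), length(unique(gl$orbit_local)),
                 info = sprintf("graphlet G%d", gl$id))
    expect_true(all(table(orb_igraph, gl$orbit_local) %in%
                      c(0L, table(orb_igraph))),
                info = sprintf("graphlet G%d partition", gl$id))
  }
})

test_that("colored-variant counts follow the combination and exhaustive schemes", {
  ct <- build_catalog(5)
  path3 <- ct$graphlets[[2]]
  expect_equal(path3$size, 3L)
  expect_equal(path3$n_edges, 2L)
  expect_equal(enumerate_colored_variants(path3, 2, "exhaustive"), 6L)
  expect_equal(enumerate_colored_variants(path3, 3, "exhaustive"), 18L)
  expect_equal(enumerate_colored_variants(path3, 2, "combination"), 3L)
  expect_equal(enumerate_colored_variants(path3, 3, "combination"), 7L)
  expect_error(enumerate_colored_variants(path3, 0), ">= 1")
  # combination scheme is 2^k - 1 for every graphlet
  for (gl in ct$graphlets[c(1, 5, 12, 30)]) {
    for (k in 1:4)
      expect_equal(enumerate_colored_variants(gl, k, "combination"), 2L^k - 1L)
  }
  # exhaustive counts for the single edge: Burnside gives k(k+1)/2
  edge <- ct$graphlets[[1]]
  for (k in 1:3)
    expect_equal(enumerate_colored_variants(edge, k, "exhaustive"),
                 k * (k + 1L) / 2L)
})

test_that("triangle and single-edge GDVs match manual enumeration", {
  tri <- colored_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  g <- count_gdv(tri)
  expect_equal(unname(g[, "o0"]), c(2, 2, 2))
  expect_equal(unname(g[, "o3"]), c(1, 1, 1))
  expect_equal(sum(g), 9)  # nothing else

  e1 <- colored_network(rbind(c("a", "b")))
  ge <- count_gdv(e1)
  expect_equal(unname(ge[, "o0"]), c(1, 1))
  expect_equal(sum(ge), 2)
})

test_that("colored path counts land in the right color combinations", {
  net <- colored_network(rbind(c("a", "b"), c("b", "c")),
                         node_color = c(a = "red", b = "red", c = "blue"))
  nc <- count_ncgdv(net)
  # colors sorted: blue, red -> combos: {blue}, {red}, {blue,red}
  expect_equal(unname(nc["b", "o1|blue+red"]), 1)  # middle orbit, both colors
  expect_equal(unname(nc["b", "o0|red"]), 1)       # edge a-b
  expect_equal(unname(nc["b", "o0|blue+red"]), 1)  # edge b-c
  expect_equal(sum(nc["b", ]), 3)

  nete <- colored_network(rbind(c("a", "b"), c("b", "c")),
                          edge_color = c("e1", "e2"))
  ec <- count_ecgdv(nete)
  expect_equal(unname(ec["b", "o1|e1+e2"]), 1)
  expect_equal(unname(ec["b", "o0|e1"]), 1)
  expect_equal(unname(ec["b", "o0|e2"]), 1)
})

test_that("one color collapses NCGDV and ECGDV to the homogeneous GDV", {
  net <- random_colored_net(10, 0.35, k = 1, k_edge = 1, seed = 3)
  g <- count_gdv(net)
  nc <- count_ncgdv(net)
  ec <- count_ecgdv(net)
  expect_equal(unname(nc), unname(g))
  expect_equal(unname(ec), unname(g))
})

test_that("fast counters match the brute-force oracle on random graphs", {
  # >= 20 seeded trials, n <= 12, up to 3 node and 2 edge colors
  n_trials <- 20L
  for (trial in seq_len(n_trials)) {
    n <- 5L + (trial %% 8L)
    net <- random_colored_net(n, 0.25 + 0.03 * (trial %% 7L),
                              k = 1L + trial %% 3L,
                              k_edge = 1L + trial %% 2L,
                              seed = 1000L + trial)
    expect_equal(count_gdv(net), count_signatures_brute(net, "gdv"),
                 info = paste("gdv trial", trial))
    nc <- count_ncgdv(net)
    expect_equal(nc, count_signatures_brute(net, "ncgdv"),
                 info = paste("ncgdv trial", trial))
    ec <- count_ecgdv(net)
    expect_equal(ec, count_signatures_brute(net, "ecgdv"),
                 info = paste("ecgdv trial", trial))

    # marginalization: summing combinations per orbit recovers the GDV
    k <- length(unique(net$node_color))
    ncomb <- 2L^k - 1L
    marg <- sapply(seq_len(73L), function(o) {
      rowSums(nc[, (o - 1L) * ncomb + seq_len(ncomb), drop = FALSE])
    })
    expect_equal(unname(marg), unname(count_gdv(net)),
                 info = paste("marginalization trial", trial))
  }
})

test_that("combinations with more colors than graphlet nodes stay zero", {
  net <- random_colored_net(10, 0.4, k = 4, seed = 17)
  k <- length(unique(net$node_color))
  skip_if(k < 4)  # coloring is random; nearly always 4 colors at n = 10
  nc <- count_ncgdv(net)
  ct <- build_catalog(5)
  sizes <- integer(ct$n_orbits)
  for (gl in ct$graphlets) sizes[gl$orbit_global] <- gl$size
  ncomb <- 2L^k - 1L
  n_col_in_comb <- vapply(seq_len(ncomb), function(m) {
    sum(bitwAnd(m, 2L^(0:(k - 1L))) > 0)
  }, 0L)
  for (o in seq_len(ct$n_orbits)) {
    too_big <- which(n_col_in_comb > sizes[o])
    if (length(too_big))
      expect_equal(sum(nc[, (o - 1L) * ncomb + too_big]), 0,
                   info = paste("orbit", o - 1L))
  }
})

test_that("concat_signatures binds columns and checks node sets", {
  net <- random_colored_net(8, 0.4, k = 2, k_edge = 2, seed = 9)
  nc <- count_ncgdv(net)
  ec <- count_ecgdv(net)
  both <- concat_signatures(nc, ec)
  expect_equal(ncol(both), ncol(nc) + ncol(ec))
  expect_equal(both[, seq_len(ncol(nc))], nc)
  expect_equal(concat_signatures(nc, NULL), nc)
  rownames(ec) <- rev(rownames(ec))
  expect_error(concat_signatures(nc, ec), "mismatched")
})
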