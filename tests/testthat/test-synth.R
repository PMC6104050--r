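test_that("geo generator hits exact sizes and is seeded", {
  net <- generate_geo(50, 120, seed = 3)
  expect_length(net$nodes, 50L)
  expect_equal(nrow(net$edges), 120L)
  net2 <- generate_geo(50, 120, seed = 3)
  expect_identical(net$edges, net2$edges)
  expect_false(identical(net$edges, generate_geo(50, 120, seed = 4)$edges))
  # m = max gives the complete graph
  k4 <- generate_geo(4, 6, seed = 1)
  expect_equal(nrow(k4$edges), 6L)
  expect_error(generate_geo(4, 7, seed = 1), "exceeds")
})

test_that("sf generator hits exact sizes with a heavy-tailed degree profile", {
  net <- generate_sf(50, 300, seed = 5)
  expect_length(net$nodes, 50L)
  expect_equal(nrow(net$edges), 300L)
  expect_identical(net$edges, generate_sf(50, 300, seed = 5)$edges)
  p3 <- generate_sf(3, 2, seed = 1)
  expect_equal(nrow(p3$edges), 2L)

  # heavy tail: max degree well above the geometric model's at same size,
  # checked over 5 seeds
  max_deg <- function(net) {
    max(tabulate(c(net$edges), nbins = length(net$nodes)))
  }
  sf_max <- vapply(1:5, function(s) max_deg(generate_sf(200, 1200, seed = s)), 0)
  geo_max <- vapply(1:5, function(s) max_deg(generate_geo(200, 1200, seed = s)), 0)
  expect_gt(mean(sf_max), 2 * mean(geo_max))
})

test_that("balanced random coloring yields class sizes within one", {
  net <- generate_geo(40, 100, seed = 7)
  n1 <- assign_colors_random(net, 1, seed = 1)
  expect_equal(unique(n1$node_color), "c1")
  n4 <- assign_colors_random(net, 4, seed = 1)
  expect_equal(unname(table(n4$node_color)), rep(10L, 4L), ignore_attr = TRUE)
  n3 <- assign_colors_random(generate_geo(10, 20, seed = 8), 3, seed = 2)
  expect_setequal(as.integer(table(n3$node_color)), c(4L, 3L))
  expect_error(assign_colors_random(net, 0, seed = 1), "k must be")
  expect_error(assign_colors_random(net, 41, seed = 1), "k must be")
})

test_that("membership coloring follows the A-precedence scheme", {
  net <- colored_network(rbind(c("1", "2"), c("2", "3"), c("3", "4")))
  lists <- list(aging = c("1", "3"), cancer = c("3", "4"))
  s4 <- assign_colors_membership(net, lists, scheme = 4)
  cols <- setNames(s4$node_color, s4$nodes)
  expect_equal(unname(cols["1"]), "aging")
  expect_equal(unname(cols["3"]), "aging-and-cancer")
  expect_equal(unname(cols["4"]), "cancer-only")
  expect_equal(unname(cols["2"]), "non-aging-non-cancer")

  s3 <- assign_colors_membership(net, lists, scheme = 3)
  cols3 <- setNames(s3$node_color, s3$nodes)
  expect_equal(unname(cols3["3"]), "aging")  # A takes precedence
  expect_equal(n_colors(s3), 3L)

  s2 <- assign_colors_membership(net, list(A = character(0)), scheme = 2)
  expect_equal(unique(s2$node_color), "non-A")
})

test_that("rewiring preserves sizes and colors, survival rate is exact", {
  net <- assign_colors_random(generate_geo(60, 360, seed = 9), 3, seed = 10)
  for (x in c(0, 0.25, 0.5, 1)) {
    nz <- rewire_noise(net, x, seed = 11)
    expect_identical(nz$network$nodes, net$nodes)
    expect_identical(nz$network$node_color, net$node_color)
    expect_equal(nrow(nz$network$edges), nrow(net$edges))
    expect_identical(nz$mapping, setNames(net$nodes, net$nodes))
    okey <- paste(net$edges[, 1], net$edges[, 2])
    nkey <- paste(nz$network$edges[, 1], nz$network$edges[, 2])
    surv <- length(intersect(okey, nkey))
    expect_equal(surv, nrow(net$edges) - round(x * nrow(net$edges)))
  }
  # x = 0 is the identity
  expect_identical(rewire_noise(net, 0, seed = 1)$network$edges, net$edges)
  # x = 1 gives a disjoint edge set (checked above via surv = 0)
  expect_identical(rewire_noise(net, 0.5, seed = 3)$network$edges,
                   rewire_noise(net, 0.5, seed = 3)$network$edges)
})

test_that("rewiring refuses infeasible levels", {
  k4 <- generate_geo(4, 6, seed = 1)  # complete graph: no non-edges
  expect_error(rewire_noise(k4, 0.5, seed = 1), "non-edges")
})
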