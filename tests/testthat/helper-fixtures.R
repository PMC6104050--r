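# shared fixtures: tiny networks built in code

# the 4-node worked example: G has edges {a-b, a-c, a-d, b-d, c-d}, H the
# primed counterpart with {a-b, a-c, b-d, c-d, b-c}; under the identity
# mapping there are 4 conserved and 2 non-conserved edges. Colors: a, b
# match their images; c, d do not.
worked_example <- function() {
  g <- colored_network(
    rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "d"), c("c", "d")),
    node_color = c(a = "red", b = "blue", c = "green", d = "yellow"))
  h <- colored_network(
    rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d"), c("b", "c")),
    node_color = c(a = "red", b = "blue", c = "purple", d = "orange"))
  f <- setNames(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  list(g = g, h = h, f = f)
}

# seeded Erdos-Renyi-ish random colored network on n nodes
random_colored_net <- function(n, p, k = 1L, k_edge = NULL, seed = 1L) {
  set.seed(seed)
  am <- matrix(stats::runif(n * n) < p, n, n)
  am[lower.tri(am, diag = TRUE)] <- FALSE
  ed <- which(am, arr.ind = TRUE)
  if (nrow(ed) < 1L) ed <- cbind(1L, 2L)
  nodes <- sprintf("n%02d", seq_len(n))
  ec <- if (!is.null(k_edge))
    sample(paste0("e", seq_len(k_edge)), nrow(ed), replace = TRUE)
  colored_network(cbind(nodes[ed[, 1L]], nodes[ed[, 2L]]), nodes = nodes,
                  node_color = setNames(
                    sample(paste0("c", seq_len(k)), n, replace = TRUE),
                    nodes),
                  edge_color = ec)
}

# random injective integer mapping as a named character alignment
random_alignment <- function(g, h, seed = 1L) {
  set.seed(seed)
  alignment(setNames(sample(h$nodes, length(g$nodes)), g$nodes))
}
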