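# Synthetic benchmark networks: geometric random graphs and scale-free
# networks at exact (n, m), balanced random node colors, membership-list
# coloring schemes, and x%-rewired noisy counterparts with a known true
# node mapping. All generators are seeded-deterministic.

synth_node_names <- function(n) sprintf("v%0*d", nchar(n), seq_len(n))

#' Geometric random graph with exact size
#'
#' Drops `n` points uniformly into the unit 3-cube and connects the `m`
#' closest pairs by Euclidean distance (equivalent to choosing the
#' connection radius so that exactly `m` edges exist; distance ties break
#' deterministically by node order).
#'
#' @param n number of nodes.
#' @param m number of edges, at most `n(n-1)/2`.
#' @param seed integer seed.
#' @return a [colored_network] with all nodes colored `"c1"`.
#' @export
generate_geo <- function(n, m, seed = 1L) {
  if (m > n * (n - 1) / 2) stop("m exceeds the number of node pairs")
  run_once(seed, {
    pts <- matrix(stats::runif(3 * n), n, 3)
    d <- as.matrix(stats::dist(pts))
    ij <- which(upper.tri(d), arr.ind = TRUE)
    dv <- d[upper.tri(d)]
    sel <- order(dv, ij[, 1L], ij[, 2L])[seq_len(m)]
    nodes <- synth_node_names(n)
    colored_network(cbind(nodes[ij[sel, 1L]], nodes[ij[sel, 2L]]),
                    nodes = nodes)
  })
}

#' Scale-free network with exact size
#'
#' Grows a preferential-attachment network with a per-step attachment count
#' near `m/n`, then randomly removes surplus edges or adds random non-edges
#' (seeded) until exactly `m` edges remain. The result keeps the
#' heavy-tailed degree distribution of the growth model.
#'
#' @inheritParams generate_geo
#' @export
generate_sf <- function(n, m, seed = 1L) {
  if (m > n * (n - 1) / 2) stop("m exceeds the number of node pairs")
  if (m < 1) stop("m must be positive")
  run_once(seed, {
    per_step <- max(1L, round(m / n))
    g <- igraph::sample_pa(n, m = per_step, directed = FALSE,
                           algorithm = "psumtree")
    em <- igraph::as_edgelist(g, names = FALSE)
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    em <- em[!duplicated(paste(em[, 1L], em[, 2L])), , drop = FALSE]
    if (nrow(em) > m) {
      em <- em[sort(sample.int(nrow(em), m)), , drop = FALSE]
    } else if (nrow(em) < m) {
      have <- new.env(hash = TRUE)
      for (r in seq_len(nrow(em)))
        assign(paste(em[r, 1L], em[r, 2L]), TRUE, envir = have)
      add <- matrix(0L, 0L, 2L)
      while (nrow(em) + nrow(add) < m) {
        a <- sample.int(n, 1L); b <- sample.int(n, 1L)
        if (a == b) next
        key <- paste(min(a, b), max(a, b))
        if (!is.null(have[[key]])) next
        assign(key, TRUE, envir = have)
        add <- rbind(add, c(min(a, b), max(a, b)))
      }
      em <- rbind(em, add)
    }
    nodes <- synth_node_names(n)
    colored_network(cbind(nodes[em[, 1L]], nodes[em[, 2L]]), nodes = nodes)
  })
}

#' Balanced random node coloring
#'
#' Randomly assigns each node one of `k` colors `c1..ck` such that the color
#' class sizes differ by at most one (about `n/k` nodes per color).
#'
#' @param network a [colored_network].
#' @param k number of colors, `1 <= k <= |V|`.
#' @param seed integer seed.
#' @return the network with `node_color` replaced.
#' @export
assign_colors_random <- function(network, k, seed = 1L) {
  n <- length(network$nodes)
  if (k < 1 || k > n) stop("k must be in 1..|V|")
  run_once(seed, {
    cols <- sample(rep_len(paste0("c", seq_len(k)), n))
    network$node_color <- cols
    network
  })
}

#' Membership-list node coloring
#'
#' Colors nodes by membership in up to two node lists A and B, mirroring
#' annotation-derived color schemes: scheme 2 distinguishes in-A from
#' not-in-A; scheme 3 uses in-A, else-in-B, else-neither (A takes
#' precedence); scheme 4 additionally separates nodes in both lists.
#'
#' @param network a [colored_network].
#' @param lists named list of node-identifier vectors; the first entry is
#'   list A, the second list B.
#' @param scheme 2, 3 or 4.
#' @return the network with `node_color` replaced.
#' @export
assign_colors_membership <- function(network, lists, scheme = 4L) {
  scheme <- as.integer(scheme)
  if (!scheme %in% 2:4) stop("scheme must be 2, 3 or 4")
  if (length(lists) < max(1L, scheme - 2L))
    stop("not enough membership lists for this scheme")
  a_name <- if (!is.null(names(lists)[1]) && nzchar(names(lists)[1]))
    names(lists)[1] else "A"
  in_a <- network$nodes %in% lists[[1L]]
  if (scheme == 2L) {
    network$node_color <- ifelse(in_a, a_name, paste0("non-", a_name))
    return(network)
  }
  b_name <- if (!is.null(names(lists)[2]) && nzchar(names(lists)[2]))
    names(lists)[2] else "B"
  in_b <- network$nodes %in% lists[[2L]]
  neither <- paste0("non-", a_name, "-non-", b_name)
  if (scheme == 3L) {
    network$node_color <- ifelse(in_a, a_name,
                                 ifelse(in_b, paste0(b_name, "-only"),
                                        neither))
  } else {
    network$node_color <- ifelse(in_a & in_b, paste0(a_name, "-and-", b_name),
                                 ifelse(in_a, a_name,
                                        ifelse(in_b, paste0(b_name, "-only"),
                                               neither)))
  }
  network
}

#' Rewire a fraction of edges to create a noisy counterpart
#'
#' Removes `round(level * |E|)` randomly chosen edges and adds the same
#' number of randomly chosen node pairs that are non-edges in the original
#' network (and distinct from each other), so node set, node colors, and
#' node/edge counts are all preserved. Returns the noisy network together
#' with the identity true node mapping.
#'
#' @param network a [colored_network].
#' @param level rewiring fraction in `[0,1]`.
#' @param seed integer seed.
#' @return list with elements `network` (the noisy [colored_network]) and
#'   `mapping` (named character vector: original node -> noisy node).
#' @export
rewire_noise <- function(network, level, seed = 1L) {
  if (level < 0 || level > 1) stop("noise level must be in [0,1]")
  m <- nrow(network$edges)
  n <- length(network$nodes)
  n_rewire <- round(level * m)
  truth <- setNames(network$nodes, network$nodes)
  if (n_rewire == 0L) return(list(network = network, mapping = truth))
  if (n * (n - 1) / 2 - m < n_rewire)
    stop("not enough non-edges to rewire at this level")
  run_once(seed, {
    drop <- sample.int(m, n_rewire)
    orig_key <- paste(network$edges[, 1L], network$edges[, 2L])
    have <- new.env(hash = TRUE)
    for (k in orig_key) assign(k, TRUE, envir = have)
    add <- matrix(0L, 0L, 2L)
    while (nrow(add) < n_rewire) {
      a <- sample.int(n, 1L); b <- sample.int(n, 1L)
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (!is.null(have[[key]])) next
      assign(key, TRUE, envir = have)
      add <- rbind(add, c(min(a, b), max(a, b)))
    }
    em <- rbind(network$edges[-drop, , drop = FALSE], add)
    ec <- NULL
    if (!is.null(network$edge_color)) {
      pool <- sort(unique(network$edge_color))
      ec <- c(network$edge_color[-drop],
              sample(pool, n_rewire, replace = TRUE))
    }
    noisy <- colored_network(
      cbind(network$nodes[em[, 1L]], network$nodes[em[, 2L]]),
      nodes = network$nodes,
      node_color = setNames(network$node_color, network$nodes),
      edge_color = ec)
    list(network = noisy, mapping = truth)
  })
}
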