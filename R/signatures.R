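# Graphlet degree vectors, homogeneous and colored. The fast path enumerates
# each connected induced subgraph on 2..5 nodes exactly once (ESU) in C++ and
# bins it per touched node by (orbit, color combination); the combination is
# the set of node (or edge) colors present anywhere in the occurrence,
# including the counted node itself. A brute-force reference counter based on
# igraph isomorphism tests is provided for validation.

comb_labels <- function(colors) {
  k <- length(colors)
  vapply(seq_len(2^k - 1L), function(mask) {
    paste(colors[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0], collapse = "+")
  }, "")
}

signature_colnames <- function(n_orbits, colors) {
  cl <- comb_labels(colors)
  as.vector(t(outer(seq_len(n_orbits) - 1L, cl,
                    function(o, l) paste0("o", o, "|", l))))
}

check_colors <- function(declared, present, what) {
  if (is.null(declared)) return(sort(unique(present)))
  declared <- as.character(declared)
  if (anyDuplicated(declared)) stop("duplicate declared colors")
  missing <- setdiff(present, declared)
  if (length(missing))
    stop(sprintf("network has %s color(s) outside the declared set: %s",
                 what, paste(missing, collapse = ", ")))
  declared
}

count_colored <- function(network, colors, by_edge, max_size) {
  catalog <- build_catalog(max_size)
  lookup <- build_lookup(catalog)
  lookup_list <- lapply(seq_len(max_size), function(s) {
    if (s < 2L) matrix(0L, 1L, 1L) else lookup[[s]]
  })
  n <- length(network$nodes)
  if (n == 0L) stop("network is empty")
  k <- length(colors)
  if (k > 16L) stop("at most 16 colors are supported")
  if (by_edge) {
    ecol <- match(network$edge_color, colors) - 1L
  } else {
    ecol <- integer(nrow(network$edges))
  }
  ncol_idx <- match(network$node_color, colors) - 1L
  m <- count_signatures_cpp(n, network$edges - 1L,
                            if (by_edge) integer(n) else ncol_idx,
                            ecol, lookup_list, max_size,
                            catalog$n_orbits, k, by_edge)
  dimnames(m) <- list(network$nodes,
                      signature_colnames(catalog$n_orbits, colors))
  m
}

#' Homogeneous graphlet degree vectors
#'
#' For each node, counts the induced occurrences of every connected
#' 2..`max_size`-node graphlet that the node touches, broken down by the
#' automorphism orbit at which it touches them. With `max_size = 5` each node
#' gets a 73-entry vector.
#'
#' @param network a [colored_network] (colors are ignored here).
#' @param max_size largest graphlet size (2..5, default 5).
#' @return numeric matrix, nodes x orbits.
#' @export
count_gdv <- function(network, max_size = 5L) {
  net1 <- network
  net1$node_color <- rep("c1", length(network$nodes))
  m <- count_colored(net1, "c1", FALSE, max_size)
  colnames(m) <- paste0("o", seq_len(ncol(m)) - 1L)
  m
}

#' Node-colored graphlet degree vectors (NCGDV)
#'
#' Counts proceed exactly as in [count_gdv()]; each induced occurrence is
#' additionally binned by the set of node colors present among all of its
#' nodes. The vector has one block of `2^k - 1` color-combination slots per
#' orbit (combinations ordered by subset bitmask over the sorted color set),
#' so summing each block recovers the homogeneous GDV. Slots whose
#' combination has more colors than the graphlet has nodes stay zero but are
#' kept for fixed-width indexing.
#'
#' @param network a [colored_network].
#' @param colors optional ordered color set to index combinations against
#'   (defaults to the sorted colors present). Two networks that will be
#'   compared must use the same color set.
#' @param max_size largest graphlet size (2..5).
#' @return numeric matrix, nodes x (orbits * (2^k - 1)).
#' @export
count_ncgdv <- function(network, colors = NULL, max_size = 5L) {
  colors <- check_colors(colors, network$node_color, "node")
  count_colored(network, colors, FALSE, max_size)
}

#' Edge-colored graphlet degree vectors (ECGDV)
#'
#' As [count_ncgdv()], but occurrences are binned by the set of edge colors
#' present among the induced edges of the occurrence.
#'
#' @inheritParams count_ncgdv
#' @export
count_ecgdv <- function(network, colors = NULL, max_size = 5L) {
  if (is.null(network$edge_color)) stop("network has no edge colors")
  colors <- check_colors(colors, network$edge_color, "edge")
  count_colored(network, colors, TRUE, max_size)
}

#' Concatenate signature matrices column-wise
#'
#' Used to combine NCGDV and ECGDV into one heterogeneous signature; the two
#' matrices must describe the same nodes in the same order.
#'
#' @param ... signature matrices with identical rownames.
#' @return the column-bound matrix.
#' @export
concat_signatures <- function(...) {
  mats <- list(...)
  mats <- mats[!vapply(mats, is.null, TRUE)]
  if (!length(mats)) stop("no matrices given")
  rn <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), rn)) stop("mismatched node sets")
  }
  do.call(cbind, mats)
}

#' Brute-force reference counter for GDV/NCGDV/ECGDV
#'
#' Independent oracle: enumerates all vertex subsets of size 2..`max_size`
#' with `utils::combn`, keeps those inducing a connected subgraph, classifies
#' each against the catalog with igraph isomorphism tests, and reads the
#' orbit of each touched node off an igraph-computed isomorphism to the
#' catalog representative. Exponential in `n`; intended for networks with at
#' most a few dozen nodes.
#'
#' @param network a [colored_network].
#' @param mode `"gdv"`, `"ncgdv"` or `"ecgdv"`.
#' @param colors optional ordered color set, as in [count_ncgdv()].
#' @param max_size largest graphlet size (2..5).
#' @return matrix matching the corresponding fast counter's output.
#' @export
count_signatures_brute <- function(network, mode = c("gdv", "ncgdv", "ecgdv"),
                                   colors = NULL, max_size = 5L) {
  mode <- match.arg(mode)
  catalog <- build_catalog(max_size)
  n <- length(network$nodes)
  by_edge <- mode == "ecgdv"
  if (by_edge && is.null(network$edge_color))
    stop("network has no edge colors")
  colors <- switch(mode,
    gdv = "c1",
    ncgdv = check_colors(colors, network$node_color, "node"),
    ecgdv = check_colors(colors, network$edge_color, "edge"))
  k <- length(colors)
  ncomb <- 2^k - 1L

  g_full <- igraph::make_empty_graph(n, directed = FALSE)
  g_full <- igraph::add_edges(g_full, t(network$edges))
  ekey <- paste(network$edges[, 1L], network$edges[, 2L])

  reps <- lapply(catalog$graphlets, function(gl) {
    igraph::graph_from_edgelist(gl$edges, directed = FALSE)
  })
  rep_size <- vapply(catalog$graphlets, `[[`, 0L, "size")
  rep_edges <- vapply(catalog$graphlets, `[[`, 0L, "n_edges")

  out <- matrix(0, n, catalog$n_orbits * ncomb,
                dimnames = list(network$nodes,
                                if (mode == "gdv")
                                  paste0("o", seq_len(catalog$n_orbits) - 1L)
                                else
                                  signature_colnames(catalog$n_orbits, colors)))

  node_col_idx <- match(network$node_color, colors)
  edge_col_idx <- if (by_edge) match(network$edge_color, colors) else NULL

  for (s in 2L:max_size) {
    if (s > n) break
    subsets <- utils::combn(n, s)
    for (ci in seq_len(ncol(subsets))) {
      vs <- subsets[, ci]
      sub <- igraph::induced_subgraph(g_full, vs)
      if (igraph::ecount(sub) < s - 1L || !igraph::is_connected(sub)) next
      cand <- which(rep_size == s & rep_edges == igraph::ecount(sub))
      hit <- NA_integer_
      map <- NULL
      for (gi in cand) {
        isos <- igraph::graph.get.isomorphisms.vf2(reps[[gi]], sub)
        if (length(isos)) {
          hit <- gi
          # vf2 mappings are indexed by the second graph's vertices, so
          # isos[[1]][p] is the rep vertex matched to sub position p
          map <- as.integer(isos[[1L]])
          break
        }
      }
      stopifnot(!is.na(hit))
      gl <- catalog$graphlets[[hit]]
      if (mode == "gdv") {
        comb <- 1L
      } else if (mode == "ncgdv") {
        comb <- sum(2^(unique(node_col_idx[vs]) - 1L))
      } else {
        prs <- utils::combn(sort(vs), 2L)
        keys <- paste(prs[1L, ], prs[2L, ])
        eidx <- match(keys, ekey)
        eidx <- eidx[!is.na(eidx)]
        comb <- sum(2^(unique(edge_col_idx[eidx]) - 1L))
      }
      for (p in seq_len(s)) {
        orb <- gl$orbit_global[map[p]]
        out[vs[p], (orb - 1L) * ncomb + comb] <-
          out[vs[p], (orb - 1L) * ncomb + comb] + 1
      }
    }
  }
  out
}
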