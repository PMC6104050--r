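# Graphlet catalog: connected non-isomorphic graphs on 2..5 nodes with their
# automorphism (node) orbits, plus labeled-graph lookup tables used by the
# fast subgraph counter.
#
# Internal graph encoding: a graph on s labeled vertices 1..s is a logical
# vector over the C(s,2) vertex pairs, in the fixed pair order
# (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),(1,5),... i.e. bit(i,j) for i<j is
# (j-1)(j-2)/2 + i (1-based). This order lets the counter extend a subgraph's
# adjacency mask incrementally as vertices are appended.

.cg_cache <- new.env(parent = emptyenv())

pair_bit <- function(i, j) {
  # 1-based bit position of unordered pair {i,j}, i < j
  ((j - 1L) * (j - 2L)) %/% 2L + i
}

all_pairs <- function(s) {
  ij <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij
}

all_perms <- function(s) {
  if (s == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(s - 1L)
  out <- vector("list", s)
  for (pos in seq_len(s)) {
    m <- cbind(sub, s)
    if (pos < s) {
      tmp <- m[, pos]
      m[, pos] <- s
      m[, ncol(m)] <- tmp
    }
    out[[pos]] <- m
  }
  do.call(rbind, out)
}

# For permutation p of 1..s, the index vector t with av_permuted[t] = av:
# edge {i,j} in the original lands on {p[i],p[j]} in the permuted graph.
perm_bit_map <- function(p, pairs) {
  pi <- p[pairs[, "i"]]
  pj <- p[pairs[, "j"]]
  lo <- pmin(pi, pj)
  hi <- pmax(pi, pj)
  pair_bit(lo, hi)
}

av_key <- function(av) sum(as.numeric(av) * 2^(seq_along(av) - 1))

is_connected_av <- function(av, s, pairs) {
  if (s == 1L) return(TRUE)
  adj <- vector("list", s)
  sel <- which(av)
  if (length(sel) < s - 1L) return(FALSE)
  for (b in sel) {
    i <- pairs[b, "i"]; j <- pairs[b, "j"]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(s)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

# Canonical form of a labeled graph: the lexicographically smallest adjacency
# vector over all vertex relabelings. Returns the canonical vector, one
# permutation achieving it, and the automorphism orbits of the graph.
canonical_info <- function(av, s, perms, bitmaps) {
  n_perm <- nrow(perms)
  best <- NULL
  best_key <- Inf
  best_perm <- NULL
  orbit_rep <- seq_len(s)   # union-find-ish: smallest vertex reachable by automorphism
  for (r in seq_len(n_perm)) {
    avp <- logical(length(av))
    avp[bitmaps[[r]]] <- av
    key <- av_key(avp)
    if (key < best_key) {
      best_key <- key
      best <- avp
      best_perm <- perms[r, ]
    }
    if (identical(avp, av)) {
      # automorphism: merge vertex classes
      p <- perms[r, ]
      for (v in seq_len(s)) {
        a <- orbit_rep[v]; b <- orbit_rep[p[v]]
        if (a != b) {
          lo <- min(a, b)
          orbit_rep[orbit_rep == a | orbit_rep == b] <- lo
        }
      }
    }
  }
  list(canon = best, perm = best_perm, orbit_rep = orbit_rep)
}

#' Build the graphlet/orbit catalog
#'
#' Enumerates all connected non-isomorphic simple graphs on 2..`max_size`
#' nodes (the graphlets) together with the automorphism node orbits of each
#' graphlet and a global orbit numbering. With `max_size = 5` there are 30
#' graphlets and 73 orbits in total.
#'
#' Graphlets are ordered deterministically by node count, then edge count,
#' then canonical adjacency form; global orbit indices follow that order.
#'
#' @param max_size largest graphlet size, an integer in 2..5.
#' @return An object of class `graphlet_catalog`: a list with elements
#'   `graphlets` (a list; each entry has `size`, `edges` (2-column matrix),
#'   `av` (canonical adjacency vector), `orbit_local` (orbit class per
#'   vertex), `orbit_global` (global orbit index per vertex, 1-based)),
#'   `n_orbits`, and `max_size`.
#' @examples
#' cat5 <- build_catalog(5)
#' cat5$n_orbits  # 73
#' @export
build_catalog <- function(max_size = 5L) {
  max_size <- as.integer(max_size)
  if (is.na(max_size) || max_size < 2L || max_size > 5L)
    stop("max_size must be an integer in 2..5")
  key <- paste0("catalog_", max_size)
  if (!is.null(.cg_cache[[key]])) return(.cg_cache[[key]])

  graphlets <- list()
  for (s in 2L:max_size) {
    pairs <- all_pairs(s)
    L <- nrow(pairs)
    perms <- all_perms(s)
    bitmaps <- lapply(seq_len(nrow(perms)),
                      function(r) perm_bit_map(perms[r, ], pairs))
    seen_keys <- numeric(0)
    entries <- list()
    for (mask in seq_len(2^L) - 1L) {
      av <- as.logical(bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0)
      if (!is_connected_av(av, s, pairs)) next
      ci <- canonical_info(av, s, perms, bitmaps)
      ck <- av_key(ci$canon)
      if (ck %in% seen_keys) next
      seen_keys <- c(seen_keys, ck)
      # re-derive orbits in the canonical labeling
      ci2 <- canonical_info(ci$canon, s, perms, bitmaps)
      orbit_local <- match(ci2$orbit_rep, sort(unique(ci2$orbit_rep)))
      entries[[length(entries) + 1L]] <- list(
        size = s,
        av = ci$canon,
        n_edges = sum(ci$canon),
        canon_key = ck,
        edges = pairs[ci$canon, , drop = FALSE],
        orbit_local = orbit_local
      )
    }
    ord <- order(vapply(entries, `[[`, 0L, "n_edges"),
                 vapply(entries, `[[`, 0, "canon_key"))
    graphlets <- c(graphlets, entries[ord])
  }

  # global orbit numbering
  next_orbit <- 1L
  for (g in seq_along(graphlets)) {
    gl <- graphlets[[g]]
    n_orb <- max(gl$orbit_local)
    graphlets[[g]]$id <- g - 1L          # G_0-style id
    graphlets[[g]]$orbit_global <- gl$orbit_local + next_orbit - 1L
    next_orbit <- next_orbit + n_orb
  }

  out <- structure(
    list(graphlets = graphlets,
         n_orbits = next_orbit - 1L,
         max_size = max_size),
    class = "graphlet_catalog"
  )
  .cg_cache[[key]] <- out
  out
}

#' @export
print.graphlet_catalog <- function(x, ...) {
  cat(sprintf("graphlet catalog: %d graphlets on 2..%d nodes, %d orbits\n",
              length(x$graphlets), x$max_size, x$n_orbits))
  invisible(x)
}

# Lookup tables for the fast counter: for each size s, an integer matrix with
# 2^C(s,2) rows (one per labeled graph, row mask+1) and s columns giving the
# 0-based global orbit of each vertex position, or -1 if the labeled graph is
# disconnected. Built once per catalog and cached.
build_lookup <- function(catalog) {
  key <- paste0("lookup_", catalog$max_size)
  if (!is.null(.cg_cache[[key]])) return(.cg_cache[[key]])
  lookup <- vector("list", catalog$max_size)
  by_size <- split(catalog$graphlets,
                   vapply(catalog$graphlets, `[[`, 0L, "size"))
  for (s in 2L:catalog$max_size) {
    pairs <- all_pairs(s)
    L <- nrow(pairs)
    perms <- all_perms(s)
    bitmaps <- lapply(seq_len(nrow(perms)),
                      function(r) perm_bit_map(perms[r, ], pairs))
    cands <- by_size[[as.character(s)]]
    cand_keys <- vapply(cands, `[[`, 0, "canon_key")
    tab <- matrix(-1L, nrow = 2^L, ncol = s)
    for (mask in seq_len(2^L) - 1L) {
      av <- as.logical(bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0)
      if (!is_connected_av(av, s, pairs)) next
      ci <- canonical_info(av, s, perms, bitmaps)
      gi <- match(av_key(ci$canon), cand_keys)
      gl <- cands[[gi]]
      # ci$perm maps this labeled graph onto the canonical representative
      tab[mask + 1L, ] <- gl$orbit_global[ci$perm] - 1L
    }
    lookup[[s]] <- tab
  }
  .cg_cache[[key]] <- lookup
  lookup
}

#' Count colored variants of a graphlet
#'
#' Under the combination scheme a colored graphlet is identified only by the
#' set of colors present in it, so every graphlet has exactly `2^k - 1`
#' variants for `k` available colors. Under the exhaustive scheme every
#' position-specific node coloring is a distinct variant, counted up to the
#' graphlet's automorphisms; this grows exponentially in `k` and is the
#' brute-force reference motivating the combination scheme.
#'
#' @param graphlet one entry of `build_catalog()$graphlets`, or an index
#'   (1-based) into that list, in which case `catalog` must be supplied.
#' @param k number of available colors, `k >= 1`.
#' @param scheme `"combination"` or `"exhaustive"`.
#' @param catalog optional catalog when `graphlet` is an index.
#' @return Integer count of colored variants.
#' @examples
#' cat5 <- build_catalog(5)
#' path3 <- cat5$graphlets[[2]]       # 3-node path
#' enumerate_colored_variants(path3, 2, "exhaustive")   # 6
#' enumerate_colored_variants(path3, 3, "combination")  # 7
#' @export
enumerate_colored_variants <- function(graphlet, k,
                                       scheme = c("combination", "exhaustive"),
                                       catalog = NULL) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (is.numeric(graphlet)) {
    if (is.null(catalog)) catalog <- build_catalog(5L)
    graphlet <- catalog$graphlets[[graphlet]]
  }
  if (scheme == "combination") return(2L^k - 1L)
  s <- graphlet$size
  pairs <- all_pairs(s)
  perms <- all_perms(s)
  bitmaps <- lapply(seq_len(nrow(perms)),
                    function(r) perm_bit_map(perms[r, ], pairs))
  autos <- which(vapply(seq_len(nrow(perms)), function(r) {
    avp <- logical(length(graphlet$av))
    avp[bitmaps[[r]]] <- graphlet$av
    identical(avp, graphlet$av)
  }, TRUE))
  colorings <- as.matrix(expand.grid(rep(list(seq_len(k)), s)))
  seen <- character(0)
  for (r in seq_len(nrow(colorings))) {
    cl <- colorings[r, ]
    reps <- vapply(autos, function(a) {
      p <- perms[a, ]
      # color at canonical position v after relabeling by p
      paste(cl[order(p)], collapse = ",")
    }, "")
    seen <- c(seen, min(reps))
  }
  length(unique(seen))
}
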