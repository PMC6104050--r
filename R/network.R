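# Colored networks: simple undirected graphs with one color per node and
# optionally one color per edge, plus the plain-text exchange formats
# (2-column edge lists and color maps, 2-column alignments, 3-column
# similarity files).

#' Construct a colored network
#'
#' A colored network is a simple undirected graph in which every node carries
#' exactly one color label and, optionally, every edge carries exactly one
#' edge-color label. With a single node color this is an ordinary
#' (homogeneous) network.
#'
#' @param edges two-column matrix or data frame of node identifiers
#'   (character); one row per undirected edge. Duplicate edges (in either
#'   orientation) are collapsed; self-loops are an error.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`. Extra isolated nodes may be listed.
#' @param node_color optional named character vector mapping node identifier
#'   to color label. Unlisted nodes get the default color `"c1"`. Names must
#'   be known nodes.
#' @param edge_color optional character vector of edge colors, parallel to
#'   the rows of `edges`, or a named vector keyed by `"u|v"` with `u < v`.
#' @return An object of class `colored_network` with elements `nodes`
#'   (character), `edges` (m x 2 integer matrix of indices into `nodes`,
#'   first column smaller), `node_color` (character, parallel to `nodes`)
#'   and `edge_color` (character parallel to edge rows, or `NULL`).
#' @export
colored_network <- function(edges, nodes = NULL, node_color = NULL,
                            edge_color = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed: ",
         paste(unique(edges[edges[, 1L] == edges[, 2L], 1L]), collapse = ", "))
  if (is.null(nodes)) nodes <- sort(unique(c(edges)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  unknown <- setdiff(unique(c(edges)), nodes)
  if (length(unknown)) stop("edge references unknown node(s): ",
                            paste(unknown, collapse = ", "))
  a <- match(edges[, 1L], nodes)
  b <- match(edges[, 2L], nodes)
  em <- cbind(pmin(a, b), pmax(a, b))
  ekey <- paste(em[, 1L], em[, 2L])
  if (!is.null(edge_color)) {
    edge_color <- setNames(as.character(edge_color), names(edge_color))
    if (!is.null(names(edge_color))) {
      want <- paste0(nodes[em[, 1L]], "|", nodes[em[, 2L]])
      miss <- setdiff(want, names(edge_color))
      if (length(miss)) stop("edge_color missing for edge(s): ",
                             paste(miss, collapse = ", "))
      edge_color <- unname(edge_color[want])
    } else if (length(edge_color) != nrow(em)) {
      stop("edge_color must be parallel to edges")
    }
  }
  keep <- !duplicated(ekey)
  if (!all(keep)) {
    # collapsing duplicates must not merge conflicting edge colors
    if (!is.null(edge_color)) {
      for (kk in unique(ekey[duplicated(ekey)])) {
        if (length(unique(edge_color[ekey == kk])) > 1L)
          stop("conflicting colors for duplicated edge ", kk)
      }
    }
    em <- em[keep, , drop = FALSE]
    if (!is.null(edge_color)) edge_color <- edge_color[keep]
  }
  ord <- order(em[, 1L], em[, 2L])
  em <- em[ord, , drop = FALSE]
  if (!is.null(edge_color)) edge_color <- edge_color[ord]

  nc <- rep("c1", length(nodes))
  names(nc) <- nodes
  if (!is.null(node_color)) {
    if (is.null(names(node_color))) stop("node_color must be a named vector")
    node_color <- setNames(as.character(node_color), names(node_color))
    bad <- setdiff(names(node_color), nodes)
    if (length(bad)) stop("node_color names unknown node(s): ",
                          paste(bad, collapse = ", "))
    nc[names(node_color)] <- node_color
  }
  structure(list(nodes = nodes, edges = em,
                 node_color = unname(nc), edge_color = edge_color),
            class = "colored_network")
}

#' @export
print.colored_network <- function(x, ...) {
  cat(sprintf("colored network: %d nodes, %d edges, %d node color(s)%s\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$node_color)),
              if (is.null(x$edge_color)) ""
              else sprintf(", %d edge color(s)", length(unique(x$edge_color)))))
  invisible(x)
}

#' Number of distinct node colors
#' @param network a `colored_network`.
#' @return integer `k >= 1`.
#' @export
n_colors <- function(network) length(unique(network$node_color))

#' Ordered color set of a network (or an explicit superset)
#'
#' The 2^k - 1 nonempty color combinations used to index NCGDV columns are
#' ordered by this color ordering (sorted unique labels), so two networks
#' compared against each other must be counted against the same color set.
#'
#' @param network a `colored_network`.
#' @keywords internal
color_set <- function(network) sort(unique(network$node_color))

read_two_cols <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected 2 fields",
                 what, bad[1L], path))
  if (!length(parts)) return(matrix(character(0), 0L, 2L))
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

#' Read a colored network from plain-text files
#'
#' @param edge_list_path path to a 2-column (whitespace-separated) edge list.
#' @param node_color_path optional path to a 2-column (node, color) file;
#'   nodes absent from the file get color `"c1"`, so a bare edge list reads
#'   as a homogeneous network.
#' @param edge_color_path optional path to a 3-column (node, node, color)
#'   file covering every edge of the network.
#' @return A [colored_network].
#' @export
read_network <- function(edge_list_path, node_color_path = NULL,
                         edge_color_path = NULL) {
  em <- read_two_cols(edge_list_path, "edge list")
  node_color <- NULL
  nodes <- sort(unique(c(em)))
  if (!is.null(node_color_path)) {
    ncm <- read_two_cols(node_color_path, "node color")
    node_color <- setNames(ncm[, 2L], ncm[, 1L])
    nodes <- sort(unique(c(nodes, ncm[, 1L])))
  }
  edge_color <- NULL
  if (!is.null(edge_color_path)) {
    lines <- readLines(edge_color_path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop(sprintf("malformed edge color line %d in %s: expected 3 fields",
                   bad[1L], edge_color_path))
    ecm <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    key <- paste0(pmin(ecm[, 1L], ecm[, 2L]), "|", pmax(ecm[, 1L], ecm[, 2L]))
    edge_color <- setNames(ecm[, 3L], key)
  }
  colored_network(em, nodes = nodes, node_color = node_color,
                  edge_color = edge_color)
}

#' Write a colored network to plain-text files
#'
#' @param network a [colored_network].
#' @param edge_list_path output edge-list path.
#' @param node_color_path optional output path for the node-color map.
#' @param edge_color_path optional output path for the edge-color map.
#' @return `network`, invisibly.
#' @export
write_network <- function(network, edge_list_path, node_color_path = NULL,
                          edge_color_path = NULL) {
  em <- network$edges
  writeLines(paste(network$nodes[em[, 1L]], network$nodes[em[, 2L]],
                   sep = "\t"), edge_list_path)
  if (!is.null(node_color_path)) {
    writeLines(paste(network$nodes, network$node_color, sep = "\t"),
               node_color_path)
  }
  if (!is.null(edge_color_path)) {
    if (is.null(network$edge_color)) stop("network has no edge colors")
    writeLines(paste(network$nodes[em[, 1L]], network$nodes[em[, 2L]],
                     network$edge_color, sep = "\t"), edge_color_path)
  }
  invisible(network)
}

#' Construct an alignment object
#'
#' @param mapping named character vector: names are source (G) nodes, values
#'   their images in H. Must be injective.
#' @param method,seed,objective optional provenance fields.
#' @return Object of class `alignment`.
#' @export
alignment <- function(mapping, method = NA_character_, seed = NA_integer_,
                      objective = NA_real_) {
  mapping <- setNames(as.character(mapping), names(mapping))
  if (length(mapping) && is.null(names(mapping)))
    stop("mapping must be named by source nodes")
  if (anyDuplicated(mapping)) stop("alignment is not injective")
  if (anyDuplicated(names(mapping))) stop("duplicate source nodes")
  structure(list(mapping = mapping, method = method, seed = seed,
                 objective = objective),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment of %d nodes (method: %s, objective: %s)\n",
              length(x$mapping), x$method,
              ifelse(is.na(x$objective), "NA",
                     format(x$objective, digits = 6))))
  invisible(x)
}

#' Write / read an alignment as a 2-column TSV
#'
#' One aligned pair per line: source node, image node. Round-trips exactly.
#'
#' @param alignment an [alignment].
#' @param path file path.
#' @return `write_alignment` returns `alignment` invisibly; `read_alignment`
#'   returns an [alignment].
#' @export
write_alignment <- function(alignment, path) {
  if (!inherits(alignment, "alignment")) alignment <- cgalign::alignment(alignment)
  writeLines(paste(names(alignment$mapping), alignment$mapping, sep = "\t"),
             path)
  invisible(alignment)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  m <- read_two_cols(path, "alignment")
  alignment(setNames(m[, 2L], m[, 1L]))
}

#' Write / read a node-similarity matrix as a 3-column text file
#'
#' Layout: node1 (row of the matrix, a G node), node2 (column, an H node),
#' similarity in `[0,1]`, printed with 6 decimal digits; one line per node
#' pair. This matches the 3-column similarity-file convention of common
#' alignment tools.
#'
#' @param sim numeric matrix with rownames (G nodes) and colnames (H nodes),
#'   values in `[0,1]`.
#' @param path file path.
#' @export
write_similarity <- function(sim, path) {
  if (is.null(rownames(sim)) || is.null(colnames(sim)))
    stop("similarity matrix must have row and column names")
  if (any(sim < 0 | sim > 1)) stop("similarity values must be in [0,1]")
  idx <- expand.grid(g = seq_len(nrow(sim)), h = seq_len(ncol(sim)))
  writeLines(sprintf("%s\t%s\t%.6f",
                     rownames(sim)[idx$g], colnames(sim)[idx$h],
                     sim[cbind(idx$g, idx$h)]), path)
  invisible(sim)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed similarity line %d in %s: expected 3 fields",
                 bad[1L], path))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  val <- as.numeric(m[, 3L])
  if (anyNA(val)) stop("non-numeric similarity value")
  g <- sort(unique(m[, 1L]))
  h <- sort(unique(m[, 2L]))
  out <- matrix(NA_real_, length(g), length(h), dimnames = list(g, h))
  out[cbind(match(m[, 1L], g), match(m[, 2L], h))] <- val
  if (anyNA(out)) stop("similarity file does not cover all node pairs")
  out
}
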