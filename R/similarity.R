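# Cross-network node similarity from signature matrices: stack the two
# matrices, optionally reduce with PCA (fewest components explaining >= 90%
# of variance, but never fewer than two), then cosine similarity per
# cross-network node pair, affinely mapped from [-1,1] to [0,1].

#' Build a cross-network node-similarity matrix
#'
#' The rows of `sig_h` are appended below the rows of `sig_g` and, with
#' `reduction = "pca"`, the stacked matrix is mean-centered and projected
#' onto its first `r` principal components, where `r` is the smallest number
#' of components explaining at least `variance_target` of the variance,
#' floored at 2. Cosine similarity is then computed between every (G node,
#' H node) pair of reduced (or raw, with `reduction = "none"`) vectors and
#' mapped to `[0,1]` as `(cos + 1)/2`. A zero vector has undefined cosine;
#' its similarity to anything is defined as the neutral 0.5.
#'
#' @param sig_g,sig_h signature matrices (nodes x features) with identical
#'   column layouts: same catalog and same ordered color set.
#' @param reduction `"pca"` (default) or `"none"` (the NoPCA variant).
#' @param variance_target fraction of variance the kept components must
#'   explain, default 0.9.
#' @return numeric matrix, `nrow(sig_g)` x `nrow(sig_h)`, values in `[0,1]`,
#'   with G nodes as rownames and H nodes as colnames. The number of
#'   components kept is attached as attribute `"r"` when PCA is used.
#' @export
build_similarity <- function(sig_g, sig_h, reduction = c("pca", "none"),
                             variance_target = 0.9) {
  reduction <- match.arg(reduction)
  if (!nrow(sig_g) || !nrow(sig_h)) stop("empty signature matrix")
  if (ncol(sig_g) != ncol(sig_h) ||
      !identical(colnames(sig_g), colnames(sig_h)))
    stop("signature matrices have mismatched column layouts")
  stacked <- rbind(sig_g, sig_h)
  r <- NA_integer_
  if (reduction == "pca") {
    pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    cum <- cumsum(ev) / sum(ev)
    r <- max(2L, which(cum >= variance_target)[1L])
    r <- min(r, ncol(pc$x))
    stacked <- pc$x[, seq_len(r), drop = FALSE]
  }
  ng <- nrow(sig_g)
  xg <- stacked[seq_len(ng), , drop = FALSE]
  xh <- stacked[ng + seq_len(nrow(sig_h)), , drop = FALSE]
  norm_g <- sqrt(rowSums(xg^2))
  norm_h <- sqrt(rowSums(xh^2))
  cosine <- (xg %*% t(xh)) / outer(norm_g, norm_h)
  cosine[!is.finite(cosine)] <- 0  # zero vectors: neutral
  # numerical guard before the affine map
  cosine[cosine > 1] <- 1
  cosine[cosine < -1] <- -1
  sim <- (cosine + 1) / 2
  dimnames(sim) <- list(rownames(sig_g), rownames(sig_h))
  attr(sim, "r") <- r
  sim
}

#' Signature-to-similarity convenience pipeline
#'
#' Counts signatures for two colored networks against their joint color set
#' and returns the node-similarity matrix. `mode = "hom"` ignores colors
#' (homogeneous GDV similarity); `"het"` uses NCGDV, adding ECGDV when both
#' networks carry edge colors.
#'
#' @param g,h [colored_network] objects.
#' @param mode `"het"` or `"hom"`.
#' @param reduction,variance_target passed to [build_similarity()].
#' @param max_size largest graphlet size.
#' @return similarity matrix as in [build_similarity()].
#' @export
network_similarity <- function(g, h, mode = c("het", "hom"),
                               reduction = c("pca", "none"),
                               variance_target = 0.9, max_size = 5L) {
  mode <- match.arg(mode)
  reduction <- match.arg(reduction)
  if (mode == "hom") {
    sg <- count_gdv(g, max_size = max_size)
    sh <- count_gdv(h, max_size = max_size)
  } else {
    colors <- sort(unique(c(g$node_color, h$node_color)))
    sg <- count_ncgdv(g, colors = colors, max_size = max_size)
    sh <- count_ncgdv(h, colors = colors, max_size = max_size)
    if (!is.null(g$edge_color) && !is.null(h$edge_color)) {
      ecolors <- sort(unique(c(g$edge_color, h$edge_color)))
      sg <- concat_signatures(sg, count_ecgdv(g, colors = ecolors,
                                              max_size = max_size))
      sh <- concat_signatures(sh, count_ecgdv(h, colors = ecolors,
                                              max_size = max_size))
    }
  }
  build_similarity(sg, sh, reduction = reduction,
                   variance_target = variance_target)
}
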