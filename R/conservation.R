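# Edge conservation under an alignment: classify each edge of G and each
# edge of H between aligned images as conserved or non-conserved, weight
# conserved edges by how many of their aligned endpoint pairs match in
# color (1, 2/3, 1/3 by default), and form the homogeneous and heterogeneous
# S3 scores. Also the alpha-blended NC+EC objective used by the search
# aligners, with an exact incremental update for swap/change moves.

check_alignment <- function(g, h, f) {
  if (inherits(f, "alignment")) f <- f$mapping
  if (is.null(names(f))) stop("alignment must be named by source nodes")
  if (anyDuplicated(f)) stop("alignment is not injective")
  if (!setequal(names(f), g$nodes))
    stop("alignment must be total on the nodes of G")
  if (!all(f %in% h$nodes)) stop("alignment image contains unknown H nodes")
  f[g$nodes]
}

#' Classify aligned edges and tally conservation weights
#'
#' An edge (u,v) of G is conserved when (f(u), f(v)) is an edge of H, and
#' non-conserved otherwise. An edge of H whose two endpoints are both images
#' of aligned nodes, but whose preimage pair is not a G edge, is also
#' non-conserved (H edges outside the image of `f` are ignored). Conserved
#' edges are binned by how many of the two endpoint pairs (u vs f(u),
#' v vs f(v)) match in node color: both (`weight_full`), exactly one
#' (`weight_partial`), none (`weight_least`).
#'
#' @param g,h [colored_network] objects; `f` maps G nodes into H nodes.
#' @param f an [alignment] or a named character vector (names: G nodes).
#' @param weights conservation weights for 2, 1 and 0 endpoint color
#'   matches; defaults `c(1, 2/3, 1/3)`.
#' @return An object of class `conservation_summary`: counts `n_conserved`,
#'   `n_nonconserved`, `weight_full`, `weight_partial`, `weight_least` and
#'   the weighted total `total_weight`.
#' @export
classify_edges <- function(g, h, f, weights = c(1, 2/3, 1/3)) {
  fv <- check_alignment(g, h, f)
  img <- match(fv, h$nodes)               # per G-node index, H index of image
  gcol <- g$node_color
  hcol <- h$node_color[img]               # color of each G node's image
  hkey <- paste(h$edges[, 1L], h$edges[, 2L])

  a <- g$edges[, 1L]; b <- g$edges[, 2L]
  ia <- img[a]; ib <- img[b]
  gkey_img <- paste(pmin(ia, ib), pmax(ia, ib))
  conserved <- gkey_img %in% hkey

  matches <- (gcol[a] == hcol[a]) + (gcol[b] == hcol[b])
  mt <- matches[conserved]
  n_full <- sum(mt == 2L)
  n_part <- sum(mt == 1L)
  n_least <- sum(mt == 0L)

  # H edges inside the image whose preimages are not adjacent in G
  in_img <- logical(length(h$nodes))
  in_img[img] <- TRUE
  hin <- h$edges[in_img[h$edges[, 1L]] & in_img[h$edges[, 2L]], ,
                 drop = FALSE]
  n_h_noncons <- nrow(hin) - sum(conserved)
  n_g_noncons <- sum(!conserved)

  structure(list(
    n_conserved = sum(conserved),
    n_nonconserved = n_g_noncons + n_h_noncons,
    weight_full = n_full,
    weight_partial = n_part,
    weight_least = n_least,
    weights = weights,
    total_weight = weights[1L] * n_full + weights[2L] * n_part +
      weights[3L] * n_least
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf(paste0("edge conservation: %d conserved ",
                     "(%d full / %d partial / %d least), %d non-conserved; ",
                     "total weight %.4f\n"),
              x$n_conserved, x$weight_full, x$weight_partial, x$weight_least,
              x$n_nonconserved, x$total_weight))
  invisible(x)
}

#' Homogeneous and heterogeneous S3 scores
#'
#' `hom_s3` is conserved / (conserved + non-conserved). `het_s3` replaces
#' the conserved count in the numerator (and its appearance in the
#' denominator) by the color-weighted total, so with all colors equal it
#' reduces exactly to `hom_s3`, and otherwise `het_s3 <= hom_s3`.
#'
#' @param summary a `conservation_summary` from [classify_edges()].
#' @return score in `[0,1]`.
#' @export
hom_s3 <- function(summary) {
  denom <- summary$n_conserved + summary$n_nonconserved
  if (denom == 0) stop("S3 undefined: no conserved or non-conserved edges")
  summary$n_conserved / denom
}

#' @rdname hom_s3
#' @export
het_s3 <- function(summary) {
  denom <- summary$total_weight + summary$n_nonconserved
  if (denom == 0) stop("S3 undefined: no conserved or non-conserved edges")
  summary$total_weight / denom
}

#' Objective configuration for the search aligners
#'
#' The blended objective is `alpha * NC + (1 - alpha) * EC`, where NC is the
#' mean similarity of aligned pairs and EC is the (homogeneous or
#' heterogeneous) S3 of the alignment; both terms lie in `[0,1]`.
#'
#' @param alpha weight of NC, in `[0,1]`; default 0.5.
#' @param ec_measure `"hets3"` or `"homs3"`.
#' @param weights heterogeneous conservation weights, default `c(1,2/3,1/3)`.
#' @export
objective_config <- function(alpha = 0.5, ec_measure = c("hets3", "homs3"),
                             weights = c(1, 2/3, 1/3)) {
  ec_measure <- match.arg(ec_measure)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0,1]")
  if (length(weights) != 3L) stop("weights must have length 3")
  structure(list(alpha = alpha, ec_measure = ec_measure, weights = weights),
            class = "objective_config")
}

# integer-index search state shared by the R-side objective machinery
# (delta_objective and the search aligners' tests). f is an integer vector
# over seq_along(g$nodes) with values in seq_along(h$nodes).
make_state <- function(g, h, f_idx, sim, config) {
  ng <- length(g$nodes)
  nh <- length(h$nodes)
  adj_h <- matrix(FALSE, nh, nh)
  adj_h[h$edges] <- TRUE
  adj_h[h$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  list(g = g, h = h, f = f_idx, sim = sim, config = config, adj_h = adj_h)
}

state_objective <- function(state) {
  g <- state$g; h <- state$h; f <- state$f; cfg <- state$config
  fm <- setNames(h$nodes[f], g$nodes)
  cs <- classify_edges(g, h, fm, weights = cfg$weights)
  num <- if (cfg$ec_measure == "hets3") cs$total_weight else cs$n_conserved
  denom <- num + cs$n_nonconserved
  ec <- if (denom > 0) num / denom else 0
  nc <- mean(state$sim[cbind(seq_along(f), f)])
  cfg$alpha * nc + (1 - cfg$alpha) * ec
}

#' Incremental objective change for a swap or change move
#'
#' Computes the exact change in `alpha * NC + (1 - alpha) * EC` caused by a
#' move, touching only edges incident to the moved nodes; applying the move
#' and recomputing from scratch gives the same value.
#'
#' @param state list from the internal search-state constructor: components
#'   `g`, `h`, `f` (integer mapping), `sim`, `config`, `adj_h`. Built by
#'   [align_state()].
#' @param move a list: `list(type = "swap", u =, v =)` with `u`, `v` aligned
#'   source indices, or `list(type = "change", u =, h_new =)` with `h_new`
#'   a currently unused H index.
#' @return numeric delta; `attr(,"state")` holds the state after the move.
#' @export
delta_objective <- function(state, move) {
  g <- state$g; h <- state$h; f <- state$f; cfg <- state$config
  ng <- length(f)
  gcolor <- g$node_color
  hcolor <- h$node_color
  w <- cfg$weights
  het <- cfg$ec_measure == "hets3"

  # current global tallies (cached on first use)
  if (is.null(state$tallies)) {
    fm <- setNames(h$nodes[f], g$nodes)
    cs <- classify_edges(g, h, fm, weights = w)
    in_img <- logical(length(h$nodes)); in_img[f] <- TRUE
    ehin <- sum(in_img[h$edges[, 1L]] & in_img[h$edges[, 2L]])
    state$tallies <- list(C = cs$n_conserved, W = cs$total_weight,
                          EHin = ehin,
                          S = sum(state$sim[cbind(seq_len(ng), f)]))
  }
  tl <- state$tallies
  eg <- nrow(g$edges)

  obj_of <- function(C, W, EHin, S) {
    num <- if (het) W else C
    denom <- num + (eg - C) + (EHin - C)
    ec <- if (denom > 0) num / denom else 0
    cfg$alpha * (S / ng) + (1 - cfg$alpha) * ec
  }

  edge_w <- function(u, hu, v, hv) {
    m <- (gcolor[u] == hcolor[hu]) + (gcolor[v] == hcolor[hv])
    w[3L - m]
  }
  nbrs <- function(u) {
    e <- g$edges
    c(e[e[, 1L] == u, 2L], e[e[, 2L] == u, 1L])
  }
  local_cw <- function(u, hu, v, hv, fvec) {
    # contribution of G edges incident to u (and v if v > 0), counted once
    C <- 0; W <- 0
    for (x in nbrs(u)) {
      hx <- if (!is.na(v) && x == v) hv else fvec[x]
      if (state$adj_h[hu, hx]) { C <- C + 1; W <- W + edge_w(u, hu, x, hx) }
    }
    if (!is.na(v)) {
      for (x in nbrs(v)) {
        if (x == u) next
        hx <- fvec[x]
        if (state$adj_h[hv, hx]) { C <- C + 1; W <- W + edge_w(v, hv, x, hx) }
      }
    }
    c(C, W)
  }

  if (move$type == "swap") {
    u <- move$u; v <- move$v
    if (u == v || u > ng || v > ng) stop("illegal swap move")
    hu <- f[u]; hv <- f[v]
    old <- local_cw(u, hu, v, hv, f)
    new <- local_cw(u, hv, v, hu, f)
    dS <- state$sim[u, hv] + state$sim[v, hu] -
      state$sim[u, hu] - state$sim[v, hv]
    newC <- tl$C + new[1L] - old[1L]
    newW <- tl$W + new[2L] - old[2L]
    newE <- tl$EHin
    newS <- tl$S + dS
    f2 <- f; f2[u] <- hv; f2[v] <- hu
  } else if (move$type == "change") {
    u <- move$u; hnew <- move$h_new
    if (hnew %in% f) stop("illegal change move: image already in use")
    hold <- f[u]
    old <- local_cw(u, hold, NA, NA, f)
    new <- local_cw(u, hnew, NA, NA, f)
    in_img <- logical(length(h$nodes)); in_img[f] <- TRUE
    hn <- function(x) {
      e <- h$edges
      c(e[e[, 1L] == x, 2L], e[e[, 2L] == x, 1L])
    }
    dE <- 0
    for (y in hn(hold)) if (y != hnew && in_img[y] && y != hold) dE <- dE - 1
    for (y in hn(hnew)) if (y != hold && in_img[y]) dE <- dE + 1
    dS <- state$sim[u, hnew] - state$sim[u, hold]
    newC <- tl$C + new[1L] - old[1L]
    newW <- tl$W + new[2L] - old[2L]
    newE <- tl$EHin + dE
    newS <- tl$S + dS
    f2 <- f; f2[u] <- hnew
  } else stop("unknown move type")

  delta <- obj_of(newC, newW, newE, newS) - obj_of(tl$C, tl$W, tl$EHin, tl$S)
  state2 <- state
  state2$f <- f2
  state2$tallies <- list(C = newC, W = newW, EHin = newE, S = newS)
  attr(delta, "state") <- state2
  delta
}

#' Build a search state for [delta_objective()]
#'
#' @param g,h [colored_network] objects.
#' @param f integer mapping (G index -> H index) or an [alignment].
#' @param sim similarity matrix (G x H).
#' @param config an [objective_config()].
#' @export
align_state <- function(g, h, f, sim, config = objective_config()) {
  if (inherits(f, "alignment")) {
    f <- match(check_alignment(g, h, f), h$nodes)
  }
  make_state(g, h, as.integer(f), sim, config)
}
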