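# Geometric and topological optimisation of grown trees, trimming of
# highly asymmetric bifurcations, and in-plane self-intersection rewiring.

tree_clone <- function(tr) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(tr)) assign(nm, get(nm, envir = tr), envir = out)
  out
}

# nodes whose position the optimiser may move
tree_movable <- function(tr, params) {
  n <- tr$n
  ch <- tree_children(tr)
  frozen_node <- tr$frozen[seq_len(n)] |
    vapply(seq_len(n), function(j) any(tr$frozen[ch[[j]]]), logical(1))
  is_term <- lengths(ch) == 0
  is_leaf <- tr$origin[seq_len(n)] %in% c("leaf", "macula-leaf")
  movable <- !frozen_node & seq_len(n) != 1L & (!is_term | is_leaf)
  movable[2] <- FALSE  # apex stays at the optic disc
  movable
}

tree_optimize_geometry <- function(tr, params, leaf_spacing = NULL,
                                   tol = 1e-4, max_sweeps = 10L,
                                   avoid = list(), within = NULL) {
  leaf_spacing <- leaf_spacing %||% params$leaf_spacing
  pin <- params$pinning_fraction * leaf_spacing
  ch <- tree_children(tr)
  movable <- tree_movable(tr, params)
  if (!is.null(within)) {
    # restrict the sweep to nodes inside a disc (e.g. macula-only passes)
    n <- tr$n
    d2 <- (tr$pos[seq_len(n), 1] - within$centre[1])^2 +
      (tr$pos[seq_len(n), 2] - within$centre[2])^2
    movable <- movable & d2 <= within$radius^2
  }
  cost0 <- tree_cost(tr)
  if (cost0 == 0) return(invisible(tr))
  for (sweep in seq_len(max_sweeps)) {
    before <- tree_cost(tr)
    for (j in which(movable)) {
      p <- tr$parent[j]
      kids <- ch[[j]]
      qs <- tr$pos[c(p, kids), , drop = FALSE]
      ws <- tr$rad[c(j, kids)]
      lens <- rownorms(sweep(qs, 2, tr$pos[j, ]))
      lens <- lens[lens > 0]
      if (length(lens) == 0) next
      h <- 0.3 * min(lens)
      anchor <- tr$anchor[j, ]
      local_cost <- function(pt) {
        sum(ws * sqrt(rowSums(sweep(qs, 2, pt)^2)))
      }
      clear_of <- function(q) {
        # incident segments must stay out of the keep-out discs
        for (av in avoid) {
          dd <- point_segment_distance(
            matrix(av$centre, 1, 2),
            q[1:2], q[1:2])$d  # the node itself
          if (dd < av$radius) return(FALSE)
          for (i2 in seq_len(nrow(qs))) {
            dd <- point_segment_distance(matrix(av$centre, 1, 2),
                                         q[1:2], qs[i2, 1:2])$d
            if (dd < av$radius) return(FALSE)
          }
        }
        TRUE
      }
      pt <- tr$pos[j, ]
      for (axis in 1:2) {
        big <- 1e18  # finite penalty: keeps optimize() quiet on barriers
        f <- function(u) {
          q <- pt; q[axis] <- u
          if (!anyNA(anchor) && vnorm(q - anchor) > pin) return(big)
          if (length(avoid) > 0 && !clear_of(q)) return(big)
          local_cost(q)
        }
        opt <- stats::optimize(f, lower = pt[axis] - h, upper = pt[axis] + h)
        if (opt$objective < min(local_cost(pt), 1e17))
          pt[axis] <- opt$minimum
      }
      tr$pos[j, ] <- pt
    }
    after <- tree_cost(tr)
    if ((before - after) / before < tol) break
  }
  invisible(tr)
}

#' Geometric optimisation of vessel node positions
#'
#' Moves bifurcation nodes (and leaf nodes, within the pinning distance of
#' their nominal position) by coordinate-wise golden-section search to
#' reduce the [network_cost()] objective. Frozen vessels are untouched, and
#' the cost never increases.
#'
#' @param net a grown [vascular_network]
#' @param params [sample_parameters()] output
#' @return the optimised [vascular_network]
#' @export
optimize_geometry <- function(net, params) {
  tt <- network_to_trees(net)
  tree_optimize_geometry(tt$artery, params)
  tree_optimize_geometry(tt$vein, params)
  trees_to_network(tt$artery, tt$vein, metadata = net$metadata)
}

tree_trim <- function(tr, threshold) {
  repeat {
    ch <- tree_children(tr)
    victim <- NULL
    for (j in seq_len(tr$n)) {
      kids <- ch[[j]]
      if (length(kids) < 2) next
      r <- tr$rad[kids]
      if (min(r) / max(r) < threshold) {
        victim <- kids[which.min(r)]
        break
      }
    }
    if (is.null(victim)) break
    tree_drop_nodes(tr, tree_subtree(tr, victim))
  }
  invisible(tr)
}

#' Trim highly asymmetric bifurcations and regrow their territory
#'
#' Bifurcations whose daughter radius ratio falls below `threshold` have
#' the smaller side removed; the vacated territory re-enters the lattice
#' growth queue at the finest stride before a final trim pass.
#'
#' @param net a grown [vascular_network]
#' @param params [sample_parameters()] output
#' @param domain a [retina_domain]
#' @param threshold daughter radius ratio below which a bifurcation is
#'   trimmed (default from the model constants).
#' @param regrow re-invade the vacated territory after trimming?
#' @return a [vascular_network]
#' @export
trim_and_regrow <- function(net, params, domain,
                            threshold = params$constants$trim_alpha_threshold,
                            regrow = TRUE) {
  tt <- network_to_trees(net)
  for (tr in tt) {
    tree_trim(tr, threshold)
    if (regrow)
      tree_lattice_growth(tr, params, domain,
                          strides_um = params$lattice_stride_min)
    tree_trim(tr, threshold)
  }
  trees_to_network(tt$artery, tt$vein, metadata = net$metadata)
}

# one pass of the two local topology moves; returns number of accepted moves
tree_topology_pass <- function(tr, params) {
  gamma <- params$murray_exponent
  k <- params$constants
  accepted <- 0L
  # move 1: highly asymmetric bifurcations push their small side downstream
  ch <- tree_children(tr)
  for (j in seq_len(tr$n)) {
    kids <- ch[[j]]
    if (length(kids) != 2) next
    r <- tr$rad[kids]
    if (min(r) / max(r) >= 0.5) next
    small <- kids[which.min(r)]; large <- kids[which.max(r)]
    if (length(ch[[large]]) == 0) next
    trial <- tree_clone(tr)
    trial$parent[small] <- large
    tree_recompute_radii(trial, gamma)
    if (tree_cost(trial) < tree_cost(tr) * (1 - 1e-12)) {
      tr$parent[small] <- large
      tree_recompute_radii(tr, gamma)
      ch <- tree_children(tr)
      accepted <- accepted + 1L
    }
  }
  # move 2: short internal branches collapse into higher-order splits.
  # dropping a node renumbers the tree, so the scan restarts after every
  # accepted collapse
  repeat {
    lens <- tree_seg_lengths(tr)
    ch <- tree_children(tr)
    collapsed <- FALSE
    for (j in seq_len(tr$n)) {
      p <- tr$parent[j]
      if (is.na(p) || is.na(tr$parent[p])) next
      if (length(ch[[j]]) < 2) next
      expected <- lens[p] * 2^(-1 / 3)  # West-Brown-Enquist scaling
      if (lens[j] >= k$wbe_short_fraction * expected) next
      trial <- tree_clone(tr)
      trial$parent[ch[[j]]] <- p
      trial$pos[j, ] <- trial$pos[p, ]  # zero-length relic, dropped below
      tree_recompute_radii(trial, gamma)
      if (tree_cost(trial) < tree_cost(tr) * (1 - 1e-12)) {
        for (c0 in ch[[j]]) tr$parent[c0] <- p
        tree_drop_nodes(tr, j)
        tree_recompute_radii(tr, gamma)
        accepted <- accepted + 1L
        collapsed <- TRUE
        break
      }
    }
    if (!collapsed) break
  }
  accepted
}

#' Topological optimisation of a grown tree
#'
#' Applies two cost-decreasing rewirings: highly asymmetric bifurcations may
#' move their low-flow side one generation downstream, and branches short
#' compared to their expected length under West-Brown-Enquist scaling
#' (child length = parent length x 2^(-1/3)) are merged into a single
#' higher-order split. Rewirings are accepted only when the
#' [network_cost()] objective decreases; the tree property is preserved.
#'
#' @inheritParams optimize_geometry
#' @param max_passes maximum number of sweeps over the tree.
#' @return a [vascular_network]
#' @export
topological_optimize <- function(net, params, max_passes = 5L) {
  tt <- network_to_trees(net)
  for (tr in tt) {
    for (i in seq_len(max_passes)) {
      if (tree_topology_pass(tr, params) == 0L) break
    }
  }
  trees_to_network(tt$artery, tt$vein, metadata = net$metadata)
}

# ---- in-plane self-intersections ------------------------------------------

# indices of crossing same-tree segment pairs (child-node indices); a
# crossing is an in-plane approach closer than the sum of radii between
# non-adjacent segments
tree_crossings <- function(tr) {
  n <- tr$n
  segs <- which(!is.na(tr$parent[seq_len(n)]))
  m <- length(segs)
  if (m < 2) return(matrix(integer(0), 0, 2))
  a <- tr$pos[tr$parent[segs], 1:2, drop = FALSE]
  b <- tr$pos[segs, 1:2, drop = FALSE]
  lo <- pmin(a, b); hi <- pmax(a, b)
  rad_mm <- tr$rad[segs] * MM_PER_UM
  out <- list()
  for (i in seq_len(m - 1)) {
    # bounding-box prefilter
    j <- which(lo[, 1] <= hi[i, 1] + 2 * rad_mm[i] &
               hi[, 1] >= lo[i, 1] - 2 * rad_mm[i] &
               lo[, 2] <= hi[i, 2] + 2 * rad_mm[i] &
               hi[, 2] >= lo[i, 2] - 2 * rad_mm[i])
    j <- j[j > i]
    for (jj in j) {
      si <- segs[i]; sj <- segs[jj]
      shared <- length(intersect(c(si, tr$parent[si]),
                                 c(sj, tr$parent[sj]))) > 0
      if (shared) next
      d <- segseg_distance_2d(a[i, ], b[i, ], a[jj, ], b[jj, ])
      if (d < rad_mm[i] + rad_mm[jj])
        out[[length(out) + 1]] <- c(si, sj)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

tree_resolve_crossings <- function(tr, params, max_rounds = 6L) {
  gamma <- params$murray_exponent
  removed <- 0L
  for (round in seq_len(max_rounds)) {
    cr <- tree_crossings(tr)
    if (nrow(cr) == 0) break
    # rewire every currently crossing pair (each offender once per round)
    touched <- logical(tr$n)
    any_rewired <- FALSE
    for (i in seq_len(nrow(cr))) {
      pair <- cr[i, ]
      if (any(touched[pair])) next
      small <- pair[which.min(tr$rad[pair])]
      other <- setdiff(pair, small)
      sub <- tree_subtree(tr, small)
      cand <- setdiff(c(other, tr$parent[other]), sub)
      if (length(cand) == 0) next
      d <- rownorms(tr$pos[cand, , drop = FALSE] -
                    matrix(tr$pos[small, ], length(cand), 3, byrow = TRUE))
      tr$parent[small] <- cand[which.min(d)]
      touched[pair] <- TRUE
      any_rewired <- TRUE
    }
    if (any_rewired) tree_recompute_radii(tr, gamma)
    else break
  }
  # guarantee the contract: drop any offender still present
  repeat {
    cr <- tree_crossings(tr)
    if (nrow(cr) == 0) break
    pair <- cr[1, ]
    small <- pair[which.min(tr$rad[pair])]
    tree_drop_nodes(tr, tree_subtree(tr, small))
    tree_recompute_radii(tr, gamma)
    removed <- removed + 1L
  }
  if (removed > 0)
    message("resolve_self_intersections: removed ", removed,
            " unresolvable segment(s)")
  invisible(tr)
}

#' Resolve in-plane self-intersections by rewiring
#'
#' Two segments of the same tree cross when their planar separation is
#' below the sum of their radii (segments sharing a node excluded).
#' Crossings are resolved by rewiring the smaller vessel's attachment to an
#' endpoint of the vessel it crossed, so later growth does not recreate the
#' same intersection; after bounded attempts an unresolvable offender is
#' removed and reported.
#'
#' @inheritParams optimize_geometry
#' @return a crossing-free [vascular_network]
#' @export
resolve_self_intersections <- function(net, params) {
  tt <- network_to_trees(net)
  tree_resolve_crossings(tt$artery, params)
  tree_resolve_crossings(tt$vein, params)
  trees_to_network(tt$artery, tt$vein, metadata = net$metadata)
}
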