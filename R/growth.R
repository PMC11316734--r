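#' Network cost under the Murray-law objective
#'
#' The growth objective is `C = sum_b r_b^rho * l_b^lambda` over segments,
#' with radii and lengths in micrometres (`r_b` is the length-weighted mean
#' radius of a segment's path). With `rho = 2, lambda = 1` the cost equals
#' total vessel volume divided by pi.
#'
#' @param net a [vascular_network]
#' @param rho,lam cost exponents (defaults 1 and 1).
#' @return scalar cost
#' @export
network_cost <- function(net, rho = 1, lam = 1) {
  stopifnot(inherits(net, "vascular_network"))
  if (n_segments(net) == 0) return(0)
  r <- segment_mean_radius_um(net)
  l <- segment_lengths_mm(net) * UM_PER_MM
  sum(r^rho * l^lam)
}

#' Distribute leaf nodes over the retina
#'
#' Jittered-grid point process covering the retina disc minus the macula
#' region with near-uniform density: grid pitch = `spacing`, jitter bounded
#' so the minimum pairwise distance stays at or above half the spacing.
#'
#' @param domain a [retina_domain]
#' @param spacing nominal leaf spacing, mm.
#' @param seed integer seed.
#' @return n x 2 matrix of planar positions (mm)
#' @export
distribute_leaf_nodes <- function(domain, spacing, seed = 0L) {
  stopifnot(spacing > 0)
  if (spacing > 2 * domain$retina_radius)
    stop("leaf spacing exceeds the domain diameter")
  set.seed(stage_seed(seed, "leaf-nodes"))
  R <- domain$retina_radius
  g <- seq(-floor(R / spacing) * spacing, R, by = spacing)
  pts <- as.matrix(expand.grid(x = g + domain$disc_centre[1],
                               y = g + domain$disc_centre[2]))
  jit <- matrix(stats::runif(length(pts), -0.22 * spacing, 0.22 * spacing),
                ncol = 2)
  pts <- pts + jit
  keep <- in_disc(pts, domain$disc_centre, R - 0.02 * R) &
    !in_disc(pts, domain$macula_centre, domain$macula_radius)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) pts <- matrix(domain$disc_centre, 1, 2)
  unname(pts)
}

# ---- internal growth machinery on trees -----------------------------------

# sample points along segment child->parent, step mm; returns matrix
seg_samples <- function(a, b, step) {
  L <- vnorm(b - a)
  k <- max(2L, ceiling(L / step) + 1L)
  tt <- seq(0, 1, length.out = k)
  outer(tt, b - a) + matrix(a, k, length(a), byrow = TRUE)
}

# exact cost increment (um^2) of attaching a terminal of radius r_t at
# fraction t along the segment feeding `child`, reaching a point l_new (mm)
# away; relies on the Murray relation holding before the attachment.
tree_attach_delta_cost <- function(tr, child, t, l_new_mm, r_t, gamma) {
  pos <- tr$pos; rad <- tr$rad; par <- tr$parent
  r_c <- rad[child]
  p <- par[child]
  dx <- pos[child, 1] - pos[p, 1]; dy <- pos[child, 2] - pos[p, 2]
  dz <- pos[child, 3] - pos[p, 3]
  l_c <- sqrt(dx * dx + dy * dy + dz * dz) * UM_PER_MM
  # upstream half (fraction t) widens to the Murray composition; the
  # downstream half keeps r_c and contributes nothing
  r_up_new <- (r_c^gamma + r_t^gamma)^(1 / gamma)
  dc <- r_t * l_new_mm * UM_PER_MM + (r_up_new - r_c) * t * l_c
  # ancestors: old child radius r_c contributes r_c^gamma to parent; replace
  r_old <- r_c; r_new <- r_up_new
  j <- p
  pj <- par[j]
  while (!is.na(pj)) {
    dx <- pos[j, 1] - pos[pj, 1]; dy <- pos[j, 2] - pos[pj, 2]
    dz <- pos[j, 3] - pos[pj, 3]
    l_j <- sqrt(dx * dx + dy * dy + dz * dz) * UM_PER_MM
    r_j_old <- rad[j]
    r_j_new <- (r_j_old^gamma + r_new^gamma - r_old^gamma)^(1 / gamma)
    dc <- dc + (r_j_new - r_j_old) * l_j
    r_old <- r_j_old; r_new <- r_j_new
    j <- pj
    pj <- par[j]
  }
  dc
}

# commit an attachment; returns index of the new terminal node
tree_attach_terminal <- function(tr, child, t, pos, r_t, gamma,
                                 origin = "growth") {
  t <- min(0.95, max(0.05, t))
  r_old_child <- tr$rad[child]
  split <- tree_split_edge(tr, child, t)
  tip <- tree_add_child(tr, split, pos, r_t, origin = origin)
  # chain update: split node feeds {child (r unchanged), tip (r_t)}
  r_old <- tr$rad[split]
  r_new <- (r_old_child^gamma + r_t^gamma)^(1 / gamma)
  tr$rad[split] <- r_new
  j <- tr$parent[split]
  while (!is.na(j) && !is.na(tr$parent[j])) {
    r_j_new <- (tr$rad[j]^gamma + r_new^gamma - r_old^gamma)^(1 / gamma)
    r_old <- tr$rad[j]; r_new <- r_j_new
    tr$rad[j] <- r_j_new
    j <- tr$parent[j]
  }
  tip
}

# candidate attachment for one planar target point: nearest admissible
# segment among those proposed by sample points near the target. `avoid` is
# a list of keep-out discs (each list(centre, radius)); `extra_ok` an
# optional predicate f(attach_pt, target, child) applied to candidates.
tree_candidate <- function(tr, target, st, params, domain,
                           max_dist = Inf, k = 8L,
                           avoid = list(list(centre = domain$macula_centre,
                                             radius = domain$macula_radius)),
                           extra_ok = NULL) {
  r_t <- params$constants$terminal_radius
  gamma <- params$murray_exponent
  cand_children <- sample_store_near(st, target,
                                     if (is.finite(max_dist)) max_dist else NA,
                                     k = k)
  best <- NULL
  alpha_min <- params$constants$trim_alpha_threshold
  for (cs in cand_children) {
    p <- tr$parent[cs]
    if (is.na(p)) next
    ax <- tr$pos[p, 1]; ay <- tr$pos[p, 2]
    bx <- tr$pos[cs, 1]; by <- tr$pos[cs, 2]
    ps <- psd1(target[1], target[2], ax, ay, bx, by)
    d <- ps[1]; tt <- ps[2]
    if (d > max_dist || d < 1e-9) next
    attach_pt <- c(ax + tt * (bx - ax), ay + tt * (by - ay))
    blocked <- FALSE
    for (av in avoid) {
      md <- psd1(av$centre[1], av$centre[2], attach_pt[1], attach_pt[2],
                 target[1], target[2])[1]
      if (md < av$radius) { blocked <- TRUE; break }
    }
    if (blocked) next
    if (!is.null(extra_ok) && !extra_ok(attach_pt, target, cs)) next
    dc <- tree_attach_delta_cost(tr, cs, tt, d, r_t, gamma)
    alpha_ok <- r_t / tr$rad[cs] >= alpha_min
    score <- dc + if (alpha_ok) 0 else 1e9  # prefer admissible asymmetry
    if (is.null(best) || score < best$score)
      best <- list(child = cs, t = tt, dist = d, dcost = dc, score = score)
  }
  best
}

# incremental growth bookkeeping: sample points along segments, bucketed on
# a uniform grid for O(1) neighbourhood queries without per-query index
# rebuilds
sample_store <- function(tr, step) {
  st <- new.env(parent = emptyenv())
  st$step <- step
  st$cell <- 2 * step
  st$n <- 0L
  cap <- 1024L
  st$pts <- matrix(NA_real_, cap, 2)
  st$child <- rep(NA_integer_, cap)
  st$grid <- new.env(parent = emptyenv())
  for (i in seq_len(tr$n)[-1]) sample_store_add(st, tr, i)
  st
}

sample_store_insert <- function(st, pts, child) {
  k <- nrow(pts)
  while (st$n + k > nrow(st$pts)) {
    newcap <- 2L * nrow(st$pts)
    m <- matrix(NA_real_, newcap, 2); m[1:st$n, ] <- st$pts[1:st$n, ]
    st$pts <- m
    st$child <- c(st$child, rep(NA_integer_, newcap - length(st$child)))
  }
  idx <- st$n + seq_len(k)
  st$pts[idx, ] <- pts
  st$child[idx] <- child
  st$n <- st$n + k
  cx <- floor(pts[, 1] / st$cell); cy <- floor(pts[, 2] / st$cell)
  keys <- paste(cx, cy)
  for (u in unique(keys)) {
    st$grid[[u]] <- c(st$grid[[u]], idx[keys == u])
  }
  invisible(st)
}

sample_store_add <- function(st, tr, child) {
  p <- tr$parent[child]
  s <- seg_samples(tr$pos[p, 1:2], tr$pos[child, 1:2], st$step)
  sample_store_insert(st, s, child)
}

# candidate segments (child-node indices) near a planar target: gathers the
# grid cells within `radius` (default: one cell ring), returns the children
# of the k nearest sample points
sample_store_near <- function(st, target, radius = NA, k = 8L) {
  r <- if (is.na(radius)) st$cell else radius
  rings <- max(1L, ceiling(r / st$cell))
  cx <- floor(target[1] / st$cell); cy <- floor(target[2] / st$cell)
  idx <- integer(0)
  repeat {
    off <- -rings:rings
    keys <- paste(rep(cx + off, times = length(off)),
                  rep(cy + off, each = length(off)))
    idx <- unlist(lapply(keys, function(u) st$grid[[u]]), use.names = FALSE)
    if (length(idx) > 0 || is.finite(radius) || rings > 64L) break
    rings <- rings * 2L  # unbounded search: widen until something is found
  }
  if (length(idx) == 0) return(integer(0))
  d2 <- (st$pts[idx, 1] - target[1])^2 + (st$pts[idx, 2] - target[2])^2
  ord <- order(d2)
  unique(st$child[idx[ord[seq_len(min(3L * k, length(ord)))]]])[
    seq_len(min(k, length(unique(st$child[idx]))))]
}

# connect pre-distributed leaf points to a tree by minimum cost increment
tree_connect_leaves <- function(tr, leaves, params, domain) {
  if (nrow(leaves) == 0) return(invisible(tr))
  ord <- order(rownorms(sweep(leaves, 2, domain$disc_centre)))
  st <- sample_store(tr, step = params$leaf_spacing / 4)
  for (i in ord) {
    cand <- tree_candidate(tr, leaves[i, ], st, params, domain,
                           k = 12L)
    if (is.null(cand)) next
    tip <- tree_attach_terminal(tr, cand$child, cand$t, c(leaves[i, ], 0),
                                params$constants$terminal_radius,
                                params$murray_exponent, origin = "leaf")
    tr$anchor[tip, ] <- c(leaves[i, ], 0)
    sample_store_add(st, tr, tip)
    sample_store_add(st, tr, tr$parent[tip])
  }
  invisible(tr)
}

# multiscale lattice invasion for one tree
tree_lattice_growth <- function(tr, params, domain, strides_um = NULL) {
  if (is.null(strides_um))
    strides_um <- seq(params$lattice_stride_max, params$lattice_stride_min,
                      length.out = params$lattice_iterations)
  R <- domain$retina_radius
  ctr <- domain$disc_centre
  for (s_um in strides_um) {
    s <- s_um * MM_PER_UM
    g <- seq(-ceiling(R / s) * s, R, by = s)
    nx <- length(g)
    sx <- rep(g + ctr[1], times = nx)
    sy <- rep(g + ctr[2], each = nx)
    inside <- (sx - ctr[1])^2 + (sy - ctr[2])^2 <= R^2 &
      !in_disc(cbind(sx, sy), domain$macula_centre, domain$macula_radius)
    ns <- nx * nx
    occ <- rep(FALSE, ns)
    st <- sample_store(tr, step = s / 2)
    site_of <- function(pts) {
      ix <- floor((pts[, 1] - (ctr[1] + g[1] - s / 2)) / s) + 1L
      iy <- floor((pts[, 2] - (ctr[2] + g[1] - s / 2)) / s) + 1L
      ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= nx
      (iy[ok] - 1L) * nx + ix[ok]
    }
    occ[site_of(st$pts)] <- TRUE
    neighbours <- function(idx) {
      ix <- (idx - 1L) %% nx + 1L
      iy <- (idx - 1L) %/% nx + 1L
      dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      jx <- rep(ix, each = 8) + dx
      jy <- rep(iy, each = 8) + dy
      ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= nx
      unique((jy[ok] - 1L) * nx + jx[ok])
    }
    frontier <- rep(FALSE, ns)
    occ_idx <- which(occ)
    if (length(occ_idx) > 0) {
      nb <- neighbours(occ_idx)
      frontier[nb[!occ[nb] & inside[nb]]] <- TRUE
    }
    cost_cache <- rep(NA_real_, ns)
    cand_cache <- vector("list", ns)
    repeat {
      todo <- which(frontier & is.na(cost_cache))
      for (idx in todo) {
        cand <- tree_candidate(tr, c(sx[idx], sy[idx]), st,
                               params, domain, max_dist = 2 * s)
        if (is.null(cand)) {
          cost_cache[idx] <- Inf
        } else {
          cost_cache[idx] <- cand$score
          cand_cache[[idx]] <- cand
        }
      }
      live <- which(frontier & is.finite(cost_cache))
      if (length(live) == 0) break
      best <- live[which.min(cost_cache[live])]
      cand <- cand_cache[[best]]
      target <- c(sx[best], sy[best])
      tip <- tree_attach_terminal(tr, cand$child, cand$t, c(target, 0),
                                  params$constants$terminal_radius,
                                  params$murray_exponent)
      sample_store_add(st, tr, tip)
      sample_store_add(st, tr, tr$parent[tip])
      new_pts <- seg_samples(tr$pos[tr$parent[tip], 1:2], target, s / 2)
      newly <- unique(site_of(new_pts))
      newly <- newly[!occ[newly]]
      occ[newly] <- TRUE
      frontier[newly] <- FALSE
      cost_cache[newly] <- NA_real_
      if (length(newly) > 0) {
        nb <- neighbours(newly)
        frontier[nb[!occ[nb] & inside[nb]]] <- TRUE
      }
      # invalidate cached candidates near the new segment
      near <- which(frontier &
                    (sx - target[1])^2 + (sy - target[2])^2 <= (2.5 * s)^2)
      cost_cache[near] <- NA_real_
    }
  }
  invisible(tr)
}

# remove the original distributed leaf tips (terminal nodes of origin
# "leaf"), keeping the branching structure they induced
tree_remove_leaf_tips <- function(tr) {
  tips <- intersect(tree_terminals(tr),
                    which(tr$origin[seq_len(tr$n)] == "leaf"))
  tree_drop_nodes(tr, tips)
  invisible(tr)
}

#' Space-filling lattice growth
#'
#' Extends a seeded network to a space-filling tree: distributed leaf nodes
#' are connected by minimum cost increment, then multiscale square lattices
#' (strides from `lattice_stride_max` to `lattice_stride_min`, linearly
#' spaced over `lattice_iterations` levels, 8-neighbour adjacency) are
#' invaded site by site, always committing the candidate attachment with the
#' smallest expected increase of the [network_cost()] objective under
#' Murray-consistent radius updates propagated to the root. The macula
#' region is kept vessel-free throughout; original leaf tips are removed
#' after the initial growth stage, and radii are finally rescaled so the
#' root calibres match the sampled parameters.
#'
#' @param net a seeded [vascular_network]
#' @param params [sample_parameters()] output
#' @param domain a [retina_domain]
#' @param seed integer seed for this stage
#' @return a grown [vascular_network]
#' @export
lattice_growth <- function(net, params, domain, seed = 0L) {
  tt <- network_to_trees(net)
  tt <- grow_trees(tt, params, domain, seed)
  trees_to_network(tt$artery, tt$vein,
                   metadata = c(net$metadata[setdiff(names(net$metadata), "stage")],
                                list(stage = "grown")))
}

# full growth stage on trees (used by the pipeline to avoid conversions)
grow_trees <- function(tt, params, domain, seed = 0L) {
  set.seed(stage_seed(seed, "growth"))
  leaves_a <- distribute_leaf_nodes(domain, params$leaf_spacing,
                                    seed = stage_seed(seed, "leaves-artery"))
  leaves_v <- distribute_leaf_nodes(domain, params$leaf_spacing,
                                    seed = stage_seed(seed, "leaves-vein"))
  tree_connect_leaves(tt$artery, leaves_a, params, domain)
  tree_connect_leaves(tt$vein, leaves_v, params, domain)
  strides <- seq(params$lattice_stride_max, params$lattice_stride_min,
                 length.out = params$lattice_iterations)
  # initial growth stage: first (coarsest) stride, then leaf tips removed
  tree_lattice_growth(tt$artery, params, domain, strides_um = strides[1])
  tree_lattice_growth(tt$vein, params, domain, strides_um = strides[1])
  tree_remove_leaf_tips(tt$artery)
  tree_remove_leaf_tips(tt$vein)
  if (length(strides) > 1) {
    tree_lattice_growth(tt$artery, params, domain, strides_um = strides[-1])
    tree_lattice_growth(tt$vein, params, domain, strides_um = strides[-1])
  }
  tree_rescale_root(tt$artery, root_radius(params, "artery"))
  tree_rescale_root(tt$vein, root_radius(params, "vein"))
  tt
}

# ---- conversion: network -> trees -----------------------------------------

# rebuild tree structures from a (tree-stage) network; segments must form
# trees rooted at the inlet (arteries) and outlet (veins)
network_to_trees <- function(net) {
  cls <- segment_classes(net)
  if (any(cls == "capillary"))
    stop("network_to_trees requires a pre-capillary network")
  build <- function(class, root_id) {
    segs <- net$segments[cls == class]
    ids <- net$nodes$id
    adj <- new.env(parent = emptyenv())
    for (s in segs) {
      for (ends in list(c(s$from, s$to), c(s$to, s$from))) {
        key <- as.character(ends[1])
        adj[[key]] <- c(adj[[key]], list(list(other = ends[2], seg = s)))
      }
    }
    tr <- tree_new(node_position(net, root_id), class = class,
                   capacity = max(256L, 2L * length(segs)))
    map <- new.env(parent = emptyenv())
    map[[as.character(root_id)]] <- 1L
    queue <- root_id
    visited <- as.character(root_id)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (e in adj[[as.character(u)]] %||% list()) {
        vkey <- as.character(e$other)
        if (vkey %in% visited) next
        visited <- c(visited, vkey)
        i <- tree_add_child(tr, map[[as.character(u)]],
                            node_position(net, e$other),
                            mean(e$seg$radius), origin = "import")
        map[[vkey]] <- i
        queue <- c(queue, e$other)
      }
    }
    tr
  }
  list(artery = build("artery", net$inlet_id),
       vein = build("vein", net$outlet_id))
}
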