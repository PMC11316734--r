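# Dedicated macula growth: radial vessel pattern in the annulus between the
# (avascular) fovea and the macula outer radius, at an elevated leaf density
# controlled by the macula flow-density factor.

# per-tree peripheral terminal density (terminals / mm^2) outside the macula
tree_peripheral_density <- function(tr, domain) {
  term <- tree_terminals(tr)
  xy <- tr$pos[term, 1:2, drop = FALSE]
  outside <- !in_disc(xy, domain$macula_centre, domain$macula_radius)
  area <- pi * domain$retina_radius^2 - pi * domain$macula_radius^2 -
    pi * domain$disc_radius^2
  sum(outside) / area
}

# nominal macula leaf positions on rings (radial pattern), jittered in a
# disc so vessels do not align with the rings
macula_leaf_points <- function(domain, density) {
  r_in <- domain$fovea_radius
  r_out <- domain$macula_radius
  spacing <- 1 / sqrt(max(density, 1e-9))
  lo <- r_in + spacing / 2; hi <- r_out - spacing / 2
  radii <- if (hi >= lo) seq(hi, lo, by = -spacing) else (r_in + r_out) / 2
  pts <- list()
  for (rr in radii) {
    nk <- max(4L, round(2 * pi * rr / spacing))
    th <- 2 * pi * seq_len(nk) / nk + stats::runif(1, 0, 2 * pi)
    jit_r <- 0.5 * spacing * sqrt(stats::runif(nk))
    jit_t <- stats::runif(nk, 0, 2 * pi)
    x <- domain$macula_centre[1] + rr * cos(th) + jit_r * cos(jit_t)
    y <- domain$macula_centre[2] + rr * sin(th) + jit_r * sin(jit_t)
    pts[[length(pts) + 1]] <- cbind(x, y)
  }
  pts <- do.call(rbind, pts)
  d2 <- (pts[, 1] - domain$macula_centre[1])^2 +
    (pts[, 2] - domain$macula_centre[2])^2
  pts[d2 > r_in^2 & d2 < r_out^2, , drop = FALSE]
}

tree_grow_macula <- function(tr, params, domain) {
  k <- params$constants
  base <- tree_peripheral_density(tr, domain)
  # post-thinning leaf density = flow-density factor x peripheral density
  density <- params$macula_flow_density / (1 - params$macula_sparsity) * base
  pts <- macula_leaf_points(domain, density)
  keep <- stats::runif(nrow(pts)) >= params$macula_sparsity
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(invisible(tr))
  # outer leaves first, so growth proceeds radially inward
  dmac <- rownorms(sweep(pts, 2, domain$macula_centre))
  ord <- order(dmac, decreasing = TRUE)
  st <- sample_store(tr, step = 0.5 / sqrt(density))
  ang_lim <- params$macula_angle_limit * pi / 180
  avoid_fovea <- list(list(centre = domain$macula_centre,
                           radius = domain$fovea_radius))
  angle_ok <- function(attach_pt, target, cs) {
    p <- tr$parent[cs]
    vpar <- tr$pos[cs, 1:2] - tr$pos[p, 1:2]
    vnew <- target - attach_pt
    if (vnorm(vpar) == 0 || vnorm(vnew) == 0) return(TRUE)
    ang <- acos(min(1, max(-1, sum(unitv(vpar) * unitv(vnew)))))
    ang <= ang_lim
  }
  for (i in ord) {
    cand <- tree_candidate(tr, pts[i, ], st, params, domain,
                           k = 10L, avoid = avoid_fovea, extra_ok = angle_ok)
    if (is.null(cand)) next
    tip <- tree_attach_terminal(tr, cand$child, cand$t, c(pts[i, ], 0),
                                k$terminal_radius, params$murray_exponent,
                                origin = "macula-leaf")
    tr$anchor[tip, ] <- c(pts[i, ], 0)
    sample_store_add(st, tr, tip)
    sample_store_add(st, tr, tr$parent[tip])
  }
  invisible(tr)
}

#' Grow the radial macula vasculature
#'
#' Fills the annulus between the fovea (kept avascular) and the macula
#' outer radius by lattice-style leaf invasion at an elevated density: the
#' post-thinning leaf density is the macula flow-density factor times the
#' peripheral terminal density. Nominal leaf positions sit on rings and are
#' offset uniformly within a disc so vessels do not align with the rings;
#' each leaf is removed i.i.d. with the sparsity probability before
#' connection; a hard limit on the angle between a new segment and its
#' parent prevents vessels doubling back; growth proceeds radially inward,
#' and the surviving vessels are geometrically optimised.
#'
#' @param net a grown [vascular_network] whose macula annulus is empty
#' @param params [sample_parameters()] output
#' @param domain a [retina_domain]
#' @param seed integer seed for this stage
#' @return a [vascular_network] with macula vessels
#' @export
grow_macula <- function(net, params, domain, seed = 0L) {
  tt <- network_to_trees(net)
  grow_macula_trees(tt, params, domain, seed)
  trees_to_network(tt$artery, tt$vein, metadata = net$metadata)
}

grow_macula_trees <- function(tt, params, domain, seed = 0L) {
  set.seed(stage_seed(seed, "macula"))
  tree_grow_macula(tt$artery, params, domain)
  tree_grow_macula(tt$vein, params, domain)
  fovea <- list(list(centre = domain$macula_centre,
                     radius = domain$fovea_radius))
  mac <- list(centre = domain$macula_centre, radius = domain$macula_radius)
  tree_optimize_geometry(tt$artery, params, max_sweeps = 2L, avoid = fovea,
                         within = mac)
  tree_optimize_geometry(tt$vein, params, max_sweeps = 2L, avoid = fovea,
                         within = mac)
  invisible(tt)
}
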