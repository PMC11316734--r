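# Wiring capillary beds into networks, arterio-venous crossing resolution
# by out-of-plane excursions, and terminal-bed interleaving.

# terminal node ids of a given vessel class
terminal_node_ids <- function(net, class) {
  cls <- segment_classes(net)
  inc <- table(unlist(lapply(net$segments[cls == class],
                             function(s) c(s$from, s$to))))
  ids <- as.integer(names(inc))
  term <- ids[net$nodes$kind[match(ids, net$nodes$id)] == "terminal"]
  # keep only nodes whose every incident segment is of this class
  term
}

net_add_segments <- function(net, segs) {
  # segs: list(a=, b=, radius=, class=) with endpoints node ids (integer)
  # or planar/3D positions; positions are deduplicated into new nodes
  nodes <- net$nodes
  pos_ids <- new.env(parent = emptyenv())
  resolve <- function(e) {
    if (length(e) == 1 && is.numeric(e)) return(as.integer(e))
    p <- if (length(e) == 2) c(e, 0) else e
    kk <- paste(signif(p, 10), collapse = "_")
    hit <- pos_ids[[kk]]
    if (!is.null(hit)) return(hit)
    id <- max(nodes$id) + 1L
    nodes <<- rbind(nodes, data.frame(id = id, x = p[1], y = p[2], z = p[3],
                                      kind = "bifurcation",
                                      stringsAsFactors = FALSE))
    pos_ids[[kk]] <- id
    id
  }
  seglist <- net$segments
  seen <- new.env(parent = emptyenv())
  for (s in seglist) seen[[paste(min(s$from, s$to), max(s$from, s$to))]] <- TRUE
  next_id <- if (length(seglist) > 0) max(segment_ids(net)) + 1L else 1L
  for (s in segs) {
    fa <- resolve(s$a); fb <- resolve(s$b)
    if (fa == fb) next
    pk <- paste(min(fa, fb), max(fa, fb))
    if (isTRUE(seen[[pk]])) next
    seen[[pk]] <- TRUE
    pa <- as.numeric(nodes[match(fa, nodes$id), c("x", "y", "z")])
    pb <- as.numeric(nodes[match(fb, nodes$id), c("x", "y", "z")])
    seglist[[length(seglist) + 1]] <- list(
      id = next_id, from = fa, to = fb, path = rbind(pa, pb),
      radius = rep(s$radius, 2), class = s$class %||% "capillary")
    next_id <- next_id + 1L
  }
  vascular_network(nodes, seglist, net$inlet_id, net$outlet_id, net$metadata)
}

#' Close the circulation with a capillary bed
#'
#' Connects the arterial and venous trees through a capillary bed built by
#' either the Voronoi or the space-colonization method, producing a single
#' connected network in which every inlet-to-outlet path crosses the bed.
#'
#' @param net a grown [vascular_network] (arterial + venous trees)
#' @param domain a [retina_domain]
#' @param spec a [capillary_bed_spec()]
#' @param seed integer seed
#' @return a connected [vascular_network] (stage `"connected"`)
#' @export
close_circulation <- function(net, domain, spec = capillary_bed_spec(),
                              seed = 0L) {
  a_ids <- terminal_node_ids(net, "artery")
  v_ids <- terminal_node_ids(net, "vein")
  if (length(a_ids) == 0 || length(v_ids) == 0)
    stop("both trees need terminals to build a capillary bed")
  a_pos <- as.matrix(net$nodes[match(a_ids, net$nodes$id), c("x", "y")])
  v_pos <- as.matrix(net$nodes[match(v_ids, net$nodes$id), c("x", "y")])
  if (spec$method == "voronoi") {
    bed <- build_capillary_bed_voronoi(a_pos, v_pos, domain, spec, seed)
    segs <- lapply(bed, function(s) {
      fix <- function(e) {
        if (is.list(e)) {
          if (e$terminal == "artery") a_ids[e$index] else v_ids[e$index]
        } else e
      }
      list(a = fix(s$a), b = fix(s$b), radius = s$radius, class = "capillary")
    })
  } else {
    set.seed(stage_seed(seed, "colonization-attractors"))
    n_attr <- max(1L, round(spec$seed_density * pi * domain$retina_radius^2))
    attractors <- runif_disc(n_attr, domain)
    half <- sample(c(TRUE, FALSE), nrow(attractors), replace = TRUE)
    bed_a <- build_capillary_bed_colonization(a_pos, domain, spec, seed,
                                              attractors = attractors[half, , drop = FALSE])
    bed_v <- build_capillary_bed_colonization(v_pos, domain, spec, seed + 1L,
                                              attractors = attractors[!half, , drop = FALSE])
    fix <- function(bed, ids) lapply(bed, function(s) {
      f <- function(e) if (is.list(e)) ids[e$index] else e
      list(a = f(s$a), b = f(s$b), radius = s$radius, class = "capillary")
    })
    segs <- c(fix(bed_a, a_ids), fix(bed_v, v_ids))
    # anastomose the two half-beds: each arterial-bed tip joins its nearest
    # venous-bed node
    nodes_a <- attr(bed_a, "nodes"); nodes_v <- attr(bed_v, "nodes")
    if (!is.null(nodes_a) && !is.null(nodes_v) &&
        nrow(nodes_a) > 0 && nrow(nodes_v) > 0) {
      nn <- FNN::get.knnx(nodes_v, nodes_a, k = 1)
      ord <- order(nn$nn.dist[, 1])
      n_join <- max(3L, ceiling(nrow(nodes_a) / 4))
      for (i in ord[seq_len(min(n_join, length(ord)))]) {
        av <- if (i <= nrow(a_pos)) a_ids[i] else nodes_a[i, ]
        j <- nn$nn.index[i, 1]
        vv <- if (j <= nrow(v_pos)) v_ids[j] else nodes_v[j, ]
        segs[[length(segs) + 1]] <- list(a = av, b = vv,
                                         radius = spec$capillary_radius,
                                         class = "capillary")
      }
    }
  }
  out <- net_add_segments(net, segs)
  out <- connect_stray_components(out, spec$capillary_radius)
  out$metadata$stage <- "connected"
  out
}

# join any leftover components to the component containing the inlet
connect_stray_components <- function(net, radius) {
  repeat {
    g <- network_igraph(net)
    comp <- igraph::components(g)
    if (comp$no == 1) return(net)
    main <- comp$membership[match(net$inlet_id, net$nodes$id)]
    other <- which(comp$membership != main)
    mainv <- which(comp$membership == main)
    pm <- as.matrix(net$nodes[mainv, c("x", "y")])
    po <- as.matrix(net$nodes[other, c("x", "y")])
    nn <- FNN::get.knnx(pm, po, k = 1)
    j <- which.min(nn$nn.dist[, 1])
    net <- net_add_segments(net, list(list(
      a = net$nodes$id[other[j]], b = net$nodes$id[mainv[nn$nn.index[j, 1]]],
      radius = radius, class = "capillary")))
  }
}

# artery-vein segment pairs approaching closer (in plane) than the sum of
# their radii; returns data frame with segment indices and approach info
find_av_crossings <- function(net, max_radius_um = Inf) {
  cls <- segment_classes(net)
  ai <- which(cls == "artery"); vi <- which(cls == "vein")
  if (length(ai) == 0 || length(vi) == 0)
    return(data.frame(artery = integer(0), vein = integer(0)))
  ends <- function(k) {
    s <- net$segments[[k]]
    c(s$path[1, 1:2], s$path[nrow(s$path), 1:2])
  }
  ea <- t(vapply(ai, ends, numeric(4)))
  ev <- t(vapply(vi, ends, numeric(4)))
  ra <- segment_mean_radius_um(net)[ai]
  rv <- segment_mean_radius_um(net)[vi]
  out <- list()
  for (i in seq_along(ai)) {
    if (ra[i] > max_radius_um) next
    lo <- pmin(ea[i, 1:2], ea[i, 3:4]); hi <- pmax(ea[i, 1:2], ea[i, 3:4])
    margin <- (ra[i] + rv) * MM_PER_UM
    cand <- which(pmin(ev[, 1], ev[, 3]) <= hi[1] + margin &
                  pmax(ev[, 1], ev[, 3]) >= lo[1] - margin &
                  pmin(ev[, 2], ev[, 4]) <= hi[2] + margin &
                  pmax(ev[, 2], ev[, 4]) >= lo[2] - margin)
    for (j in cand) {
      if (rv[j] > max_radius_um) next
      d <- segseg_distance_2d(ea[i, 1:2], ea[i, 3:4], ev[j, 1:2], ev[j, 3:4])
      if (d < (ra[i] + rv[j]) * MM_PER_UM)
        out[[length(out) + 1]] <- data.frame(artery = ai[i], vein = vi[j],
                                             dist_mm = d,
                                             r_a = ra[i], r_v = rv[j])
    }
  }
  if (length(out) == 0)
    return(data.frame(artery = integer(0), vein = integer(0),
                      dist_mm = numeric(0), r_a = numeric(0),
                      r_v = numeric(0)))
  do.call(rbind, out)
}

#' Resolve artery-vein crossings by out-of-plane excursions
#'
#' Wherever an artery and a vein approach closer in plane than the sum of
#' their radii, the smaller vessel's path is lifted out of plane by a
#' smooth cosine bump whose clearance is at least the sum of radii
#' (support 4 local radii to each side of the contact), so no
#' artery-vein pair remains closer than the sum of radii in 3D.
#'
#' @param net a [vascular_network]
#' @return a [vascular_network] with displaced paths
#' @export
resolve_av_crossings <- function(net) {
  cr <- find_av_crossings(net)
  if (nrow(cr) == 0) return(net)
  for (i in seq_len(nrow(cr))) {
    small_is_a <- cr$r_a[i] <= cr$r_v[i]
    k <- if (small_is_a) cr$artery[i] else cr$vein[i]
    other <- if (small_is_a) cr$vein[i] else cr$artery[i]
    clearance <- (cr$r_a[i] + cr$r_v[i]) * MM_PER_UM * 1.15
    net$segments[[k]] <- bump_segment(net$segments[[k]],
                                      net$segments[[other]], clearance)
  }
  net
}

# lift `seg`'s path over `other` with a cosine bump of height `clearance`
bump_segment <- function(seg, other, clearance) {
  r_mm <- mean(seg$radius) * MM_PER_UM
  support <- max(8 * r_mm, 4 * clearance)
  dens <- densify_polyline(seg$path, max_step = support / 6, vals = seg$radius)
  path <- dens$path; rad <- dens$vals
  # closest approach along the (densified) path to the other segment
  o1 <- other$path[1, 1:2]; o2 <- other$path[nrow(other$path), 1:2]
  d <- point_segment_distance(path[, 1:2], o1, o2)$d
  x <- polyline_cumlen(path)
  x0 <- x[which.min(d)]
  w <- support
  bump <- ifelse(abs(x - x0) <= w,
                 clearance * 0.5 * (1 + cos(pi * (x - x0) / w)), 0)
  # endpoints stay put (bifurcation nodes must not move)
  bump[c(1, length(bump))] <- 0
  path[, 3] <- path[, 3] + bump
  seg$path <- path
  seg$radius <- rad
  seg
}

#' Interleave terminal beds at fine arterio-venous intersections
#'
#' For artery-vein intersections where both radii are below the critical
#' threshold, the lower-flow side's crossing segment is removed, leaving
#' surviving geometry untouched; removed attachments are regrown toward the
#' surviving bed by a nearest-neighbour colonization step so dead ends do
#' not persist.
#'
#' @param net a connected [vascular_network]
#' @param sol its `flow_solution` (identifies the low-flow side)
#' @param radius_threshold critical radius, um (default 5).
#' @param regrow reconnect dangling ends afterwards?
#' @return a [vascular_network]
#' @export
interleave_terminal_beds <- function(net, sol, radius_threshold = 5,
                                     regrow = TRUE) {
  stopifnot(inherits(sol, "flow_solution"))
  cr <- find_av_crossings(net, max_radius_um = radius_threshold)
  if (nrow(cr) == 0) return(net)
  flows <- abs(sol$segments$flow_ul_min[match(segment_ids(net),
                                              sol$segments$id)])
  drop <- integer(0)
  for (i in seq_len(nrow(cr))) {
    qa <- flows[cr$artery[i]]; qv <- flows[cr$vein[i]]
    drop <- c(drop, if (qa <= qv) cr$artery[i] else cr$vein[i])
  }
  drop <- unique(drop)
  dangling <- unique(unlist(lapply(net$segments[drop],
                                   function(s) c(s$from, s$to))))
  net$segments <- net$segments[-drop]
  if (regrow) {
    deg <- table(unlist(lapply(net$segments, function(s) c(s$from, s$to))))
    ends <- dangling[dangling %in% as.integer(names(deg)[deg == 1])]
    ends <- setdiff(ends, c(net$inlet_id, net$outlet_id))
    if (length(ends) > 0) {
      keep_ids <- setdiff(net$nodes$id, ends)
      pm <- as.matrix(net$nodes[match(keep_ids, net$nodes$id), c("x", "y")])
      pe <- as.matrix(net$nodes[match(ends, net$nodes$id), c("x", "y")])
      nn <- FNN::get.knnx(pm, pe, k = 1)
      segs <- lapply(seq_along(ends), function(i)
        list(a = ends[i], b = keep_ids[nn$nn.index[i, 1]],
             radius = radius_threshold * 0.8, class = "capillary"))
      net <- net_add_segments(net, segs)
    }
  }
  net
}
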