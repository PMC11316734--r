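#' Capillary bed specification
#'
#' @param method `"voronoi"` (capillaries along Voronoi edges of a random
#'   seed-point process) or `"space-colonization"`.
#' @param capillary_radius capillary radius, um.
#' @param seed_density seed/attractor point density, points per mm^2.
#' @param attraction_radius,kill_radius space-colonization radii, um.
#' @return list of class `capillary_bed_spec`
#' @export
capillary_bed_spec <- function(method = c("voronoi", "space-colonization"),
                               capillary_radius = 4,
                               seed_density = 25,
                               attraction_radius = 600,
                               kill_radius = 150) {
  method <- match.arg(method)
  stopifnot(capillary_radius > 0, seed_density > 0,
            attraction_radius > kill_radius, kill_radius > 0)
  structure(list(method = method, capillary_radius = capillary_radius,
                 seed_density = seed_density,
                 attraction_radius = attraction_radius,
                 kill_radius = kill_radius),
            class = "capillary_bed_spec")
}

# uniform points in the retina disc minus the fovea
runif_disc <- function(n, domain) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- domain$retina_radius * sqrt(stats::runif(n))
  pts <- cbind(domain$disc_centre[1] + rr * cos(th),
               domain$disc_centre[2] + rr * sin(th))
  pts[!in_disc(pts, domain$macula_centre, domain$fovea_radius), , drop = FALSE]
}

#' Build a capillary bed from the Voronoi diagram of random seed points
#'
#' Voronoi edges of a uniform seed-point process become capillary segments
#' at the specified radius; every arterial and venous terminal is connected
#' to its nearest Voronoi vertex, and any disconnected patches are stitched
#' to the main bed so the closed network has an inlet-to-outlet path. The
#' fovea disc is kept capillary-free.
#'
#' @param arterial_terminals,venous_terminals n x 2 matrices of terminal
#'   positions, mm.
#' @param domain a [retina_domain]
#' @param spec a [capillary_bed_spec()]
#' @param seed integer seed
#' @return list of capillary segments `list(a =, b =, radius =)`, each
#'   endpoint a planar position (mm) or an index into the supplied terminal
#'   matrices (`list(terminal = "artery"|"vein", index =)`).
#' @export
build_capillary_bed_voronoi <- function(arterial_terminals, venous_terminals,
                                        domain, spec = capillary_bed_spec(),
                                        seed = 0L) {
  stopifnot(nrow(arterial_terminals) > 0, nrow(venous_terminals) > 0)
  set.seed(stage_seed(seed, "voronoi-bed"))
  n_seed <- max(4L, round(spec$seed_density * pi * domain$retina_radius^2))
  pts <- runif_disc(n_seed, domain)
  if (nrow(pts) < 3) stop("fewer than 3 capillary seed points")
  R <- domain$retina_radius
  rw <- c(domain$disc_centre[1] - R, domain$disc_centre[1] + R,
          domain$disc_centre[2] - R, domain$disc_centre[2] + R)
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = rw, suppressMsge = TRUE)
  ed <- dd$dirsgs
  keep <- rep(TRUE, nrow(ed))
  for (i in seq_len(nrow(ed))) {
    a <- c(ed$x1[i], ed$y1[i]); b <- c(ed$x2[i], ed$y2[i])
    if (vnorm(a - domain$disc_centre) > R || vnorm(b - domain$disc_centre) > R) {
      keep[i] <- FALSE; next
    }
    # avascular fovea
    if (psd1(domain$macula_centre[1], domain$macula_centre[2],
             a[1], a[2], b[1], b[2])[1] < domain$fovea_radius)
      keep[i] <- FALSE
  }
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed) == 0) stop("no capillary edges inside the domain")
  segs <- lapply(seq_len(nrow(ed)), function(i)
    list(a = c(ed$x1[i], ed$y1[i]), b = c(ed$x2[i], ed$y2[i]),
         radius = spec$capillary_radius))

  verts <- unique(round(rbind(cbind(ed$x1, ed$y1), cbind(ed$x2, ed$y2)), 9))
  link <- function(tm, label) {
    nn <- FNN::get.knnx(verts, tm, k = 1)
    lapply(seq_len(nrow(tm)), function(i)
      list(a = list(terminal = label, index = i),
           b = verts[nn$nn.index[i, 1], ],
           radius = spec$capillary_radius))
  }
  segs <- c(segs, link(arterial_terminals, "artery"),
            link(venous_terminals, "vein"))

  # stitch disconnected patches of the bed to the largest component
  key <- function(p) paste(round(p[1], 9), round(p[2], 9))
  vkeys <- apply(verts, 1, function(p) key(p))
  epts <- vapply(segs, function(s) {
    c(if (is.list(s$a)) NA_character_ else key(s$a),
      if (is.list(s$b)) NA_character_ else key(s$b))
  }, character(2))
  g <- igraph::graph_from_edgelist(
    cbind(ifelse(is.na(epts[1, ]), paste0("T", seq_along(segs)), epts[1, ]),
          ifelse(is.na(epts[2, ]), paste0("T", seq_along(segs)), epts[2, ])),
    directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    main <- which.max(comp$csize)
    vnames <- igraph::V(g)$name
    main_keys <- vnames[comp$membership == main]
    main_idx <- match(main_keys, vkeys); main_idx <- main_idx[!is.na(main_idx)]
    for (ci in setdiff(seq_len(comp$no), main)) {
      ck <- vnames[comp$membership == ci]
      cidx <- match(ck, vkeys); cidx <- cidx[!is.na(cidx)]
      if (length(cidx) == 0 || length(main_idx) == 0) next
      nn <- FNN::get.knnx(verts[main_idx, , drop = FALSE],
                          verts[cidx, , drop = FALSE], k = 1)
      j <- which.min(nn$nn.dist[, 1])
      segs[[length(segs) + 1]] <- list(a = verts[cidx[j], ],
                                       b = verts[main_idx[nn$nn.index[j, 1]], ],
                                       radius = spec$capillary_radius)
    }
  }
  segs
}

#' Build a capillary bed by space colonization
#'
#' Classic space-colonization growth: attractor points are scattered over
#' the domain (fovea excluded); tips grow from the supplied terminals
#' toward the mean direction of attractors within the attraction radius,
#' and attractors within the kill radius of new tips are removed, until all
#' attractors are killed, nothing grows, or the iteration cap is reached.
#'
#' @param terminals n x 2 matrix of starting tips, mm.
#' @param domain a [retina_domain]
#' @param spec a [capillary_bed_spec()]
#' @param seed integer seed
#' @param max_iter iteration guard
#' @param attractors optional preset attractor matrix (mm); default random.
#' @return list of capillary segments as in [build_capillary_bed_voronoi()]
#' @export
build_capillary_bed_colonization <- function(terminals, domain,
                                             spec = capillary_bed_spec("space-colonization"),
                                             seed = 0L, max_iter = 200L,
                                             attractors = NULL) {
  stopifnot(nrow(terminals) > 0)
  set.seed(stage_seed(seed, "colonization-bed"))
  if (is.null(attractors)) {
    n_attr <- max(1L, round(spec$seed_density * pi * domain$retina_radius^2))
    attractors <- runif_disc(n_attr, domain)
  }
  if (nrow(attractors) == 0) return(list())
  r_attr <- spec$attraction_radius * MM_PER_UM
  r_kill <- spec$kill_radius * MM_PER_UM
  nodes <- terminals
  node_src <- seq_len(nrow(terminals))  # originating terminal per node
  alive <- rep(TRUE, nrow(attractors))
  segs <- list()
  for (it in seq_len(max_iter)) {
    if (!any(alive)) break
    attr_idx <- which(alive)
    nn <- FNN::get.knnx(nodes, attractors[attr_idx, , drop = FALSE], k = 1)
    near <- nn$nn.dist[, 1] <= r_attr
    if (!any(near)) break
    grew <- FALSE
    for (nd in unique(nn$nn.index[near, 1])) {
      mine <- attr_idx[near & nn$nn.index[, 1] == nd]
      dirs <- sweep(attractors[mine, , drop = FALSE], 2, nodes[nd, ])
      dn <- rownorms(dirs)
      dirs <- dirs / pmax(dn, 1e-12)
      d <- colMeans(dirs)
      if (vnorm(d) < 1e-9) d <- dirs[1, ]
      new_pt <- nodes[nd, ] + unitv(d) * r_kill
      if (in_disc(new_pt, domain$macula_centre, domain$fovea_radius)) next
      if (vnorm(new_pt - domain$disc_centre) > domain$retina_radius) next
      segs[[length(segs) + 1]] <- list(
        a = if (nd <= nrow(terminals)) list(terminal = "any", index = nd)
            else nodes[nd, ],
        b = new_pt, radius = spec$capillary_radius)
      nodes <- rbind(nodes, new_pt)
      node_src <- c(node_src, node_src[nd])
      grew <- TRUE
    }
    # kill reached attractors
    if (nrow(nodes) > 0 && any(alive)) {
      nn2 <- FNN::get.knnx(nodes, attractors[which(alive), , drop = FALSE],
                           k = 1)
      killed <- which(alive)[nn2$nn.dist[, 1] <= r_kill]
      alive[killed] <- FALSE
    }
    if (!grew) break
  }
  attr(segs, "nodes") <- nodes
  attr(segs, "node_src") <- node_src
  segs
}
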