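# Shared fixtures. Expensive generated networks are cached per session so
# several test files can reuse the same mini retina.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

mini_run_fixture <- function(seed = 1L) {
  cached(paste0("mini-run-", seed), function()
    suppressWarnings(make_toy_fixture("mini-retina", seed = seed)))
}

# seed + growth only (tree-stage network), reduced scale
grown_net_fixture <- function(seed = 1L) {
  cached(paste0("grown-", seed), function() {
    params <- mini_parameters(seed)
    domain <- retinavasc:::mini_domain()
    run <- generate_retina(seed = seed, params = params, domain = domain,
                           stages = c("seed", "grow"))
    list(net = run$network, params = params, domain = domain)
  })
}

# a small random closed network: random interior points joined by Delaunay
# edges, plus designated inlet/outlet; used as solver test-bed
random_closed_network <- function(n = 40, seed = 1) {
  set.seed(seed)
  pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  del <- dd$delsgs
  nodes <- data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2], z = 0,
                      kind = "bifurcation", stringsAsFactors = FALSE)
  nodes$kind[1] <- "inlet-root"
  nodes$kind[2] <- "outlet-root"
  segs <- lapply(seq_len(nrow(del)), function(i) {
    a <- del$ind1[i]; b <- del$ind2[i]
    list(id = i, from = a, to = b,
         path = rbind(c(pts[a, ], 0), c(pts[b, ], 0)),
         radius = runif(1, 5, 40), class = "capillary")
  })
  vascular_network(nodes, segs, inlet_id = 1L, outlet_id = 2L)
}

# independent dense Poiseuille solver: same physics, straight-line dense
# linear algebra, no sparse machinery
dense_poiseuille_oracle <- function(net, p_in, p_out,
                                    mu = 3.5e-3) {
  ids <- net$nodes$id
  n <- length(ids)
  g <- vapply(net$segments, function(s) {
    r <- mean(s$radius) * 1e-6
    l <- sum(sqrt(rowSums(diff(s$path * 1e-3)^2)))
    pi * r^4 / (8 * mu * l)
  }, numeric(1))
  from <- match(vapply(net$segments, `[[`, numeric(1), "from"), ids)
  to <- match(vapply(net$segments, `[[`, numeric(1), "to"), ids)
  A <- matrix(0, n, n)
  for (k in seq_along(g)) {
    A[from[k], from[k]] <- A[from[k], from[k]] + g[k]
    A[to[k], to[k]] <- A[to[k], to[k]] + g[k]
    A[from[k], to[k]] <- A[from[k], to[k]] - g[k]
    A[to[k], from[k]] <- A[to[k], from[k]] - g[k]
  }
  i_in <- match(net$inlet_id, ids); i_out <- match(net$outlet_id, ids)
  b <- rep(0, n)
  for (i in c(i_in, i_out)) {
    A[i, ] <- 0; A[i, i] <- 1
  }
  b[i_in] <- p_in * 133.322; b[i_out] <- p_out * 133.322
  p <- solve(A, b)
  q <- g * (p[from] - p[to]) / (1e-9 / 60)
  list(pressure_mmHg = p / 133.322, flow_ul_min = q)
}

# brute-force all-pairs crossing count within one vessel class (oracle for
# the rewiring contract); crossing = 2D separation below the radius sum.
# A vectorised bounding-box prefilter discards pairs that cannot possibly
# approach; the exact segment-segment distance decides the rest.
brute_force_crossings <- function(net, class) {
  idx <- which(retinavasc:::segment_classes(net) == class)
  segs <- net$segments[idx]
  r <- vapply(segs, function(s) mean(s$radius), numeric(1)) * 1e-3
  ends <- t(vapply(segs, function(s)
    c(s$path[1, 1:2], s$path[nrow(s$path), 1:2]), numeric(4)))
  lo_x <- pmin(ends[, 1], ends[, 3]); hi_x <- pmax(ends[, 1], ends[, 3])
  lo_y <- pmin(ends[, 2], ends[, 4]); hi_y <- pmax(ends[, 2], ends[, 4])
  count <- 0L
  for (i in seq_along(segs)) {
    m <- r[i] + r
    cand <- which(lo_x < hi_x[i] + m & hi_x > lo_x[i] - m &
                  lo_y < hi_y[i] + m & hi_y > lo_y[i] - m)
    cand <- cand[cand < i]
    for (j in cand) {
      si <- segs[[i]]; sj <- segs[[j]]
      if (length(intersect(c(si$from, si$to), c(sj$from, sj$to))) > 0) next
      d <- retinavasc:::segseg_distance_2d(
        si$path[1, 1:2], si$path[nrow(si$path), 1:2],
        sj$path[1, 1:2], sj$path[nrow(sj$path), 1:2])
      if (d < r[i] + r[j]) count <- count + 1L
    }
  }
  count
}

# diamond network: inlet -> stem -> two symmetric arms -> stem -> outlet
diamond_network <- function(r_stem = 50, r_arm = 40) {
  nd <- function(id, x, y, kind)
    data.frame(id = id, x = x, y = y, z = 0, kind = kind,
               stringsAsFactors = FALSE)
  nodes <- rbind(nd(1, 0, 0, "inlet-root"), nd(2, 1, 0, "bifurcation"),
                 nd(3, 2, 1, "bifurcation"), nd(4, 2, -1, "bifurcation"),
                 nd(5, 3, 0, "bifurcation"), nd(6, 4, 0, "outlet-root"))
  sg <- function(id, a, b, pa, pb, r, cl)
    list(id = id, from = a, to = b, path = rbind(c(pa, 0), c(pb, 0)),
         radius = r, class = cl)
  segs <- list(
    sg(1, 1, 2, c(0, 0), c(1, 0), r_stem, "artery"),
    sg(2, 2, 3, c(1, 0), c(2, 1), r_arm, "artery"),
    sg(3, 2, 4, c(1, 0), c(2, -1), r_arm, "artery"),
    sg(4, 3, 5, c(2, 1), c(3, 0), r_arm, "vein"),
    sg(5, 4, 5, c(2, -1), c(3, 0), r_arm, "vein"),
    sg(6, 5, 6, c(3, 0), c(4, 0), r_stem, "vein"))
  vascular_network(nodes, segs, 1L, 6L)
}
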