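test_that("network cost follows the r^rho l^lambda sum", {
  nodes <- data.frame(id = 1:3, x = c(0, 3e-3, 7e-3), y = 0, z = 0,
                      kind = c("inlet-root", "bifurcation", "terminal"))
  sg <- function(id, a, b, r) list(id = id, from = a, to = b,
    path = rbind(as.numeric(nodes[a, 2:4]), as.numeric(nodes[b, 2:4])),
    radius = r, class = "artery")
  one <- vascular_network(
    data.frame(id = 1:2, x = c(0, 1e-3), y = 0, z = 0,
               kind = c("inlet-root", "terminal")),
    list(list(id = 1, from = 1, to = 2,
              path = rbind(c(0, 0, 0), c(1e-3, 0, 0)), radius = 1,
              class = "artery")), 1)
  expect_equal(network_cost(one, 1, 1), 1)  # r = 1 um, l = 1 um

  # segments (r = 2, l = 3) and (r = 1, l = 4): cost 2*3 + 1*4 = 10
  two <- vascular_network(nodes, list(sg(1, 1, 2, 2), sg(2, 2, 3, 1)), 1)
  expect_equal(network_cost(two, 1, 1), 10)
  # rho = 2, lambda = 1: cost equals total volume / pi
  expect_equal(network_cost(two, 2, 1),
               network_summary(two)$total_volume_um3 / pi, tolerance = 1e-9)
})

test_that("leaf nodes cover the retina uniformly outside the macula", {
  domain <- retina_domain()
  pts <- distribute_leaf_nodes(domain, 3, seed = 4)
  target <- pi * 12.5^2 / 9
  expect_gt(nrow(pts), target * 0.7)
  expect_lt(nrow(pts), target * 1.3)
  expect_false(any(retinavasc:::in_disc(pts, domain$macula_centre,
                                        domain$macula_radius)))
  dmat <- as.matrix(dist(pts))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 0.5 * 3)

  expect_equal(nrow(distribute_leaf_nodes(domain, 25, seed = 1)), 1)
  expect_error(distribute_leaf_nodes(domain, 26), "spacing")
  expect_error(distribute_leaf_nodes(domain, 0), "spacing")
})

test_that("lattice growth fills the domain and keeps the macula avascular", {
  fx <- grown_net_fixture()
  net <- fx$net; params <- fx$params; domain <- fx$domain
  s <- params$lattice_stride_min * 1e-3
  R <- domain$retina_radius
  g <- seq(-ceiling(R / s) * s, R, by = s)
  ctr <- expand.grid(x = g, y = g)
  inside <- retinavasc:::in_disc(as.matrix(ctr), domain$disc_centre, R) &
    !retinavasc:::in_disc(as.matrix(ctr), domain$macula_centre,
                          domain$macula_radius)
  allp <- do.call(rbind, lapply(net$segments, function(sg) {
    retinavasc:::densify_polyline(sg$path, max_step = s / 2)$path
  }))
  ix <- floor((allp[, 1] - (g[1] - s / 2)) / s) + 1L
  iy <- floor((allp[, 2] - (g[1] - s / 2)) / s) + 1L
  ok <- ix >= 1 & ix <= length(g) & iy >= 1 & iy <= length(g)
  occ <- rep(FALSE, length(g)^2)
  occ[(iy[ok] - 1L) * length(g) + ix[ok]] <- TRUE
  expect_gte(mean(occ[inside]), 0.9)

  # macula region vessel-free at the end of main growth
  inmac <- retinavasc:::in_disc(allp[, 1:2], domain$macula_centre,
                                domain$macula_radius)
  expect_equal(sum(inmac), 0)
})

test_that("growth is reproducible and Murray-exact at every stage", {
  params <- mini_parameters(6)
  domain <- retinavasc:::mini_domain()
  r1 <- generate_retina(seed = 6, params = params, domain = domain,
                        stages = c("seed", "grow"))
  r2 <- generate_retina(seed = 6, params = params, domain = domain,
                        stages = c("seed", "grow"))
  expect_identical(r1$network$segments, r2$network$segments)

  fit <- fit_murray_exponent(r1$network)
  expect_equal(fit$median_exponent, params$murray_exponent, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("geometric optimisation never increases the cost and respects
           freezing", {
  fx <- grown_net_fixture()
  params <- fx$params
  tt <- retinavasc:::network_to_trees(fx$net)
  tr <- tt$artery
  c0 <- retinavasc:::tree_cost(tr)
  frozen_nodes <- which(tr$frozen[seq_len(tr$n)])
  retinavasc:::tree_optimize_geometry(tr, params, max_sweeps = 3L)
  expect_lte(retinavasc:::tree_cost(tr), c0 * (1 + 1e-12))

  # a perturbed interior bifurcation strictly improves
  tr2 <- retinavasc:::tree_clone(tr)
  ch <- retinavasc:::tree_children(tr2)
  j <- which(lengths(ch) == 2 & !is.na(tr2$parent[seq_len(tr2$n)]))[5]
  tr2$pos[j, 1:2] <- tr2$pos[j, 1:2] + 0.2
  c_pert <- retinavasc:::tree_cost(tr2)
  retinavasc:::tree_optimize_geometry(tr2, params, max_sweeps = 3L)
  expect_lt(retinavasc:::tree_cost(tr2), c_pert)

  # frozen vessels are untouched
  tr3 <- retinavasc:::tree_clone(tr)
  tr3$frozen[seq_len(tr3$n)] <- TRUE
  pos_before <- tr3$pos[seq_len(tr3$n), ]
  retinavasc:::tree_optimize_geometry(tr3, params, max_sweeps = 2L)
  expect_identical(tr3$pos[seq_len(tr3$n), ], pos_before)
})

test_that("asymmetric bifurcations are trimmed, symmetric ones are not", {
  params <- sample_parameters(1)
  # hand-built tree: root - apex - {thick child, thin child}
  tr <- retinavasc:::tree_new(c(0, 0, 0), "artery")
  apex <- retinavasc:::tree_add_child(tr, 1, c(0, 0, 1), 100, "seed")
  b1 <- retinavasc:::tree_add_child(tr, apex, c(1, 0, 1), 99, "seed")
  b2 <- retinavasc:::tree_add_child(tr, apex, c(0, 1, 1), 10, "seed")
  retinavasc:::tree_recompute_radii(tr, 2.4)
  retinavasc:::tree_trim(tr, 0.2)
  expect_equal(tr$n, 3)  # thin side (alpha = 0.1) removed

  tr2 <- retinavasc:::tree_new(c(0, 0, 0), "artery")
  apex <- retinavasc:::tree_add_child(tr2, 1, c(0, 0, 1), 100, "seed")
  retinavasc:::tree_add_child(tr2, apex, c(1, 0, 1), 60, "seed")
  retinavasc:::tree_add_child(tr2, apex, c(0, 1, 1), 40, "seed")
  retinavasc:::tree_recompute_radii(tr2, 2.4)
  n_before <- tr2$n
  retinavasc:::tree_trim(tr2, 0.2)
  expect_equal(tr2$n, n_before)  # alpha = 0.67 kept

  # postcondition on a grown network
  fx <- grown_net_fixture()
  out <- trim_and_regrow(fx$net, fx$params, fx$domain, regrow = FALSE)
  fit <- fit_murray_exponent(out)
  tt <- retinavasc:::network_to_trees(out)
  for (tr in tt) {
    ch <- retinavasc:::tree_children(tr)
    for (j in seq_len(tr$n)) {
      kids <- ch[[j]]
      if (length(kids) >= 2)
        expect_gte(min(tr$rad[kids]) / max(tr$rad[kids]),
                   fx$params$constants$trim_alpha_threshold - 1e-12)
    }
  }
})

test_that("topological rewiring lowers cost when and only when possible", {
  params <- sample_parameters(1, overrides = list(murray_exponent = 2.4))
  # three-level tree where the small branch sits too far upstream: the stem
  # is long, so carrying the small branch's Murray increment along it is
  # costly; moving it downstream must win
  build <- function() {
    tr <- retinavasc:::tree_new(c(0, 0, 0), "artery")
    apex <- retinavasc:::tree_add_child(tr, 1, c(0, 0, 0.1), 50, "seed")
    big <- retinavasc:::tree_add_child(tr, apex, c(10, 0, 0), 49, "seed")
    small <- retinavasc:::tree_add_child(tr, apex, c(10.5, 0.5, 0), 8, "seed")
    l1 <- retinavasc:::tree_add_child(tr, big, c(12, 1, 0), 35, "seed")
    l2 <- retinavasc:::tree_add_child(tr, big, c(12, -1, 0), 35, "seed")
    retinavasc:::tree_recompute_radii(tr, 2.4)
    tr
  }
  tr <- build()
  # oracle: enumerate both topologies by brute force
  cost_now <- retinavasc:::tree_cost(tr)
  alt <- retinavasc:::tree_clone(tr)
  alt$parent[4] <- 3  # small branch one generation downstream
  retinavasc:::tree_recompute_radii(alt, 2.4)
  cost_alt <- retinavasc:::tree_cost(alt)
  expect_lt(cost_alt, cost_now)

  moved <- retinavasc:::tree_topology_pass(tr, params)
  expect_gte(moved, 1)
  expect_lt(retinavasc:::tree_cost(tr), cost_now)
  expect_equal(retinavasc:::tree_cost(tr), cost_alt, tolerance = 1e-9)

  # an already-optimal configuration is a fixed point
  moved2 <- retinavasc:::tree_topology_pass(tr, params)
  expect_equal(retinavasc:::tree_cost(tr), cost_alt, tolerance = 1e-9)

  # acyclicity (parent pointers remain a forest rooted at node 1)
  for (s in 1:20) {
    set.seed(s)
    trr <- retinavasc:::tree_new(c(0, 0, 0), "artery")
    for (i in 1:30) {
      parent <- sample(trr$n, 1)
      retinavasc:::tree_add_child(trr, parent, runif(3, -5, 5),
                                  runif(1, 5, 50), "seed")
    }
    retinavasc:::tree_recompute_radii(trr, 2.4)
    retinavasc:::tree_topology_pass(trr, params)
    depth <- retinavasc:::tree_depths(trr)
    expect_false(anyNA(depth))  # every node still reaches the root
  }
})

test_that("self-intersection rewiring leaves zero crossings", {
  params <- sample_parameters(1)
  # two crossing segments in one tree, sharing no node
  tr <- retinavasc:::tree_new(c(-2, 0, 0), "artery")
  a <- retinavasc:::tree_add_child(tr, 1, c(2, 0, 0), 20, "seed")
  b <- retinavasc:::tree_add_child(tr, a, c(3, -2, 0), 15, "seed")
  d <- retinavasc:::tree_add_child(tr, b, c(0, 2, 0), 12, "seed")  # crosses 1->a
  retinavasc:::tree_recompute_radii(tr, 2.4)
  expect_gt(nrow(retinavasc:::tree_crossings(tr)), 0)
  suppressMessages(retinavasc:::tree_resolve_crossings(tr, params))
  expect_equal(nrow(retinavasc:::tree_crossings(tr)), 0)

  # crossing-free tree is untouched
  tr2 <- retinavasc:::tree_new(c(0, 0, 0), "artery")
  a2 <- retinavasc:::tree_add_child(tr2, 1, c(1, 0, 0), 20, "seed")
  retinavasc:::tree_add_child(tr2, a2, c(2, 1, 0), 15, "seed")
  retinavasc:::tree_recompute_radii(tr2, 2.4)
  before <- list(n = tr2$n, pos = tr2$pos[1:tr2$n, ], par = tr2$parent[1:tr2$n])
  retinavasc:::tree_resolve_crossings(tr2, params)
  expect_equal(tr2$n, before$n)
  expect_identical(tr2$parent[1:tr2$n], before$par)

  # grown networks end up crossing-free under the brute-force oracle
  fx <- grown_net_fixture()
  out <- suppressMessages(resolve_self_intersections(fx$net, fx$params))
  expect_equal(brute_force_crossings(out, "artery"), 0)
  expect_equal(brute_force_crossings(out, "vein"), 0)
})
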