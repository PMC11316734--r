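test_that("tortuosity at zero amplitude is the identity", {
  net <- grown_net_fixture()$net
  params <- grown_net_fixture()$params
  p0 <- params
  p0$tort_amplitude_artery <- 0
  p0$tort_amplitude_vein <- 0
  out <- apply_tortuosity(net, p0, seed = 2)
  k <- sample(n_segments(net), 5)
  for (i in k)
    expect_equal(out$segments[[i]]$path, net$segments[[i]]$path)
})

test_that("tortuosity displacement is bounded, node-preserving, and
           increases path/chord tortuosity", {
  net <- grown_net_fixture()$net
  params <- grown_net_fixture()$params
  out <- apply_tortuosity(net, params, seed = 3)
  for (k in sample(n_segments(net), 30)) {
    s0 <- net$segments[[k]]; s1 <- out$segments[[k]]
    # branch-node endpoints unchanged to 1e-9
    expect_lt(max(abs(s1$path[1, ] - s0$path[1, ])), 1e-9)
    expect_lt(max(abs(s1$path[nrow(s1$path), ] - s0$path[nrow(s0$path), ])),
              1e-9)
    # displacement from the chord bounded by (a0 + a1) = total amplitude x r
    amp <- if (s0$class == "artery") params$tort_amplitude_artery
           else params$tort_amplitude_vein
    r_mm <- mean(s0$radius) * 1e-3
    d <- retinavasc:::point_segment_distance(
      s1$path, s0$path[1, ], s0$path[nrow(s0$path), ])$d
    expect_lte(max(d), amp * r_mm * (1 + 1e-6))
    # strictly longer path over the same chord
    L0 <- retinavasc:::polyline_length(s0$path)
    L1 <- retinavasc:::polyline_length(s1$path)
    if (L0 > 1e-6) expect_gte(L1, L0)
  }
  # tortuosity metric strictly above 1 for the most-displaced branch
  gain <- vapply(seq_len(n_segments(net)), function(i)
    retinavasc:::polyline_length(out$segments[[i]]$path) -
      retinavasc:::polyline_length(net$segments[[i]]$path), numeric(1))
  k <- which.max(gain)
  s1 <- out$segments[[k]]
  chord <- retinavasc:::vnorm(s1$path[nrow(s1$path), ] - s1$path[1, ])
  expect_gt(retinavasc:::polyline_length(s1$path) / chord, 1 + 1e-6)
})

test_that("the eye surface is a hemisphere with prescribed relief", {
  domain <- retina_domain()
  flat <- build_eye_surface(24, domain,
                            fovea_profile = data.frame(amplitude = 0,
                                                       width = 1),
                            disc_profile = data.frame(amplitude = 0,
                                                      width = 1))
  centre <- c(domain$disc_centre, -12)
  rad <- sqrt(rowSums(sweep(flat$vertices, 2, centre)^2))
  expect_lt(max(abs(rad - 12)), 1e-9)

  # pit depth d appears as a -d radial offset at the fovea centre
  d <- 0.4
  pit <- build_eye_surface(24, domain,
                           fovea_profile = data.frame(amplitude = -d,
                                                      width = 0.3),
                           disc_profile = data.frame(amplitude = 0,
                                                     width = 1))
  expect_equal(pit$relief(matrix(domain$macula_centre, 1, 2)), -d,
               tolerance = 1e-12)

  # edge-manifold mesh: every interior edge appears in at most two faces
  f <- flat$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_lte(max(table(keys)), 2)
})

test_that("projection is azimuthal-equidistant and topology-preserving", {
  domain <- retina_domain()
  surface <- build_eye_surface(24, domain,
                               fovea_profile = data.frame(amplitude = 0,
                                                          width = 1),
                               disc_profile = data.frame(amplitude = 0,
                                                         width = 1))
  # planar origin maps to the projection centre (pole) of the sphere
  p0 <- retinavasc:::project_points(matrix(c(0, 0, 0), 1), surface)
  expect_equal(as.numeric(p0), c(0, 0, 0), tolerance = 1e-12)

  # planar radial distance rho = great-circle distance from the pole
  R <- 12
  centre <- c(0, 0, -R)
  for (rho in c(1, 5, 10)) {
    p <- retinavasc:::project_points(matrix(c(rho, 0, 0), 1), surface)
    v1 <- p0[1, ] - centre; v2 <- p[1, ] - centre
    arc <- R * acos(sum(v1 * v2) / (R * R))
    expect_equal(arc, rho, tolerance = 1e-6)
  }

  net <- grown_net_fixture()$net
  proj <- project_to_surface(net, surface)
  expect_equal(n_nodes(proj), n_nodes(net))
  expect_equal(n_segments(proj), n_segments(net))
  expect_identical(vapply(proj$segments, `[[`, numeric(1), "from"),
                   vapply(net$segments, `[[`, numeric(1), "from"))
  # radial arcs are length-preserving; azimuthal arcs contract by at most
  # the sin(theta)/theta factor of the mapping at the segment's largest
  # planar radius (differential-geometry bound on sampled segments)
  for (k in sample(n_segments(net), 25)) {
    s <- net$segments[[k]]
    s$path <- retinavasc:::densify_polyline(s$path, 0.05)$path
    Ld <- retinavasc:::polyline_length(s$path)
    L1 <- retinavasc:::polyline_length(
      retinavasc:::project_points(s$path, surface))
    rho_max <- max(sqrt(s$path[, 1]^2 + s$path[, 2]^2))
    th <- rho_max / R
    shrink <- if (th > 0) sin(th) / th else 1
    expect_lte(L1, Ld * (1 + 1e-9))
    expect_gte(L1, Ld * shrink * (1 - 1e-9))
  }
})
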