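test_that("points are labelled by region with disc precedence", {
  domain <- retina_domain()
  expect_equal(label_regions(c(domain$macula_centre, 0), domain), "macula")
  expect_equal(label_regions(c(domain$disc_centre, 0), domain), "optic-disc")
  expect_equal(label_regions(c(10, 10, 0), domain), "periphery")
  # precedence on a (non-physical) overlapping geometry
  both <- domain
  both$macula_centre <- domain$disc_centre
  expect_equal(label_regions(c(both$disc_centre, 0), both), "optic-disc")
})

test_that("branch metrics recover exact geometry on constructed branches", {
  domain <- retina_domain()
  # straight branch: tortuosity 1
  net <- make_toy_fixture("single-vessel")
  bm <- compute_branch_metrics(net, domain)
  expect_equal(bm$branches$tortuosity, 1, tolerance = 1e-12)
  expect_equal(bm$branches$length_um, 1000, tolerance = 1e-9)
  expect_equal(bm$branches$mean_diameter_um, 20, tolerance = 1e-9)

  # semicircular branch: tortuosity pi/2
  th <- seq(0, pi, length.out = 400)
  arc <- cbind(5 + cos(th), 5 + sin(th) * 1, 0)  # unit-radius semicircle
  nodes <- data.frame(id = 1:2, x = arc[c(1, 400), 1], y = arc[c(1, 400), 2],
                      z = 0, kind = c("inlet-root", "terminal"))
  semi <- vascular_network(nodes,
                           list(list(id = 1, from = 1, to = 2, path = arc,
                                     radius = rep(10, 400),
                                     class = "artery")), 1)
  bm2 <- compute_branch_metrics(semi, domain)
  expect_equal(bm2$branches$tortuosity, pi / 2, tolerance = 1e-4)

  # symmetric Murray bifurcation built from the optimal angles at alpha = 1
  g <- bifurcation_angles(1)
  th2 <- g$theta2 * pi / 180
  nodes3 <- data.frame(id = 1:4,
                       x = c(0, 1, 1 + cos(th2), 1 + cos(th2)),
                       y = c(0, 0, sin(th2), -sin(th2)), z = 0,
                       kind = c("inlet-root", "bifurcation", "terminal",
                                "terminal"))
  rd <- 100 / 2^(1 / 3)
  mk <- function(id, a, b, r) list(id = id, from = a, to = b,
    path = rbind(as.numeric(nodes3[a, 2:4]), as.numeric(nodes3[b, 2:4])),
    radius = r, class = "artery")
  y <- vascular_network(nodes3, list(mk(1, 1, 2, 100), mk(2, 2, 3, rd),
                                     mk(3, 2, 4, rd)), 1)
  bmy <- compute_branch_metrics(y, domain)
  expect_equal(bmy$angles$angle_deg, 2 * 37.467, tolerance = 0.01)
  # daughter-parent convention halves it
  bmy2 <- compute_branch_metrics(y, domain,
                                 angle_convention = "daughter-parent")
  expect_equal(bmy2$angles$angle_deg, rep(37.467, 2), tolerance = 0.01)
})

test_that("branch metrics are invariant to path re-densification", {
  fx <- grown_net_fixture()
  bm1 <- compute_branch_metrics(fx$net, fx$domain)
  refined <- fx$net
  for (k in seq_along(refined$segments)) {
    s <- refined$segments[[k]]
    d <- retinavasc:::densify_polyline(s$path, max_step = 0.05,
                                       vals = s$radius)
    refined$segments[[k]]$path <- d$path
    refined$segments[[k]]$radius <- d$vals
  }
  bm2 <- compute_branch_metrics(refined, fx$domain)
  expect_equal(nrow(bm2$branches), nrow(bm1$branches))
  expect_equal(bm2$branches$length_um, bm1$branches$length_um,
               tolerance = 0.01)
  expect_equal(bm2$branches$tortuosity, bm1$branches$tortuosity,
               tolerance = 0.01)
  expect_equal(mean(bm2$angles$angle_deg), mean(bm1$angles$angle_deg),
               tolerance = 0.01)
})

test_that("the Murray exponent is recovered by root-finding", {
  domain <- retina_domain()
  mk_bif <- function(rp, r1, r2) {
    nodes <- data.frame(id = 1:4, x = c(0, 1, 2, 2), y = c(0, 0, 1, -1),
                        z = 0, kind = c("inlet-root", "bifurcation",
                                        "terminal", "terminal"))
    sg <- function(id, a, b, r) list(id = id, from = a, to = b,
      path = rbind(as.numeric(nodes[a, 2:4]), as.numeric(nodes[b, 2:4])),
      radius = r, class = "artery")
    vascular_network(nodes, list(sg(1, 1, 2, rp), sg(2, 2, 3, r1),
                                 sg(3, 2, 4, r2)), 1)
  }
  f3 <- fit_murray_exponent(mk_bif(2^(1 / 3), 1, 1))
  expect_equal(f3$median_exponent, 3, tolerance = 1e-8)
  f2 <- fit_murray_exponent(mk_bif(sqrt(2), 1, 1))
  expect_equal(f2$median_exponent, 2, tolerance = 1e-8)
  # degenerate bifurcation skipped with count
  fd <- fit_murray_exponent(mk_bif(1, 1.2, 1))
  expect_equal(fd$n_skipped, 1)

  fx <- grown_net_fixture()
  fit <- fit_murray_exponent(fx$net)
  expect_equal(fit$median_exponent, fx$params$murray_exponent,
               tolerance = 0.05)
})

test_that("Dice score handles the worked case and both extremes", {
  a <- matrix(0, 4, 4); a[1:2, 1:3] <- 1   # |P| = 6
  b <- matrix(0, 4, 4); b[2, ] <- 1        # |L| = 4, overlap 3
  expect_equal(dice_score(a, b), 2 * 3 / (6 + 4))
  expect_equal(dice_score(a, a), 1)
  c2 <- matrix(0, 4, 4); c2[4, 4] <- 1
  expect_equal(dice_score(a * 0 + (row(a) == 4 & col(a) == 4), a), 0)
  expect_message(d0 <- dice_score(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(d0, 1)
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("rasterisation renders tubes at the configured spacing", {
  # empty network: all-zero volume
  empty <- vascular_network(
    data.frame(id = 1L, x = 0, y = 0, z = 0, kind = "inlet-root"),
    list(), 1, NA)
  vol0 <- rasterize_network(empty)
  expect_true(all(vol0$data == 0))

  # axis-aligned cylinder, r = 42 um, lateral spacing 21 um: per-slice
  # cross-section ~ pi (42/21)^2 ~ 12.6 voxels
  nodes <- data.frame(id = 1:2, x = c(0, 2), y = 0.5, z = 0.25,
                      kind = c("inlet-root", "terminal"))
  cyl <- vascular_network(nodes,
    list(list(id = 1, from = 1, to = 2,
              path = rbind(c(0, 0.5, 0.25), c(2, 0.5, 0.25)),
              radius = rep(42, 2), class = "artery")), 1)
  # bounds trimmed to the cylinder: end caps clip, which is reported
  vol <- suppressWarnings(
    rasterize_network(cyl, lateral_um = 21, axial_um = 21,
                      bounds = list(x = c(0, 2), y = c(0, 1),
                                    z = c(0, 0.5))))
  # voxels per x-slice away from the end caps
  nx <- dim(vol$data)[1]
  mid <- round(nx / 2)
  per_slice <- sum(vol$data[mid, , ] > 0)
  expect_gt(per_slice, pi * 4 * 0.7)
  expect_lt(per_slice, pi * 4 * 1.3)

  # deterministic: Dice of a raster with itself is 1
  expect_equal(dice_score(vol$data > 0, vol$data > 0), 1)

  # volume estimate converges at fine spacing (r / 4)
  vol_fine <- rasterize_network(cyl, lateral_um = 42 / 4, axial_um = 42 / 4,
                                bounds = list(x = c(-0.1, 2.1),
                                              y = c(0, 1), z = c(0, 0.5)))
  est <- sum(vol_fine$data > 0) * prod(vol_fine$spacing_um)
  analytic <- pi * 42^2 * 2000
  expect_equal(est, analytic, tolerance = 0.1)

  # en-face projection collapses the axial direction by maximum intensity
  ef <- enface_projection(vol)
  expect_equal(dim(ef), dim(vol$data)[1:2])
  expect_equal(max(ef), max(vol$data))
})
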