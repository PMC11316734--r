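# Independent evaluation of the optimal-bifurcation cosines, written out
# directly from the closed form (kept separate from the production code).
oracle_angles <- function(alpha) {
  c1 <- ((1 + alpha^3)^(4 / 3) + alpha^4 - 1) /
    (2 * alpha^2 * (1 + alpha^3)^(2 / 3))
  c2 <- ((1 + alpha^3)^(4 / 3) + 1 - alpha^4) / (2 * (1 + alpha^3)^(2 / 3))
  c(acos(c1), acos(c2)) * 180 / pi
}

test_that("optimal bifurcation angles match the closed form and limits", {
  # symmetric split: both daughters at acos(2^(-1/3)) ~ 37.47 deg
  g <- bifurcation_angles(1)
  expect_equal(g$theta1, acos(2^(-1 / 3)) * 180 / pi, tolerance = 1e-12)
  expect_equal(g$theta2, g$theta1, tolerance = 1e-12)
  expect_equal(g$theta1, 37.467, tolerance = 1e-4)

  for (a in c(0.25, 0.5, 0.75, 0.9)) {
    g <- bifurcation_angles(a)
    o <- oracle_angles(a)
    expect_equal(g$theta1, o[1], tolerance = 1e-9)
    expect_equal(g$theta2, o[2], tolerance = 1e-9)
    expect_gte(g$theta1, g$theta2)  # smaller daughter deflects more
  }

  # vanishing branch leaves perpendicular, trunk undeflected
  g0 <- bifurcation_angles(1e-4)
  expect_equal(g0$theta1, 90, tolerance = 0.01)
  expect_equal(g0$theta2, 0, tolerance = 0.01)

  expect_error(bifurcation_angles(0), "alpha")
  expect_error(bifurcation_angles(1.2), "alpha")
})

test_that("Murray daughter radii satisfy both defining constraints", {
  rr <- murray_daughter_radii(100, 1, 3)
  expect_equal(unname(rr["large"]), 100 / 2^(1 / 3), tolerance = 1e-12)
  rr2 <- murray_daughter_radii(100, 1, 2)
  expect_equal(unname(rr2["large"]), 100 / sqrt(2), tolerance = 1e-12)

  # general case checked against a root-finder solving the 2x2 system
  rr3 <- murray_daughter_radii(100, 0.6, 2.4)
  f <- function(rl) rl^2.4 + (0.6 * rl)^2.4 - 100^2.4
  rl_oracle <- uniroot(f, c(1, 100), tol = 1e-12)$root
  expect_equal(unname(rr3["large"]), rl_oracle, tolerance = 1e-9)
  expect_equal(unname(rr3["small"] / rr3["large"]), 0.6, tolerance = 1e-12)
  expect_equal(sum(rr3^2.4), 100^2.4, tolerance = 1e-9)

  expect_error(murray_daughter_radii(-1, 0.5, 3))
})

test_that("seed networks have full binary depth on an unbounded domain and
           are reproducible", {
  params <- sample_parameters(3)
  big <- retina_domain(retina_radius = 500)
  net1 <- grow_seed_network(params, big, seed = 11)
  net2 <- grow_seed_network(params, big, seed = 11)
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$segments, net2$segments)

  # 2^5 terminals per tree after five full generations
  expect_equal(sum(net1$nodes$kind == "terminal"), 2 * 32)
  expect_equal(nrow(validate_network(net1, "seeded")), 0)
})

test_that("seed radii are Murray-consistent and non-increasing to the tips", {
  params <- sample_parameters(5)
  domain <- retina_domain()
  net <- grow_seed_network(params, domain, seed = 2)
  tt <- retinavasc:::network_to_trees(net)
  g <- params$murray_exponent
  for (tr in tt) {
    ch <- retinavasc:::tree_children(tr)
    n <- tr$n
    for (j in seq_len(n)) {
      kids <- ch[[j]]
      if (length(kids) >= 2) {
        expect_equal(tr$rad[j], sum(tr$rad[kids]^g)^(1 / g),
                     tolerance = 1e-9)
      }
      if (length(kids) > 0 && !is.na(tr$rad[j])) {
        # radius never grows towards the terminals (root carries no
        # feeding segment, so it has no radius of its own)
        expect_true(all(tr$rad[kids] <= tr$rad[j] + 1e-9))
      }
    }
  }
})

test_that("injected branching-angle noise is zero-mean with sd near 5 deg", {
  params <- sample_parameters(9)
  big <- retina_domain(retina_radius = 500)
  resid <- c()
  for (s in 1:8) {
    net <- grow_seed_network(params, big, seed = s)
    tt <- retinavasc:::network_to_trees(net)
    for (tr in tt) {
      ch <- retinavasc:::tree_children(tr)
      for (j in seq_len(tr$n)) {
        kids <- ch[[j]]
        if (length(kids) != 2 || is.na(tr$parent[j])) next
        p <- tr$parent[j]
        dpar <- tr$pos[j, 1:2] - tr$pos[p, 1:2]
        if (sqrt(sum(dpar^2)) == 0) next
        r <- tr$rad[kids]
        alpha <- min(r) / max(r)
        pred <- oracle_angles(alpha)  # theta1 small daughter, theta2 large
        for (ki in seq_along(kids)) {
          d <- tr$pos[kids[ki], 1:2] - tr$pos[j, 1:2]
          ang <- acos(max(-1, min(1, sum(d * dpar) /
                                    sqrt(sum(d^2) * sum(dpar^2))))) * 180 / pi
          expected <- if (r[ki] == min(r)) pred[1] else pred[2]
          resid <- c(resid, ang - expected)
        }
      }
    }
  }
  expect_gt(length(resid), 200)
  expect_lt(abs(mean(resid)), 1)        # zero-mean
  expect_equal(sd(resid), 5, tolerance = 0.25)  # sd ~ 5 degrees
})
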