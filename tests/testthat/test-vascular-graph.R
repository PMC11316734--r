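test_that("validation accepts a minimal seeded tree and flags breaches", {
  nodes <- data.frame(id = 1:2, x = c(0, 1), y = 0, z = 0,
                      kind = c("inlet-root", "terminal"))
  seg <- list(list(id = 1, from = 1, to = 2,
                   path = rbind(c(0, 0, 0), c(1, 0, 0)),
                   radius = 10, class = "artery"))
  net <- vascular_network(nodes, seg, inlet_id = 1)
  expect_equal(nrow(validate_network(net, "seeded")), 0)

  bad <- net
  bad$segments[[1]]$radius <- c(0, 0)
  rep <- validate_network(bad, "seeded")
  expect_equal(rep$code, "nonpositive-radius")
  expect_equal(rep$id, 1L)

  # arterial cycle: triangle
  nodes3 <- data.frame(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1), z = 0,
                       kind = c("inlet-root", "bifurcation", "bifurcation"))
  mk <- function(id, a, b) list(id = id, from = a, to = b,
    path = rbind(as.numeric(nodes3[a, 2:4]), as.numeric(nodes3[b, 2:4])),
    radius = 10, class = "artery")
  cyc <- vascular_network(nodes3, list(mk(1, 1, 2), mk(2, 2, 3), mk(3, 3, 1)),
                          inlet_id = 1)
  expect_true("component-not-tree" %in% validate_network(cyc, "seeded")$code)
})

test_that("network summary follows the cylinder integral and is additive", {
  net <- make_toy_fixture("single-vessel")  # r = 10 um, length 1 mm
  s <- network_summary(net)
  expect_equal(s$total_volume_um3, pi * 10^2 * 1000, tolerance = 1e-12)
  expect_equal(s$total_length_mm, 1)

  # duplicating the segment doubles the totals
  net2 <- net
  net2$nodes <- rbind(net2$nodes,
                      data.frame(id = 3, x = 2, y = 0, z = 0,
                                 kind = "terminal"))
  net2$segments[[2]] <- list(id = 2, from = 2, to = 3,
                             path = rbind(c(1, 0, 0), c(2, 0, 0)),
                             radius = rep(10, 2), class = "artery")
  s2 <- network_summary(net2)
  expect_equal(s2$total_volume_um3, 2 * s$total_volume_um3)
  expect_equal(s2$total_length_mm, 2 * s$total_length_mm)

  empty <- vascular_network(net$nodes, list(), 1, 2)
  se <- network_summary(empty)
  expect_equal(se$total_volume_um3, 0)
  expect_equal(se$total_length_mm, 0)
})

test_that("summary totals are stable under 2x path refinement", {
  net <- grown_net_fixture()$net
  s1 <- network_summary(net)
  refined <- net
  for (k in seq_along(refined$segments)) {
    s <- refined$segments[[k]]
    L <- retinavasc:::polyline_length(s$path)
    d <- retinavasc:::densify_polyline(s$path, max_step = L / (2 * nrow(s$path)),
                                       vals = s$radius)
    refined$segments[[k]]$path <- d$path
    refined$segments[[k]]$radius <- d$vals
  }
  s2 <- network_summary(refined)
  expect_equal(s2$total_volume_um3, s1$total_volume_um3, tolerance = 0.01)
  expect_equal(s2$total_length_mm, s1$total_length_mm, tolerance = 1e-9)
})

test_that("Amira writer declares counts matching the body", {
  net <- make_toy_fixture("single-vessel")
  net$segments[[1]]$path <- rbind(c(0, 0, 0), c(0.5, 0.1, 0), c(1, 0, 0))
  net$segments[[1]]$radius <- c(10, 9, 8)
  f <- withr::local_tempfile(fileext = ".am")
  write_amira_spatialgraph(net, f)
  lines <- readLines(f)
  expect_true("define VERTEX 2" %in% lines)
  expect_true("define EDGE 1" %in% lines)
  expect_true("define POINT 3" %in% lines)
  at1 <- which(trimws(lines) == "@1")
  expect_length(grep("^@\\d+$", trimws(lines)), 7)

  empty <- vascular_network(net$nodes, list(), 1, 2)
  expect_error(write_amira_spatialgraph(empty, f), "empty")
})

test_that("Amira round trip preserves counts, topology, coordinates, radii", {
  net <- grown_net_fixture()$net
  f <- withr::local_tempfile(fileext = ".am")
  write_amira_spatialgraph(net, f)
  back <- read_amira_spatialgraph(f)
  expect_equal(n_nodes(back), n_nodes(net))
  expect_equal(n_segments(back), n_segments(net))
  expect_equal(back$inlet_id, net$inlet_id)
  expect_equal(back$outlet_id, net$outlet_id)
  for (k in sample(n_segments(net), 25)) {
    expect_equal(unname(back$segments[[k]]$path),
                 unname(net$segments[[k]]$path), tolerance = 1e-6)
    expect_equal(back$segments[[k]]$radius, net$segments[[k]]$radius,
                 tolerance = 1e-6)
    expect_equal(back$segments[[k]]$class, net$segments[[k]]$class)
  }
  expect_equal(back$nodes$kind, net$nodes$kind)
})

test_that("Amira reader diagnoses corruption distinctly", {
  net <- make_toy_fixture("single-vessel")
  f <- withr::local_tempfile(fileext = ".am")
  write_amira_spatialgraph(net, f)
  lines <- readLines(f)

  # header claims an extra edge
  bad <- sub("define EDGE 1", "define EDGE 2", lines)
  f2 <- withr::local_tempfile(fileext = ".am")
  writeLines(bad, f2)
  expect_error(read_amira_spatialgraph(f2), "count mismatch")

  # non-numeric payload
  bad2 <- lines
  at7 <- which(trimws(bad2) == "@7")
  bad2[at7 + 1] <- "ten"
  writeLines(bad2, f2)
  expect_error(read_amira_spatialgraph(f2), "non-numeric")

  writeLines(c("not an amira file", lines[-1]), f2)
  expect_error(read_amira_spatialgraph(f2), "malformed header")
})

test_that("unrecognised per-edge Amira fields are kept in metadata", {
  net <- make_toy_fixture("single-vessel")
  f <- withr::local_tempfile(fileext = ".am")
  write_amira_spatialgraph(net, f)
  lines <- readLines(f)
  decl_at <- grep("EDGE \\{ int VesselClass \\} @5", lines)
  lines <- append(lines, "EDGE { float CustomScore } @8", after = decl_at)
  lines <- c(lines, "", "@8", "0.75")
  f2 <- withr::local_tempfile(fileext = ".am")
  writeLines(lines, f2)
  back <- read_amira_spatialgraph(f2)
  expect_equal(back$metadata$amira_extra$CustomScore, 0.75)
  expect_equal(n_segments(back), 1)
})

test_that("JSON dialect round trips exactly", {
  net <- grown_net_fixture()$net
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_equal(n_nodes(back), n_nodes(net))
  expect_equal(n_segments(back), n_segments(net))
  k <- n_segments(net)
  expect_equal(back$segments[[k]]$radius, net$segments[[k]]$radius)
  expect_equal(unname(back$segments[[k]]$path), unname(net$segments[[k]]$path))
  junk <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', junk)
  expect_error(read_network_json(junk), "not a retinavasc")
})
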