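test_that("single-segment flow matches the Hagen-Poiseuille closed form", {
  net <- make_toy_fixture("single-vessel")  # r = 10 um, l = 1 mm
  mu <- 3.5e-3
  sol <- solve_poiseuille(net, 50, 20, viscosity = mu)
  q_closed <- pi * (10e-6)^4 * (30 * 133.322) / (8 * mu * 1e-3) / (1e-9 / 60)
  expect_equal(sol$segments$flow_ul_min[1], q_closed, tolerance = 1e-10)
  expect_equal(total_inlet_flow(sol), q_closed, tolerance = 1e-10)

  expect_error(solve_poiseuille(net, 20, 50), "exceed")
})

test_that("series resistances add and parallel arms split evenly", {
  ser <- make_toy_fixture("series-pair")
  mu <- 3.5e-3
  sol <- solve_poiseuille(ser, 40, 10, viscosity = mu)
  R1 <- 8 * mu * 1e-3 / (pi * (10e-6)^4)
  R2 <- 8 * mu * 2e-3 / (pi * (8e-6)^4)
  q_closed <- (30 * 133.322) / (R1 + R2) / (1e-9 / 60)
  expect_equal(total_inlet_flow(sol), q_closed, tolerance = 1e-10)

  par <- make_toy_fixture("parallel-pair")
  solp <- solve_poiseuille(par, 40, 10)
  q <- solp$segments$flow_ul_min
  expect_equal(abs(q[1]), abs(q[2]), tolerance = 1e-10)
  expect_equal(abs(q[1]), total_inlet_flow(solp) / 2, tolerance = 1e-10)
})

test_that("sparse solve agrees with a dense brute-force solve to 1e-8", {
  for (seed in 1:3) {
    net <- random_closed_network(n = 60, seed = seed)
    sol <- solve_poiseuille(net, 56.2, 20)
    oracle <- dense_poiseuille_oracle(net, 56.2, 20)
    expect_equal(sol$nodes$pressure_mmHg, oracle$pressure_mmHg,
                 tolerance = 1e-8)
    expect_equal(sol$segments$flow_ul_min, oracle$flow_ul_min,
                 tolerance = 1e-8)
  }
})

test_that("mass is conserved, radii scale as k^4, reversal negates flows", {
  net <- random_closed_network(n = 80, seed = 9)
  sol <- solve_poiseuille(net, 56.2, 20)
  expect_lt(retinavasc:::flow_conservation_error(net, sol), 1e-8)

  k <- 1.3
  net2 <- net
  for (i in seq_along(net2$segments))
    net2$segments[[i]]$radius <- net2$segments[[i]]$radius * k
  sol2 <- solve_poiseuille(net2, 56.2, 20)
  expect_equal(sol2$segments$flow_ul_min, sol$segments$flow_ul_min * k^4,
               tolerance = 1e-9)

  rev <- net
  rev$inlet_id <- net$outlet_id; rev$outlet_id <- net$inlet_id
  rev$nodes$kind[match(c(net$inlet_id, net$outlet_id), rev$nodes$id)] <-
    c("outlet-root", "inlet-root")
  sol3 <- solve_poiseuille(rev, 56.2, 20)
  expect_equal(sol3$segments$flow_ul_min, -sol$segments$flow_ul_min,
               tolerance = 1e-9)

  # disconnected networks are diagnosed
  broken <- net
  broken$nodes <- rbind(broken$nodes,
                        data.frame(id = 999, x = 99, y = 99, z = 0,
                                   kind = "bifurcation"))
  expect_error(solve_poiseuille(broken, 56.2, 20), "disconnected")
})

# independent evaluation of the bolus input with the fixed conventions:
# unit-peak Gaussians, step-gated exponential washout, unit-max rescale
oracle_bolus <- function(t) {
  raw <- function(tt) {
    0.833 * exp(-(tt - 0.171 * 60)^2 / (2 * 10^2)) +
      0.336 * exp(-(tt - 0.364 * 60)^2 / (2 * 25^2)) +
      ifelse(tt >= 0.482 * 60,
             1.064 * exp(-(0.043 / 60) * (tt - 0.482 * 60)), 0)
  }
  grid <- seq(0, 0.482 * 60 + 5 * 60 / 0.043, by = 0.1)
  t0 <- grid[which.max(raw(grid))]
  peak <- max(optimize(raw, c(t0 - 0.2, t0 + 0.2), maximum = TRUE,
                       tol = 1e-10)$objective,
              raw(0.482 * 60))
  raw(t) / peak
}

test_that("the fluorescein input curve is unit-peak with a dominant first
           pass", {
  m <- retinavasc:::model_constants()$bolus
  # the curve rises from injection towards the first-pass peak
  expect_lt(bolus_concentration(0), bolus_concentration(m$t1))
  grid <- sort(c(seq(0, 600, by = 0.05), m$t3))
  expect_equal(max(bolus_concentration(grid)), 1, tolerance = 1e-6)
  expect_gte(min(bolus_concentration(grid)), 0)
  # first-pass peak exceeds the second-pass shoulder
  expect_gt(bolus_concentration(m$t1), bolus_concentration(m$t2))
  for (t in c(5, 10, 10.26, 21.84, 30, 60, 120))
    expect_equal(bolus_concentration(t), oracle_bolus(t), tolerance = 1e-9)
})

test_that("bolus propagation is pure advection with flow partitioning", {
  net <- make_toy_fixture("single-vessel")
  sol <- solve_poiseuille(net, 50, 20)
  times <- seq(0, 120, by = 0.05)
  tc <- propagate_bolus(net, sol, times = times)
  delay <- 1 / sol$segments$velocity_mm_s[1]  # l / v in seconds
  shifted <- bolus_concentration(pmax(0, times - delay))
  on <- times >= delay
  expect_equal(tc$conc[1, on], shifted[on], tolerance = 1e-9)
  expect_equal(tc$amplitude[1], 1)

  dia <- diamond_network()
  sold <- solve_poiseuille(dia, 50, 20)
  tcd <- propagate_bolus(dia, sold, times = times)
  # symmetric arms: equal delays, amplitude one half of the stem
  expect_equal(tcd$delay_s[2], tcd$delay_s[3], tolerance = 1e-12)
  expect_equal(tcd$amplitude[2], tcd$amplitude[1] / 2, tolerance = 1e-12)
  expect_equal(tcd$amplitude[3], tcd$amplitude[1] / 2, tolerance = 1e-12)

  # partition identity at the bifurcation: flow-weighted daughter signals
  # at their shared entry equal the parent signal at its exit
  q <- abs(sold$segments$flow_ul_min)
  entry2 <- bolus_concentration(pmax(0, times - tcd$delay_s[1]))
  expect_equal(q[2] * entry2 + q[3] * entry2, q[1] * entry2, tolerance = 1e-9)
})

test_that("arterio-venous delay equals total transit on a uniform path", {
  net <- make_toy_fixture("series-pair")
  sol <- solve_poiseuille(net, 50, 20)
  tc <- propagate_bolus(net, sol, times = seq(0, 180, by = 0.02))
  expected <- sum(sol$segments$length_mm / abs(sol$segments$velocity_mm_s))
  expect_equal(arteriovenous_delay(tc, net), expected, tolerance = 0.05)
})

test_that("flow and time-course tables export to CSV and join by id", {
  net <- make_toy_fixture("series-pair")
  sol <- solve_poiseuille(net, 50, 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(sol, f)
  back <- read.csv(f)
  expect_equal(back$flow_ul_min, sol$segments$flow_ul_min)
  expect_true(file.exists(sub("\\.csv$", "_nodes.csv", f)))
  tc <- propagate_bolus(net, sol, times = seq(0, 60, by = 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f2)
  long <- read.csv(f2)
  expect_equal(nrow(long), 2 * 61)
  expect_setequal(unique(long$segment_id), sol$segments$id)
})
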