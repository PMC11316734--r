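#' Solve one-dimensional Poiseuille flow on a closed network
#'
#' Each segment is a Poiseuille resistor: conductance
#' `g = pi r^4 / (8 mu l)` with the path arclength `l` and the harmonic
#' composition of `r^4` along the path (equivalently, sub-segment
#' resistances in series). Node pressures solve the linear mass
#' conservation system with Dirichlet conditions at the single arterial
#' inlet and venous outlet; segment flows are `q = g (p_from - p_to)`.
#'
#' @param net a connected [vascular_network] with inlet and outlet set.
#' @param inlet_pressure,outlet_pressure boundary pressures, mmHg.
#' @param viscosity blood viscosity, Pa s (default constant 3.5e-3).
#' @return object of class `flow_solution`: data frames `nodes`
#'   (`id`, `pressure_mmHg`) and `segments` (`id`, `from`, `to`,
#'   `flow_ul_min` signed from -> to, `velocity_mm_s`, `radius_um`,
#'   `length_mm`), plus `total_inlet_flow_ul_min`.
#' @export
solve_poiseuille <- function(net, inlet_pressure, outlet_pressure,
                             viscosity = model_constants()$viscosity) {
  stopifnot(inherits(net, "vascular_network"))
  if (is.na(net$inlet_id) || is.na(net$outlet_id))
    stop("network must designate an inlet and an outlet")
  if (inlet_pressure <= outlet_pressure)
    stop("inlet pressure must exceed outlet pressure")
  ids <- net$nodes$id
  n <- length(ids)
  g <- segment_conductances(net, viscosity)  # m^3 / (s Pa)
  from <- match(vapply(net$segments, `[[`, numeric(1), "from"), ids)
  to <- match(vapply(net$segments, `[[`, numeric(1), "to"), ids)

  comp <- igraph::components(network_igraph(net))
  if (comp$no != 1) {
    sizes <- comp$csize
    stop("network is disconnected (", comp$no, " components of sizes ",
         paste(sizes, collapse = ", "), "); flow system is singular")
  }

  # graph Laplacian with Dirichlet rows at the boundary nodes
  i_in <- match(net$inlet_id, ids)
  i_out <- match(net$outlet_id, ids)
  trip_i <- c(from, to, from, to)
  trip_j <- c(to, from, from, to)
  trip_x <- c(-g, -g, g, g)
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  b <- rep(0, n)
  bc <- c(i_in, i_out)
  pbc <- c(inlet_pressure, outlet_pressure) * PA_PER_MMHG
  # eliminate Dirichlet unknowns symmetrically
  free <- setdiff(seq_len(n), bc)
  A_ff <- A[free, free, drop = FALSE]
  b_f <- b[free] - as.vector(A[free, bc, drop = FALSE] %*% pbc)
  p <- rep(0, n)
  p[bc] <- pbc
  if (length(free) > 0)
    p[free] <- as.vector(Matrix::solve(A_ff, b_f))

  dp <- p[from] - p[to]
  q_si <- g * dp                     # m^3/s, signed from -> to
  q <- q_si / M3S_PER_ULMIN          # uL/min
  r_um <- segment_mean_radius_um(net)
  area_m2 <- pi * (r_um * 1e-6)^2
  vel <- (q_si / area_m2) * 1e3      # mm/s
  lens <- segment_lengths_mm(net)

  inc_in <- which(from == i_in | to == i_in)
  total_in <- sum(q[inc_in] * ifelse(from[inc_in] == i_in, 1, -1))
  structure(list(
    nodes = data.frame(id = ids, pressure_mmHg = p / PA_PER_MMHG),
    segments = data.frame(
      id = segment_ids(net),
      from = vapply(net$segments, `[[`, numeric(1), "from"),
      to = vapply(net$segments, `[[`, numeric(1), "to"),
      flow_ul_min = q, velocity_mm_s = vel,
      radius_um = r_um, length_mm = lens),
    total_inlet_flow_ul_min = total_in,
    viscosity = viscosity,
    inlet_pressure = inlet_pressure, outlet_pressure = outlet_pressure),
    class = "flow_solution")
}

# conductances in SI (m^3 s^-1 Pa^-1); per-point radii enter through the
# series (harmonic r^4) composition along the path
segment_conductances <- function(net, viscosity) {
  vapply(net$segments, function(s) {
    path_m <- s$path * 1e-3
    r_m <- s$radius * 1e-6
    if (nrow(path_m) < 2) return(0)
    dl <- rownorms(diff(path_m))
    r4 <- ((r_m[-1]^4 + r_m[-length(r_m)]^4) / 2)
    resist <- sum(8 * viscosity * dl / (pi * r4))
    if (resist <= 0) return(Inf)
    1 / resist
  }, numeric(1))
}

#' Total inflow through the arterial inlet
#'
#' Sum of signed flows over segments incident on the inlet node; equals the
#' outlet sum by mass conservation.
#'
#' @param sol a `flow_solution` from [solve_poiseuille()]
#' @return flow in uL/min
#' @export
total_inlet_flow <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  sol$total_inlet_flow_ul_min
}

# worst relative mass-conservation violation over interior nodes
flow_conservation_error <- function(net, sol) {
  ids <- net$nodes$id
  bal <- rep(0, length(ids)); thru <- rep(0, length(ids))
  from <- match(sol$segments$from, ids); to <- match(sol$segments$to, ids)
  for (k in seq_along(from)) {
    q <- sol$segments$flow_ul_min[k]
    bal[from[k]] <- bal[from[k]] - q; thru[from[k]] <- thru[from[k]] + abs(q)
    bal[to[k]] <- bal[to[k]] + q; thru[to[k]] <- thru[to[k]] + abs(q)
  }
  interior <- setdiff(seq_along(ids),
                      match(c(net$inlet_id, net$outlet_id), ids))
  interior <- interior[thru[interior] > 0]
  if (length(interior) == 0) return(0)
  max(abs(bal[interior]) / thru[interior])
}

#' Systemic fluorescein bolus concentration
#'
#' Input function for contrast delivery: two unit-peak Gaussian passes plus
#' an exponential washout,
#' `C(t) = s1 G(t; t1, sigma1) + s2 G(t; t2, sigma2)
#'         + alpha H(t - t3) exp(-beta (t - t3))`,
#' rescaled so the maximum over time equals one (peak concentration is
#' normalised to unity at the inlet).
#'
#' @param t time, seconds (vectorised).
#' @param model named list of bolus constants (see
#'   `model_constants()$bolus`): `s1 = 0.833`, `s2 = 0.336`,
#'   `alpha = 1.064`, first/second-pass peak times `t1 = 0.171` min,
#'   `t2 = 0.364` min, washout onset `t3 = 0.482` min, widths
#'   `sigma1 = 10` s, `sigma2 = 25` s, decay `beta = 0.043`/min.
#' @return concentration values (dimensionless, unit peak)
#' @export
bolus_concentration <- function(t, model = model_constants()$bolus) {
  stopifnot(all(t >= 0))
  bolus_raw(t, model) / bolus_peak(model)
}

bolus_raw <- function(tt, model) {
  g1 <- exp(-(tt - model$t1)^2 / (2 * model$sigma1^2))
  g2 <- exp(-(tt - model$t2)^2 / (2 * model$sigma2^2))
  wash <- ifelse(tt >= model$t3,
                 model$alpha * exp(-model$beta * (tt - model$t3)), 0)
  model$s1 * g1 + model$s2 * g2 + wash
}

# The washout term switches on discontinuously at t3, so the global
# maximum is either the (smooth) first-pass peak or the value at t3 itself.
bolus_peak <- function(model) {
  grid <- seq(0, model$t3 + 5 / model$beta, by = 0.1)
  t0 <- grid[which.max(bolus_raw(grid, model))]
  smooth <- stats::optimize(function(t) bolus_raw(t, model),
                            c(max(0, t0 - 0.2), t0 + 0.2), maximum = TRUE,
                            tol = 1e-10)$objective
  max(smooth, bolus_raw(model$t3, model))
}

#' Propagate a fluorescein bolus through a solved network
#'
#' The inlet curve is advected along the direction of flow: each node's
#' arrival delay is the transit time `sum(l / v)` accumulated along the
#' dominant-flow (maximum incoming flow) path from the inlet, and each
#' segment carries the inlet curve delayed by the arrival time at its
#' downstream end. Signal amplitude partitions with flow at branch points:
#' a segment's amplitude is the product of child/parent flow fractions
#' along its path, which collapses to `|q| / q_inlet`. Concentration itself
#' is intensive (undiluted at splits), so flow-weighted recombination at
#' merges conserves tracer exactly.
#'
#' @param net a [vascular_network]
#' @param sol matching `flow_solution`
#' @param model bolus constants, see [bolus_concentration()]
#' @param times shared time axis, seconds
#' @return object of class `time_course_set`: `times`, matrix `conc`
#'   (segments x times, unit-peak inlet concentration delayed per segment),
#'   `amplitude` (flow fraction per segment), `delay_s` (per-segment
#'   arrival time at the downstream end), `segment_id`.
#' @export
propagate_bolus <- function(net, sol, model = model_constants()$bolus,
                            times = seq(0, 120, by = 0.25)) {
  stopifnot(inherits(sol, "flow_solution"))
  segs <- sol$segments
  zero <- abs(segs$flow_ul_min) <= 0
  if (any(zero))
    warning(sum(zero), " zero-flow segment(s) excluded from bolus transport")
  ids <- net$nodes$id
  n <- length(ids)
  # orient segments along flow
  up <- ifelse(segs$flow_ul_min >= 0, segs$from, segs$to)
  dn <- ifelse(segs$flow_ul_min >= 0, segs$to, segs$from)
  q <- abs(segs$flow_ul_min)
  transit <- segs$length_mm / pmax(abs(segs$velocity_mm_s), 1e-12)

  # node arrival times along the dominant-flow (max incoming |q|) path from
  # the inlet; the oriented flow graph of a solved network is acyclic, so a
  # single sweep in topological order suffices
  arrive <- rep(NA_real_, n)
  best_in <- rep(-Inf, n)
  arrive[match(net$inlet_id, ids)] <- 0
  upi <- match(up, ids); dni <- match(dn, ids)
  live <- which(!zero)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::add_edges(g, rbind(upi[live], dni[live]))
  ord <- tryCatch(as.integer(igraph::topo_sort(g)),
                  error = function(e) NULL, warning = function(w) NULL)
  relax <- function(ks) {
    for (k in ks) {
      u <- upi[k]; v <- dni[k]
      if (is.na(arrive[u])) next
      if (q[k] > best_in[v]) {
        arrive[v] <<- arrive[u] + transit[k]
        best_in[v] <<- q[k]
      }
    }
  }
  if (!is.null(ord) && length(ord) == n) {
    pos_of <- integer(n); pos_of[ord] <- seq_len(n)
    relax(live[order(pos_of[upi[live]])])
  } else {
    # numerical cycle fallback: bounded relaxation passes
    for (pass in seq_len(min(n, 200L))) relax(live)
  }

  q_in <- max(abs(sol$total_inlet_flow_ul_min), 1e-300)
  amp <- pmin(1, q / q_in)
  delay <- arrive[match(dn, ids)]
  conc <- matrix(0, nrow(segs), length(times))
  peak <- bolus_peak(model)
  for (k in seq_along(q)) {
    if (zero[k] || is.na(delay[k])) next
    tt <- times - delay[k]
    conc[k, tt >= 0] <- bolus_raw(tt[tt >= 0], model) / peak
  }
  structure(list(times = times, conc = conc, amplitude = amp,
                 delay_s = delay, segment_id = segs$id, model = model),
            class = "time_course_set")
}

#' Arterio-venous filling delay
#'
#' Time between arterial and venous filling: the half-maximum onset of the
#' first-pass peak in the outlet-adjacent venous curve minus the half-max
#' onset of the (undelayed) arterial input at the inlet.
#'
#' @param tc a `time_course_set` from [propagate_bolus()]
#' @param net the matching [vascular_network]
#' @return delay in seconds
#' @export
arteriovenous_delay <- function(tc, net) {
  onset_of <- function(curve) {
    if (all(curve <= 0)) stop("curve never rises above zero")
    half <- max(curve) / 2
    i <- which(curve >= half)[1]
    if (i == 1) return(tc$times[1])
    # linear interpolation to the half-max crossing
    t0 <- tc$times[i - 1]; t1 <- tc$times[i]
    c0 <- curve[i - 1]; c1 <- curve[i]
    t0 + (half - c0) / (c1 - c0) * (t1 - t0)
  }
  adj <- which(vapply(net$segments, function(s)
    s$from == net$outlet_id || s$to == net$outlet_id, logical(1)))
  if (length(adj) == 0) stop("no segment adjacent to the outlet")
  k <- adj[which.max(tc$amplitude[adj])]
  inlet_curve <- bolus_concentration(tc$times, tc$model)
  onset_of(tc$conc[k, ]) - onset_of(inlet_curve)
}

#' Export a flow solution to CSV
#'
#' Writes the per-segment table (joinable to Amira/JSON exports by segment
#' id) and, alongside it, a `<stem>_nodes.csv` with nodal pressures.
#'
#' @param sol a `flow_solution`
#' @param destination path of the per-segment CSV
#' @export
write_flow_csv <- function(sol, destination) {
  utils::write.csv(sol$segments, destination, row.names = FALSE)
  nodes_path <- sub("\\.csv$", "_nodes.csv", destination)
  utils::write.csv(sol$nodes, nodes_path, row.names = FALSE)
  invisible(destination)
}

#' Export bolus time courses to CSV (long format: segment, time, conc)
#' @param tc a `time_course_set`
#' @param destination file path
#' @export
write_timecourse_csv <- function(tc, destination) {
  long <- data.frame(
    segment_id = rep(tc$segment_id, times = length(tc$times)),
    time_s = rep(tc$times, each = length(tc$segment_id)),
    concentration = as.vector(tc$conc),
    amplitude = rep(tc$amplitude, times = length(tc$times)))
  utils::write.csv(long, destination, row.names = FALSE)
  invisible(destination)
}
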