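#' Superimpose sinusoidal tortuosity on vessel paths
#'
#' Each arterial/venous path point is displaced perpendicular to the local
#' vessel axis (in the retinal plane) by the sum of two sinusoids,
#' `a0 sin(x/tau0 + d0) + a1 sin(x/tau1 + d1)` with `x` the arclength.
#' Amplitudes and periods are multiples of the local vessel radius: the
#' total amplitude `a0 + a1` is the per-class sampled factor (arteries in
#' 1-3.5 r, veins 1-7.5 r, split uniformly between the two oscillations per
#' vessel), with periods `tau0` in 15-25 r and `tau1` in 30-50 r. Phases
#' are matched at bifurcations by constraining the displacement to vanish
#' at both branch nodes: each period is snapped to the nearest value
#' with an integer number of half-waves along the branch. Capillaries are
#' left straight.
#'
#' @param net a [vascular_network]
#' @param params [sample_parameters()] output
#' @param seed integer seed
#' @return a [vascular_network] with displaced, re-densified paths
#' @export
apply_tortuosity <- function(net, params, seed = 0L) {
  set.seed(stage_seed(seed, "tortuosity"))
  for (k in seq_along(net$segments)) {
    s <- net$segments[[k]]
    if (s$class == "capillary") next
    amp_total <- if (s$class == "artery") params$tort_amplitude_artery
                 else params$tort_amplitude_vein
    split <- stats::runif(1)
    r_um <- mean(s$radius)
    net$segments[[k]] <- displace_segment(
      s,
      a0 = split * amp_total * r_um,
      a1 = (1 - split) * amp_total * r_um,
      tau0 = params$tort_period_low * r_um,
      tau1 = params$tort_period_high * r_um)
  }
  net
}

# displace one segment; amplitudes and periods in um
displace_segment <- function(s, a0, a1, tau0, tau1) {
  if (a0 + a1 <= 0) return(s)
  L_um <- polyline_length(s$path) * UM_PER_MM
  if (L_um <= 0) return(s)
  r_um <- mean(s$radius)
  step_um <- min(max(r_um, tau1 / 40), 50)
  dens <- densify_polyline(s$path, max_step = step_um * MM_PER_UM,
                           vals = s$radius)
  path <- dens$path
  x <- polyline_cumlen(path) * UM_PER_MM
  # snap periods so an integer number of half-waves fits the branch:
  # displacement is then exactly zero at both branch nodes
  snap <- function(tau) {
    m <- max(1, round(L_um / (pi * tau)))
    L_um / (pi * m)
  }
  t0 <- snap(tau0); t1 <- snap(tau1)
  disp_um <- a0 * sin(x / t0) + a1 * sin(x / t1)
  # in-plane normal to the chord axis
  chord <- path[nrow(path), 1:2] - path[1, 1:2]
  if (vnorm(chord) < 1e-12) return(s)
  nrm <- unitv(c(-chord[2], chord[1]))
  path[, 1] <- path[, 1] + disp_um * MM_PER_UM * nrm[1]
  path[, 2] <- path[, 2] + disp_um * MM_PER_UM * nrm[2]
  s$path <- path
  s$radius <- dens$vals
  s
}

#' Construct the hemispherical eye surface
#'
#' Hemisphere of the given diameter carrying macula-pit and optic-disc
#' relief, each a mixture of radial Gaussians (offsets along the surface
#' normal as a function of planar arc distance from the feature centre).
#' The mesh is a triangulated polar grid in the azimuthal-equidistant
#' chart used by [project_to_surface()].
#'
#' @param eye_diameter hemisphere diameter, mm.
#' @param domain a [retina_domain] (feature centres).
#' @param fovea_profile,disc_profile data frames with columns `amplitude`
#'   (mm, negative = pit) and `width` (mm) — one Gaussian per row.
#' @param n_ring,n_theta mesh resolution (rings x spokes).
#' @return object of class `eye_surface` with fields `radius`, `vertices`
#'   (V x 3), `faces` (F x 3), `relief` (function of planar points), and
#'   the generating parameters.
#' @export
build_eye_surface <- function(eye_diameter = 24, domain = retina_domain(),
                              fovea_profile = data.frame(
                                amplitude = c(-0.25, 0.05),
                                width = c(0.35, 0.9)),
                              disc_profile = data.frame(
                                amplitude = c(-0.30, 0.10),
                                width = c(0.45, 1.0)),
                              n_ring = 40L, n_theta = 72L) {
  R <- eye_diameter / 2
  relief <- function(pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
    out <- rep(0, nrow(pts))
    mix <- function(centre, prof) {
      d2 <- (pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2
      acc <- rep(0, nrow(pts))
      for (i in seq_len(nrow(prof)))
        acc <- acc + prof$amplitude[i] * exp(-d2 / (2 * prof$width[i]^2))
      acc
    }
    mix(domain$macula_centre, fovea_profile) +
      mix(domain$disc_centre, disc_profile)
  }
  rho_max <- min(pi * R / 2, domain$retina_radius * 1.05)
  rho <- seq(0, rho_max, length.out = n_ring + 1L)
  verts <- matrix(0, 1 + n_ring * n_theta, 2)
  idx <- 2L
  for (i in seq_len(n_ring)) {
    th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
    verts[idx:(idx + n_theta - 1L), ] <- cbind(
      domain$disc_centre[1] + rho[i + 1] * cos(th),
      domain$disc_centre[2] + rho[i + 1] * sin(th))
    idx <- idx + n_theta
  }
  faces <- list()
  ring_start <- function(i) 2L + (i - 1L) * n_theta
  for (j in seq_len(n_theta)) {  # innermost fan
    a <- ring_start(1L) + j - 1L
    b <- ring_start(1L) + (j %% n_theta)
    faces[[length(faces) + 1]] <- c(1L, a, b)
  }
  for (i in seq_len(n_ring - 1L)) {
    for (j in seq_len(n_theta)) {
      a <- ring_start(i) + j - 1L
      b <- ring_start(i) + (j %% n_theta)
      c2 <- ring_start(i + 1L) + j - 1L
      d2 <- ring_start(i + 1L) + (j %% n_theta)
      faces[[length(faces) + 1]] <- c(a, c2, d2)
      faces[[length(faces) + 1]] <- c(a, d2, b)
    }
  }
  sf <- structure(list(radius = R, centre = domain$disc_centre,
                       relief = relief, planar_vertices = verts,
                       fovea_profile = fovea_profile,
                       disc_profile = disc_profile,
                       eye_diameter = eye_diameter),
                  class = "eye_surface")
  sf$vertices <- project_points(verts3(verts, relief(verts) * 0), sf,
                                apply_relief = TRUE)
  sf$faces <- do.call(rbind, faces)
  sf
}

verts3 <- function(xy, z) cbind(xy, z)

# azimuthal-equidistant inverse: planar distance from the optic-disc centre
# equals arc length on the sphere; the planar z offset (out-of-plane
# excursions) and the relief ride along the outward surface normal
project_points <- function(pts, surface, apply_relief = TRUE) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  R <- surface$radius
  dx <- pts[, 1] - surface$centre[1]
  dy <- pts[, 2] - surface$centre[2]
  rho <- sqrt(dx^2 + dy^2)
  if (any(rho > pi * R / 2 + 1e-9))
    stop("network exceeds hemisphere coverage")
  phi <- atan2(dy, dx)
  theta <- rho / R
  nx <- sin(theta) * cos(phi)
  ny <- sin(theta) * sin(phi)
  nz <- cos(theta)
  off <- pts[, 3]
  if (apply_relief) off <- off + surface$relief(pts[, 1:2, drop = FALSE])
  cbind(surface$centre[1] + (R + off) * nx,
        surface$centre[2] + (R + off) * ny,
        -R + (R + off) * nz)
}

#' Project a planar network onto the eye surface
#'
#' Maps every node and path point by the azimuthal-equidistant inverse
#' (planar distance from the optic-disc centre becomes great-circle
#' distance on the sphere) and offsets along the surface normal by the
#' local relief plus any pre-existing out-of-plane excursion. Topology is
#' untouched; path lengths are recomputed implicitly from the new
#' coordinates.
#'
#' @param net a planar [vascular_network]
#' @param surface an [build_eye_surface()] result
#' @return the projected [vascular_network]
#' @export
project_to_surface <- function(net, surface) {
  stopifnot(inherits(surface, "eye_surface"))
  np <- project_points(as.matrix(net$nodes[, c("x", "y", "z")]), surface)
  net$nodes$x <- np[, 1]; net$nodes$y <- np[, 2]; net$nodes$z <- np[, 3]
  for (k in seq_along(net$segments)) {
    net$segments[[k]]$path <- project_points(net$segments[[k]]$path, surface)
  }
  net$metadata$projected <- TRUE
  net
}

#' Export the eye surface as a Wavefront OBJ mesh
#' @param surface an `eye_surface`
#' @param destination file path
#' @export
write_surface_obj <- function(surface, destination) {
  v <- surface$vertices; f <- surface$faces
  writeLines(c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
             destination)
  invisible(destination)
}
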