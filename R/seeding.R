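#' Optimal bifurcation angles under Murray's law
#'
#' For a bifurcation with daughter-radius ratio `alpha` (smaller/larger,
#' 0 < alpha <= 1), the deflection angles of the daughters from the parent
#' axis that minimise pumping work are
#' \deqn{\cos\theta_1 = \frac{(1+\alpha^3)^{4/3} + \alpha^4 - 1}
#'                           {2\alpha^2 (1+\alpha^3)^{2/3}}}
#' \deqn{\cos\theta_2 = \frac{(1+\alpha^3)^{4/3} + 1 - \alpha^4}
#'                           {2 (1+\alpha^3)^{2/3}}}
#' where `theta1` is the (larger) deflection of the smaller daughter and
#' `theta2` that of the larger daughter. Cosines are clamped to `[-1, 1]`
#' before `acos`; clamping is recorded on the result.
#'
#' @param alpha daughter radius ratio in (0, 1].
#' @return list of class `bifurcation_geometry` with `alpha`, `theta1`,
#'   `theta2` (degrees) and a `clamped` flag.
#' @export
bifurcation_angles <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  a3 <- (1 + alpha^3)
  c1 <- (a3^(4 / 3) + alpha^4 - 1) / (2 * alpha^2 * a3^(2 / 3))
  c2 <- (a3^(4 / 3) + 1 - alpha^4) / (2 * a3^(2 / 3))
  clamped <- (c1 < -1 || c1 > 1 || c2 < -1 || c2 > 1)
  c1 <- min(1, max(-1, c1)); c2 <- min(1, max(-1, c2))
  structure(list(alpha = alpha,
                 theta1 = acos(c1) * 180 / pi,
                 theta2 = acos(c2) * 180 / pi,
                 clamped = clamped),
            class = "bifurcation_geometry")
}

#' Daughter radii from Murray's law
#'
#' Solves `r_large^gamma + r_small^gamma = r_parent^gamma` subject to
#' `r_small / r_large = alpha`, giving
#' `r_large = r_parent / (1 + alpha^gamma)^(1/gamma)`.
#'
#' @param parent_radius parent vessel radius, micrometres.
#' @param alpha daughter ratio in (0, 1].
#' @param gamma Murray exponent (> 0).
#' @return named numeric vector `c(large = ..., small = ...)`, micrometres.
#' @export
murray_daughter_radii <- function(parent_radius, alpha, gamma) {
  if (parent_radius <= 0 || gamma <= 0 || alpha <= 0 || alpha > 1)
    stop("parent_radius and gamma must be positive; alpha in (0, 1]")
  r_large <- parent_radius / (1 + alpha^gamma)^(1 / gamma)
  c(large = r_large, small = alpha * r_large)
}

# Internal: L-system seed growth on tree structures. Returns
# list(artery = tree, vein = tree).
seed_trees <- function(params, domain, seed = 0L) {
  set.seed(stage_seed(seed, "seeding"))
  k <- params$constants
  build <- function(class, root_xy, branch_sign_first) {
    r_root <- root_radius(params, class)
    l_root <- params$interbif_length_factor * 2 * r_root * MM_PER_UM
    tr <- tree_new(c(root_xy, -l_root), class = class)
    # central vessel runs parallel to the optic nerve (z) into the plane
    apex <- tree_add_child(tr, 1L, c(root_xy, 0), r_root, origin = "seed")

    grow <- function(node, direction, radius, generation) {
      if (generation > params$seed_generations) return(invisible(NULL))
      alpha <- stats::runif(1, k$seed_alpha_range[1], k$seed_alpha_range[2])
      rr <- murray_daughter_radii(radius, alpha, params$murray_exponent)
      ang <- bifurcation_angles(alpha)
      noise <- stats::rnorm(2, 0, params$branch_angle_noise_sd)
      th_small <- (ang$theta1 + noise[1]) * pi / 180
      th_large <- (ang$theta2 + noise[2]) * pi / 180
      # steer the larger daughter toward the macula
      p0 <- tr$pos[node, 1:2]
      to_mac <- domain$macula_centre - p0
      s <- if (cross2(direction, to_mac) >= 0) 1 else -1
      d_large <- rot2(direction, s * th_large)
      d_small <- rot2(direction, -s * th_small)
      for (b in list(list(d = d_large, r = rr[["large"]]),
                     list(d = d_small, r = rr[["small"]]))) {
        len <- params$interbif_length_factor * 2 * b$r * MM_PER_UM
        p1 <- p0 + b$d * len
        if (vnorm(p1 - domain$disc_centre) > domain$retina_radius) next
        child <- tree_add_child(tr, node, c(p1, 0), b$r, origin = "seed")
        grow(child, b$d, b$r, generation + 1)
      }
      invisible(NULL)
    }
    # first bifurcation: one branch above and one below the retinal midline
    rr <- murray_daughter_radii(r_root, 1, params$murray_exponent)
    base <- unitv(c(0.35, branch_sign_first * 0.94))
    for (sgn in c(1, -1)) {
      d0 <- c(base[1], sgn * abs(base[2]))
      len <- params$interbif_length_factor * 2 * rr[["large"]] * MM_PER_UM
      p1 <- root_xy + d0 * len
      if (vnorm(p1 - domain$disc_centre) > domain$retina_radius) next
      child <- tree_add_child(tr, apex, c(p1, 0), rr[["large"]], origin = "seed")
      grow(child, d0, rr[["large"]], 2)
    }
    tr
  }
  scale <- domain$disc_radius / 9  # root separation scales with the disc
  artery <- build("artery", domain$disc_centre + c(-2 * scale, 0), 1)
  vein <- build("vein", domain$disc_centre + c(2 * scale, 0), 1)
  list(artery = artery, vein = vein)
}

#' Grow the L-system seed network
#'
#' Places the central retinal artery and vein at the optic disc (first
#' segments out-of-plane, parallel to the optic nerve), adds one branch
#' above and one below the retinal midline, then branches stochastically
#' for the configured number of generations with inter-bifurcation lengths
#' of `interbif_length_factor` times the local calibre, Murray-law radii
#' and angles, 5 degree angle noise, and the larger daughter steered toward
#' the macula. Branching stops at the configured depth or when a segment
#' would breach the retina boundary.
#'
#' @param params [sample_parameters()] output.
#' @param domain a [retina_domain].
#' @param seed integer seed for this stage.
#' @return a [vascular_network] (stage `"seeded"`)
#' @export
grow_seed_network <- function(params, domain, seed = 0L) {
  if (domain$retina_radius < 4 * domain$disc_radius / 9)
    stop("domain too small to place the vessel roots")
  tt <- seed_trees(params, domain, seed)
  trees_to_network(tt$artery, tt$vein,
                   metadata = list(stage = "seeded", seed = seed))
}
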