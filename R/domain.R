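#' Geometric description of the retinal domain
#'
#' The planar simulation domain is a disc centred on the optic disc, with a
#' macula region centred on the fovea, an avascular fovea disc inside it,
#' and the eye diameter used for the later hemispherical projection.
#' Clinically motivated defaults: macula 5.5 mm diameter centred on the
#' fovea, optic-disc region 3.6 mm diameter, fovea ~0.8 mm.
#'
#' @param retina_radius planar disc radius, mm.
#' @param disc_centre optic-disc centre (x, y), mm; the planar origin.
#' @param disc_diameter diameter of the optic-disc region, mm.
#' @param macula_centre fovea position (x, y), mm.
#' @param macula_diameter diameter of the macula region, mm.
#' @param fovea_diameter diameter of the avascular fovea, mm.
#' @param eye_diameter eye globe diameter for projection, mm.
#' @return object of class `retina_domain`
#' @export
retina_domain <- function(retina_radius = 12.5,
                          disc_centre = c(0, 0), disc_diameter = 3.6,
                          macula_centre = c(4.7, 0), macula_diameter = 5.5,
                          fovea_diameter = 0.8, eye_diameter = 24) {
  d <- list(retina_radius = retina_radius,
            disc_centre = disc_centre, disc_radius = disc_diameter / 2,
            macula_centre = macula_centre, macula_radius = macula_diameter / 2,
            fovea_radius = fovea_diameter / 2, eye_diameter = eye_diameter)
  if (d$fovea_radius >= d$macula_radius)
    stop("fovea must lie strictly inside the macula region")
  if (vnorm(macula_centre - disc_centre) + d$macula_radius > retina_radius)
    stop("macula region must lie inside the retina disc")
  if (vnorm(macula_centre - disc_centre) < d$macula_radius + d$disc_radius)
    stop("optic-disc and macula regions must be disjoint")
  structure(d, class = "retina_domain")
}

# domain scaled for fast, reduced problem sizes; geometry ratios preserved
mini_domain <- function() {
  retina_domain(retina_radius = 6, disc_centre = c(0, 0), disc_diameter = 1.8,
                macula_centre = c(2.9, 0), macula_diameter = 2.4,
                fovea_diameter = 0.5, eye_diameter = 24)
}

in_disc <- function(xy, centre, radius) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  (xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2 <= radius^2
}

#' Label points by retinal region
#'
#' Assigns each planar point to `"optic-disc"`, `"macula"` or
#' `"periphery"`; the optic-disc test takes precedence over the macula on
#' (non-physical) overlap.
#'
#' @param points n x 2 (or n x 3; z ignored) matrix of coordinates, mm.
#' @param domain a [retina_domain]
#' @return character vector of region labels
#' @export
label_regions <- function(points, domain) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  xy <- points[, 1:2, drop = FALSE]
  out <- rep("periphery", nrow(xy))
  out[in_disc(xy, domain$macula_centre, domain$macula_radius)] <- "macula"
  out[in_disc(xy, domain$disc_centre, domain$disc_radius)] <- "optic-disc"
  out
}
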