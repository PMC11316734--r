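#' Per-branch network morphometry by retinal region
#'
#' A branch is a maximal vessel path between bifurcation/terminal nodes
#' (interior path points of degree 2 are merged). For each branch the
#' length, tortuosity (path length divided by the Euclidean chord between
#' its branch points), length-weighted mean diameter and cylindrical
#' volume are reported, with the branch assigned to the region of its
#' midpoint. Branching angles are measured per bifurcation between the two
#' daughter directions over the first 50 um of each daughter path (set
#' `angle_convention = "daughter-parent"` for the angle of each daughter to
#' the parent axis instead).
#'
#' @param net a [vascular_network]
#' @param domain a [retina_domain]
#' @param classes vessel classes included (default artery + vein)
#' @param angle_convention `"daughters"` or `"daughter-parent"`
#' @return list of class `branch_metrics`: data frames `branches` and
#'   `angles`, per-region summary `by_region`, and `total_volume_um3`.
#' @export
compute_branch_metrics <- function(net, domain,
                                   classes = c("artery", "vein"),
                                   angle_convention = c("daughters",
                                                        "daughter-parent")) {
  angle_convention <- match.arg(angle_convention)
  cls <- segment_classes(net)
  segs <- net$segments[cls %in% classes]
  if (length(segs) == 0) stop("no segments of the requested classes")
  deg <- table(unlist(lapply(segs, function(s) c(s$from, s$to))))
  junction <- as.integer(names(deg)[deg != 2])
  junction <- union(junction, c(net$inlet_id, net$outlet_id))
  out_of <- new.env(parent = emptyenv())  # node -> outgoing segment idx
  in_of <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) {
    kf <- as.character(segs[[i]]$from); kt <- as.character(segs[[i]]$to)
    out_of[[kf]] <- c(out_of[[kf]], i)
    in_of[[kt]] <- c(in_of[[kt]], i)
  }
  used <- rep(FALSE, length(segs))
  branches <- list()
  for (jn in junction) {
    for (i in out_of[[as.character(jn)]] %||% integer(0)) {
      if (used[i]) next
      # walk downstream merging degree-2 chains
      chain <- i; used[i] <- TRUE
      node <- segs[[i]]$to
      while (!(node %in% junction)) {
        nxt <- setdiff(out_of[[as.character(node)]] %||% integer(0),
                       chain)
        if (length(nxt) == 0) break
        chain <- c(chain, nxt[1]); used[nxt[1]] <- TRUE
        node <- segs[[nxt[1]]]$to
      }
      path <- do.call(rbind, lapply(seq_along(chain), function(j) {
        p <- segs[[chain[j]]]$path
        if (j > 1) p <- p[-1, , drop = FALSE]
        p
      }))
      rad <- do.call(c, lapply(seq_along(chain), function(j) {
        r <- segs[[chain[j]]]$radius
        if (j > 1) r <- r[-1]
        r
      }))
      L <- polyline_length(path)
      chord <- vnorm(path[nrow(path), ] - path[1, ])
      dl <- rownorms(diff(path))
      rmid <- (rad[-1] + rad[-length(rad)]) / 2
      branches[[length(branches) + 1]] <- data.frame(
        from = segs[[chain[1]]]$from, to = node,
        class = segs[[chain[1]]]$class,
        length_um = L * UM_PER_MM,
        tortuosity = if (chord > 0) L / chord else NA_real_,
        mean_diameter_um = 2 * (if (sum(dl) > 0) sum(rmid * dl) / sum(dl)
                                else mean(rad)),
        volume_um3 = sum(pi * rmid^2 * dl * UM_PER_MM),
        mid_x = path[ceiling(nrow(path) / 2), 1],
        mid_y = path[ceiling(nrow(path) / 2), 2])
    }
  }
  br <- do.call(rbind, branches)
  br$region <- label_regions(cbind(br$mid_x, br$mid_y), domain)

  # branching angles at bifurcations
  first_dir <- function(i, reverse = FALSE) {
    p <- segs[[i]]$path
    if (reverse) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    cl <- polyline_cumlen(p)
    j <- max(2L, which(cl <= 0.05)[length(which(cl <= 0.05))])
    d <- p[j, ] - p[1, ]
    if (vnorm(d) == 0) d <- p[nrow(p), ] - p[1, ]
    unitv(d)
  }
  angles <- list()
  for (jn in setdiff(junction, c(net$inlet_id, net$outlet_id))) {
    outs <- out_of[[as.character(jn)]] %||% integer(0)
    ins <- in_of[[as.character(jn)]] %||% integer(0)
    if (length(outs) != 2) next
    d1 <- first_dir(outs[1]); d2 <- first_dir(outs[2])
    pos <- net$nodes[match(jn, net$nodes$id), ]
    if (angle_convention == "daughters") {
      a <- acos(min(1, max(-1, sum(d1 * d2)))) * 180 / pi
      angles[[length(angles) + 1]] <- data.frame(
        node = jn, angle_deg = a, x = pos$x, y = pos$y)
    } else {
      if (length(ins) != 1) next
      dp <- first_dir(ins[1], reverse = TRUE)  # points upstream; flip
      dp <- -dp
      for (d in list(d1, d2)) {
        a <- acos(min(1, max(-1, sum(dp * d)))) * 180 / pi
        angles[[length(angles) + 1]] <- data.frame(
          node = jn, angle_deg = a, x = pos$x, y = pos$y)
      }
    }
  }
  ang <- if (length(angles) > 0) do.call(rbind, angles)
         else data.frame(node = integer(0), angle_deg = numeric(0),
                         x = numeric(0), y = numeric(0))
  if (nrow(ang) > 0)
    ang$region <- label_regions(cbind(ang$x, ang$y), domain)

  by_region <- do.call(rbind, lapply(split(br, br$region), function(d)
    data.frame(region = d$region[1], n_branches = nrow(d),
               mean_length_um = mean(d$length_um),
               mean_tortuosity = mean(d$tortuosity, na.rm = TRUE),
               mean_diameter_um = mean(d$mean_diameter_um),
               volume_um3 = sum(d$volume_um3))))
  rownames(by_region) <- NULL
  structure(list(branches = br, angles = ang, by_region = by_region,
                 total_volume_um3 = sum(br$volume_um3)),
            class = "branch_metrics")
}

#' Recover the Murray exponent from a network
#'
#' At every bifurcation with a parent and exactly two daughters, solves
#' `r_p^x = r_1^x + r_2^x` for `x` by bracketed root-finding on
#' (0.5, 6); degenerate bifurcations (daughter at least as wide as the
#' parent, or no bracketed root) are skipped and counted.
#'
#' @param net a [vascular_network]
#' @param classes vessel classes examined
#' @return list with `median_exponent`, per-bifurcation `exponents`,
#'   `residuals` (at the median), and `n_skipped`.
#' @export
fit_murray_exponent <- function(net, classes = c("artery", "vein")) {
  cls <- segment_classes(net)
  segs <- net$segments[cls %in% classes]
  out_of <- new.env(parent = emptyenv())
  in_rad <- new.env(parent = emptyenv())
  for (s in segs) {
    kf <- as.character(s$from)
    out_of[[kf]] <- c(out_of[[kf]], mean(s$radius))
    in_rad[[as.character(s$to)]] <- c(in_rad[[as.character(s$to)]],
                                      mean(s$radius))
  }
  exponents <- numeric(0)
  skipped <- 0L
  for (key in ls(out_of)) {
    daughters <- out_of[[key]]
    parent <- in_rad[[key]]
    if (length(daughters) != 2 || length(parent) != 1) next
    a <- daughters[1] / parent; b <- daughters[2] / parent
    if (a >= 1 || b >= 1 || a <= 0 || b <= 0) { skipped <- skipped + 1L; next }
    f <- function(x) a^x + b^x - 1
    if (f(0.5) < 0 || f(6) > 0) { skipped <- skipped + 1L; next }
    exponents <- c(exponents, stats::uniroot(f, c(0.5, 6), tol = 1e-10)$root)
  }
  if (length(exponents) < 1)
    return(list(median_exponent = NA_real_, exponents = numeric(0),
                residuals = numeric(0), n_skipped = skipped))
  med <- stats::median(exponents)
  list(median_exponent = med, exponents = exponents,
       residuals = exponents - med, n_skipped = skipped)
}

#' Dice overlap score between two binary masks
#'
#' `D = 2 |L intersect P| / (|P| + |L|)`. When both masks are empty the
#' score is defined as 1 (reported via a message, as the formula is 0/0).
#'
#' @param prediction,label binary (logical or 0/1) arrays of equal shape
#' @return Dice score in `[0, 1]`
#' @export
dice_score <- function(prediction, label) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(label) %||% length(label)))
    stop("mask shapes differ")
  p <- as.logical(prediction); l <- as.logical(label)
  denom <- sum(p) + sum(l)
  if (denom == 0) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(p & l) / denom
}

#' Rasterise a network into an image volume
#'
#' Renders every segment as a filled tube of its local radius on a regular
#' voxel grid (centre-in-tube test via dense spherical sampling along the
#' path). Default spacings follow OCT-A-like resolution: 21 um lateral
#' (x, y) and 6.3 um axial (z). Optional per-segment intensity values
#' (e.g. flow or bolus signal); the default is a binary mask.
#'
#' @param net a [vascular_network]
#' @param lateral_um,axial_um voxel spacing, um.
#' @param bounds list with `x`, `y`, `z` ranges (mm); default the network
#'   bounding box padded by the maximum radius.
#' @param values optional per-segment intensities (length = n segments)
#' @return object of class `image_volume`: 3D array `data` (x, y, z),
#'   `spacing_um` and `origin_mm`; voxels outside every tube are 0.
#' @export
rasterize_network <- function(net, lateral_um = 21, axial_um = 6.3,
                              bounds = NULL, values = NULL) {
  stopifnot(lateral_um > 0, axial_um > 0)
  sp <- c(lateral_um, lateral_um, axial_um) * MM_PER_UM
  if (n_segments(net) == 0) {
    if (is.null(bounds)) bounds <- list(x = c(0, 1), y = c(0, 1), z = c(0, 0.1))
  }
  if (is.null(bounds)) {
    allp <- do.call(rbind, lapply(net$segments, `[[`, "path"))
    rmax <- max(unlist(lapply(net$segments, `[[`, "radius"))) * MM_PER_UM
    bounds <- list(x = range(allp[, 1]) + c(-1, 1) * (rmax + sp[1]),
                   y = range(allp[, 2]) + c(-1, 1) * (rmax + sp[2]),
                   z = range(allp[, 3]) + c(-1, 1) * (rmax + sp[3]))
  }
  dims <- pmax(1L, ceiling(c(diff(bounds$x) / sp[1], diff(bounds$y) / sp[2],
                             diff(bounds$z) / sp[3])))
  vol <- array(0, dim = dims)
  origin <- c(bounds$x[1], bounds$y[1], bounds$z[1])
  clipped <- FALSE
  if (n_segments(net) > 0) {
    vals <- values %||% rep(1, n_segments(net))
    for (k in seq_along(net$segments)) {
      s <- net$segments[[k]]
      step <- min(sp) / 2
      dens <- densify_polyline(s$path, max_step = step, vals = s$radius)
      pts <- dens$path
      rr <- dens$vals * MM_PER_UM
      for (i in seq_len(nrow(pts))) {
        r <- rr[i]
        lo <- floor((pts[i, ] - r - origin) / sp) + 1L
        hi <- ceiling((pts[i, ] + r - origin) / sp)
        if (any(hi < 1) || any(lo > dims)) { clipped <- TRUE; next }
        if (any(lo < 1) || any(hi > dims)) clipped <- TRUE
        lo <- pmax(lo, 1L); hi <- pmin(hi, dims)
        ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
        cx <- origin[1] + (ix - 0.5) * sp[1]
        cy <- origin[2] + (iy - 0.5) * sp[2]
        cz <- origin[3] + (iz - 0.5) * sp[3]
        d2 <- outer(outer((cx - pts[i, 1])^2, (cy - pts[i, 2])^2, `+`),
                    (cz - pts[i, 3])^2, `+`)
        sel <- d2 <= r^2
        if (any(sel)) {
          sub <- vol[ix, iy, iz, drop = FALSE]
          sub[sel] <- pmax(sub[sel], vals[k])
          vol[ix, iy, iz] <- sub
        }
      }
    }
  }
  if (clipped) warning("network extends beyond the raster bounds; clipped")
  structure(list(data = vol, spacing_um = c(lateral_um, lateral_um, axial_um),
                 origin_mm = origin),
            class = "image_volume")
}

#' En-face maximum-intensity projection of an image volume
#' @param vol an `image_volume`
#' @return 2D matrix (x, y): maximum intensity along the axial direction
#' @export
enface_projection <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  apply(vol$data, c(1, 2), max)
}

#' Write an image volume or en-face image as TIFF
#'
#' Requires the optional `tiff` package; intensities are rescaled to
#' `[0, 1]`.
#'
#' @param img an `image_volume` or a 2D matrix
#' @param destination file path
#' @export
write_image_tiff <- function(img, destination) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  data <- if (inherits(img, "image_volume")) img$data else img
  mx <- max(data)
  if (mx > 0) data <- data / mx
  if (length(dim(data)) == 3) {
    slices <- lapply(seq_len(dim(data)[3]), function(i) t(data[, , i]))
    tiff::writeTIFF(slices, destination)
  } else {
    tiff::writeTIFF(t(data), destination)
  }
  invisible(destination)
}

#' Regional perfusion (flow) density
#'
#' Flow delivered per unit area: the summed absolute flow through arterial
#' terminal segments whose tip lies in the region, divided by the region
#' area. Reported for the macula annulus (macula region minus the fovea)
#' and the periphery (outside macula and optic-disc regions), with their
#' ratio.
#'
#' @param net a connected [vascular_network]
#' @param sol its `flow_solution`
#' @param domain a [retina_domain]
#' @return list with `macula_density`, `periphery_density` (uL/min/mm^2)
#'   and `ratio`
#' @export
perfusion_density <- function(net, sol, domain) {
  cls <- segment_classes(net)
  term <- terminal_node_ids(net, "artery")
  # terminal arterial segments: artery segments incident on a terminal node
  q <- rep(NA_real_, length(term))
  pos <- matrix(NA_real_, length(term), 2)
  for (i in seq_along(term)) {
    k <- which(vapply(net$segments, function(s)
      (s$from == term[i] || s$to == term[i]), logical(1)) & cls == "artery")
    if (length(k) == 0) next
    q[i] <- sum(abs(sol$segments$flow_ul_min[k]))
    pos[i, ] <- as.numeric(net$nodes[match(term[i], net$nodes$id),
                                     c("x", "y")])
  }
  ok <- !is.na(q)
  q <- q[ok]; pos <- pos[ok, , drop = FALSE]
  reg <- label_regions(pos, domain)
  in_fovea <- in_disc(pos, domain$macula_centre, domain$fovea_radius)
  mac <- reg == "macula" & !in_fovea
  per <- reg == "periphery"
  a_mac <- pi * (domain$macula_radius^2 - domain$fovea_radius^2)
  a_per <- pi * domain$retina_radius^2 - pi * domain$macula_radius^2 -
    pi * domain$disc_radius^2
  md <- sum(q[mac]) / a_mac
  pd <- sum(q[per]) / a_per
  list(macula_density = md, periphery_density = pd,
       ratio = if (pd > 0) md / pd else NA_real_)
}
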