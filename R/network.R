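#' Spatial-graph model of a vascular network
#'
#' A `vascular_network` is a spatial graph: nodes with 3D positions and
#' segments carrying polyline paths with per-point radii. Coordinates are in
#' millimetres, radii in micrometres. A complete network designates one
#' arterial inlet root and one venous outlet root.
#'
#' @param nodes data frame with columns `id` (integer), `x`, `y`, `z`
#'   (millimetres) and `kind` (one of `"inlet-root"`, `"outlet-root"`,
#'   `"bifurcation"`, `"terminal"`, `"interior-path-point"`).
#' @param segments list of segments; each segment is a list with fields
#'   `id`, `from`, `to` (node ids), `path` (k x 3 matrix, mm), `radius`
#'   (length-k vector or scalar, micrometres) and `class` (one of
#'   `"artery"`, `"vein"`, `"capillary"`).
#' @param inlet_id,outlet_id node ids of the arterial inlet and venous
#'   outlet roots (`NA` while a tree is under construction).
#' @param metadata free-form named list of provenance (seed, parameters,
#'   pipeline stage).
#' @return object of class `vascular_network`
#' @export
vascular_network <- function(nodes, segments, inlet_id = NA_integer_,
                             outlet_id = NA_integer_, metadata = list()) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "x", "y", "z", "kind") %in% names(nodes)),
            is.list(segments))
  nodes$id <- as.integer(nodes$id)
  segments <- lapply(segments, function(s) {
    s$path <- as.matrix(s$path)
    colnames(s$path) <- c("x", "y", "z")
    if (length(s$radius) == 1) s$radius <- rep(s$radius, nrow(s$path))
    stopifnot(length(s$radius) == nrow(s$path))
    s$id <- as.integer(s$id)
    s$from <- as.integer(s$from)
    s$to <- as.integer(s$to)
    s
  })
  structure(list(nodes = nodes, segments = segments,
                 inlet_id = as.integer(inlet_id),
                 outlet_id = as.integer(outlet_id),
                 metadata = metadata),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  s <- network_summary(x)
  cat("<vascular_network> ", s$n_nodes, " nodes, ", s$n_segments,
      " segments\n", sep = "")
  cat("  total length: ", signif(s$total_length_mm, 4), " mm; volume: ",
      signif(s$total_volume_um3 / 1e9, 4), " mm^3 x 10^-3\n", sep = "")
  if (s$n_segments > 0)
    cat("  radius range: ", signif(s$radius_range_um[1], 4), "-",
        signif(s$radius_range_um[2], 4), " um\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)
n_segments <- function(net) length(net$segments)

node_position <- function(net, id) {
  i <- match(id, net$nodes$id)
  as.numeric(net$nodes[i, c("x", "y", "z")])
}

segment_ids <- function(net) vapply(net$segments, `[[`, integer(1), "id")
segment_classes <- function(net) vapply(net$segments, `[[`, character(1), "class")

segment_lengths_mm <- function(net) {
  vapply(net$segments, function(s) polyline_length(s$path), numeric(1))
}

# length-weighted mean radius per segment, um
segment_mean_radius_um <- function(net) {
  vapply(net$segments, function(s) {
    if (nrow(s$path) < 2) return(mean(s$radius))
    dl <- rownorms(diff(s$path))
    rmid <- (s$radius[-1] + s$radius[-length(s$radius)]) / 2
    if (sum(dl) == 0) return(mean(s$radius))
    sum(rmid * dl) / sum(dl)
  }, numeric(1))
}

#' Validate a vascular network against stage-appropriate invariants
#'
#' Reports (rather than throws) violations of the structural invariants:
#' finite positions, strictly positive radii, path/endpoint consistency, no
#' duplicated ordered segment, tree-ness of the arterial and venous
#' components before capillary closure, and single-component connectivity
#' with exactly one inlet and one outlet once capillaries are present.
#'
#' @param net a [vascular_network]
#' @param stage one of `"seeded"`, `"grown"` (arterial/venous components
#'   must each be trees) or `"connected"` (whole graph one component).
#' @return data frame of violations with columns `code`, `what`, `id`,
#'   `message`; zero rows iff the network is valid for the stage.
#' @export
validate_network <- function(net, stage = c("seeded", "grown", "connected")) {
  stage <- match.arg(stage)
  stopifnot(inherits(net, "vascular_network"))
  if (n_nodes(net) == 0) stop("empty network: nothing to validate")
  v <- list()
  add <- function(code, what, id, msg) {
    v[[length(v) + 1L]] <<- data.frame(code = code, what = what,
                                       id = as.integer(id), message = msg,
                                       stringsAsFactors = FALSE)
  }

  bad <- !is.finite(net$nodes$x) | !is.finite(net$nodes$y) | !is.finite(net$nodes$z)
  for (id in net$nodes$id[bad])
    add("nonfinite-position", "node", id, "node position has non-finite component")

  pairs <- character(0)
  for (s in net$segments) {
    if (any(!is.finite(s$radius)) || any(s$radius <= 0))
      add("nonpositive-radius", "segment", s$id, "radius must be > 0 along path")
    p0 <- node_position(net, s$from); p1 <- node_position(net, s$to)
    if (anyNA(p0) || anyNA(p1)) {
      add("dangling-endpoint", "segment", s$id, "endpoint node id not found")
    } else {
      tol <- 1e-6
      if (vnorm(s$path[1, ] - p0) > tol || vnorm(s$path[nrow(s$path), ] - p1) > tol)
        add("path-endpoint-mismatch", "segment", s$id,
            "path endpoints do not coincide with node positions")
      chord <- vnorm(p1 - p0)
      if (polyline_length(s$path) < chord * (1 - 1e-9))
        add("path-shorter-than-chord", "segment", s$id,
            "path length below Euclidean endpoint distance")
    }
    key <- paste(s$from, s$to)
    if (key %in% pairs)
      add("duplicate-segment", "segment", s$id,
          "duplicated segment between the same ordered node pair")
    pairs <- c(pairs, key)
  }

  # a complete network has exactly one inlet and one outlet root; a single
  # tree under construction may carry only one of the two
  n_in <- sum(net$nodes$kind == "inlet-root")
  n_out <- sum(net$nodes$kind == "outlet-root")
  strict <- stage == "connected"
  if (n_in > 1 || (strict && n_in != 1))
    add("inlet-count", "node", NA, sprintf("expected 1 inlet-root, found %d", n_in))
  if (n_out > 1 || (strict && n_out != 1))
    add("outlet-count", "node", NA, sprintf("expected 1 outlet-root, found %d", n_out))
  if (n_in + n_out == 0)
    add("no-root", "node", NA, "network has neither an inlet nor an outlet root")

  if (n_segments(net) > 0) {
    g <- network_igraph(net)
    cls <- segment_classes(net)
    if (stage %in% c("seeded", "grown")) {
      for (k in c("artery", "vein")) {
        gs <- igraph::subgraph_from_edges(g, which(cls == k),
                                          delete.vertices = TRUE)
        if (igraph::ecount(gs) > 0 &&
            (igraph::ecount(gs) != igraph::vcount(gs) - 1 ||
             igraph::components(gs)$no != 1))
          add("component-not-tree", "segment", NA,
              sprintf("%s component not a tree", k))
      }
    } else {
      if (igraph::components(g)$no != 1)
        add("disconnected", "node", NA,
            "connected-stage network has more than one component")
    }
  }

  if (length(v) == 0)
    return(data.frame(code = character(0), what = character(0),
                      id = integer(0), message = character(0)))
  do.call(rbind, v)
}

# undirected igraph over node ids; edge order matches net$segments
network_igraph <- function(net) {
  ids <- net$nodes$id
  ed <- t(vapply(net$segments,
                 function(s) c(match(s$from, ids), match(s$to, ids)),
                 numeric(2)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (length(net$segments) > 0) g <- igraph::add_edges(g, t(ed))
  g
}

#' Summarise a vascular network
#'
#' Totals are sums over segments; vessel volume is the cylinder integral
#' sum(pi r^2 dl) along each polyline path.
#'
#' @param net a [vascular_network]
#' @return list with counts, total length (mm), total volume (um^3), radius
#'   range (um) and a per-class breakdown data frame.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  if (n_segments(net) == 0) {
    return(list(n_nodes = n_nodes(net), n_segments = 0L,
                total_length_mm = 0, total_volume_um3 = 0,
                radius_range_um = c(NA_real_, NA_real_),
                by_class = data.frame(class = character(0), n = integer(0),
                                      length_mm = numeric(0),
                                      volume_um3 = numeric(0))))
  }
  seg_vol <- vapply(net$segments, function(s) {
    if (nrow(s$path) < 2) return(0)
    dl_um <- rownorms(diff(s$path)) * UM_PER_MM
    rmid <- (s$radius[-1] + s$radius[-length(s$radius)]) / 2
    sum(pi * rmid^2 * dl_um)
  }, numeric(1))
  lens <- segment_lengths_mm(net)
  cls <- segment_classes(net)
  rng <- range(unlist(lapply(net$segments, `[[`, "radius")))
  by_class <- do.call(rbind, lapply(split(seq_along(cls), cls), function(i) {
    data.frame(class = cls[i[1]], n = length(i), length_mm = sum(lens[i]),
               volume_um3 = sum(seg_vol[i]), stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  list(n_nodes = n_nodes(net), n_segments = n_segments(net),
       total_length_mm = sum(lens), total_volume_um3 = sum(seg_vol),
       radius_range_um = rng, by_class = by_class)
}
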