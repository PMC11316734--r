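# Pathology models: retinal vein occlusion (RVO) and progressive diabetic
# retinopathy (DR), with perfusion-based pruning of ischaemic vessels.

# scale a segment's diameter by (1 - reduction)
occlude_segment <- function(net, k, reduction) {
  stopifnot(reduction >= 0, reduction <= 1)
  f <- 1 - reduction
  # full occlusion: conductance suppressed by 1e-8 (diameter x 0.01) so the
  # linear system stays numerically regular while the branch is dead
  if (f <= 0) f <- 1e-2
  net$segments[[k]]$radius <- net$segments[[k]]$radius * f
  net
}

# vein segments downstream of segment k: on the directed (flow-oriented)
# path from k toward the outlet
downstream_vein_segments <- function(net, sol, k) {
  segs <- sol$segments
  up <- ifelse(segs$flow_ul_min >= 0, segs$from, segs$to)
  dn <- ifelse(segs$flow_ul_min >= 0, segs$to, segs$from)
  cls <- segment_classes(net)
  out <- integer(0)
  node <- dn[k]
  guard <- 0L
  while (node != net$outlet_id && guard < length(segs$id)) {
    nxt <- which(up == node & abs(segs$flow_ul_min) > 0)
    if (length(nxt) == 0) break
    nxt <- nxt[which.max(abs(segs$flow_ul_min[nxt]))]
    if (cls[nxt] == "vein") out <- c(out, nxt)
    node <- dn[nxt]
    guard <- guard + 1L
  }
  out
}

#' Simulate a retinal vein occlusion
#'
#' Picks a random artery-vein crossover on a large retinal vein (top radius
#' quartile among veins with an arterial crossing), reduces that vein's
#' diameter by the given fraction, re-solves the flow, and reports the
#' regional perfusion deficit: the loss of flow carried by the occluded
#' vein, together with the summed loss over the downstream venous path.
#'
#' @param net a connected [vascular_network]
#' @param sol its healthy `flow_solution`
#' @param seed integer seed (selects the crossing)
#' @param reduction diameter reduction fraction (default 0.8)
#' @return list with `net` (perturbed), `sol` (re-solved), `segment`
#'   (occluded segment index), `flow_change_ul_min` (drop through the
#'   occluded vein) and `downstream_change_ul_min`.
#' @export
apply_rvo <- function(net, sol, seed = 0L,
                      reduction = model_constants()$rvo_reduction) {
  stopifnot(inherits(sol, "flow_solution"))
  set.seed(stage_seed(seed, "rvo"))
  cr <- find_av_crossings(net)
  if (nrow(cr) == 0) stop("no artery-vein crossing found")
  rv <- segment_mean_radius_um(net)[cr$vein]
  big <- cr[rv >= stats::quantile(rv, 0.75), , drop = FALSE]
  if (nrow(big) == 0) stop("no crossing on a large vein")
  pick <- big[sample(nrow(big), 1), ]
  k <- pick$vein
  q_before <- abs(sol$segments$flow_ul_min[k])
  dn_before <- abs(sol$segments$flow_ul_min[downstream_vein_segments(net, sol, k)])
  net2 <- occlude_segment(net, k, reduction)
  sol2 <- solve_poiseuille(net2, sol$inlet_pressure, sol$outlet_pressure,
                           viscosity = sol$viscosity)
  q_after <- abs(sol2$segments$flow_ul_min[k])
  dn_after <- abs(sol2$segments$flow_ul_min[downstream_vein_segments(net, sol, k)])
  list(net = net2, sol = sol2, segment = k,
       flow_change_ul_min = q_before - q_after,
       downstream_change_ul_min = sum(dn_before - dn_after))
}

#' Simulate progressive diabetic retinopathy
#'
#' Arterioles with radius below the threshold are occluded in batches
#' (default 5), first in the periphery (beyond the first minimum distance
#' from the macula centre) and then at decreasing minimum distances.
#' After each batch the flow is re-solved and non-perfused vessels are
#' pruned, leaving ischaemic regions. The sequence ends when no candidate
#' arterioles remain.
#'
#' @param net a connected [vascular_network]
#' @param inlet_pressure,outlet_pressure boundary pressures, mmHg
#' @param seed integer seed
#' @param radius_threshold arteriole radius threshold, um (default 35)
#' @param batch_size occlusions per batch (default 5)
#' @param distance_schedule decreasing minimum distances from the macula
#'   centre, mm (default 10, 7.5, 5, 2.5)
#' @param domain a [retina_domain] (for macula distances)
#' @return list of steps, each `list(net, sol, occluded, min_distance)`
#' @export
apply_dr_progression <- function(net, inlet_pressure, outlet_pressure,
                                 domain, seed = 0L,
                                 radius_threshold = 35,
                                 batch_size = model_constants()$dr_batch_size,
                                 distance_schedule = model_constants()$dr_distance_schedule) {
  set.seed(stage_seed(seed, "dr"))
  steps <- list()
  cur <- net
  for (dmin in distance_schedule) {
    repeat {
      sol <- solve_poiseuille(cur, inlet_pressure, outlet_pressure)
      cls <- segment_classes(cur)
      r <- segment_mean_radius_um(cur)
      mid <- t(vapply(cur$segments, function(s)
        s$path[ceiling(nrow(s$path) / 2), 1:2], numeric(2)))
      dmac <- sqrt((mid[, 1] - domain$macula_centre[1])^2 +
                   (mid[, 2] - domain$macula_centre[2])^2)
      cand <- which(cls == "artery" & r < radius_threshold & dmac >= dmin &
                    abs(sol$segments$flow_ul_min) >
                      model_constants()$nonperfused_threshold)
      if (length(cand) == 0) break
      batch <- sample(cand, min(batch_size, length(cand)))
      for (k in batch) cur <- occlude_segment(cur, k, 1)
      sol2 <- solve_poiseuille(cur, inlet_pressure, outlet_pressure)
      cur <- prune_nonperfused(cur, sol2,
                               model_constants()$nonperfused_threshold)
      sol2 <- solve_poiseuille(cur, inlet_pressure, outlet_pressure)
      steps[[length(steps) + 1]] <- list(net = cur, sol = sol2,
                                         occluded = length(batch),
                                         min_distance = dmin)
      if (length(batch) < batch_size) break
    }
  }
  steps
}

#' Prune non-perfused vessels
#'
#' Removes segments whose absolute flow is below the threshold, then keeps
#' only the connected component containing the inlet and outlet so every
#' surviving segment lies on an inlet-to-outlet path. Idempotent.
#'
#' @param net a connected [vascular_network]
#' @param sol its `flow_solution`
#' @param flow_threshold minimum perfusion, uL/min
#' @return the pruned [vascular_network]
#' @export
prune_nonperfused <- function(net, sol,
                              flow_threshold = model_constants()$nonperfused_threshold) {
  stopifnot(inherits(sol, "flow_solution"))
  q <- abs(sol$segments$flow_ul_min[match(segment_ids(net),
                                          sol$segments$id)])
  keep <- q >= flow_threshold
  if (all(keep)) keep_net <- net
  else keep_net <- vascular_network(net$nodes, net$segments[keep],
                                    net$inlet_id, net$outlet_id,
                                    net$metadata)
  g <- network_igraph(keep_net)
  comp <- igraph::components(g)
  main <- comp$membership[match(keep_net$inlet_id, keep_net$nodes$id)]
  if (comp$membership[match(keep_net$outlet_id, keep_net$nodes$id)] != main)
    stop("pruning disconnected the inlet from the outlet: fully ischaemic network")
  node_keep <- keep_net$nodes$id[comp$membership == main]
  segs <- Filter(function(s) s$from %in% node_keep && s$to %in% node_keep,
                 keep_net$segments)
  vascular_network(keep_net$nodes[keep_net$nodes$id %in% node_keep, ],
                   segs, keep_net$inlet_id, keep_net$outlet_id,
                   keep_net$metadata)
}
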