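#' Reduced-scale simulation parameters
#'
#' Parameter set scaled for fast runs on a reduced domain ([mini_domain()]):
#' fewer seed generations, tighter leaf spacing and a shorter, coarser
#' stride schedule. Sampling distributions for calibres, the Murray
#' exponent, pressures and the macula factor are untouched.
#'
#' @param seed integer seed
#' @param overrides additional parameter overrides (win over the mini
#'   defaults)
#' @return a `simulation_parameters` object
#' @export
mini_parameters <- function(seed = 0L, overrides = list()) {
  mini <- list(seed_generations = 4, leaf_spacing = 1.5,
               lattice_stride_max = 1200, lattice_stride_min = 300,
               lattice_iterations = 3)
  mini[names(overrides)] <- overrides
  sample_parameters(seed = seed, overrides = mini)
}

#' Run the full retina-generation pipeline
#'
#' Orchestrates the stages in order: seed (L-system), grow (leaf
#' connection + multiscale lattice invasion), optimise (geometric +
#' topological + self-intersection rewiring), macula, tortuosity,
#' capillaries (circulation closure), overpass (artery-vein crossing
#' excursions), project (hemispherical surface), flow (Poiseuille) and
#' bolus (fluorescein). Any prefix subset of stages can be requested.
#' Every stage derives its own seed from the run seed, so a run is
#' reproducible end to end.
#'
#' @param seed run seed
#' @param params a `simulation_parameters` object (default: sampled from
#'   `seed` at full scale)
#' @param domain a [retina_domain] (default full-scale)
#' @param stages character vector of stages to run (in pipeline order)
#' @param out_dir optional directory for per-stage Amira/JSON/CSV snapshots
#' @param bed_spec a [capillary_bed_spec()]
#' @return list of class `retina_run`: `network`, `flow`, `timecourses`
#'   (when those stages ran), `params`, `domain`, and a `manifest` data
#'   frame of per-stage status, wall time and outputs.
#' @export
generate_retina <- function(seed = 0L, params = NULL, domain = NULL,
                            stages = c("seed", "grow", "optimize", "macula",
                                       "tortuosity", "capillaries",
                                       "overpass", "project", "flow",
                                       "bolus"),
                            out_dir = NULL,
                            bed_spec = capillary_bed_spec(
                              capillary_radius = if (!is.null(params))
                                params$capillary_radius else 4)) {
  all_stages <- c("seed", "grow", "optimize", "macula", "tortuosity",
                  "capillaries", "overpass", "project", "flow", "bolus")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  params <- params %||% sample_parameters(seed)
  domain <- domain %||% retina_domain(eye_diameter = params$eye_diameter)
  manifest <- list()
  outputs <- list(params = params, domain = domain, seed = seed)
  net <- NULL
  tt <- NULL
  snapshot <- function(stage, net) {
    if (is.null(out_dir)) return(NA_character_)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, paste0("stage-", stage, ".am"))
    write_amira_spatialgraph(net, path)
    path
  }
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    status <- "ok"; msg <- ""
    res <- tryCatch(fn(), error = function(e) {
      status <<- "error"; msg <<- conditionMessage(e); NULL
    })
    # cost trace: the growth objective after each stage, where defined
    cost <- NA_real_
    if (status == "ok") {
      if (is.environment(res$artery %||% NULL))
        cost <- tree_cost(res$artery) + tree_cost(res$vein)
      else if (inherits(res, "vascular_network"))
        cost <- network_cost(res)
    }
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, status = status,
      wall_s = as.numeric(Sys.time() - t0, units = "secs"),
      cost_um2 = cost, note = msg, stringsAsFactors = FALSE)
    if (status == "error")
      stop("stage '", stage, "' failed: ", msg)
    res
  }

  for (stage in all_stages) {
    if (!stage %in% stages) next
    if (stage == "seed") {
      tt <- run_stage("seed", function() seed_trees(params, domain, seed))
    } else if (stage == "grow") {
      tt <- run_stage("grow", function() grow_trees(tt, params, domain, seed))
    } else if (stage == "optimize") {
      tt <- run_stage("optimize", function() {
        avoid <- list(list(centre = domain$macula_centre,
                           radius = domain$macula_radius))
        tree_optimize_geometry(tt$artery, params, max_sweeps = 2L,
                               avoid = avoid)
        tree_optimize_geometry(tt$vein, params, max_sweeps = 2L,
                               avoid = avoid)
        tree_topology_pass(tt$artery, params)
        tree_topology_pass(tt$vein, params)
        tree_resolve_crossings(tt$artery, params)
        tree_resolve_crossings(tt$vein, params)
        tt
      })
    } else if (stage == "macula") {
      tt <- run_stage("macula", function()
        grow_macula_trees(tt, params, domain, seed))
    } else if (stage == "tortuosity") {
      net <- net %||% trees_to_network(tt$artery, tt$vein,
                                       metadata = run_metadata(params, seed))
      net <- run_stage("tortuosity", function()
        apply_tortuosity(net, params, seed))
    } else if (stage == "capillaries") {
      net <- net %||% trees_to_network(tt$artery, tt$vein,
                                       metadata = run_metadata(params, seed))
      net <- run_stage("capillaries", function()
        close_circulation(net, domain, bed_spec, seed))
    } else if (stage == "overpass") {
      net <- run_stage("overpass", function() resolve_av_crossings(net))
    } else if (stage == "project") {
      net <- run_stage("project", function() {
        surface <- build_eye_surface(params$eye_diameter, domain)
        project_to_surface(net, surface)
      })
    } else if (stage == "flow") {
      outputs$flow <- run_stage("flow", function()
        solve_poiseuille(net, params$inlet_pressure, params$outlet_pressure))
    } else if (stage == "bolus") {
      outputs$timecourses <- run_stage("bolus", function()
        propagate_bolus(net, outputs$flow))
    }
    if (!is.null(out_dir) && stage %in% c("grow", "capillaries", "project")) {
      snap_net <- net %||% trees_to_network(tt$artery, tt$vein,
                                            metadata = run_metadata(params, seed))
      snapshot(stage, snap_net)
    }
  }
  if (is.null(net) && !is.null(tt))
    net <- trees_to_network(tt$artery, tt$vein,
                            metadata = run_metadata(params, seed))
  outputs$network <- net
  outputs$manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    write_network_json(net, file.path(out_dir, "network.json"))
    if (!is.null(outputs$flow))
      write_flow_csv(outputs$flow, file.path(out_dir, "flow.csv"))
    utils::write.csv(outputs$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(outputs, class = "retina_run")
}

run_metadata <- function(params, seed) {
  list(seed = seed,
       murray_exponent = params$murray_exponent,
       root_artery_calibre = params$root_artery_calibre,
       root_vein_calibre = params$root_vein_calibre)
}

#' Deterministic toy fixtures with analytically known properties
#'
#' Minimal networks used throughout the test suite: a single vessel, a
#' symmetric Murray Y-bifurcation (gamma = 3), two resistances in series,
#' two identical parallel arms, an artery-vein crossing pair, and a
#' reduced-scale end-to-end retina.
#'
#' @param kind one of `"single-vessel"`, `"Y-bifurcation"`,
#'   `"series-pair"`, `"parallel-pair"`, `"crossing-pair"`, `"mini-retina"`
#' @param seed integer seed (only used by `"mini-retina"`)
#' @return a [vascular_network] (for `"mini-retina"`, a `retina_run`)
#' @export
make_toy_fixture <- function(kind = c("single-vessel", "Y-bifurcation",
                                      "series-pair", "parallel-pair",
                                      "crossing-pair", "mini-retina"),
                             seed = 1L) {
  kind <- match.arg(kind)
  nd <- function(id, x, y, z, kind2)
    data.frame(id = id, x = x, y = y, z = z, kind = kind2,
               stringsAsFactors = FALSE)
  sg <- function(id, from, to, path, radius, class)
    list(id = id, from = from, to = to, path = path, radius = radius,
         class = class)
  if (kind == "single-vessel") {
    nodes <- rbind(nd(1, 0, 0, 0, "inlet-root"), nd(2, 1, 0, 0, "outlet-root"))
    segs <- list(sg(1, 1, 2, rbind(c(0, 0, 0), c(1, 0, 0)), 10, "artery"))
    return(vascular_network(nodes, segs, 1, 2))
  }
  if (kind == "Y-bifurcation") {
    rd <- 100 / 2^(1 / 3)
    nodes <- rbind(nd(1, 0, 0, 0, "inlet-root"),
                   nd(2, 1, 0, 0, "bifurcation"),
                   nd(3, 2, 0.8, 0, "terminal"),
                   nd(4, 2, -0.8, 0, "terminal"))
    segs <- list(
      sg(1, 1, 2, rbind(c(0, 0, 0), c(1, 0, 0)), 100, "artery"),
      sg(2, 2, 3, rbind(c(1, 0, 0), c(2, 0.8, 0)), rd, "artery"),
      sg(3, 2, 4, rbind(c(1, 0, 0), c(2, -0.8, 0)), rd, "artery"))
    return(vascular_network(nodes, segs, 1, NA))
  }
  if (kind == "series-pair") {
    nodes <- rbind(nd(1, 0, 0, 0, "inlet-root"),
                   nd(2, 1, 0, 0, "interior-path-point"),
                   nd(3, 3, 0, 0, "outlet-root"))
    segs <- list(
      sg(1, 1, 2, rbind(c(0, 0, 0), c(1, 0, 0)), 10, "artery"),
      sg(2, 2, 3, rbind(c(1, 0, 0), c(3, 0, 0)), 8, "vein"))
    return(vascular_network(nodes, segs, 1, 3))
  }
  if (kind == "parallel-pair") {
    nodes <- rbind(nd(1, 0, 0, 0, "inlet-root"), nd(2, 2, 0, 0, "outlet-root"))
    segs <- list(
      sg(1, 1, 2, rbind(c(0, 0, 0), c(1, 0.5, 0), c(2, 0, 0)), 10, "artery"),
      sg(2, 1, 2, rbind(c(0, 0, 0), c(1, -0.5, 0), c(2, 0, 0)), 10, "vein"))
    return(vascular_network(nodes, segs, 1, 2))
  }
  if (kind == "crossing-pair") {
    nodes <- rbind(nd(1, -1, 0, 0, "inlet-root"), nd(2, 1, 0, 0, "terminal"),
                   nd(3, 0, -1, 0, "terminal"), nd(4, 0, 1, 0, "outlet-root"))
    segs <- list(
      sg(1, 1, 2, rbind(c(-1, 0, 0), c(1, 0, 0)), 20, "artery"),
      sg(2, 4, 3, rbind(c(0, 1, 0), c(0, -1, 0)), 30, "vein"))
    return(vascular_network(nodes, segs, 1, 4))
  }
  # mini-retina: reduced-scale end-to-end pipeline run
  generate_retina(seed = seed, params = mini_parameters(seed),
                  domain = mini_domain(),
                  stages = c("seed", "grow", "macula", "capillaries",
                             "flow", "bolus"),
                  bed_spec = capillary_bed_spec(seed_density = 3))
}
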