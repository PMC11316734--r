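#' The simulation parameter table
#'
#' The procedural retina model is governed by 26 sampled parameters, each
#' with its own sampling distribution (normal, uniform or fixed). Calibres
#' are expressed as vessel diameters (micrometres); an interpretation switch
#' on [sample_parameters()] allows the root calibres to be read as radii
#' instead. Tortuosity amplitudes and periods are dimensionless multiples of
#' the local vessel radius.
#'
#' @return data frame with one row per parameter: `name`, `dist`
#'   (`"normal"`, `"uniform"` or `"fixed"`), `p1`, `p2` (mean/sd, lo/hi, or
#'   value/NA), `units`, `stage`.
#' @export
parameter_table <- function() {
  if (!is.null(.retinavasc_cache$param_table))
    return(.retinavasc_cache$param_table)
  p <- function(name, dist, p1, p2, units, stage)
    data.frame(name = name, dist = dist, p1 = p1, p2 = p2, units = units,
               stage = stage, stringsAsFactors = FALSE)
  tab <- rbind(
    p("root_artery_calibre",    "normal",  135,  15,  "um",    "seeding"),
    p("root_vein_calibre",      "normal",  151,  15,  "um",    "seeding"),
    p("murray_exponent",        "normal",  2.4,  0.11, "",     "seeding"),
    p("interbif_length_factor", "normal",  18,   3,   "x calibre", "seeding"),
    p("branch_angle_noise_sd",  "fixed",   5,    NA,  "deg",   "seeding"),
    p("seed_generations",       "fixed",   5,    NA,  "",      "seeding"),
    p("leaf_spacing",           "fixed",   3,    NA,  "mm",    "growth"),
    p("lattice_stride_max",     "fixed",   3000, NA,  "um",    "growth"),
    p("lattice_stride_min",     "fixed",   150,  NA,  "um",    "growth"),
    p("lattice_iterations",     "fixed",   5,    NA,  "",      "growth"),
    p("macula_diameter",        "fixed",   5.5,  NA,  "mm",    "domain"),
    p("optic_disc_diameter",    "fixed",   3.6,  NA,  "mm",    "domain"),
    p("eye_diameter",           "uniform", 23,   25,  "mm",    "projection"),
    p("macula_flow_density",    "uniform", 1.5,  2.0, "ratio", "macula"),
    p("interleave_radius_threshold", "fixed", 5, NA,  "um",    "microvasculature"),
    p("inlet_pressure",         "normal",  56.2, 14.0, "mmHg", "flow"),
    p("outlet_pressure",        "normal",  20.0, 10.0, "mmHg", "flow"),
    p("dr_occlusion_radius",    "fixed",   35,   NA,  "um",    "pathology"),
    p("tort_amplitude_artery",  "uniform", 1,    3.5, "x r",   "augmentation"),
    p("tort_amplitude_vein",    "uniform", 1,    7.5, "x r",   "augmentation"),
    p("tort_period_low",        "uniform", 15,   25,  "x r",   "augmentation"),
    p("tort_period_high",       "uniform", 30,   50,  "x r",   "augmentation"),
    p("capillary_radius",       "fixed",   4,    NA,  "um",    "microvasculature"),
    p("pinning_fraction",       "fixed",   0.5,  NA,  "x leaf spacing", "growth"),
    p("macula_sparsity",        "fixed",   0.3,  NA,  "probability", "macula"),
    p("macula_angle_limit",     "fixed",   90,   NA,  "deg",   "macula"))
  .retinavasc_cache$param_table <- tab
  tab
}

# Fixed model constants that are not part of the sampled parameter set:
# cost exponents, trimming/merging thresholds, pathology defaults, the
# fluorescein bolus constants, and the blood viscosity.
model_constants <- function() {
  list(
    cost_rho = 1, cost_lambda = 1,
    trim_alpha_threshold = 0.2,
    wbe_short_fraction = 0.5,
    terminal_radius = 12,        # um, radius of newly grown terminal vessels
    fovea_diameter = 0.8,        # mm, avascular central disc
    seed_alpha_range = c(0.4, 0.9),
    voronoi_seed_density = 25,   # points / mm^2
    rvo_reduction = 0.8,
    dr_batch_size = 5L,
    dr_distance_schedule = c(10, 7.5, 5, 2.5),  # mm from macula centre
    nonperfused_threshold = 1e-4,               # uL/min
    viscosity = 3.5e-3,                         # Pa s, constant model
    bolus = list(s1 = 0.833, s2 = 0.336, alpha = 1.064,
                 t1 = 0.171 * 60, t2 = 0.364 * 60, t3 = 0.482 * 60,  # s
                 sigma1 = 10, sigma2 = 25,                           # s
                 beta = 0.043 / 60))                                 # 1/s
}

#' Sample a full simulation parameter set
#'
#' Draws every parameter in [parameter_table()] from its distribution,
#' deterministically for a given seed. Sets violating the physical
#' constraints (positive calibres, lengths, pressures and Murray exponent;
#' arterial pressure strictly above venous) are resampled; the number of
#' resampling rounds is recorded in the result's metadata.
#'
#' @param seed non-negative integer seed.
#' @param overrides named list of parameter values that replace sampling
#'   (must use names from [parameter_table()]).
#' @param calibre_interpretation `"diameter"` (default) or `"radius"`:
#'   how the root artery/vein calibre values are to be read downstream.
#' @return object of class `simulation_parameters`: named list of values
#'   plus `constants`, `calibre_interpretation` and `metadata`.
#' @export
sample_parameters <- function(seed = 0L, overrides = list(),
                              calibre_interpretation = c("diameter", "radius")) {
  stopifnot(is.numeric(seed), seed >= 0)
  calibre_interpretation <- match.arg(calibre_interpretation)
  tab <- parameter_table()
  unknown <- setdiff(names(overrides), tab$name)
  if (length(unknown) > 0)
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  set.seed(stage_seed(seed, "parameters"))
  resamples <- 0L
  repeat {
    vals <- stats::setNames(vector("list", nrow(tab)), tab$name)
    for (i in seq_len(nrow(tab))) {
      vals[[i]] <- switch(tab$dist[i],
        normal = stats::rnorm(1, tab$p1[i], tab$p2[i]),
        uniform = stats::runif(1, tab$p1[i], tab$p2[i]),
        fixed = tab$p1[i])
    }
    for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
    ok <- vals$root_artery_calibre > 0 && vals$root_vein_calibre > 0 &&
      vals$murray_exponent > 0 && vals$interbif_length_factor > 0 &&
      vals$inlet_pressure > 0 && vals$outlet_pressure > 0 &&
      vals$inlet_pressure > vals$outlet_pressure
    if (ok) break
    resamples <- resamples + 1L
    if (resamples > 1000L) stop("parameter constraints unsatisfiable")
  }
  structure(c(vals,
              list(constants = model_constants(),
                   calibre_interpretation = calibre_interpretation,
                   metadata = list(seed = seed, resamples = resamples))),
            class = "simulation_parameters")
}

# root calibres as radii (um), honouring the interpretation switch
root_radius <- function(params, which = c("artery", "vein")) {
  which <- match.arg(which)
  cal <- if (which == "artery") params$root_artery_calibre else params$root_vein_calibre
  if (identical(params$calibre_interpretation, "radius")) cal else cal / 2
}

#' Save / load simulation parameters as YAML
#'
#' The YAML file holds the sampled values (plus the calibre interpretation
#' and seed); loading validates every key against [parameter_table()] and
#' rejects unknown names. A partial config overrides only the named values,
#' the rest being sampled from the given seed.
#'
#' @param params a `simulation_parameters` object.
#' @param destination,source file paths.
#' @param seed seed used to sample parameters absent from the config.
#' @rdname parameters_io
#' @export
save_parameters <- function(params, destination) {
  stopifnot(inherits(params, "simulation_parameters"))
  keep <- intersect(names(params), parameter_table()$name)
  obj <- c(params[keep],
           list(.calibre_interpretation = params$calibre_interpretation,
                .seed = params$metadata$seed))
  yaml::write_yaml(obj, destination, precision = 15)
  invisible(destination)
}

#' @rdname parameters_io
#' @export
load_parameters <- function(source, seed = 0L) {
  obj <- yaml::yaml.load_file(source)
  interp <- obj$.calibre_interpretation %||% "diameter"
  seed <- obj$.seed %||% seed
  obj <- obj[!startsWith(names(obj), ".")]
  tab <- parameter_table()
  unknown <- setdiff(names(obj), tab$name)
  if (length(unknown) > 0)
    stop("unknown parameter name(s) in config: ",
         paste(unknown, collapse = ", "))
  for (nm in names(obj)) {
    row <- tab[tab$name == nm, ]
    if (row$dist == "uniform" && (obj[[nm]] < row$p1 || obj[[nm]] > row$p2))
      stop("value for ", nm, " outside its support [", row$p1, ", ", row$p2, "]")
  }
  sample_parameters(seed = seed, overrides = obj,
                    calibre_interpretation = interp)
}
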