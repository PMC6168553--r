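## Configuration and the umbrella pipeline tying the stages together:
## simulate -> index -> refine (-> build -> interfaces).

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = c("simulate", "index", "refine"),
    simulate = list(
      twist_deg = -101.124, rise_ang = 4.848, handedness = "left",
      radius_ang = 25, length_ang = 280, box_px = 256,
      pixel_size_ang = 1.21, n_images = 24, step_ang = 70,
      noise_sigma = 0, blob_sigma_px = 1),
    index = list(min_snr = 5, max_l = 64, rel_tol = 0.02, n_max = 10),
    refine = list(
      pitch_min = 17.2, pitch_max = 17.4, pitch_step = 0.02,
      upt_min = 3.4, upt_max = 3.6, upt_step = 0.02,
      z_max = 0.22, r_max = Inf),
    build = list(monomer_path = NULL, n_subunits = 10),
    interfaces = list(annotation_path = NULL, cutoff = 4.0, max_offset = 4))
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]; unknown keys, at
#' the top level or within a stage block, are rejected. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param ... Overrides: top-level keys (`seed`, `out_dir`, `stages`) or
#'   stage blocks (`simulate`, `index`, `refine`, `build`, `interfaces`)
#'   given as named lists of parameter overrides.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("configuration overrides must be named")
  for (key in names(over)) {
    if (!key %in% names(cfg))
      stop("unknown configuration key: ", key)
    if (is.list(cfg[[key]]) && key != "stages") {
      sub <- over[[key]]
      bad <- setdiff(names(sub), names(cfg[[key]]))
      if (length(bad))
        stop("unknown configuration key: ", key, "$",
             paste(bad, collapse = ", "))
      cfg[[key]][names(sub)] <- sub
    } else {
      cfg[key] <- list(over[[key]])   # [<- keeps NULL values (e.g. out_dir)
    }
  }
  known_stages <- c("simulate", "index", "refine", "build", "interfaces")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (length(cfg$stages)) {
    pos <- match(cfg$stages, known_stages)
    if (any(diff(pos) != 1L))
      stop("stages must form a contiguous subset of: ",
           paste(known_stages, collapse = " -> "))
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the configured contiguous subset of
#' simulate -> index -> refine -> build -> interfaces on synthetic data,
#' carrying intermediate products forward, and returns (optionally writes) a
#' JSON-serialisable report. Identical config and seed give an identical
#' report. All numeric report fields carry units in their names.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report` with one element per executed
#'   stage; written to `<out_dir>/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = config$stages)
  state <- list()
  for (stage in config$stages) {
    state <- switch(stage,
      simulate = .stage_simulate(config, state),
      index = .stage_index(config, state),
      refine = .stage_refine(config, state),
      build = .stage_build(config, state),
      interfaces = .stage_interfaces(config, state))
    report[[stage]] <- state$report
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

.stage_simulate <- function(config, state) {
  p <- config$simulate
  sym <- helical_symmetry(p$twist_deg, p$rise_ang)
  au <- data.frame(r = p$radius_ang, phi = 0, z = 0)
  fil <- make_filament(au, sym, p$length_ang)
  stack <- project_filament(fil, pixel_size_ang = p$pixel_size_ang,
                            box = p$box_px,
                            noise = noise_model(p$noise_sigma,
                                                seed = config$seed),
                            n_images = p$n_images, step_ang = p$step_ang,
                            blob_sigma_px = p$blob_sigma_px)
  state$stack <- stack
  state$sim_params <- p
  state$report <- list(twist_deg = p$twist_deg, rise_ang = p$rise_ang,
                       n_subunits = fil$n_subunits, n_images = p$n_images,
                       noise_sigma = p$noise_sigma)
  state
}

.stage_index <- function(config, state) {
  if (is.null(state$stack)) stop("index stage needs a simulated stack")
  p <- config$index
  ps <- average_power_spectrum(state$stack)
  heights <- detect_layer_lines(ps, min_snr = p$min_snr)
  if (length(heights) < 2) stop("fewer than two layer lines detected")
  strength <- attr(heights, "strength")
  fit <- fit_repeat(as.numeric(heights), max_l = p$max_l, rel_tol = p$rel_tol)
  radius <- state$sim_params$radius_ang
  orders <- vapply(as.numeric(heights), function(h) {
    assign_bessel_order(layer_line_first_max(ps, h), radius, p$n_max)$n
  }, integer(1))
  # the pitch line is the strongest n = 1 line (sinc tails of a strong line
  # can contaminate the order assignment of weak neighbours); the meridional
  # line is the strongest n = 0 line above it (l = u > t)
  pit_cand <- which(orders == 1L)
  if (!length(pit_cand))
    stop("could not identify the pitch (n=1) layer line")
  pit <- pit_cand[which.max(strength[pit_cand])]
  mer_cand <- which(orders == 0L & fit$l > fit$l[pit])
  if (!length(mer_cand))
    stop("could not identify the meridional (n=0) layer line")
  mer <- mer_cand[which.max(strength[mer_cand])]
  idx <- index_symmetry(fit$c_ang, fit$l[mer], fit$l[pit],
                        handedness = state$sim_params$handedness)
  state$spectrum <- ps
  state$indexed <- idx
  state$report <- list(
    c_ang = fit$c_ang,
    lines = data.frame(l = fit$l, height_inv_ang = heights, n = orders),
    u = idx$repeat_$u, t = idx$repeat_$t,
    twist_deg = idx$symmetry$twist_deg, rise_ang = idx$symmetry$rise_ang,
    pitch_ang = idx$pitch_ang)
  state
}

.stage_refine <- function(config, state) {
  if (is.null(state$spectrum)) stop("refine stage needs an indexed spectrum")
  p <- config$refine
  sp <- state$sim_params
  grid <- grid_spec(p$pitch_min, p$pitch_max, p$pitch_step,
                    p$upt_min, p$upt_max, p$upt_step)
  mask <- default_correlation_mask(state$spectrum, z_max = p$z_max,
                                   r_max = p$r_max)
  fit <- grid_refine(state$spectrum, grid, radius = sp$radius_ang,
                     length_ang = sp$length_ang, handedness = sp$handedness,
                     mask = mask,
                     blob_sigma_ang = sp$blob_sigma_px * sp$pixel_size_ang)
  sym <- pitch_units_to_symmetry(fit$pitch_ang, fit$units_per_turn,
                                 sp$handedness)
  state$refined <- fit
  state$refined_symmetry <- sym
  state$report <- list(pitch_ang = fit$pitch_ang,
                       units_per_turn = fit$units_per_turn,
                       twist_deg = sym$twist_deg, rise_ang = sym$rise_ang,
                       n_nodes = length(fit$grid$pitch) * length(fit$grid$upt),
                       max_correlation = max(fit$surface))
  state
}

.stage_build <- function(config, state) {
  p <- config$build
  if (is.null(p$monomer_path))
    stop("build stage needs `build$monomer_path` (a PDB/mmCIF monomer)")
  monomer <- read_structure(p$monomer_path)
  sym <- if (!is.null(state$refined_symmetry)) state$refined_symmetry
         else helical_symmetry(config$simulate$twist_deg,
                               config$simulate$rise_ang)
  asm <- build_filament(monomer, sym, c(0L, p$n_subunits - 1L))
  ext <- radial_extents(asm)
  state$assembly <- asm
  state$report <- list(n_subunits = p$n_subunits,
                       twist_deg = sym$twist_deg, rise_ang = sym$rise_ang,
                       inner_radius_ang = unname(ext["inner"]),
                       outer_radius_ang = unname(ext["outer"]))
  state
}

.stage_interfaces <- function(config, state) {
  if (is.null(state$assembly)) stop("interfaces stage needs a built assembly")
  p <- config$interfaces
  ann <- if (is.null(p$annotation_path)) read_interface_annotations()
         else read_interface_annotations(p$annotation_path)
  contacts <- subunit_contacts(state$assembly, p$cutoff, p$max_offset)
  cls <- classify_offsets(contacts, ann)
  state$report <- list(n_contacts = nrow(contacts), offsets = cls)
  state
}
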