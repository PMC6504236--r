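## Configuration, run orchestration and fixture generation. A run is fully
## described by a plain-text (YAML) config; every run writes its resolved
## config next to its outputs so results are reproducible from the bundle.

run_config_keys <- c("surface", "mechanics", "translocation", "solver",
                     "simulation", "analysis", "stages", "seed", "out_dir")

#' Assemble and validate a run configuration
#'
#' @param surface list: `kind`, `dims` (named list), optional `resolution`.
#' @param mechanics list passed to [filament_properties()] /
#'   [membrane_properties()] plus `Rcell` (um) for the binding scan.
#' @param translocation list passed to [translocation_params()].
#' @param solver list: `n_u`, `n_v` grid for the continuum solve.
#' @param simulation list: `n_filaments`, `max_steps` for the Langevin stage.
#' @param analysis list: `band_halfwidth_deg`, `seam_exclusion`.
#' @param stages character subset of `c("binding", "langevin",
#'   "fokker_planck", "analysis")`.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir output directory.
#' @return A validated `run_config`.
#' @export
run_config <- function(surface = list(kind = "cylinder"),
                       mechanics = list(), translocation = list(),
                       solver = list(), simulation = list(),
                       analysis = list(),
                       stages = c("langevin", "fokker_planck", "analysis"),
                       seed = 1L, out_dir = tempfile("mrebdyn_run_")) {
  cfg <- list(surface = surface, mechanics = mechanics,
              translocation = translocation, solver = solver,
              simulation = simulation, analysis = analysis,
              stages = match.arg(stages, c("binding", "langevin",
                                           "fokker_planck", "analysis"),
                                 several.ok = TRUE),
              seed = as.integer(seed), out_dir = out_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$surface$kind)) stop("config needs surface$kind")
  allowed <- list(
    mechanics = c("rf", "Y", "kappa_s", "Lf", "kb", "kt", "Hs", "gamma",
                  "p", "Rcell", "adhesion", "n_mesh", "half_width_factor"),
    translocation = names(formals(translocation_params)),
    solver = c("n_u", "n_v"),
    simulation = c("n_filaments", "max_steps", "n_u", "n_v", "chunk"),
    analysis = c("band_halfwidth_deg", "seam_exclusion"))
  for (blk in names(allowed)) {
    bad <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read / write run configurations (YAML)
#' @param path file path.
#' @return `read_run_config`: a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_seed <- function(master, stage)
  (as.integer(master) * 131L +
     match(stage, c("binding", "langevin", "fokker_planck", "analysis"))) %%
  2147483647L

surface_from_config <- function(cfg) {
  sp <- do.call(surface_spec,
                c(list(kind = cfg$surface$kind), cfg$surface$dims,
                  if (!is.null(cfg$surface$resolution))
                    list(resolution = unlist(cfg$surface$resolution))))
  make_surface(sp)
}

field_table <- function(surface, field) {
  g <- field$grid
  xyz <- sg_eval(surface, g$U, g$V)$r
  data.frame(u = g$U, v = g$V, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             dA = as.vector(field$dA), NF = as.vector(field$NF),
             CF = as.vector(field$CF))
}

#' Execute a configured run
#'
#' Runs the requested stages (binding-energy scan, Langevin ensemble,
#' Fokker-Planck steady state, enrichment analysis), writes all tables as CSV
#' plus a machine-readable JSON summary of the headline quantities, and
#' writes the resolved configuration beside the outputs.
#'
#' @param cfg a [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with the in-memory results and `out_dir`.
#' @export
run <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  surface <- surface_from_config(cfg)
  tp <- do.call(translocation_params, cfg$translocation)
  res <- list(out_dir = cfg$out_dir)
  summary <- list(surface = surface$kind, seed = cfg$seed)

  if ("binding" %in% cfg$stages) {
    note("stage binding: free-energy scan")
    mk <- cfg$mechanics
    fil <- do.call(filament_properties,
                   mk[intersect(names(mk), c("rf", "Y", "kappa_s", "Lf"))])
    mem <- do.call(membrane_properties,
                   mk[intersect(names(mk), c("kb", "kt", "Hs", "gamma", "p"))])
    sc <- binding_scan(fil, mem, Rcell = mk$Rcell %||% 0.5,
                       adhesion = mk$adhesion %||% 0)
    utils::write.csv(
      data.frame(theta_rad = sc$table$theta, deltaG_kBT = sc$table$deltaG,
                 filament_energy = sc$table$E_filament,
                 membrane_energy = sc$table$E_membrane),
      file.path(cfg$out_dir, "binding_scan.csv"), row.names = FALSE)
    summary$binding <- list(theta_star = sc$theta_star,
                            well_depth_kBT = sc$well_depth,
                            phase = sc$phase)
    res$binding <- sc
  }
  if ("langevin" %in% cfg$stages) {
    note("stage langevin: ", cfg$simulation$n_filaments %||% 1000,
         " filament lifetimes")
    sim <- cfg$simulation
    en <- simulate_ensemble(surface, tp,
                            n_filaments = sim$n_filaments %||% 1000L,
                            n_u = sim$n_u %||% cfg$solver$n_u,
                            n_v = sim$n_v %||% cfg$solver$n_v,
                            max_steps = sim$max_steps %||% 10000L,
                            chunk = sim$chunk %||% 4000L,
                            seed = stage_seed(cfg$seed, "langevin"))
    utils::write.csv(field_table(surface, en$field),
                     file.path(cfg$out_dir, "langevin_field.csv"),
                     row.names = FALSE)
    res$langevin <- en
  }
  if ("fokker_planck" %in% cfg$stages) {
    note("stage fokker_planck: steady-state solve")
    fp <- solve_steady_state(surface, tp, n_u = cfg$solver$n_u,
                             n_v = cfg$solver$n_v)
    utils::write.csv(field_table(surface, fp),
                     file.path(cfg$out_dir, "fokker_planck_field.csv"),
                     row.names = FALSE)
    res$fokker_planck <- fp
  }
  if ("analysis" %in% cfg$stages &&
      surface$kind %in% c("spherocylinder", "torus", "bent_rod",
                          "bulged_cylinder")) {
    note("stage analysis: region enrichment")
    an <- cfg$analysis
    pairs <- switch(surface$kind,
                    spherocylinder = c("bulk", "pole"),
                    torus = , bent_rod = c("inner", "midline"),
                    bulged_cylinder = c("bulge", "cylinder"))
    enr <- list()
    for (nm in intersect(c("langevin", "fokker_planck"), names(res))) {
      fl <- if (nm == "langevin") res$langevin$field else res$fokker_planck
      part <- region_partition(
        surface, fl$grid,
        band_halfwidth = (an$band_halfwidth_deg %||% 15) * pi / 180,
        seam_exclusion = an$seam_exclusion %||% 0)
      enr[[nm]] <- region_enrichment(fl, part, pairs[1], pairs[2])
    }
    summary$enrichment <- c(
      list(regions = paste(pairs, collapse = "/")), enr,
      if (length(enr) == 2) list(discrepancy = abs(enr[[1]] - enr[[2]])))
    res$enrichment <- enr
  }
  summary$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(res)
}

#' Write reference fixtures
#'
#' Emits the eight reference surface specifications with the default
#' dimensions, a three-filament canned trajectory set with a fixed seed, and
#' a small table of analytic reference values (cylinder curvatures, torus
#' inner/midline concentration ratio, total-curvature integrals) used by the
#' test suite and for manual checking.
#'
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c("cylinder", "spherocylinder", "torus", "helix_tube",
             "ellipsoid", "bulged_cylinder", "undulating_cylinder",
             "noncircular_cylinder")
  paths <- character(0)
  for (k in kinds) {
    sp <- surface_spec(k)
    p <- file.path(out_dir, paste0("surface_", k, ".yaml"))
    yaml::write_yaml(list(kind = sp$kind, dims = sp$dims,
                          resolution = sp$resolution), p)
    paths <- c(paths, p)
  }
  tp <- translocation_params(seed = 424242L)
  s <- make_surface("cylinder")
  en <- simulate_ensemble(s, tp, n_filaments = 3L, max_steps = 200L,
                          record_trajectories = TRUE, seed = 424242L)
  tr <- do.call(rbind, lapply(seq_along(en$trajectories), function(i)
    cbind(filament_id = i, en$trajectories[[i]])))
  p <- file.path(out_dir, "canned_trajectories.csv")
  utils::write.csv(tr, p, row.names = FALSE)
  paths <- c(paths, p)
  tor <- surface_spec("torus")
  ref <- data.frame(
    quantity = c("cylinder_k1", "cylinder_k2",
                 "torus_inner_midline_ratio",
                 "gauss_bonnet_closed", "gauss_bonnet_torus"),
    value = c(1 / surface_spec("cylinder")$dims$radius, 0,
              tor$dims$centerline_radius /
                (tor$dims$centerline_radius - tor$dims$tube_radius),
              4 * pi, 0))
  p <- file.path(out_dir, "analytic_reference.csv")
  utils::write.csv(ref, p, row.names = FALSE)
  invisible(c(paths, p))
}
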