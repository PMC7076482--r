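#' Pipeline configuration
#'
#' Builds and validates the configuration driving the end-to-end chain
#' (deposition -> voxelization -> pore analysis -> flow -> mechanics).
#' Unknown keys are rejected outright; quantities may carry unit suffixes
#' (\code{"2.5 nm"}, \code{"1000 Pa"}, \code{"9 GPa"}), the likeliest
#' silent-error source in a code that mixes nm geometry with SI solvers.
#'
#' @param config a named list (typically from \code{read_pipeline_config})
#'   with sections \code{seeds}, \code{deposition}, \code{voxel},
#'   \code{flow}, \code{mechanics}, \code{output}.
#' @return validated \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  known_top <- c("seeds", "deposition", "voxel", "flow", "mechanics",
                 "output")
  .check_keys(config, known_top, "top level")
  seeds <- as.integer(config$seeds %||% 1L)
  dep <- config$deposition %||% list()
  .check_keys(dep, c("domain_x", "domain_y", "fibril_diameter",
                     "fibril_length", "target_count",
                     "target_volume_fraction", "clip_radius"),
              "deposition")
  vx <- config$voxel %||% list()
  .check_keys(vx, c("size"), "voxel")
  fl <- config$flow %||% list()
  .check_keys(fl, c("enabled", "dP", "density", "viscosity", "tol",
                    "max_outer", "bc_lateral", "characteristic_diameter",
                    "pad_z"), "flow")
  me <- config$mechanics %||% list()
  .check_keys(me, c("enabled", "Ef", "failure_strain", "max_strain",
                    "steps", "grip_axis"), "mechanics")
  outp <- config$output %||% list()
  .check_keys(outp, c("dir", "vtk"), "output")

  len <- function(x, def) if (is.null(x)) def else
    parse_quantity(x, "length")
  cfg <- list(
    seeds = seeds,
    deposition = list(
      domain_x = len(dep$domain_x, 500),
      domain_y = len(dep$domain_y, 500),
      fibril_diameter = len(dep$fibril_diameter, 10),
      fibril_length = if (is.null(dep$fibril_length)) NULL else
        parse_quantity(dep$fibril_length, "length"),
      target_count = if (is.null(dep$target_count)) NULL else
        as.integer(dep$target_count),
      target_volume_fraction = dep$target_volume_fraction,
      clip_radius = if (is.null(dep$clip_radius)) NULL else
        parse_quantity(dep$clip_radius, "length")),
    voxel = list(size = len(vx$size, 2.5)),
    flow = list(
      enabled = isTRUE(fl$enabled %||% TRUE),
      dP = if (is.null(fl$dP)) 1000 else parse_quantity(fl$dP, "pressure"),
      density = fl$density %||% 998,
      viscosity = fl$viscosity %||% 1e-3,
      tol = fl$tol %||% 1e-5,
      max_outer = as.integer(fl$max_outer %||% 500L),
      bc_lateral = fl$bc_lateral %||% "periodic",
      characteristic_diameter =
        len(fl$characteristic_diameter, len(dep$fibril_diameter, 10)),
      pad_z = as.integer(fl$pad_z %||% 4L)),
    mechanics = list(
      enabled = isTRUE(me$enabled %||% FALSE),
      Ef = if (is.null(me$Ef)) 9e9 else parse_quantity(me$Ef, "pressure"),
      failure_strain = me$failure_strain,
      max_strain = me$max_strain %||% 0.02,
      steps = as.integer(me$steps %||% 5L),
      grip_axis = me$grip_axis %||% "y"),
    output = list(dir = outp$dir, vtk = isTRUE(outp$vtk)))
  class(cfg) <- "pipeline_config"
  cfg
}

.check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
  invisible()
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full simulation chain
#'
#' For each seed: deposit a network, voxelize, extract the pore graph,
#' solve Stokes flow and summarize it, attribute per-pore fluxes and
#' relate them to pore diameter and obstruction, and (optionally) run the
#' beam tension simulation. One failing seed is reported in its entry and
#' never aborts the batch. With a fixed configuration the report is
#' reproducible bit for bit.
#'
#' @param config a \code{pipeline_config} (or plain list, validated on
#'   entry).
#' @return a \code{run_report}: list with provenance (version, config
#'   hash) and one complete entry per seed.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  report <- list(version = as.character(utils::packageVersion("pitflow")),
                 config_hash = .config_hash(config),
                 seeds = list())
  outdir <- config$output$dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  for (seed in config$seeds) {
    entry <- tryCatch(.run_one_seed(config, seed, outdir),
                      error = function(e)
                        list(seed = seed, error = conditionMessage(e)))
    report$seeds[[as.character(seed)]] <- entry
  }
  class(report) <- "run_report"
  report
}

.run_one_seed <- function(config, seed, outdir) {
  dep <- config$deposition
  params <- deposition_params(
    domain_x = dep$domain_x, domain_y = dep$domain_y,
    fibril_diameter = dep$fibril_diameter,
    fibril_length = dep$fibril_length %||% 20,
    target_count = dep$target_count,
    target_volume_fraction = dep$target_volume_fraction,
    seed = seed, clip_radius = dep$clip_radius)
  net <- deposit_network(params)
  grid <- voxelize(net, config$voxel$size)
  pg <- extract_pore_graph(grid)
  entry <- list(
    seed = seed,
    n_fibrils = nrow(net$fibrils),
    thickness_nm = net$thickness,
    porosity = porosity(grid),
    volume_fraction = volume_fraction(net),
    n_pores = nrow(pg$pores),
    n_constrictions = nrow(pg$constrictions),
    median_constriction_nm = if (nrow(pg$constrictions) > 0)
      stats::median(pg$constrictions$diameter_nm) else NA_real_,
    percolates = percolates(grid))
  if (config$flow$enabled) {
    if (!entry$percolates) {
      entry$flow <- list(no_through_flow = TRUE, Q = 0, permeability = NA,
                         reynolds = 0)
    } else {
      fl <- config$flow
      field <- solve_stokes(grid,
                            fluid_props(fl$density, fl$viscosity),
                            dP = fl$dP, bc_lateral = fl$bc_lateral,
                            pad_z = fl$pad_z, tol = fl$tol,
                            max_outer = fl$max_outer)
      fs <- summarize_flow(field, fl$characteristic_diameter)
      flux <- per_pore_flux(field, pg)
      obr <- obstruction_report(pg)
      openness <- 1 - obr$obstruction_index
      entry$flow <- list(
        Q = fs$Q, permeability = fs$permeability,
        conductivity_per_area = fs$conductivity_per_area,
        mean_velocity = fs$mean_velocity,
        pore_velocity = fs$pore_velocity,
        reynolds = fs$reynolds, flux_spread = fs$flux_spread,
        momentum_residual = field$mom_res,
        cor_flux_openness = .safe_spearman(flux, openness),
        cor_flux_diameter = .safe_spearman(flux, obr$diameter_nm))
      if (isTRUE(config$output$vtk) && !is.null(outdir)) {
        wc <- (field$w[, , seq_len(dim(field$u)[3])] +
               field$w[, , 1 + seq_len(dim(field$u)[3])]) / 2
        write_vtk_image(file.path(outdir,
                                  sprintf("flow_seed%d.vtk", seed)),
                        list(speed = sqrt(field$u^2 + field$v^2 + wc^2),
                             pressure = field$p,
                             solid = array(as.numeric(field$mask),
                                           dim(field$mask))),
                        field$voxel_size)
      }
    }
  }
  if (config$mechanics$enabled) {
    me <- config$mechanics
    model <- build_beam_model(net, grip_axis = me$grip_axis)
    if (model$connected) {
      resp <- uniaxial_tension(model,
                               fibril_material(me$Ef, me$failure_strain),
                               max_strain = me$max_strain,
                               steps = me$steps)
      entry$mechanics <- list(
        effective_modulus = resp$effective_modulus,
        peak_force = max(resp$response$force),
        n_broken = length(resp$broken),
        cox_modulus = cox_modulus(entry$volume_fraction, me$Ef))
    } else {
      entry$mechanics <- list(disconnected = TRUE)
    }
  }
  if (!is.null(outdir)) {
    write_fibril_csv(net, file.path(outdir,
                                    sprintf("network_seed%d.csv", seed)))
    write_pore_graph(pg, file.path(outdir, sprintf("pores_seed%d", seed)))
  }
  entry
}

.safe_spearman <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> version ", x$version, ", ", length(x$seeds),
      " seed(s), config ", substr(x$config_hash, 1, 8), "\n", sep = "")
  for (e in x$seeds) {
    if (!is.null(e$error)) {
      cat("  seed ", e$seed, ": ERROR ", e$error, "\n", sep = "")
    } else {
      cat("  seed ", e$seed, ": ", e$n_fibrils, " fibrils, porosity ",
          signif(e$porosity, 3),
          if (!is.null(e$flow$permeability))
            paste0(", k = ", signif(e$flow$permeability, 3), " m^2"),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a run report to JSON
#'
#' @param report a \code{run_report}.
#' @param path output JSON file.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
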