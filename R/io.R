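#' Write / read a fibril network as CSV with a JSON sidecar
#'
#' The CSV holds one fibril per row (deposit_index, endpoints, diameter,
#' all nm); the sidecar \code{<path>.json} records the deposition
#' parameters, seed and package version so a network can be re-created or
#' audited.
#'
#' @param network a \code{fibril_network}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_fibril_csv <- function(network, path) {
  f <- network$fibrils
  out <- data.frame(deposit_index = f$deposit_index,
                    x0 = f$x0, y0 = f$y0, z0 = f$z0,
                    x1 = f$x1, y1 = f$y1, z1 = f$z1,
                    diameter_nm = f$diameter)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(
    version = as.character(utils::packageVersion("pitflow")),
    seed = network$seed,
    domain = as.list(network$domain),
    thickness_nm = network$thickness,
    params = .params_to_list(network$params))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.params_to_list <- function(p) {
  lapply(unclass(p), function(v)
    if (is.function(v)) "<function>" else v)
}

#' @rdname write_fibril_csv
#' @export
read_fibril_csv <- function(path) {
  tab <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  fibrils <- data.frame(deposit_index = tab$deposit_index,
                        x0 = tab$x0, y0 = tab$y0, z0 = tab$z0,
                        x1 = tab$x1, y1 = tab$y1, z1 = tab$z1,
                        diameter = tab$diameter_nm)
  dom <- if (!is.null(meta)) c(x = meta$domain$x, y = meta$domain$y) else
    c(x = max(tab$x0, tab$x1), y = max(tab$y0, tab$y1))
  params <- deposition_params(domain_x = dom[["x"]], domain_y = dom[["y"]],
                              target_count = nrow(fibrils),
                              seed = meta$seed %||% NA_integer_)
  net <- .new_network(fibrils, params)
  net$seed <- meta$seed %||% NA_integer_
  net
}

#' Write a pore graph as JSON plus CSV tables
#'
#' @param pg a \code{pore_graph}.
#' @param prefix output path prefix; writes \code{<prefix>.json},
#'   \code{<prefix>_pores.csv}, \code{<prefix>_constrictions.csv}.
#' @export
write_pore_graph <- function(pg, prefix) {
  utils::write.csv(pg$pores, paste0(prefix, "_pores.csv"),
                   row.names = FALSE)
  utils::write.csv(pg$constrictions, paste0(prefix, "_constrictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(voxel_size_nm = pg$voxel_size, dim = pg$dim,
         nodes = pg$pores, edges = pg$constrictions),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(prefix)
}

#' Export a voxel field as legacy ASCII VTK image data
#'
#' Writes cell-centred scalar fields (mask, distance map, pressure,
#' velocity magnitude, ...) on the regular voxel lattice in the legacy
#' VTK STRUCTURED_POINTS format readable by ParaView.
#'
#' @param path output file (.vtk).
#' @param fields named list of 3D arrays with identical dimensions.
#' @param voxel_size voxel edge (nm; written as the VTK spacing).
#' @param origin grid corner.
#' @export
write_vtk_image <- function(path, fields, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  d <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pitflow field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", voxel_size, voxel_size,
                       voxel_size),
               sprintf("CELL_DATA %d", prod(d))), con)
  for (nmf in names(fields)) {
    a <- fields[[nmf]]
    stopifnot(all(dim(a) == d))
    writeLines(c(sprintf("SCALARS %s float 1", nmf),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(as.vector(a), format = "g", digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export nodal values of a beam model as VTK polydata
#'
#' @param path output file (.vtk).
#' @param model a \code{beam_model}.
#' @param values named list of per-node scalar vectors (e.g. the U2
#'   displacement field).
#' @export
write_vtk_beam <- function(path, model, values = list()) {
  nodes <- model$nodes
  el <- model$elements
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pitflow beam model", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(nodes))), con)
  writeLines(apply(nodes, 1, function(r) paste(formatC(r, format = "g"),
                                               collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", nrow(el), 3 * nrow(el)), con)
  writeLines(sprintf("2 %d %d", el$n1 - 1L, el$n2 - 1L), con)
  if (length(values)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nmv in names(values)) {
      writeLines(c(sprintf("SCALARS %s float 1", nmv),
                   "LOOKUP_TABLE default"), con)
      writeLines(paste(formatC(values[[nmv]], format = "g", digits = 7),
                       collapse = " "), con)
    }
  }
  invisible(path)
}
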