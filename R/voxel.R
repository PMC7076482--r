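#' Voxelize a fibril network
#'
#' Discretizes the membrane on a regular grid: a voxel is solid iff its
#' centre lies within one fibril radius of some fibril axis. The grid
#' spans the deposition tile laterally and the stack thickness vertically;
#' the two z-faces are the flow inlet and outlet.
#'
#' @param network a \code{fibril_network}.
#' @param voxel_size edge length of a voxel (nm). A resolution of at most
#'   a quarter of the fibril diameter is required to resolve the
#'   constrictions; coarser grids are accepted with a warning.
#' @param nz optional number of z-layers (defaults to covering the stack
#'   thickness).
#' @return a \code{voxel_grid}: list with \code{mask} (logical array,
#'   \code{TRUE} = solid), \code{voxel_size} (nm), \code{origin} (nm) and
#'   \code{dim}.
#' @export
voxelize <- function(network, voxel_size, nz = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  f <- network$fibrils
  dmin <- if (nrow(f) > 0) min(f$diameter) else Inf
  if (voxel_size > dmin / 4)
    warning("voxel_size exceeds fibril_diameter/4; constrictions may be ",
            "under-resolved")
  nx <- max(1L, as.integer(round(network$domain[["x"]] / voxel_size)))
  ny <- max(1L, as.integer(round(network$domain[["y"]] / voxel_size)))
  if (is.null(nz))
    nz <- max(1L, as.integer(ceiling(network$thickness / voxel_size)))
  mask <- .voxelize_cpp(.fibril_matrix(network), nx, ny, as.integer(nz),
                        voxel_size, 0, 0, 0)
  new_voxel_grid(mask, voxel_size)
}

#' Construct a voxel grid from a logical mask
#'
#' @param mask 3D logical array, \code{TRUE} = solid.
#' @param voxel_size voxel edge (nm).
#' @param origin physical position of the grid corner (nm).
#' @return a \code{voxel_grid}.
#' @export
new_voxel_grid <- function(mask, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, voxel_size > 0)
  structure(list(mask = mask, voxel_size = voxel_size,
                 origin = origin, dim = dim(mask)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dim, collapse = " x "), " voxels @ ",
      x$voxel_size, " nm, solid fraction ",
      signif(mean(x$mask), 4), "\n", sep = "")
  invisible(x)
}

#' Porosity (fluid fraction) of a voxel grid
#' @param grid a \code{voxel_grid}.
#' @export
porosity <- function(grid) 1 - mean(grid$mask)

#' Does the fluid phase percolate from inlet to outlet?
#'
#' Independent flood-fill check on the voxel mask (6-connectivity,
#' lateral faces treated as walls): TRUE iff some fluid component touches
#' both z-faces.
#'
#' @param grid a \code{voxel_grid}.
#' @export
percolates <- function(grid) {
  d <- grid$dim
  if (all(grid$mask)) return(FALSE)
  lab <- .flood_components_cpp(grid$mask, d[1], d[2], d[3])
  bottom <- unique(as.vector(lab[, , 1]))
  top <- unique(as.vector(lab[, , d[3]]))
  any(setdiff(intersect(bottom, top), 0L) > 0L)
}

#' Euclidean distance map of the fluid phase
#'
#' Distance (nm) from each fluid voxel centre to the nearest solid voxel
#' centre, computed with an exact separable distance transform.
#'
#' @param grid a \code{voxel_grid}.
#' @return numeric 3D array (nm); solid voxels are 0.
#' @export
distance_map <- function(grid) {
  d <- grid$dim
  .edt_cpp(grid$mask, d[1], d[2], d[3]) * grid$voxel_size
}
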