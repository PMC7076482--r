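#' Analytic fixture geometries
#'
#' Exact voxel masks of simple geometries with known flow solutions, used
#' as solver oracles: a plane slit, a cylindrical tube, a periodic square
#' array of transverse cylinders, a through-channel next to a sealed
#' cavity, and twin parallel channels. Dimensions are nm.
#'
#' @param name one of \code{"slit"}, \code{"tube"},
#'   \code{"cylinder_array"}, \code{"sealed_cavity"},
#'   \code{"twin_channel"}.
#' @param params named list of dimensions, all nm:
#'   \describe{
#'     \item{slit}{\code{gap}, \code{wall} (solid slab each side),
#'       \code{width} (y extent), \code{length} (z extent).}
#'     \item{tube}{\code{radius}, \code{tile} (x = y extent),
#'       \code{length}.}
#'     \item{cylinder_array}{\code{tile} (y = z unit cell edge), and
#'       \code{radius} or \code{solid_fraction}; \code{span} (x extent,
#'       cylinder axis direction). Flow is along z, transverse to the
#'       cylinder axes; use periodic boundaries.}
#'     \item{sealed_cavity}{\code{tile}, \code{length}, \code{channel_radius},
#'       \code{cavity_radius}.}
#'     \item{twin_channel}{\code{tile}, \code{length}, \code{radius}.}
#'   }
#' @param voxel_size voxel edge (nm).
#' @return a \code{voxel_grid}.
#' @export
fixture_geometry <- function(name, params, voxel_size) {
  stopifnot(voxel_size > 0)
  h <- voxel_size
  vox <- function(len) max(1L, as.integer(round(len / h)))
  centers <- function(n) (seq_len(n) - 0.5) * h
  grid3 <- function(nx, ny, nz) {
    list(x = centers(nx), y = centers(ny), z = centers(nz),
         d = c(nx, ny, nz))
  }
  name <- match.arg(name, c("slit", "tube", "cylinder_array",
                            "sealed_cavity", "twin_channel"))
  p <- params
  mask <- switch(name,
    slit = {
      gapv <- vox(p$gap); wallv <- vox(p$wall %||% p$gap)
      nx <- gapv + 2L * wallv
      ny <- vox(p$width %||% p$gap)
      nz <- vox(p$length)
      m <- array(TRUE, c(nx, ny, nz))
      m[wallv + seq_len(gapv), , ] <- FALSE
      m
    },
    tube = {
      nx <- vox(p$tile); nz <- vox(p$length)
      g <- grid3(nx, nx, nz)
      cx <- nx * h / 2
      r2 <- outer((g$x - cx)^2, (g$y - cx)^2, "+")
      m <- array(TRUE, g$d)
      inside <- r2 <= p$radius^2
      for (k in seq_len(nz)) m[, , k] <- !inside
      m
    },
    cylinder_array = {
      tile <- p$tile
      R <- p$radius %||% sqrt((p$solid_fraction * tile^2) / pi)
      nyz <- vox(tile)
      nx <- vox(p$span %||% (4 * h))
      g <- grid3(nx, nyz, nyz)
      cc <- nyz * h / 2
      r2 <- outer((g$y - cc)^2, (g$z - cc)^2, "+")
      m <- array(FALSE, g$d)
      solid <- r2 <= R^2
      for (i in seq_len(nx)) m[i, , ] <- solid
      m
    },
    sealed_cavity = {
      nx <- vox(p$tile); nz <- vox(p$length)
      g <- grid3(nx, nx, nz)
      m <- array(TRUE, c(nx, nx, nz))
      ccx <- nx * h / 4; ccy <- nx * h / 2
      r2 <- outer((g$x - ccx)^2, (g$y - ccy)^2, "+")
      open <- r2 <= p$channel_radius^2
      for (k in seq_len(nz)) m[, , k][open] <- FALSE
      # sealed spherical cavity centred in the other half, mid-thickness
      cvx <- 3 * nx * h / 4; cvz <- nz * h / 2
      for (k in seq_len(nz)) {
        dz2 <- (g$z[k] - cvz)^2
        if (dz2 > p$cavity_radius^2) next
        rr <- outer((g$x - cvx)^2, (g$y - ccy)^2, "+") + dz2
        m[, , k][rr <= p$cavity_radius^2] <- FALSE
      }
      m
    },
    twin_channel = {
      nx <- vox(p$tile); nz <- vox(p$length)
      g <- grid3(nx, nx, nz)
      m <- array(TRUE, c(nx, nx, nz))
      cy <- nx * h / 2
      for (cx in c(nx * h / 4, 3 * nx * h / 4)) {
        r2 <- outer((g$x - cx)^2, (g$y - cy)^2, "+")
        open <- r2 <= p$radius^2
        for (k in seq_len(nz)) m[, , k][open] <- FALSE
      }
      m
    })
  new_voxel_grid(mask, h)
}
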