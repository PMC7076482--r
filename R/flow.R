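#' Fluid properties
#'
#' Density and dynamic viscosity of the permeating liquid. Defaults are
#' water at 20 degrees C: 998 kg/m^3 and 1e-3 Pa s.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @export
fluid_props <- function(density = 998, viscosity = 1e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Solve steady creeping (Stokes) flow through a voxelized membrane
#'
#' Solves the Stokes momentum balance (pressure gradient balancing viscous
#' stresses) together with incompressibility on a staggered marker-and-cell
#' grid over the voxel mask, with no-slip on all solid surfaces. The flow
#' is driven through the thickness either by a pressure difference applied
#' between the two z-faces (mode \code{"pressure"}, with a few open fluid
#' layers padded onto each face as inlet/outlet reservoirs) or by a body
#' force with z-periodicity (mode \code{"periodic"}, useful for unit-cell
#' permeability of periodic fixtures). Lateral faces are periodic by
#' default.
#'
#' The outer iteration interleaves red-black SOR momentum sweeps with an
#' exact pressure projection; the projection Poisson problem is solved by
#' conjugate gradients preconditioned with a geometric multigrid V-cycle.
#' Iteration stops when the relative momentum residual falls below
#' \code{tol}. Discrete continuity is enforced to near round-off by a
#' final tight projection, so the cross-sectional flux is the same at
#' every z-plane.
#'
#' A non-percolating geometry is not an error: it returns a zero flow
#' field flagged \code{no_through_flow}.
#'
#' @param grid a \code{voxel_grid} of the membrane.
#' @param fluid a \code{\link{fluid_props}}.
#' @param dP applied pressure drop (Pa, >= 0) across the thickness.
#' @param bc_lateral \code{"periodic"} or \code{"wall"} (free-slip).
#' @param bc_z \code{"pressure"} or \code{"periodic"}.
#' @param pad_z fluid reservoir layers added on each z-face in pressure
#'   mode.
#' @param tol relative continuity (Schur) residual tolerance.
#' @param max_outer outer (Uzawa-CG) iteration cap.
#' @param mom_tol relative tolerance of the inner momentum solves.
#' @param continuation solve first on a 2x-coarsened grid and refine
#'   (speeds up large membranes); \code{NULL} decides by grid size.
#' @param verbose print residuals.
#' @return a \code{flow_field}: velocity component arrays \code{u,v,w}
#'   (m/s; \code{w} is the through-thickness component on z-faces),
#'   pressure \code{p} (Pa), the padded mask, pad size, grid metadata,
#'   applied \code{dP}, fluid properties, residuals.
#' @export
solve_stokes <- function(grid, fluid = fluid_props(), dP = 1000,
                         bc_lateral = c("periodic", "wall"),
                         bc_z = c("pressure", "periodic"),
                         pad_z = 4L, tol = 1e-8, max_outer = 500L,
                         mom_tol = 1e-4,
                         continuation = NULL, verbose = FALSE) {
  bc_lateral <- match.arg(bc_lateral)
  bc_z <- match.arg(bc_z)
  stopifnot(dP >= 0)
  d <- grid$dim
  h <- .nm(grid$voxel_size)
  mu <- fluid$viscosity

  if (bc_z == "pressure") {
    pad <- as.integer(pad_z)
    mask <- array(FALSE, d + c(0, 0, 2 * pad))
    mask[, , pad + seq_len(d[3])] <- grid$mask
  } else {
    pad <- 0L
    mask <- grid$mask
  }
  dm <- dim(mask)

  if (bc_z == "pressure" && !percolates(grid)) {
    zero <- array(0, dm)
    return(structure(list(
      u = zero, v = zero, w = array(0, dm + c(0, 0, 1)),
      p = array(0, dm), mask = mask, pad = pad,
      voxel_size = grid$voxel_size, membrane_dim = d,
      dP = dP, fluid = fluid, bc_lateral = bc_lateral, bc_z = bc_z,
      mom_res = 0, div_res = 0, outer = 0L,
      no_through_flow = TRUE), class = "flow_field"))
  }

  # thickness over which the pressure drop acts (membrane + reservoirs)
  Lz <- dm[3] * h
  qbot <- dP / mu
  qtop <- 0
  gz <- if (bc_z == "periodic") dP / (mu * Lz) else 0
  zmode <- if (bc_z == "periodic") 1L else 0L
  lat <- if (bc_lateral == "periodic") 0L else 1L

  if (is.null(continuation)) continuation <- prod(dm) > 1.5e6
  init <- list(u = NULL, v = NULL, w = NULL, q = NULL)
  if (continuation && all(dm %% 2 == 0)) {
    cm <- .coarsen_mask(mask)
    cres <- .stokes_cpp(cm, dim(cm)[1], dim(cm)[2], dim(cm)[3], 2 * h,
                        qbot, qtop, gz, zmode, lat,
                        mom_tol, 100L, max(tol, 1e-6), max_outer, 50L,
                        verbose)
    init <- .prolong_flow(cres, dm, zmode)
  }
  res <- .stokes_cpp(mask, dm[1], dm[2], dm[3], h, qbot, qtop, gz,
                     zmode, lat, mom_tol, 100L, tol, max_outer, 50L,
                     verbose, init$u, init$v, init$w, init$q)
  structure(list(
    u = res$u, v = res$v, w = res$w, p = res$q * mu,
    mask = mask, pad = pad, voxel_size = grid$voxel_size,
    membrane_dim = d, dP = dP, fluid = fluid,
    bc_lateral = bc_lateral, bc_z = bc_z,
    mom_res = res$mom_res, div_res = res$div_res, outer = res$outer,
    no_through_flow = FALSE), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> ", paste(dim(x$u), collapse = " x "),
      " cells, dP = ", x$dP, " Pa, momentum residual ",
      signif(x$mom_res, 3), if (isTRUE(x$no_through_flow))
        " (no through-flow)" else "", "\n", sep = "")
  invisible(x)
}

# coarse cell solid if at least half of its 8 children are solid
.coarsen_mask <- function(mask) {
  d <- dim(mask)
  stopifnot(all(d %% 2 == 0))
  m <- array(0L, d)
  m[mask] <- 1L
  s <- m[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2)] +
       m[seq(2, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2)] +
       m[seq(1, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2)] +
       m[seq(2, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2)] +
       m[seq(1, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2)] +
       m[seq(2, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2)] +
       m[seq(1, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2)] +
       m[seq(2, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2)]
  s >= 4
}

# nearest-neighbour prolongation of a coarse solve as fine initial guess
.prolong_flow <- function(cres, dm, zmode) {
  up <- function(a, dfine) {
    ix <- pmin((seq_len(dfine[1]) + 1L) %/% 2L, dim(a)[1])
    iy <- pmin((seq_len(dfine[2]) + 1L) %/% 2L, dim(a)[2])
    iz <- pmin((seq_len(dfine[3]) + 1L) %/% 2L, dim(a)[3])
    a[ix, iy, iz, drop = FALSE]
  }
  wdim <- if (zmode == 1L) dm else dm + c(0, 0, 1)
  list(u = up(cres$u, dm), v = up(cres$v, dm),
       w = up(cres$w, wdim), q = up(cres$q, dm))
}

#' Darcy-scale summary of a flow solution
#'
#' Volumetric flow rate, superficial and pore velocities, Darcy
#' permeability, hydraulic conductivity per membrane area, and the
#' particle Reynolds number of a solved flow field. The flow rate is the
#' z-flux integrated over a cross-section; by discrete mass conservation
#' every section gives the same value (the maximum relative spread over
#' planes is reported). Permeability follows one-dimensional Darcy's law
#' \code{k = Q mu L / (A dP)} with \code{A} the full tile area and
#' \code{L} the membrane thickness.
#'
#' @param field a \code{flow_field}.
#' @param characteristic_diameter length scale (nm) for the Reynolds
#'   number; conventionally the fibril diameter (particle-based Re).
#'   Defaults to the 10 nm default fibril diameter.
#' @return a \code{flow_summary} list: \code{Q} (m^3/s),
#'   \code{mean_velocity} (superficial, m/s), \code{pore_velocity}
#'   (volume-averaged magnitude in the membrane pore space, m/s),
#'   \code{permeability} (m^2), \code{conductivity_per_area}
#'   (m s^-1 Pa^-1), \code{reynolds}, \code{flux_spread} (max relative
#'   plane-to-plane flux deviation).
#' @export
summarize_flow <- function(field, characteristic_diameter = 10) {
  h <- .nm(field$voxel_size)
  fluid <- field$fluid
  dm <- dim(field$u)
  # plane fluxes through every z-face inside the membrane region
  wfaces <- if (field$bc_z == "pressure") dm[3] + 1L else dm[3]
  flux <- vapply(seq_len(wfaces), function(k) sum(field$w[, , k]) * h^2,
                 numeric(1))
  Q <- mean(flux)
  spread <- if (abs(Q) > 0) max(abs(flux - Q)) / abs(Q) else 0
  A <- dm[1] * dm[2] * h^2
  Lmem <- field$membrane_dim[3] * h
  mean_v <- Q / A
  kz <- field$pad + seq_len(field$membrane_dim[3])
  fluidvox <- !field$mask[, , kz, drop = FALSE]
  if (any(fluidvox)) {
    wc <- (field$w[, , kz, drop = FALSE] +
           field$w[, , kz + if (field$bc_z == "pressure") 1L else 0L,
                   drop = FALSE]) / 2
    if (field$bc_z == "periodic") {
      kz2 <- ifelse(kz %% dm[3] + 1L > dm[3], 1L, kz %% dm[3] + 1L)
      wc <- (field$w[, , kz, drop = FALSE] + field$w[, , kz2, drop = FALSE]) / 2
    }
    speed <- sqrt(field$u[, , kz, drop = FALSE]^2 +
                  field$v[, , kz, drop = FALSE]^2 + wc^2)
    pore_v <- mean(speed[fluidvox])
  } else pore_v <- 0
  k <- if (field$dP > 0) Q * fluid$viscosity * Lmem / (A * field$dP) else NA_real_
  cond <- if (field$dP > 0) Q / (A * field$dP) else NA_real_
  Re <- fluid$density * pore_v * .nm(characteristic_diameter) /
    fluid$viscosity
  structure(list(Q = Q, mean_velocity = mean_v, pore_velocity = pore_v,
                 permeability = k, conductivity_per_area = cond,
                 reynolds = Re, flux_spread = spread,
                 dP = field$dP, membrane_thickness_nm = Lmem / 1e-9,
                 dP_undefined = field$dP == 0),
            class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat("<flow_summary> Q = ", signif(x$Q, 4), " m^3/s, k = ",
      signif(x$permeability, 4), " m^2, Re = ", signif(x$reynolds, 3),
      ", flux spread ", signif(x$flux_spread, 2), "\n", sep = "")
  invisible(x)
}

#' Attribute through-flux to individual pores
#'
#' For each pore of the watershed segmentation, sums the through-thickness
#' (z) velocity over the pore's voxels slice by slice, averages over the
#' slices the pore spans, and normalizes by the total flow rate. Over any
#' full cross-section the pore fractions add up to one; pores that carry
#' no flow (sealed cavities) get a fraction near zero.
#'
#' @param field a \code{flow_field} solved on the same grid the pore
#'   graph was extracted from.
#' @param pg a \code{pore_graph}.
#' @return named numeric vector: flux fraction per pore id.
#' @export
per_pore_flux <- function(field, pg) {
  if (!all(pg$dim == field$membrane_dim))
    stop("flow field and pore graph come from different grids")
  h <- .nm(field$voxel_size)
  dmem <- pg$dim
  n <- nrow(pg$pores)
  if (n == 0) return(setNames(numeric(0), character(0)))
  kz <- field$pad + seq_len(dmem[3])
  # cell-centred z-velocity inside the membrane
  if (field$bc_z == "pressure") {
    wc <- (field$w[, , kz, drop = FALSE] + field$w[, , kz + 1L, drop = FALSE]) / 2
  } else {
    kz2 <- kz %% dim(field$u)[3] + 1L
    wc <- (field$w[, , kz, drop = FALSE] + field$w[, , kz2, drop = FALSE]) / 2
  }
  lab <- pg$labels
  Q <- sum(field$w[, , field$pad + 1L]) * h^2
  flux <- numeric(n)
  nsl <- integer(n)
  for (k in seq_len(dmem[3])) {
    lk <- lab[, , k]
    wk <- wc[, , k]
    s <- rowsum(as.vector(wk)[lk > 0], as.vector(lk)[lk > 0])
    ids <- as.integer(rownames(s))
    flux[ids] <- flux[ids] + s[, 1] * h^2
    nsl[ids] <- nsl[ids] + 1L
  }
  frac <- ifelse(nsl > 0, flux / pmax(nsl, 1L), 0)
  if (abs(Q) > 0) frac <- frac / Q
  setNames(frac, pg$pores$id)
}
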