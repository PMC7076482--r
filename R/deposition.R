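#' Deposition parameters for a virtual pit-membrane network
#'
#' Describes the random sequential deposition process that builds the
#' membrane: rigid, horizontal cellulose microfibrils fall one by one onto
#' a flat plate until they touch the plate or an earlier fibril, with
#' completely random in-plane orientation and location. Exactly one of
#' \code{target_count} and \code{target_volume_fraction} must be given.
#'
#' The defaults encode a generic fresh angiosperm membrane: a 500 x 500 nm
#' tile, 10 nm diameter fibril segments of 20 nm length, and a fibril
#' count calibrated so the deposited stack reaches a thickness of roughly
#' 300 nm with constriction sizes in the 5-20 nm range typical of fresh
#' angiosperm membranes. Short rigid segments stand in for the
#' conformability of real, much longer microfibrils, which drape over one
#' another instead of propping each other up; long rigid rods would stack
#' into an unrealistically loose pile.
#'
#' @param domain_x,domain_y tile extents (nm).
#' @param fibril_diameter fibril diameter (nm), or a function \code{n ->
#'   diameters} for a distribution.
#' @param fibril_length fibril length (nm), or a function \code{n ->
#'   lengths}; lengths may exceed the domain and are truncated at the tile.
#' @param target_count number of fibrils to deposit (mutually exclusive
#'   with \code{target_volume_fraction}).
#' @param target_volume_fraction stop once the solid fraction of the
#'   deposited stack reaches this value (in \[0, 1)).
#' @param in_plane_only logical; fibrils stay horizontal (the only mode
#'   currently implemented).
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical network.
#' @param clip_radius optional radius (nm) for circular clipping after
#'   deposition (see \code{\link{clip_circular}}).
#' @param contact_tol relative contact tolerance (fraction of the contact
#'   distance).
#' @param batch fibrils drawn per deposition step (deposition order is the
#'   draw order; the default of 1 matches sequential settling).
#' @param max_iter iteration cap when chasing a target volume fraction.
#' @return an object of class \code{deposition_params}.
#' @export
deposition_params <- function(domain_x = 500, domain_y = 500,
                              fibril_diameter = 10,
                              fibril_length = 20,
                              target_count = NULL,
                              target_volume_fraction = NULL,
                              in_plane_only = TRUE,
                              seed = 1L,
                              clip_radius = NULL,
                              contact_tol = 1e-6,
                              batch = 1L,
                              max_iter = 50000L) {
  if (is.null(target_count) && is.null(target_volume_fraction))
    target_count <- 3400L  # calibrated: stack thickness ~ 300 nm
  if (!is.null(target_count) && !is.null(target_volume_fraction))
    stop("set exactly one of target_count / target_volume_fraction")
  stopifnot(domain_x > 0, domain_y > 0)
  if (is.numeric(fibril_diameter)) stopifnot(fibril_diameter > 0)
  if (is.numeric(fibril_length)) stopifnot(fibril_length > 0)
  if (!is.null(target_count))
    stopifnot(target_count >= 0, target_count == round(target_count))
  if (!is.null(target_volume_fraction))
    stopifnot(target_volume_fraction >= 0, target_volume_fraction < 1)
  if (!isTRUE(in_plane_only))
    stop("only in-plane (horizontal) deposition is implemented")
  structure(list(
    domain_x = domain_x, domain_y = domain_y,
    fibril_diameter = fibril_diameter,
    fibril_length = fibril_length,
    target_count = if (!is.null(target_count)) as.integer(target_count),
    target_volume_fraction = target_volume_fraction,
    in_plane_only = TRUE,
    seed = as.integer(seed),
    clip_radius = clip_radius,
    contact_tol = contact_tol,
    batch = as.integer(batch),
    max_iter = as.integer(max_iter)
  ), class = "deposition_params")
}

.fibril_matrix <- function(network) {
  f <- network$fibrils
  as.matrix(f[, c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")])
}

.empty_fibrils <- function() {
  data.frame(deposit_index = integer(), x0 = numeric(), y0 = numeric(),
             z0 = numeric(), x1 = numeric(), y1 = numeric(),
             z1 = numeric(), diameter = numeric())
}

.new_network <- function(fibrils, params) {
  thickness <- if (nrow(fibrils) == 0) 0 else
    max(fibrils$z0 + fibrils$diameter / 2)
  structure(list(
    fibrils = fibrils,
    domain = c(x = params$domain_x, y = params$domain_y),
    thickness = thickness,
    params = params,
    seed = params$seed
  ), class = "fibril_network")
}

#' @export
print.fibril_network <- function(x, ...) {
  cat("<fibril_network> ", nrow(x$fibrils), " fibrils, tile ",
      x$domain[1], " x ", x$domain[2], " nm, thickness ",
      signif(x$thickness, 4), " nm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Resting height of a falling horizontal fibril
#'
#' The lowest axis height \code{z >= d/2} at which a horizontal candidate
#' fibril, translated straight down, first contacts the plate (axis height
#' equal to its radius) or a previously deposited fibril (centre-line
#' distance equal to the sum of radii). Because all fibrils are
#' horizontal, the first-contact height with an existing fibril has the
#' closed form \code{z_i + sqrt(R^2 - dxy^2)} where \code{dxy} is the
#' in-plane closest approach of the two axes and \code{R} the sum of
#' radii.
#'
#' @param p0,p1 in-plane endpoints (length-2 numeric, nm) of the candidate
#'   axis.
#' @param diameter candidate diameter (nm).
#' @param network a \code{fibril_network} (may be empty).
#' @return axis height (nm).
#' @export
resting_height <- function(p0, p1, diameter, network) {
  stopifnot(diameter > 0, length(p0) >= 2, length(p1) >= 2)
  fib <- .fibril_matrix(network)
  tol <- if (!is.null(network$params)) network$params$contact_tol else 1e-6
  .resting_height_cpp(as.numeric(p0[1:2]), as.numeric(p1[1:2]),
                      diameter, fib, tol)
}

# clip a 2D segment to the rectangle [0,dx] x [0,dy]; returns NULL if the
# clipped segment is degenerate
.clip_segment_rect <- function(p0, p1, dx, dy) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (ax in 1:2) {
    lim <- c(dx, dy)[ax]
    if (abs(d[ax]) < 1e-300) {
      if (p0[ax] < 0 || p0[ax] > lim) return(NULL)
    } else {
      ta <- (0 - p0[ax]) / d[ax]
      tb <- (lim - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 - t0 <= 1e-12) return(NULL)
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d)
}

#' Deposit a virtual microfibril network
#'
#' Runs the random sequential deposition: each fibril is drawn with
#' uniform random in-plane orientation over \[0, pi) and uniform random
#' centre over the tile, then lowered to its \code{\link{resting_height}}.
#' Deposition stops at \code{target_count} fibrils, or as soon as the
#' measured solid volume fraction of the stack reaches
#' \code{target_volume_fraction}.
#'
#' @param params a \code{\link{deposition_params}} object.
#' @return a \code{fibril_network}.
#' @export
deposit_network <- function(params) {
  stopifnot(inherits(params, "deposition_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  draw_diam <- if (is.function(params$fibril_diameter)) params$fibril_diameter
    else function(n) rep(params$fibril_diameter, n)
  draw_len <- if (is.function(params$fibril_length)) params$fibril_length
    else function(n) rep(params$fibril_length, n)

  fib <- matrix(numeric(0), ncol = 7)
  rows <- list()
  n <- 0L
  by_count <- !is.null(params$target_count)
  target <- if (by_count) params$target_count else params$max_iter
  it <- 0L
  while (TRUE) {
    if (by_count && n >= target) break
    if (!by_count) {
      if (n > 0 && it %% max(params$batch, 5L) == 0L) {
        net_now <- .new_network(do.call(rbind, rows), params)
        if (volume_fraction(net_now) >= params$target_volume_fraction) break
      }
      if (it >= params$max_iter)
        stop("target_volume_fraction not reached after ", params$max_iter,
             " depositions; the target exceeds what sequential settling ",
             "of rigid fibrils can pack")
    }
    it <- it + 1L
    d <- draw_diam(1L)
    len <- draw_len(1L)
    theta <- stats::runif(1L, 0, pi)
    cx <- stats::runif(1L, 0, params$domain_x)
    cy <- stats::runif(1L, 0, params$domain_y)
    dir <- c(cos(theta), sin(theta))
    p0 <- c(cx, cy) - dir * len / 2
    p1 <- c(cx, cy) + dir * len / 2
    seg <- .clip_segment_rect(p0, p1, params$domain_x, params$domain_y)
    if (is.null(seg)) next
    z <- .resting_height_cpp(seg$p0, seg$p1, d, fib, params$contact_tol)
    n <- n + 1L
    row <- data.frame(deposit_index = n,
                      x0 = seg$p0[1], y0 = seg$p0[2], z0 = z,
                      x1 = seg$p1[1], y1 = seg$p1[2], z1 = z,
                      diameter = d)
    rows[[n]] <- row
    fib <- rbind(fib, c(seg$p0[1], seg$p0[2], z,
                        seg$p1[1], seg$p1[2], z, d))
  }
  fibrils <- if (n == 0L) .empty_fibrils() else do.call(rbind, rows)
  net <- .new_network(fibrils, params)
  if (!is.null(params$clip_radius))
    net <- clip_circular(net, params$clip_radius)
  net
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Clip a circular membrane from a deposited network
#'
#' Removes fibrils wholly outside a vertical cylinder and truncates
#' crossing fibrils so their endpoints lie on the clipping circle; heights
#' are unchanged. This mirrors the way a circular membrane is cut
#' numerically from the rectangular deposition tile.
#'
#' @param network a \code{fibril_network}.
#' @param radius clip radius (nm).
#' @param center length-2 centre of the clipping circle (nm); defaults to
#'   the tile centre.
#' @return the clipped \code{fibril_network}.
#' @export
clip_circular <- function(network, radius,
                          center = network$domain / 2) {
  stopifnot(radius >= 0)
  f <- network$fibrils
  if (nrow(f) == 0 || radius == 0) {
    out <- network
    out$fibrils <- .empty_fibrils()
    out$thickness <- 0
    return(out)
  }
  keep <- list()
  for (i in seq_len(nrow(f))) {
    p0 <- c(f$x0[i], f$y0[i]) - center
    p1 <- c(f$x1[i], f$y1[i]) - center
    d <- p1 - p0
    a <- sum(d * d)
    b <- 2 * sum(p0 * d)
    cc <- sum(p0 * p0) - radius^2
    if (a < 1e-300) { if (cc <= 0) keep[[length(keep) + 1L]] <- f[i, ]; next }
    disc <- b * b - 4 * a * cc
    if (disc <= 0) next  # misses (or grazes) the circle
    t0 <- max(0, (-b - sqrt(disc)) / (2 * a))
    t1 <- min(1, (-b + sqrt(disc)) / (2 * a))
    if (t1 - t0 <= 1e-12) next
    q0 <- p0 + t0 * d + center
    q1 <- p0 + t1 * d + center
    row <- f[i, ]
    row$x0 <- q0[1]; row$y0 <- q0[2]
    row$x1 <- q1[1]; row$y1 <- q1[2]
    keep[[length(keep) + 1L]] <- row
  }
  out <- network
  out$fibrils <- if (length(keep)) do.call(rbind, keep) else .empty_fibrils()
  rownames(out$fibrils) <- NULL
  out$thickness <- if (nrow(out$fibrils) == 0) 0 else
    max(out$fibrils$z0 + out$fibrils$diameter / 2)
  out$clip <- list(radius = radius, center = center)
  out
}

#' Solid volume fraction of a fibril network
#'
#' Fraction of a region occupied by fibril material. A fibril is the set
#' of points within one radius of its axis segment — a spherocylinder
#' (capsule), the same convention used by the contact detection and the
#' voxelizer. Deposited fibrils never interpenetrate (they touch at
#' isolated points at most), so the solid volume is the sum of
#' per-fibril capsule volumes clipped to the region: the exact closed
#' form \eqn{\pi r^2 L + \frac{4}{3}\pi r^3} when the capsule lies wholly
#' inside, axial slice quadrature (disk area times an inside indicator)
#' otherwise. A fibril whose axis spans the region wall contributes
#' exactly \eqn{\pi r^2 L} inside, matching the plain-cylinder intuition.
#'
#' @param network a \code{fibril_network}.
#' @param region \code{NULL} for the bounding slab (tile area times stack
#'   thickness), or a list \code{list(type = "box", min = c(x,y,z), max =
#'   c(x,y,z))} or \code{list(type = "cylinder", center = c(x,y), radius =
#'   r, zlim = c(z0,z1))} (nm).
#' @param n_slices axial quadrature slices per fibril.
#' @return solid fraction in \[0, 1).
#' @export
volume_fraction <- function(network, region = NULL, n_slices = 200L) {
  f <- network$fibrils
  if (is.null(region)) {
    if (nrow(f) == 0) return(0)
    region <- list(type = "box", min = c(0, 0, 0),
                   max = c(network$domain[["x"]], network$domain[["y"]],
                           network$thickness))
  }
  vol_region <- switch(region$type,
    box = prod(region$max - region$min),
    cylinder = pi * region$radius^2 * diff(region$zlim),
    stop("unknown region type"))
  if (!is.finite(vol_region) || vol_region <= 0)
    stop("region must have positive volume")
  if (nrow(f) == 0) return(0)

  inside <- function(p) {
    if (region$type == "box") {
      all(p >= region$min & p <= region$max)
    } else {
      sum((p[1:2] - region$center)^2) <= region$radius^2 &&
        p[3] >= region$zlim[1] && p[3] <= region$zlim[2]
    }
  }
  # is the whole ball of radius r around p inside the region?
  ball_inside <- function(p, r) {
    if (region$type == "box") {
      all(p >= region$min + r & p <= region$max - r)
    } else {
      sqrt(sum((p[1:2] - region$center)^2)) <= region$radius - r &&
        p[3] >= region$zlim[1] + r && p[3] <= region$zlim[2] - r
    }
  }
  solid <- 0
  for (i in seq_len(nrow(f))) {
    p0 <- c(f$x0[i], f$y0[i], f$z0[i])
    p1 <- c(f$x1[i], f$y1[i], f$z1[i])
    r <- f$diameter[i] / 2
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) next
    if (ball_inside(p0, r) && ball_inside(p1, r)) {
      solid <- solid + pi * r^2 * L + 4 / 3 * pi * r^3
    } else {
      # slice the extended axis [-r, L + r]; beyond the segment the
      # cross-section disk shrinks as a spherical cap
      u <- (p1 - p0) / L
      ts <- seq(-r, L + r, length.out = n_slices)
      dt <- ts[2] - ts[1]
      acc <- 0
      for (t in ts) {
        over <- max(0, -t, t - L)
        rs2 <- r^2 - over^2
        if (rs2 <= 0) next
        if (inside(p0 + t * u)) acc <- acc + pi * rs2 * dt
      }
      solid <- solid + acc
    }
  }
  min(solid / vol_region, 1 - 1e-12)
}

#' Structural validity checks for a deposited network
#'
#' Verifies the two geometric invariants of sequential settling:
#' non-penetration (no fibril pair closer than the sum of radii, up to the
#' contact tolerance) and support (every fibril rests on the plate or on
#' at least one earlier-deposited fibril).
#'
#' @param network a \code{fibril_network}.
#' @return list with \code{min_clearance} (most negative clearance, nm;
#'   >= -tol when valid), \code{unsupported} (deposit indices of fibrils
#'   with no support), and \code{ok}.
#' @export
validate_network <- function(network) {
  f <- network$fibrils
  if (nrow(f) == 0)
    return(list(min_clearance = Inf, unsupported = integer(), ok = TRUE))
  tol_rel <- network$params$contact_tol %||% 1e-6
  dmax <- max(f$diameter)
  con <- .contacts_cpp(.fibril_matrix(network), tol_abs = 2 * tol_rel * dmax)
  clearance <- Inf
  supported <- f$z0 <= f$diameter / 2 * (1 + 10 * tol_rel)  # plate contact
  if (nrow(con) > 0) {
    R <- (f$diameter[con[, "i"]] + f$diameter[con[, "j"]]) / 2
    clearance <- min(con[, "dist"] - R)
    # support: contact with an earlier fibril at (essentially) touching
    # distance, the earlier fibril lying below
    for (k in seq_len(nrow(con))) {
      i <- con[k, "i"]; j <- con[k, "j"]
      lo <- if (f$z0[i] < f$z0[j]) i else j
      hi <- if (f$z0[i] < f$z0[j]) j else i
      if (f$deposit_index[lo] < f$deposit_index[hi] &&
          con[k, "dist"] <= R[k] * (1 + 10 * tol_rel))
        supported[hi] <- TRUE
    }
  }
  unsupported <- f$deposit_index[!supported]
  list(min_clearance = clearance,
       unsupported = unsupported,
       ok = clearance >= -2 * tol_rel * dmax && length(unsupported) == 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
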