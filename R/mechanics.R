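#' Cox shear-lag estimate of membrane stiffness
#'
#' Effective in-plane Young's modulus of a planar network of long,
#' randomly oriented fibres: \code{E = vf * Ef / 3}, where \code{vf} is
#' the fibril volume fraction and \code{Ef} the modulus of a single
#' microfibril.
#'
#' @param vf fibril volume fraction in \[0, 1\].
#' @param Ef fibril Young's modulus (Pa).
#' @return effective membrane modulus (Pa).
#' @examples
#' cox_modulus(0.3, 9e9)  # 0.9 GPa
#' @export
cox_modulus <- function(vf, Ef) {
  if (any(vf < 0 | vf > 1)) stop("vf must lie in [0, 1]")
  if (any(Ef <= 0)) stop("Ef must be positive")
  vf * Ef / 3
}

#' Fibril material properties
#'
#' @param Ef Young's modulus of a microfibril (Pa).
#' @param failure_strain optional axial strain at which a fibril segment
#'   breaks; \code{NULL} for purely linear response.
#' @param poisson Poisson ratio used for the beam shear modulus.
#' @export
fibril_material <- function(Ef, failure_strain = NULL, poisson = 0.3) {
  stopifnot(Ef > 0)
  if (!is.null(failure_strain)) stopifnot(failure_strain > 0)
  structure(list(Ef = Ef, failure_strain = failure_strain,
                 poisson = poisson), class = "fibril_material")
}

#' Build a bonded beam model from a fibril network
#'
#' Detects all fibril-fibril contacts (centre-line distance within the sum
#' of radii plus the bond tolerance), splits each fibril into beam
#' elements at its contact points, and ties the two touching fibrils
#' rigidly at each contact (the contact nodes share all six degrees of
#' freedom; the small lever arm across the bond is neglected). Grip node
#' sets are the nodes within one fibril diameter of the two opposite tile
#' edges along the grip axis.
#'
#' Sequential settling leaves each fibril touching only the fibrils it
#' came to rest on, which by itself gives a forest of support chains with
#' little lateral connectivity. Physical microfibrils bond (hydrogen
#' bonding, matrix polysaccharides) wherever they lie within molecular
#' range, so near-contacts within \code{bond_tol} are welded too; the
#' default is 5 percent of the largest fibril diameter.
#'
#' @param network a \code{fibril_network}.
#' @param grip_axis \code{"y"} (default) or \code{"x"}.
#' @param grip_margin distance from the edge (nm) within which nodes are
#'   gripped; defaults to one (maximum) fibril diameter.
#' @param bond_tol gap (nm) below which two fibrils count as bonded.
#' @return a \code{beam_model}: nodes (nm coordinates), elements (node
#'   pair, diameter, parent fibril), dof groups implementing the rigid
#'   ties, grip node sets, and a connectivity flag.
#' @export
build_beam_model <- function(network, grip_axis = c("y", "x"),
                             grip_margin = NULL, bond_tol = NULL) {
  grip_axis <- match.arg(grip_axis)
  f <- network$fibrils
  if (nrow(f) == 0) stop("network is empty")
  dmax <- max(f$diameter)
  if (is.null(grip_margin)) grip_margin <- dmax
  if (is.null(bond_tol)) bond_tol <- 0.05 * dmax
  con <- .contacts_cpp(.fibril_matrix(network), tol_abs = bond_tol)

  # split points per fibril: endpoints plus contact parameters
  splits <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) splits[[i]] <- c(0, 1)
  contacts <- list()
  if (nrow(con) > 0) {
    for (k in seq_len(nrow(con))) {
      i <- unname(con[k, "i"]); j <- unname(con[k, "j"])
      s <- unname(con[k, "s"]); t <- unname(con[k, "t"])
      splits[[i]] <- c(splits[[i]], s)
      splits[[j]] <- c(splits[[j]], t)
      contacts[[k]] <- c(i = i, s = s, j = j, t = t)
    }
  }

  nodes <- list()        # each: c(x, y, z)
  node_key <- character() # "fibril:param" for contact tying
  elements <- list()      # each: c(n1, n2, fibril)
  fib_node <- function(i, t) {
    p0 <- c(f$x0[i], f$y0[i], f$z0[i])
    p1 <- c(f$x1[i], f$y1[i], f$z1[i])
    p0 + t * (p1 - p0)
  }
  node_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(f))) {
    ts <- sort(unique(round(splits[[i]], 9)))
    # drop splits closer than a tiny fraction of the fibril
    keep <- c(TRUE, diff(ts) > 1e-7)
    ts <- ts[keep]
    ids <- integer(length(ts))
    for (q in seq_along(ts)) {
      key <- paste0(i, ":", format(ts[q], digits = 10))
      nodes[[length(nodes) + 1L]] <- fib_node(i, ts[q])
      ids[q] <- length(nodes)
      assign(key, ids[q], envir = node_of)
      node_key <- c(node_key, key)
    }
    for (q in seq_len(length(ts) - 1L))
      elements[[length(elements) + 1L]] <-
        c(n1 = ids[q], n2 = ids[q + 1L], fibril = i)
  }
  nodes <- do.call(rbind, nodes)
  el <- do.call(rbind, elements)
  el <- data.frame(n1 = el[, 1], n2 = el[, 2], fibril = el[, 3])
  el$diameter <- f$diameter[el$fibril]

  # rigid ties: union-find over nodes
  parent <- seq_len(nrow(nodes))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  lookup <- function(i, t) {
    ts <- sort(unique(round(splits[[i]], 9)))
    ts <- ts[c(TRUE, diff(ts) > 1e-7)]
    q <- which.min(abs(ts - t))
    get(paste0(i, ":", format(ts[q], digits = 10)), envir = node_of)
  }
  for (ct in contacts) {
    a <- lookup(ct["i"], ct["s"])
    b <- lookup(ct["j"], ct["t"])
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  group <- vapply(seq_len(nrow(nodes)), find, integer(1))
  group <- match(group, unique(group))

  ax <- if (grip_axis == "y") 2L else 1L
  lim <- network$domain[[if (grip_axis == "y") "y" else "x"]]
  grip_lo <- which(nodes[, ax] <= grip_margin)
  grip_hi <- which(nodes[, ax] >= lim - grip_margin)

  # connectivity between grips through the tied-group graph
  gsrc <- unique(group[grip_lo]); gdst <- unique(group[grip_hi])
  connected <- FALSE
  if (length(gsrc) > 0 && length(gdst) > 0) {
    gg <- igraph::graph_from_edgelist(
      cbind(group[el$n1], group[el$n2]), directed = FALSE)
    comp <- igraph::components(gg)$membership
    connected <- length(intersect(comp[gsrc], comp[gdst])) > 0
  }

  structure(list(nodes = nodes, elements = el, group = group,
                 n_contacts = length(contacts),
                 grip_axis = grip_axis, grip_lo = grip_lo,
                 grip_hi = grip_hi, domain = network$domain,
                 thickness = network$thickness,
                 connected = connected), class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat("<beam_model> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " elements, ", x$n_contacts, " contacts, grips ",
      length(x$grip_lo), "/", length(x$grip_hi),
      if (!x$connected) " (disconnected specimen)" else "", "\n", sep = "")
  invisible(x)
}

# 12x12 elastic stiffness of a 3D Euler-Bernoulli frame element in global
# coordinates
.frame_k <- function(E, G, A, Iy, Iz, J, L, dc) {
  k <- matrix(0, 12, 12)
  EA <- E * A / L
  t <- G * J / L
  a1 <- 12 * E * Iz / L^3; a2 <- 6 * E * Iz / L^2
  a3 <- 4 * E * Iz / L;    a4 <- 2 * E * Iz / L
  b1 <- 12 * E * Iy / L^3; b2 <- 6 * E * Iy / L^2
  b3 <- 4 * E * Iy / L;    b4 <- 2 * E * Iy / L
  idx <- function(n, d) 6 * (n - 1) + d
  # axial (local x)
  k[idx(1,1), idx(1,1)] <- EA;  k[idx(2,1), idx(2,1)] <- EA
  k[idx(1,1), idx(2,1)] <- -EA; k[idx(2,1), idx(1,1)] <- -EA
  # torsion
  k[idx(1,4), idx(1,4)] <- t;   k[idx(2,4), idx(2,4)] <- t
  k[idx(1,4), idx(2,4)] <- -t;  k[idx(2,4), idx(1,4)] <- -t
  # bending about local z (displacement in local y)
  m <- matrix(c(a1,  a2, -a1,  a2,
                a2,  a3, -a2,  a4,
               -a1, -a2,  a1, -a2,
                a2,  a4, -a2,  a3), 4, 4, byrow = TRUE)
  dz <- c(idx(1,2), idx(1,6), idx(2,2), idx(2,6))
  k[dz, dz] <- k[dz, dz] + m
  # bending about local y (displacement in local z; signs mirror)
  m2 <- matrix(c(b1, -b2, -b1, -b2,
                -b2,  b3,  b2,  b4,
                -b1,  b2,  b1,  b2,
                -b2,  b4,  b2,  b3), 4, 4, byrow = TRUE)
  dy <- c(idx(1,3), idx(1,5), idx(2,3), idx(2,5))
  k[dy, dy] <- k[dy, dy] + m2
  # rotate to global: T block-diagonal with dc (3x3 direction cosines)
  T <- matrix(0, 12, 12)
  for (b in 0:3) T[3 * b + 1:3, 3 * b + 1:3] <- dc
  t(T) %*% k %*% T
}

.dircos <- function(p1, p2) {
  ex <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  up <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ez <- up - sum(up * ex) * ex
  ez <- ez / sqrt(sum(ez^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  rbind(ex, ey, ez)
}

#' Displacement-controlled tension of a bonded fibril network
#'
#' Quasi-static displacement-controlled loading of the beam model: one
#' grip is fixed, the other displaced along the grip axis in equal
#' increments. Each step is a linear-elastic solve; elements whose axial
#' strain exceeds the material failure strain are removed (fracture)
#' before the next step. With no failure criterion the response is
#' exactly linear. In \code{"biaxial"} mode both in-plane axes are
#' stretched simultaneously (uniform stretching).
#'
#' @param model a \code{beam_model}.
#' @param material a \code{\link{fibril_material}}.
#' @param max_strain final nominal strain (grip displacement / gauge
#'   length).
#' @param steps number of load increments (>= 1).
#' @param mode \code{"uniaxial"} or \code{"biaxial"}.
#' @return a \code{mechanical_response}: per-step data frame (strain,
#'   force N, nominal stress Pa, broken element count), effective modulus
#'   (initial slope, Pa), final nodal displacement field \code{U2} along
#'   the tension axis (nm), and status flags.
#' @export
uniaxial_tension <- function(model, material, max_strain = 0.02,
                             steps = 10L, mode = c("uniaxial", "biaxial")) {
  mode <- match.arg(mode)
  stopifnot(steps >= 1)
  if (!model$connected) stop("disconnected specimen: no load path between grips")
  nm <- 1e-9
  nodes <- model$nodes * nm
  ngrp <- max(model$group)
  ax <- if (model$grip_axis == "y") 2L else 1L
  axo <- if (ax == 2L) 1L else 2L
  L0 <- diff(range(model$nodes[, ax])) * nm
  W <- diff(range(model$nodes[, axo])) * nm
  tthick <- max(model$thickness, max(model$elements$diameter)) * nm
  E <- material$Ef
  G <- E / (2 * (1 + material$poisson))

  alive <- rep(TRUE, nrow(model$elements))
  el <- model$elements
  p1g <- model$group[el$n1]
  p2g <- model$group[el$n2]

  # groups containing grip nodes
  grp_lo <- unique(model$group[model$grip_lo])
  grp_hi <- unique(model$group[model$grip_hi])

  response <- data.frame(step = integer(), strain = numeric(),
                         force = numeric(), stress = numeric(),
                         n_broken = integer())
  U2 <- rep(0, ngrp)
  broken_total <- integer(0)
  failed <- FALSE
  Eeff <- NA_real_

  for (s in seq_len(steps)) {
    strain <- max_strain * s / steps
    disp <- strain * L0
    live <- which(alive)
    if (length(live) == 0) { failed <- TRUE; break }
    # keep only groups connected to a grip through live elements
    gg <- igraph::graph_from_edgelist(
      cbind(p1g[live], p2g[live]), directed = FALSE)
    if (igraph::vcount(gg) < ngrp)
      gg <- igraph::add_vertices(gg, ngrp - igraph::vcount(gg))
    comp <- igraph::components(gg)$membership
    if (length(intersect(comp[grp_lo], comp[grp_hi])) == 0) {
      failed <- TRUE
      break
    }
    anchored <- comp %in% unique(c(comp[grp_lo], comp[grp_hi]))
    # assemble
    trip_i <- vector("list", length(live))
    trip_j <- vector("list", length(live))
    trip_x <- vector("list", length(live))
    for (q in seq_along(live)) {
      e <- live[q]
      pa <- nodes[el$n1[e], ]; pb <- nodes[el$n2[e], ]
      Le <- sqrt(sum((pb - pa)^2))
      if (Le <= 0) next
      r <- el$diameter[e] / 2 * nm
      A <- pi * r^2; I <- pi * r^4 / 4; J <- pi * r^4 / 2
      ke <- .frame_k(E, G, A, I, I, J, Le, .dircos(pa, pb))
      dofs <- c(6 * (p1g[e] - 1) + 1:6, 6 * (p2g[e] - 1) + 1:6)
      ii <- rep(dofs, each = 12)
      jj <- rep(dofs, times = 12)
      trip_i[[q]] <- ii; trip_j[[q]] <- jj; trip_x[[q]] <- as.vector(ke)
    }
    ndof <- 6 * ngrp
    K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(ndof, ndof))
    # boundary conditions on tied groups
    fixed <- rep(FALSE, ndof)
    uval <- rep(0, ndof)
    clamp <- function(grps, trans_vals) {
      for (g in grps) {
        for (dd in 1:3) {
          fixed[6 * (g - 1) + dd] <<- TRUE
          uval[6 * (g - 1) + dd] <<- trans_vals[dd]
        }
      }
    }
    pull <- c(0, 0, 0); pull[ax] <- disp
    clamp(grp_lo, c(0, 0, 0))
    clamp(grp_hi, pull)
    if (mode == "biaxial") {
      lim2 <- model$domain[[if (axo == 1L) "x" else "y"]]
      g2lo <- unique(model$group[model$nodes[, axo] <=
                                   model$nodes[, axo][which.min(model$nodes[, axo])] + 1e-9 + max(el$diameter)])
      g2hi <- unique(model$group[model$nodes[, axo] >= lim2 - max(el$diameter)])
      pull2 <- c(0, 0, 0); pull2[axo] <- disp
      clamp(g2lo, c(0, 0, 0))
      clamp(g2hi, pull2)
    }
    # anchor free-floating anchored==FALSE groups (removed fragments)
    for (g in which(!anchored)) {
      fixed[6 * (g - 1) + 1:6] <- TRUE
      uval[6 * (g - 1) + 1:6] <- 0
    }
    free <- which(!fixed)
    presc <- which(fixed)
    u <- uval
    rhs <- -K[free, presc, drop = FALSE] %*% uval[presc]
    Kff <- K[free, free, drop = FALSE] +
      Matrix::Diagonal(length(free), x = 1e-8 * max(abs(K@x)))
    sol <- tryCatch(Matrix::solve(Kff, rhs),
                    error = function(e) NULL)
    if (is.null(sol)) { failed <- TRUE; break }
    u[free] <- as.numeric(sol)
    # reactions at moving grip along the pull axis
    hi_dofs <- 6 * (grp_hi - 1) + ax
    force <- sum((K %*% u)[hi_dofs])
    stressN <- force / (W * tthick)
    # axial strains, fracture
    nbrk <- 0L
    if (!is.null(material$failure_strain)) {
      for (q in seq_along(live)) {
        e <- live[q]
        pa <- nodes[el$n1[e], ]; pb <- nodes[el$n2[e], ]
        Le <- sqrt(sum((pb - pa)^2))
        if (Le <= 0) next
        exv <- (pb - pa) / Le
        d1 <- u[6 * (p1g[e] - 1) + 1:3]
        d2 <- u[6 * (p2g[e] - 1) + 1:3]
        eps <- sum((d2 - d1) * exv) / Le
        if (eps > material$failure_strain) {
          alive[e] <- FALSE
          nbrk <- nbrk + 1L
          broken_total <- c(broken_total, e)
        }
      }
    }
    response <- rbind(response, data.frame(
      step = s, strain = strain, force = force, stress = stressN,
      n_broken = length(broken_total)))
    if (s == 1L && strain > 0)
      Eeff <- max(stressN / strain, 0)
    U2 <- u[6 * (seq_len(ngrp) - 1) + ax] / nm
  }
  node_U2 <- U2[model$group]
  structure(list(response = response, effective_modulus = Eeff,
                 U2 = node_U2, broken = broken_total, failed = failed,
                 mode = mode, grip_axis = model$grip_axis),
            class = "mechanical_response")
}

#' @export
print.mechanical_response <- function(x, ...) {
  cat("<mechanical_response> ", nrow(x$response), " steps, E_eff = ",
      signif(x$effective_modulus, 4), " Pa, ", length(x$broken),
      " broken elements", if (x$failed) " (specimen failed)" else "",
      "\n", sep = "")
  invisible(x)
}
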