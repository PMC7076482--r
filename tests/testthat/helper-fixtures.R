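# shared fixture builders: all geometry is generated in code at test time

# a network object wrapping a hand-written fibril table
manual_network <- function(fibrils, domain_x = 100, domain_y = 100) {
  params <- deposition_params(domain_x = domain_x, domain_y = domain_y,
                              target_count = 0L, seed = 1L)
  net <- pitflow:::.new_network(fibrils, params)
  net
}

fibril_row <- function(idx, p0, p1, z, d) {
  data.frame(deposit_index = idx, x0 = p0[1], y0 = p0[2], z0 = z,
             x1 = p1[1], y1 = p1[2], z1 = z, diameter = d)
}

# two spherical cavities (radius R nm, centres 30 nm apart) joined by a
# narrow cylindrical neck (radius rneck nm) in a solid 41 x 41 x 61 nm
# block; h sets the voxel size so the same physical shape can be
# discretized at several resolutions
two_cavity_grid <- function(R = 12, rneck = 4, h = 1) {
  d <- round(c(41, 41, 61) / h)
  ax <- (seq_len(d[1]) - 0.5) * h
  az <- (seq_len(d[3]) - 0.5) * h
  cx <- 20.5
  m <- array(TRUE, d)
  r2xy <- outer((ax - cx)^2, (ax - cx)^2, "+")
  for (k in seq_len(d[3])) {
    dz1 <- (az[k] - 15)^2
    dz2 <- (az[k] - 45)^2
    sl <- m[, , k]
    sl[r2xy + dz1 <= R^2] <- FALSE
    sl[r2xy + dz2 <= R^2] <- FALSE
    if (az[k] > 15 && az[k] < 45)
      sl[r2xy <= rneck^2] <- FALSE
    m[, , k] <- sl
  }
  new_voxel_grid(m, h)
}

# cavity with a wide shaft to the inlet and a half-width neck to the
# outlet: best through-path bottleneck = neck diameter
necked_cavity_grid <- function(R = 10, h = 1) {
  d <- c(41, 41, 51)
  ax <- (seq_len(d[1]) - 0.5) * h
  az <- (seq_len(d[3]) - 0.5) * h
  cx <- 20.5 * h
  m <- array(TRUE, d)
  r2xy <- outer((ax - cx)^2, (ax - cx)^2, "+")
  zc <- 25 * h
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (az[k] < zc) sl[r2xy <= (R * h)^2] <- FALSE        # wide shaft
    sl[r2xy + (az[k] - zc)^2 <= (R * h)^2] <- FALSE       # cavity
    if (az[k] > zc) sl[r2xy <= (R * h / 2)^2] <- FALSE    # narrow neck
    m[, , k] <- sl
  }
  new_voxel_grid(m, h)
}

# central cavity with two disjoint bulged channels to the inlet and two
# to the outlet; the bulges become their own watershed basins so each
# pathway is a distinct constriction chain (count of edge-disjoint
# inlet-outlet paths through the cavity = 2)
twin_neck_grid <- function(h = 1) {
  d <- c(41, 21, 41)
  m <- array(TRUE, d)
  m[8:34, 8:14, 19:23] <- FALSE  # central cavity slab
  ax <- (seq_len(d[1]) - 0.5) * h
  ay <- (seq_len(d[2]) - 0.5) * h
  az <- (seq_len(d[3]) - 0.5) * h
  bulge <- function(cx, cy, cz, R) {
    for (k in seq_len(d[3])) {
      dz2 <- (az[k] - cz)^2
      if (dz2 > R^2) next
      sl <- m[, , k]
      sl[outer((ax - cx)^2, (ay - cy)^2, "+") + dz2 <= R^2] <- FALSE
      m[, , k] <<- sl
    }
  }
  chan <- function(xr, kr) m[xr, 10:12, kr] <<- FALSE
  # bottom pair (to inlet)
  chan(11:13, 1:19); bulge(12 * h - 0.5, 10.5 * h, 10 * h, 4 * h)
  chan(29:31, 1:19); bulge(30 * h - 0.5, 10.5 * h, 10 * h, 4 * h)
  # top pair (to outlet)
  chan(11:13, 23:41); bulge(12 * h - 0.5, 10.5 * h, 32 * h, 4 * h)
  chan(29:31, 23:41); bulge(30 * h - 0.5, 10.5 * h, 32 * h, 4 * h)
  new_voxel_grid(m, h)
}

# brute-force EDT oracle (nearest solid voxel centre) on small grids
edt_brute <- function(solid) {
  d <- dim(solid)
  idx <- which(solid, arr.ind = TRUE)
  out <- array(0, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        if (solid[i, j, k]) next
        dd <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2 +
                         (idx[, 3] - k)^2))
        out[i, j, k] <- dd
      }
  out
}

default_water <- function() fluid_props(998, 1e-3)
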