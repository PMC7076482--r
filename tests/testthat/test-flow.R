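# Solver oracles use the z-periodic body-force mode where the analytic
# solution is exact (no entrance effects); membrane runs use the
# prescribed-pressure mode with reservoir padding.

mu <- 1e-3

test_that("plane Poiseuille flow is reproduced in a slit", {
  gap <- 50; L <- 100; h <- 2.5
  g <- fixture_geometry("slit", list(gap = gap, wall = 25, width = 40,
                                     length = L), h)
  f <- solve_stokes(g, dP = 1000, bc_z = "periodic", tol = 1e-8,
                    continuation = FALSE)
  umax_t <- 1000 * (gap * 1e-9)^2 / (8 * mu * L * 1e-9)
  expect_equal(max(abs(f$w)), umax_t, tolerance = 0.03)
  fs <- summarize_flow(f)
  # mean velocity over the gap = 2/3 of the peak
  expect_equal(fs$Q / (gap * 40 * 1e-18), umax_t * 2 / 3, tolerance = 0.03)
  # slit permeability referred to the full tile width W: k = gap^3/(12 W)
  W <- (gap + 2 * 25) * 1e-9
  expect_equal(fs$permeability, (gap * 1e-9)^3 / (12 * W), tolerance = 0.03)
  expect_lt(fs$flux_spread, 1e-10)
})

test_that("Hagen-Poiseuille flow is reproduced in a tube", {
  R <- 25; W <- 100; L <- 100; h <- 2.5
  g <- fixture_geometry("tube", list(radius = R, tile = W, length = L), h)
  f <- solve_stokes(g, dP = 1000, bc_z = "periodic", tol = 1e-8,
                    continuation = FALSE)
  fs <- summarize_flow(f)
  Qth <- pi * (R * 1e-9)^4 * 1000 / (8 * mu * L * 1e-9)
  expect_equal(fs$Q, Qth, tolerance = 0.05)
})

test_that("velocities scale exactly with the applied pressure drop", {
  g <- fixture_geometry("tube", list(radius = 20, tile = 80, length = 60), 2.5)
  f1 <- solve_stokes(g, dP = 1000, bc_z = "periodic", tol = 1e-8,
                     continuation = FALSE)
  f2 <- solve_stokes(g, dP = 2000, bc_z = "periodic", tol = 1e-8,
                     continuation = FALSE)
  expect_lt(max(abs(f2$w - 2 * f1$w)) / max(abs(f2$w)), 1e-10)
  expect_lt(max(abs(f2$u - 2 * f1$u)) / max(abs(f2$w)), 1e-10)
})

test_that("transverse permeability of a square cylinder array matches the
          closed-form estimate", {
  phi <- 0.3; tile <- 100; h <- 0.625
  g <- fixture_geometry("cylinder_array",
                        list(tile = tile, solid_fraction = phi, span = 4 * h),
                        h)
  f <- solve_stokes(g, dP = 1000, bc_z = "periodic", tol = 1e-8,
                    continuation = FALSE)
  fs <- summarize_flow(f)
  # independent closed-form oracle (Drummond-Tahir series for transverse
  # flow through a square array, radius a)
  a <- sqrt(phi / pi) * tile * 1e-9
  k_dt <- a^2 / (8 * phi) *
    (-log(phi) - 1.476 + 2 * phi - 1.774 * phi^2 + 4.076 * phi^3)
  expect_equal(fs$permeability, k_dt, tolerance = 0.15)
  # tile-translation invariance of the periodic mask
  m <- g$mask
  shifted <- m[, c(11:dim(m)[2], 1:10), ]
  gs <- new_voxel_grid(shifted, h)
  fsh <- summarize_flow(solve_stokes(gs, dP = 1000, bc_z = "periodic",
                                     tol = 1e-8, continuation = FALSE))
  expect_equal(fsh$permeability, fs$permeability, tolerance = 1e-6)
})

test_that("pressure-driven membrane flow conserves mass plane by plane", {
  net <- deposit_network(deposition_params(target_count = 1200, seed = 4))
  g <- suppressWarnings(voxelize(net, 5))
  f <- solve_stokes(g, default_water(), dP = 1000, tol = 1e-5,
                    mom_tol = 3e-3)
  fs <- summarize_flow(f)
  expect_lt(fs$flux_spread, 0.005)
  expect_gt(fs$Q, 0)
  expect_false(f$no_through_flow)
})

test_that("a non-percolating geometry gives zero flow, not a crash", {
  m <- array(FALSE, c(10, 10, 9))
  m[, , 5] <- TRUE  # solid wall all the way across
  g <- new_voxel_grid(m, 2)
  f <- solve_stokes(g, dP = 1000)
  expect_true(f$no_through_flow)
  fs <- summarize_flow(f)
  expect_equal(fs$Q, 0)
  expect_equal(fs$reynolds, 0)
})

test_that("permeability is undefined at zero pressure drop", {
  g <- fixture_geometry("tube", list(radius = 16, tile = 64, length = 40), 2)
  f <- solve_stokes(g, dP = 0, bc_z = "periodic", continuation = FALSE)
  fs <- summarize_flow(f)
  expect_true(fs$dP_undefined)
  expect_true(is.na(fs$permeability))
})

test_that("per-pore flux attribution is exact on symmetric fixtures", {
  g <- fixture_geometry("twin_channel", list(tile = 60, length = 30,
                                             radius = 8), 1)
  pg <- extract_pore_graph(g)
  f <- solve_stokes(g, dP = 1000, tol = 1e-8, continuation = FALSE)
  fr <- per_pore_flux(f, pg)
  expect_equal(unname(sort(fr)), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(fr), 1, tolerance = 1e-6)

  # sealed large cavity next to an open channel: the cavity carries
  # essentially nothing
  g2 <- fixture_geometry("sealed_cavity",
                         list(tile = 60, length = 40, channel_radius = 8,
                              cavity_radius = 10), 1)
  pg2 <- extract_pore_graph(g2)
  f2 <- solve_stokes(g2, dP = 1000, tol = 1e-8, continuation = FALSE)
  fr2 <- per_pore_flux(f2, pg2)
  sealed <- as.character(pg2$pores$id[!pg2$pores$inlet & !pg2$pores$outlet])
  open_p <- as.character(pg2$pores$id[pg2$pores$inlet & pg2$pores$outlet])
  expect_lt(abs(fr2[[sealed[1]]]), 0.01)
  expect_equal(fr2[[open_p[1]]], 1, tolerance = 1e-3)
})

test_that("slit fixtures have exactly the requested fluid layers", {
  g <- fixture_geometry("slit", list(gap = 20, wall = 10, width = 10,
                                     length = 20), 2.5)
  profile <- apply(!g$mask, 1, any)
  expect_equal(sum(profile), round(20 / 2.5))
  expect_true(all(diff(which(profile)) == 1))  # contiguous
  g2 <- fixture_geometry("tube", list(radius = 10, tile = 50, length = 20), 1)
  expect_equal(mean(!g2$mask), pi * 10^2 / 50^2, tolerance = 0.05)
  expect_error(fixture_geometry("nope", list(), 1), "arg")
})
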