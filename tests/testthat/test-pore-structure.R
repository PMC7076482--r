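test_that("voxelization reproduces cylinder volume and symmetry", {
  # empty network -> all fluid
  g0 <- voxelize(deposit_network(deposition_params(target_count = 0)), 2.5,
                 nz = 4)
  expect_false(any(g0$mask))

  # one axis-aligned cylinder at fine resolution: voxel count converges
  # to pi r^2 L
  net <- manual_network(fibril_row(1L, c(0, 50), c(100, 50), z = 20, d = 16))
  g <- voxelize(net, 0.5, nz = 80)
  vol_vox <- sum(g$mask) * 0.5^3
  expect_equal(vol_vox, pi * 8^2 * 100, tolerance = 0.05)

  # 90-degree rotation symmetry: a cross of two perpendicular fibrils at
  # the same height pattern
  netx <- manual_network(rbind(
    fibril_row(1L, c(0, 50), c(100, 50), z = 10, d = 10),
    fibril_row(2L, c(50, 0), c(50, 100), z = 10, d = 10)))
  gx <- voxelize(netx, 1, nz = 20)
  m <- gx$mask
  rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]  # 90-degree rotation in-plane
  expect_identical(m, rot)

  expect_error(voxelize(netx, 0), "positive")
  expect_warning(voxelize(netx, 4, nz = 10), "under-resolved")
})

test_that("the exact distance transform matches brute force", {
  set.seed(42)
  for (rep in 1:3) {
    d <- c(9, 8, 7)
    solid <- array(runif(prod(d)) < 0.2, d)
    solid[5, 4, 4] <- TRUE  # guarantee a solid voxel
    g <- new_voxel_grid(solid, 1)
    expect_equal(distance_map(g), edt_brute(solid), tolerance = 1e-12)
  }
})

test_that("watershed finds pores and constrictions of analytic fixtures", {
  # solid slab pierced by one cylindrical hole: one pore, inlet to outlet
  g <- fixture_geometry("tube", list(radius = 8, tile = 41, length = 30), 1)
  pg <- extract_pore_graph(g)
  expect_equal(nrow(pg$pores), 1L)
  expect_true(pg$pores$inlet[1] && pg$pores$outlet[1])
  expect_equal(pg$pores$diameter_nm[1], 16, tolerance = 1 / 16 + 1e-9)
  expect_equal(nrow(pg$constrictions), 0L)

  # two spherical cavities joined by a narrow neck: 2 pores, 1
  # constriction whose diameter is the neck diameter within one voxel
  g2 <- two_cavity_grid(R = 12, rneck = 4, h = 1)
  pg2 <- extract_pore_graph(g2)
  expect_equal(nrow(pg2$pores), 2L)
  expect_equal(nrow(pg2$constrictions), 1L)
  expect_equal(pg2$constrictions$diameter_nm[1], 8, tolerance = 1 / 8)
  expect_equal(pg2$pores$diameter_nm, c(24, 24), tolerance = 1 / 12)

  # all-solid grid: empty graph, not an error
  pg3 <- extract_pore_graph(new_voxel_grid(array(TRUE, c(5, 5, 5)), 1))
  expect_equal(nrow(pg3$pores), 0L)
})

test_that("pore labels partition the fluid volume", {
  net <- deposit_network(deposition_params(target_count = 400, seed = 2))
  g <- voxelize(net, 2.5)
  pg <- extract_pore_graph(g)
  expect_equal(sum(pg$pores$voxels), sum(!g$mask))
  expect_true(all(pg$labels[!g$mask] > 0))
  expect_true(all(pg$labels[g$mask] == 0))
  # constrictions are never wider than either adjacent pore
  ed <- pg$constrictions
  expect_true(all(ed$diameter_nm <=
                    pg$pores$diameter_nm[ed$a] + 1e-9))
  expect_true(all(ed$diameter_nm <=
                    pg$pores$diameter_nm[ed$b] + 1e-9))
})

test_that("graph connectivity agrees with voxel flood-fill percolation", {
  set.seed(7)
  for (rep in 1:4) {
    d <- c(12, 12, 10)
    solid <- array(runif(prod(d)) < 0.55, d)
    g <- new_voxel_grid(solid, 1)
    if (all(solid)) next
    pg <- extract_pore_graph(g)
    graph_perc <- FALSE
    if (nrow(pg$pores) > 0) {
      gg <- pitflow:::.pore_igraph(pg, 0)
      graph_perc <- igraph::edge_connectivity(
        gg, source = "inlet", target = "outlet") > 0 ||
        any(pg$pores$inlet & pg$pores$outlet)
    }
    expect_equal(graph_perc, percolates(g))
  }
})

test_that("refining the grid is stable for porosity and constrictions", {
  g1 <- two_cavity_grid(h = 1)
  g2 <- two_cavity_grid(h = 0.5)  # same physical shape, halved voxel
  p1 <- extract_pore_graph(g1)
  p2 <- extract_pore_graph(g2)
  expect_equal(porosity(g1), porosity(g2), tolerance = 0.02)
  # constriction diameter moves by less than one coarse voxel
  expect_equal(p2$constrictions$diameter_nm[1],
               p1$constrictions$diameter_nm[1], tolerance = 1 / 8)
})

test_that("through-path counting matches constructed topologies", {
  g <- fixture_geometry("tube", list(radius = 8, tile = 41, length = 30), 1)
  pg <- extract_pore_graph(g)
  expect_gte(through_path_count(pg, pg$pores$id[1]), 1)
  expect_error(through_path_count(pg, 999), "unknown")

  # sealed cavity: no pathway at all
  gs <- fixture_geometry("sealed_cavity",
                         list(tile = 60, length = 40, channel_radius = 6,
                              cavity_radius = 10), 1)
  pgs <- extract_pore_graph(gs)
  sealed <- pgs$pores$id[!pgs$pores$inlet & !pgs$pores$outlet]
  expect_equal(through_path_count(pgs, sealed[1]), 0L)

  # exactly two disjoint pathways to inlet and outlet
  gt <- twin_neck_grid()
  pgt <- extract_pore_graph(gt)
  interior <- !pgt$pores$inlet & !pgt$pores$outlet
  central <- pgt$pores$id[interior][which.max(pgt$pores$voxels[interior])]
  expect_equal(through_path_count(pgt, central), 2L)
})

test_that("obstruction index spans sealed to straight-through", {
  g <- fixture_geometry("tube", list(radius = 8, tile = 41, length = 30), 1)
  pg <- extract_pore_graph(g)
  expect_equal(obstruction_index(pg, pg$pores$id[1]), 0)

  gs <- fixture_geometry("sealed_cavity",
                         list(tile = 60, length = 40, channel_radius = 6,
                              cavity_radius = 10), 1)
  pgs <- extract_pore_graph(gs)
  sealed <- pgs$pores$id[!pgs$pores$inlet & !pgs$pores$outlet]
  expect_equal(obstruction_index(pgs, sealed[1]), 1)

  # cavity of diameter D with a single neck of diameter D/2: index 0.5
  gn <- necked_cavity_grid(R = 10, h = 1)
  pgn <- extract_pore_graph(gn)
  cav <- pgn$pores$id[which.max(pgn$pores$diameter_nm)]
  expect_equal(obstruction_index(pgn, cav), 0.5, tolerance = 0.12)

  rep <- obstruction_report(pgn)
  expect_equal(nrow(rep), nrow(pgn$pores))
  expect_true(all(rep$obstruction_index >= 0 & rep$obstruction_index <= 1))
})
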