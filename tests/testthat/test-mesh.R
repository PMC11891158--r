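# Morphology fixtures are built in code on small lattices (NBC = 1000).

test_that("overloaded GCs unload excess-to-NBC into the freest neighbor", {
  mesh <- make_test_mesh(rbind(c(4, 4, 4), c(5, 4, 4)), fill = c(1150, 700))
  set.seed(1)
  mesh <- rebalance_overloaded(mesh, 1)
  tots <- colSums(mesh$state$M)
  expect_equal(tots[mesh$map[5, 5, 5]], 1000)
  expect_equal(tots[mesh$map[6, 5, 5]], 850)
})

test_that("equal-free-space ties are broken reproducibly by the seed", {
  build <- function(seed) {
    mesh <- make_test_mesh(rbind(c(4, 4, 4), c(5, 4, 4), c(3, 4, 4)),
                           fill = c(1120, 900, 900))
    set.seed(seed)
    colSums(rebalance_overloaded(mesh, 1)$state$M)
  }
  expect_identical(build(7), build(7))
  # excess 120 into two receivers with 100 free each: the seed decides which
  # one fills completely
  filled <- vapply(1:20, function(s) which(abs(build(s) - 1000) < 1e-9)[2],
                   numeric(1))
  expect_gt(length(unique(filled)), 1)
})

test_that("when all 26 neighbors are full a chain shift adds one GC", {
  co <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
  mesh <- make_test_mesh(co, fill = 1000)
  center <- mesh$map[5, 5, 5]
  mesh$state$M[1, center] <- 1150
  set.seed(2)
  n0 <- nrow(mesh$coords)
  tot0 <- sum(mesh$state$M)
  mesh <- rebalance_overloaded(mesh, center)
  expect_equal(nrow(mesh$coords), n0 + 1)
  expect_equal(sum(mesh$state$M), tot0)
  expect_lte(sum(mesh$state$M[, center]), 1100)
})

test_that("underloaded GCs push contents to neighbors and may vacate", {
  # last GC of a 2-GC tumor underloaded, neighbor can absorb it fully
  mesh <- make_test_mesh(rbind(c(4, 4, 4), c(5, 4, 4)), fill = c(500, 400))
  set.seed(3)
  mesh <- rebalance_underloaded(mesh, 1)
  expect_equal(nrow(mesh$coords), 1)
  expect_equal(sum(mesh$state$M), 900)
  # a GC inside the band is left alone
  mesh2 <- make_test_mesh(rbind(c(4, 4, 4), c(5, 4, 4)), fill = c(950, 950))
  before <- mesh2$state$M
  mesh2 <- rebalance_underloaded(mesh2, 1)
  expect_identical(mesh2$state$M, before)
})

test_that("an emptied interior GC triggers an inward chain fill", {
  co <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
  mesh <- make_test_mesh(co, fill = 950)
  center <- mesh$map[5, 5, 5]
  mesh$state$M[1, center] <- 100   # far below band; neighbors can absorb it
  set.seed(4)
  n0 <- nrow(mesh$coords)
  tot0 <- sum(mesh$state$M)
  mesh <- rebalance_underloaded(mesh, center)
  mesh <- repair_fragmentation(mesh)
  expect_equal(sum(mesh$state$M), tot0)
  expect_equal(nrow(mesh$coords), n0 - 1)
  # no interior hole remains
  lab <- color_necrotic(mesh, 0.9)
  expect_equal(lab[5, 5, 5] > 0 ||
                 sum(vapply(1:nrow(mesh$coords), function(j)
                   all(oncosim:::.neighbor_ids(mesh, mesh$coords[j, ],
                                               oncosim:::.nb6)$ids == 0L),
                   logical(1))) == 0, TRUE)
})

test_that("stray GCs drift toward the center of mass along the smallest offset axis", {
  mesh <- make_test_mesh(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0),
                               c(7, 3, 0)),
                         fill = c(1000, 1000, 1000, 1000, 200),
                         dims = c(9, 9, 3))
  tot0 <- sum(mesh$state$M)
  set.seed(5)
  mesh1 <- repair_fragmentation(mesh)
  # first displacement is along y, the smallest non-zero offset to the mass
  expect_false(any(mesh1$coords[, 1] == 7 & mesh1$coords[, 2] == 3))
  # iterated to fixpoint: no isolated GC remains, cells conserved
  isolated <- vapply(seq_len(nrow(mesh1$coords)), function(j)
    all(oncosim:::.neighbor_ids(mesh1, mesh1$coords[j, ],
                                oncosim:::.nb6)$ids == 0L), logical(1))
  expect_false(any(isolated & nrow(mesh1$coords) > 1))
  expect_equal(sum(mesh1$state$M), tot0)
  # a cohesive block is left unchanged
  co <- as.matrix(expand.grid(x = 3:4, y = 3:4, z = 3:4))
  mesh2 <- make_test_mesh(co, fill = 1000)
  before <- mesh2$coords
  mesh2 <- repair_fragmentation(mesh2)
  expect_identical(mesh2$coords, before)
})

test_that("an enclosed hole in a 3x3x3 shell is filled", {
  co <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
  co <- co[!(co[, 1] == 4 & co[, 2] == 4 & co[, 3] == 4), ]
  mesh <- make_test_mesh(co, fill = 1000)
  set.seed(6)
  mesh <- repair_fragmentation(mesh)
  expect_gt(mesh$map[5, 5, 5], 0)
})

test_that("necrotic coloring applies the dead-fraction criterion", {
  mesh <- make_test_mesh(rbind(c(4, 4, 4), c(5, 4, 4)), fill = 0)
  L <- mesh$state$layout
  # GC 1: 95% dead; GC 2: 85% dead
  mesh$state$M[L$nec_rows[1], 1] <- 950; mesh$state$M[L$diff_row, 1] <- 50
  mesh$state$M[L$nec_rows[1], 2] <- 850; mesh$state$M[L$diff_row, 2] <- 150
  lab <- color_necrotic(mesh, 0.9)
  expect_equal(lab[5, 5, 5], 2L)
  expect_equal(lab[6, 5, 5], 1L)
  expect_equal(lab[1, 1, 1], 0L)
  expect_error(color_necrotic(mesh, 0.5), "color_criterion")
})

test_that("tumor volume is the occupied count times the voxel volume", {
  co <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))[1:100, ]
  mesh <- make_test_mesh(co, fill = 1000)
  expect_equal(tumor_volume(mesh), 100)
  p2 <- toy_params(voxel_edge = 2, cell_density = 1000,
                   spatial_evolution = TRUE)
  geo <- list(dims = c(9L, 9L, 9L), occupied = co,
              necrotic = matrix(integer(0), 0, 3))
  mesh2 <- tumor_mesh(geo, p2)
  for (j in 1:100) mesh2$state$M[1, j] <- 1
  expect_equal(tumor_volume(mesh2), 800)      # x8 with a 2 mm edge
  mesh$state$M[] <- 0
  expect_equal(tumor_volume(mesh), 0)
})

test_that("a full second scan conserves cells and restores the occupancy band", {
  co <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
  mesh <- make_test_mesh(co, fill = 1000)
  set.seed(11)
  mesh$state$M[1, ] <- runif(27, 700, 1300)
  tot0 <- sum(mesh$state$M)
  fb0 <- mesh$events$chain_expansions
  mesh <- second_scan(mesh)
  expect_equal(sum(mesh$state$M), tot0, tolerance = 1e-12)
  expect_band_ok(mesh, mesh$events$chain_expansions > fb0)
})

test_that("identical seeds give bit-identical meshes after many scans", {
  scan_many <- function(seed) {
    co <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
    mesh <- make_test_mesh(co, fill = 1000)
    set.seed(seed)
    mesh$state$M[1, ] <- runif(27, 500, 1500)
    for (i in 1:5) {
      mesh$state$M[1, ] <- mesh$state$M[1, ] * runif(ncol(mesh$state$M), 0.9, 1.15)
      mesh <- second_scan(mesh)
    }
    mesh
  }
  a <- scan_many(123); b <- scan_many(123)
  expect_identical(a$state$M, b$state$M)
  expect_identical(a$coords, b$coords)
})

test_that("free growth of an initialized sphere stays near-spherical", {
  p <- virtual_tumor_params(1, spatial_evolution = TRUE, rng_seed = 5)
  eq <- bootstrap_equilibrium(p, seed = 5)
  geo <- build_geometry(tumor_geometry(6, 6, 6), dims = c(20, 20, 20))
  mesh <- init_mesh(tumor_mesh(geo, p), eq)
  run <- run_simulation(mesh, p, days = 100, seed = 5, record_stride = 240)
  expect_true(all(diff(run$series$volume_mm3) >= 0))
  # principal axis lengths from the cell-weighted coordinate spread
  w <- colSums(run$final$state$M)
  ax <- vapply(1:3, function(k) {
    mu <- sum(run$final$coords[, k] * w) / sum(w)
    sqrt(sum(w * (run$final$coords[, k] - mu)^2) / sum(w))
  }, numeric(1))
  expect_lt((max(ax) - min(ax)) / mean(ax), 0.10)
})
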