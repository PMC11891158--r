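# Shared fixtures, built in code.

# A fast toy tumor: short cycle, mild rates, two LIMP generations.
toy_params <- function(...) {
  defaults <- list(T_c = 10, T_G0 = 24, T_N = 5, T_A = 5,
                   R_A = 1e-3, R_NDiff = 0, R_ADiff = 5e-4,
                   P_G0toG1 = 0.8, P_sleep = 0.2, P_sym = 0.3, N_LIMP = 2)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

# Pure growth, no death, fully symmetric: population doubles every T_c.
doubling_params <- function(...) {
  defaults <- list(T_c = 10, T_G0 = 1e6, T_N = 5, T_A = 5,
                   R_A = 0, R_NDiff = 0, R_ADiff = 0,
                   P_G0toG1 = 1, P_sleep = 0, P_sym = 1, N_LIMP = 2)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

# Band invariant with the documented exemptions: never above band; below band
# only where no occupied neighbor has free space, or where the overload
# fallback deposited a fresh excess column this scan.
expect_band_ok <- function(mesh, fallback_fired) {
  NBC <- mesh$NBC
  tots <- colSums(mesh$state$M)
  expect_true(all(tots <= (1 + mesh$margin) * NBC + 1e-6))
  if (fallback_fired) return(invisible())
  under <- which(tots > 0 & tots < (1 - mesh$margin) * NBC - 1e-6)
  for (j in under) {
    ids <- oncosim:::.neighbor_ids(mesh, mesh$coords[j, ], oncosim:::.nb26)$ids
    ids <- ids[ids > 0]
    expect_true(all(tots[ids] >= NBC - 1e-6))
  }
}

# A small mesh whose GC contents can be set directly. `fill` gives the total
# cells per occupied GC (recycled); cells are parked in the first compartment
# row, which is all the morphology rules care about.
make_test_mesh <- function(coords, fill, dims = c(9, 9, 9),
                           cell_density = 1000, margin = 0.1) {
  p <- toy_params(cell_density = cell_density, margin_percent = margin,
                  spatial_evolution = TRUE)
  geo <- list(dims = as.integer(dims),
              occupied = as.matrix(coords),
              necrotic = matrix(integer(0), 0, 3))
  mesh <- tumor_mesh(geo, p)
  fill <- rep_len(fill, nrow(mesh$coords))
  for (j in seq_len(nrow(mesh$coords))) mesh$state$M[1, j] <- fill[j]
  mesh
}

# Random parameter draws over plausible prostate ranges.
draw_params <- function() {
  model_params(T_c = runif(1, 25, 40), T_G0 = runif(1, 48, 400),
               T_N = runif(1, 2, 150), T_A = runif(1, 2, 20),
               R_A = runif(1, 0, 70e-4), R_NDiff = runif(1, 0, 6e-4),
               R_ADiff = runif(1, 0, 16e-4),
               P_G0toG1 = runif(1, 0.05, 1), P_sleep = runif(1, 0.05, 0.5),
               P_sym = runif(1, 0, 0.6), N_LIMP = sample(3:9, 1))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
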