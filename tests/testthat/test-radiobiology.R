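test_that("linear-quadratic survival matches its closed form", {
  expect_equal(surviving_fraction(0.15, 0.05, 2), exp(-0.5))
  expect_equal(surviving_fraction(0.3, 0.1, 0), 1)
  expect_equal(surviving_fraction(0, 0, 10), 1)
  expect_error(surviving_fraction(0.1, 0.01, -2), "dose")
  # fraction splitting: survivals multiply with the dose-squared terms summed
  a <- 0.2; b <- 0.02
  expect_equal(surviving_fraction(a, b, 2) * surviving_fraction(a, b, 3),
               exp(-(a * 5 + b * (4 + 9))))
})

test_that("OER perturbations give the phase-specific sensitivities", {
  rs <- derive_phase_sensitivities(0.026, 0.026 / 3, OER = 2)
  expect_equal(rs$alpha_G0, 0.013)
  expect_equal(rs$alpha_s, 0.6 * 0.026 + 0.4 * 0.013)
  expect_equal(rs$alpha_s, 0.0208)
  expect_equal(rs$beta_G0, (0.026 / 3) / 4)

  rs <- derive_phase_sensitivities(0.15, 0.05, OER = 2.388)
  expect_equal(rs$alpha_G0, 0.06281407, tolerance = 1e-7)
  expect_equal(rs$beta_G0, 0.008768017, tolerance = 1e-7)

  # OER = 1 degeneracy: all phases share the proliferating values
  rs <- derive_phase_sensitivities(0.1, 0.033, OER = 1)
  expect_equal(rs$alpha_G0, rs$alpha_p)
  expect_equal(rs$alpha_s, rs$alpha_p)
  expect_equal(rs$beta_G0, rs$beta_p)
  expect_equal(rs$beta_s, rs$beta_p)

  expect_error(derive_phase_sensitivities(0.1, 0.03, OER = 0.5), "OER")
})

test_that("irradiation marks the LQ-killed fraction as hit, conserving totals", {
  p <- toy_params()
  st <- new_compartment_state(p)
  L <- st$layout
  # 1000 unhit LIMP cells in G1
  g1_bins <- which(L$phase_of[[2]] == 1)
  st$M[L$cyc_rows[[2]][g1_bins], 1] <- 1000 / length(g1_bins)
  rs <- derive_phase_sensitivities(0.15, 0.05, OER = 1)
  out <- apply_irradiation(st, 2, rs)
  hit <- sum(out$M[L$cyc_rows[[L$hit2_i]], 1])
  expect_equal(hit, 1000 * (1 - exp(-0.5)), tolerance = 1e-9)
  expect_equal(sum(out$M), 1000)                       # marking moves, not kills
  # zero dose is the identity
  expect_equal(apply_irradiation(st, 0, rs)$M, st$M)
  # cell_kill_factor = 0: no stem cell is ever marked
  st2 <- seed_stem(new_compartment_state(p), 500)
  rs0 <- derive_phase_sensitivities(0.3, 0.1, OER = 1, cell_kill_factor = 0)
  out2 <- apply_irradiation(st2, 10, rs0)
  expect_equal(sum(out2$M[L$cyc_rows[[L$stem_i]], 1]), 500)
  expect_equal(sum(out2$M[c(L$cyc_rows[[L$hit2_i]], L$cyc_rows[[L$hit1_i]]), 1]), 0)
})

test_that("hit cells die through necrosis after two further mitoses", {
  p <- toy_params(R_A = 0, R_NDiff = 0, R_ADiff = 0, P_sleep = 0)
  st <- new_compartment_state(p)
  L <- st$layout
  st$M[L$g1_rows[L$hit2_i], 1] <- 100       # freshly hit cells entering G1
  Tc <- sum(phase_bins(p$T_c))
  st <- step_compartments(st, p, steps = Tc)$state
  expect_equal(sum(st$M[L$cyc_rows[[L$hit1_i]], 1]), 200)  # first mitosis
  st <- step_compartments(st, p, steps = Tc)$state
  # second mitosis: every offspring goes to the necrotic pool
  expect_equal(sum(st$M[unlist(L$cyc_rows), 1]), 0)
  expect_equal(sum(st$M[L$nec_rows, 1]), 400)
})

test_that("weekday schedules pause over weekends", {
  s <- make_schedule(0, 5, 2, hour_of_day = 8)
  expect_equal(s$time_hours, c(0, 1, 2, 3, 4) * 24 + 8)
  s <- make_schedule(0, 7, 2, hour_of_day = 8)
  expect_equal(s$time_hours, c(0, 1, 2, 3, 4, 7, 8) * 24 + 8)
  s <- make_schedule(0, 0, 2)
  expect_equal(nrow(s), 0)
  expect_error(make_schedule(0, 3, dose_per_fraction = 0), "dose")
  s <- make_schedule(0, 10, 2, skip_weekends = FALSE)
  expect_equal(diff(s$time_hours), rep(24, 9))
  # schedules round-trip through CSV
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_schedule(make_schedule(0, 7, 1.8), path)
  expect_equal(read_schedule(path)$dose_Gy, rep(1.8, 7))
})
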