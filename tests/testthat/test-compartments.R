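test_that("stepping an empty state is the identity with zero deltas", {
  p <- toy_params()
  st <- new_compartment_state(p, 3)
  out <- step_compartments(st, p, steps = 5, track_deltas = TRUE)
  expect_equal(sum(out$state$M), 0)
  expect_true(all(unlist(out$deltas) == 0))
})

test_that("per-hour death rates move the stated fractions of differentiated cells", {
  p <- toy_params(R_ADiff = 0.01, R_NDiff = 0)
  st <- new_compartment_state(p)
  L <- st$layout
  st$M[L$diff_row, 1] <- 1000
  out <- step_compartments(st, p)$state
  expect_equal(out$M[L$diff_row, 1], 990)
  expect_equal(sum(out$M[L$apo_rows, 1]), 10)
  expect_equal(sum(out$M[L$nec_rows, 1]), 0)
})

test_that("mitosis outcomes follow the stem/LIMP branching rules", {
  p <- toy_params(N_LIMP = 4)
  # fully asymmetric: every division yields one stem and one LIMP daughter
  p$P_sym <- 0
  o <- mitosis_outcome("STEM", 100, p)
  expect_equal(o$stem, 100)
  expect_equal(o$limp, 100)
  expect_equal(o$limp_remaining, 4)
  # fully symmetric: two stem daughters
  p$P_sym <- 1
  o <- mitosis_outcome("STEM", 100, p)
  expect_equal(o$stem, 200)
  expect_equal(o$limp, 0)
  # terminal LIMP division: two differentiated daughters, no G0 routing
  o <- mitosis_outcome("LIMP", 50, p, remaining = 1)
  expect_equal(o$diff, 100)
  expect_equal(o$to_g0 + o$to_g1, 0)
  # intermediate LIMP division decrements the mitotic reserve
  o <- mitosis_outcome("LIMP", 50, p, remaining = 3)
  expect_equal(o$limp, 100)
  expect_equal(o$limp_remaining, 2)
  expect_error(mitosis_outcome("DIFF", 1, p), "category")
})

test_that("newborns split P_sleep to G0 with siblings routed together", {
  p <- toy_params(P_sleep = 0.2)
  p$P_sym <- 1
  # 100 stem cells about to exit M: expect 200 newborns, 160 G1 / 40 G0
  st <- new_compartment_state(p)
  L <- st$layout
  st$M[L$m_rows[L$stem_i], 1] <- 100
  out <- step_compartments(st, p)$state
  newborn_g1 <- out$M[L$g1_rows[L$stem_i], 1]
  g0 <- out$M[L$g0_rows[L$stem_i], 1]
  loss <- 1 - p$R_A              # one hour of spontaneous apoptosis
  expect_equal(newborn_g1, 160 * loss, tolerance = 1e-10)
  expect_equal(g0, 40 * loss, tolerance = 1e-10)
  # Monte-Carlo branching converges to the expectation over seeds
  sims <- vapply(1:400, function(i) {
    set.seed(i)
    st2 <- new_compartment_state(p)
    st2$M[L$m_rows[L$stem_i], 1] <- 100
    out2 <- step_compartments(st2, p, stochastic = TRUE)$state
    out2$M[L$g0_rows[L$stem_i], 1]
  }, numeric(1))
  expect_equal(mean(sims), 40, tolerance = 0.05)
  expect_true(all(sims %% 2 == 0))   # sibling pairs routed together
})

test_that("cell number is conserved through every step", {
  set.seed(99)
  for (i in 1:20) {
    p <- draw_params()
    st <- new_compartment_state(p, 2)
    st$M[] <- stats::runif(length(st$M), 0, 50)
    before <- sum(total_cells(st))
    out <- step_compartments(st, p, track_deltas = TRUE)
    d <- out$deltas
    after <- sum(total_cells(out$state))
    expect_equal(after,
                 before + d$births - d$cleared_apoptotic - d$cleared_necrotic,
                 tolerance = 1e-9)
    expect_true(all(out$state$M >= 0))
  }
})

test_that("without death or dormancy the population never decreases", {
  p <- toy_params(R_A = 0, R_NDiff = 0, R_ADiff = 0, T_G0 = 1e6)
  st <- seed_stem(new_compartment_state(p), 100)
  tot <- sum(total_cells(st))
  for (i in 1:100) {
    st <- step_compartments(st, p)$state
    tot2 <- sum(total_cells(st))
    expect_gte(tot2, tot - 1e-9)
    tot <- tot2
  }
})

test_that("a pure symmetric stem cohort doubles every cycle", {
  p <- doubling_params()
  st <- new_compartment_state(p)
  L <- st$layout
  st$M[L$g1_rows[L$stem_i], 1] <- 1000   # cohort entering G1 together
  for (k in 1:3) {
    st <- step_compartments(st, p, steps = sum(phase_bins(p$T_c)))$state
    expect_equal(sum(total_cells(st)), 1000 * 2^k)
  }
})

test_that("composition fractions of living cells sum to one", {
  p <- virtual_tumor_params(1)
  eq <- bootstrap_equilibrium(p, n_gcs = 2, max_days = 400)
  expect_equal(eq$gf + eq$diff_frac + eq$g0_frac, 1, tolerance = 1e-12)

  # degenerate states
  st <- new_compartment_state(p)
  expect_error(summarize_state(st), "no cells")
  st$M[st$layout$diff_row, 1] <- 10
  s <- summarize_state(st)
  expect_equal(s$diff_frac, 1)
  expect_equal(s$gf, 0)
  st$M[st$layout$diff_row, 1] <- 0
  st$M[st$layout$nec_rows[1], 1] <- 10
  expect_error(summarize_state(st), "living")
})

test_that("mean time-in-phase registers stay within the phase durations", {
  p <- toy_params()
  st <- seed_stem(new_compartment_state(p, 2), 50)
  st <- step_compartments(st, p, steps = 200)$state
  reg <- mean_time_in_phase(st)
  b <- phase_bins(p$T_c)
  for (ph in 1:4) {
    v <- reg[, ph]
    v <- v[is.finite(v)]
    expect_true(all(v >= 0 & v <= b[ph]))
  }
})
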