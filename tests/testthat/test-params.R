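test_that("phase durations follow the 0.41/0.41/0.18 split with 1-h mitosis", {
  expect_equal(unlist(phase_durations(31)),
               c(T_G1 = 12.30, T_S = 12.30, T_G2 = 5.40, T_M = 1.00))
  expect_equal(unlist(phase_durations(30)),
               c(T_G1 = 11.89, T_S = 11.89, T_G2 = 5.22, T_M = 1.00))
  expect_error(phase_durations(1.0), "T_c")
  expect_error(phase_durations(-3), "T_c")
})

test_that("integer phase bins preserve the total cycle length", {
  for (Tc in c(10, 24, 30, 31, 37, 48)) {
    b <- phase_bins(Tc)
    expect_identical(sum(b), as.integer(round(Tc)))
    expect_identical(unname(b["M"]), 1L)
    expect_identical(b[["G1"]], b[["S"]])
  }
  expect_identical(unname(phase_bins(31)), c(12L, 12L, 6L, 1L))
  expect_identical(unname(phase_bins(30)), c(12L, 12L, 5L, 1L))
})

test_that("free-growth condition evaluates the adopted parenthesization", {
  # neutral parameters: exactly one stem daughter survives per division
  p <- toy_params()
  p$P_sym <- 0; p$P_sleep <- 0; p$R_A <- 0
  expect_equal(free_growth_lhs(p), 1)
  # frozen direct-arithmetic values for the reference virtual tumors
  expect_equal(free_growth_lhs(virtual_tumor_params(1)), 1.011415,
               tolerance = 1e-5)
  expect_equal(free_growth_lhs(virtual_tumor_params(5)), 1.003770,
               tolerance = 1e-5)
  # every reference solution sustains growth under the adopted parse
  for (s in 1:5) expect_gte(free_growth_lhs(virtual_tumor_params(s)), 1)
  # the alternative literal parse is exposed and differs
  expect_false(isTRUE(all.equal(
    free_growth_lhs(virtual_tumor_params(1), parse = "literal"),
    free_growth_lhs(virtual_tumor_params(1)))))
})

test_that("growth regime thresholds are 0.9 and 1.1", {
  expect_identical(classify_growth_regime(0.85), "self-diminishing")
  expect_identical(classify_growth_regime(1.2), "growing")
  expect_identical(classify_growth_regime(1.0), "indeterminate")
  expect_identical(classify_growth_regime(0.9), "indeterminate")
  expect_identical(classify_growth_regime(1.1), "indeterminate")
  expect_error(classify_growth_regime(-0.1))
})

test_that("LHS is monotone in P_sym and P_G0toG1, antitone in R_A and P_sleep", {
  set.seed(421)
  for (i in 1:100) {
    p <- draw_params()
    eps <- 1e-4
    bump <- function(field, d) { q <- p; q[[field]] <- q[[field]] + d; q }
    l0 <- free_growth_lhs(p)
    expect_gt(free_growth_lhs(bump("P_sym", eps)), l0)
    expect_gt(free_growth_lhs(bump("P_G0toG1", -eps)) , 0) # stays defined
    expect_lt(free_growth_lhs(bump("P_G0toG1", -eps)), l0)
    expect_lt(free_growth_lhs(bump("R_A", eps)), l0)
    expect_lt(free_growth_lhs(bump("P_sleep", eps)), l0)
  }
})

test_that("parameter validation reports range violations by field", {
  rep <- validate_parameters(virtual_tumor_params(2))
  expect_true(rep$ok)
  expect_length(rep$violations, 0)

  p <- unclass(toy_params())
  p$P_sleep <- 1.5
  p$R_A <- -0.1
  rep <- validate_parameters(p)
  expect_false(rep$ok)
  fields <- vapply(rep$violations, `[[`, character(1), "field")
  expect_setequal(fields, c("P_sleep", "R_A"))
  expect_error(model_params(T_c = 31, T_G0 = 131, T_N = 29, T_A = 7,
                            R_A = -0.1, R_NDiff = 0, R_ADiff = 0,
                            P_G0toG1 = 0.5, P_sleep = 0.3, P_sym = 0.4,
                            N_LIMP = 8),
               "R_A")
})

test_that("parameter configs round-trip through YAML", {
  p <- toy_params(rng_seed = 11L, voxel_edge = 2)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  save_params_config(p, path)
  q <- load_params_config(path)
  expect_equal(unclass(q), unclass(p))

  bad <- yaml::read_yaml(path)
  bad$T_c <- NULL
  yaml::write_yaml(bad, path)
  expect_error(load_params_config(path), "T_c")
  bad$T_c <- 31; bad$bogus <- 1
  yaml::write_yaml(bad, path)
  expect_error(load_params_config(path), "bogus")
})
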