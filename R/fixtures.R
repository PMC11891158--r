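# Reference virtual-tumor parameter sets and synthetic fixtures.
#
# The five "solution" tumors are the reference prostate virtual-tumor
# parameterizations (slow-growing, low growth fraction, negligible necrosis);
# the numbered "cases" are single-parameter variations of the slowest-growing
# solution used for parametric exploration. These printed parameter sets are
# inputs to the simulator, not fitted quantities.

.ref_solutions <- list(
  `1` = list(T_c = 31, T_G0 = 131, T_N = 29, T_A = 7, N_LIMP = 8,
             R_A = 44.999e-4, R_NDiff = 5.951e-4, R_ADiff = 4.062e-4,
             P_G0toG1 = 0.5, P_sleep = 0.308, P_sym = 0.474,
             alpha_beta_ratio = 3, OER = 1.960, alpha_patient1 = 10.068e-3),
  `2` = list(T_c = 30, T_G0 = 113, T_N = 98, T_A = 16, N_LIMP = 7,
             R_A = 5.425e-4, R_NDiff = 2.775e-4, R_ADiff = 16.102e-4,
             P_G0toG1 = 0.5, P_sleep = 0.255, P_sym = 0.190,
             alpha_beta_ratio = 3, OER = 2.187, alpha_patient1 = 9.969e-3),
  `3` = list(T_c = 31, T_G0 = 146, T_N = 5, T_A = 1, N_LIMP = 9,
             R_A = 69.285e-4, R_NDiff = 0.189e-4, R_ADiff = 0.845e-4,
             P_G0toG1 = 1, P_sleep = 0.288, P_sym = 0.453,
             alpha_beta_ratio = 3, OER = 2.989, alpha_patient1 = 25.998e-3),
  `4` = list(T_c = 30, T_G0 = 109, T_N = 143, T_A = 4, N_LIMP = 7,
             R_A = 46.744e-4, R_NDiff = 0.600e-4, R_ADiff = 1.102e-4,
             P_G0toG1 = 1, P_sleep = 0.289, P_sym = 0.278,
             alpha_beta_ratio = 3, OER = 2.942, alpha_patient1 = 16.496e-3),
  `5` = list(T_c = 31, T_G0 = 373, T_N = 186, T_A = 17, N_LIMP = 7,
             R_A = 10.230e-4, R_NDiff = 0, R_ADiff = 2.591e-4,
             P_G0toG1 = 1, P_sleep = 0.179, P_sym = 0.090,
             alpha_beta_ratio = 3, OER = 2.388, alpha_patient1 = 9.336e-3)
)

#' Reference virtual-tumor parameter sets
#'
#' `virtual_tumor_params()` returns one of the five reference prostate
#' virtual-tumor parameterizations ("solutions") as an [model_params()]
#' object; `exploratory_case_params()` returns one of the seven exploratory
#' cases (0 = baseline, identical to solution 5; 1-6 single-parameter edits).
#' The radiosensitivity entries (alpha, alpha/beta ratio, OER) attached as
#' the `radiosensitivity` attribute can be fed to [radiosensitivity()].
#'
#' @param solution Integer 1-5.
#' @param ... Overrides passed on to [model_params()].
#' @return An `oncosim_params` object with a `radiosensitivity` attribute
#'   (list with `alpha`, `alpha_beta_ratio`, `OER`).
#' @export
virtual_tumor_params <- function(solution, ...) {
  key <- as.character(solution)
  if (!key %in% names(.ref_solutions))
    stop("solution must be 1..5", call. = FALSE)
  preset <- .ref_solutions[[key]]
  rs <- list(alpha = preset$alpha_patient1,
             alpha_beta_ratio = preset$alpha_beta_ratio, OER = preset$OER)
  preset$alpha_patient1 <- preset$alpha_beta_ratio <- preset$OER <- NULL
  over <- list(...)
  preset[names(over)] <- over
  p <- do.call(model_params, preset)
  attr(p, "radiosensitivity") <- rs
  p
}

#' @rdname virtual_tumor_params
#' @param case Integer 0-6.
#' @export
exploratory_case_params <- function(case, ...) {
  case <- as.integer(case)
  if (is.na(case) || case < 0L || case > 6L)
    stop("case must be 0..6", call. = FALSE)
  edits <- switch(as.character(case),
    "0" = list(),
    "1" = list(T_N = 1, T_A = 1),
    "2" = list(R_ADiff = 0),
    "3" = list(P_sleep = 0.060),
    "4" = list(P_sym = 0.15),
    "5" = list(),             # radiosensitivity edit, alpha = 0.15
    "6" = list())             # radiosensitivity edit, OER = 1
  p <- do.call(virtual_tumor_params, c(list(solution = 5), edits, list(...)))
  rs <- attr(p, "radiosensitivity")
  rs$alpha <- if (case == 5L) 0.150 else 9.254e-3
  if (case == 6L) rs$OER <- 1.00
  attr(p, "radiosensitivity") <- rs
  p
}

#' Generate a self-contained synthetic fixture
#'
#' Emits everything needed for an end-to-end run without clinical data: a
#' parameter file (prefilled from a reference virtual tumor), a voxel mask
#' (ellipsoidal `"ellipsoid-patient"` or a small `"toy-cube"`), and a weekday
#' fractionation schedule. Stands in for patient imaging and treatment plans;
#' all outputs are synthetic.
#'
#' @param kind `"ellipsoid-patient"` or `"toy-cube"`.
#' @param dir Output directory (created if needed).
#' @param solution Reference parameter set for `"ellipsoid-patient"`.
#' @param diameters Tumor diameters in mm (ellipsoid) or cube side in GCs.
#' @param n_fractions,dose_per_fraction,start_weekday Schedule settings
#'   (weekday fractions, weekend pause).
#' @param voxel_edge GC edge, mm.
#' @param seed RNG seed recorded in the config.
#' @return Invisibly, a list with the written file paths (`config`, `mask`,
#'   `schedule`).
#' @export
generate_fixture <- function(kind = c("ellipsoid-patient", "toy-cube"),
                             dir = tempfile("fixture"), solution = 1,
                             diameters = c(10, 10, 10), n_fractions = 35,
                             dose_per_fraction = 2, start_weekday = 1,
                             voxel_edge = 1, seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- virtual_tumor_params(solution, voxel_edge = voxel_edge,
                                 rng_seed = as.integer(seed), mode = 2)
  cfg <- file.path(dir, "params.yaml")
  save_params_config(params, cfg)
  if (kind == "toy-cube") {
    side <- as.integer(diameters[1])
    grid <- expand.grid(x = seq_len(side) - 1L, y = seq_len(side) - 1L,
                        z = seq_len(side) - 1L)
    mask <- data.frame(grid, label = 1L)
  } else {
    geo <- build_geometry(tumor_geometry(diameters[1], diameters[2],
                                         diameters[3]),
                          voxel_edge = voxel_edge)
    mask <- data.frame(geo$occupied, label = 1L)
  }
  mask_path <- file.path(dir, "mask.csv")
  write_voxel_mask(mask, mask_path)
  sched <- make_schedule(start_day = start_weekday - 1, n_fractions = n_fractions,
                         dose_per_fraction = dose_per_fraction)
  sched_path <- file.path(dir, "schedule.csv")
  write_schedule(sched, sched_path)
  invisible(list(config = cfg, mask = mask_path, schedule = sched_path))
}
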