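#' Model parameter set
#'
#' Bundles every tunable of the tumor simulator: cell-cycle and dormancy
#' timings, category transition rates, mesh settings and run controls.
#' Durations are in hours, rates in fraction per hour.
#'
#' @param T_c Cell cycle duration of stem cells, hours (> 1; mitosis is fixed
#'   at 1 h).
#' @param T_G0 Mean dormant (G0) phase residence, hours. A dormant cell leaves
#'   G0 at rate `1/T_G0` per hour; a fraction `P_G0toG1` of leavers re-enters
#'   G1, the rest die through necrosis.
#' @param T_N Time for necrosis to complete and its lysis products to be
#'   cleared from the tumor, hours.
#' @param T_A Time for apoptosis to complete and its products to be cleared,
#'   hours.
#' @param R_A Spontaneous apoptosis rate of living stem and LIMP cells
#'   (cycling and dormant), fraction per hour.
#' @param R_NDiff Necrosis rate of terminally differentiated cells, per hour.
#' @param R_ADiff Apoptosis rate of terminally differentiated cells, per hour.
#' @param P_G0toG1 Fraction of dormant cells that re-enter the cell cycle
#'   (rather than die through necrosis) when they leave G0, in `[0, 1]`.
#' @param P_sleep Fraction of newborn cells entering G0 after mitosis.
#' @param P_sym Fraction of stem divisions that are symmetric (two stem
#'   daughters); the rest are asymmetric (one stem + one LIMP daughter).
#' @param N_LIMP Number of mitoses a LIMP (limited mitotic potential,
#'   committed progenitor) cell performs before terminal differentiation
#'   (integer, >= 1).
#' @param T_c_limp,T_G0_limp,P_G0toG1_limp Optional LIMP-class overrides;
#'   default to the stem values.
#' @param cell_density Biological cells per mm^3 at nominal packing.
#' @param voxel_edge Edge of a geometrical cell (GC, one mesh voxel), mm.
#' @param margin_percent Tolerated relative over/under-loading of a GC before
#'   the morphological rules rebalance it (0-0.5).
#' @param color_criterion Minimum dead-cell fraction for a GC to be painted
#'   necrotic (0.9-0.999).
#' @param mode 1 = free growth, 2 = treatment response.
#' @param spatial_evolution Logical; enable the second (morphological) mesh
#'   scan. When `FALSE` the simulator runs in its lattice-free, well-mixed
#'   limit.
#' @param execution_time Simulated duration after initialization, days.
#' @param rng_seed Integer seed controlling every source of randomness.
#'
#' @return An object of class `oncosim_params` (a validated named list).
#' @seealso [validate_parameters()], [free_growth_lhs()], [phase_durations()]
#' @export
#' @examples
#' p <- model_params(T_c = 31, T_G0 = 131, T_N = 29, T_A = 7,
#'                   R_A = 44.999e-4, R_NDiff = 5.951e-4, R_ADiff = 4.062e-4,
#'                   P_G0toG1 = 0.5, P_sleep = 0.308, P_sym = 0.474, N_LIMP = 8)
#' free_growth_lhs(p)
model_params <- function(T_c, T_G0, T_N, T_A,
                         R_A, R_NDiff, R_ADiff,
                         P_G0toG1, P_sleep, P_sym, N_LIMP,
                         T_c_limp = T_c, T_G0_limp = T_G0,
                         P_G0toG1_limp = P_G0toG1,
                         cell_density = 1e6, voxel_edge = 1,
                         margin_percent = 0.1, color_criterion = 0.9,
                         mode = 1, spatial_evolution = FALSE,
                         execution_time = 120, rng_seed = 1L) {
  p <- list(T_c = T_c, T_G0 = T_G0, T_N = T_N, T_A = T_A,
            R_A = R_A, R_NDiff = R_NDiff, R_ADiff = R_ADiff,
            P_G0toG1 = P_G0toG1, P_sleep = P_sleep, P_sym = P_sym,
            N_LIMP = as.integer(round(N_LIMP)),
            T_c_limp = T_c_limp, T_G0_limp = T_G0_limp,
            P_G0toG1_limp = P_G0toG1_limp,
            cell_density = cell_density, voxel_edge = voxel_edge,
            margin_percent = margin_percent,
            color_criterion = color_criterion,
            mode = as.integer(mode),
            spatial_evolution = isTRUE(spatial_evolution),
            execution_time = execution_time,
            rng_seed = as.integer(rng_seed))
  class(p) <- "oncosim_params"
  rep <- validate_parameters(p)
  if (!rep$ok) {
    msgs <- vapply(rep$violations, function(v) paste0(v$field, ": ", v$message),
                   character(1))
    stop("invalid model parameters:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  p
}

#' @export
print.oncosim_params <- function(x, ...) {
  cat("Tumor model parameters\n")
  cat(sprintf("  cycle: T_c = %g h (phases %s h), T_G0 = %g h\n",
              x$T_c, paste(unlist(phase_durations(x$T_c)), collapse = "/"),
              x$T_G0))
  cat(sprintf("  clearance: T_N = %g h, T_A = %g h\n", x$T_N, x$T_A))
  cat(sprintf("  rates/h: R_A = %g, R_NDiff = %g, R_ADiff = %g\n",
              x$R_A, x$R_NDiff, x$R_ADiff))
  cat(sprintf("  fractions: P_G0toG1 = %g, P_sleep = %g, P_sym = %g, N_LIMP = %d\n",
              x$P_G0toG1, x$P_sleep, x$P_sym, x$N_LIMP))
  lhs <- free_growth_lhs(x)
  cat(sprintf("  free-growth condition: LHS = %.4f (%s)\n",
              lhs, classify_growth_regime(lhs)))
  invisible(x)
}

#' Cell-cycle phase durations
#'
#' Mitosis is fixed at 1 h; the remaining cycle time is split as
#' `T_G1 = T_S = 0.41 (T_c - T_M)` and `T_G2 = 0.18 (T_c - T_M)`.
#' Values are returned as real hours; the hourly engine discretizes them with
#' a largest-remainder integer partition that preserves `T_c` exactly
#' (see [phase_bins()]).
#'
#' @param T_c Cell cycle duration in hours, must exceed 1 (the mitosis time).
#' @return A list with elements `T_G1`, `T_S`, `T_G2`, `T_M` (hours).
#' @export
#' @examples
#' phase_durations(31)  # 12.30, 12.30, 5.40, 1.00
phase_durations <- function(T_c) {
  if (!is.numeric(T_c) || length(T_c) != 1L || !is.finite(T_c) || T_c <= 1)
    stop("T_c must be a single number > 1 (hours)", call. = FALSE)
  rest <- T_c - 1
  list(T_G1 = 0.41 * rest, T_S = 0.41 * rest, T_G2 = 0.18 * rest, T_M = 1)
}

#' Integer hour bins per cell-cycle phase
#'
#' Discretizes [phase_durations()] onto the 1-h clock so that the bins sum
#' to `round(T_c)` -- the total cycle length, which controls the doubling
#' time, is preserved exactly -- and the `T_G1 = T_S` symmetry is kept: M is
#' 1 bin, G2 gets its rounded duration (nudged by one hour when needed to
#' leave an even remainder), and the remainder splits evenly between G1 and
#' S.
#'
#' @param T_c Cell cycle duration in hours.
#' @return Integer vector `c(G1, S, G2, M)` of hour bins, summing to
#'   `round(T_c)`.
#' @export
phase_bins <- function(T_c) {
  d <- unlist(phase_durations(T_c))
  total <- as.integer(round(T_c))
  if (total < 4)
    stop("T_c too short to resolve all four phases on the hourly clock",
         call. = FALSE)
  g2 <- max(1L, as.integer(round(d[["T_G2"]])))
  g2 <- min(g2, total - 3L)
  rest <- total - 1L - g2
  if (rest %% 2L == 1L) {             # nudge G2 to keep G1 = S
    g2 <- if (d[["T_G2"]] > g2 || g2 == 1L) g2 + 1L else g2 - 1L
    g2 <- min(max(g2, 1L), total - 3L)
    rest <- total - 1L - g2
  }
  c(G1 = rest %/% 2L, S = rest %/% 2L, G2 = g2, M = 1L)
}

#' Analytic free-growth condition
#'
#' Evaluates the left-hand side of the stem-cell self-renewal condition: the
#' expected number of stem-fated daughters per stem mitosis that survive to
#' their own mitosis,
#' `(1 + P_sym) * ((1 - P_sleep) + P_sleep * P_G0toG1 / (T_G0 * R_A + 1)) *
#' exp(-R_A * T_c)`.
#' Values above 1 indicate a self-sustaining (growing) tumor. The factor
#' `P_G0toG1 / (T_G0 * R_A + 1)` is the probability that a newborn routed
#' through the dormant pool survives dormancy and re-enters the cycle.
#'
#' @param params An [model_params()] object (stem-class values are used).
#' @param parse `"expected-daughters"` (default) multiplies the whole bracket
#'   by `(1 + P_sym)`; `"literal"` uses `1 + P_sym * bracket * exp(-R_A T_c)`,
#'   an alternative reading kept for comparison.
#' @return A dimensionless number.
#' @seealso [classify_growth_regime()]
#' @export
free_growth_lhs <- function(params, parse = c("expected-daughters", "literal")) {
  parse <- match.arg(parse)
  bracket <- (1 - params$P_sleep) +
    params$P_sleep * params$P_G0toG1 / (params$T_G0 * params$R_A + 1)
  surv <- exp(-params$R_A * params$T_c)
  if (parse == "expected-daughters")
    (1 + params$P_sym) * bracket * surv
  else
    1 + params$P_sym * bracket * surv
}

#' Classify the free-growth regime
#'
#' Maps the value of [free_growth_lhs()] onto the three regimes used when
#' screening parameter sets: below 0.9 free growth cannot be sustained, above
#' 1.1 it is ensured, and in between the outcome must be resolved by
#' simulation.
#'
#' @param lhs Non-negative number, usually from [free_growth_lhs()].
#' @return One of `"self-diminishing"`, `"indeterminate"`, `"growing"`.
#' @export
classify_growth_regime <- function(lhs) {
  if (!is.numeric(lhs) || length(lhs) != 1L || is.na(lhs) || lhs < 0)
    stop("lhs must be a single non-negative number", call. = FALSE)
  if (lhs < 0.9) "self-diminishing" else if (lhs > 1.1) "growing" else "indeterminate"
}

.check_range <- function(violations, value, field, lo, hi,
                         lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(value) || length(value) != 1L || !is.finite(value) ||
    (if (lo_open) value <= lo else value < lo) ||
    (if (hi_open) value >= hi else value > hi)
  if (bad)
    violations[[length(violations) + 1L]] <-
      list(field = field,
           message = sprintf("must be in %s%g, %g%s, got %s",
                             if (lo_open) "(" else "[", lo, hi,
                             if (hi_open) ")" else "]",
                             paste(format(value), collapse = ",")))
  violations
}

#' Validate a parameter set
#'
#' Range-checks every field against its admissible interval and embeds the
#' analytic free-growth diagnostic.
#'
#' @param params An `oncosim_params` object (or a bare named list with the
#'   same fields).
#' @return A list of class `oncosim_validation` with elements `ok`,
#'   `violations` (list of `(field, message)`), `lhs` and `growth_regime`.
#' @export
validate_parameters <- function(params) {
  v <- list()
  v <- .check_range(v, params$T_c, "T_c", 1, Inf, lo_open = TRUE)
  v <- .check_range(v, params$T_c_limp, "T_c_limp", 1, Inf, lo_open = TRUE)
  v <- .check_range(v, params$T_G0, "T_G0", 1, Inf)
  v <- .check_range(v, params$T_G0_limp, "T_G0_limp", 1, Inf)
  v <- .check_range(v, params$T_N, "T_N", 1, Inf)
  v <- .check_range(v, params$T_A, "T_A", 1, Inf)
  for (f in c("R_A", "R_NDiff", "R_ADiff"))
    v <- .check_range(v, params[[f]], f, 0, 1)
  for (f in c("P_G0toG1", "P_G0toG1_limp", "P_sleep", "P_sym"))
    v <- .check_range(v, params[[f]], f, 0, 1)
  if (!is.numeric(params$N_LIMP) || params$N_LIMP < 1 ||
      params$N_LIMP != round(params$N_LIMP))
    v[[length(v) + 1L]] <- list(field = "N_LIMP",
                                message = "must be an integer >= 1")
  v <- .check_range(v, params$cell_density, "cell_density", 0, Inf, lo_open = TRUE)
  v <- .check_range(v, params$voxel_edge, "voxel_edge", 0, Inf, lo_open = TRUE)
  v <- .check_range(v, params$margin_percent, "margin_percent", 0, 0.5)
  v <- .check_range(v, params$color_criterion, "color_criterion", 0.9, 0.999)
  if (!params$mode %in% c(1L, 2L))
    v[[length(v) + 1L]] <- list(field = "mode", message = "must be 1 or 2")
  v <- .check_range(v, params$execution_time, "execution_time", 0, Inf)

  lhs <- tryCatch(free_growth_lhs(params), error = function(e) NA_real_)
  out <- list(ok = length(v) == 0L, violations = v, lhs = lhs,
              growth_regime = if (is.na(lhs)) NA_character_
                              else classify_growth_regime(max(lhs, 0)))
  class(out) <- "oncosim_validation"
  out
}

#' @export
print.oncosim_validation <- function(x, ...) {
  cat(sprintf("Parameter validation: %s\n", if (x$ok) "OK" else "FAILED"))
  for (v in x$violations) cat(sprintf("  %s: %s\n", v$field, v$message))
  cat(sprintf("  free-growth LHS = %.4f -> %s\n", x$lhs, x$growth_regime))
  invisible(x)
}

# Fields serialized to/from flat key-value config files.
.param_config_keys <- c("T_c", "T_G0", "T_N", "T_A", "R_A", "R_NDiff",
                        "R_ADiff", "P_G0toG1", "P_sleep", "P_sym", "N_LIMP",
                        "T_c_limp", "T_G0_limp", "P_G0toG1_limp",
                        "cell_density", "voxel_edge", "margin_percent",
                        "color_criterion", "mode", "spatial_evolution",
                        "execution_time", "rng_seed")
.param_required_keys <- c("T_c", "T_G0", "T_N", "T_A", "R_A", "R_NDiff",
                          "R_ADiff", "P_G0toG1", "P_sleep", "P_sym", "N_LIMP")

#' Read / write a parameter configuration file
#'
#' Flat YAML key-value files using the parameter symbol names of
#' [model_params()]. Unknown keys are rejected; missing required keys are
#' reported by name.
#'
#' @param path File path.
#' @return `load_params_config()` returns an `oncosim_params` object;
#'   `save_params_config()` returns `path` invisibly.
#' @export
load_params_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), .param_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.param_required_keys, names(raw))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(model_params, raw)
}

#' @rdname load_params_config
#' @param params An `oncosim_params` object to serialize.
#' @export
save_params_config <- function(params, path) {
  stopifnot(inherits(params, "oncosim_params"))
  x <- unclass(params)[.param_config_keys]
  yaml::write_yaml(x, path)
  invisible(path)
}
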