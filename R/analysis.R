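# One-factor-at-a-time sensitivity analysis and radiosensitivity calibration.

#' One-factor-at-a-time sensitivity index
#'
#' Perturbs a single parameter by `+delta` and `-delta` (relative), re-runs
#' the model, and reports the percentage change in the output per +/-1%
#' change in the input:
#' `SI+ = ((Y(+) - Y) / Y) / ((p(+) - p) / p)` and analogously `SI-`.
#' A positive correlation gives `SI+ > 0` and `SI- < 0`. When the perturbed
#' run is biologically unrealistic (the evaluation fails, e.g. a
#' non-convergent bootstrap), the fallback perturbation is tried. Integer
#' parameters are perturbed to the nearest distinct integer and normalized
#' by the relative change actually applied.
#'
#' @param runner A function `params -> named numeric vector` of output
#'   measures (use common random numbers: the runner should fix its own
#'   seed).
#' @param params Baseline [model_params()].
#' @param param_name Name of the parameter to perturb.
#' @param output_name Which output of the runner to analyze.
#' @param delta Relative perturbation (default 0.05).
#' @param fallback_delta Tried when `delta` fails (default 0.025).
#' @return A list of class `sensitivity_result` with `SI_plus`, `SI_minus`,
#'   the deltas actually used, and the raw outputs.
#' @export
sensitivity_index <- function(runner, params, param_name, output_name,
                              delta = 0.05, fallback_delta = 0.025) {
  base_out <- runner(params)
  if (!output_name %in% names(base_out))
    stop("runner does not produce output '", output_name, "'", call. = FALSE)
  Y <- unname(base_out[[output_name]])
  if (!is.finite(Y) || Y == 0)
    stop("baseline output is zero; sensitivity index undefined", call. = FALSE)
  p0 <- params[[param_name]]
  if (is.null(p0) || !is.numeric(p0))
    stop("unknown parameter: ", param_name, call. = FALSE)
  integerish <- param_name == "N_LIMP"

  eval_side <- function(sign) {
    for (d in unique(c(delta, fallback_delta))) {
      p1 <- p0 * (1 + sign * d)
      if (integerish) {
        p1 <- round(p1)
        if (p1 == p0) p1 <- p0 + sign   # nearest distinct integer
        if (p1 < 1) p1 <- 1
      }
      pp <- params
      pp[[param_name]] <- p1
      if (param_name %in% c("T_c", "T_G0", "P_G0toG1"))
        pp[[paste0(param_name, "_limp")]] <- p1
      rel <- (p1 - p0) / p0
      if (rel == 0) return(list(si = 0, rel = 0, Y = Y))
      out <- tryCatch(runner(pp), error = function(e) NULL)
      if (is.null(out)) next
      Y1 <- unname(out[[output_name]])
      if (!is.finite(Y1)) next
      # normalize by the magnitude of the input change so that a positive
      # correlation gives SI+ > 0 and SI- < 0
      return(list(si = ((Y1 - Y) / Y) / abs(rel), rel = rel, Y = Y1))
    }
    list(si = NA_real_, rel = NA_real_, Y = NA_real_)
  }
  plus <- eval_side(+1)
  minus <- eval_side(-1)
  out <- list(parameter = param_name, output = output_name,
              SI_plus = plus$si, SI_minus = minus$si,
              delta_plus = plus$rel, delta_minus = minus$rel,
              Y_base = Y, Y_plus = plus$Y, Y_minus = minus$Y)
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("%s -> %s: SI+ = %.3f, SI- = %.3f (deltas %+.3g / %+.3g)\n",
              x$parameter, x$output, x$SI_plus, x$SI_minus,
              x$delta_plus, x$delta_minus))
  invisible(x)
}

#' Rank parameters by sensitivity
#'
#' Orders sensitivity results by `max(|SI+|, |SI-|)`, descending. All results
#' must refer to the same output measure.
#'
#' @param results A list of [sensitivity_index()] results.
#' @return A data.frame with one row per parameter, strongest first.
#' @export
rank_sensitivities <- function(results) {
  if (!length(results)) stop("no sensitivity results to rank", call. = FALSE)
  outs <- unique(vapply(results, `[[`, character(1), "output"))
  if (length(outs) != 1L)
    stop("results mix different output measures: ",
         paste(outs, collapse = ", "), call. = FALSE)
  df <- data.frame(
    parameter = vapply(results, `[[`, character(1), "parameter"),
    SI_plus = vapply(results, `[[`, numeric(1), "SI_plus"),
    SI_minus = vapply(results, `[[`, numeric(1), "SI_minus"))
  df$SI_max_abs <- pmax(abs(df$SI_plus), abs(df$SI_minus), na.rm = TRUE)
  df <- df[order(-df$SI_max_abs), ]
  rownames(df) <- NULL
  attr(df, "output") <- outs
  df
}

#' Calibrate the linear-quadratic alpha to an observed volume reduction
#'
#' Finds, by bracketing scalar root finding, the proliferating-phase alpha
#' for which the simulated percent volume reduction matches the observed one;
#' beta is slaved to alpha through the alpha/beta ratio. The runner must be
#' deterministic (fixed seed) for the root find to be well posed.
#'
#' @param runner A function `(alpha, beta) -> percent volume reduction`.
#' @param target_reduction Observed reduction, percent.
#' @param alpha_bracket Bracket for alpha, Gy^-1; its endpoints must produce
#'   reductions straddling the target, otherwise a no-solution error reports
#'   the reduction attainable at the bracket top.
#' @param alpha_beta_ratio Gy.
#' @param tol Absolute tolerance on the achieved-minus-target residual,
#'   percentage points.
#' @return A list of class `calibration_result` with `alpha`, `beta`,
#'   `achieved`, `target`, `iterations`, `residual`.
#' @export
calibrate_alpha <- function(runner, target_reduction,
                            alpha_bracket = c(0.001, 0.4),
                            alpha_beta_ratio = 3, tol = 0.1) {
  f <- function(a) runner(a, a / alpha_beta_ratio) - target_reduction
  f_lo <- f(alpha_bracket[1])
  f_hi <- f(alpha_bracket[2])
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
    stop(sprintf(paste("no alpha in [%g, %g] Gy^-1 reaches the target reduction",
                       "of %.2f%% (reduction at the bracket top: %.2f%%)"),
                 alpha_bracket[1], alpha_bracket[2], target_reduction,
                 f_hi + target_reduction), call. = FALSE)
  root <- stats::uniroot(f, interval = alpha_bracket,
                         f.lower = f_lo, f.upper = f_hi, tol = 1e-6)
  achieved <- root$f.root + target_reduction
  out <- list(alpha = root$root, beta = root$root / alpha_beta_ratio,
              achieved = achieved, target = target_reduction,
              iterations = root$iter, residual = root$f.root,
              converged = abs(root$f.root) < tol)
  if (!out$converged)
    warning(sprintf("calibration residual %.3f%% exceeds tol %.3f%%",
                    out$residual, tol))
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibrated alpha = %.5g Gy^-1 (beta = %.5g Gy^-2)\n",
              x$alpha, x$beta))
  cat(sprintf("  reduction %.3f%% vs target %.3f%% (residual %.3g, %d iterations)\n",
              x$achieved, x$target, x$residual, x$iterations))
  invisible(x)
}

#' Free-growth characteristics of a parameter set
#'
#' Runs the equilibrium bootstrap and reports the characteristics row of the
#' virtual tumor: doubling time, growth rate and the equilibrium cell
#' composition.
#'
#' @param params An [model_params()] object.
#' @param ... Passed to [bootstrap_equilibrium()].
#' @return A one-row data.frame with `doubling_time_days`,
#'   `growth_rate_per_h`, `dead_pct`, `gf_pct`, `stem_pct`, `diff_pct`,
#'   `g0_pct`.
#' @export
tumor_characteristics <- function(params, ...) {
  eq <- bootstrap_equilibrium(params, ...)
  data.frame(doubling_time_days = eq$doubling_time,
             growth_rate_per_h = eq$growth_rate,
             dead_pct = 100 * eq$dead_frac,
             gf_pct = 100 * eq$gf,
             stem_pct = 100 * eq$stem_frac,
             diff_pct = 100 * eq$diff_frac,
             g0_pct = 100 * eq$g0_frac)
}

#' Lattice-free treatment-response runner
#'
#' Convenience constructor of the deterministic runner used for calibration
#' and sensitivity studies: initializes a well-mixed tumor from the
#' equilibrium composition, applies a fractionation schedule, and measures
#' the percent volume reduction at follow-up.
#'
#' @param params An [model_params()] object (mode is forced to 2).
#' @param schedule An [make_schedule()] result.
#' @param follow_up_days Day of the follow-up measurement.
#' @param OER,cell_kill_factor Radiosensitivity settings.
#' @param initial_cells Initial tumor burden in cells.
#' @param eq Optional precomputed [bootstrap_equilibrium()] (saves repeating
#'   the bootstrap across calibration iterations).
#' @return A function `(alpha, beta) -> percent volume reduction`.
#' @export
treatment_runner <- function(params, schedule, follow_up_days,
                             OER = 1, cell_kill_factor = 1,
                             initial_cells = 1e8, eq = NULL) {
  params$mode <- 2L
  if (is.null(eq)) eq <- bootstrap_equilibrium(params)
  state0 <- new_compartment_state(params)
  state0$M[, 1] <- eq$profile * initial_cells
  function(alpha, beta) {
    rs <- derive_phase_sensitivities(alpha, beta, OER, cell_kill_factor)
    run <- run_simulation(state0, params, rs = rs, schedule = schedule,
                          days = follow_up_days, seed = params$rng_seed)
    volume_reduction(run)
  }
}
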