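# Linear-quadratic cell kill with OER-derived phase-specific sensitivities.

#' Linear-quadratic surviving fraction
#'
#' `S(D) = exp(-(alpha * D + beta * D^2))` for a uniform dose `D` (Gy).
#'
#' @param alpha Gy^-1, >= 0.
#' @param beta Gy^-2, >= 0.
#' @param D Dose in Gy, >= 0.
#' @return Surviving fraction in (0, 1].
#' @export
#' @examples
#' surviving_fraction(0.15, 0.05, 2)  # exp(-0.5)
surviving_fraction <- function(alpha, beta, D) {
  if (any(D < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(alpha < 0) || any(beta < 0))
    stop("radiosensitivity parameters must be >= 0", call. = FALSE)
  exp(-(alpha * D + beta * D^2))
}

#' Phase-specific radiosensitivities from the oxygen enhancement ratio
#'
#' The S phase is the most radioresistant proliferating phase and hypoxic
#' dormant (G0) cells are more resistant than any cycling phase. Given the
#' proliferating-phase values `(alpha_p, beta_p)` the others follow as
#' `alpha_G0 = alpha_p / OER`, `beta_G0 = beta_p / OER^2`,
#' `alpha_s = 0.6 alpha_p + 0.4 alpha_G0`, `beta_s = 0.6 beta_p + 0.4 beta_G0`.
#' With `OER = 1` all phases collapse to the proliferating values.
#'
#' @param alpha_p,beta_p Proliferating-phase (G1/G2/M) parameters.
#' @param OER Oxygen enhancement ratio, >= 1.
#' @param cell_kill_factor Multiplier (0-1) on the kill probability of stem
#'   cells.
#' @return An object of class `radiosensitivity`.
#' @export
derive_phase_sensitivities <- function(alpha_p, beta_p, OER,
                                       cell_kill_factor = 1) {
  if (OER < 1) stop("OER must be >= 1", call. = FALSE)
  if (alpha_p < 0 || beta_p < 0)
    stop("alpha_p and beta_p must be >= 0", call. = FALSE)
  if (cell_kill_factor < 0 || cell_kill_factor > 1)
    stop("cell_kill_factor must be in [0, 1]", call. = FALSE)
  alpha_G0 <- alpha_p / OER
  beta_G0 <- beta_p / OER^2
  out <- list(alpha_p = alpha_p, beta_p = beta_p,
              alpha_s = 0.6 * alpha_p + 0.4 * alpha_G0,
              beta_s = 0.6 * beta_p + 0.4 * beta_G0,
              alpha_G0 = alpha_G0, beta_G0 = beta_G0,
              OER = OER, cell_kill_factor = cell_kill_factor)
  class(out) <- "radiosensitivity"
  out
}

#' @rdname derive_phase_sensitivities
#' @param alpha Proliferating-phase alpha, Gy^-1.
#' @param alpha_beta_ratio alpha/beta ratio in Gy (3 Gy is the prostate
#'   convention); `beta = alpha / alpha_beta_ratio`.
#' @export
radiosensitivity <- function(alpha, alpha_beta_ratio = 3, OER = 1,
                             cell_kill_factor = 1) {
  derive_phase_sensitivities(alpha, alpha / alpha_beta_ratio, OER,
                             cell_kill_factor)
}

#' @export
print.radiosensitivity <- function(x, ...) {
  cat("Phase-specific LQ radiosensitivities (Gy^-1 / Gy^-2)\n")
  cat(sprintf("  G1/G2/M: alpha = %.4g, beta = %.4g\n", x$alpha_p, x$beta_p))
  cat(sprintf("  S      : alpha = %.4g, beta = %.4g\n", x$alpha_s, x$beta_s))
  cat(sprintf("  G0     : alpha = %.4g, beta = %.4g\n", x$alpha_G0, x$beta_G0))
  cat(sprintf("  OER = %.3f, stem cell kill factor = %g\n",
              x$OER, x$cell_kill_factor))
  invisible(x)
}

#' Mark cells hit by a radiation fraction
#'
#' Applies the linear-quadratic kill probability `1 - S(D)` compartment by
#' compartment at the instant of administration, with `(alpha, beta)` chosen
#' by phase: proliferating values for G1/G2/M, the S-phase values for S, and
#' the G0 values for dormant and (as the most radioresistant, non-cycling
#' population) terminally differentiated cells. Killed cycling and dormant
#' cells are not removed but marked as lethally hit: they enter the
#' rudimentary cycle ending in necrotic death after two further mitoses
#' (mitotic catastrophe). Killed differentiated cells transfer to the
#' necrotic pool at the next hourly step. Stem-cell kill probabilities are
#' scaled by `cell_kill_factor`. Already-hit cells are not re-marked.
#'
#' @param state An `oncosim_state`.
#' @param dose Fraction dose, Gy.
#' @param rs A [radiosensitivity()] object.
#' @param stochastic Binomial draws instead of fractional transfer.
#' @return The updated state.
#' @export
apply_irradiation <- function(state, dose, rs, stochastic = FALSE) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (dose == 0) return(state)
  L <- state$layout
  M <- state$M
  p_phase <- 1 - surviving_fraction(
    c(rs$alpha_p, rs$alpha_s, rs$alpha_p, rs$alpha_p),
    c(rs$beta_p, rs$beta_s, rs$beta_p, rs$beta_p), dose)   # G1, S, G2, M
  p_g0 <- 1 - surviving_fraction(rs$alpha_G0, rs$beta_G0, dose)
  hit2_rows <- L$cyc_rows[[L$hit2_i]]
  len_h <- length(hit2_rows)
  for (i in which(!L$is_hit)) {
    rows <- L$cyc_rows[[i]]
    p <- p_phase[L$phase_of[[i]]]
    if (i == L$stem_i) p <- p * rs$cell_kill_factor
    killed <- if (stochastic)
      matrix(stats::rbinom(length(rows) * ncol(M), round(M[rows, ]),
                           rep(p, ncol(M))), nrow = length(rows))
    else M[rows, , drop = FALSE] * p
    M[rows, ] <- M[rows, ] - killed
    tgt <- hit2_rows[pmin(ceiling(seq_along(rows) * len_h / length(rows)), len_h)]
    for (a in seq_along(rows))
      M[tgt[a], ] <- M[tgt[a], ] + killed[a, ]
    pk <- if (i == L$stem_i) p_g0 * rs$cell_kill_factor else p_g0
    g0r <- L$g0_rows[i]
    kg <- .flow(M[g0r, ], pk, stochastic)
    M[g0r, ] <- M[g0r, ] - kg
    M[L$g0_rows[L$hit2_i], ] <- M[L$g0_rows[L$hit2_i], ] + kg
  }
  kd <- .flow(M[L$diff_row, ], p_g0, stochastic)
  M[L$diff_row, ] <- M[L$diff_row, ] - kd
  M[L$diff_hit_row, ] <- M[L$diff_hit_row, ] + kd
  state$M <- M
  state
}

#' Build a fractionated radiotherapy schedule
#'
#' Daily weekday fractions with a pause during weekends (the standard
#' external-beam pattern), or uninterrupted daily fractions.
#'
#' @param start_day Day index of the first fraction; weekday = `start_day
#'   mod 7` with 0 = Monday.
#' @param n_fractions Number of fractions, >= 0.
#' @param dose_per_fraction Dose per fraction, Gy (> 0 when fractions are
#'   scheduled).
#' @param hour_of_day Administration hour (0-23).
#' @param skip_weekends Pause on Saturday/Sunday.
#' @return An object of class `rt_schedule`: a data.frame with columns
#'   `time_hours` (strictly increasing, since simulation start) and
#'   `dose_Gy`.
#' @export
make_schedule <- function(start_day = 0, n_fractions, dose_per_fraction = 2,
                          hour_of_day = 8, skip_weekends = TRUE) {
  if (n_fractions < 0) stop("n_fractions must be >= 0", call. = FALSE)
  if (n_fractions > 0 && dose_per_fraction <= 0)
    stop("dose_per_fraction must be > 0", call. = FALSE)
  days <- integer(0)
  day <- start_day
  while (length(days) < n_fractions) {
    if (!skip_weekends || !(day %% 7) %in% c(5, 6)) days <- c(days, day)
    day <- day + 1
  }
  out <- data.frame(time_hours = days * 24 + hour_of_day,
                    dose_Gy = rep(dose_per_fraction, n_fractions))
  class(out) <- c("rt_schedule", "data.frame")
  out
}

#' Read / write a radiotherapy schedule CSV
#'
#' Plain CSV with columns `time_hours`, `dose_Gy`.
#'
#' @param path File path.
#' @return `read_schedule()` returns an `rt_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_hours", "dose_Gy") %in% names(x)))
    stop("schedule CSV needs columns time_hours, dose_Gy", call. = FALSE)
  if (is.unsorted(x$time_hours, strictly = TRUE))
    stop("schedule times must be strictly increasing", call. = FALSE)
  if (any(x$dose_Gy <= 0)) stop("schedule doses must be > 0", call. = FALSE)
  class(x) <- c("rt_schedule", "data.frame")
  x
}

#' @rdname read_schedule
#' @param schedule An `rt_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("time_hours", "dose_Gy")],
                   path, row.names = FALSE)
  invisible(path)
}
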