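# Hourly simulation orchestration: irradiation events, first scan
# (cytokinetics), second scan (morphology), recording.

#' Run a tumor simulation
#'
#' Advances a tumor hour by hour. Each hour: (a) if a radiotherapy fraction
#' falls in this hour it is applied to every occupied GC before the
#' cytokinetic update (cells are marked at the instant of administration);
#' (b) the first mesh scan applies the cytokinetic diagram
#' ([step_compartments()]); (c) when spatial evolution is enabled on a mesh,
#' the second scan applies the morphological rules ([second_scan()]);
#' (d) the state is recorded every `record_stride` hours.
#'
#' A plain compartment state (or a mesh with `spatial_evolution = FALSE`)
#' runs the lattice-free, well-mixed limit in which the tumor volume is the
#' total cell count over the nominal density.
#'
#' @param object An `oncosim_state` or `oncosim_mesh`, already initialized.
#' @param params An [model_params()] object; `mode = 1` (free growth)
#'   requires an empty schedule.
#' @param rs A [radiosensitivity()] object (required when irradiating).
#' @param schedule An [make_schedule()] result or `NULL`.
#' @param days Simulated days.
#' @param seed RNG seed for the run (morphological tie-breaks, Monte-Carlo
#'   mode).
#' @param record_stride Hours between records.
#' @param stochastic Monte-Carlo integer flows.
#' @return An object of class `oncosim_run` with the record data.frame
#'   `series` (columns `t_hours`, `volume_mm3`, `total`, `stem`, `limp`,
#'   `hit`, `diff`, `g0`, `apoptotic`, `necrotic`, `gf`, `stem_frac`,
#'   `diff_frac`, `g0_frac`, `dead_frac`, `occupied`), the event log, and the
#'   run settings.
#' @export
run_simulation <- function(object, params, rs = NULL, schedule = NULL,
                           days = params$execution_time,
                           seed = params$rng_seed, record_stride = 24L,
                           stochastic = FALSE) {
  is_mesh <- inherits(object, "oncosim_mesh")
  if (!is_mesh && !inherits(object, "oncosim_state"))
    stop("object must be an oncosim_state or oncosim_mesh", call. = FALSE)
  has_rt <- !is.null(schedule) && nrow(schedule) > 0
  if (params$mode == 1L && has_rt)
    stop("mode 1 simulates free growth; pass no schedule (or set mode = 2)",
         call. = FALSE)
  if (has_rt && is.null(rs))
    stop("a radiosensitivity object is needed to irradiate", call. = FALSE)
  set.seed(seed)
  spatial <- is_mesh && params$spatial_evolution
  t_end <- as.integer(round(days * 24))
  event_hours <- if (has_rt) as.integer(floor(schedule$time_hours)) else integer(0)
  doses <- if (has_rt) schedule$dose_Gy else numeric(0)

  state <- if (is_mesh) object$state else object
  L <- state$layout
  rec_rows <- list(
    stem = c(L$cyc_rows[[L$stem_i]]), limp = unlist(L$cyc_rows[L$limp_i]),
    hit = c(L$cyc_rows[[L$hit2_i]], L$cyc_rows[[L$hit1_i]]),
    diff = c(L$diff_row, L$diff_hit_row), g0 = L$g0_rows,
    apo = L$apo_rows, nec = L$nec_rows)
  n_rec <- t_end %/% record_stride + 1L
  series <- matrix(NA_real_, n_rec, 16L)
  colnames(series) <- c("t_hours", "volume_mm3", "total", "stem", "limp",
                        "hit", "diff", "g0", "apoptotic", "necrotic", "gf",
                        "stem_frac", "diff_frac", "g0_frac", "dead_frac",
                        "occupied")
  irec <- 0L
  record <- function(t) {
    M <- if (is_mesh) object$state$M else state$M
    tot <- sum(M)
    cyc <- sum(M[L$all_cyc_rows, ])
    g0 <- sum(M[L$g0_rows, ])
    diff <- sum(M[rec_rows$diff, ])
    dead <- sum(M[c(L$apo_rows, L$nec_rows), ])
    living <- cyc + g0 + diff
    stem <- sum(M[rec_rows$stem, ]) + sum(M[L$g0_rows[L$stem_i], ])
    vol <- if (spatial) tumor_volume(object)
           else tot / params$cell_density
    occ <- if (is_mesh) sum(colSums(M) > 0) else ncol(M)
    irec <<- irec + 1L
    series[irec, ] <<- c(t, vol, tot,
                         sum(M[rec_rows$stem, ]), sum(M[rec_rows$limp, ]),
                         sum(M[rec_rows$hit, ]), diff, g0,
                         sum(M[L$apo_rows, ]), sum(M[L$nec_rows, ]),
                         cyc / living, stem / living, diff / living,
                         g0 / living, dead / tot, occ)
  }
  record(0L)
  events <- list()
  for (t in seq_len(t_end)) {
    hit_now <- which(event_hours == t - 1L)
    for (e in hit_now) {
      if (is_mesh)
        object$state <- apply_irradiation(object$state, doses[e], rs, stochastic)
      else
        state <- apply_irradiation(state, doses[e], rs, stochastic)
      events[[length(events) + 1L]] <-
        list(t = t - 1L, type = "irradiation", dose = doses[e])
    }
    if (is_mesh) {
      object$state <- step_compartments(object$state, params,
                                        stochastic = stochastic)$state
      if (spatial) object <- second_scan(object)
    } else {
      state <- step_compartments(state, params, stochastic = stochastic)$state
    }
    if (t %% record_stride == 0L) record(t)
  }
  out <- list(series = as.data.frame(series[seq_len(irec), , drop = FALSE]),
              events = events, params = params, rs = rs,
              schedule = schedule, seed = seed, spatial = spatial,
              final = if (is_mesh) object else state)
  class(out) <- "oncosim_run"
  out
}

#' @export
print.oncosim_run <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat(sprintf("Tumor simulation: %g days (%s%s), %d records\n",
              s$t_hours[n] / 24,
              if (x$spatial) "3-D mesh" else "lattice-free",
              if (length(x$events)) sprintf(", %d irradiations", length(x$events))
              else ", free growth", n))
  cat(sprintf("  volume %.4g -> %.4g mm^3 (%+.2f%%)\n", s$volume_mm3[1],
              s$volume_mm3[n],
              100 * (s$volume_mm3[n] - s$volume_mm3[1]) / s$volume_mm3[1]))
  cat(sprintf("  final composition: GF %.2f%% | diff %.2f%% | G0 %.2f%% | dead %.2f%%\n",
              100 * s$gf[n], 100 * s$diff_frac[n], 100 * s$g0_frac[n],
              100 * s$dead_frac[n]))
  invisible(x)
}

#' @export
summary.oncosim_run <- function(object, ...) {
  s <- object$series
  out <- list(days = s$t_hours[nrow(s)] / 24,
              volume_start = s$volume_mm3[1],
              volume_end = s$volume_mm3[nrow(s)],
              volume_reduction_pct = volume_reduction(object),
              n_fractions = length(object$events),
              final = as.list(s[nrow(s), ]))
  class(out) <- "summary.oncosim_run"
  out
}

#' @export
print.summary.oncosim_run <- function(x, ...) {
  cat(sprintf("%g simulated days, %d fractions\n", x$days, x$n_fractions))
  cat(sprintf("volume %.4g -> %.4g mm^3, reduction %.2f%%\n",
              x$volume_start, x$volume_end, x$volume_reduction_pct))
  invisible(x)
}

#' @export
plot.oncosim_run <- function(x, which = c("volume", "fractions"), ...) {
  which <- match.arg(which)
  s <- x$series
  if (which == "volume") {
    graphics::plot(s$t_hours / 24, s$volume_mm3, type = "l",
                   xlab = "time (days)", ylab = expression(volume ~ (mm^3)),
                   main = "Tumor volume", ...)
    if (length(x$events))
      graphics::rug(vapply(x$events, `[[`, numeric(1), "t") / 24)
  } else {
    graphics::matplot(s$t_hours / 24,
                      100 * cbind(s$gf, s$stem_frac, s$diff_frac, s$g0_frac,
                                  s$dead_frac),
                      type = "l", lty = 1, xlab = "time (days)",
                      ylab = "fraction (%)", main = "Tumor composition", ...)
    graphics::legend("topright", c("GF", "stem", "diff", "G0", "dead"),
                     col = 1:5, lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Percent tumor volume reduction between two time points
#'
#' `100 (V(t0) - V(t1)) / V(t0)`; negative values indicate regrowth.
#'
#' @param run An `oncosim_run`.
#' @param t0,t1 Hours since simulation start (defaults: first and last
#'   record).
#' @return Percent reduction.
#' @export
volume_reduction <- function(run, t0 = NULL, t1 = NULL) {
  s <- run$series
  if (is.null(t0)) t0 <- s$t_hours[1]
  if (is.null(t1)) t1 <- s$t_hours[nrow(s)]
  v0 <- stats::approx(s$t_hours, s$volume_mm3, t0)$y
  v1 <- stats::approx(s$t_hours, s$volume_mm3, t1)$y
  if (is.na(v0) || is.na(v1)) stop("t0/t1 outside the record range", call. = FALSE)
  if (v0 <= 0) stop("volume at t0 is zero; reduction undefined", call. = FALSE)
  100 * (v0 - v1) / v0
}

#' Write a simulation series to CSV
#'
#' @param run An `oncosim_run`.
#' @param path Output file.
#' @export
write_series <- function(run, path) {
  utils::write.csv(run$series, path, row.names = FALSE)
  invisible(path)
}
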