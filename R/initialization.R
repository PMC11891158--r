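# Tumor initialization: equilibrium bootstrap, geometry, mesh population.

#' Equilibrium bootstrap of the tumor cell composition
#'
#' Grows a small stem-cell seed with the cytokinetic update alone (no mesh
#' mechanics) until the relative sizes of all cell categories stabilize, then
#' fits a log-linear model to the total-cell series to report the free-growth
#' rate. The converged composition is used to initialize tumors whose volume
#' then grows monotonically from the first simulated hour, avoiding the
#' initial-dip artifact of ad hoc initializations. Parameter sets that cannot
#' sustain growth make the bootstrap fail with an error.
#'
#' @param params An [model_params()] object.
#' @param n_gcs Number of independently seeded GCs evolved side by side.
#' @param seed_stem_count Stem cells seeded per GC.
#' @param seed RNG seed for the initial time-in-phase draws.
#' @param max_days Simulated-day budget before giving up on stabilization.
#' @param stability_tol Relative variation of every composition fraction over
#'   the sliding window below which equilibrium is declared.
#' @param window_days Length of the sliding stability window, days.
#' @param stochastic Use Monte-Carlo integer flows.
#' @param g0_seed_fraction Fraction of the seed started in G0.
#' @return An object of class `oncosim_equilibrium`: composition fractions
#'   (`gf`, `stem_frac`, `diff_frac`, `g0_frac`, `dead_frac`), the normalized
#'   compartment `profile` (the equilibrium age-structure eigenvector used by
#'   [init_mesh()]), `growth_rate` (per hour), `doubling_time` (days),
#'   `converged`, `days`, and the daily `trace`.
#' @export
bootstrap_equilibrium <- function(params, n_gcs = 10, seed_stem_count = 100,
                                  seed = params$rng_seed, max_days = 3000,
                                  stability_tol = 0.01, window_days = 30,
                                  stochastic = FALSE, g0_seed_fraction = 0) {
  lhs <- free_growth_lhs(params)
  if (classify_growth_regime(lhs) == "self-diminishing")
    stop(sprintf(paste("parameter set cannot sustain free growth",
                       "(condition LHS = %.3f < 0.9); initial tumor not created"),
                 lhs), call. = FALSE)
  set.seed(seed)
  state <- seed_stem(new_compartment_state(params, n_gcs),
                     count = seed_stem_count, g0_fraction = g0_seed_fraction)
  keys <- c("gf", "stem_frac", "diff_frac", "g0_frac", "dead_frac")
  trace <- matrix(NA_real_, nrow = max_days + 1L, ncol = length(keys) + 2L,
                  dimnames = list(NULL, c("day", "total", keys)))
  record <- function(day) {
    s <- summarize_state(state)
    trace[day + 1L, ] <<- c(day, sum(total_cells(state)), unlist(s)[keys])
  }
  record(0L)
  win <- as.integer(window_days)
  converged <- FALSE
  day <- 0L
  while (day < max_days) {
    day <- day + 1L
    state <- step_compartments(state, params, steps = 24L,
                               stochastic = stochastic)$state
    tot <- sum(total_cells(state))
    if (!is.finite(tot) || tot < 1e-6 * seed_stem_count * n_gcs)
      stop("tumor population collapsed during the bootstrap; the parameter set cannot sustain free growth",
           call. = FALSE)
    record(day)
    if (day >= 2L * win) {
      w <- trace[(day - win + 1L):(day + 1L), keys, drop = FALSE]
      rng <- apply(w, 2, function(x) diff(range(x)) / max(mean(x), 1e-4))
      if (all(rng < stability_tol)) { converged <- TRUE; break }
    }
  }
  trace <- as.data.frame(trace[seq_len(day + 1L), , drop = FALSE])
  fit_rows <- (day - min(win, day) + 1L):(day + 1L)
  fit <- stats::lm(log(total) ~ I(day * 24), data = trace[fit_rows, ])
  rate <- unname(stats::coef(fit)[2])
  if (converged && rate <= 0)
    stop(sprintf(paste("composition stabilized but the population is not growing",
                       "(rate = %.3g per hour); the parameter set cannot sustain",
                       "free growth"), rate), call. = FALSE)
  if (!converged && rate <= 0)
    stop("no equilibrium reached and the population is not growing; the parameter set cannot sustain free growth",
         call. = FALSE)
  comp <- summarize_state(state)
  profile <- rowSums(state$M) / sum(state$M)
  out <- list(gf = comp$gf, stem_frac = comp$stem_frac,
              diff_frac = comp$diff_frac, g0_frac = comp$g0_frac,
              dead_frac = comp$dead_frac,
              profile = profile, layout = state$layout,
              growth_rate = rate, doubling_time = log(2) / rate / 24,
              converged = converged, days = day,
              n_gcs = n_gcs, seed_stem_count = seed_stem_count, seed = seed,
              trace = trace)
  class(out) <- "oncosim_equilibrium"
  out
}

#' @export
print.oncosim_equilibrium <- function(x, ...) {
  cat("Equilibrium free-growth composition",
      if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  after %d simulated days (%d GCs x %g seed stem cells)\n",
              x$days, x$n_gcs, x$seed_stem_count))
  cat(sprintf("  doubling time %.1f days (growth rate %.3g /h)\n",
              x$doubling_time, x$growth_rate))
  cat(sprintf("  GF %.2f%% | stem %.3f%% | diff %.2f%% | G0 %.2f%% | dead %.2f%%\n",
              100 * x$gf, 100 * x$stem_frac, 100 * x$diff_frac,
              100 * x$g0_frac, 100 * x$dead_frac))
  invisible(x)
}

#' Tumor geometry
#'
#' Either a triaxial ellipsoid given by its three diameters (mm), optionally
#' with an ellipsoidal necrotic core, or an explicit voxel mask (0-based
#' integer coordinates, label 1 = tumor, 2 = necrotic).
#'
#' @param tumor_length,tumor_breadth,tumor_width Ellipsoid diameters, mm.
#' @param necrotic_length,necrotic_breadth,necrotic_width Optional necrotic
#'   core diameters, in GC units of the mesh they will be built on.
#' @param mask Optional data.frame with columns `x`, `y`, `z`, `label`
#'   (0-based voxel list); overrides the ellipsoid.
#' @return An object of class `tumor_geometry`.
#' @export
tumor_geometry <- function(tumor_length = NULL, tumor_breadth = tumor_length,
                           tumor_width = tumor_length,
                           necrotic_length = NULL,
                           necrotic_breadth = necrotic_length,
                           necrotic_width = necrotic_length,
                           mask = NULL) {
  if (is.null(mask)) {
    stopifnot(is.numeric(tumor_length), tumor_length > 0,
              tumor_breadth > 0, tumor_width > 0)
    if (!is.null(necrotic_length) &&
        (necrotic_length > tumor_length || necrotic_breadth > tumor_breadth ||
         necrotic_width > tumor_width))
      stop("necrotic core must fit inside the tumor", call. = FALSE)
  } else {
    stopifnot(is.data.frame(mask), all(c("x", "y", "z", "label") %in% names(mask)))
  }
  out <- list(tumor = c(tumor_length, tumor_breadth, tumor_width),
              necrotic = if (is.null(necrotic_length)) NULL
                         else c(necrotic_length, necrotic_breadth, necrotic_width),
              mask = mask)
  class(out) <- "tumor_geometry"
  out
}

#' Rasterize a tumor geometry onto the mesh lattice
#'
#' A GC is occupied when its center, at `(i + 0.5) * voxel_edge` for 0-based
#' index `i`, lies inside the ellipsoid (semi-axes = diameters / 2) centered
#' in the lattice. Mask geometries are passed through unchanged.
#'
#' @param geom A [tumor_geometry()].
#' @param voxel_edge GC edge, mm.
#' @param dims Lattice dimensions (GC counts); defaults to the tumor bounding
#'   box plus a two-GC margin on each side.
#' @return A list with `dims`, `occupied` and `necrotic` (integer matrices of
#'   0-based `(x, y, z)` rows).
#' @export
build_geometry <- function(geom, voxel_edge = 1, dims = NULL) {
  stopifnot(inherits(geom, "tumor_geometry"))
  if (!is.null(geom$mask)) {
    m <- geom$mask
    if (is.null(dims)) dims <- apply(m[, c("x", "y", "z")], 2, max) + 3L
    if (any(m$x >= dims[1] | m$y >= dims[2] | m$z >= dims[3] |
            m$x < 0 | m$y < 0 | m$z < 0))
      stop("mask voxels fall outside the mesh dimensions", call. = FALSE)
    occ <- as.matrix(m[m$label >= 1, c("x", "y", "z")])
    nec <- as.matrix(m[m$label == 2, c("x", "y", "z")])
    return(list(dims = as.integer(dims), occupied = occ, necrotic = nec))
  }
  if (any(geom$tumor < voxel_edge))
    stop("tumor extents must be at least one voxel edge", call. = FALSE)
  if (is.null(dims))
    dims <- as.integer(ceiling(geom$tumor / voxel_edge) + 4L)
  center <- dims * voxel_edge / 2
  semi <- geom$tumor / 2
  idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1L), y = 0:(dims[2] - 1L),
                               z = 0:(dims[3] - 1L)))
  cent <- (idx + 0.5) * voxel_edge
  inside <- function(semi_axes) {
    d <- sweep(cent, 2, center)
    rowSums(sweep(d, 2, semi_axes, "/")^2) <= 1
  }
  occ <- idx[inside(semi), , drop = FALSE]
  nec <- if (is.null(geom$necrotic)) occ[integer(0), , drop = FALSE]
         else idx[inside(geom$necrotic * voxel_edge / 2), , drop = FALSE]
  list(dims = as.integer(dims), occupied = occ, necrotic = nec)
}

#' Populate a mesh from an equilibrium composition
#'
#' Fills every occupied GC with `NBC` cells distributed over the
#' compartments. The default profile is the converged bootstrap state itself
#' (each category, phase and age bin at its equilibrium share), which makes
#' subsequent free growth monotone from t = 0. `profile = "uniform"` instead
#' splits cycling cells proportionally to the phase durations with the time
#' already spent in phase drawn uniformly at random per GC.
#'
#' Each GC's total is scaled by a small seeded jitter (uniform within
#' `1 +/- jitter`, inside the occupancy band) so that neighboring GCs do not
#' cross the band limits in the same hour: without it the whole tumor
#' overloads synchronously and the resulting avalanche of expansion events
#' distorts the shape.
#'
#' @param mesh A [tumor_mesh()].
#' @param eq A converged [bootstrap_equilibrium()] result.
#' @param profile `"equilibrium"` or `"uniform"`.
#' @param jitter Relative half-width of the per-GC load jitter (default 0.05,
#'   half the default band margin); 0 disables it.
#' @return The populated mesh.
#' @export
init_mesh <- function(mesh, eq, profile = c("equilibrium", "uniform"),
                      jitter = 0.05) {
  profile <- match.arg(profile)
  stopifnot(inherits(eq, "oncosim_equilibrium"))
  if (!eq$converged)
    stop("equilibrium composition has not converged; cannot initialize", call. = FALSE)
  L <- mesh$state$layout
  if (!identical(L$signature, eq$layout$signature))
    stop("mesh and equilibrium were built from different durations", call. = FALSE)
  n <- ncol(mesh$state$M)
  if (profile == "equilibrium") {
    mesh$state$M <- matrix(eq$profile * mesh$NBC, nrow = L$n_rows, ncol = n)
  } else {
    prof <- eq$profile
    col <- prof
    for (i in seq_len(L$nc)) {
      rows <- L$cyc_rows[[i]]
      class_tot <- sum(prof[rows])
      if (class_tot <= 0) next
      ph <- L$phase_of[[i]]
      dur <- unlist(phase_durations(if (i %in% L$limp_i) mesh$params$T_c_limp
                                    else mesh$params$T_c))
      share <- dur / sum(dur)                 # phase split ~ real durations
      w <- (share / tabulate(ph, 4))[ph]      # even over each phase's age bins
      col[rows] <- class_tot * w
    }
    mesh$state$M <- matrix(col * mesh$NBC, nrow = L$n_rows, ncol = n)
  }
  if (jitter > 0) {
    set.seed(mesh$params$rng_seed)
    scale <- 1 + stats::runif(n, -jitter, jitter)
    mesh$state$M <- mesh$state$M * rep(scale, each = L$n_rows)
  }
  mesh
}
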