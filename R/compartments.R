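# Per-GC cell bookkeeping.
#
# A compartment state is a numeric vector (one column per geometrical cell)
# laid out as:
#   * one age-structured delay line per cycling class (STEM, LIMP with k
#     remaining mitoses, and the lethally hit classes HIT2/HIT1), one bin per
#     hour of the cycle; phase boundaries (G1|S|G2|M) fall at the integer
#     partition of phase_bins();
#   * one dormant (G0) scalar per cycling class (exponential residence);
#   * scalars for differentiated cells and for differentiated cells marked
#     for necrotic death by irradiation;
#   * delay lines for the apoptotic and necrotic pools (cells disappear from
#     the tumor when they have resided T_A / T_N hours).
# All counts are non-negative reals (deterministic fractional flows) or
# integers in Monte-Carlo mode.

.layout_signature <- function(params) {
  paste(params$T_c, params$T_c_limp, params$N_LIMP, params$T_G0,
        params$T_G0_limp, params$T_A, params$T_N, sep = "|")
}

#' Compartment layout for a parameter set
#'
#' Precomputes the row indices of every (category, phase, hit-status, age)
#' compartment used by [step_compartments()]. Internal plumbing, exported for
#' inspection.
#'
#' @param params An [model_params()] object.
#' @return A list of class `oncosim_layout`.
#' @keywords internal
#' @export
compartment_layout <- function(params) {
  N <- params$N_LIMP
  nc <- N + 3L                                  # STEM, LIMP_N..LIMP_1, HIT2, HIT1
  class_names <- c("STEM", paste0("LIMP", N:1), "HIT2", "HIT1")
  is_hit <- c(rep(FALSE, N + 1L), TRUE, TRUE)
  bins_stem <- phase_bins(params$T_c)
  bins_limp <- phase_bins(params$T_c_limp)
  bins_by_class <- c(list(bins_stem), rep(list(bins_limp), N),
                     list(bins_stem), list(bins_stem))
  cyc_len <- vapply(bins_by_class, sum, integer(1))

  cyc_rows <- vector("list", nc)
  phase_of <- vector("list", nc)
  at <- 0L
  for (i in seq_len(nc)) {
    cyc_rows[[i]] <- at + seq_len(cyc_len[i])
    phase_of[[i]] <- rep(1:4, times = bins_by_class[[i]])
    at <- at + cyc_len[i]
  }
  g0_rows <- at + seq_len(nc); at <- at + nc
  diff_row <- at + 1L; diff_hit_row <- at + 2L; at <- at + 2L
  n_apo <- as.integer(ceiling(params$T_A))
  n_nec <- as.integer(ceiling(params$T_N))
  apo_rows <- at + seq_len(n_apo); at <- at + n_apo
  nec_rows <- at + seq_len(n_nec); at <- at + n_nec

  all_cyc <- unlist(cyc_rows)
  shift_from <- unlist(lapply(cyc_rows, function(r) r[-length(r)]))
  shift_to <- unlist(lapply(cyc_rows, function(r) r[-1L]))

  L <- list(
    nc = nc, n_rows = at, class_names = class_names, is_hit = is_hit,
    stem_i = 1L, limp_i = if (N > 0) 1L + seq_len(N) else integer(0),
    limp_last_i = N + 1L, hit2_i = nc - 1L, hit1_i = nc,
    cyc_rows = cyc_rows, phase_of = phase_of, cyc_len = cyc_len,
    all_cyc_rows = all_cyc,
    m_rows = vapply(cyc_rows, function(r) r[length(r)], integer(1)),
    g1_rows = vapply(cyc_rows, function(r) r[1L], integer(1)),
    shift_from = shift_from, shift_to = shift_to,
    g0_rows = g0_rows, diff_row = diff_row, diff_hit_row = diff_hit_row,
    apo_rows = apo_rows, nec_rows = nec_rows,
    T_G0_class = c(params$T_G0, rep(params$T_G0_limp, N),
                   params$T_G0, params$T_G0),
    P_G0toG1_class = c(params$P_G0toG1, rep(params$P_G0toG1_limp, N),
                       params$P_G0toG1, params$P_G0toG1),
    signature = .layout_signature(params)
  )
  class(L) <- "oncosim_layout"
  L
}

#' Create an empty compartment state
#'
#' @param params An [model_params()] object.
#' @param n_gc Number of geometrical cells (columns) tracked side by side.
#' @return An object of class `oncosim_state`: a list with the layout and the
#'   count matrix `M` (compartments x GCs).
#' @export
new_compartment_state <- function(params, n_gc = 1L) {
  L <- compartment_layout(params)
  s <- list(layout = L, M = matrix(0, nrow = L$n_rows, ncol = n_gc))
  class(s) <- "oncosim_state"
  s
}

#' Seed stem cells into a state
#'
#' Places `count` stem cells per GC into the cycling delay line, with the time
#' already spent in phase drawn uniformly at random (different draws per GC so
#' the GCs are not artificially synchronized). Optionally a fraction starts
#' dormant.
#'
#' @param state An `oncosim_state`.
#' @param count Stem cells per GC.
#' @param g0_fraction Fraction of the seed placed in G0 (default 0: all seeds
#'   cycling; the dormant pool populates dynamically).
#' @return The seeded state.
#' @export
seed_stem <- function(state, count = 100, g0_fraction = 0) {
  L <- state$layout
  rows <- L$cyc_rows[[L$stem_i]]
  n_cyc <- count * (1 - g0_fraction)
  for (g in seq_len(ncol(state$M))) {
    ages <- sample.int(length(rows), size = max(1, round(n_cyc)), replace = TRUE)
    tab <- tabulate(ages, nbins = length(rows))
    state$M[rows, g] <- tab * (n_cyc / sum(tab))
    state$M[L$g0_rows[L$stem_i], g] <- count * g0_fraction
  }
  state
}

#' Total and living cell counts
#'
#' @param state An `oncosim_state`.
#' @return Numeric vector, one entry per GC.
#' @export
total_cells <- function(state) colSums(state$M)

#' @rdname total_cells
#' @export
living_cells <- function(state) {
  L <- state$layout
  colSums(state$M[c(L$all_cyc_rows, L$g0_rows, L$diff_row, L$diff_hit_row), ,
                  drop = FALSE])
}

.flow <- function(n, p, stochastic) {
  if (!stochastic) return(n * p)
  if (any(n > .Machine$integer.max))
    stop("Monte-Carlo mode supports counts below 2^31; use the deterministic mode",
         call. = FALSE)
  stats::rbinom(length(n), round(n), pmin(pmax(p, 0), 1))
}

#' Advance compartments by hourly steps (first mesh scan)
#'
#' Applies the cytokinetic diagram for `steps` hours to every GC column:
#' spontaneous apoptosis of living stem/LIMP cells and apoptosis/necrosis of
#' differentiated cells; dormant-pool exits (re-entry into G1 or necrosis);
#' aging along the cycle delay lines with mitosis at M-exit
#' ([mitosis_outcome()] semantics, including the post-mitotic G0-vs-G1
#' routing of newborn pairs); the rudimentary cycle of lethally hit cells
#' ending in necrotic death after their second mitosis; and clearance of
#' apoptotic/necrotic debris after `T_A`/`T_N` hours.
#'
#' @param state An `oncosim_state`.
#' @param params The [model_params()] the layout was built from (rates may
#'   differ; durations must match).
#' @param steps Number of 1-h steps.
#' @param stochastic Use integer Monte-Carlo draws instead of deterministic
#'   fractional flows.
#' @param track_deltas Record per-step audit totals.
#' @return A list with the updated `state` and, if `track_deltas`, a `deltas`
#'   list (`births`, `apoptotic_deaths`, `necrotic_deaths`,
#'   `cleared_apoptotic`, `cleared_necrotic`, `g0_reentries`,
#'   `differentiations`), each summed over the steps and GCs.
#' @export
step_compartments <- function(state, params, steps = 1L, stochastic = FALSE,
                              track_deltas = FALSE) {
  L <- state$layout
  if (!identical(L$signature, .layout_signature(params)))
    stop("state layout was built for different durations; rebuild with new_compartment_state()",
         call. = FALSE)
  M <- state$M
  g <- ncol(M)
  d <- list(births = 0, apoptotic_deaths = 0, necrotic_deaths = 0,
            cleared_apoptotic = 0, cleared_necrotic = 0,
            g0_reentries = 0, differentiations = 0)
  RA <- params$R_A
  Psym <- params$P_sym
  Psleep <- params$P_sleep
  liv_rows <- c(L$all_cyc_rows, L$g0_rows)
  unhit <- which(!L$is_hit)
  inv_TG0 <- 1 / L$T_G0_class
  pg01 <- L$P_G0toG1_class
  apo_first <- L$apo_rows[1L]; apo_last <- L$apo_rows[length(L$apo_rows)]
  nec_first <- L$nec_rows[1L]; nec_last <- L$nec_rows[length(L$nec_rows)]

  for (s in seq_len(steps)) {
    ## (1) spontaneous death rates over the past hour
    if (stochastic) {
      dying <- matrix(stats::rbinom(length(liv_rows) * g,
                                    round(M[liv_rows, ]), RA),
                      nrow = length(liv_rows))
      M[liv_rows, ] <- M[liv_rows, ] - dying
      apo_in <- colSums(dying)
    } else {
      apo_in <- RA * colSums(M[liv_rows, , drop = FALSE])
      M[liv_rows, ] <- M[liv_rows, ] * (1 - RA)
    }
    dif <- M[L$diff_row, ]
    d_apo <- .flow(dif, params$R_ADiff, stochastic)
    d_nec <- .flow(dif - d_apo,
                   if (stochastic) params$R_NDiff / max(1 - params$R_ADiff, 1e-12)
                   else params$R_NDiff, stochastic)
    M[L$diff_row, ] <- dif - d_apo - d_nec
    apo_in <- apo_in + d_apo
    nec_in <- d_nec

    ## (2) dormant-pool exits: leave at rate 1/T_G0, split G1 vs necrosis
    g0 <- M[L$g0_rows, , drop = FALSE]
    if (stochastic) {
      leave <- matrix(stats::rbinom(L$nc * g, round(g0), inv_TG0), nrow = L$nc)
      reenter <- matrix(stats::rbinom(L$nc * g, leave, pg01), nrow = L$nc)
    } else {
      leave <- g0 * inv_TG0
      reenter <- leave * pg01
    }
    nec_in <- nec_in + colSums(leave - reenter)
    M[L$g0_rows, ] <- g0 - leave

    ## irradiation-killed differentiated cells complete necrotic death
    nec_in <- nec_in + M[L$diff_hit_row, ]
    M[L$diff_hit_row, ] <- 0

    ## (3) cycle aging and mitosis at M-exit
    mout <- M[L$m_rows, , drop = FALSE]
    M[L$shift_to, ] <- M[L$shift_from, ]

    nb <- matrix(0, L$nc, g)             # unhit newborns per class
    d_stem <- mout[L$stem_i, ]
    if (stochastic) {
      sym <- stats::rbinom(g, round(d_stem), Psym)
      nb[L$stem_i, ] <- d_stem + sym
      nb[L$stem_i + 1L, ] <- d_stem - sym
    } else {
      nb[L$stem_i, ] <- (1 + Psym) * d_stem
      nb[L$stem_i + 1L, ] <- (1 - Psym) * d_stem
    }
    if (length(L$limp_i) > 1L)
      for (i in L$limp_i[-length(L$limp_i)])
        nb[i + 1L, ] <- nb[i + 1L, ] + 2 * mout[i, ]
    new_diff <- 2 * mout[L$limp_last_i, ]
    M[L$diff_row, ] <- M[L$diff_row, ] + new_diff
    entry_h1 <- 2 * mout[L$hit2_i, ]
    nec_in <- nec_in + 2 * mout[L$hit1_i, ]

    ## G0-vs-G1 routing of newborn pairs (siblings routed together)
    if (stochastic) {
      sleepers <- matrix(stats::rbinom(length(unhit) * g,
                                       round(nb[unhit, ] / 2), Psleep) * 2,
                         nrow = length(unhit))
      # odd newborn counts: route the unpaired cell by its own draw
      odd <- round(nb[unhit, ]) %% 2
      sleepers <- sleepers + matrix(stats::rbinom(length(unhit) * g, odd, Psleep),
                                    nrow = length(unhit))
      sleepers <- pmin(sleepers, nb[unhit, ])
    } else {
      sleepers <- Psleep * nb[unhit, , drop = FALSE]
    }
    M[L$g0_rows[unhit], ] <- M[L$g0_rows[unhit], ] + sleepers
    entry <- reenter
    entry[unhit, ] <- entry[unhit, ] + nb[unhit, ] - sleepers
    entry[L$hit1_i, ] <- entry[L$hit1_i, ] + entry_h1
    M[L$g1_rows, ] <- entry

    ## (4) dead-pool clearance after T_A / T_N hours
    cl_a <- M[apo_last, ]
    if (length(L$apo_rows) > 1L)
      M[L$apo_rows[-1L], ] <- M[L$apo_rows[-length(L$apo_rows)], ]
    M[apo_first, ] <- apo_in
    cl_n <- M[nec_last, ]
    if (length(L$nec_rows) > 1L)
      M[L$nec_rows[-1L], ] <- M[L$nec_rows[-length(L$nec_rows)], ]
    M[nec_first, ] <- nec_in

    if (track_deltas) {
      divisions <- sum(mout)
      d$births <- d$births + divisions
      d$apoptotic_deaths <- d$apoptotic_deaths + sum(apo_in)
      d$necrotic_deaths <- d$necrotic_deaths + sum(nec_in)
      d$cleared_apoptotic <- d$cleared_apoptotic + sum(cl_a)
      d$cleared_necrotic <- d$cleared_necrotic + sum(cl_n)
      d$g0_reentries <- d$g0_reentries + sum(reenter)
      d$differentiations <- d$differentiations + sum(new_diff)
    }
  }
  if (any(M < 0)) {
    if (min(M) < -1e-9 * max(sum(M), 1))
      stop("internal consistency error: negative compartment count", call. = FALSE)
    M[M < 0] <- 0
  }
  state$M <- M
  if (track_deltas) list(state = state, deltas = d) else list(state = state)
}

#' Mitosis outcome for a cohort of dividing cells
#'
#' Allocates the offspring of `count` simultaneous divisions. Stem divisions
#' are symmetric (two stem daughters) with probability `P_sym`, otherwise
#' asymmetric (one stem + one LIMP daughter with full mitotic reserve).
#' LIMP(k) divisions yield two LIMP(k-1) daughters for k > 1 and two
#' terminally differentiated daughters for k = 1. Non-differentiated newborn
#' pairs are then routed together to G0 (probability `P_sleep`) or back to G1.
#'
#' @param category `"STEM"` or `"LIMP"`.
#' @param count Number of dividing cells.
#' @param params An [model_params()] object.
#' @param remaining For LIMP, the number of mitoses the dividing cells still
#'   had (1..`N_LIMP`).
#' @param stochastic Draw the branchings instead of using expectations.
#' @return A list of newborn counts: `stem`, `limp` (with `limp_remaining`
#'   indicating their mitotic reserve), `diff`, and the G0/G1 routing
#'   `to_g0`, `to_g1` of the non-differentiated newborns.
#' @export
mitosis_outcome <- function(category, count, params, remaining = params$N_LIMP,
                            stochastic = FALSE) {
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  if (!category %in% c("STEM", "LIMP"))
    stop("unknown category: ", category, call. = FALSE)
  if (category == "STEM") {
    sym <- if (stochastic) stats::rbinom(1, round(count), params$P_sym)
           else params$P_sym * count
    stem <- count + sym
    limp <- count - sym
    limp_remaining <- params$N_LIMP
    diff <- 0
  } else {
    if (remaining < 1 || remaining > params$N_LIMP)
      stop("remaining must be in 1..N_LIMP", call. = FALSE)
    stem <- 0
    if (remaining > 1) {
      limp <- 2 * count; limp_remaining <- remaining - 1L; diff <- 0
    } else {
      limp <- 0; limp_remaining <- NA_integer_; diff <- 2 * count
    }
  }
  routed <- stem + limp
  to_g0 <- if (stochastic) {
    pairs <- stats::rbinom(1, floor(round(routed) / 2), params$P_sleep) * 2
    pairs + stats::rbinom(1, round(routed) %% 2, params$P_sleep)
  } else params$P_sleep * routed
  list(stem = stem, limp = limp, limp_remaining = limp_remaining,
       diff = diff, to_g0 = to_g0, to_g1 = routed - to_g0)
}

#' Composition of a compartment state
#'
#' @param state An `oncosim_state`.
#' @param per_gc Return one column of fractions per GC instead of the
#'   aggregate over all GCs.
#' @return A list (or matrix when `per_gc`) with fractions of living cells:
#'   `gf` (cycling stem+LIMP, including hit cells), `stem_frac` (stem cells,
#'   all phases), `diff_frac`, `g0_frac`, and `dead_frac` =
#'   (apoptotic+necrotic)/total. `gf + diff_frac + g0_frac` sums to 1.
#' @export
summarize_state <- function(state, per_gc = FALSE) {
  L <- state$layout
  M <- state$M
  agg <- function(rows) {
    x <- colSums(M[rows, , drop = FALSE])
    if (per_gc) x else sum(x)
  }
  cycling <- agg(L$all_cyc_rows)
  g0 <- agg(L$g0_rows)
  diff <- agg(c(L$diff_row, L$diff_hit_row))
  dead <- agg(c(L$apo_rows, L$nec_rows))
  stem <- agg(c(L$cyc_rows[[L$stem_i]], L$g0_rows[L$stem_i]))
  living <- cycling + g0 + diff
  total <- living + dead
  if (any(total <= 0))
    stop("state holds no cells; composition undefined", call. = FALSE)
  if (any(living <= 0))
    stop("no living cells; composition undefined", call. = FALSE)
  out <- list(gf = cycling / living, stem_frac = stem / living,
              diff_frac = diff / living, g0_frac = g0 / living,
              dead_frac = dead / total)
  if (per_gc) do.call(rbind, out) else out
}

#' Mean time in phase registers
#'
#' Mean hours already spent in each cycling phase, by class, computed from the
#' age structure of the delay lines.
#'
#' @param state An `oncosim_state`.
#' @return A matrix classes x phases (G1, S, G2, M) of count-weighted mean
#'   ages within the phase; `NaN` where a phase is empty.
#' @export
mean_time_in_phase <- function(state) {
  L <- state$layout
  tot <- rowSums(state$M)
  out <- matrix(NA_real_, L$nc, 4,
                dimnames = list(L$class_names, c("G1", "S", "G2", "M")))
  for (i in seq_len(L$nc)) {
    rows <- L$cyc_rows[[i]]
    ph <- L$phase_of[[i]]
    for (p in 1:4) {
      r <- rows[ph == p]
      w <- tot[r]
      out[i, p] <- if (sum(w) > 0) sum(w * (seq_along(r) - 1)) / sum(w) else NaN
    }
  }
  out
}
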