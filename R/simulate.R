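#' Passive-mode dual-trap model
#'
#' Fixed-trap ("passive mode") tether geometry: the trap positions are
#' constant within a trace, so the force changes as the enzyme changes the
#' tether length. `k_eff` is the combined stiffness of the two traps in
#' series. In the opposing-force geometry the tether is a dsDNA track of
#' `handle_bp` base pairs whose contour shortens as the enzyme translocates;
#' in the hairpin geometry fixed dsDNA handles (`handle_bp` total) are in
#' series with the hairpin, and each unwound base pair releases two
#' nucleotides of ssDNA into the tether.
#'
#' @param k_eff combined trap stiffness (pN/nm), in `[0.1, 2]`.
#' @param handle_bp dsDNA contour in the tether (bp).
#' @param hairpin_bp hairpin stem length (bp; hairpin geometry only).
#' @param f_init force at the start of the trace (pN); fixes the trap
#'   separation.
#' @return An object of class `trap_model`.
#' @export
trap_model <- function(k_eff = 0.4, handle_bp = 4500, hairpin_bp = 0,
                       f_init = 3) {
  if (k_eff < 0.1 || k_eff > 2) stop("`k_eff` must lie in [0.1, 2] pN/nm")
  if (handle_bp <= 0) stop("`handle_bp` must be positive")
  if (f_init <= 0) stop("`f_init` must be positive")
  structure(list(k_eff = k_eff, handle_bp = handle_bp,
                 hairpin_bp = hairpin_bp, f_init = f_init),
            class = "trap_model")
}

#' Default tether fixtures for the two assay geometries
#'
#' Opposing-force assay: a 4500 bp dsDNA track starting at 3 pN, so the
#' force develops upward as the enzyme shortens the tether. Hairpin assay:
#' 3400 bp of dsDNA handles plus a 2000 bp hairpin starting at 14.5 pN, so
#' the force relaxes as unwinding lengthens the tether.
#'
#' @param mode `"opposing_force"` or `"hairpin_assisting"`.
#' @export
default_trap <- function(mode = c("opposing_force", "hairpin_assisting")) {
  mode <- match.arg(mode)
  if (mode == "opposing_force") {
    trap_model(k_eff = 0.4, handle_bp = 4500, hairpin_bp = 0, f_init = 3)
  } else {
    trap_model(k_eff = 0.4, handle_bp = 3400, hairpin_bp = 2000, f_init = 14.5)
  }
}

# Noise-free tether extension (nm) at force F with `pos_bp` base pairs
# translocated/unwound. Vectorized over force and pos_bp.
tether_extension <- function(force, pos_bp, mode, trap, polymer, kBT = 4.11) {
  if (mode == "opposing_force") {
    (trap$handle_bp - pos_bp) * polymer$nm_per_bp *
      ewlc_fraction(force, polymer, kBT)
  } else {
    trap$handle_bp * polymer$nm_per_bp * ewlc_fraction(force, polymer, kBT) +
      2 * pos_bp * fjc_extension_per_nt(force, polymer, kBT)
  }
}

tether_extension_deriv <- function(force, pos_bp, mode, trap, polymer,
                                   kBT = 4.11) {
  if (mode == "opposing_force") {
    (trap$handle_bp - pos_bp) * polymer$nm_per_bp *
      ewlc_fraction_deriv(force, polymer, kBT)
  } else {
    trap$handle_bp * polymer$nm_per_bp *
      ewlc_fraction_deriv(force, polymer, kBT) +
      2 * pos_bp * fjc_extension_deriv(force, polymer, kBT)
  }
}

# Solve the passive-mode force balance F = k_eff * (sep - x_tether(F))
# for each element of pos_bp (vectorized damped Newton; g is strictly
# increasing in F). Returns forces in pN.
solve_force_balance <- function(pos_bp, separation, mode, trap, polymer,
                                kBT = 4.11, f_start = NULL, tol = 1e-9) {
  f <- rep_len(if (is.null(f_start)) trap$f_init else f_start,
               length(pos_bp))
  f <- pmax(f, 0.05)
  for (it in 1:100) {
    x <- tether_extension(f, pos_bp, mode, trap, polymer, kBT)
    g <- f + trap$k_eff * (x - separation)
    if (all(abs(g) < tol)) break
    dg <- 1 + trap$k_eff *
      tether_extension_deriv(f, pos_bp, mode, trap, polymer, kBT)
    f_new <- f - g / dg
    # keep iterates inside the physical domain
    f <- pmin(pmax(f_new, f / 4), pmax(4 * f, 1e-3))
    if (it == 100L && any(abs(g) > 1e-6)) {
      stop("force-balance Newton iteration failed to converge; ",
           "worst residual ", signif(max(abs(g)), 3), " pN at position ",
           pos_bp[which.max(abs(g))], " bp")
    }
  }
  f
}

# Discrete position grid (net ratchet steps k, position = k * delta bp) and
# the associated equilibrium forces for one trace. The grid spans backward
# fluctuations (k_min < 0) up to either a force limit or the end of the
# track/hairpin.
position_grid <- function(rates, mode, trap, polymer, kBT = 4.11,
                          k_back = 50L, f_stop = c(58, 1)) {
  delta <- rates$delta
  k_max_geom <- if (mode == "opposing_force") {
    floor(0.9 * trap$handle_bp / delta)
  } else {
    floor(trap$hairpin_bp / delta)
  }
  k <- seq.int(-k_back, k_max_geom)
  sep0 <- tether_extension(trap$f_init, 0, mode, trap, polymer, kBT) +
    trap$f_init / trap$k_eff
  force <- solve_force_balance(k * delta, sep0, mode, trap, polymer, kBT)
  keep <- if (mode == "opposing_force") force <= f_stop[1] else force >= f_stop[2]
  # always keep the backward part of the grid
  keep <- keep | k <= 0
  last <- max(which(keep))
  k <- k[seq_len(last)]
  force <- force[seq_len(last)]
  list(k = k, force = force, separation = sep0, delta = delta)
}

# Directed transition list of a scheme: forward transitions plus explicit
# reverse transitions for the reversible ones.
directed_transitions <- function(sch) {
  tr <- sch$transitions
  n_states <- length(sch$states)
  idx <- function(s) match(s, sch$states)
  from <- idx(tr$from); to <- idx(tr$to)
  d_from <- from; d_to <- to
  d_pos <- ifelse(tr$translocation, 1L, 0L)
  d_kind <- paste0(tr$role, "+")
  rev <- which(tr$reversible)
  d_from <- c(d_from, to[rev]); d_to <- c(d_to, from[rev])
  d_pos <- c(d_pos, ifelse(tr$translocation[rev], -1L, 0L))
  d_kind <- c(d_kind, paste0(tr$role[rev], "-"))
  list(from = d_from, to = d_to, dpos = d_pos, kind = d_kind,
       n_states = n_states)
}

# Propensity table: one row per grid position, one column per directed
# transition, at the given ATP concentration.
propensity_table <- function(sch, rates, geometry, grid_force, atp) {
  rw <- cycle_rates(sch, rates, grid_force, atp, geometry)
  tr <- sch$transitions
  A <- t(rw$u)                                  # n_pos x n_forward
  rev <- which(tr$reversible)
  A <- cbind(A, t(rw$w[rev, , drop = FALSE]))
  A
}

#' Exact stochastic simulation of one stepping trace
#'
#' Gillespie simulation of the cycle's state transitions under the
#' passive-mode force balance: the enzyme position takes discrete values
#' (multiples of the step size), the equilibrium force at every reachable
#' position is precomputed by solving
#' `F = k_eff * (separation - x_tether(F))`, and the force-modulated
#' propensities are refreshed whenever the position changes (positions are
#' the only extension changes, so the simulation is exact). Identical seeds
#' give identical event lists.
#'
#' @param sch a [scheme()].
#' @param rates a [rate_set()].
#' @param geometry a [geometry_context()].
#' @param trap a [trap_model()]; defaults to [default_trap()] for the mode.
#' @param atp ATP concentration (M).
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param force_clamp if non-`NULL`, hold the force constant at this value
#'   (pN) instead of solving the force balance (constant-force oracle runs).
#' @param dissociation optional list `list(k0, x_dag_nm)` adding a
#'   force-dependent off-rate `k0 * exp(F * x_dag_nm / kBT)` from every
#'   state; a firing terminates the trace.
#' @param max_events event-count guard.
#' @return A list of class `ssa_run` with `time` and `position_bp` of every
#'   position-changing event, `t_end`, an end `code`, and the position grid
#'   with its forces (as attributes) for rendering.
#' @export
gillespie_run <- function(sch, rates, geometry, trap = NULL, atp = 2e-3,
                          duration = 1, seed = 1, force_clamp = NULL,
                          dissociation = NULL, max_events = 5e6) {
  if (duration <= 0) stop("`duration` must be positive")
  if (is.null(trap)) trap <- default_trap(geometry$mode)
  dt <- directed_transitions(sch)

  if (is.null(force_clamp)) {
    grid <- position_grid(rates, geometry$mode, trap, geometry$polymer,
                          geometry$kBT)
    A <- propensity_table(sch, rates, geometry, grid$force, atp)
    pos0 <- match(0L, grid$k)
    clamp <- FALSE
  } else {
    grid <- list(k = 0L, force = force_clamp, separation = NA_real_,
                 delta = rates$delta)
    A <- propensity_table(sch, rates, geometry, force_clamp, atp)
    pos0 <- 1L
    clamp <- TRUE
  }
  to <- dt$to
  if (!is.null(dissociation)) {
    k_off <- dissociation$k0 *
      exp(grid$force * dissociation$x_dag_nm / geometry$kBT)
    # absorbing column reachable from every state
    for (s in seq_len(dt$n_states)) {
      A <- cbind(A, k_off)
      dt$from <- c(dt$from, s); to <- c(to, 0L); dt$dpos <- c(dt$dpos, 0L)
    }
  }
  set.seed(seed)
  res <- ssa_run_cpp(dt$n_states, as.integer(dt$from), as.integer(to),
                     as.integer(dt$dpos), A, 1L, pos0, duration,
                     max_events, clamp)
  k_of_event <- if (clamp) res$pos - pos0 else grid$k[pmin(pmax(res$pos, 1L), length(grid$k))]
  out <- list(
    time = res$time,
    position_bp = k_of_event * grid$delta,
    t_end = res$t_end,
    code = res$code,
    n_events = res$n_events,
    atp = atp, seed = seed, mode = geometry$mode
  )
  attr(out, "grid") <- grid
  attr(out, "trap") <- trap
  attr(out, "rates") <- rates
  attr(out, "scheme_id") <- sch$id
  attr(out, "clamp") <- clamp
  class(out) <- "ssa_run"
  out
}

#' Render a stochastic run into a sampled trace
#'
#' Samples the extension and force channels of a [gillespie_run()] on a
#' uniform time grid at `f_s`, adds white Gaussian measurement noise of
#' standard deviation `noise_sd` to the extension, and propagates it to the
#' force channel through the trap stiffness (`dF = -k_eff * dx` at fixed
#' trap separation).
#'
#' @param run an `ssa_run` (not force-clamped).
#' @param noise_sd extension noise s.d. (nm); 0 gives the noiseless
#'   force-balance channels.
#' @param f_s sampling rate (Hz).
#' @param seed integer seed for the noise.
#' @return An object of class `sm_trace`: a list with `time`, `extension`
#'   (nm), `force` (pN), `geometry`, `atp`, `f_s` and a `meta` list carrying
#'   the generating seeds, trap, rate set and true step annotations.
#' @export
render_trace <- function(run, noise_sd = 2, f_s = 2500, seed = 1) {
  if (isTRUE(attr(run, "clamp"))) {
    stop("cannot render a force-clamped oracle run into a tether trace")
  }
  grid <- attr(run, "grid")
  trap <- attr(run, "trap")
  n <- floor(run$t_end * f_s)
  if (n < 2L) stop("run too short to render at the requested sampling rate")
  t_grid <- seq_len(n) / f_s
  pos_seq <- c(0, run$position_bp)
  k_idx <- findInterval(t_grid, run$time) + 1L
  pos <- pos_seq[k_idx]
  row <- match(round(pos / grid$delta), grid$k)
  force <- grid$force[row]
  extension <- grid$separation - force / trap$k_eff
  if (noise_sd > 0) {
    set.seed(seed)
    eps <- stats::rnorm(n, 0, noise_sd)
    extension <- extension + eps
    force <- force - trap$k_eff * eps
  }
  structure(
    list(time = t_grid, extension = extension, force = force,
         geometry = run$mode, atp = run$atp, f_s = f_s,
         meta = list(seed_run = run$seed, seed_noise = seed,
                     noise_sd = noise_sd, trap = trap,
                     rates = attr(run, "rates"),
                     scheme_id = attr(run, "scheme_id"),
                     annotations = data.frame(time = run$time,
                                              position_bp = run$position_bp))),
    class = "sm_trace"
  )
}

#' @export
print.sm_trace <- function(x, ...) {
  cat(sprintf("Single-molecule trace (%s): %.3g s at %g Hz, [ATP] = %g uM\n",
              x$geometry, max(x$time), x$f_s, 1e6 * x$atp))
  cat(sprintf("  force %.2f -> %.2f pN, extension %.0f -> %.0f nm\n",
              x$force[1], x$force[length(x$force)],
              x$extension[1], x$extension[length(x$extension)]))
  invisible(x)
}

#' Simulate one trace (stochastic run + rendering)
#'
#' @inheritParams gillespie_run
#' @inheritParams render_trace
#' @export
simulate_trace <- function(sch, rates, geometry, trap = NULL, atp = 2e-3,
                           duration = 1, seed = 1, noise_sd = 2, f_s = 2500) {
  run <- gillespie_run(sch, rates, geometry, trap, atp, duration, seed)
  render_trace(run, noise_sd = noise_sd, f_s = f_s, seed = seed + 1L)
}

#' Generate a reproducible multi-condition synthetic dataset
#'
#' Simulates traces over an experimental plan (geometry x ATP grid),
#' emulating the passive-mode design: in the opposing geometry each trace
#' develops force upward from `f_init` as the enzyme shortens the tether;
#' in the hairpin geometry the force relaxes from `f_init` as the fork is
#' unwound. Per-trace seeds are derived deterministically from the master
#' seed.
#'
#' @param plan data frame with columns `geometry`
#'   (`"opposing_force"`/`"hairpin_assisting"`), `atp` (M) and `n_traces`.
#' @param sch the ground-truth [scheme()].
#' @param rates a [rate_set()], or a named list of rate sets by geometry
#'   mode (different enzyme contexts per assay).
#' @param geometry named list of [geometry_context()] objects by mode.
#' @param duration named vector of trace durations (s) by mode.
#' @param seed master seed.
#' @inheritParams render_trace
#' @return A list of `sm_trace` objects.
#' @export
generate_dataset <- function(plan, sch, rates,
                             geometry = list(
                               opposing_force = geometry_context("opposing_force"),
                               hairpin_assisting = geometry_context("hairpin_assisting")),
                             duration = c(opposing_force = 4,
                                          hairpin_assisting = 1.5),
                             seed = 1, noise_sd = 2, f_s = 2500) {
  stopifnot(nrow(plan) > 0, all(c("geometry", "atp", "n_traces") %in% names(plan)))
  n_total <- sum(plan$n_traces)
  set.seed(seed)
  trace_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_total)
  out <- vector("list", n_total)
  i <- 0L
  for (r in seq_len(nrow(plan))) {
    mode <- as.character(plan$geometry[r])
    geom <- geometry[[mode]]
    if (is.null(geom)) stop("no geometry context supplied for mode ", mode)
    rs <- if (inherits(rates, "rate_set")) rates else rates[[mode]]
    for (j in seq_len(plan$n_traces[r])) {
      i <- i + 1L
      run <- gillespie_run(sch, rs, geom, trap = default_trap(mode),
                           atp = plan$atp[r], duration = duration[[mode]],
                           seed = trace_seeds[2L * i - 1L])
      out[[i]] <- render_trace(run, noise_sd = noise_sd, f_s = f_s,
                               seed = trace_seeds[2L * i])
    }
  }
  out
}

#' Ensemble mean velocity at clamped force (stochastic oracle)
#'
#' Runs `n` independent constant-force simulations and reports the ensemble
#' mean and standard error of the per-run velocity. Each run starts in the
#' first cycle state, so the position at early times carries an O(delta)
#' initialization offset; the velocity is therefore measured from the
#' stationary increment between `burn_in * duration` and `duration`, which
#' is unbiased once the cycle has relaxed. Converges to
#' [steady_state_velocity()] at rate `1/sqrt(n)`; used as the independent
#' stochastic check of the analytic steady-state solution.
#'
#' @inheritParams gillespie_run
#' @param force clamped force (pN).
#' @param n number of runs.
#' @param burn_in fraction of the run discarded before the velocity window.
#' @export
ensemble_velocity <- function(sch, rates, geometry, force, atp, n = 200,
                              duration = 0.3, seed = 1, burn_in = 0.2) {
  stopifnot(burn_in >= 0, burn_in < 1)
  t_burn <- burn_in * duration
  v <- numeric(n)
  for (i in seq_len(n)) {
    run <- gillespie_run(sch, rates, geometry, atp = atp,
                         duration = duration, seed = seed + i,
                         force_clamp = force)
    if (length(run$position_bp) == 0L) {
      v[i] <- 0
    } else {
      pos <- c(0, run$position_bp)
      at <- function(t) pos[findInterval(t, run$time) + 1L]
      v[i] <- (at(duration) - at(t_burn)) / (duration - t_burn)
    }
  }
  list(mean = mean(v), sem = stats::sd(v) / sqrt(n), n = n,
       velocities = v)
}

#' Reference enzyme contexts
#'
#' Two rate sets sharing all chemistry but differing in the
#' pre/post-translocation equilibrium of the ratchet: the in-complex
#' context has the equilibrium shifted 200-fold toward the
#' post-translocation state relative to the isolated enzyme
#' (`K_eq = 0.05` vs `10`), and the isolated enzyme carries only a weak
#' fork-destabilization energy (0.6 kBT). At 2 mM ATP the in-complex
#' context unwinds at ~480 bp/s with half-velocity near 26 pN of opposing
#' force; the isolated context is nearly inactive at zero force and
#' plateaus once tension opens the fork.
#'
#' @return A [rate_set()].
#' @export
recd_in_complex <- function() {
  rate_set(k_plus_b = 2e7, k_minus_b = 500, k_h = 300, k_r = 300,
           k_plus_tr = 2e5, k_minus_tr = 1e4, delta = 3.3, dG_dest = 0)
}

#' @rdname recd_in_complex
#' @export
recd_isolated <- function() {
  rate_set(k_plus_b = 2e7, k_minus_b = 500, k_h = 300, k_r = 300,
           k_plus_tr = 2e5, k_minus_tr = 2e6, delta = 3.3, dG_dest = 0.6)
}
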