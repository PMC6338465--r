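#' @useDynLib helicycle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Per-transition forward (u) and backward (w) rates of a cycle at one or
# more (force, atp) conditions. Returns N x M matrices (transition x cell),
# cells recycled from `force` and `atp`.
cycle_rates <- function(sch, rates, force, atp, geometry) {
  m <- max(length(force), length(atp))
  force <- rep_len(force, m)
  atp <- rep_len(atp, m)
  if (any(atp < 0)) stop("`atp` must be >= 0")
  tr <- sch$transitions
  n <- nrow(tr)
  u <- matrix(0, n, m)
  w <- matrix(0, n, m)
  for (i in seq_len(n)) {
    base <- switch(tr$role[i],
      binding = list(f = rates$k_plus_b * atp, b = rates$k_minus_b),
      hydrolysis = list(f = rates$k_h, b = 0),
      release = list(f = rates$k_r, b = 0),
      translocation = list(f = rates$k_plus_tr, b = rates$k_minus_tr)
    )
    fwd <- rep_len(base$f, m)
    bwd <- if (tr$reversible[i]) rep_len(base$b, m) else rep_len(0, m)
    if (tr$translocation[i]) {
      if (geometry$mode == "opposing_force") {
        bf <- bell_factors(force, rates$delta, rates$x_dagger,
                           geometry$kBT, geometry$nm_per_bp)
        fwd <- fwd * bf$forward
        if (tr$reversible[i]) bwd <- bwd * bf$backward
      } else {
        fk <- geometry$fork
        fk$dG_dest <- rates$dG_dest
        fwd <- fwd * p_open(force, fk, geometry$polymer, geometry$kBT)
      }
    }
    u[i, ] <- fwd
    w[i, ] <- bwd
  }
  list(u = u, w = w)
}

# Closed-form steady-state cycle flux (cycles/s) of a unicyclic chain with
# forward rates u_i (state i -> i+1) and backward rates w_i (reverse of
# transition i, i.e. the rate i+1 -> i). With at least one irreversible
# step the backward cycle product vanishes and J = 1 / sum_n r_n, with
# r_n = (1/u_n) * (1 + sum_k prod_{j=1..k} w_{n+j-1} / u_{n+j})
# (indices mod N). Vectorized over the M columns of u and w.
unicycle_flux <- function(u, w) {
  n <- nrow(u)
  m <- ncol(u)
  zero <- colSums(u == 0) > 0
  denom <- numeric(m)
  for (s in seq_len(n)) {
    acc <- rep(1, m)
    term <- rep(1, m)
    for (k in seq_len(n - 1)) {
      j <- ((s - 1 + k) %% n) + 1          # state n+k
      jm <- ((s - 2 + k) %% n) + 1         # transition whose reverse leaves it
      term <- term * w[jm, ] / u[j, ]
      acc <- acc + term
    }
    denom <- denom + acc / u[s, ]
  }
  out <- 1 / denom
  out[zero] <- 0  # no ATP (or blocked step): no completed cycles
  out[!is.finite(out)] <- 0
  out
}

# Null-space reference: stationary distribution of the full generator,
# flux read out at the committed release transition.
nullspace_flux <- function(u, w) {
  n <- nrow(u)
  vapply(seq_len(ncol(u)), function(m) {
    if (any(u[, m] == 0)) return(0)
    Q <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      Q[i, j] <- Q[i, j] + u[i, m]
      Q[i, i] <- Q[i, i] - u[i, m]
      if (w[i, m] > 0) {
        Q[j, i] <- Q[j, i] + w[i, m]
        Q[j, j] <- Q[j, j] - w[i, m]
      }
    }
    A <- rbind(t(Q), rep(1, n))
    b <- c(rep(0, n), 1)
    pi_hat <- qr.solve(A, b)
    if (any(pi_hat < -1e-8)) stop("steady-state solve produced negative occupancy")
    rel <- max(abs(t(Q) %*% pi_hat))
    scale <- max(abs(Q))
    if (rel > 1e-6 * max(scale, 1)) {
      stop("ill-conditioned generator: residual ", signif(rel, 3))
    }
    # net flux through the last transition (always irreversible release or
    # the transition closing the cycle)
    pi_hat[n] * u[n, m] - pi_hat[1] * w[n, m]
  }, numeric(1))
}

#' Steady-state unwinding velocity of a mechano-chemical cycle
#'
#' Builds the cycle's transition rates at the given force and ATP
#' concentration (force-modulated according to the geometry), solves for the
#' stationary occupancies, and returns `delta` times the net flux through
#' the cycle's committed irreversible step. The default `"nullspace"` method
#' solves the full generator; `"closed"` uses the closed-form unicyclic flux
#' (identical result, much faster, used internally for fitting).
#'
#' @param sch a [scheme()].
#' @param rates a [rate_set()].
#' @param force applied force (pN); vectorized with `atp`.
#' @param atp ATP concentration (M).
#' @param geometry a [geometry_context()].
#' @param method `"nullspace"` or `"closed"`.
#' @return Velocity in bp/s (0 at `atp = 0`).
#' @examples
#' sch <- scheme("brownian_ratchet", "binding")
#' steady_state_velocity(sch, rate_set(), force = 5, atp = 2e-3,
#'                       geometry = geometry_context("opposing_force"))
#' @export
steady_state_velocity <- function(sch, rates, force, atp, geometry,
                                  method = c("nullspace", "closed")) {
  method <- match.arg(method)
  rw <- cycle_rates(sch, rates, force, atp, geometry)
  flux <- switch(method,
    closed = unicycle_flux(rw$u, rw$w),
    nullspace = nullspace_flux(rw$u, rw$w)
  )
  rates$delta * flux
}

#' Force-dependent Michaelis-Menten parameters of a cycle
#'
#' All six schemes predict hyperbolic (Michaelis-Menten) dependence of the
#' velocity on ATP at fixed force, `v = v_max * T / (K_M + T)`, with
#' force-dependent `v_max` and `K_M`. `v_max` is obtained as the saturating
#' limit (ATP increased decade by decade until the relative change per
#' decade is below `tol_sat`); `K_M` by root bracketing of
#' `v(T) = v_max / 2` to relative tolerance `tol_km`.
#'
#' @inheritParams steady_state_velocity
#' @param force a single force (pN).
#' @param tol_sat relative saturation tolerance per decade.
#' @param tol_km relative root tolerance for `K_M`.
#' @return A list with `v_max` (bp/s), `K_M` (M) and `force` (pN), of class
#'   `mm_params`.
#' @export
mm_parameters <- function(sch, rates, force, geometry,
                          tol_sat = 1e-6, tol_km = 1e-8) {
  stopifnot(length(force) == 1L)
  v_at <- function(T) {
    steady_state_velocity(sch, rates, force, T, geometry, method = "closed")
  }
  T <- 1e-4
  v <- v_at(T)
  for (i in 1:24) {
    T2 <- T * 10
    v2 <- v_at(T2)
    if (v2 <= 0) stop("velocity vanished while seeking the saturating limit")
    if (abs(v2 - v) / v2 < tol_sat) break
    T <- T2
    v <- v2
    if (i == 24L) stop("saturating-ATP limit did not converge")
  }
  v_max <- v2
  f <- function(logT) v_at(exp(logT)) - v_max / 2
  # v is monotone increasing in T: bracket on a log grid
  lo <- log(1e-12); hi <- log(T2)
  if (f(lo) > 0 || f(hi) < 0) stop("failed to bracket K_M")
  root <- stats::uniroot(f, c(lo, hi), tol = tol_km)$root
  structure(list(v_max = v_max, K_M = exp(root), force = force),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten parameters at F = %.3g pN:\n", x$force))
  cat(sprintf("  v_max = %.4g bp/s, K_M = %.4g uM\n", x$v_max, 1e6 * x$K_M))
  invisible(x)
}

#' Logistic force-velocity law
#'
#' `v(F) = v0 / (1 + exp((F - F_half) / F0))`: the closed form to which all
#' power-stroke schemes (and Brownian-ratchet schemes with the transition
#' state at the full step and fast translocation) reduce at fixed ATP in the
#' opposing-force geometry. `F0 = kBT / delta` is the force scale of the
#' step and `F_half` the force of half-maximal velocity.
#'
#' @param force force (pN), vectorized.
#' @param v0 zero-force velocity plateau (bp/s).
#' @param f_half half-velocity force (pN).
#' @param f0 force scale `kBT / delta` (pN).
#' @return Velocity (bp/s).
#' @export
logistic_velocity <- function(force, v0, f_half, f0) {
  if (any(force < 0)) stop("`force` must be >= 0")
  v0 / (1 + exp((force - f_half) / f0))
}

#' Fit the logistic force-velocity law to a binned curve
#'
#' Weighted least squares (weights `1 / sem^2`) of [logistic_velocity()] to
#' a binned force-velocity curve, as used to summarize saturating-ATP
#' force-velocity data.
#'
#' @param curve a data frame with columns `force`, `velocity` and optionally
#'   `sem` (a `fv_dataset` works directly).
#' @param start optional named list of starting values.
#' @return A list of class `logistic_fit` with elements `coefficients`
#'   (`v0`, `f_half`, `f0`), `se`, `fitted`, `residuals` and the underlying
#'   `nls` object.
#' @export
fit_logistic <- function(curve, start = NULL) {
  curve <- as.data.frame(curve)
  if (!all(c("force", "velocity") %in% names(curve))) {
    stop("`curve` needs columns `force` and `velocity`")
  }
  if (nrow(curve) < 4L) stop("need at least 4 force bins")
  if (stats::sd(curve$velocity) < 1e-12) {
    stop("degenerate curve: velocity is constant, logistic fit is unidentifiable")
  }
  wts <- if ("sem" %in% names(curve) && all(curve$sem > 0)) {
    1 / curve$sem^2
  } else {
    rep(1, nrow(curve))
  }
  if (is.null(start)) {
    v0 <- max(curve$velocity)
    f_half <- curve$force[which.min(abs(curve$velocity - v0 / 2))]
    start <- list(v0 = v0, f_half = f_half, f0 = 4)
  }
  fit <- minpack.lm::nlsLM(
    velocity ~ v0 / (1 + exp((force - f_half) / f0)),
    data = curve, start = start, weights = wts,
    lower = c(v0 = 1e-6, f_half = 0.1, f0 = 0.01),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(coefficients = est, se = se,
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit), nls = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic force-velocity fit: v(F) = v0 / (1 + exp((F - F_half)/F0))\n")
  est <- x$coefficients
  cat(sprintf("  v0     = %.4g +/- %.2g bp/s\n", est["v0"], x$se[1]))
  cat(sprintf("  F_half = %.4g +/- %.2g pN\n", est["f_half"], x$se[2]))
  cat(sprintf("  F0     = %.4g +/- %.2g pN\n", est["f0"], x$se[3]))
  invisible(x)
}

#' Fit a Michaelis-Menten curve to velocities across ATP at one force
#'
#' Weighted least squares of `v = v_max * T / (K_M + T)`; used per force
#' bin to produce force-resolved `v_max(F)` and `K_M(F)` profiles from a
#' binned dataset.
#'
#' @param atp ATP concentrations (M).
#' @param velocity mean velocities (bp/s).
#' @param sem optional standard errors (weights `1 / sem^2`).
#' @return A list of class `mm_fit` with `coefficients` (`v_max`, `K_M`),
#'   `se` and the `nls` object. A warning attribute flags non-identifiable
#'   designs (all ATP far above or below `K_M`).
#' @export
fit_mm <- function(atp, velocity, sem = NULL) {
  if (length(atp) < 3L) stop("need at least 3 ATP concentrations")
  wts <- if (!is.null(sem) && all(sem > 0)) 1 / sem^2 else rep(1, length(atp))
  df <- data.frame(atp = atp, velocity = velocity)
  start <- list(v_max = max(velocity) * 1.05, K_M = stats::median(atp))
  fit <- minpack.lm::nlsLM(velocity ~ v_max * atp / (K_M + atp), data = df,
                           start = start, weights = wts,
                           lower = c(v_max = 1e-9, K_M = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  flag <- NULL
  if (est["K_M"] < min(atp) / 50 || est["K_M"] > max(atp) * 50) {
    flag <- "K_M outside the sampled ATP range: estimate poorly identified"
  }
  structure(list(coefficients = est, se = se, nls = fit, note = flag),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  est <- x$coefficients
  cat(sprintf("MM fit: v_max = %.4g +/- %.2g bp/s, K_M = %.4g +/- %.2g uM\n",
              est["v_max"], x$se[1], 1e6 * est["K_M"], 1e6 * x$se[2]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
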