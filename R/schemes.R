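#' The six candidate mechano-chemical cycles
#'
#' A helicase ATPase cycle is reduced to a minimal three-step chemistry:
#' reversible ATP binding (`k_plus_b * [ATP]`, `k_minus_b`), irreversible
#' hydrolysis (`k_h`) and irreversible product release (`k_r`). A processive
#' cycle must also advance the enzyme by one step of `delta` base pairs, and
#' the step can be incorporated in two ways: as a *power stroke* (PS), where
#' one chemical transition itself carries the translocation, or as a
#' *Brownian ratchet* (BR), where a fast reversible pre/post-translocation
#' fluctuation is inserted immediately before a chemical step that rectifies
#' (traps) the post-translocation state. Combining the two mechanisms with
#' the three possible placements (binding, hydrolysis, release) yields
#' exactly six schemes.
#'
#' @param mechanism `"brownian_ratchet"` or `"power_stroke"`.
#' @param coupling_step which chemical transition carries (PS) or rectifies
#'   (BR) the translocation: `"binding"`, `"hydrolysis"` or `"release"`.
#'
#' @return An object of class `mc_scheme`: a list with elements
#'   `id`, `mechanism`, `coupling_step`, `states` (ordered state labels) and
#'   `transitions` (a data frame with columns `from`, `to`, `role`,
#'   `reversible`, `translocation`, in cycle order).
#'
#' @examples
#' scheme("brownian_ratchet", "binding")
#' length(enumerate_schemes())
#' @export
scheme <- function(mechanism = c("brownian_ratchet", "power_stroke"),
                   coupling_step = c("binding", "hydrolysis", "release")) {
  mechanism <- match.arg(mechanism)
  coupling_step <- match.arg(coupling_step)

  if (mechanism == "power_stroke") {
    states <- c("E", "E.T", "E.DP")
    tr <- data.frame(
      from = c("E", "E.T", "E.DP"),
      to = c("E.T", "E.DP", "E"),
      role = c("binding", "hydrolysis", "release"),
      reversible = c(TRUE, FALSE, FALSE),
      translocation = FALSE,
      stringsAsFactors = FALSE
    )
    tr$translocation[tr$role == coupling_step] <- TRUE
  } else {
    # Insert a reversible pre <-> post translocation transition immediately
    # before the rectifying chemical step.
    base_states <- c("E", "E.T", "E.DP")
    base_roles <- c("binding", "hydrolysis", "release")
    i <- match(coupling_step, base_roles)
    pre <- paste0(base_states[i], ".pre")
    post <- paste0(base_states[i], ".post")
    states <- append(base_states[-i], c(pre, post), after = i - 1L)
    from <- states
    to <- c(states[-1L], states[1L])
    role <- append(base_roles, "translocation", after = i - 1L)
    tr <- data.frame(
      from = from, to = to, role = role,
      reversible = role %in% c("binding", "translocation"),
      translocation = role == "translocation",
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      id = paste0(if (mechanism == "brownian_ratchet") "br_" else "ps_",
                  coupling_step),
      mechanism = mechanism,
      coupling_step = coupling_step,
      states = states,
      transitions = tr
    ),
    class = "mc_scheme"
  )
}

#' @export
print.mc_scheme <- function(x, ...) {
  cat("Mechano-chemical cycle:", x$id, "\n")
  cat("  mechanism:    ", x$mechanism, "\n")
  cat("  coupling step:", x$coupling_step, "\n")
  cat("  states:       ", paste(x$states, collapse = " -> "), "-> (cycle)\n")
  step_at <- x$transitions$role[x$transitions$translocation]
  cat("  translocation carried by:", step_at, "transition\n")
  invisible(x)
}

#' Enumerate all six mechano-chemical schemes
#'
#' @param mechanism,coupling_step optional filters.
#' @return A named list of [scheme()] objects in stable order
#'   (Brownian-ratchet schemes first, each in binding/hydrolysis/release
#'   order).
#' @examples
#' names(enumerate_schemes())
#' @export
enumerate_schemes <- function(mechanism = NULL, coupling_step = NULL) {
  grid <- expand.grid(
    coupling_step = c("binding", "hydrolysis", "release"),
    mechanism = c("brownian_ratchet", "power_stroke"),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    scheme(grid$mechanism[i], grid$coupling_step[i])
  })
  names(out) <- vapply(out, `[[`, "", "id")
  if (!is.null(mechanism)) {
    out <- out[vapply(out, function(s) s$mechanism %in% mechanism, FALSE)]
  }
  if (!is.null(coupling_step)) {
    out <- out[vapply(out, function(s) s$coupling_step %in% coupling_step,
                      FALSE)]
  }
  out
}

#' Microscopic rate constants for one enzyme context
#'
#' Bundles the microscopic rates of the minimal ATPase cycle together with
#' the mechanical parameters of the translocation step. The translocation
#' attempt rates `k_plus_tr`/`k_minus_tr` are only used by Brownian-ratchet
#' schemes; their ratio `K_eq = k_minus_tr / k_plus_tr` is the
#' pre/post-translocation equilibrium constant of the ratchet.
#'
#' @param k_plus_b second-order ATP binding rate (1/M/s).
#' @param k_minus_b ATP unbinding rate (1/s).
#' @param k_h hydrolysis rate (1/s).
#' @param k_r product release rate (1/s).
#' @param k_plus_tr,k_minus_tr forward/backward translocation attempt rates
#'   (1/s; BR schemes only).
#' @param delta step size (bp).
#' @param x_dagger distance to the translocation transition state
#'   (bp-equivalent, `0 < x_dagger <= delta`). Defaults to `delta`.
#' @param dG_dest fork destabilization free energy provided by the helicase
#'   (kBT units, >= 0); enters only through the fork-opening probability in
#'   the hairpin geometry.
#' @return An object of class `rate_set`.
#' @examples
#' r <- rate_set()
#' k_c_eff(r)  # effective catalytic rate k_h k_r / (k_h + k_r)
#' @export
rate_set <- function(k_plus_b = 2e7, k_minus_b = 500, k_h = 300, k_r = 300,
                     k_plus_tr = 2e5, k_minus_tr = 1e4,
                     delta = 3.3, x_dagger = NULL, dG_dest = 0) {
  if (is.null(x_dagger)) x_dagger <- delta
  rates <- c(k_plus_b = k_plus_b, k_minus_b = k_minus_b, k_h = k_h,
             k_r = k_r, k_plus_tr = k_plus_tr, k_minus_tr = k_minus_tr)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rate constants must be finite and strictly positive")
  }
  if (delta <= 0) stop("step size `delta` must be positive")
  if (x_dagger <= 0 || x_dagger > delta) {
    stop("`x_dagger` must satisfy 0 < x_dagger <= delta")
  }
  if (dG_dest < 0) stop("`dG_dest` must be >= 0")
  structure(
    list(k_plus_b = k_plus_b, k_minus_b = k_minus_b, k_h = k_h, k_r = k_r,
         k_plus_tr = k_plus_tr, k_minus_tr = k_minus_tr, delta = delta,
         x_dagger = x_dagger, dG_dest = dG_dest),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set (minimal ATPase cycle + translocation)\n")
  cat(sprintf("  k+b = %.3g /M/s, k-b = %.3g /s, k_h = %.3g /s, k_r = %.3g /s\n",
              x$k_plus_b, x$k_minus_b, x$k_h, x$k_r))
  cat(sprintf("  k+tr = %.3g /s, k-tr = %.3g /s (K_eq = %.3g)\n",
              x$k_plus_tr, x$k_minus_tr, x$k_minus_tr / x$k_plus_tr))
  cat(sprintf("  delta = %.3g bp, x_dagger = %.3g bp, dG_dest = %.3g kBT\n",
              x$delta, x$x_dagger, x$dG_dest))
  invisible(x)
}

#' Effective catalytic rate of the composite hydrolysis + release step
#'
#' `k_c_eff = k_h * k_r / (k_h + k_r)`, the rate of the two irreversible
#' chemical steps in series; always `<= min(k_h, k_r)`.
#' @param rates a [rate_set()].
#' @export
k_c_eff <- function(rates) {
  rates$k_h * rates$k_r / (rates$k_h + rates$k_r)
}

#' Pre/post translocation equilibrium constant
#'
#' `K_eq = k_minus_tr / k_plus_tr` (> 1 favours the pre-translocation state).
#' @param rates a [rate_set()].
#' @export
ratchet_keq <- function(rates) rates$k_minus_tr / rates$k_plus_tr

#' Experimental geometry and thermal context
#'
#' Declares how force couples to the cycle. In the opposing-force geometry
#' (dual-trap "in-complex" assay) the applied force loads the translocation
#' step directly, through Bell factors on the forward and backward
#' translocation rates. In the hairpin-under-tension geometry the force
#' never loads the enzyme; it destabilizes the fork, and the forward
#' translocation rate is multiplied by the probability `P_open` that at
#' least `n_step` base pairs ahead are transiently open.
#'
#' @param mode `"opposing_force"` or `"hairpin_assisting"`.
#' @param kBT thermal energy (pN nm); 4.11 pN nm at 25 C.
#' @param nm_per_bp rise used to convert bp distances into nm in the Bell
#'   exponents (B-DNA, 0.34 nm/bp).
#' @param fork a [fork_params()] object (hairpin mode).
#' @param polymer a [polymer_params()] object (hairpin mode, for the
#'   single-stranded DNA stretching free energy inside `P_open`).
#' @return An object of class `geometry_context`.
#' @export
geometry_context <- function(mode = c("opposing_force", "hairpin_assisting"),
                             kBT = 4.11, nm_per_bp = 0.34,
                             fork = fork_params(), polymer = polymer_params()) {
  mode <- match.arg(mode)
  stopifnot(kBT > 0, nm_per_bp > 0)
  structure(list(mode = mode, kBT = kBT, nm_per_bp = nm_per_bp,
                 fork = fork, polymer = polymer),
            class = "geometry_context")
}

#' Bell factors for a force-loaded translocation step
#'
#' For a single-barrier translocation of step size `delta` against an
#' opposing force `F`, the forward attempt rate is reduced by
#' `exp(-F * x_dagger / kBT)` and the backward rate increased by
#' `exp(+F * (delta - x_dagger) / kBT)`, with distances converted at
#' `nm_per_bp`. The ratio forward/backward always equals
#' `exp(-F * delta / kBT)`, independent of the transition-state position.
#'
#' @param force applied force (pN), >= 0; vectorized.
#' @param delta step size (bp).
#' @param x_dagger distance to the transition state (bp), in `(0, delta]`.
#' @param kBT thermal energy (pN nm).
#' @param nm_per_bp bp-to-distance conversion (nm/bp).
#' @return A list with numeric vectors `forward` and `backward`.
#' @examples
#' bell_factors(0, 3.3, 3.3)           # c(1, 1)
#' bell_factors(10, 3.3, 3.3)$backward # 1 when x_dagger == delta
#' @export
bell_factors <- function(force, delta, x_dagger = delta, kBT = 4.11,
                         nm_per_bp = 0.34) {
  if (any(force < 0)) stop("`force` must be >= 0")
  if (x_dagger <= 0 || x_dagger > delta) {
    stop("`x_dagger` must satisfy 0 < x_dagger <= delta")
  }
  list(
    forward = exp(-force * x_dagger * nm_per_bp / kBT),
    backward = exp(force * (delta - x_dagger) * nm_per_bp / kBT)
  )
}

#' Force-shifted translocation equilibrium constant
#'
#' Under rapid equilibrium an opposing force shifts the pre/post
#' equilibrium constant as `K_eq -> K_eq * exp(F * delta / kBT)`
#' (equivalently `exp(F / F0)` with `F0 = kBT / delta`). Consistent with
#' [bell_factors()] for any transition-state position.
#'
#' @inheritParams bell_factors
#' @param K_eq zero-force equilibrium constant `k_minus_tr / k_plus_tr`.
#' @export
equilibrium_shift <- function(K_eq, force, delta, kBT = 4.11,
                              nm_per_bp = 0.34) {
  if (any(K_eq <= 0)) stop("`K_eq` must be positive")
  if (any(force < 0)) stop("`force` must be >= 0")
  K_eq * exp(force * delta * nm_per_bp / kBT)
}
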