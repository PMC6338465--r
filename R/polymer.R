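#' Polymer elasticity parameters
#'
#' Elastic constants for the tether: extensible worm-like chain (eWLC) for
#' double-stranded DNA and a freely-jointed chain (FJC) for single-stranded
#' DNA.
#'
#' @param L_p dsDNA persistence length (nm).
#' @param S dsDNA stretching modulus (pN).
#' @param nm_per_bp dsDNA contour rise (nm/bp).
#' @param ss_kuhn ssDNA Kuhn length (nm).
#' @param ss_nm_per_nt ssDNA contour length per nucleotide (nm/nt).
#' @return An object of class `polymer_params`.
#' @export
polymer_params <- function(L_p = 40, S = 1000, nm_per_bp = 0.34,
                           ss_kuhn = 1.5, ss_nm_per_nt = 0.59) {
  vals <- c(L_p, S, nm_per_bp, ss_kuhn, ss_nm_per_nt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all polymer parameters must be finite and positive")
  }
  structure(list(L_p = L_p, S = S, nm_per_bp = nm_per_bp,
                 ss_kuhn = ss_kuhn, ss_nm_per_nt = ss_nm_per_nt),
            class = "polymer_params")
}

#' DNA fork stability parameters
#'
#' Parameters of the zipper partition function behind the fork-opening
#' probability [p_open()]: a sequence-averaged base-pairing free energy
#' `dg_bp` per bp, a helicase-supplied destabilization energy `dG_dest`
#' applied uniformly per open bp, the helicase step size `n_step` (the fork
#' must be open over at least `n_step` bp for a translocation attempt to
#' succeed) and the maximum number `m_window` of transiently open bp kept in
#' the partition sum.
#'
#' @param dg_bp base-pairing free energy per bp (kBT), > 0.
#' @param dG_dest helicase destabilization energy per open bp (kBT), >= 0.
#' @param n_step helicase step size (bp), integer >= 1.
#' @param m_window partition-function window (bp), >= `n_step`.
#' @return An object of class `fork_params`.
#' @export
fork_params <- function(dg_bp = 2.5, dG_dest = 0, n_step = 3, m_window = 20) {
  if (dg_bp <= 0) stop("`dg_bp` must be > 0")
  if (dG_dest < 0) stop("`dG_dest` must be >= 0")
  n_step <- as.integer(n_step); m_window <- as.integer(m_window)
  if (n_step < 1L || n_step > m_window) {
    stop("need 1 <= n_step <= m_window")
  }
  structure(list(dg_bp = dg_bp, dG_dest = dG_dest, n_step = n_step,
                 m_window = m_window),
            class = "fork_params")
}

# Fractional dsDNA extension x/L at force F (high-force extensible
# Marko-Siggia interpolation).
ewlc_fraction <- function(force, polymer, kBT = 4.11) {
  1 - 0.5 * sqrt(kBT / (force * polymer$L_p)) + force / polymer$S
}

# d(x/L)/dF, used by the Newton force-balance solver.
ewlc_fraction_deriv <- function(force, polymer, kBT = 4.11) {
  0.25 * sqrt(kBT / polymer$L_p) * force^(-1.5) + 1 / polymer$S
}

#' Extensible worm-like chain extension and its inverse
#'
#' High-force extensible Marko-Siggia interpolation for dsDNA:
#' `x = L * (1 - 1/2 * sqrt(kBT / (F * L_p)) + F / S)`. The inverse is the
#' exact algebraic rearrangement `L = x / (...)` at the same force, so the
#' roundtrip is an identity.
#'
#' @param force force (pN), > 0; vectorized.
#' @param contour contour length L (nm).
#' @param extension measured extension x (nm).
#' @param polymer a [polymer_params()].
#' @param kBT thermal energy (pN nm).
#' @return Extension (nm) or contour length (nm).
#' @examples
#' p <- polymer_params()
#' x <- ewlc_extension(10, 1000, p)
#' ewlc_inverse(x, 10, p)  # 1000
#' @export
ewlc_extension <- function(force, contour, polymer = polymer_params(),
                           kBT = 4.11) {
  if (any(force <= 0)) stop("eWLC interpolation requires force > 0")
  if (any(contour <= 0)) stop("`contour` must be positive")
  contour * ewlc_fraction(force, polymer, kBT)
}

#' @rdname ewlc_extension
#' @export
ewlc_inverse <- function(extension, force, polymer = polymer_params(),
                         kBT = 4.11) {
  if (any(force <= 0)) stop("eWLC interpolation requires force > 0")
  extension / ewlc_fraction(force, polymer, kBT)
}

#' Freely-jointed chain extension per nucleotide
#'
#' `x_nt(F) = l_c * (coth(u) - 1/u)` with `u = F * b / kBT`, `b` the Kuhn
#' length and `l_c` the contour length per nucleotide. Continuous at F = 0
#' (x = 0).
#'
#' @inheritParams ewlc_extension
#' @return Extension per nucleotide (nm), vectorized over `force`.
#' @export
fjc_extension_per_nt <- function(force, polymer = polymer_params(),
                                 kBT = 4.11) {
  if (any(force < 0)) stop("`force` must be >= 0")
  u <- force * polymer$ss_kuhn / kBT
  out <- numeric(length(u))
  small <- u < 1e-6
  # Langevin function; series u/3 near zero avoids 0/0.
  out[small] <- u[small] / 3
  us <- u[!small]
  out[!small] <- 1 / tanh(us) - 1 / us
  polymer$ss_nm_per_nt * out
}

# d x_nt / dF (nm per pN per nt)
fjc_extension_deriv <- function(force, polymer, kBT = 4.11) {
  u <- force * polymer$ss_kuhn / kBT
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- 1 / 3
  us <- u[!small]
  out[!small] <- 1 / us^2 - 1 / sinh(us)^2
  polymer$ss_nm_per_nt * out * polymer$ss_kuhn / kBT
}

#' Stretching free energy of released single-stranded DNA
#'
#' Free-energy credit (in kBT) gained by presenting `nt` nucleotides of
#' ssDNA to a tension `F`:
#' `nt * integral_0^F x_nt(F') dF' / kBT`, evaluated in closed form for the
#' FJC (`integral x dF = l_c * (kBT/b) * log(sinh(u)/u)`). Zero at F = 0 and
#' monotone non-decreasing in F; linear in `nt`.
#'
#' @inheritParams fjc_extension_per_nt
#' @param nt number of released nucleotides.
#' @return Free energy (kBT), vectorized over `force`.
#' @export
ss_release_energy <- function(force, nt = 1, polymer = polymer_params(),
                              kBT = 4.11) {
  if (any(force < 0)) stop("`force` must be >= 0")
  u <- force * polymer$ss_kuhn / kBT
  g <- numeric(length(u))
  small <- u < 1e-6
  g[small] <- u[small]^2 / 6
  us <- u[!small]
  # log(sinh(u)/u), written to stay finite for large u
  g[!small] <- us + log1p(-exp(-2 * us)) - log(2 * us)
  nt * (polymer$ss_nm_per_nt / polymer$ss_kuhn) * g
}

#' Fork-opening probability
#'
#' Probability that at least `n_step` base pairs ahead of the helicase are
#' transiently open, from a single-exponential zipper partition function.
#' Opening one bp costs the pairing energy `dg_bp`, reduced by the helicase
#' destabilization `dG_dest` and by the stretching free energy of the two
#' released nucleotides under tension, giving a per-bp opening free energy
#' `dg(F) = dg_bp - dG_dest - 2 * ss_release_energy(F, 1)`. With `j` open
#' bp costing `j * dg(F)`,
#' `P_open = sum_(j = n)^(m) exp(-j dg) / sum_(j = 0)^(m) exp(-j dg)`.
#'
#' @param force tension on the hairpin (pN), vectorized.
#' @param fork a [fork_params()].
#' @param polymer a [polymer_params()] (ssDNA constants).
#' @param kBT thermal energy (pN nm).
#' @return Probability in `[0, 1]`, non-decreasing in `force`.
#' @examples
#' # uniform zipper: dg = 0 gives (m - n + 1) / (m + 1)
#' f <- fork_params(dg_bp = 1e-12, n_step = 3, m_window = 20)
#' p_open(0, f)
#' @export
p_open <- function(force, fork = fork_params(), polymer = polymer_params(),
                   kBT = 4.11) {
  dg <- fork$dg_bp - fork$dG_dest - 2 * ss_release_energy(force, 1, polymer, kBT)
  j <- 0:fork$m_window
  # log-weights -j * dg, stabilized per force value
  lw <- outer(-dg, j)                      # n_force x (m+1)
  lw <- lw - apply(lw, 1L, max)
  w <- exp(lw)
  num <- rowSums(w[, j >= fork$n_step, drop = FALSE])
  num / rowSums(w)
}
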