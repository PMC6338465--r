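#' @export
print.cycle_fit <- function(x, ...) {
  cat("Mechano-chemical cycle fit\n")
  cat("  scheme:", x$scheme$id,
      sprintf("(%s, translocation at %s)\n", x$scheme$mechanism,
              x$scheme$coupling_step))
  cat("  rate sharing:", x$mode, "\n")
  cat(sprintf("  total SSE = %.6g, R^2 = %.4f\n", x$sse_total, x$r_squared))
  for (g in names(x$contexts)) {
    r <- x$contexts[[g]]$rates
    cat(sprintf("  [%s] delta = %.2f bp, K_eq = %.3g, k_c_eff = %.3g /s\n",
                g, r$delta, ratchet_keq(r), k_c_eff(r)))
  }
  invisible(x)
}

#' @export
summary.cycle_fit <- function(object, ...) {
  d <- as.data.frame(object$data)
  out <- list(fit = object,
              n_obs = nrow(d),
              sse = object$sse,
              r_squared = object$r_squared,
              params = lapply(object$contexts, function(cc) {
                r <- cc$rates
                c(k_plus_b = r$k_plus_b, k_minus_b = r$k_minus_b,
                  k_c_eff = k_c_eff(r), k_plus_tr = r$k_plus_tr,
                  k_minus_tr = r$k_minus_tr, K_eq = ratchet_keq(r),
                  delta = r$delta, x_dagger = r$x_dagger,
                  dG_dest = r$dG_dest)
              }))
  class(out) <- "summary.cycle_fit"
  out
}

#' @export
print.summary.cycle_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted parameters by context:\n")
  for (g in names(x$params)) {
    cat(" ", g, "\n")
    p <- x$params[[g]]
    for (nm in names(p)) cat(sprintf("    %-10s %.4g\n", nm, p[nm]))
  }
  cat(sprintf("\n%d binned observations; per-geometry SSE: %s\n", x$n_obs,
              paste(sprintf("%s = %.5g", names(x$sse), x$sse),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.cycle_fit <- function(object, ...) {
  unlist(lapply(object$contexts, function(cc) cc$theta))
}

#' @export
deviance.cycle_fit <- function(object, ...) object$sse_total

#' Predicted velocities from a fitted cycle
#'
#' @param object a `cycle_fit`.
#' @param newdata data frame with columns `force` (pN), `atp` (M) and
#'   `geometry`; defaults to the fitted bins.
#' @param ... unused.
#' @return Numeric vector of velocities (bp/s).
#' @export
predict.cycle_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) as.data.frame(object$data) else as.data.frame(newdata)
  out <- numeric(nrow(d))
  for (g in unique(as.character(d$geometry))) {
    i <- d$geometry == g
    cc <- object$contexts[[g]]
    if (is.null(cc)) stop("fit has no context for geometry ", g)
    out[i] <- steady_state_velocity(object$scheme, cc$rates, d$force[i],
                                    d$atp[i], object$geometry[[g]],
                                    method = "closed")
  }
  out
}

#' @export
residuals.cycle_fit <- function(object, ...) {
  d <- as.data.frame(object$data)
  d$velocity - predict(object)
}

#' @export
fitted.cycle_fit <- function(object, ...) predict(object)

#' Plot a fitted cycle against the binned data
#'
#' One panel per geometry: binned velocities (with s.e.m. bars) against
#' force, one colour per ATP concentration, with the fitted model curves.
#'
#' @param x a `cycle_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cycle_fit <- function(x, ...) {
  d <- as.data.frame(x$data)
  modes <- names(x$contexts)
  old <- graphics::par(mfrow = c(1, length(modes)))
  on.exit(graphics::par(old))
  for (g in modes) {
    dg <- d[d$geometry == g, ]
    atps <- sort(unique(dg$atp))
    cols <- grDevices::hcl.colors(max(length(atps), 2L), "viridis")
    graphics::plot(dg$force, dg$velocity, type = "n",
                   xlab = "Force (pN)", ylab = "Velocity (bp/s)",
                   main = paste(x$scheme$id, "-", g), ...)
    for (k in seq_along(atps)) {
      dk <- dg[dg$atp == atps[k], ]
      graphics::points(dk$force, dk$velocity, col = cols[k], pch = 16)
      graphics::arrows(dk$force, dk$velocity - dk$sem, dk$force,
                       dk$velocity + dk$sem, angle = 90, code = 3,
                       length = 0.02, col = cols[k])
      fgrid <- seq(min(dg$force), max(dg$force), length.out = 100)
      vf <- steady_state_velocity(x$scheme, x$contexts[[g]]$rates, fgrid,
                                  atps[k], x$geometry[[g]], method = "closed")
      graphics::lines(fgrid, vf, col = cols[k])
    }
    graphics::legend("topright", legend = sprintf("%g uM", 1e6 * atps),
                     col = cols[seq_along(atps)], lty = 1, cex = 0.7,
                     bty = "n")
  }
  invisible(x)
}

#' Simulate traces from a fitted cycle
#'
#' Draws synthetic passive-mode traces from the fitted scheme and rate
#' sets, one condition plan entry per geometry present in the fit.
#'
#' @param object a `cycle_fit`.
#' @param nsim traces per condition.
#' @param seed integer seed.
#' @param atp ATP concentrations (M) to simulate at.
#' @param ... passed to [generate_dataset()].
#' @return List of `sm_trace`.
#' @export
simulate.cycle_fit <- function(object, nsim = 1, seed = 1, atp = 2e-3, ...) {
  modes <- names(object$contexts)
  plan <- expand.grid(geometry = modes, atp = atp, stringsAsFactors = FALSE)
  plan$n_traces <- nsim
  rates <- lapply(object$contexts, `[[`, "rates")
  generate_dataset(plan, object$scheme, rates, geometry = object$geometry,
                   seed = seed, ...)
}

#' @export
print.scheme_selection <- function(x, ...) {
  cat("Scheme selection by total minimized SSE\n")
  r <- x$ranking
  r$sse <- signif(r$sse, 5)
  r$r_squared <- round(r$r_squared, 4)
  r$aic <- round(r$aic, 1)
  print(r, row.names = TRUE)
  cat("\nSelected scheme:", x$best, "\n")
  if (length(x$errors)) {
    cat("Failed fits:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.scheme_selection <- function(x, ...) {
  r <- x$ranking
  graphics::barplot(r$sse, names.arg = r$scheme, las = 2,
                    ylab = "total SSE", ...)
  invisible(x)
}

#' @export
print.fv_dataset <- function(x, ...) {
  conds <- unique(as.data.frame(x)[c("geometry", "atp")])
  cat(sprintf("Force-velocity dataset: %d bins over %d conditions\n",
              nrow(x), nrow(conds)))
  NextMethod()
}
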