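# ---- parameter transform ----------------------------------------------
# Rates are optimized on log10 scale; delta, x_dagger ratio and dG_dest on
# linear scale. `hairpin` adds the fork destabilization energy.

par_spec <- function(sch, hairpin, tie_catalysis = TRUE,
                     fit_x_dagger = FALSE) {
  nm <- c("lkb", "lkmb")
  lo <- c(-2, -2); hi <- c(8, 8)
  if (tie_catalysis) {
    nm <- c(nm, "lkc"); lo <- c(lo, -2); hi <- c(hi, 8)
  } else {
    nm <- c(nm, "lkh", "lkr"); lo <- c(lo, -2, -2); hi <- c(hi, 8, 8)
  }
  if (sch$mechanism == "brownian_ratchet") {
    nm <- c(nm, "lktrp", "lktrm"); lo <- c(lo, -2, -2); hi <- c(hi, 8, 8)
  }
  nm <- c(nm, "delta"); lo <- c(lo, 0.5); hi <- c(hi, 10)
  if (fit_x_dagger) {
    nm <- c(nm, "xratio"); lo <- c(lo, 0.05); hi <- c(hi, 1)
  }
  if (hairpin) {
    nm <- c(nm, "dgdest"); lo <- c(lo, 0); hi <- c(hi, 5)
  }
  list(names = nm, lower = stats::setNames(lo, nm),
       upper = stats::setNames(hi, nm))
}

decode_rates <- function(theta, spec) {
  th <- stats::setNames(theta, spec$names)
  g <- function(x) 10^th[[x]]
  if ("lkc" %in% spec$names) {
    k_h <- k_r <- 2 * g("lkc")   # tied: k_c_eff = k_h k_r/(k_h + k_r)
  } else {
    k_h <- g("lkh"); k_r <- g("lkr")
  }
  delta <- th[["delta"]]
  x_dag <- if ("xratio" %in% spec$names) th[["xratio"]] * delta else delta
  ktrp <- if ("lktrp" %in% spec$names) g("lktrp") else 1
  ktrm <- if ("lktrm" %in% spec$names) g("lktrm") else 1
  rate_set(k_plus_b = g("lkb"), k_minus_b = g("lkmb"), k_h = k_h, k_r = k_r,
           k_plus_tr = ktrp, k_minus_tr = ktrm, delta = delta,
           x_dagger = x_dag,
           dG_dest = if ("dgdest" %in% spec$names) th[["dgdest"]] else 0)
}

encode_rates <- function(rates, spec) {
  th <- numeric(length(spec$names))
  names(th) <- spec$names
  th["lkb"] <- log10(rates$k_plus_b)
  th["lkmb"] <- log10(rates$k_minus_b)
  if ("lkc" %in% spec$names) th["lkc"] <- log10(k_c_eff(rates))
  if ("lkh" %in% spec$names) th["lkh"] <- log10(rates$k_h)
  if ("lkr" %in% spec$names) th["lkr"] <- log10(rates$k_r)
  if ("lktrp" %in% spec$names) th["lktrp"] <- log10(rates$k_plus_tr)
  if ("lktrm" %in% spec$names) th["lktrm"] <- log10(rates$k_minus_tr)
  th["delta"] <- rates$delta
  if ("xratio" %in% spec$names) th["xratio"] <- rates$x_dagger / rates$delta
  if ("dgdest" %in% spec$names) th["dgdest"] <- rates$dG_dest
  pmin(pmax(th, spec$lower), spec$upper)
}

# ---- objective ---------------------------------------------------------

#' Sum of squared errors of a cycle against a binned velocity dataset
#'
#' The model velocity is evaluated at each bin's center force and ATP
#' concentration and compared with the binned mean; the objective is the
#' plain (optionally `1/sem^2`-weighted) sum of squared differences.
#'
#' @param sch a [scheme()].
#' @param rates a [rate_set()].
#' @param dataset an `fv_dataset` (a single geometry).
#' @param geometry the matching [geometry_context()].
#' @param weighted use `1/sem^2` weights instead of the plain SSE.
#' @return Non-negative scalar.
#' @export
sse_velocity <- function(sch, rates, dataset, geometry, weighted = FALSE) {
  d <- as.data.frame(dataset)
  v <- steady_state_velocity(sch, rates, d$force, d$atp, geometry,
                             method = "closed")
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))[1]
    stop(sprintf("model velocity not finite at F = %g pN, [ATP] = %g M",
                 d$force[bad], d$atp[bad]))
  }
  w <- if (weighted) 1 / d$sem^2 else rep(1, nrow(d))
  sum(w * (d$velocity - v)^2)
}

#' Coefficient of determination of a fit
#'
#' `R^2 = 1 - SSE / SST`, with SST the total sum of squares about the
#' dataset grand mean.
#'
#' @param sse sum of squared errors.
#' @param velocity observed bin velocities.
#' @export
r_squared <- function(sse, velocity) {
  sst <- sum((velocity - mean(velocity))^2)
  if (sst <= 0) stop("zero-variance dataset: R^2 undefined")
  1 - sse / sst
}

# Data-informed but truth-agnostic starting point: amplitude scales from
# the fastest bin, K_M scale from the ATP design.
heuristic_start <- function(spec, d) {
  th <- (spec$lower + spec$upper) / 2
  vtop <- max(d$velocity)
  delta0 <- 3
  th["delta"] <- delta0
  kc <- max(vtop, 1) / delta0
  if ("lkc" %in% spec$names) th["lkc"] <- log10(kc)
  if ("lkh" %in% spec$names) th["lkh"] <- log10(2 * kc)
  if ("lkr" %in% spec$names) th["lkr"] <- log10(2 * kc)
  km0 <- stats::median(unique(d$atp))
  th["lkb"] <- log10(pmax(kc / km0, 1))
  th["lkmb"] <- log10(kc)
  if ("lktrp" %in% spec$names) th["lktrp"] <- log10(100 * kc)
  if ("lktrm" %in% spec$names) th["lktrm"] <- log10(100 * kc)
  if ("dgdest" %in% spec$names) th["dgdest"] <- 0.5
  pmin(pmax(th, spec$lower), spec$upper)
}

fit_one_geometry <- function(sch, d, geometry, spec, n_starts, seed,
                             weighted, start_rates = NULL) {
  obj <- function(theta) {
    rs <- tryCatch(decode_rates(theta, spec), error = function(e) NULL)
    if (is.null(rs)) return(1e12)
    val <- tryCatch(sse_velocity(sch, rs, d, geometry, weighted),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }
  p <- length(spec$names)
  set.seed(seed)
  starts <- lhs::randomLHS(max(n_starts - 1L, 1L), p)
  starts <- sweep(starts, 2, spec$upper - spec$lower, "*")
  starts <- sweep(starts, 2, spec$lower, "+")
  starts <- rbind(heuristic_start(spec, d), starts)
  if (!is.null(start_rates)) {
    starts <- rbind(encode_rates(start_rates, spec), starts)
  }
  starts <- starts[seq_len(min(nrow(starts), max(n_starts, 1L))), ,
                   drop = FALSE]
  best <- NULL
  log <- data.frame(start = integer(), objective = numeric(),
                    convergence = integer())
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], obj, lower = spec$lower,
                    upper = spec$upper,
                    control = list(iter.max = 400, eval.max = 800)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    log <- rbind(log, data.frame(start = i, objective = res$objective,
                                 convergence = res$convergence))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")
  list(theta = stats::setNames(best$par, spec$names),
       rates = decode_rates(best$par, spec),
       sse = best$objective, starts_log = log)
}

#' Globally fit one mechano-chemical cycle to binned velocity data
#'
#' Multi-start bounded least squares of a cycle's predicted velocity
#' surface `v(F, [ATP])` against a binned dataset from one or both assay
#' geometries. Rates are optimized on a log scale with Latin-hypercube
#' start placement plus a data-scaled heuristic start; the step size (and,
#' optionally, the transition-state position and the fork destabilization
#' energy) are optimized on a linear scale. `mode = "separate"` fits an
#' independent rate set to each geometry (different enzyme contexts in the
#' two assays, e.g. allosteric modulation of the microscopic rates by
#' partner subunits); `mode = "joint"` shares one rate set across both.
#'
#' @param dataset an `fv_dataset` from [bin_fv()] (may contain one or both
#'   geometries).
#' @param sch a [scheme()].
#' @param geometry named list of [geometry_context()] objects by mode.
#' @param mode `"separate"` or `"joint"` rate sharing across geometries.
#' @param n_starts number of optimization starts.
#' @param seed integer seed controlling start placement.
#' @param tie_catalysis fit a single composite catalytic rate (ties
#'   `k_h = k_r`), halving the catalytic parameter count.
#' @param fit_x_dagger also fit the transition-state position (default:
#'   pinned at the full step, `x_dagger = delta`).
#' @param weighted use `1/sem^2` weights.
#' @param start_rates optional [rate_set()] (or list by geometry) used as
#'   an additional start.
#' @return An object of class `cycle_fit`.
#' @export
fit_cycle <- function(dataset, sch,
                      geometry = list(
                        opposing_force = geometry_context("opposing_force"),
                        hairpin_assisting = geometry_context("hairpin_assisting")),
                      mode = c("separate", "joint"), n_starts = 50, seed = 1,
                      tie_catalysis = TRUE, fit_x_dagger = FALSE,
                      weighted = FALSE, start_rates = NULL) {
  mode <- match.arg(mode)
  d <- as.data.frame(dataset)
  modes <- unique(as.character(d$geometry))
  if (!all(modes %in% names(geometry))) {
    stop("missing geometry context for: ",
         paste(setdiff(modes, names(geometry)), collapse = ", "))
  }
  contexts <- list()
  sse_by <- numeric(0)

  if (mode == "separate" || length(modes) == 1L) {
    for (k in seq_along(modes)) {
      g <- modes[k]
      dg <- d[d$geometry == g, ]
      spec <- par_spec(sch, hairpin = g == "hairpin_assisting",
                       tie_catalysis, fit_x_dagger)
      sr <- if (inherits(start_rates, "rate_set")) start_rates else start_rates[[g]]
      fit <- fit_one_geometry(sch, dg, geometry[[g]], spec, n_starts,
                              seed + k - 1L, weighted, sr)
      contexts[[g]] <- fit
      sse_by[g] <- fit$sse
    }
  } else {
    # joint: shared rates, hairpin-only dG_dest appended
    spec <- par_spec(sch, hairpin = "hairpin_assisting" %in% modes,
                     tie_catalysis, fit_x_dagger)
    obj_d <- list()
    for (g in modes) obj_d[[g]] <- d[d$geometry == g, ]
    obj <- function(theta) {
      rs <- tryCatch(decode_rates(theta, spec), error = function(e) NULL)
      if (is.null(rs)) return(1e12)
      tot <- 0
      for (g in modes) {
        val <- tryCatch(sse_velocity(sch, rs, obj_d[[g]], geometry[[g]],
                                     weighted),
                        error = function(e) NA_real_)
        if (!is.finite(val)) return(1e12)
        tot <- tot + val
      }
      tot
    }
    p <- length(spec$names)
    set.seed(seed)
    starts <- lhs::randomLHS(max(n_starts - 1L, 1L), p)
    starts <- sweep(starts, 2, spec$upper - spec$lower, "*")
    starts <- sweep(starts, 2, spec$lower, "+")
    starts <- rbind(heuristic_start(spec, d), starts)
    best <- NULL
    log <- data.frame(start = integer(), objective = numeric(),
                      convergence = integer())
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::nlminb(starts[i, ], obj, lower = spec$lower,
                      upper = spec$upper,
                      control = list(iter.max = 400, eval.max = 800)),
        error = function(e) NULL)
      if (is.null(res)) next
      log <- rbind(log, data.frame(start = i, objective = res$objective,
                                   convergence = res$convergence))
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    if (is.null(best)) stop("all optimization starts failed")
    shared <- list(theta = stats::setNames(best$par, spec$names),
                   rates = decode_rates(best$par, spec),
                   sse = best$objective, starts_log = log)
    for (g in modes) {
      contexts[[g]] <- shared
      sse_by[g] <- sse_velocity(sch, shared$rates, obj_d[[g]],
                                geometry[[g]], weighted)
    }
  }

  sse_total <- sum(sse_by)
  r2 <- r_squared(sse_total, d$velocity)
  structure(
    list(scheme = sch, mode = mode, contexts = contexts,
         sse = sse_by, sse_total = sse_total, r_squared = r2,
         data = dataset, geometry = geometry[modes],
         weighted = weighted,
         n_par = sum(vapply(contexts[unique(names(contexts))],
                            function(x) length(x$theta), 0L)),
         call = match.call()),
    class = "cycle_fit"
  )
}

#' Fit all six cycles and rank them by total minimized SSE
#'
#' Fits every scheme from [enumerate_schemes()] to the dataset with
#' [fit_cycle()] and ranks the schemes by the sum of minimized SSE across
#' geometries (the selection statistic); the full ranking is always
#' reported, never only the winner. Schemes whose fits fail are recorded
#' with the error and excluded from the ranking.
#'
#' @inheritParams fit_cycle
#' @param schemes list of schemes to compare.
#' @return An object of class `scheme_selection`: a list with `ranking`
#'   (data frame: scheme, sse, r_squared, n_par, aic), `fits` (named list
#'   of `cycle_fit`), `errors`.
#' @export
select_scheme <- function(dataset, schemes = enumerate_schemes(),
                          geometry = list(
                            opposing_force = geometry_context("opposing_force"),
                            hairpin_assisting = geometry_context("hairpin_assisting")),
                          mode = c("separate", "joint"), n_starts = 50,
                          seed = 1, ...) {
  mode <- match.arg(mode)
  fits <- list(); errors <- list()
  for (s in schemes) {
    res <- tryCatch(
      fit_cycle(dataset, s, geometry = geometry, mode = mode,
                n_starts = n_starts, seed = seed, ...),
      error = function(e) e)
    if (inherits(res, "error")) errors[[s$id]] <- conditionMessage(res)
    else fits[[s$id]] <- res
  }
  if (length(fits) < 2L) stop("fewer than two schemes could be fitted")
  n_obs <- nrow(as.data.frame(dataset))
  ranking <- data.frame(
    scheme = names(fits),
    sse = vapply(fits, `[[`, 0, "sse_total"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    n_par = vapply(fits, `[[`, 0L, "n_par"),
    row.names = NULL
  )
  # informational only; selection is strictly by SSE
  ranking$aic <- n_obs * log(ranking$sse / n_obs) + 2 * ranking$n_par
  ranking <- ranking[order(ranking$sse), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, fits = fits, errors = errors,
                 best = ranking$scheme[1]),
            class = "scheme_selection")
}

#' Residual-bootstrap standard errors for a cycle fit
#'
#' Resamples the fit residuals with replacement onto the fitted values and
#' refits (single start at the fitted parameters) `n` times; reports the
#' bootstrap standard deviation of every parameter per geometry context.
#'
#' @param fit a `cycle_fit`.
#' @param n number of bootstrap resamples.
#' @param seed integer seed.
#' @return Named list by geometry of named numeric vectors (s.d. of each
#'   transformed parameter), attached to a copy of the fit as `boot_se`.
#' @export
bootstrap_se <- function(fit, n = 200, seed = 1) {
  d <- as.data.frame(fit$data)
  out <- list()
  for (g in names(fit$contexts)) {
    dg <- d[d$geometry == g, ]
    spec <- par_spec(fit$scheme, hairpin = g == "hairpin_assisting",
                     tie_catalysis = !("lkh" %in% names(fit$contexts[[g]]$theta)),
                     fit_x_dagger = "xratio" %in% names(fit$contexts[[g]]$theta))
    pred <- steady_state_velocity(fit$scheme, fit$contexts[[g]]$rates,
                                  dg$force, dg$atp, fit$geometry[[g]],
                                  method = "closed")
    resid <- dg$velocity - pred
    set.seed(seed)
    boots <- matrix(NA_real_, n, length(spec$names))
    for (b in seq_len(n)) {
      db <- dg
      db$velocity <- pred + sample(resid, length(resid), replace = TRUE)
      fb <- tryCatch(
        fit_one_geometry(fit$scheme, db, fit$geometry[[g]], spec,
                         n_starts = 1L, seed = seed + b,
                         weighted = fit$weighted,
                         start_rates = fit$contexts[[g]]$rates),
        error = function(e) NULL)
      if (!is.null(fb)) boots[b, ] <- fb$theta
    }
    out[[g]] <- apply(boots, 2, stats::sd, na.rm = TRUE)
    names(out[[g]]) <- spec$names
  }
  out
}
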