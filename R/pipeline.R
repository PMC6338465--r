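# Centered moving average with window truncation at the edges.
run_mean_trunc <- function(x, w) {
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a trace to a target bandwidth
#'
#' Centered moving-average filter reducing the bandwidth from the sampling
#' rate `f_s` to `f_c`, with a window of `round(f_s / f_c)` samples
#' (truncated at the edges; output length preserved). Both the extension
#' and the force channel are smoothed identically.
#'
#' @param trace an `sm_trace`.
#' @param f_c target bandwidth (Hz), must be below `f_s / 2`.
#' @return The smoothed `sm_trace`.
#' @export
smooth_to_bandwidth <- function(trace, f_c = 250) {
  if (f_c >= trace$f_s / 2) {
    stop("`f_c` must be below the Nyquist frequency f_s / 2")
  }
  w <- max(1L, round(trace$f_s / f_c))
  trace$extension <- run_mean_trunc(trace$extension, w)
  trace$force <- run_mean_trunc(trace$force, w)
  trace$meta$f_c <- f_c
  trace
}

#' Convert a trace to contour length in bp of dsDNA
#'
#' Per-sample eWLC inversion of the measured extension at the measured
#' force, converted to base pairs at the dsDNA rise. Samples below the
#' low-force cutoff are masked (`NA`) rather than extrapolated.
#'
#' @param trace an `sm_trace`.
#' @param polymer a [polymer_params()].
#' @param cutoff low-force cutoff (pN).
#' @param kBT thermal energy (pN nm).
#' @return Numeric vector of contour lengths (bp), `NA` where masked.
#' @export
to_contour <- function(trace, polymer = polymer_params(), cutoff = 0.5,
                       kBT = 4.11) {
  ok <- trace$force >= cutoff
  if (!any(ok)) {
    stop("all samples fall below the low-force cutoff of ", cutoff, " pN")
  }
  out <- rep(NA_real_, length(trace$force))
  out[ok] <- ewlc_inverse(trace$extension[ok], trace$force[ok], polymer, kBT) /
    polymer$nm_per_bp
  out
}

#' Base pairs unwound along a trace
#'
#' Geometry-aware conversion of the measured channels into the number of
#' base pairs the enzyme has unwound. Opposing-force geometry: the dsDNA
#' contour from [to_contour()] is subtracted from the track length, so
#' unwinding counts in bp of dsDNA. Hairpin geometry: the fixed ds-handle
#' extension is subtracted and the remainder attributed to released ssDNA
#' (two nucleotides per unwound bp) at the FJC extension per nucleotide.
#'
#' @inheritParams to_contour
#' @return Numeric vector (bp unwound), `NA` where masked.
#' @export
unwound_series <- function(trace, polymer = polymer_params(), cutoff = 0.5,
                           kBT = 4.11) {
  trap <- trace$meta$trap
  if (is.null(trap)) stop("trace carries no trap metadata")
  if (trace$geometry == "opposing_force") {
    trap$handle_bp - to_contour(trace, polymer, cutoff, kBT)
  } else {
    ok <- trace$force >= cutoff
    if (!any(ok)) {
      stop("all samples fall below the low-force cutoff of ", cutoff, " pN")
    }
    out <- rep(NA_real_, length(trace$force))
    f <- trace$force[ok]
    x_handles <- trap$handle_bp * polymer$nm_per_bp *
      ewlc_fraction(f, polymer, kBT)
    nt <- (trace$extension[ok] - x_handles) / fjc_extension_per_nt(f, polymer, kBT)
    out[ok] <- nt / 2
    out
  }
}

#' Instantaneous force-velocity points from one trace
#'
#' The contour (bp-unwound) series is cut into non-overlapping time windows
#' of `window` seconds; the velocity in each window is the slope of an
#' ordinary least-squares line through the contour-time data and the force
#' is the window mean. The resulting velocity sequence is then passed
#' through a running median filter whose length is `median_frac` of the
#' number of windows (shrinking windows at the edges). Windows containing
#' masked samples are dropped.
#'
#' @param unwound numeric vector (bp), e.g. from [unwound_series()].
#' @param force force vector (pN), same sampling.
#' @param f_s sampling rate (Hz).
#' @param window window length (s).
#' @param median_frac length of the median filter as a fraction of the
#'   number of windows.
#' @return Data frame with columns `force` (pN) and `velocity` (bp/s).
#' @export
instantaneous_fv <- function(unwound, force, f_s = 2500, window = 0.1,
                             median_frac = 0.1) {
  wlen <- round(window * f_s)
  n_w <- length(unwound) %/% wlen
  if (n_w < 2L) stop("fewer than 2 complete windows in the trace")
  idx <- seq_len(n_w * wlen)
  Y <- matrix(unwound[idx], nrow = wlen)
  Fm <- matrix(force[idx], nrow = wlen)
  t_w <- (seq_len(wlen) - (wlen + 1) / 2) / f_s   # centered time design
  sxx <- sum(t_w^2)
  ybar <- colMeans(Y)
  slope <- as.numeric(crossprod(t_w, Y)) / sxx    # OLS, centered predictor
  f_mean <- colMeans(Fm)
  keep <- is.finite(slope) & is.finite(f_mean)
  slope <- slope[keep]; f_mean <- f_mean[keep]
  if (length(slope) >= 3L) {
    k <- round(length(slope) * median_frac)
    k <- max(1L, k - (1L - k %% 2L))              # odd, >= 1
    if (k >= 3L) slope <- as.numeric(stats::runmed(slope, k, endrule = "median"))
  }
  data.frame(force = f_mean, velocity = slope)
}

#' Process traces into pooled force-velocity points
#'
#' The full per-trace chain: bandwidth smoothing, conversion to bp unwound,
#' windowed velocity estimation and median filtering, pooled over traces
#' with condition labels attached.
#'
#' @param traces list of `sm_trace` objects.
#' @param f_c smoothing bandwidth (Hz).
#' @param polymer a [polymer_params()].
#' @param cutoff low-force cutoff (pN).
#' @param window velocity window (s).
#' @param median_frac median-filter length fraction.
#' @return Data frame with columns `geometry`, `atp`, `trace`, `force`,
#'   `velocity`.
#' @export
process_traces <- function(traces, f_c = 250, polymer = polymer_params(),
                           cutoff = 0.5, window = 0.1, median_frac = 0.1) {
  pieces <- lapply(seq_along(traces), function(i) {
    tr <- smooth_to_bandwidth(traces[[i]], f_c)
    u <- unwound_series(tr, polymer, cutoff)
    fv <- instantaneous_fv(u, tr$force, tr$f_s, window, median_frac)
    fv$geometry <- tr$geometry
    fv$atp <- tr$atp
    fv$trace <- i
    fv
  })
  do.call(rbind, pieces)
}

#' Bin force-velocity points into a dataset
#'
#' Pools the windowed (force, velocity) points of all traces of a condition
#' and quantizes them over a force range, reporting per-bin mean velocity,
#' standard error of the mean and count. Bins with fewer than `min_count`
#' points are dropped. Default bin widths follow the two assays: 3 pN for
#' the opposing-force (in-complex) data and 2 pN for the hairpin (isolated
#' enzyme) data, over 0-60 pN.
#'
#' @param points data frame from [process_traces()] (columns `geometry`,
#'   `atp`, `force`, `velocity`).
#' @param width bin width (pN); `NULL` selects 3 or 2 pN by geometry.
#' @param range force range covered by the bins (pN).
#' @param min_count minimum points per kept bin.
#' @return A data frame of class `fv_dataset` with columns `geometry`,
#'   `atp`, `force` (bin center), `velocity`, `sem`, `n`.
#' @export
bin_fv <- function(points, width = NULL, range = c(0, 60), min_count = 5) {
  stopifnot(nrow(points) > 0)
  conds <- unique(points[c("geometry", "atp")])
  out <- lapply(seq_len(nrow(conds)), function(i) {
    g <- conds$geometry[i]; a <- conds$atp[i]
    w <- if (is.null(width)) (if (g == "opposing_force") 3 else 2) else width
    if (w <= 0) stop("bin width must be positive")
    edges <- seq(range[1], range[2], by = w)
    p <- points[points$geometry == g & points$atp == a, ]
    bin <- findInterval(p$force, edges, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin < length(edges)
    p <- p[keep, ]; bin <- bin[keep]
    agg <- lapply(split(p$velocity, bin), function(v) {
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    b <- as.integer(names(agg))
    m <- do.call(rbind, agg)
    d <- data.frame(geometry = g, atp = a,
                    force = edges[b] + w / 2,
                    velocity = m[, "mean"], sem = m[, "sem"], n = m[, "n"])
    d[d$n >= min_count, ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fv_dataset", "data.frame")
  attr(out, "range") <- range
  out
}

#' Per-force Michaelis-Menten parameters across ATP
#'
#' For every (geometry, force bin) with at least three ATP concentrations,
#' fits `v = v_max * T / (K_M + T)` by weighted least squares across the
#' ATP dimension of a binned dataset, giving the force-resolved `v_max(F)`
#' and `K_M(F)` profiles.
#'
#' @param dataset an `fv_dataset` (from [bin_fv()]).
#' @return Data frame with columns `geometry`, `force`, `v_max`,
#'   `v_max_se`, `K_M`, `K_M_se`, `n_atp`, `note`.
#' @export
fit_mm_per_force <- function(dataset) {
  dataset <- as.data.frame(dataset)
  keys <- unique(dataset[c("geometry", "force")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- dataset[dataset$geometry == keys$geometry[i] &
                   dataset$force == keys$force[i], ]
    if (nrow(d) < 3L) return(NULL)
    fit <- tryCatch(fit_mm(d$atp, d$velocity, d$sem), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(geometry = keys$geometry[i], force = keys$force[i],
               v_max = fit$coefficients[["v_max"]], v_max_se = fit$se[1],
               K_M = fit$coefficients[["K_M"]], K_M_se = fit$se[2],
               n_atp = nrow(d),
               note = if (is.null(fit$note)) "" else fit$note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
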