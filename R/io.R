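# Tabular trace format: tab-separated columns time_s, extension_nm,
# force_pN, with a JSON metadata sidecar (<path>.json) carrying geometry,
# [ATP], sampling rate, seeds and generating parameters.

#' Read and write single-molecule traces
#'
#' Traces are stored as tab-separated text (`time_s`, `extension_nm`,
#' `force_pN`; unknown extra columns are preserved on round-trip) with a
#' JSON sidecar `<path>.json` holding the metadata.
#'
#' @param trace an `sm_trace`.
#' @param path file path for the tabular part.
#' @return `read_trace()` returns an `sm_trace`; `write_trace()` the path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, extension_nm = trace$extension,
                   force_pN = trace$force)
  extra <- trace$meta$extra_columns
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(geometry = trace$geometry, atp = trace$atp, f_s = trace$f_s)
  keep <- c("seed_run", "seed_noise", "noise_sd", "scheme_id", "f_c")
  for (k in keep) if (!is.null(trace$meta[[k]])) meta[[k]] <- trace$meta[[k]]
  if (!is.null(trace$meta$trap)) meta$trap <- unclass(trace$meta$trap)
  if (!is.null(trace$meta$rates)) meta$rates <- unclass(trace$meta$rates)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = NA, check.names = FALSE),
    error = function(e) stop("failed to parse trace file ", path, ": ",
                             conditionMessage(e)))
  need <- c("time_s", "extension_nm", "force_pN")
  if (!all(need %in% names(df))) {
    stop("trace file ", path, " lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("malformed numeric cell in column '%s', data row %d of %s",
                   cn, bad, path))
    }
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  trap <- if (!is.null(meta$trap)) {
    do.call(trap_model, meta$trap)
  } else NULL
  rates <- if (!is.null(meta$rates)) do.call(rate_set, meta$rates) else NULL
  extra <- df[setdiff(names(df), need)]
  structure(
    list(time = df$time_s, extension = df$extension_nm, force = df$force_pN,
         geometry = meta$geometry %||% "opposing_force",
         atp = meta$atp %||% NA_real_, f_s = meta$f_s %||% 2500,
         meta = list(seed_run = meta$seed_run, seed_noise = meta$seed_noise,
                     noise_sd = meta$noise_sd, scheme_id = meta$scheme_id,
                     trap = trap, rates = rates,
                     extra_columns = if (ncol(extra)) extra else NULL)),
    class = "sm_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write binned force-velocity datasets
#'
#' Tab-separated table with the bin metadata (force range) in `#`-prefixed
#' header lines.
#'
#' @param dataset an `fv_dataset`.
#' @param path file path.
#' @export
write_fv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rng <- attr(dataset, "range") %||% c(0, 60)
  writeLines(sprintf("# fv_dataset force_range_pN=%g,%g", rng[1], rng[2]), con)
  utils::write.table(as.data.frame(dataset), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fv
#' @export
read_fv <- function(path) {
  lines <- readLines(path, n = 5L)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("geometry", "atp", "force", "velocity", "sem", "n")
  if (!all(need %in% names(df))) {
    stop("force-velocity file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  class(df) <- c("fv_dataset", "data.frame")
  m <- regmatches(hdr, regexec("force_range_pN=([0-9.]+),([0-9.]+)", hdr))
  m <- Filter(length, m)
  if (length(m)) {
    attr(df, "range") <- as.numeric(m[[1]][2:3])
  }
  df
}

#' Run configuration
#'
#' Bundles every tunable of the simulate/process/fit chain with its default
#' value, so a single JSON document fully reproduces a run. Defaults follow
#' the standard processing chain: 2500 Hz sampling, 250 Hz smoothing,
#' 100 ms velocity windows, tenth-length median filter, 3 / 2 pN bins over
#' 0-60 pN, eWLC with `L_p` = 40 nm and `S` = 1000 pN.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    f_s = 2500, f_c = 250, window = 0.1, median_frac = 0.1,
    bin_width_opposing = 3, bin_width_hairpin = 2, force_range = c(0, 60),
    min_count = 5, cutoff = 0.5,
    L_p = 40, S = 1000, nm_per_bp = 0.34, ss_kuhn = 1.5, ss_nm_per_nt = 0.59,
    kBT = 4.11,
    dg_bp = 2.5, n_step = 3, m_window = 20,
    k_eff = 0.4, noise_sd = 2,
    n_starts = 50, seed = 1, mode = "separate"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed configuration file ",
                                           path, ": ", conditionMessage(e)))
  cfg <- run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration fields in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  defaulted <- setdiff(names(cfg), names(raw))
  cfg[names(raw)] <- raw
  attr(cfg, "defaulted") <- defaulted
  cfg
}
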