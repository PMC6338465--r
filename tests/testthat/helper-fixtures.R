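# Shared fixtures: geometry contexts, reference rate sets, and a cached
# closure-style synthetic dataset (simulated once per test run).

geo2 <- function() {
  list(opposing_force = geometry_context("opposing_force"),
       hairpin_assisting = geometry_context("hairpin_assisting"))
}

rates2 <- function() {
  list(opposing_force = recd_in_complex(),
       hairpin_assisting = recd_isolated())
}

atp_design <- function() c(2e-5, 5e-5, 1.5e-4, 5e-4, 2e-3)

closure_plan <- function(n_traces = 10) {
  plan <- expand.grid(geometry = c("opposing_force", "hairpin_assisting"),
                      atp = atp_design(), stringsAsFactors = FALSE)
  plan$n_traces <- n_traces
  plan
}

.fixture_cache <- new.env(parent = emptyenv())

# Closure dataset: BR-before-binding truth, 10 traces x 5 [ATP] per
# geometry, in-complex rates in the opposing assay and isolated rates in
# the hairpin assay, processed with the default pipeline.
closure_dataset <- function(seed = 1) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]])) {
    traces <- generate_dataset(closure_plan(), enumerate_schemes()$br_binding,
                               rates2(), geometry = geo2(), seed = seed)
    .fixture_cache[[key]] <- bin_fv(process_traces(traces))
  }
  .fixture_cache[[key]]
}

# Analytic velocity surface evaluated at the bins of a dataset.
analytic_surface <- function(dataset, sch = enumerate_schemes()$br_binding,
                             rates = rates2(), geoms = geo2()) {
  d <- as.data.frame(dataset)
  v <- numeric(nrow(d))
  for (g in unique(as.character(d$geometry))) {
    i <- d$geometry == g
    v[i] <- steady_state_velocity(sch, rates[[g]], d$force[i], d$atp[i],
                                  geoms[[g]], method = "closed")
  }
  v
}

# Noiseless binned dataset built directly from the analytic surface
# (for fitting tests that need an exact target).
analytic_dataset <- function(sch, rates, geoms, forces, atps) {
  rows <- list()
  for (g in names(geoms)) {
    cells <- expand.grid(force = forces[[g]], atp = atps)
    v <- steady_state_velocity(sch, rates[[g]], cells$force, cells$atp,
                               geoms[[g]], method = "closed")
    rows[[g]] <- data.frame(geometry = g, atp = cells$atp,
                            force = cells$force, velocity = v,
                            sem = 1, n = 100L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fv_dataset", "data.frame")
  out
}
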