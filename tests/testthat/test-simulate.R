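test_that("identical seeds give bit-identical event lists", {
  br <- enumerate_schemes()$br_binding
  go <- geo2()$opposing_force
  a <- gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 1,
                     seed = 5)
  b <- gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 1,
                     seed = 5)
  expect_identical(a$time, b$time)
  expect_identical(a$position_bp, b$position_bp)
  c <- gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 1,
                     seed = 6)
  expect_false(identical(a$time, c$time))
})

test_that("without ATP a ratchet fluctuates with zero mean drift", {
  br <- enumerate_schemes()$br_binding
  go <- geo2()$opposing_force
  final_at <- function(duration, seed) {
    run <- gillespie_run(br, recd_in_complex(), go, atp = 0,
                         duration = duration, seed = seed, force_clamp = 5)
    n <- length(run$position_bp)
    if (n == 0L) 0 else run$position_bp[n]
  }
  short <- vapply(1:20, function(i) final_at(0.02, i), numeric(1))
  long <- vapply(1:20, function(i) final_at(1, 100 + i), numeric(1))
  # excursions stay bounded by a single pre/post step: no rectification
  expect_true(all(abs(c(short, long)) <= recd_in_complex()$delta + 1e-9))
  # and the implied velocity vanishes as the observation time grows
  expect_lt(mean(abs(long)) / 1, mean(abs(short)) / 0.02)
  expect_lt(abs(mean(long / 1)), 5)   # bp/s, versus ~500 bp/s with ATP
})

test_that("clamped ensembles converge to the analytic steady state", {
  br <- enumerate_schemes()$br_binding
  conds <- list(list(g = "opposing_force", F = 8, atp = 2e-3),
                list(g = "opposing_force", F = 22, atp = 5e-5),
                list(g = "hairpin_assisting", F = 12, atp = 2e-4))
  for (cn in conds) {
    g <- geo2()[[cn$g]]
    r <- rates2()[[cn$g]]
    ev <- ensemble_velocity(br, r, g, cn$F, cn$atp, n = 120,
                            duration = 0.25, seed = 77)
    va <- steady_state_velocity(br, r, cn$F, cn$atp, g)
    expect_lt(abs(ev$mean - va), 3.5 * ev$sem)
  }
})

test_that("rendered traces satisfy the passive-mode force balance", {
  br <- enumerate_schemes()$br_binding
  go <- geo2()$opposing_force
  run <- gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 1,
                       seed = 9)
  tr <- render_trace(run, noise_sd = 0, f_s = 2500, seed = 1)
  grid <- attr(run, "grid")
  trap <- attr(run, "trap")
  # F = k_eff (sep - x_tether(F)) at every sample, before noise;
  # recompute the tether extension independently from the recorded positions
  pos_seq <- c(0, run$position_bp)
  k_idx <- findInterval(tr$time, run$time) + 1L
  pos <- pos_seq[k_idx]
  x_tether <- helicycle:::tether_extension(tr$force, pos, "opposing_force",
                                           trap, go$polymer)
  resid <- tr$force - trap$k_eff * (grid$separation - x_tether)
  expect_lt(max(abs(resid)), 1e-6)
  # extension channel equals the force-balance solution
  expect_equal(tr$extension, grid$separation - tr$force / trap$k_eff,
               tolerance = 1e-12)
})

test_that("measurement noise has the requested magnitude and force coupling", {
  br <- enumerate_schemes()$br_binding
  go <- geo2()$opposing_force
  run <- gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 1.2,
                       seed = 15)
  t0 <- render_trace(run, noise_sd = 0, f_s = 2500, seed = 3)
  t2 <- render_trace(run, noise_sd = 2, f_s = 2500, seed = 3)
  eps <- t2$extension - t0$extension
  expect_equal(stats::sd(eps), 2, tolerance = 0.1)
  # propagated to force through the trap stiffness
  expect_equal(t2$force - t0$force, -0.4 * eps, tolerance = 1e-12)
})

test_that("trace phenomenology matches the two assays", {
  br <- enumerate_schemes()$br_binding
  run_o <- gillespie_run(br, recd_in_complex(), geo2()$opposing_force,
                         atp = 2e-3, duration = 3, seed = 21)
  tr_o <- render_trace(run_o, noise_sd = 0, seed = 1)
  n <- length(tr_o$force)
  expect_gte(tr_o$force[n], tr_o$force[1])        # rising force
  expect_lte(tr_o$extension[n], tr_o$extension[1])
  run_h <- gillespie_run(br, recd_isolated(), geo2()$hairpin_assisting,
                         atp = 2e-3, duration = 1.5, seed = 22)
  tr_h <- render_trace(run_h, noise_sd = 0, seed = 1)
  n <- length(tr_h$force)
  expect_lte(tr_h$force[n], tr_h$force[1])        # relaxing force
  expect_gte(tr_h$extension[n], tr_h$extension[1])
})

test_that("datasets are reproducible and cover the requested plan", {
  br <- enumerate_schemes()$br_binding
  plan <- expand.grid(geometry = c("opposing_force", "hairpin_assisting"),
                      atp = c(1e-4, 2e-3), stringsAsFactors = FALSE)
  plan$n_traces <- 2
  d1 <- generate_dataset(plan, br, rates2(), geometry = geo2(), seed = 31,
                         duration = c(opposing_force = 0.5,
                                      hairpin_assisting = 0.5))
  d2 <- generate_dataset(plan, br, rates2(), geometry = geo2(), seed = 31,
                         duration = c(opposing_force = 0.5,
                                      hairpin_assisting = 0.5))
  expect_length(d1, sum(plan$n_traces))
  tags <- unique(vapply(d1, function(t) paste(t$geometry, t$atp), ""))
  expect_length(tags, 4L)
  expect_equal(d1[[1]]$extension, d2[[1]]$extension)
  expect_equal(d1[[8]]$force, d2[[8]]$force)
})

test_that("a force-dependent off-rate shortens opposing traces", {
  br <- enumerate_schemes()$br_binding
  go <- geo2()$opposing_force
  ends <- function(diss) {
    vapply(1:8, function(i) {
      gillespie_run(br, recd_in_complex(), go, atp = 2e-3, duration = 6,
                    seed = 40 + i, dissociation = diss)$t_end
    }, numeric(1))
  }
  t_free <- ends(NULL)
  t_diss <- ends(list(k0 = 1e-4, x_dag_nm = 1.2))
  expect_lt(mean(t_diss), mean(t_free))
})
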