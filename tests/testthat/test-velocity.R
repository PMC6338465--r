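# Independent oracle: direct steady-state solution of the 3-state
# power-stroke cycle (binding reversible, hydrolysis/release irreversible),
# derived by hand from the balance equations.
ps3_flux <- function(u1, w1, u2, u3) {
  u1 * u2 * u3 / (u3 * (u2 + w1) + u1 * u3 + u1 * u2)
}

test_that("no ATP means no net velocity for every scheme and geometry", {
  for (s in enumerate_schemes()) {
    for (g in geo2()) {
      expect_identical(steady_state_velocity(s, recd_in_complex(), 5, 0, g), 0)
      expect_identical(
        steady_state_velocity(s, recd_in_complex(), 5, 0, g, method = "closed"), 0)
    }
  }
})

test_that("null-space and closed-form velocities agree everywhere", {
  cells <- expand.grid(force = c(0.5, 3, 11, 24, 41, 58),
                       atp = c(1e-6, 2e-5, 3.5e-4, 2e-3, 1e-1))
  for (s in enumerate_schemes()) {
    for (g in geo2()) {
      for (r in rates2()) {
        v1 <- steady_state_velocity(s, r, cells$force, cells$atp, g,
                                    method = "nullspace")
        v2 <- steady_state_velocity(s, r, cells$force, cells$atp, g,
                                    method = "closed")
        expect_equal(v1, v2, tolerance = 1e-9)
      }
    }
  }
})

test_that("the 3-state power-stroke cycle matches the hand-derived solution", {
  go <- geo2()$opposing_force
  r <- rate_set(k_plus_b = 5e6, k_minus_b = 700, k_h = 250, k_r = 410,
                delta = 3.3)
  f0 <- go$kBT / (r$delta * go$nm_per_bp)
  for (F in c(0, 7, 21)) {
    for (T in c(5e-5, 2e-3)) {
      # translocation at binding: both Bell factors on the binding step
      v_exp <- r$delta * ps3_flux(r$k_plus_b * T * exp(-F / f0),
                                  r$k_minus_b, r$k_h, r$k_r)
      v_got <- steady_state_velocity(scheme("power_stroke", "binding"), r,
                                     F, T, go)
      expect_equal(v_got, v_exp, tolerance = 1e-10)
    }
  }
})

test_that("BR-before-binding reaches the rapid-equilibrium limits", {
  go <- geo2()$opposing_force
  # very fast translocation: vmax is force-independent and K_M(F)/K_M(0)
  # follows the shifted-equilibrium form (1 + K e^(F/F0)) / (1 + K)
  K <- 0.4
  r <- rate_set(k_plus_tr = 1e10, k_minus_tr = K * 1e10, delta = 3.3)
  br <- scheme("brownian_ratchet", "binding")
  f0 <- go$kBT / (r$delta * go$nm_per_bp)
  mm0 <- mm_parameters(br, r, 0, go)
  expect_equal(mm0$v_max, r$delta * k_c_eff(r), tolerance = 1e-4)
  for (F in c(6, 12)) {
    mmF <- mm_parameters(br, r, F, go)
    expect_equal(mmF$v_max, mm0$v_max, tolerance = 1e-3)
    expect_equal(mmF$K_M / mm0$K_M,
                 (1 + K * exp(F / f0)) / (1 + K), tolerance = 1e-3)
  }
})

test_that("every scheme follows Michaelis-Menten kinetics in ATP", {
  # v(T) = v_max T / (K_M + T) to < 1e-3 relative over 4 decades around K_M
  for (s in enumerate_schemes()) {
    for (gname in names(geo2())) {
      g <- geo2()[[gname]]
      r <- rates2()[[gname]]
      F <- if (gname == "opposing_force") 15 else 10
      mm <- mm_parameters(s, r, F, g)
      T <- mm$K_M * 10^seq(-2, 2, length.out = 9)
      v <- steady_state_velocity(s, r, F, T, g, method = "closed")
      v_mm <- mm$v_max * T / (mm$K_M + T)
      expect_lt(max(abs(v - v_mm) / v_mm), 1e-3)
    }
  }
})

test_that("the degenerate three-step chain matches the textbook closed form", {
  # at zero force the translocation placement is invisible and every PS
  # scheme reduces to the plain chain: v_max = d k_h k_r/(k_h + k_r),
  # K_M = ((k_minus_b + k_h)/k_plus_b) (k_r/(k_h + k_r))
  go <- geo2()$opposing_force
  r <- rate_set(k_plus_b = 8e6, k_minus_b = 900, k_h = 220, k_r = 500,
                delta = 2.1)
  for (s in enumerate_schemes(mechanism = "power_stroke")) {
    mm <- mm_parameters(s, r, 0, go)
    expect_equal(mm$v_max, r$delta * r$k_h * r$k_r / (r$k_h + r$k_r),
                 tolerance = 1e-5)
    expect_equal(mm$K_M,
                 (r$k_minus_b + r$k_h) / r$k_plus_b * r$k_r / (r$k_h + r$k_r),
                 tolerance = 1e-5)
  }
})

test_that("velocity is monotone in force and ATP as the geometry dictates", {
  forces <- seq(0.5, 55, length.out = 12)
  atps <- 10^seq(-6, -2, length.out = 10)
  for (s in enumerate_schemes()) {
    for (gname in names(geo2())) {
      g <- geo2()[[gname]]
      r <- rates2()[[gname]]
      vF <- steady_state_velocity(s, r, forces, 2e-3, g, method = "closed")
      if (gname == "opposing_force") {
        expect_true(all(diff(vF) <= 1e-9))   # non-increasing under load
      } else {
        expect_true(all(diff(vF) >= -1e-9))  # assisted by fork opening
      }
      vT <- steady_state_velocity(s, r, 10, atps, g, method = "closed")
      expect_true(all(diff(vT) > 0))
    }
  }
})

test_that("logistic force-velocity law evaluates and fits correctly", {
  expect_equal(logistic_velocity(43, 1000, 43, 4), 500)
  expect_equal(logistic_velocity(0, 860, 29, 3.7),
               860 / (1 + exp(-29 / 3.7)))
  curve <- data.frame(force = seq(1, 60, 3))
  curve$velocity <- logistic_velocity(curve$force, 1000, 43, 4)
  curve$sem <- 1
  fit <- fit_logistic(curve)
  expect_equal(unname(fit$coefficients), c(1000, 43, 4), tolerance = 1e-5)
  flat <- data.frame(force = 1:10, velocity = rep(250, 10))
  expect_error(fit_logistic(flat), "degenerate")
  expect_error(fit_logistic(curve[1:3, ]), "at least 4")
})
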