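test_that("eWLC extension matches the interpolation formula and inverts", {
  p <- polymer_params()
  # F = 10 pN, L_p = 40 nm, S = 1000 pN: x/L = 1 - sqrt(4.11/400)/2 + 0.01
  expect_equal(ewlc_extension(10, 1, p),
               1 - 0.5 * sqrt(4.11 / 400) + 10 / 1000, tolerance = 1e-12)
  # inextensible, high-force limit
  p_stiff <- polymer_params(S = 1e12)
  expect_equal(ewlc_extension(5e3, 1, p_stiff), 1, tolerance = 1e-2)
  # roundtrip identity over the working force range
  F <- seq(0.5, 60, length.out = 40)
  L <- 1400
  x <- ewlc_extension(F, L, p)
  expect_lt(max(abs(ewlc_inverse(x, F, p) - L) / L), 1e-6)
  expect_error(ewlc_extension(0, 100, p), "force")
  expect_error(ewlc_inverse(100, -2, p), "force")
})

test_that("ssDNA release energy matches numerical quadrature of the FJC", {
  p <- polymer_params()
  expect_identical(ss_release_energy(0, 1, p), 0)
  # linear in nt
  expect_equal(ss_release_energy(8, 6, p), 6 * ss_release_energy(8, 1, p))
  # closed form vs numerical integral of the extension
  for (F in c(2, 9, 25)) {
    num <- stats::integrate(function(f) fjc_extension_per_nt(f, p), 0, F,
                            rel.tol = 1e-10)$value / 4.11
    expect_equal(ss_release_energy(F, 1, p), num, tolerance = 1e-7)
  }
  # high-force asymptote: energy/nt -> (F l_c - const)/kBT, slope l_c/kBT
  e1 <- ss_release_energy(500, 1, p)
  e2 <- ss_release_energy(501, 1, p)
  expect_equal(e2 - e1, p$ss_nm_per_nt * 1 / 4.11, tolerance = 1e-2)
  # monotone non-decreasing
  e <- ss_release_energy(seq(0, 40, 0.5), 1, p)
  expect_true(all(diff(e) >= 0))
})

test_that("fork-opening probability matches brute-force partition sums", {
  p <- polymer_params()
  # uniform zipper: dg = 0 gives (m - n + 1)/(m + 1)
  f_uni <- fork_params(dg_bp = 1e-14, n_step = 3, m_window = 20)
  expect_equal(p_open(0, f_uni, p), (20 - 3 + 1) / 21, tolerance = 1e-10)
  # two-state coin: n = m = 1, dg = 0
  f_coin <- fork_params(dg_bp = 1e-14, n_step = 1, m_window = 1)
  expect_equal(p_open(0, f_coin, p), 0.5, tolerance = 1e-10)
  # explicit 21-term sum at dg = 1 kBT
  f1 <- fork_params(dg_bp = 1, n_step = 3, m_window = 20)
  j <- 0:20
  expect_equal(p_open(0, f1, p),
               sum(exp(-j[j >= 3])) / sum(exp(-j)), tolerance = 1e-12)
  # limits
  expect_lt(p_open(0, fork_params(dg_bp = 50, n_step = 3), p), 1e-12)
  expect_gt(p_open(60, fork_params(dg_bp = 0.5, n_step = 3), p), 1 - 1e-6)
})

test_that("P_open is a probability, monotone in force, step size and stability", {
  p <- polymer_params()
  F <- seq(0, 25, 0.5)
  for (dg in c(1.5, 2.5)) for (n in c(1, 3, 6)) {
    pr <- p_open(F, fork_params(dg_bp = dg, n_step = n), p)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_true(all(diff(pr) >= 0))
  }
  # harder fork or larger step means less opening
  expect_lt(p_open(8, fork_params(dg_bp = 3, n_step = 3), p),
            p_open(8, fork_params(dg_bp = 2, n_step = 3), p))
  expect_lt(p_open(8, fork_params(dg_bp = 2.5, n_step = 5), p),
            p_open(8, fork_params(dg_bp = 2.5, n_step = 3), p))
  # a closed mixed-sequence fork is essentially never open 3 bp at F = 0
  expect_lt(p_open(0, fork_params(dg_bp = 2.5, dG_dest = 0, n_step = 3), p),
            1e-2)
})

test_that("destabilization energy enters P_open as a per-bp offset", {
  p <- polymer_params()
  pr0 <- p_open(6, fork_params(dg_bp = 2.5, dG_dest = 0.6), p)
  pr1 <- p_open(6, fork_params(dg_bp = 1.9, dG_dest = 0), p)
  expect_equal(pr0, pr1, tolerance = 1e-12)
})
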