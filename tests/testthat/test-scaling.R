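test_that("fractal dimension closed form matches known values", {
  expect_equal(round(fractal_dimension(scaling_params(0.638, 3.76)), 2), 2.33)
  expect_equal(fractal_dimension(scaling_params(1.0, 4)), 3.0)
  expect_equal(fractal_dimension(scaling_params(1.0, 0.37)), 3.0)
  expect_equal(fractal_dimension(scaling_params(0.5, 1)), 1.5)  # 3 ln2 / ln4
})

test_that("parameter validation rejects non-physical inputs", {
  expect_error(scaling_params(0, 1), "positive")
  expect_error(scaling_params(1.2, 1), "<= 1")
  expect_error(scaling_params(0.5, -1), "positive")
  expect_error(scaling_params(0.5, 1, R0 = 0), "positive")
})

test_that("assembly recursion reproduces cluster counts and the monomer", {
  it <- iterate_assembly(scaling_params(2 / 3, 4, R0 = 1.6, M0 = 9.06), 2)
  expect_equal(it$N, c(1, 5, 25))
  p <- scaling_params(0.638, 3.76, R0 = 1.6, M0 = 9.06)
  it0 <- iterate_assembly(p, 0)
  expect_equal(it0$N, 1)
  expect_equal(it0$M, p$M0)
  expect_equal(it0$R, p$R0)
  V0 <- 4 / 3 * pi * p$R0^3
  expect_equal(it0$V, V0)
  expect_equal(it0$C, 1e27 / 6.02214076e23 / V0)
})

test_that("iteration invariants: growth, self-similarity, unit consistency", {
  for (pars in list(c(0.638, 3.76), c(0.397, 2.0), c(0.9, 0.8))) {
    p <- scaling_params(pars[1], pars[2], R0 = 1.3, M0 = 8)
    it <- iterate_assembly(p, 6)
    expect_equal(it$N, (p$n + 1)^(0:6))
    expect_true(all(diff(it$V) > 0))
    expect_true(all(diff(it$C) < 0))                  # phi < 1
    expect_equal(it$M, it$N * p$M0)
    expect_equal(it$C, it$C[1] * p$phi^(0:6))
    # C V N_A = N (C in mM, V in nm^3)
    expect_equal(it$C * it$V * 6.02214076e23 / 1e27, it$N)
    # exact self-similarity with k_f = 1, to 10 significant digits
    df <- fractal_dimension(p)
    expect_equal(it$N, (it$R / p$R0)^df, tolerance = 1e-10)
  }
})

test_that("mass-size fit is exact on model points and on a two-point line", {
  p <- scaling_params(0.638, 3.76, R0 = 1.6, M0 = 9.06)
  f <- fit_mass_size(iterate_assembly(p, 5))
  expect_equal(f$A, fractal_dimension(p), tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  f2 <- fit_mass_size(data.frame(R = c(1, 10), M = c(10, 1000)))
  expect_equal(f2$A, 2)
  expect_equal(f2$B, 1)
  expect_error(fit_mass_size(data.frame(R = c(2, 2), M = c(1, 5))), "distinct")
  expect_error(fit_mass_size(data.frame(R = 1, M = 1)), "2 points")
})

test_that("mass-size fit on noisy points matches an OLS oracle and the planted slope", {
  set.seed(42)
  p <- scaling_params(0.55, 3, R0 = 1.5, M0 = 9)
  it <- iterate_assembly(p, 8)
  M_noisy <- it$M * exp(rnorm(nrow(it), 0, 0.05))    # log-normal mass noise
  f <- fit_mass_size(data.frame(R = it$R, M = M_noisy))
  orc <- oracle_ols(log10(it$R), log10(M_noisy))
  expect_equal(f$A, unname(orc["slope"]), tolerance = 1e-12)
  expect_equal(f$B, unname(orc["intercept"]), tolerance = 1e-12)
  expect_lt(abs(f$A - fractal_dimension(p)), 0.1)
})

test_that("inverting the fit recovers compactness and valency", {
  for (pars in list(c(0.638, 3.76, 1.60, 9.06), c(0.397, 2.0, 1.97, 8.0))) {
    p <- scaling_params(pars[1], pars[2], pars[3], pars[4])
    f <- fit_mass_size(iterate_assembly(p, 5))
    V_vdw <- p$phi * 4 / 3 * pi * p$R0^3
    q <- invert_fit(f, p$M0, V_vdw)
    expect_equal(q$phi, p$phi, tolerance = 1e-7)
    expect_equal(q$n, p$n, tolerance = 1e-7)
    expect_equal(q$R0, p$R0, tolerance = 1e-7)
  }
  expect_error(invert_fit(list(A = 3.2, B = 1), 9, 10), "\\(0, 3\\)")
  # V_vdw exceeding the apparent volume implies phi > 1: inconsistent
  p <- scaling_params(0.5, 2, 1.5, 9)
  f <- fit_mass_size(iterate_assembly(p, 4))
  expect_error(invert_fit(f, 9, 100), "inconsistent")
})

test_that("valency diverges as the fitted slope approaches 3 at fixed phi", {
  # work on log(n + 1): n itself overflows long before the limit
  log_n1 <- vapply(c(1e-1, 1e-2, 1e-3, 1e-4), function(eps) {
    A <- 3 - eps
    A * log(1 / 0.6) / (3 - A)
  }, numeric(1))
  expect_true(all(diff(log_n1) > 0))
  expect_gt(log_n1[4], log(1e50))
  # finite slope away from the limit still inverts cleanly
  n_mid <- exp(2.9 * log(1 / 0.6) / 0.1) - 1
  expect_true(is.finite(n_mid) && n_mid > 1e5)
})

test_that("scale-dependent concentration follows the d_f - 3 power law", {
  p <- scaling_params(0.638, 3.76, R0 = 1.60, M0 = 9.06)
  C0 <- concentration_at_size(p, p$R0)
  it <- iterate_assembly(p, 6)
  expect_equal(C0, it$C[1])
  # cross-check closed form against the recursion at every iterate radius
  expect_equal(concentration_at_size(p, it$R) / C0, p$phi^(0:6))
  # space-filling limit: constant density
  p1 <- scaling_params(1, 3, R0 = 2, M0 = 10)
  expect_equal(concentration_at_size(p1, c(2, 20, 2000)),
               rep(concentration_at_size(p1, 2), 3))
  expect_error(concentration_at_size(p, 0.5), ">= R0")
})

test_that("fixed size-and-concentration isocurve trades compactness for valency", {
  iso <- isocurve_phi_of_n(R = 1000, C = 1, M0 = 9.06, n_grid = c(2, 3, 6))
  expect_true(all(is.finite(iso$phi)))
  expect_gt(iso$phi[iso$n == 2], iso$phi[iso$n == 6])
  expect_true(all(diff(iso$phi) < 0))
  # each returned point reproduces the demanded concentration
  V_vdw <- 1.21 * 9.06
  for (k in seq_len(nrow(iso))) {
    R0 <- (3 * V_vdw / (4 * pi * iso$phi[k]))^(1 / 3)
    p <- scaling_params(iso$phi[k], iso$n[k], R0, 9.06)
    expect_equal(concentration_at_size(p, 1000), 1, tolerance = 1e-6)
  }
  # infeasible demand: concentration beyond the space-filling limit
  bad <- isocurve_phi_of_n(R = 1000, C = 1e9, M0 = 9.06, n_grid = c(2, 4))
  expect_true(all(is.na(bad$phi)))
})

test_that("Flory-Stockmayer percolation threshold", {
  expect_equal(percolation_threshold(2)$p_crit, 1.0)
  expect_equal(percolation_threshold(3)$p_crit, 0.5)
  expect_equal(percolation_threshold(5)$p_crit, 0.25)
  expect_true(percolation_threshold(1.5)$clipped)
  expect_false(percolation_threshold(2.5)$clipped)
  expect_error(percolation_threshold(1), "exceed 1")
})

test_that("fractal dimension is monotone in compactness and valency", {
  phis <- seq(0.1, 1, length.out = 10)
  ns <- seq(0.5, 10, length.out = 10)
  for (n in ns) {
    d <- vapply(phis, function(ph) fractal_dimension(scaling_params(ph, n)),
                numeric(1))
    expect_true(all(diff(d) > 0))
  }
  for (ph in phis[phis < 1]) {
    d <- vapply(ns, function(n) fractal_dimension(scaling_params(ph, n)),
                numeric(1))
    expect_true(all(diff(d) > 0))
  }
})
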