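# P2 autocorrelation, multi-exponential fitting, spectral densities, rates.

test_that("P2 autocorrelation handles static and uncorrelated limits", {
  v <- matrix(rep(c(1, 0, 0), each = 200), ncol = 3)
  cf <- p2_autocorrelation(vector_series(1, v, 1e-11), n_chunks = 4)
  expect_equal(cf$values, rep(1, length(cf$lags)), tolerance = 1e-9)
  # frame-to-frame independent directions: <P2> over the sphere is 0
  withr::with_seed(2, {
    g <- matrix(rnorm(3 * 20000), ncol = 3)
  })
  g <- g / sqrt(rowSums(g^2))
  cfi <- p2_autocorrelation(vector_series(1, g, 1e-11), n_chunks = 10)
  i <- cf_lags <- cfi$lags > 0
  expect_true(all(abs(cfi$values[i]) < 3 * cfi$se[i] + 0.02))
  expect_equal(cfi$values[1], 1, tolerance = 1e-9)
})

test_that("chunk count does not bias C(t)", {
  vs <- gen_rotdiff_vectors(rotdiff_spec(2e-9, 1e-11, 40000, seed = 8))
  c10 <- p2_autocorrelation(vs, n_chunks = 10, max_lag_fraction = 0.25)
  c20 <- p2_autocorrelation(vs, n_chunks = 20, max_lag_fraction = 0.5)
  n <- min(length(c10$values), length(c20$values))
  se <- sqrt(c10$se[1:n]^2 + c20$se[1:n]^2)
  expect_true(all(abs(c10$values[1:n] - c20$values[1:n]) <= 3 * pmax(se, 1e-3)))
})

test_that("multi-exponential fits recover closed-form inputs", {
  t <- seq(0, 50e-9, by = 5e-11)
  # pure single exponential: one surviving component
  f1 <- fit_triexponential(list(lags = t, values = exp(-t / 2e-9)))
  expect_length(f1$A, 1L)
  expect_equal(f1$A[1], 1, tolerance = 0.01)
  expect_equal(f1$tau[1], 2e-9, tolerance = 0.02)
  # two dominant components recovered within 5%; any residual component is tiny
  y <- 0.6 * exp(-t / 1e-9) + 0.4 * exp(-t / 20e-9)
  f2 <- fit_triexponential(list(lags = t, values = y))
  top <- order(f2$A, decreasing = TRUE)[1:2]
  top <- top[order(f2$tau[top])]
  expect_equal(f2$A[top], c(0.6, 0.4), tolerance = 0.05)
  expect_equal(f2$tau[top], c(1e-9, 20e-9), tolerance = 0.05)
  expect_lt(sum(f2$A[-top]), 0.01)
  # constant 0.8: plateau component with tau far beyond the lag window
  f3 <- fit_triexponential(list(lags = t, values = rep(0.8, length(t))))
  expect_equal(sum(f3$A), 0.8, tolerance = 0.01)
  expect_gte(max(f3$tau), 100 * max(t))
  expect_error(fit_triexponential(list(lags = t[1:5], values = y[1:5])), "10 lag")
})

test_that("amplitude and time constraints hold on noisy input", {
  vs <- gen_rotdiff_vectors(rotdiff_spec(3e-9, 2e-11, 30000, seed = 12))
  fit <- fit_triexponential(p2_autocorrelation(vs, n_chunks = 10))
  expect_true(all(fit$A >= 0))
  expect_lte(sum(fit$A), 1 + 1e-6)
  expect_true(all(fit$tau > 0))
  expect_true(!is.unsorted(fit$tau))
})

test_that("tumbling reintroduction combines times harmonically", {
  # A = {0.5, 0.5}, tau = {1 ns, Inf}, tau_rot = 10 ns:
  # J(0) = (2/5)(0.5 * 10/11 + 0.5 * 10) ns
  m <- spectral_density_model(c(0.5, 0.5), c(1e-9, Inf), tau_rot = 10e-9)
  expect_equal(m$tau_eff, c(10 / 11 * 1e-9, 10e-9))
  expect_equal(spectral_density(m, 0), 0.4 * (0.5 * 10 / 11 + 0.5 * 10) * 1e-9)
  # plateau + tumbling = rigid rotor
  mr <- spectral_density_model(1, Inf, tau_rot = 163.4e-9)
  w <- 2 * pi * 60.8e6
  expect_equal(spectral_density(mr, w),
               0.4 * 163.4e-9 / (1 + (w * 163.4e-9)^2))
  # tau_rot = Inf leaves internal times untouched
  fit <- structure(list(A = c(0.3, 0.7), tau = c(1e-9, 5e-9)), class = "triexp_fit")
  expect_equal(apply_tumbling(fit, Inf)$tau_eff, c(1e-9, 5e-9))
  expect_true(all(spectral_density(m, 10^seq(6, 10, 0.5)) >= 0))
})

test_that("relaxation rates match an independent evaluation of the formulas", {
  sc <- spin_constants()
  for (tau in c(5e-9, 50e-9, 163.4e-9)) {
    r <- relaxation_rates(spectral_density_model(1, tau, Inf), sc)
    o <- oracle_rates(tau)
    expect_equal(r$R1, o$R1, tolerance = 1e-12)
    expect_equal(r$R2, o$R2, tolerance = 1e-12)
    expect_gt(r$R2, r$R1)
  }
  # J == 0: zero rates, NOE flagged undefined
  z <- relaxation_rates(spectral_density_model(0, 1e-9, Inf), sc)
  expect_equal(z$R1, 0)
  expect_equal(z$R2, 0)
  expect_true(is.na(z$NOE))
  # R2 strictly increases with tau for a rigid rotor
  taus <- seq(1e-9, 300e-9, length.out = 40)
  r2 <- vapply(taus, function(tt)
    relaxation_rates(spectral_density_model(1, tt, Inf), sc)$R2, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("R2/R1 inversion is exact when high-frequency terms vanish", {
  # algebraic identity: (d^2/8 + c^2/6) = (1/6)(3 d^2/4 + c^2) makes the
  # ratio depend on J(0)/J(wN) alone, for any tau and any CSA
  for (tau in c(1e-9, 20e-9, 163.4e-9, 500e-9)) {
    for (csa_ppm in c(0, -120, -172, 250)) {
      sc <- spin_constants(csa_ppm = csa_ppm)
      r <- relaxation_rates(spectral_density_model(1, tau, Inf), sc,
                            include_high_freq = FALSE)
      tc <- residue_tau_c(r, sc)
      expect_equal(tc$tau_c, tau, tolerance = 1e-12)
    }
  }
})

test_that("full chain on rotational-diffusion input matches the closed form", {
  sc <- spin_constants()
  vs <- gen_rotdiff_vectors(rotdiff_spec(5e-9, 1e-11, 100000, seed = 21))
  rec <- relaxation_from_vectors(vs, tau_rot = Inf, constants = sc, n_chunks = 10)
  o <- oracle_rates(5e-9)
  expect_lt(abs(rec$R1 / o$R1 - 1), 0.10)
  expect_lt(abs(rec$R2 / o$R2 - 1), 0.10)
})

test_that("cone motion plus tumbling reproduces the model-free spectral density", {
  sc <- spin_constants()
  tau_rot <- 163.4e-9; tau_int <- 2e-9
  vs <- gen_cone_vectors(cone_spec(30, tau_int, 2e-11, 100000, seed = 5))
  S2 <- attr(vs, "truth")$S2
  rec <- relaxation_from_vectors(vs, tau_rot = tau_rot, constants = sc, n_chunks = 10)
  taup <- 1 / (1 / tau_int + 1 / tau_rot)
  o <- oracle_rates(c(tau_rot, taup), amps = c(S2, 1 - S2))
  expect_lt(abs(rec$R1 / o$R1 - 1), 0.15)
  expect_lt(abs(rec$R2 / o$R2 - 1), 0.15)
})

test_that("residue tau_c flags the undefined branch instead of erroring", {
  sc <- spin_constants()
  r0 <- list(R1 = 2, R2 = 2)                 # ratio 1 < 7/6
  tc <- residue_tau_c(r0, sc)
  expect_false(tc$defined)
  expect_true(is.na(tc$tau_c))
  tc2 <- residue_tau_c(list(R1 = 6, R2 = 7), sc)   # ratio exactly 7/6
  expect_equal(tc2$tau_c, 0)
  expect_false(tc2$defined)
})

test_that("computed-vs-measured comparison reproduces hand-computed Pearson r", {
  a <- data.frame(residue_id = 1:4, tau_c = c(1, 2, 3, 5))
  b <- data.frame(residue_id = 1:4, tau_c = c(2, 1, 4, 6))
  cmp <- compare_to_experiment(a, b)
  # hand covariance formula
  r_hand <- sum((a$tau_c - mean(a$tau_c)) * (b$tau_c - mean(b$tau_c))) /
    sqrt(sum((a$tau_c - mean(a$tau_c))^2) * sum((b$tau_c - mean(b$tau_c))^2))
  expect_equal(cmp$pearson_r, r_hand)
  expect_equal(compare_to_experiment(a, a)$pearson_r, 1)
  b2 <- a; b2$tau_c <- 2 * a$tau_c
  expect_equal(compare_to_experiment(b2, a)$pearson_r, 1)  # scale invariance
  expect_error(compare_to_experiment(a[1:2, ], b), "3 shared")
})
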