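test_that("single-metal solver conserves mass and respects affinity limits", {
  # no-binding limit
  weak <- solve_single(8e-4, 4e-4, 1e3, 2)
  expect_lt(weak$Y, 1e-6)
  # stoichiometric limit: vanishing K_D, half an equivalent of metal
  tight <- solve_single(8e-4, 4e-4, 1e-12, 2)
  expect_equal(tight$Y, 1, tolerance = 1e-4)
  # mass conservation across a parameter sweep
  for (Kd in c(1e-6, 85e-6, 1e-3)) for (Mt in c(1e-5, 4e-4, 2e-3)) {
    r <- solve_single(8e-4, Mt, Kd, 2)
    expect_lt(abs(r$P_f + 2 * r$complex - 8e-4) / 8e-4, 1e-9)
    expect_lt(abs(r$M_f + r$complex - Mt) / Mt, 1e-9)
    expect_gte(r$Y, 0); expect_lte(r$Y, 1 + 1e-12)
  }
})

test_that("solver agrees with an independent bisection oracle on the cubic", {
  P_t <- 8.0e-4; M_t <- 4.0e-4; K_D <- 85e-6; n <- 2
  # oracle: plain bisection on f(p) = p + n M p^n/(K^n + p^n) - P_t
  f <- function(p) p + n * M_t * p^n / (K_D^n + p^n) - P_t
  lo <- 1e-18; hi <- P_t
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  p_oracle <- (lo + hi) / 2
  y_oracle <- n * (M_t * p_oracle^n / (K_D^n + p_oracle^n)) / P_t
  r <- solve_single(P_t, M_t, K_D, n)
  expect_equal(r$Y, y_oracle, tolerance = 1e-9)
})

test_that("saturation is monotone nondecreasing in titrant total", {
  grid <- seq(1e-6, 2.5 * 8e-4, length.out = 60)
  y <- vapply(grid, function(m) solve_single(8e-4, m, 85e-6, 2)$Y,
              numeric(1))
  expect_true(all(diff(y) >= -1e-12))
})

test_that("competition solver satisfies the exchange identity and its limits", {
  P_t <- 1e-3; Co <- 3.5e-3; K1 <- 85e-6; Kex <- (85 / 5.6)^2
  r <- solve_competition(P_t, Co, 1e-3, K1, Kex)
  # K_D2 = K_D1 / sqrt(K_ex) holds algebraically between parameterizations
  expect_equal(r$K_D2, K1 / sqrt(Kex), tolerance = 1e-12)
  # the exchange ratio at equilibrium equals K_ex
  kex_obs <- (r$complex2 * r$M1_f) / (r$complex1 * r$M2_f)
  expect_equal(kex_obs, Kex, tolerance = 1e-9)
  # mass balances
  expect_lt(abs(r$P_f + 2 * (r$complex1 + r$complex2) - P_t) / P_t, 1e-9)
  # K_ex = 1 with equal totals: equal complexes
  sym <- solve_competition(1e-3, 2e-3, 2e-3, 85e-6, 1)
  expect_equal(sym$complex1, sym$complex2, tolerance = 1e-12)
  # no competitor: reduces exactly to the single-metal solver
  r0 <- solve_competition(P_t, Co, 0, K1, Kex)
  r1 <- solve_single(P_t, Co, K1, 2)
  expect_equal(r0$Y1, r1$Y, tolerance = 1e-12)
})

test_that("titration simulation is seed-reproducible with calibrated noise", {
  d1 <- simulate_titration(8e-4, seq(1e-5, 2e-3, length.out = 20),
                           85e-6, noise_sd = 0.02, seed = 5)
  d2 <- simulate_titration(8e-4, seq(1e-5, 2e-3, length.out = 20),
                           85e-6, noise_sd = 0.02, seed = 5)
  expect_identical(d1, d2)
  clean <- simulate_titration(8e-4, seq(1e-5, 2e-3, length.out = 20),
                              85e-6, noise_sd = 0)
  expect_equal(clean$observed,
               vapply(clean$titrant_total_M, function(m)
                 solve_single(8e-4, m, 85e-6, 2)$Y, numeric(1)))
  # Monte-Carlo: residual SD over many draws approaches the nominal noise
  grid5 <- seq(1e-5, 2e-3, length.out = 5)
  clean5 <- simulate_titration(8e-4, grid5, 85e-6, noise_sd = 0)$observed
  set.seed(31)
  res <- replicate(300, {
    simulate_titration(8e-4, grid5, 85e-6, noise_sd = 0.02)$observed - clean5
  })
  expect_equal(sd(as.vector(res)), 0.02, tolerance = 0.1)
})

test_that("direct fit recovers the generator exactly on noiseless data", {
  d <- make_titration("direct", noise_sd = 0, seed = 1)
  f <- fit_direct(d, P_t = 8e-4)
  expect_equal(f$estimates[["K_D"]], 85e-6, tolerance = 1e-6)
  fn <- fit_direct(d, P_t = 8e-4, fit_n = TRUE)
  expect_equal(fn$estimates[["n"]], 2, tolerance = 1e-4)
  # n = 1 on 2:1 data fits systematically worse
  f1 <- fit_direct(d, P_t = 8e-4, n = 1)
  expect_gt(f1$rss, 10 * f$rss + 1e-6)
})

test_that("noisy direct and competition fits recover generator constants within 10%", {
  d <- make_titration("direct", noise_sd = 0.02, seed = 42)
  f <- fit_direct(d, P_t = 8e-4, fit_n = TRUE)
  expect_lt(abs(f$estimates[["K_D"]] - 85e-6) / 85e-6, 0.10)
  expect_equal(f$n_rounded, 2)
  dc <- make_titration("competition", noise_sd = 0.02, seed = 7)
  fc <- fit_competition(dc, K_D1 = 85e-6, P_t = 1e-3, M1_t = 3.5e-3)
  expect_lt(abs(fc$estimates[["K_D2"]] - 5.6e-6) / 5.6e-6, 0.10)
  # cadmium-like generator at K_D2 = 5.0 uM; the measured constant itself
  # carries a 20% relative uncertainty (5.0 +/- 1.0 uM), which is the
  # recovery band asserted here
  kex_cd <- (85 / 5.0)^2
  dcd <- make_titration("competition", params = list(K_ex = kex_cd),
                        noise_sd = 0.02, seed = 13)
  fcd <- fit_competition(dcd, K_D1 = 85e-6, P_t = 1e-3, M1_t = 3.5e-3)
  expect_lt(abs(fcd$estimates[["K_D2"]] - 5.0e-6) / 5.0e-6, 0.20)
})

test_that("median K_D recovery error over seeded replicates stays below 5%", {
  errs <- vapply(1:200, function(seed) {
    d <- make_titration("direct", noise_sd = 0.02, seed = seed,
                        n_points = 40)
    f <- fit_direct(d, P_t = 8e-4)
    abs(f$estimates[["K_D"]] - 85e-6) / 85e-6
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("pH midpoint fit is exact on clean data and sign-agnostic", {
  d <- make_titration("ph", noise_sd = 0, seed = 1)
  f <- fit_ph_midpoint(d$ph, d$observed)
  expect_equal(f$estimates[["pH_mid"]], 7.1, tolerance = 1e-6)
  # decreasing variant: same midpoint
  f2 <- fit_ph_midpoint(d$ph, 1 - d$observed)
  expect_equal(f2$estimates[["pH_mid"]], 7.1, tolerance = 1e-6)
  # 2% amplitude noise: midpoint within 0.1 pH unit
  dn <- make_titration("ph", noise_sd = 0.02, seed = 9)
  fn <- fit_ph_midpoint(dn$ph, dn$observed)
  expect_lt(abs(fn$estimates[["pH_mid"]] - 7.1), 0.1)
})

test_that("binding_fit objects expose the standard modelling methods", {
  d <- make_titration("direct", noise_sd = 0.01, seed = 2)
  f <- fit_direct(d, P_t = 8e-4)
  expect_s3_class(f, "binding_fit")
  expect_named(coef(f), "K_D")
  expect_length(residuals(f), nrow(d))
  expect_equal(predict(f), f$fitted, tolerance = 1e-9)
  expect_output(print(f), "K_D")
  expect_output(print(summary(f)), "residual SD")
  pr <- predict(f, newdata = c(1e-4, 1e-3))
  expect_length(pr, 2)
  expect_true(all(diff(pr) > 0))
})
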