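test_that("Hill decay fits recover exact parameters and honor the half-max
           identity", {
  tt <- seq(0, 12, 0.3)
  conc <- 0.1 * 5^6 / (5^6 + tt^6)
  fit <- fit_hill_decay(tt, conc)
  expect_equal(fit$s0, 0.1, tolerance = 1e-6)
  expect_equal(fit$k_half, 5, tolerance = 1e-6)
  expect_equal(fit$n_hill, 6, tolerance = 1e-5)
  expect_equal(predict(fit, fit$k_half), (fit$s0 + fit$floor) / 2,
               tolerance = 1e-9)
  # fitted curve is non-increasing
  expect_true(all(diff(predict(fit, seq(0, 20, 0.1))) <= 1e-12))
})

test_that("Hill fits tolerate measurement noise and reject flat series", {
  set.seed(9)
  tt <- seq(0, 12, length.out = 40)
  truth <- 0.1 * 5^6 / (5^6 + tt^6)
  noisy <- truth * (1 + rnorm(40, 0, 0.02))
  fit <- fit_hill_decay(tt, pmax(noisy, 0))
  expect_lt(abs(fit$k_half - 5) / 5, 0.05)

  expect_error(fit_hill_decay(tt, rep(0.1, 40)), "non-decaying")
  expect_error(fit_hill_decay(tt[1:4], truth[1:4]))
})

test_that("half-max shifts are relative changes with the expected algebra", {
  tt <- seq(0, 12, 0.3)
  mk <- function(k) fit_hill_decay(tt, 0.1 * k^4 / (k^4 + tt^4))
  f4 <- mk(4); f6 <- mk(6)
  expect_equal(halfmax_shift(f4, f4), 0, tolerance = 1e-9)
  expect_equal(halfmax_shift(f6, f4), 0.5, tolerance = 1e-6)
  s <- halfmax_shift(f6, f4)
  expect_equal(halfmax_shift(f4, f6), -s / (1 + s), tolerance = 1e-6)
  expect_equal(metabolic_delay(f4, f6), 2, tolerance = 1e-6)
  expect_equal(metabolic_delay(f6, f6), 0, tolerance = 1e-9)
})

test_that("OD growth rates are exact on noiseless exponentials", {
  tt <- sort(c(seq(0, 8, 0.4), 1.03, 2.71))
  g <- od_growth_rate(tt, 0.01 * exp(0.3 * tt), smooth_window = 5)
  expect_equal(g$rate, rep(0.3, length(tt) - 1), tolerance = 1e-12)
  expect_equal(g$rate_smooth[3:(length(tt) - 3)],
               rep(0.3, length(tt) - 5), tolerance = 1e-12)
  g0 <- od_growth_rate(tt, rep(0.05, length(tt)), smooth_window = 1)
  expect_true(all(g0$rate == 0))
  expect_error(od_growth_rate(tt, c(0, rep(1, length(tt) - 1))))
})

test_that("growth rate of a synthetic diauxic culture dips at depletion and
           the dip deepens with the configured lag", {
  dip_depth <- function(lag) {
    ex <- generate_experiment(quick_config(lag = lag, seed = 33))
    g <- od_growth_rate(ex$od$time_h, ex$od$od600, smooth_window = 1)
    t_dep <- ex$truth$t_depletion
    pre <- g$rate[g$t < t_dep - 1]
    dip <- min(g$rate[g$t > t_dep - 0.5 & g$t < t_dep + lag + 1])
    mean(pre) - dip
  }
  d_small <- dip_depth(0.4); d_large <- dip_depth(1.5)
  expect_gt(d_small, 0)
  expect_gt(d_large, d_small)
})

test_that("expected consumption scales the reference rate by f_on and
           density", {
  tt <- seq(0, 5, 0.5)
  ref_rate <- rep(2e-6, length(tt))
  dens <- rep(1000, length(tt))
  full <- expected_consumption(tt, rep(1, length(tt)), tt, ref_rate, tt, dens)
  expect_equal(full$rate, ref_rate * dens, tolerance = 1e-12)
  expect_equal(max(full$cumulative), 2e-6 * 1000 * 5, tolerance = 1e-9)
  none <- expected_consumption(tt, rep(0, length(tt)), tt, ref_rate, tt, dens)
  expect_true(all(none$rate == 0) && all(none$cumulative == 0))
})

test_that("observed pre-depletion galactose use is far below the expected
           consumption when the leak is off", {
  ex <- generate_experiment(quick_config(gal_leak = 0, seed = 14))
  m <- galswitch:::.synth_model(ex$config)
  t_dep <- ex$truth$t_depletion
  tt <- ex$sugars$time_h[ex$sugars$sugar == "galactose"]
  gal <- ex$sugars$concentration[ex$sugars$sugar == "galactose"]
  pre <- tt < t_dep

  # expected consumption if ON cells consumed at the galactose-only rate
  exp_c <- expected_consumption(tt[pre], m$f_on_true(tt[pre]),
                                tt[pre], rep(ex$config$c_gal, sum(pre)),
                                tt[pre], m$n_tot(tt[pre]))
  observed <- gal[1] - gal[pre][sum(pre)]
  expect_lt(observed, 0.1 * max(exp_c$cumulative))
})
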