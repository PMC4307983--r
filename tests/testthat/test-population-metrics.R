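test_that("normalization is the log10 fluorescence/side-scatter ratio with
           rejection and clipping accounted", {
  raw <- data.frame(fluorescence = c(200, 100, 50, -3, 10),
                    side_scatter = c(100, 100, 0, 100, 100),
                    time_h = 0)
  out <- normalize_events(raw, floor = 1e-3)
  expect_equal(attr(out, "n_rejected"), 1)
  expect_equal(attr(out, "n_clipped"), 1)
  expect_equal(out$norm_log10[1:2], c(log10(2), 0), tolerance = 1e-12)
  expect_equal(out$norm_log10[out$fluorescence < 0], log10(1e-3 / 100))
})

test_that("normalized medians recover the generator's configured ratio", {
  set.seed(5)
  n <- 4000
  ss <- rlnorm(n, log(100), 0.3)
  raw <- data.frame(fluorescence = 10^rnorm(n, 0.5, 0.1) * ss,
                    side_scatter = ss, time_h = 0)
  out <- normalize_events(raw)
  expect_lt(abs(median(out$norm_log10) - 0.5), 0.02)
})

test_that("mixture classification separates unimodal from bimodal samples
           and is deterministic", {
  set.seed(1)
  uni <- rnorm(5000, 0, 0.1)
  f1 <- fit_mixture(uni, seed = 3)
  expect_identical(f1$modality, "unimodal")

  bi <- c(rnorm(2500, -1, 0.1), rnorm(2500, 0.5, 0.1))
  f2 <- fit_mixture(bi, seed = 3)
  expect_identical(f2$modality, "bimodal")
  expect_equal(f2$weights, c(0.5, 0.5), tolerance = 0.02 / 0.5)
  expect_equal(f2$means, c(-1, 0.5), tolerance = 0.05)
  expect_lt(max(abs(f2$means - c(-1, 0.5))), 0.02)

  expect_identical(fit_mixture(bi, seed = 3), f2)
  expect_error(fit_mixture(rnorm(100)), "too few")
  expect_error(fit_mixture(c(rnorm(300), NA)))

  # affine relocation flips neither the call nor the component order rule
  f3 <- fit_mixture(-bi, seed = 3)
  expect_identical(f3$modality, "bimodal")
  expect_true(all(diff(f3$means) > 0))
})

test_that("mixture component estimates agree with an independent GMM engine", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  set.seed(8)
  x <- c(rnorm(3000, -0.9, 0.12), rnorm(2000, 0.6, 0.15))
  ours <- fit_mixture(x, seed = 2)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_identical(ours$modality, "bimodal")
  expect_equal(sort(ours$means), sort(unname(ref$parameters$mean)),
               tolerance = 0.01)
  expect_equal(min(ours$weights), min(ref$parameters$pro), tolerance = 0.02)
})

test_that("half-max times interpolate the first upward crossing", {
  expect_equal(half_max_time(0:4, c(0, 2.5, 5, 7.5, 10)), 2)
  expect_true(is.na(half_max_time(0:5, rep(3, 6))))

  tt <- seq(0, 10, 1 / 3)
  y <- 1 / (1 + exp(-(tt - 3.7) / 0.6))
  expect_equal(half_max_time(tt, y), 3.7, tolerance = 0.05 / 3.7)
})

test_that("bimodal metrics follow from the half-max construction", {
  tt <- seq(0, 10, 0.5)
  rise <- function(t0) plogis((tt - t0) / 0.2)
  series <- structure(
    data.frame(t = tt, f_on = 0.4 + 0.6 * rise(6.5),
               modality = ifelse(tt > 0.5 & tt < 7, "bimodal", "unimodal"),
               mean_on = -1 + 2 * rise(1.5), mean_off = -1 + 2 * rise(6.5),
               n_on = 100, n_off = 100),
    class = c("subpop_series", "data.frame"))
  m <- bimodal_metrics(series)
  expect_equal(m$delta_a, 1.5, tolerance = 0.02)
  expect_equal(m$delta_g, 5.0, tolerance = 0.04)
  expect_equal(m$response_time, 6.5, tolerance = 0.1)

  series$mean_off <- series$mean_on
  m0 <- bimodal_metrics(series)
  expect_equal(m0$delta_g, 0, tolerance = 1e-9)

  # constant branches are flagged, not defaulted
  series$mean_on <- series$mean_off <- 0
  mna <- bimodal_metrics(series)
  expect_true(is.na(mna$delta_g))
  expect_true("delta_g" %in% names(mna$reasons))
})

test_that("tracking reports absent ON cohort, default threshold and density
           scaling", {
  set.seed(2)
  ev <- data.frame(time_h = rep(0:3, each = 400),
                   norm_log10 = rnorm(1600, -1, 0.1),
                   events_per_ul = rep(c(100, 200, 400, 800), each = 400))
  s <- track_subpopulations(ev, min_events = 200)
  expect_true(all(s$f_on == 0))
  expect_true(all(is.na(s$mean_on)))
  expect_true(attr(s, "scaled"))
  expect_identical(attr(s, "threshold"), -0.2)
  expect_equal(s$n_off, c(100, 200, 400, 800))
})

test_that("f_on is monotone non-increasing in the threshold", {
  set.seed(4)
  ev <- data.frame(time_h = rep(0:1, each = 500),
                   norm_log10 = c(rnorm(500, -0.8, 0.2), rnorm(500, 0.5, 0.2)))
  f <- vapply(seq(-1.5, 1, 0.25), function(thr)
    mean(track_subpopulations(ev, threshold = thr, min_events = 200)$f_on), 0)
  expect_true(all(diff(f) <= 1e-12))
})

test_that("tracked subpopulation means follow the generator truth", {
  ex <- generate_experiment(quick_config(seed = 21))
  m <- galswitch:::.synth_model(ex$config)
  ev <- normalize_events(ex$events)
  s <- track_subpopulations(ev, seed = 5)
  bi <- s$modality == "bimodal"
  expect_gt(sum(bi), 5)
  expect_lt(max(abs(s$mean_on[bi] - m$mean_on_t(s$t[bi]))), 0.05)
  expect_lt(max(abs(s$mean_off[bi] - m$mean_off_t(s$t[bi]))), 0.05)
})

test_that("growth-rate slopes are exact on exponential and constant counts", {
  tt <- seq(0, 5, 0.5)
  series <- structure(
    data.frame(t = tt, f_on = 0.5, modality = "bimodal",
               mean_on = 1, mean_off = -1,
               n_on = 100 * 2^tt, n_off = 500),
    class = c("subpop_series", "data.frame"))
  g <- subpop_growth_rates(series, c(0, 5))
  expect_equal(g$rate_on, 1, tolerance = 1e-9)
  expect_equal(g$rate_off, 0, tolerance = 1e-9)
  series$n_on[3] <- 0
  g2 <- subpop_growth_rates(series, c(0, 5))
  expect_identical(g2$n_excluded, 1L)
  expect_error(subpop_growth_rates(series[1:2, ], c(0, 1)))
})
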