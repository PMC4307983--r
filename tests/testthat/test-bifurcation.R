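p_def <- default_params("repressor")

test_that("scan finds contiguous ON -> bistable -> OFF blocks with ordered
           saddle-node thresholds", {
  grid <- 10^seq(0.5, 3.2, length.out = 18)
  bs <- bifurcation_scan(p_def, 150, grid)
  expect_identical(rle(bs$regime)$values,
                   c("mono_ON", "bistable", "mono_OFF"))
  expect_lt(bs$glu_low_star, bs$glu_high_star)

  # at the band midpoint there are exactly two stable states
  mid <- sqrt(bs$glu_low_star * bs$glu_high_star)
  eqs <- find_equilibria(p_def, mid, 150)
  expect_identical(sum(vapply(eqs, function(e) e$stable, NA)), 2L)

  # a grid entirely above the band is all mono_OFF with no thresholds
  hi <- bifurcation_scan(p_def, 150, seq(bs$glu_high_star * 1.5,
                                         bs$glu_high_star * 4,
                                         length.out = 4))
  expect_true(all(hi$regime == "mono_OFF"))
  expect_true(is.na(hi$glu_low_star) && is.na(hi$glu_high_star))
})

test_that("regime map is consistent with the scan and counts bistable area", {
  rm1 <- regime_map(p_def, glu_grid = c(150), gal_grid = c(150))
  bs <- bifurcation_scan(p_def, 150, c(100, 150, 300))
  expect_identical(rm1$labels[1, 1], bs$regime[2])
  expect_identical(rm1$bistable_area, sum(rm1$labels == "bistable"))
})

test_that("quasi-static labels predict coherent activation at the threshold
           crossing and a larger bimodal window under a second glucose step", {
  # constant mono-ON inputs: activation at the first grid point
  tgrid <- seq(0, 4, 0.5)
  qs <- quasi_static_regimes(p_def, tgrid, rep(30, length(tgrid)),
                             rep(150, length(tgrid)))
  expect_true(all(qs$regime == "mono_ON"))
  expect_identical(qs$t_activation, 0)

  # exponential glucose decay engineered to cross glu_low_star at t = 5 h
  bs <- bifurcation_scan(p_def, 150, 10^seq(1, 3, length.out = 12))
  k <- 0.4
  glu0 <- bs$glu_low_star * exp(k * 5)
  tgrid <- seq(0, 14, 0.25)
  qs <- quasi_static_regimes(p_def, tgrid, glu0 * exp(-k * tgrid),
                             rep(150, length(tgrid)))
  expect_lt(abs(qs$t_activation - 5), 0.25 + 1e-9)
  expect_true(!is.na(qs$pred_delta_g))

  # a second glucose step at 5 h keeps the system out of mono_ON longer
  glu_two <- glu0 * exp(-k * tgrid) + ifelse(tgrid >= 5,
                                             glu0 * exp(-k * (tgrid - 5)), 0)
  qs2 <- quasi_static_regimes(p_def, tgrid, glu_two, rep(150, length(tgrid)))
  expect_gt(qs2$pred_delta_g, qs$pred_delta_g)
})

test_that("delta_b matches the exponential closed form and clips at zero", {
  bs <- bifurcation_scan(p_def, 150, 10^seq(1, 3, length.out = 12))
  gstar <- bs$glu_low_star
  k <- 0.5; glu0 <- 500
  tt <- seq(0, 20, 0.001)
  db <- delta_b(p_def, tt, glu0 * exp(-k * tt), 150, gal_delay = 0,
                glu_star = gstar)
  expect_equal(as.numeric(db), log(glu0 / gstar) / k, tolerance = 1e-6)

  t_star <- log(glu0 / gstar) / k
  expect_identical(as.numeric(delta_b(p_def, tt, glu0 * exp(-k * tt), 150,
                                      gal_delay = t_star + 1,
                                      glu_star = gstar)), 0)

  # the delayed-galactose design: non-increasing delta_b over the delays
  delays <- c(0, 3.1, 4.2, 5.3, 6.3)
  dbs <- vapply(delays, function(d)
    as.numeric(delta_b(p_def, tt, glu0 * exp(-k * tt), 150, gal_delay = d,
                       glu_star = gstar)), 0)
  expect_true(all(diff(dbs) <= 0))
  expect_identical(dbs[delays > t_star], rep(0, sum(delays > t_star)))

  # a trajectory that never reaches the threshold is flagged
  expect_error(delta_b(p_def, tt, rep(gstar * 2, length(tt)), 150,
                       glu_star = gstar), "no bifurcation crossing")
})
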