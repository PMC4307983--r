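p_def <- default_params("repressor")

test_that("algebraic reduction matches limits and a mass-action oracle", {
  st <- species_state(400, 120, 60, 50)

  # no galactose: no activated transducer
  expect_equal(reduced_inputs(st, p_def, 100, 0)$g1_star, 0)

  # vanishing binding affinity: everything stays free
  p_free <- validate_params(within(unclass(p_def),
                                   { K_seq80 <- 1e12; K_seq4 <- 1e12 }))
  red <- reduced_inputs(st, p_free, 100, 150)
  expect_equal(red$g80_free, 120, tolerance = 1e-6)
  expect_equal(red$g4_free, 60, tolerance = 1e-6)

  # generic state: compare with the long-time limit of explicit mass-action
  # binding kinetics (complexes C80 = G1*.G80, C4 = G4.G80)
  red <- reduced_inputs(st, p_def, 100, 150)
  g1s_tot <- st[["g1_total"]] * 150^p_def$m / (p_def$K_gal^p_def$m + 150^p_def$m)
  kon <- 50
  bind_rhs <- function(t, y, parms) {
    g80f <- 120 - y[1] - y[2]
    g1sf <- g1s_tot - y[1]
    g4f <- 60 - y[2]
    list(c(kon * g1sf * g80f - kon * p_def$K_seq80 * y[1],
           kon * g4f * g80f - kon * p_def$K_seq4 * y[2]))
  }
  sol <- deSolve::ode(c(0, 0), c(0, 2000), bind_rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  g80f_oracle <- unname(120 - sum(sol[nrow(sol), 2:3]))
  g4f_oracle <- unname(60 - sol[nrow(sol), 3])
  expect_equal(red$g80_free, g80f_oracle, tolerance = 1e-6)
  expect_equal(red$g4_free, g4f_oracle, tolerance = 1e-6)

  expect_error(reduced_inputs(st, p_def, -1, 0))
})

test_that("rhs reduces to pure decay without production and is zero at roots", {
  p0 <- validate_params(within(unclass(p_def),
                               { alpha1 <- 1e-12; alpha80 <- 1e-12
                                 alpha4 <- 1e-12; b1 <- 0; b80 <- 0; b4 <- 0 }))
  st <- species_state(40, 30, 20, 0)
  dv <- gal_rhs(st, p0, 0, 0)
  expect_equal(unname(dv[1:3]), unname(-p0$d * unclass(st)[1:3]),
               tolerance = 1e-9)
  expect_equal(unname(dv[4]), 0)   # glu = 0, r = 0: repressor inert

  for (eq in find_equilibria(p_def, 150, 150)) {
    expect_lt(max(abs(gal_rhs(species_state(eq$state[1], eq$state[2],
                                            eq$state[3], eq$state[4]),
                              p_def, 150, 150))), 1e-8)
    expect_lt(eq$residual_norm, 1e-8)
  }
})

test_that("R and compiled right-hand sides integrate to the same endpoint", {
  for (v in c("repressor", "dilution", "gal80_open_loop")) {
    p <- default_params(v)
    y0 <- c(g1_total = 200, g80_total = 50, g4_total = 10, r_active = 20)
    if (v == "dilution") y0[4] <- 0
    glu <- 120; gal <- 150
    r_end <- simulate(p, const_schedule(glu, gal),
                      species_state(y0[1], y0[2], y0[3], y0[4]),
                      c(0, 5))[2, 2:5]
    c_end <- deSolve::ode(y = unname(y0), times = c(0, 5),
                          func = "gal_derivs",
                          parms = galswitch:::.pack_parms(p, glu, gal),
                          dllname = "galswitch", initfunc = "gal_initmod",
                          rtol = 1e-10, atol = 1e-12)[2, 2:5]
    expect_equal(unlist(r_end), unname(c_end), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("trajectories stay on equilibria and follow the decay closed form", {
  eqs <- find_equilibria(p_def, 150, 150)
  on <- eqs[[length(eqs)]]$state
  tr <- simulate(p_def, const_schedule(150, 150),
                 species_state(on[1], on[2], on[3], on[4]), seq(0, 100, 10))
  expect_lt(max(abs(tr$g1_total - on[["g1_total"]])), 1e-4)
  expect_true(all(tr[, 2:5] > -1e-9))

  p0 <- validate_params(within(unclass(p_def),
                               { alpha1 <- 1e-12; alpha80 <- 1e-12
                                 alpha4 <- 1e-12; b1 <- 0; b80 <- 0; b4 <- 0 }))
  x0 <- c(80, 40, 20)
  tr0 <- simulate(p0, const_schedule(0, 0), species_state(80, 40, 20, 0),
                  seq(0, 10, 1))
  for (i in 1:3)
    expect_equal(tr0[[i + 1]], x0[i] * exp(-p0$d * tr0$time),
                 tolerance = 1e-6)
})

test_that("mono-ON conditions assimilate arbitrary initial states", {
  # glu below the bistable band at gal = 150 nM: single ON attractor
  eqs <- find_equilibria(p_def, 30, 150)
  expect_length(eqs, 1)
  on <- eqs[[1]]$state
  set.seed(11)
  for (k in 1:3) {
    x0 <- runif(4) * c(1000, 200, 100, 200)
    tr <- simulate(p_def, const_schedule(30, 150),
                   species_state(x0[1], x0[2], x0[3], x0[4]), c(0, 400))
    expect_equal(unlist(tr[2, 2:5]), unclass(on), tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("equilibrium search agrees with the dense-grid oracle", {
  cases <- rbind(c(150, 150), c(120, 150), c(30, 150), c(500, 150),
                 c(100, 75), c(200, 300), c(100, 0), c(0, 0))
  for (i in seq_len(nrow(cases))) {
    glu <- cases[i, 1]; gal <- cases[i, 2]
    eqs <- find_equilibria(p_def, glu, gal)
    orc <- oracle_equilibria(p_def, glu, gal)
    expect_equal(length(eqs), nrow(orc),
                 label = sprintf("count at glu=%g gal=%g", glu, gal))
    expect_equal(vapply(eqs, function(e) e$state[["g1_total"]], 0),
                 sort(orc$g1_total), tolerance = 1e-4,
                 label = sprintf("locations at glu=%g gal=%g", glu, gal))
  }
  # inside the band: exactly 2 stable + 1 unstable
  eqs <- find_equilibria(p_def, 150, 150)
  expect_identical(vapply(eqs, function(e) e$stable, NA), c(TRUE, FALSE, TRUE))
  # no galactose: single stable low-G1 state
  eqs0 <- find_equilibria(p_def, 100, 0)
  expect_length(eqs0, 1)
  expect_true(eqs0[[1]]$stable)
  expect_lt(eqs0[[1]]$state[["g1_total"]], 10)
})

test_that("stable equilibria attract a 1% perturbation; unstable ones repel", {
  eqs <- find_equilibria(p_def, 150, 150)
  for (eq in eqs) {
    x0 <- eq$state * 1.01
    tr <- simulate(p_def, const_schedule(150, 150),
                   species_state(x0[1], x0[2], x0[3], x0[4]), c(0, 300))
    dev <- abs(tr$g1_total[2] - eq$state[["g1_total"]]) /
      (1 + eq$state[["g1_total"]])
    if (eq$stable) expect_lt(dev, 1e-4) else expect_gt(dev, 0.05)
  }
})

test_that("dominant eigenvalue equals d for a pure-decay system and the FD
           Jacobian is exact on a linear map", {
  p0 <- validate_params(within(unclass(p_def),
                               { alpha1 <- 1e-12; alpha80 <- 1e-12
                                 alpha4 <- 1e-12
                                 b1 <- 100; b80 <- 5; b4 <- 2 }))
  # single equilibrium at b/d; Jacobian is -d I on the protein block
  ev <- dominant_eigenvalue(p0, 0, 0, g1_threshold = 0)
  expect_equal(ev, p0$d, tolerance = 1e-6)

  A <- matrix(c(-2, 1, 0.5, -3), 2, 2)
  J <- galswitch:::.jacobian_fd(function(x) as.numeric(A %*% x), c(1, 2))
  expect_equal(J, A, tolerance = 1e-6)
})

test_that("basin fractions are trivial at monostable points and reproducible", {
  expect_identical(as.numeric(basin_fraction_on(p_def, 30, 150,
                                                n_samples = 10, seed = 1)), 1)
  expect_identical(as.numeric(basin_fraction_on(p_def, 600, 150,
                                                n_samples = 10, seed = 1)), 0)
  b1 <- basin_fraction_on(p_def, 150, 150, n_samples = 150, seed = 42)
  b2 <- basin_fraction_on(p_def, 150, 150, n_samples = 150, seed = 42)
  expect_identical(b1, b2)
  expect_gte(as.numeric(b1), 0)
  expect_lte(as.numeric(b1), 1)
})
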