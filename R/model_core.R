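#' Construct a species state for the GAL model
#'
#' @param g1_total,g80_total,g4_total,r_active concentrations (nM), all
#'   finite and non-negative.  `r_active` is the active repressor R*;
#'   the inactive pool is `R_total - r_active`.
#' @return named numeric vector of class `gal_state`.
#' @export
species_state <- function(g1_total, g80_total, g4_total, r_active = 0) {
  x <- c(g1_total = unname(g1_total), g80_total = unname(g80_total),
         g4_total = unname(g4_total), r_active = unname(r_active))
  if (any(!is.finite(x)) || any(x < 0))
    stop("state components must be finite and >= 0")
  structure(x, class = "gal_state")
}

# indices of dynamic coordinates: the dilution variant has no repressor state
.active_idx <- function(params) if (params$variant == "dilution") 1:3 else 1:4

# free G80 from the monotone conservation relation; plain bisection mirrors
# the compiled solver in src/gal_model.c
.solve_g80_free <- function(g80_total, g1_star, g4_total, K80, K4) {
  if (g80_total <= 0) return(0)
  lo <- 0; hi <- g80_total
  for (i in 1:90) {
    mid <- 0.5 * (lo + hi)
    f <- mid + g1_star * mid / (K80 + mid) + g4_total * mid / (K4 + mid) -
      g80_total
    if (f > 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

#' Fast-equilibrium algebraic reductions
#'
#' Computes the activated transducer G1* and the free (unsequestered) G80
#' and G4 pools implied by a total-species state under the fast binding
#' equilibria G1*–G80 (dissociation constant `K_seq80`) and G4–G80
#' (`K_seq4`).  G1* is the galactose-activated fraction of the G1 pool,
#' `g1_total * gal^m / (K_gal^m + gal^m)`.
#'
#' @param state a [species_state()] (or named vector with its fields).
#' @param params a `gal_params` parameter set.
#' @param glu,gal constant sugar inputs (nM), `>= 0`.
#' @return list with `g1_star`, `g80_free`, `g4_free` (nM).
#' @export
reduced_inputs <- function(state, params, glu, gal) {
  if (glu < 0 || gal < 0) stop("sugar inputs must be >= 0")
  s <- unclass(state)
  g1s <- s[["g1_total"]] * hill_act(gal, params$K_gal, params$m)
  g80f <- .solve_g80_free(s[["g80_total"]], g1s, s[["g4_total"]],
                          params$K_seq80, params$K_seq4)
  g4f <- s[["g4_total"]] * params$K_seq4 / (params$K_seq4 + g80f)
  list(g1_star = unname(g1s), g80_free = g80f, g4_free = unname(g4f))
}

#' Right-hand side of the GAL network ODEs
#'
#' Time derivatives (nM/h) of the total-species state under constant sugar
#' inputs.  The repressor variant couples glucose through mass-action
#' activation of a repressor pool (`dR*/dt = k_R glu (R_total - R*) -
#' k_Rd R*`) whose active form represses the *G1* and *G4* promoters; the
#' open-loop variant replaces G80 production by the constant `g80_const`;
#' the dilution variant has no repressor and instead scales each species'
#' decay rate by `1 + s_i * hill_act(glu, K_g, n_g)`.
#'
#' @inheritParams reduced_inputs
#' @return named numeric derivative vector (same layout as the state).
#' @export
gal_rhs <- function(state, params, glu, gal) {
  s <- pmax(unclass(state), 0)
  if (any(is.na(s))) stop("state contains NA/NaN")
  red <- reduced_inputs(s, params, glu, gal)
  act <- hill_act(red$g4_free, params$K_A, params$n_A)
  y <- unclass(state)
  if (params$variant == "dilution") {
    hg <- hill_act(glu, params$K_g, params$n_g)
    d1 <- params$d * (1 + params$s1 * hg)
    d80 <- params$d * (1 + params$s80 * hg)
    d4 <- params$d * (1 + params$s4 * hg)
    out <- c(params$b1 + params$alpha1 * act - d1 * y[["g1_total"]],
             params$b80 + params$alpha80 * act - d80 * y[["g80_total"]],
             params$b4 + params$alpha4 - d4 * y[["g4_total"]],
             0)
  } else {
    rep1 <- hill_rep(s[["r_active"]], params$K_R1, params$n_R)
    rep4 <- hill_rep(s[["r_active"]], params$K_R4, params$n_R)
    dg80 <- if (params$variant == "gal80_open_loop") params$g80_const
            else params$b80 + params$alpha80 * act
    out <- c(params$b1 + params$alpha1 * act * rep1 - params$d * y[["g1_total"]],
             dg80 - params$d * y[["g80_total"]],
             params$b4 + params$alpha4 * rep4 - params$d * y[["g4_total"]],
             params$k_R * glu * (params$R_total - y[["r_active"]]) -
               params$k_Rd * y[["r_active"]])
  }
  names(out) <- c("g1_total", "g80_total", "g4_total", "r_active")
  out
}

# central finite-difference Jacobian of the rhs over the active coordinates
# (relative step 1e-6); fn maps active-coordinate vector -> derivatives
.jacobian_fd <- function(fn, x, rel_step = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# rhs over active coordinates only (dilution variant drops the repressor row)
.rhs_active <- function(params, glu, gal) {
  idx <- .active_idx(params)
  full0 <- c(0, 0, 0, 0)
  function(x) {
    y <- full0
    y[idx] <- x
    names(y) <- c("g1_total", "g80_total", "g4_total", "r_active")
    unname(gal_rhs(y, params, glu, gal))[idx]
  }
}

#' Locate all equilibria of the GAL model at constant inputs
#'
#' Multistart damped Newton root search on the steady-state system, started
#' from Latin-hypercube samples of the state space (bounds
#' `[0, 2 (alpha_i + b_i) / d]` per protein, `[0, R_total]` for R*) plus
#' the deterministic basal and fully-induced corner states.  Converged
#' roots are deduplicated at a relative distance of `1e-4`, annotated with
#' Jacobian eigenvalues and stability, and sorted by increasing `g1_total`.
#'
#' @inheritParams reduced_inputs
#' @param n_starts number of Latin-hypercube starts.
#' @param seed integer seed for the start sample.
#' @param tol residual infinity-norm tolerance (nM/h) for convergence.
#' @return list of `gal_equilibrium` objects, each with fields `state`,
#'   `stable`, `eigenvalues`, `residual_norm`.
#' @export
find_equilibria <- function(params, glu, gal, n_starts = 32, seed = 101,
                            tol = 1e-10) {
  idx <- .active_idx(params)
  bounds <- .state_bounds(params)[, idx, drop = FALSE]
  fn <- .rhs_active(params, glu, gal)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(idx))
  starts <- sweep(u, 2, bounds["upper", ], `*`)
  # deterministic anchors: basal (OFF-like) and fully induced (ON-like)
  basal <- with(params, c(b1, b80, b4, 0) / d)
  full <- with(params, c(b1 + alpha1, b80 + alpha80, b4 + alpha4, 0) / d)
  if (params$variant != "dilution") {
    r_eq <- with(params, R_total * k_R * glu / (k_R * glu + k_Rd))
    basal[4] <- full[4] <- r_eq
  }
  starts <- rbind(starts, basal[idx], full[idx])

  newton <- function(x) {
    f <- fn(x)
    for (it in 1:60) {
      nf <- max(abs(f))
      if (!is.finite(nf)) return(NULL)
      if (nf < tol) return(x)
      J <- .jacobian_fd(fn, x)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        xn <- pmax(x + lambda * step, 0)
        fnew <- fn(xn)
        if (all(is.finite(fnew)) && max(abs(fnew)) < (1 - 1e-4 * lambda) * nf)
          break
        lambda <- lambda / 2
        if (lambda < 1e-7) return(NULL)
      }
      x <- pmax(x + lambda * step, 0)
      f <- fn(x)
    }
    NULL
  }

  dedupe <- function(roots) {
    uniq <- list()
    for (r in roots) {
      dup <- any(vapply(uniq, function(u2)
        max(abs(r - u2)) / (1 + max(abs(r), abs(u2))) < 1e-4, NA))
      if (!isTRUE(dup)) uniq[[length(uniq) + 1]] <- r
    }
    uniq
  }

  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- newton(starts[i, ])
    if (!is.null(x)) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots))
    stop("equilibrium search failed at glu = ", glu, ", gal = ", gal)
  uniq <- dedupe(roots)

  # saddles between attractors have thin Newton basins and are easily missed
  # by space-filling starts: polish from interpolants between each distinct
  # pair of roots until the root set stops growing
  repeat {
    n_before <- length(uniq)
    if (n_before >= 2) {
      for (a in seq_len(n_before - 1)) for (b in (a + 1):n_before) {
        for (w in c(0.25, 0.5, 0.75)) {
          x <- newton(w * uniq[[a]] + (1 - w) * uniq[[b]])
          if (!is.null(x)) uniq <- dedupe(c(uniq, list(x)))
        }
      }
    }
    if (length(uniq) == n_before) break
  }

  # between each pair of adjacent attractors there is a saddle whose stable
  # manifold forms the basin boundary: bisect along the connecting segment
  # by forward-flow classification, then start Newton from a short
  # integration of the boundary point (which flows toward the saddle)
  stab <- vapply(uniq, function(x) {
    ev <- eigen(.jacobian_fd(fn, x), only.values = TRUE)$values
    all(Re(ev) < 0)
  }, NA)
  stable_roots <- uniq[stab]
  if (length(stable_roots) >= 2 && sum(!stab) < length(stable_roots) - 1) {
    ord <- order(vapply(stable_roots, `[`, 0, 1))
    stable_roots <- stable_roots[ord]
    parms <- .pack_parms(params, glu, gal)
    flow <- function(x, t_end) {
      y <- c(0, 0, 0, 0); y[idx] <- x
      sol <- deSolve::ode(y = y, times = c(0, t_end), func = "gal_derivs",
                          parms = parms, dllname = "galswitch",
                          initfunc = "gal_initmod", method = "lsoda",
                          rtol = 1e-8, atol = 1e-10)
      sol[nrow(sol), 1 + idx]
    }
    for (a in seq_len(length(stable_roots) - 1)) {
      xa <- stable_roots[[a]]; xb <- stable_roots[[a + 1]]
      goes_to_b <- function(w) {
        yT <- flow((1 - w) * xa + w * xb, 150)
        sum((log1p(pmax(yT, 0)) - log1p(xb))^2) <
          sum((log1p(pmax(yT, 0)) - log1p(xa))^2)
      }
      lo <- 0; hi <- 1
      if (!goes_to_b(1) || goes_to_b(0)) next
      for (it in 1:45) {
        mid <- 0.5 * (lo + hi)
        if (goes_to_b(mid)) hi <- mid else lo <- mid
      }
      for (t_end in c(5, 15, 40)) {
        x <- newton(flow((1 - 0.5 * (lo + hi)) * xa + 0.5 * (lo + hi) * xb,
                         t_end))
        if (!is.null(x)) {
          n_before <- length(uniq)
          uniq <- dedupe(c(uniq, list(x)))
          if (length(uniq) > n_before) break
        }
      }
    }
  }

  eqs <- lapply(uniq, function(x) {
    J <- .jacobian_fd(fn, x)
    ev <- eigen(J, only.values = TRUE)$values
    full_state <- c(0, 0, 0, 0)
    full_state[idx] <- x
    names(full_state) <- c("g1_total", "g80_total", "g4_total", "r_active")
    structure(list(state = full_state,
                   stable = all(Re(ev) < 0),
                   eigenvalues = ev,
                   residual_norm = max(abs(fn(x)))),
              class = "gal_equilibrium")
  })
  eqs[order(vapply(eqs, function(e) e$state[["g1_total"]], 0))]
}

#' @export
print.gal_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium (%s): g1_total = %.3f nM, |rhs| = %.2g\n",
              if (x$stable) "stable" else "unstable",
              x$state[["g1_total"]], x$residual_norm))
  invisible(x)
}

# ON/OFF call for a single equilibrium's g1_total level.  Default threshold
# is the geometric mean of the basal and fully-induced G1 levels; scans
# override it with the geometric mean of the local ON/OFF branches.
.g1_threshold_default <- function(params) {
  with(params, sqrt((b1 / d) * ((b1 + alpha1) / d)))
}

#' Magnitude of the dominant (slowest) eigenvalue at the ON equilibrium
#'
#' The smallest-magnitude eigenvalue of the Jacobian linearization at the
#' ON equilibrium (the highest-`g1_total` stable state) sets the slowest
#' relaxation rate toward it; its magnitude shrinks toward zero as a
#' saddle-node bifurcation is approached.
#'
#' @inheritParams find_equilibria
#' @param g1_threshold ON/OFF call threshold on `g1_total` (nM) used when
#'   only one stable state exists; defaults to the geometric mean of the
#'   basal and fully induced G1 levels.
#' @return `|lambda|` (1/h) of the smallest-magnitude eigenvalue.
#' @export
dominant_eigenvalue <- function(params, glu, gal,
                                g1_threshold = .g1_threshold_default(params),
                                ...) {
  eqs <- find_equilibria(params, glu, gal, ...)
  stable <- Filter(function(e) e$stable, eqs)
  if (!length(stable)) stop("no stable equilibrium at (", glu, ", ", gal, ")")
  on <- stable[[length(stable)]]
  if (on$state[["g1_total"]] < g1_threshold)
    stop("no stable ON equilibrium at (", glu, ", ", gal, ")")
  min(abs(on$eigenvalues))
}

#' Fraction of initial conditions attracted to the ON equilibrium
#'
#' Latin-hypercube samples of the state space (same bounds as
#' [find_equilibria()]) are integrated forward with the compiled model
#' right-hand side; each endpoint is assigned to the nearest equilibrium in
#' log-scaled state space.  The returned value is the fraction assigned to
#' the ON (highest-`g1_total` stable) equilibrium.  When the point is
#' monostable every sample converges to the unique stable state and the
#' fraction is 1 or 0 by its ON/OFF call.
#'
#' @inheritParams dominant_eigenvalue
#' @param n_samples number of Latin-hypercube initial conditions.
#' @param seed integer seed; fixed seed gives bit-identical fractions.
#' @param t_max integration horizon (h) for basin classification.
#' @return fraction in `[0, 1]`, with attributes `n_unconverged` (samples
#'   whose endpoint residual still exceeded 1e-8 nM/h) and `n_samples`.
#' @export
basin_fraction_on <- function(params, glu, gal, n_samples = 5000, seed = 1,
                              t_max = 200,
                              g1_threshold = .g1_threshold_default(params)) {
  stopifnot(n_samples >= 1)
  eqs <- find_equilibria(params, glu, gal)
  stable <- Filter(function(e) e$stable, eqs)
  if (!length(stable)) stop("no stable equilibrium resolvable")
  if (length(stable) == 1) {
    on <- stable[[1]]$state[["g1_total"]] >= g1_threshold
    return(structure(as.numeric(on), n_unconverged = 0L,
                     n_samples = as.integer(n_samples)))
  }
  idx <- .active_idx(params)
  bounds <- .state_bounds(params)[, idx, drop = FALSE]
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, length(idx))
  ics <- sweep(u, 2, bounds["upper", ], `*`)

  targets <- t(vapply(stable, function(e) log1p(e$state[idx]), numeric(length(idx))))
  on_row <- which.max(vapply(stable, function(e) e$state[["g1_total"]], 0))
  parms <- .pack_parms(params, glu, gal)
  fn <- .rhs_active(params, glu, gal)

  n_on <- 0L; n_unconv <- 0L
  y0 <- c(0, 0, 0, 0)
  for (i in seq_len(n_samples)) {
    y0[idx] <- ics[i, ]
    sol <- deSolve::ode(y = y0, times = c(0, t_max), func = "gal_derivs",
                        parms = parms, dllname = "galswitch",
                        initfunc = "gal_initmod", method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    yT <- sol[nrow(sol), 1 + idx]
    if (max(abs(fn(pmax(yT, 0)))) >= 1e-8) {
      # passage near a saddle can outlast t_max; give stragglers more time
      sol <- deSolve::ode(y = c(0, 0, 0, 0)[seq_len(4)] + sol[nrow(sol), -1],
                          times = c(0, 4 * t_max), func = "gal_derivs",
                          parms = parms, dllname = "galswitch",
                          initfunc = "gal_initmod", method = "lsoda",
                          rtol = 1e-8, atol = 1e-10)
      yT <- sol[nrow(sol), 1 + idx]
      if (max(abs(fn(pmax(yT, 0)))) >= 1e-8) n_unconv <- n_unconv + 1L
    }
    dists <- rowSums((targets - matrix(log1p(pmax(yT, 0)), nrow(targets),
                                       length(idx), byrow = TRUE))^2)
    if (which.min(dists) == on_row) n_on <- n_on + 1L
  }
  if (n_unconv > 0.001 * n_samples)
    warning("more than 0.1% of basin samples did not converge (",
            n_unconv, "/", n_samples, ")")
  structure(n_on / n_samples, n_unconverged = n_unconv,
            n_samples = as.integer(n_samples))
}

# regime labels along a glucose grid at fixed galactose, plus per-point
# equilibria.  Mono points are called ON/OFF against the geometric mean of
# the ON/OFF branch values at the nearest bistable grid point (falling back
# to the basal/induced geometric mean when the scan has no bistable cell).
.scan_labels <- function(params, gal, glu_grid, ...) {
  eqs_per_point <- lapply(glu_grid, function(glu)
    find_equilibria(params, glu, gal, ...))
  n_stable <- vapply(eqs_per_point, function(eqs)
    sum(vapply(eqs, function(e) e$stable, NA)), 0L)
  bist <- which(n_stable >= 2)
  thr_at <- function(i) {
    if (!length(bist)) return(.g1_threshold_default(params))
    j <- bist[which.min(abs(bist - i))]
    g1 <- vapply(Filter(function(e) e$stable, eqs_per_point[[j]]),
                 function(e) e$state[["g1_total"]], 0)
    sqrt(min(g1) * max(g1))
  }
  regime <- vapply(seq_along(glu_grid), function(i) {
    if (n_stable[i] >= 2) return("bistable")
    g1 <- max(vapply(Filter(function(e) e$stable, eqs_per_point[[i]]),
                     function(e) e$state[["g1_total"]], 0))
    if (g1 >= thr_at(i)) "mono_ON" else "mono_OFF"
  }, "")
  list(equilibria = eqs_per_point, regime = regime)
}

#' Saddle-node bifurcation scan along glucose at fixed galactose
#'
#' Classifies each glucose grid point as `mono_ON`, `bistable` or
#' `mono_OFF` from the stable-equilibrium count, then locates the
#' saddle-node thresholds `glu_low_star` (mono_ON | bistable boundary) and
#' `glu_high_star` (bistable | mono_OFF boundary) by bisection between
#' neighbouring grid cells of different regime, to relative precision
#' `1e-3`.  Both thresholds are `NA` when the grid contains no bistable
#' cell.
#'
#' @inheritParams find_equilibria
#' @param gal_fixed galactose level (nM) held constant.
#' @param glu_grid ordered glucose grid (nM), at least 3 points.
#' @param ... passed on to [find_equilibria()].
#' @return object of class `gal_bifurcation` with fields `gal_fixed`,
#'   `glu_grid`, `equilibria` (list of equilibrium lists), `regime`
#'   (character vector), `glu_low_star`, `glu_high_star`.
#' @export
bifurcation_scan <- function(params, gal_fixed, glu_grid, ...) {
  stopifnot(length(glu_grid) >= 3, !is.unsorted(glu_grid))
  sc <- .scan_labels(params, gal_fixed, glu_grid, ...)
  regime <- sc$regime

  n_stable_at <- function(glu) {
    eqs <- find_equilibria(params, glu, gal_fixed, ...)
    sum(vapply(eqs, function(e) e$stable, NA))
  }
  bisect_edge <- function(lo, hi, lo_bistable) {
    # refine the glucose value where the stable count changes
    while ((hi - lo) / max(hi, 1e-12) > 1e-3) {
      mid <- sqrt(lo * hi)
      if (lo <= 0) mid <- 0.5 * (lo + hi)
      if ((n_stable_at(mid) >= 2) == lo_bistable) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }

  glu_low <- glu_high <- NA_real_
  bist <- which(regime == "bistable")
  if (length(bist)) {
    i0 <- min(bist); i1 <- max(bist)
    if (i0 > 1)
      glu_low <- bisect_edge(glu_grid[i0 - 1], glu_grid[i0], lo_bistable = FALSE)
    if (i1 < length(glu_grid))
      glu_high <- bisect_edge(glu_grid[i1], glu_grid[i1 + 1], lo_bistable = TRUE)
  }
  structure(list(gal_fixed = gal_fixed, glu_grid = glu_grid,
                 equilibria = sc$equilibria, regime = regime,
                 glu_low_star = glu_low, glu_high_star = glu_high),
            class = "gal_bifurcation")
}

#' @export
print.gal_bifurcation <- function(x, ...) {
  cat("bifurcation scan at gal =", x$gal_fixed, "nM\n")
  cat("  regimes:", paste(rle(x$regime)$values, collapse = " -> "), "\n")
  cat(sprintf("  glu_low_star = %.4g nM, glu_high_star = %.4g nM\n",
              x$glu_low_star, x$glu_high_star))
  invisible(x)
}

#' Regime map over a glucose x galactose grid
#'
#' @inheritParams find_equilibria
#' @param glu_grid,gal_grid ordered concentration grids (nM).
#' @param ... passed on to [find_equilibria()].
#' @return object of class `gal_regime_map`: list with `glu_grid`,
#'   `gal_grid`, `labels` (glu x gal character matrix) and
#'   `bistable_area` (count of bistable cells).
#' @export
regime_map <- function(params, glu_grid, gal_grid, ...) {
  stopifnot(!is.unsorted(glu_grid), !is.unsorted(gal_grid))
  labels <- matrix(NA_character_, length(glu_grid), length(gal_grid),
                   dimnames = list(NULL, NULL))
  for (j in seq_along(gal_grid)) {
    labels[, j] <- .scan_labels(params, gal_grid[j], glu_grid, ...)$regime
  }
  structure(list(glu_grid = glu_grid, gal_grid = gal_grid, labels = labels,
                 bistable_area = sum(labels == "bistable")),
            class = "gal_regime_map")
}

#' Quasi-steady-state regime classification along a sugar trajectory
#'
#' Labels each time point with the regime of the frozen-input system at
#' `(glu(t), gal(t))`.  The predicted coherent-activation time is the first
#' time the regime becomes `mono_ON` after having been `bistable` or
#' `mono_OFF`; the predicted duration of bimodality is that time minus the
#' first entry into the bistable regime.
#'
#' @inheritParams find_equilibria
#' @param t time grid (h) shared by both series.
#' @param glu_series,gal_series sugar concentrations (nM) at `t`.
#' @param ... passed on to [find_equilibria()].
#' @return list with `time`, `regime`, `t_activation` (NA if the system is
#'   never mono_ON after suppression), `t_bimodal_onset`, `pred_delta_g`.
#' @export
quasi_static_regimes <- function(params, t, glu_series, gal_series, ...) {
  stopifnot(length(t) == length(glu_series), length(t) == length(gal_series))
  sc_regime <- vapply(seq_along(t), function(i)
    .scan_labels(params, gal_series[i], glu_series[i], ...)$regime, "")
  suppressed <- cumsum(sc_regime %in% c("bistable", "mono_OFF")) > 0
  act_idx <- which(sc_regime == "mono_ON" & (suppressed | seq_along(t) == 1))
  t_act <- if (length(act_idx)) t[min(act_idx)] else NA_real_
  onset_idx <- which(sc_regime == "bistable")
  t_onset <- if (length(onset_idx)) t[min(onset_idx)] else NA_real_
  pred_dg <- if (!is.na(t_act) && !is.na(t_onset)) max(0, t_act - t_onset)
             else NA_real_
  list(time = t, regime = sc_regime, t_activation = t_act,
       t_bimodal_onset = t_onset, pred_delta_g = pred_dg)
}

#' Time for glucose to decay to the bifurcation threshold
#'
#' With `glu_star` the lower saddle-node threshold at the given galactose
#' level, the bistable window closes (and coherent activation of the
#' repressed cohort is predicted) when the glucose trajectory first crosses
#' `glu_star`.  For galactose added `gal_delay` hours after glucose, the
#' remaining window is `delta_b = max(0, t_star - gal_delay)`.
#'
#' @inheritParams find_equilibria
#' @param glu_t,glu_v glucose trajectory: times (h) and concentrations (nM).
#' @param gal_level galactose level (nM) defining the bifurcation diagram.
#' @param gal_delay galactose addition delay (h), `>= 0`.
#' @param glu_star optional precomputed threshold (nM); when `NULL` it is
#'   taken from a [bifurcation_scan()] over the trajectory's glucose range.
#' @param ... passed on to [bifurcation_scan()] / [find_equilibria()].
#' @return `delta_b` (h), with attribute `glu_star`.
#' @export
delta_b <- function(params, glu_t, glu_v, gal_level, gal_delay = 0,
                    glu_star = NULL, ...) {
  stopifnot(gal_delay >= 0, length(glu_t) == length(glu_v))
  if (is.null(glu_star)) {
    hi <- max(glu_v)
    grid <- exp(seq(log(max(min(glu_v[glu_v > 0], hi * 1e-4), 1e-3)),
                    log(hi), length.out = 25))
    bs <- bifurcation_scan(params, gal_level, grid, ...)
    glu_star <- bs$glu_low_star
    if (is.na(glu_star))
      stop("no saddle-node threshold found at gal = ", gal_level)
  }
  below <- which(glu_v <= glu_star)
  if (!length(below))
    stop("no bifurcation crossing: glucose trajectory never reaches glu_star")
  i <- min(below)
  t_star <- if (i == 1) glu_t[1] else {
    # linear interpolation between bracketing samples
    glu_t[i - 1] + (glu_v[i - 1] - glu_star) /
      (glu_v[i - 1] - glu_v[i]) * (glu_t[i] - glu_t[i - 1])
  }
  structure(max(0, t_star - gal_delay), glu_star = glu_star, t_star = t_star)
}
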