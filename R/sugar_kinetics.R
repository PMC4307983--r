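#' Fit a decreasing Hill function to a sugar-depletion curve
#'
#' Nonlinear least squares of
#' `s(t) = floor + (s0 - floor) * k_half^n / (k_half^n + t^n)`,
#' the decreasing Hill form whose value at `t = k_half` is exactly halfway
#' between `s0` and `floor`.  Fitting uses Levenberg–Marquardt
#' (`minpack.lm::nlsLM`) with the initialization: `s0` = maximum
#' concentration, `k_half` = time of the sample nearest `s0 / 2`,
#' `n_hill = 4`, `floor` = series minimum (fixed at 0 unless
#' `free_floor = TRUE`).
#'
#' @param t times (h, increasing).
#' @param conc concentrations (% w/v, finite, `>= 0`).
#' @param free_floor estimate a residual floor instead of fixing it at 0.
#' @param min_decline required fractional decline from the maximum; series
#'   declining less are rejected as non-decaying.
#' @return object of class `hill_fit`: list with `s0`, `k_half`, `n_hill`,
#'   `floor`, `rss`, `fitted`, and `predict(fit, t)` support.
#' @export
fit_hill_decay <- function(t, conc, free_floor = FALSE, min_decline = 0.2) {
  stopifnot(length(t) == length(conc), all(is.finite(t)), all(is.finite(conc)))
  if (length(t) < 5) stop("need >= 5 points")
  if (max(conc) <= 0 || (max(conc) - min(conc)) / max(conc) < min_decline)
    stop("non-decaying input: decline < ", min_decline * 100, "% of maximum")

  s0_init <- max(conc)
  floor_init <- if (free_floor) min(conc) else 0
  k_init <- t[which.min(abs(conc - (s0_init + floor_init) / 2))]
  k_init <- max(k_init, min(t[t > 0], na.rm = TRUE) / 2, 1e-3)

  df <- data.frame(t = t, conc = conc)
  fit1 <- function(k0, n0) {
    if (free_floor) {
      minpack.lm::nlsLM(
        conc ~ fl + (s0 - fl) * k^n / (k^n + t^n), data = df,
        start = list(s0 = s0_init, k = k0, n = n0, fl = floor_init),
        lower = c(0, 1e-6, 1e-6, 0),
        upper = c(Inf, Inf, Inf, min(conc)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        conc ~ s0 * k^n / (k^n + t^n), data = df,
        start = list(s0 = s0_init, k = k0, n = n0),
        lower = c(0, 1e-6, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  fit <- NULL
  for (init in list(c(k_init, 4), c(k_init * 2, 2), c(k_init / 2, 6),
                    c(max(t) / 2, 4))) {
    fit <- tryCatch(fit1(init[1], init[2]), error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Hill fit did not converge after restarts")
  cf <- coef(fit)
  structure(list(s0 = unname(cf["s0"]), k_half = unname(cf["k"]),
                 n_hill = unname(cf["n"]),
                 floor = if (free_floor) unname(cf["fl"]) else 0,
                 rss = sum(residuals(fit)^2),
                 fitted = fitted(fit), t = t),
            class = "hill_fit")
}

#' Evaluate a fitted Hill decay curve
#'
#' @param object a [fit_hill_decay()] result.
#' @param t times (h).
#' @param ... unused.
#' @return concentrations at `t`.
#' @export
predict.hill_fit <- function(object, t, ...) {
  kn <- object$k_half^object$n_hill
  object$floor + (object$s0 - object$floor) * kn / (kn + t^object$n_hill)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill decay fit: s0 = %.4g, k_half = %.4g h, n = %.3g, floor = %.4g, rss = %.3g\n",
              x$s0, x$k_half, x$n_hill, x$floor, x$rss))
  invisible(x)
}

#' Fractional change in depletion half-max relative to a reference
#'
#' `(k_half - k_half_ref) / k_half_ref`, the fractional shift of a sugar
#' decay curve's half-depletion time relative to a reference culture.
#'
#' @param fit,reference [fit_hill_decay()] results.
#' @return dimensionless fraction.
#' @export
halfmax_shift <- function(fit, reference) {
  if (reference$k_half == 0) stop("reference k_half is zero")
  (fit$k_half - reference$k_half) / reference$k_half
}

#' Metabolic delay between glucose and galactose depletion
#'
#' Difference of the half-depletion times, `k_half(galactose) -
#' k_half(glucose)` (h): the lag between exhausting the preferred and the
#' secondary sugar.
#'
#' @param glu_fit,gal_fit [fit_hill_decay()] results for the two sugars.
#' @return delay (h).
#' @export
metabolic_delay <- function(glu_fit, gal_fit) {
  gal_fit$k_half - glu_fit$k_half
}

#' Instantaneous growth rate from an OD600 series
#'
#' The finite difference of the natural logarithm of OD600 divided by the
#' time step, assigned to interval midpoints, optionally smoothed with a
#' centered moving average (width `smooth_window`, odd; edge values where
#' the window is incomplete are `NA` in the smoothed column).
#'
#' @param t times (h, strictly increasing).
#' @param od600 optical densities (`> 0`).
#' @param smooth_window odd moving-average width; 1 disables smoothing.
#' @return data.frame with `t` (midpoints), `rate` (1/h) and
#'   `rate_smooth`.
#' @export
od_growth_rate <- function(t, od600, smooth_window = 5) {
  stopifnot(all(diff(t) > 0), smooth_window %% 2 == 1)
  if (any(od600 <= 0)) stop("OD600 must be > 0")
  rate <- diff(log(od600)) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  sm <- if (smooth_window > 1)
    as.numeric(stats::filter(rate, rep(1 / smooth_window, smooth_window)))
  else rate
  data.frame(t = tm, rate = rate, rate_smooth = sm)
}

#' Expected galactose consumption from the ON fraction
#'
#' Scales a reference per-density consumption rate (from a galactose-only
#' culture) by the measured ON fraction and population density:
#' `expected_rate(t) = f_on(t) * ref_rate(t) * density(t)`.  Series on
#' different grids are linearly interpolated onto the `f_on` grid (flagged
#' via the `resampled` attribute).  The cumulative (trapezoid) integral is
#' returned alongside.
#'
#' @param t times (h) of the `f_on` series.
#' @param f_on ON fractions in `[0, 1]`.
#' @param ref_t,ref_rate reference per-density consumption rate series
#'   (`% w/v / (h * cells/ul)`).
#' @param dens_t,density population density series (cells/ul).
#' @return data.frame with `t`, `rate` (% w/v per h) and `cumulative`
#'   (% w/v consumed since `t[1]`).
#' @export
expected_consumption <- function(t, f_on, ref_t, ref_rate, dens_t, density) {
  stopifnot(length(t) == length(f_on))
  resampled <- !(identical(t, ref_t) && identical(t, dens_t))
  rr <- approxfun(ref_t, ref_rate, rule = 2)(t)
  dd <- approxfun(dens_t, density, rule = 2)(t)
  rate <- f_on * rr * dd
  cumulative <- c(0, cumsum(diff(t) * (rate[-1] + rate[-length(rate)]) / 2))
  structure(data.frame(t = t, rate = rate, cumulative = cumulative),
            resampled = resampled)
}
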