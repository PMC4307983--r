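#' Normalize flow-cytometry events to log10 fluorescence per cell
#'
#' Per-cell expression is quantified as the ratio of reporter fluorescence
#' to side scatter; the returned value is `log10(fluorescence /
#' side_scatter)`.  Events with non-positive side scatter are rejected;
#' events with fluorescence below `floor` are clipped to `floor` before the
#' log.  Both counts are reported as attributes.
#'
#' @param raw data.frame of events with numeric columns `fluorescence`
#'   (a.u., `>= 0`) and `side_scatter` (a.u., `> 0`); other columns
#'   (e.g. `time_h`, `condition`, `events_per_ul`) pass through.
#' @param floor clipping floor for non-positive fluorescence (a.u.).
#' @return `raw` minus rejected rows, with an added `norm_log10` column;
#'   attributes `n_rejected` (bad side scatter) and `n_clipped`.
#' @export
normalize_events <- function(raw, floor = 1e-3) {
  stopifnot(is.data.frame(raw),
            all(c("fluorescence", "side_scatter") %in% names(raw)))
  bad <- !is.finite(raw$side_scatter) | raw$side_scatter <= 0
  out <- raw[!bad, , drop = FALSE]
  clip <- !is.finite(out$fluorescence) | out$fluorescence < floor
  fl <- out$fluorescence
  fl[clip] <- floor
  out$norm_log10 <- log10(fl / out$side_scatter)
  structure(out, n_rejected = sum(bad), n_clipped = sum(clip))
}

# log-likelihood of a 1- or 2-component normal mixture
.mix_loglik <- function(x, w, mu, sigma) {
  dens <- rep(0, length(x))
  for (k in seq_along(w)) dens <- dens + w[k] * dnorm(x, mu[k], sigma[k])
  sum(log(pmax(dens, 1e-300)))
}

# one EM run for a 2-component normal mixture from given initial means
.em_2comp <- function(x, mu0, max_iter = 120, tol = 1e-7, sd_floor = 1e-4) {
  n <- length(x)
  w <- c(0.5, 0.5)
  mu <- mu0
  sigma <- rep(max(sd(x) / 2, sd_floor), 2)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- pmax(d1 + d2, 1e-300)
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- pmax(c(sqrt(sum(g * (x - mu[1])^2) / n1),
                    sqrt(sum((1 - g) * (x - mu[2])^2) / n2)), sd_floor)
    ll <- .mix_loglik(x, w, mu, sigma)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(w = w[ord], mu = mu[ord], sigma = sigma[ord],
       loglik = .mix_loglik(x, w, mu, sigma))
}

#' Gaussian-mixture modality classification of a fluorescence distribution
#'
#' Fits 1- and 2-component normal mixtures to log10-normalized values by
#' expectation-maximization with seeded restarts and classifies the
#' distribution as unimodal or bimodal.  The distribution is called
#' bimodal only if the 2-component fit wins by BIC *and* the minor
#' component weight is at least `w_min` *and* the component means are
#' separated by at least `sep_factor * sqrt((s1^2 + s2^2) / 2)`.
#' Deterministic for a fixed seed.
#'
#' @param values numeric vector of log10-normalized fluorescence.
#' @param seed integer seed for the EM restarts.
#' @param min_events minimum number of values required.
#' @param w_min minimum component weight for a bimodal call.
#' @param sep_factor required mean separation in pooled-sd units.
#' @param restarts number of seeded EM restarts for the 2-component fit.
#' @return object of class `mixture_fit`: list with `n_components`,
#'   `weights`, `means`, `sds`, `loglik` (per candidate count), `bic`,
#'   `modality`.
#' @export
fit_mixture <- function(values, seed = 1, min_events = 200, w_min = 0.05,
                        sep_factor = 2, restarts = 5) {
  if (length(values) < min_events)
    stop("too few events: ", length(values), " < ", min_events)
  if (any(!is.finite(values))) stop("non-finite values")
  x <- as.numeric(values)
  n <- length(x)

  mu1 <- mean(x); s1 <- max(sd(x) * sqrt((n - 1) / n), 1e-4)
  ll1 <- sum(dnorm(x, mu1, s1, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)

  set.seed(seed)
  qs <- quantile(x, c(0.15, 0.85))
  best <- .em_2comp(x, as.numeric(qs))
  for (r in seq_len(max(restarts - 1, 0))) {
    mu0 <- sort(sample(x, 2))
    if (diff(mu0) < 1e-12) mu0 <- mu0 + c(-1e-3, 1e-3)
    cand <- .em_2comp(x, mu0)
    if (cand$loglik > best$loglik) best <- cand
  }
  bic2 <- -2 * best$loglik + 5 * log(n)

  sep <- abs(diff(best$mu)) /
    sqrt((best$sigma[1]^2 + best$sigma[2]^2) / 2)
  bimodal <- (bic2 < bic1) && min(best$w) >= w_min && sep >= sep_factor

  if (bimodal) {
    structure(list(n_components = 2L, weights = best$w, means = best$mu,
                   sds = best$sigma,
                   loglik = c(`1` = ll1, `2` = best$loglik),
                   bic = c(`1` = bic1, `2` = bic2),
                   modality = "bimodal"),
              class = "mixture_fit")
  } else {
    structure(list(n_components = 1L, weights = 1, means = mu1, sds = s1,
                   loglik = c(`1` = ll1, `2` = best$loglik),
                   bic = c(`1` = bic1, `2` = bic2),
                   modality = "unimodal"),
              class = "mixture_fit")
  }
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture fit:", x$modality, "\n")
  cat("  means:", round(x$means, 4), " sds:", round(x$sds, 4),
      " weights:", round(x$weights, 4), "\n")
  invisible(x)
}

#' Track ON/OFF subpopulations through a time series of event tables
#'
#' For each time point: the fraction of ON cells `f_on` is the fraction of
#' events above `threshold`; subpopulation means are the mixture-component
#' means when the distribution is bimodal, and otherwise the single mean is
#' assigned wholly to ON or OFF by threshold comparison (so the repressed
#' cohort's trajectory is defined before its activation).  Counts are
#' scaled to culture density when an `events_per_ul` column is present.
#'
#' @param events normalized event table ([normalize_events()]) with columns
#'   `time_h`, `norm_log10` and optionally `events_per_ul`.
#' @param threshold ON/OFF threshold in log10 units.  The default `-0.2`
#'   corresponds to a fluorescence ratio of `10^-0.2` a.u.
#' @param seed seed passed to [fit_mixture()].
#' @param ... further arguments to [fit_mixture()].
#' @return object of class `subpop_series`: data.frame with `t`, `f_on`,
#'   `modality`, `mean_on`, `mean_off`, `n_on`, `n_off` and attribute
#'   `scaled` (FALSE when raw event counts were used).
#' @export
track_subpopulations <- function(events, threshold = -0.2, seed = 1, ...) {
  stopifnot(is.data.frame(events), "norm_log10" %in% names(events),
            "time_h" %in% names(events))
  times <- sort(unique(events$time_h))
  if (length(times) < 2) stop("need >= 2 time points")
  scaled <- "events_per_ul" %in% names(events) &&
    all(is.finite(events$events_per_ul))
  seen_bimodal <- FALSE
  rows <- lapply(times, function(tt) {
    x <- events$norm_log10[events$time_h == tt]
    f_on <- mean(x > threshold)
    fit <- fit_mixture(x, seed = seed, ...)
    if (fit$modality == "bimodal") {
      seen_bimodal <<- TRUE
      mean_on <- fit$means[2]; mean_off <- fit$means[1]
    } else if (fit$means[1] > threshold) {
      # unimodal-high after a bimodal epoch means the repressed cohort has
      # activated and merged: the single mean is then both branches' mean
      mean_on <- fit$means[1]
      mean_off <- if (seen_bimodal) fit$means[1] else NA_real_
    } else {
      mean_on <- NA_real_; mean_off <- fit$means[1]
    }
    dens <- if (scaled)
      events$events_per_ul[events$time_h == tt][1] else sum(events$time_h == tt)
    data.frame(t = tt, f_on = f_on, modality = fit$modality,
               mean_on = mean_on, mean_off = mean_off,
               n_on = f_on * dens, n_off = (1 - f_on) * dens)
  })
  out <- do.call(rbind, rows)
  # before the mixture first resolves, the two cohorts are coincident: the
  # single unimodal-low mean is also the best estimate of the activated
  # cohort's mean, so fill it backward from the first bimodal time point
  first_bi <- which(out$modality == "bimodal")[1]
  if (!is.na(first_bi) && first_bi > 1) {
    pre <- seq_len(first_bi - 1)
    fill <- pre[is.na(out$mean_on[pre]) & is.finite(out$mean_off[pre])]
    out$mean_on[fill] <- out$mean_off[fill]
  }
  structure(out, scaled = scaled, threshold = threshold,
            class = c("subpop_series", "data.frame"))
}

#' First time a series reaches half of its observed range
#'
#' The half-max level is `(min + max) / 2` over the observed window; the
#' returned time is the first upward crossing, linearly interpolated
#' between samples.  `NA` values are dropped.  A series that never crosses
#' upward returns `NA` with a `reason` attribute.
#'
#' @param t times (h).
#' @param value series values.
#' @return crossing time (h), or `NA` with attribute `reason`.
#' @export
half_max_time <- function(t, value) {
  keep <- is.finite(value) & is.finite(t)
  t <- t[keep]; value <- value[keep]
  if (length(t) < 3)
    return(structure(NA_real_, reason = "fewer than 3 finite points"))
  half <- (min(value) + max(value)) / 2
  if (max(value) - min(value) <= 0)
    return(structure(NA_real_, reason = "constant series"))
  up <- which(value[-1] >= half & value[-length(value)] < half)
  if (value[1] >= half) return(t[1])
  if (!length(up))
    return(structure(NA_real_, reason = "no upward half-max crossing"))
  i <- up[1]
  t[i] + (half - value[i]) / (value[i + 1] - value[i]) * (t[i + 1] - t[i])
}

#' Bimodality metrics of a tracked subpopulation series
#'
#' * `delta_a` — response time of the early activated subpopulation: time
#'   for `mean_on` to reach its half-max.
#' * `delta_g` — duration of bimodality: difference between the half-max
#'   times of the repressed (`mean_off`) and activated (`mean_on`)
#'   subpopulation means.
#' * `f_on_mid` — `f_on` interpolated at the midpoint between the two
#'   half-max times.
#' * `response_time` — first time `f_on` crosses 0.5 (interpolated).
#'
#' Metrics whose ingredients are undefined are returned as `NA` with a
#' reason recorded in the `reasons` field, never silently defaulted.
#'
#' @param series a [track_subpopulations()] result.
#' @return object of class `bimodal_metrics`: list with `delta_a`,
#'   `delta_g`, `f_on_mid`, `response_time`, `t_half_on`, `t_half_off`,
#'   `reasons`.
#' @export
bimodal_metrics <- function(series) {
  stopifnot(inherits(series, "subpop_series") || is.data.frame(series))
  reasons <- character()
  t_on <- half_max_time(series$t, series$mean_on)
  t_off <- half_max_time(series$t, series$mean_off)
  if (is.na(t_on))
    reasons["delta_a"] <- paste("activated branch:", attr(t_on, "reason"))
  if (is.na(t_off))
    reasons["delta_g"] <- paste("repressed branch:", attr(t_off, "reason"))
  delta_a <- as.numeric(t_on)
  delta_g <- if (is.na(t_on) || is.na(t_off)) NA_real_
             else as.numeric(t_off - t_on)

  f_on_mid <- NA_real_
  if (!is.na(t_on) && !is.na(t_off)) {
    if (!any(series$modality == "bimodal")) {
      reasons["f_on_mid"] <- "no bimodal time point"
    } else {
      f_on_mid <- approxfun(series$t, series$f_on)((t_on + t_off) / 2)
    }
  } else reasons["f_on_mid"] <- "half-max time undefined"

  rt <- NA_real_
  fo <- series$f_on
  cross <- which(fo[-1] >= 0.5 & fo[-length(fo)] < 0.5)
  if (fo[1] >= 0.5) rt <- series$t[1]
  else if (length(cross)) {
    i <- cross[1]
    rt <- series$t[i] + (0.5 - fo[i]) / (fo[i + 1] - fo[i]) *
      (series$t[i + 1] - series$t[i])
  } else reasons["response_time"] <- "f_on never crosses 0.5"

  structure(list(delta_a = delta_a, delta_g = delta_g, f_on_mid = f_on_mid,
                 response_time = rt, t_half_on = as.numeric(t_on),
                 t_half_off = as.numeric(t_off), reasons = reasons),
            class = "bimodal_metrics")
}

#' @export
print.bimodal_metrics <- function(x, ...) {
  cat(sprintf("delta_a = %.3f h, delta_g = %.3f h, f_on_mid = %.3f, response_time = %.3f h\n",
              x$delta_a, x$delta_g, x$f_on_mid, x$response_time))
  if (length(x$reasons))
    cat("  undefined:", paste(names(x$reasons), collapse = ", "), "\n")
  invisible(x)
}

# stable bimodal plateau: bimodal time points where the activated branch
# has completed its rise and the repressed cohort is still clearly below
# threshold, so threshold counts track cohort sizes rather than the rise
# edges.  Returns NULL when fewer than 3 such points exist.
.stable_bimodal_window <- function(series, threshold = attr(series, "threshold")) {
  if (is.null(threshold)) threshold <- -0.2
  on_hi <- max(series$mean_on, na.rm = TRUE) - 0.1
  sel <- series$modality == "bimodal" &
    is.finite(series$mean_on) & series$mean_on >= on_hi &
    is.finite(series$mean_off) & series$mean_off <= threshold - 0.3
  if (sum(sel) < 3) return(NULL)
  range(series$t[sel])
}

#' Subpopulation growth rates from accumulated ON/OFF counts
#'
#' Ordinary least-squares slope of `log2(count)` against time for the ON
#' and OFF subpopulations over a window, the standard exponential-growth
#' estimate on density-scaled cell counts.  Zero or negative counts are
#' excluded (reported in the result).
#'
#' @param series a [track_subpopulations()] result.
#' @param window `c(t_start, t_end)` in hours.
#' @return list with `rate_on`, `rate_off` (log2 cells/h), `n_on_used`,
#'   `n_off_used`, `n_excluded`.
#' @export
subpop_growth_rates <- function(series, window = range(series$t)) {
  sel <- series$t >= window[1] & series$t <= window[2]
  slope <- function(t, n) {
    use <- sel & is.finite(n) & n > 0
    if (sum(use) < 3) stop("fewer than 3 usable points in window")
    unname(coef(lm(log2(n[use]) ~ t[use]))[2])
  }
  n_excl <- sum(sel & !(is.finite(series$n_on) & series$n_on > 0)) +
    sum(sel & !(is.finite(series$n_off) & series$n_off > 0))
  list(rate_on = slope(series$t, series$n_on),
       rate_off = slope(series$t, series$n_off),
       n_on_used = sum(sel & series$n_on > 0),
       n_off_used = sum(sel & series$n_off > 0),
       n_excluded = n_excl)
}
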