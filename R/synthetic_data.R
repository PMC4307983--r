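#' Configuration for a synthetic diauxic-shift experiment
#'
#' Defines the ground truth of a simulated mixed-sugar induction
#' experiment with robot-style sampling: an early activated (ON) cohort
#' and a repressed (OFF) cohort with distinct growth rates, glucose
#' consumed before galactose, an abrupt coherent activation of the OFF
#' cohort at glucose depletion, and transiently bimodal log-fluorescence
#' distributions.  Defaults emulate a 0.1% glucose + 0.1% galactose
#' culture sampled every 20 min for 14 h.
#'
#' @param glu0,gal0 initial sugars (% w/v).
#' @param n0 initial density (cells/ul).
#' @param mu_glu,mu_gal growth rates on glucose and galactose (1/h).
#'   During the glucose phase the OFF cohort grows at `mu_glu` and the ON
#'   cohort at `mu_glu / rate_ratio_off_on` (GAL expression carries a
#'   growth cost).
#' @param rate_ratio_off_on OFF:ON growth-rate ratio in the bimodal epoch.
#' @param c_glu,c_gal per-density consumption rates (% w/v per h per
#'   cells/ul).
#' @param p_on ON-cohort fraction at the midpoint of the bimodal epoch.
#' @param lag diauxic lag of the OFF cohort after glucose depletion (h).
#' @param rise_half_on half-rise time of the ON-cohort mean after the
#'   stimulus (h); `rise_half_off` is the OFF cohort's half-rise measured
#'   from glucose depletion.
#' @param rise_scale logistic time scale of both rises (h).
#' @param mean_off_log,mean_on_log asymptotic log10 expression levels.
#' @param sd_log event-level log10 noise sd.
#' @param gal_leak pre-depletion galactose consumption multiplier in
#'   `[0, 1]` (1 = ON cells consume at the full per-density rate).
#' @param sample_interval,horizon sampling cadence and duration (h).
#' @param events_per_sample events collected per time point.
#' @param ss_meanlog,ss_sdlog side-scatter lognormal parameters.
#' @param od_per_cell OD600 per cells/ul.
#' @param seed integer seed; the generated experiment is a deterministic
#'   function of the full configuration.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(glu0 = 0.1, gal0 = 0.1, n0 = 200,
                             mu_glu = 0.45, mu_gal = 0.35,
                             rate_ratio_off_on = 1.15,
                             c_glu = 1.27e-5, c_gal = 8e-6,
                             p_on = 0.45, lag = 0.6,
                             rise_half_on = 1.2, rise_half_off = 1.0,
                             rise_scale = 0.35,
                             mean_off_log = -0.8, mean_on_log = 0.7,
                             sd_log = 0.15, gal_leak = 0.05,
                             sample_interval = 1 / 3, horizon = 14,
                             events_per_sample = 2000,
                             ss_meanlog = log(100), ss_sdlog = 0.25,
                             od_per_cell = 5e-5, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$p_on >= 0, cfg$p_on <= 1, cfg$sample_interval > 0,
            cfg$gal_leak >= 0, cfg$gal_leak <= 1, cfg$horizon > 0)
  for (f in c("glu0", "gal0", "n0", "mu_glu", "mu_gal", "c_glu", "c_gal",
              "lag", "rise_half_on", "rise_half_off", "sd_log"))
    if (cfg[[f]] < 0) stop("negative configuration field: ", f)
  structure(cfg, class = "synthetic_config")
}

# cohort and sugar trajectories implied by a config; shares are anchored so
# that the ON share equals p_on exactly at the bimodal midpoint
.synth_model <- function(cfg) {
  mu_off <- cfg$mu_glu
  mu_on <- cfg$mu_glu / cfg$rate_ratio_off_on
  threshold <- -0.2

  a <- cfg$p_on  # ON-cohort weight at t = 0; refined below
  t_dep <- NA
  for (iter in 1:6) {
    cum_n <- function(tt)
      cfg$n0 * (a * (exp(mu_on * tt) - 1) / mu_on +
                (1 - a) * (exp(mu_off * tt) - 1) / mu_off)
    gfun <- function(tt) cfg$glu0 - cfg$c_glu * cum_n(tt)
    if (gfun(cfg$horizon) > 0)
      stop("infeasible config: glucose never depletes within the horizon")
    t_dep <- uniroot(gfun, c(0, cfg$horizon), tol = 1e-10)$root
    t_mid <- (cfg$rise_half_on + t_dep + cfg$rise_half_off) / 2
    a_new <- cfg$p_on * exp(-mu_on * t_mid) /
      (cfg$p_on * exp(-mu_on * t_mid) + (1 - cfg$p_on) * exp(-mu_off * t_mid))
    if (abs(a_new - a) < 1e-12) { a <- a_new; break }
    a <- a_new
  }

  n_on_dep <- cfg$n0 * a * exp(mu_on * t_dep)
  n_off_dep <- cfg$n0 * (1 - a) * exp(mu_off * t_dep)
  n_on <- function(tt) ifelse(tt <= t_dep, cfg$n0 * a * exp(mu_on * tt),
                              n_on_dep * exp(cfg$mu_gal * (tt - t_dep)))
  n_off <- function(tt) ifelse(
    tt <= t_dep, cfg$n0 * (1 - a) * exp(mu_off * tt),
    ifelse(tt <= t_dep + cfg$lag, n_off_dep,
           n_off_dep * exp(cfg$mu_gal * (tt - t_dep - cfg$lag))))
  n_tot <- function(tt) n_on(tt) + n_off(tt)
  share_on <- function(tt) n_on(tt) / n_tot(tt)

  mean_on_t <- function(tt) cfg$mean_off_log +
    (cfg$mean_on_log - cfg$mean_off_log) *
    plogis((tt - cfg$rise_half_on) / cfg$rise_scale)
  mean_off_t <- function(tt) cfg$mean_off_log +
    (cfg$mean_on_log - cfg$mean_off_log) *
    plogis((tt - t_dep - cfg$rise_half_off) / cfg$rise_scale)
  f_on_true <- function(tt)
    share_on(tt) * pnorm((mean_on_t(tt) - threshold) / cfg$sd_log) +
    (1 - share_on(tt)) * pnorm((mean_off_t(tt) - threshold) / cfg$sd_log)

  glu_t <- function(tt) pmax(cfg$glu0 - cfg$c_glu *
    (cfg$n0 * (a * (exp(mu_on * pmin(tt, t_dep)) - 1) / mu_on +
               (1 - a) * (exp(mu_off * pmin(tt, t_dep)) - 1) / mu_off)), 0)

  # galactose: leak consumption by ON cells until the diauxic lag ends,
  # then full-rate consumption by the whole population
  gal_t <- local({
    tg <- seq(0, cfg$horizon, by = 0.01)
    rate <- ifelse(tg < t_dep + cfg$lag,
                   cfg$gal_leak * cfg$c_gal * n_tot(tg) * f_on_true(tg),
                   cfg$c_gal * n_tot(tg))
    consumed <- c(0, cumsum(0.01 * (rate[-1] + rate[-length(rate)]) / 2))
    approxfun(tg, pmax(cfg$gal0 - consumed, 0), rule = 2)
  })

  list(t_dep = t_dep, a = a, mu_on = mu_on, mu_off = mu_off,
       n_on = n_on, n_off = n_off, n_tot = n_tot, share_on = share_on,
       mean_on_t = mean_on_t, mean_off_t = mean_off_t,
       f_on_true = f_on_true, glu_t = glu_t, gal_t = gal_t,
       threshold = threshold)
}

#' Generate a synthetic ground-truth experiment
#'
#' Draws event tables, sugar series and an OD series from the two-cohort
#' statistical model defined by a [synthetic_config()].  Truth metrics are
#' computed analytically from the configured mean trajectories, never
#' re-estimated from the draws:
#' `delta_a_true = rise_half_on`,
#' `delta_g_true = (t_depletion + rise_half_off) - rise_half_on`,
#' `f_on_mid_true = p_on`, and the subpopulation growth rates are the
#' configured cohort exponents (log2 units).
#'
#' @param config a [synthetic_config()].
#' @param condition condition identifier written into every output table.
#' @return object of class `synthetic_experiment`: list with `config`,
#'   `truth`, `events` (data.frame: `condition`, `time_h`, `fluorescence`,
#'   `side_scatter`, `events_per_ul`), `sugars` (`condition`, `sugar`,
#'   `time_h`, `concentration`) and `od` (`condition`, `time_h`, `od600`).
#' @export
generate_experiment <- function(config, condition = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  m <- .synth_model(config)
  times <- seq(0, config$horizon, by = config$sample_interval)
  set.seed(config$seed)

  ev <- lapply(times, function(tt) {
    n_ev <- config$events_per_sample
    k_on <- rbinom(1, n_ev, m$share_on(tt))
    vals <- c(rnorm(k_on, m$mean_on_t(tt), config$sd_log),
              rnorm(n_ev - k_on, m$mean_off_t(tt), config$sd_log))
    ss <- rlnorm(n_ev, config$ss_meanlog, config$ss_sdlog)
    data.frame(condition = condition, time_h = tt,
               fluorescence = 10^vals * ss, side_scatter = ss,
               events_per_ul = m$n_tot(tt))
  })
  events <- do.call(rbind, ev)

  sugars <- rbind(
    data.frame(condition = condition, sugar = "glucose", time_h = times,
               concentration = m$glu_t(times)),
    data.frame(condition = condition, sugar = "galactose", time_h = times,
               concentration = m$gal_t(times)))
  od <- data.frame(condition = condition, time_h = times,
                   od600 = config$od_per_cell * m$n_tot(times))

  truth <- list(
    t_depletion = m$t_dep,
    delta_a_true = config$rise_half_on,
    delta_g_true = (m$t_dep + config$rise_half_off) - config$rise_half_on,
    f_on_mid_true = config$p_on,
    rate_on_log2 = m$mu_on / log(2),
    rate_off_log2 = m$mu_off / log(2),
    rate_ratio_true = config$rate_ratio_off_on,
    mu_gal = config$mu_gal, lag = config$lag)

  structure(list(config = config, truth = truth, events = events,
                 sugars = sugars, od = od, condition = condition),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic experiment", x$condition, "\n")
  cat(sprintf("  t_depletion = %.2f h, delta_g_true = %.2f h, p_on = %.2f\n",
              x$truth$t_depletion, x$truth$delta_g_true,
              x$truth$f_on_mid_true))
  cat(sprintf("  %d time points x %d events\n",
              length(unique(x$events$time_h)), x$config$events_per_sample))
  invisible(x)
}

# ON fraction map over the condition grid: increasing in galactose,
# decreasing in glucose (% w/v scale)
.p_on_map <- function(glu0, gal0) {
  0.9 * hill_act(gal0, 0.15, 1) * hill_rep(glu0, 0.35, 1)
}

#' Generate a grid of synthetic conditions
#'
#' One experiment per (glucose, galactose, seed) combination.  The
#' configured ON fraction increases with galactose and decreases with
#' glucose, and the glucose depletion time increases with the glucose
#' dose, so the grid reproduces the qualitative input phase diagram:
#' near-monomodal activation at low glucose, transient bimodality in the
#' mid range, and long-delayed activation at high glucose.
#'
#' @param glu_levels,gal_levels initial sugar doses (% w/v).
#' @param seeds integer vector of replicate seeds.
#' @param base a [synthetic_config()] supplying all other fields.
#' @param p_on either `"map"` (the built-in monotone dose map) or
#'   `"from_model"`, which derives the ON fraction from
#'   [basin_fraction_on()] under `model_params`, converting % w/v to nM
#'   with `sugar_to_nm`.
#' @param model_params,sugar_to_nm see `p_on`.
#' @return list of [generate_experiment()] results.
#' @export
generate_condition_grid <- function(glu_levels, gal_levels, seeds = 1L,
                                    base = synthetic_config(),
                                    p_on = c("map", "from_model"),
                                    model_params = default_params("repressor"),
                                    sugar_to_nm = 1000) {
  stopifnot(length(glu_levels) >= 1, length(gal_levels) >= 1,
            length(seeds) >= 1)
  p_on <- match.arg(p_on)
  out <- list()
  for (s in seeds) for (g in glu_levels) for (ga in gal_levels) {
    cfg <- base
    cfg$glu0 <- g; cfg$gal0 <- ga
    cfg$p_on <- if (p_on == "map") .p_on_map(g, ga) else
      as.numeric(basin_fraction_on(model_params, g * sugar_to_nm,
                                   ga * sugar_to_nm, n_samples = 500,
                                   seed = s))
    cfg$seed <- s * 100003L + round(1e4 * g) * 97L + round(1e4 * ga)
    id <- sprintf("glu%g_gal%g_s%d", g, ga, s)
    out[[id]] <- generate_experiment(cfg, condition = id)
  }
  out
}
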