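# Drift-diffusion characterization of the translocation coordinate:
# drift velocity, entropic drift model, variance/diffusion exponents,
# log-normal first-passage fits, retardation, and the waiting-time hump.

#' Drift velocity from the waiting-time function
#'
#' `v(s) = ds/dt ~ 1 / w(s)` in states per tau_u.
#'
#' @param w Waiting times per state (tau_u), `s = 1..N-1`.
#' @return Numeric vector `v(s)`; zero waiting times yield `Inf` with a
#'   warning (infinite-rate flag).
#' @export
drift_velocity <- function(w) {
  if (any(w < 0)) stop("waiting times must be non-negative")
  if (any(w == 0)) warning("zero waiting time: infinite transition rate flagged")
  v <- 1 / w
  names(v) <- names(w)
  v
}

#' Entropic drift model of the threading velocity
#'
#' The tug-of-war free energy of the two equilibrated sub-chains,
#' `F(s) = kBT [(1 - gamma_I) ln(N - s) + (1 - gamma_III) ln(s)]`,
#' yields (for equal exponents gamma') the entropic force per threaded
#' monomer `f_entropic = kBT (1 - gamma') (2 s~ - 1) / (N l0 s~ (1 - s~))`.
#' The pore driving force is `f_driving = e E (N_mII - N_cII)` with
#' `N_mII` monomers and `N_cII` condensed (+1)-ions in the pore, the
#' effective Rouse friction `zeta_eff = zeta (N_mII + N_cII)`, and the
#' predicted velocity `v_es = (f_entropic + f_driving) / (l0 zeta_eff)`.
#'
#' @param N Chain length.
#' @param s Translocation state(s), strictly between 0 and N.
#' @param E Field strength (kBT/(e sigma)).
#' @param N_mII Monomers in the pore region (scalar or per-s vector).
#' @param N_cII Condensed (+1)-ions in the pore (scalar or per-s vector).
#' @param gamma_I,gamma_III Sub-chain surface exponents (0.69 for
#'   self-avoiding chains).
#' @param l0 Bond length (sigma).
#' @param zeta Solvent friction per bead (m/tau_u).
#' @return A data.frame with `s`, `s_tilde`, `F_entropic`, `f_entropic`,
#'   `f_driving`, `zeta_eff`, `v_es`.
#' @export
entropic_drift_model <- function(N, s, E, N_mII = 4.5, N_cII = 0,
                                 gamma_I = 0.69, gamma_III = 0.69,
                                 l0 = 1.0, zeta = 1.0) {
  if (any(s <= 0 | s >= N))
    stop("the entropic free energy diverges at s = 0 and s = N; it is only ",
         "valid for 0 < s < N (both sub-chains large)")
  st <- s / N
  Fent <- (1 - gamma_I) * log(N - s) + (1 - gamma_III) * log(s)
  fent <- if (gamma_I == gamma_III) {
    (1 - gamma_I) * (2 * st - 1) / (N * l0 * st * (1 - st))
  } else {
    # general two-exponent form: -dF/ds / l0
    ((1 - gamma_I) / (N - s) - (1 - gamma_III) / s) / l0
  }
  fdrv <- E * (N_mII - N_cII)
  zeff <- zeta * (N_mII + N_cII)
  data.frame(s = s, s_tilde = st, F_entropic = Fent, f_entropic = fent,
             f_driving = rep_len(fdrv, length(s)),
             zeta_eff = rep_len(zeff, length(s)),
             v_es = (fent + rep_len(fdrv, length(s))) /
               (l0 * rep_len(zeff, length(s))))
}

#' Pore occupancy along a trajectory
#'
#' Counts, for every stored frame, the monomers inside the pore region II
#' and the (+1)-ions that are both inside region II and within the Bjerrum
#' length of some monomer (the ion-condensation criterion).
#'
#' @param traj A `trajectory`.
#' @return data.frame with `time`, `N_mII`, `N_cII`.
#' @export
pore_occupancy <- function(traj) {
  cfg <- traj$cfg
  wh <- cfg$wall_thickness / 2
  is_cat <- traj$charge > 0
  rows <- lapply(seq_along(traj$frames), function(fi) {
    p <- traj$frames[[fi]]
    mono <- p[seq_len(traj$n_mono), , drop = FALSE]
    nm <- sum(abs(mono[, 3]) <= wh)
    nc <- 0L
    if (any(is_cat)) {
      cat_in <- which(is_cat & abs(p[, 3]) <= wh)
      for (ci in cat_in) {
        d2 <- (mono[, 1] - p[ci, 1])^2 + (mono[, 2] - p[ci, 2])^2 +
          (mono[, 3] - p[ci, 3])^2
        if (any(d2 <= cfg$lambda_B^2)) nc <- nc + 1L
      }
    }
    data.frame(time = traj$times[fi], N_mII = nm, N_cII = nc)
  })
  do.call(rbind, rows)
}

#' Variance of the translocation coordinate across runs
#'
#' Population variance of `s(t)` over the ensemble, on a real-time grid and
#' on a scaled-time grid (each run's clock divided by its own tau_k, so
#' every run spans `[0, 1]` and the variance is pinned to zero at both
#' ends).  Completed runs hold `s = N` beyond their completion time.
#'
#' @param records List of `translocation_record`s (>= 2 completed).
#' @param n_grid Number of grid points.
#' @return List of two data.frames, `real` (`t`, `mean_s`, `var_s`) and
#'   `scaled` (`t_tilde`, `mean_s`, `var_s`).
#' @export
variance_curve <- function(records, n_grid = 200) {
  recs <- Filter(function(r) isTRUE(r$completed), records)
  if (length(recs) < 2)
    stop("variance across runs needs at least 2 completed runs")
  taus <- vapply(recs, `[[`, 0, "tau")
  s_at <- function(r, tq) {
    # piecewise-constant interpolation of the recorded series
    i <- findInterval(tq, r$time)
    out <- r$s[pmax(i, 1)]
    out[tq >= r$tau] <- r$N
    out
  }
  tg <- seq(0, max(taus), length.out = n_grid)
  S <- vapply(recs, s_at, numeric(n_grid), tq = tg)
  pop_var <- function(m) rowMeans(m^2) - rowMeans(m)^2
  real <- data.frame(t = tg, mean_s = rowMeans(S), var_s = pop_var(S))
  ttg <- seq(0, 1, length.out = n_grid)
  St <- vapply(recs, function(r) s_at(r, ttg * r$tau), numeric(n_grid))
  scaled <- data.frame(t_tilde = ttg, mean_s = rowMeans(St),
                       var_s = pop_var(St))
  list(real = real, scaled = scaled)
}

#' Anomalous-diffusion exponent of the variance curve
#'
#' Least-squares slope of `log <Delta s^2>` against `log t` on a stated
#' time window: 1 for normal diffusion, 2 for ballistic spreading.
#'
#' @param t Times (tau_u).
#' @param var_s Variance values.
#' @param window `c(t_min, t_max)` fitting window.
#' @return List with `xi` (exponent), `se`, `n`.
#' @export
diffusion_exponent <- function(t, var_s, window = range(t[t > 0])) {
  keep <- t >= window[1] & t <= window[2] & t > 0
  if (any(var_s[keep] <= 0))
    stop("non-positive variance inside the fitting window; choose a window ",
         "inside the growth part of the curve")
  if (sum(keep) < 3) stop("fitting window contains fewer than 3 points")
  x <- log(t[keep]); y <- log(var_s[keep])
  fit <- stats::lm(y ~ x)
  # slope standard error computed directly (an exact power law makes
  # summary.lm() complain about a perfect fit)
  res <- stats::resid(fit)
  se <- sqrt(sum(res^2) / (length(x) - 2) / sum((x - mean(x))^2))
  list(xi = unname(stats::coef(fit)[2]), se = se, n = sum(keep))
}

#' First-passage times to a translocation state
#'
#' Time of first arrival at (or past) state `s` in each run; revisits are
#' ignored.
#'
#' @param records List of `translocation_record`s.
#' @param s Target state.
#' @return Numeric vector, one entry per completed run (`NA` if the run
#'   never reaches `s`).
#' @export
first_passage_times <- function(records, s) {
  vapply(records, function(r) {
    i <- which(r$s >= s)[1]
    if (is.na(i)) NA_real_ else r$time[i]
  }, 0)
}

#' Log-normal density of the first-passage distribution
#'
#' `p(s, t) = A / (sqrt(2 pi) sigma t) exp(-(ln t - ln mu)^2 / (2 sigma^2))`.
#'
#' @param t Times (> 0).
#' @param A Amplitude (the time integral of the density).
#' @param sigma,mu Log-normal shape and scale parameters.
#' @return Density values.
#' @export
lognormal_density <- function(t, A, sigma, mu) {
  A / (sqrt(2 * pi) * sigma * t) * exp(-(log(t) - log(mu))^2 / (2 * sigma^2))
}

#' Fit a log-normal first-passage density for one state
#'
#' Two-parameter damped (Levenberg-Marquardt) least squares over
#' `(sigma_s, mu_s)` with the amplitude `A_s` held fixed at its
#' waiting-time value `w(s)/<tau>`.  The fit is performed on a log-spaced
#' histogram of the first-passage samples whose density is scaled to
#' integrate to `A_s`.  Derived quantities: full width at half maximum
#' `W_s = 2 sinh(sqrt(2 ln 2) sigma) exp(-sigma^2) mu` and mean
#' first-passage time `<t_s> = exp(sigma^2 / 2) mu`.
#'
#' @param samples First-passage times for the state (>= 20).
#' @param A_s Fixed amplitude.
#' @param n_bins Number of log-spaced histogram bins.
#' @return Object of class `lognormal_fit`: list with `sigma_s`, `mu_s`,
#'   `A_s`, `W_s`, `t_mean`, `residual` (sum of squares), `converged`,
#'   and the binned data (`t`, `density`).
#' @export
lognormal_fit <- function(samples, A_s = 1.0, n_bins = 24) {
  samples <- samples[is.finite(samples) & samples > 0]
  if (length(samples) < 20)
    stop("need at least 20 first-passage samples to fit the density")
  lo <- min(samples) * 0.999
  hi <- max(samples) * 1.001
  breaks <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  dens <- A_s * h$counts / (length(samples) * diff(breaks))
  tc <- sqrt(breaks[-1] * breaks[-length(breaks)])  # geometric bin centers
  keep <- h$counts > 0
  start <- list(sigma = max(stats::sd(log(samples)), 1e-3),
                mu = exp(mean(log(samples))))
  dat <- data.frame(t = tc[keep], y = dens[keep])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lognormal_density(t, A_s, sigma, mu),
                      data = dat, start = start,
                      lower = c(1e-6, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res0 <- sum((dat$y - lognormal_density(dat$t, A_s, start$sigma,
                                           start$mu))^2)
    out <- list(sigma_s = start$sigma, mu_s = start$mu, A_s = A_s,
                residual = res0, converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- list(sigma_s = unname(cf["sigma"]), mu_s = unname(cf["mu"]),
                A_s = A_s, residual = sum(stats::resid(fit)^2),
                converged = TRUE)
  }
  out$W_s <- lognormal_fwhm(out$sigma_s, out$mu_s)
  out$t_mean <- exp(out$sigma_s^2 / 2) * out$mu_s
  out$t <- dat$t
  out$density <- dat$y
  class(out) <- "lognormal_fit"
  out
}

#' Full width at half maximum of the log-normal density
#'
#' @param sigma,mu Log-normal parameters.
#' @return `2 sinh(sqrt(2 ln 2) sigma) exp(-sigma^2) mu`.
#' @export
lognormal_fwhm <- function(sigma, mu) {
  2 * sinh(sqrt(2 * log(2)) * sigma) * exp(-sigma^2) * mu
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Log-normal fit: sigma_s = %.4g, mu_s = %.4g tau_u (A_s = %.4g, %s, rss = %.3g)\n",
              x$sigma_s, x$mu_s, x$A_s,
              if (x$converged) "converged" else "NOT converged", x$residual))
  cat(sprintf("  FWHM W_s = %.4g tau_u, <t_s> = %.4g tau_u\n", x$W_s, x$t_mean))
  invisible(x)
}

#' Retardation of the mean arrival times
#'
#' `delta_s = (<t_s> - s / vbar) / <tau>` with the mean threading speed
#' `vbar = N / <tau>`: the relative delay of the mean first-arrival time
#' behind a constant-speed schedule.
#'
#' @param t_s Mean first-arrival times per state (tau_u).
#' @param tau_mean Mean translocation time.
#' @param N Chain length.
#' @param s States matching `t_s` (default `seq_along(t_s)`).
#' @return List with `delta` (per state), `s`, `zero_crossings`
#'   (interpolated s values where delta changes sign), `min`, `max`
#'   (locations and values of the extremes, where the threading speed
#'   equals vbar).
#' @export
retardation <- function(t_s, tau_mean, N, s = seq_along(t_s)) {
  vbar <- N / tau_mean
  if (vbar <= 0) stop("mean threading speed must be positive")
  delta <- (t_s - s / vbar) / tau_mean
  sgn <- sign(delta)
  zc <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  zeros <- vapply(zc, function(i) {
    s[i] + (s[i + 1] - s[i]) * abs(delta[i]) / (abs(delta[i]) +
                                                  abs(delta[i + 1]))
  }, 0)
  list(delta = delta, s = s, zero_crossings = zeros,
       min = list(s = s[which.min(delta)], delta = min(delta)),
       max = list(s = s[which.max(delta)], delta = max(delta)))
}

#' Hump position of the normalized waiting-time function
#'
#' Argmax of `w~(s~)` restricted to an interior window that excludes the
#' field-switch-on peak near 0 and the crowding overshoot near 1.
#'
#' @param w_tilde data.frame with `s_tilde`, `w_tilde` (as produced by
#'   [ensemble_waiting()]), or an `ensemble_record`.
#' @param window Interior search window on `s~`.
#' @return `s~*`, the hump position.
#' @export
hump_position <- function(w_tilde, window = c(0.05, 0.95)) {
  if (inherits(w_tilde, "ensemble_record")) w_tilde <- w_tilde$w_tilde
  keep <- w_tilde$s_tilde >= window[1] & w_tilde$s_tilde <= window[2]
  if (!any(keep)) stop("search window contains no states")
  d <- w_tilde[keep, ]
  d$s_tilde[which.max(d$w_tilde)]
}

#' Hump positions across chain lengths and the tension-extent scaling
#'
#' Collects `s~*` for several chain lengths at fixed field and fits
#' `log(N - s*) ~ log(N)`; the slope estimates the scaling exponent of the
#' maximum tension extent `N - s*` with chain length.
#'
#' @param ensembles Named list: each element either an `ensemble_record`
#'   or a list/data.frame with `s_tilde`, `w_tilde` plus an `N` entry.
#' @param Ns Chain lengths (taken from the elements when omitted).
#' @param window Hump search window (see [hump_position()]).
#' @return List with `table` (data.frame `N`, `s_tilde_star`, `s_star`,
#'   `extent`), `exponent`, `se`.
#' @export
hump_and_scaling <- function(ensembles, Ns = NULL, window = c(0.05, 0.95)) {
  if (is.null(Ns))
    Ns <- vapply(ensembles, function(e) as.numeric(e$N), 0)
  if (length(ensembles) < 3)
    stop("scaling fit needs at least 3 chain lengths")
  sstar_t <- vapply(ensembles, function(e) {
    wt <- if (inherits(e, "ensemble_record")) e$w_tilde else
      data.frame(s_tilde = e$s_tilde, w_tilde = e$w_tilde)
    hump_position(wt, window)
  }, 0)
  s_star <- sstar_t * Ns
  extent <- Ns - s_star
  fit <- stats::lm(log(extent) ~ log(Ns))
  list(table = data.frame(N = Ns, s_tilde_star = sstar_t, s_star = s_star,
                          extent = extent),
       exponent = unname(stats::coef(fit)[2]),
       se = summary(fit)$coefficients[2, 2])
}
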