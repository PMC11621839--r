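#' Logistic frequency of the cultural innovation in rescaled time
#'
#' With time rescaled as T = s_C t and the sweep's midpoint at T = 0, the
#' deterministically spreading innovation follows x(T) = 1 / (1 + exp(-T)),
#' so that dx/dT = x(1 - x).
#'
#' @param T rescaled time (vectorised).
#' @return frequency x of the cultural innovation.
#' @export
sweep_frequency <- function(T) {
  stats::plogis(T)
}

#' Effective selection on the cultural trait under copying bias
#'
#' Under cultural trait bias, biased copying by the resident a-bearing
#' majority itself changes the trait's transmission success, adding to its
#' fitness advantage. To first order in the selection coefficients the
#' overall selection on the trait is
#' s_C + 2 (gamma2 - 1/2) (1 + s_C - 2 s_C x). With gamma2 = 1/2 (no
#' distortion among residents) this reduces to s_C and the logistic sweep
#' applies unchanged.
#'
#' @param x current frequency of the cultural innovation (vectorised).
#' @param s_C fitness advantage of the innovation.
#' @param gamma2 copying bias of a-bearing offspring toward C.
#' @return effective selection coefficient.
#' @export
effective_selection <- function(x, s_C, gamma2) {
  s_C + 2 * (gamma2 - 0.5) * (1 + s_C - 2 * s_C * x)
}

#' Background-jump rates of a rare A mutation
#'
#' The rates at which a rare A-bearing lineage leaves the C background (r1)
#' and the c background (r2) through cultural transmission. For affinity
#' bias both equal beta1 (only the similarity error of A-bearing offspring
#' matters while A is rare); for cultural trait bias r1 = 1 - gamma1 and
#' r2 = gamma1.
#'
#' @param model a \code{\link{transmission_model}}.
#' @return named numeric vector \code{c(r1, r2)}.
#' @export
jump_rates <- function(model) {
  stopifnot(inherits(model, "transmission_model"))
  if (model$variant == "affinity")
    c(r1 = model$beta1, r2 = model$beta1)
  else
    c(r1 = 1 - model$gamma1, r2 = model$gamma1)
}

#' Dimensionless parameters of the fixation-probability system
#'
#' @param model a \code{\link{transmission_model}}.
#' @param s_A selective advantage of the new mutation (> 0).
#' @param s_C selective advantage of the cultural trait (> 0; required for
#'   the rescaling).
#' @return list with \code{rho1} = r1/s_C, \code{rho2} = r2/s_C,
#'   \code{theta} = s_A/s_C.
#' @export
rescaled_params <- function(model, s_A, s_C) {
  stopifnot(s_C > 0, s_A > 0)
  r <- jump_rates(model)
  list(rho1 = unname(r["r1"]) / s_C, rho2 = unname(r["r2"]) / s_C,
       theta = s_A / s_C)
}

#' Scaled fixation probability during a cultural sweep
#'
#' Solves the coupled system for Pi(T), the fixation probability of a new
#' beneficial mutation arising at rescaled time T averaged over cultural
#' backgrounds, and Delta(T), the background difference, both scaled by the
#' no-sweep probability 2 s_A:
#' \deqn{dPi/dT = x y (rho1 - rho2) Delta - theta Pi (1 - Pi) + theta x y Delta^2}
#' \deqn{dDelta/dT = Delta((rho1 y + rho2 x) + (2 Pi - 1) theta + (x - y)(1 - theta Delta)) - Pi}
#' with x = x(T) the logistic sweep and y = 1 - x.
#'
#' The natural boundary lies after the sweep: a mutation arising once C has
#' fixed is unaffected, so Pi = 1 at the right end of the grid. The system
#' is integrated backward in T from T_max with boundary values Pi = 1 and
#' Delta = \code{delta_end} (default 0; the backward dynamics are
#' contracting in Delta, so the solution relaxes to the slaved branch within
#' a unit or so of rescaled time regardless of this choice).
#'
#' @param rho1,rho2 scaled background-jump rates (r_i / s_C).
#' @param theta scaled mutant advantage (s_A / s_C).
#' @param T_grid increasing grid of rescaled times (default
#'   \code{seq(-20, 20, by = 0.05)}).
#' @param delta_end boundary value of Delta at the right end (default 0).
#' @param rtol,atol integrator tolerances (lsoda).
#' @return an object of class \code{pi_delta_solution}: a data.frame with
#'   columns \code{T, x, Pi, Delta}, forward-ordered.
#' @export
solve_pi_delta <- function(rho1, rho2, theta,
                           T_grid = seq(-20, 20, by = 0.05),
                           delta_end = 0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(T_grid) >= 2L, !is.unsorted(T_grid))
  deriv <- function(T, y, parms) {
    x <- stats::plogis(T)
    yy <- 1 - x
    Pi <- y[1]; De <- y[2]
    dPi <- x * yy * (rho1 - rho2) * De - theta * Pi * (1 - Pi) +
      theta * x * yy * De^2
    dDe <- De * ((rho1 * yy + rho2 * x) + (2 * Pi - 1) * theta +
                   (x - yy) * (1 - theta * De)) - Pi
    list(c(dPi, dDe))
  }
  times <- rev(T_grid)
  sol <- deSolve::ode(y = c(Pi = 1, Delta = delta_end), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration of the Pi/Delta system did not converge")
  sol <- as.data.frame(sol)
  sol <- sol[order(sol$time), ]
  out <- data.frame(T = sol$time, x = stats::plogis(sol$time),
                    Pi = sol$Pi, Delta = sol$Delta)
  rownames(out) <- NULL
  class(out) <- c("pi_delta_solution", "data.frame")
  out
}

#' Fixation probability of a beneficial mutation across sweep timings
#'
#' Composes \code{\link{jump_rates}}, the rescaling and
#' \code{\link{solve_pi_delta}} for a given transmission model, and recovers
#' the unscaled fixation probabilities P_x (mutation arising on the C
#' background), P_y (on c) and the background-averaged Pbar = 2 s_A Pi.
#'
#' For affinity bias the curve is independent of beta2 and coincides with
#' purely genetic hitchhiking with recombination rate beta1. For cultural
#' trait bias with gamma1 < 1/2 the curve dips below 1 (interference); with
#' gamma1 > 1/2 it rises above 1 (facilitation).
#'
#' @param model a \code{\link{transmission_model}}. For trait bias, gamma2
#'   must be 1/2 for the logistic sweep to apply exactly; other values are
#'   accepted with a warning and the logistic is still used.
#' @param s_A,s_C selection coefficients (> 0).
#' @param T_grid increasing grid of rescaled times.
#' @param ... passed to \code{\link{solve_pi_delta}}.
#' @return a \code{pi_delta_solution} data.frame with additional columns
#'   \code{Px, Py, Pbar} and attributes \code{rho1, rho2, theta}.
#' @examples
#' fc <- fixation_curve(trait_bias(0.45, 0.5), s_A = 0.1, s_C = 0.1)
#' min(fc$Pi)  # < 1: interference
#' @export
fixation_curve <- function(model, s_A, s_C,
                           T_grid = seq(-20, 20, by = 0.05), ...) {
  if (model$variant == "trait_bias" && abs(model$gamma2 - 0.5) > 1e-12)
    warning("gamma2 != 1/2: the logistic sweep is only approximate")
  p <- rescaled_params(model, s_A, s_C)
  sol <- solve_pi_delta(p$rho1, p$rho2, p$theta, T_grid = T_grid, ...)
  sol$Pbar <- 2 * s_A * sol$Pi
  sol$Px <- 2 * s_A * (sol$Pi + (1 - sol$x) * sol$Delta)
  sol$Py <- 2 * s_A * (sol$Pi - sol$x * sol$Delta)
  attr(sol, "rho1") <- p$rho1
  attr(sol, "rho2") <- p$rho2
  attr(sol, "theta") <- p$theta
  sol
}

#' Net effect of the sweep on fixation probability, integrated over timings
#'
#' Trapezoidal integral of (Pi - 1) over the rescaled-time grid: the
#' cumulative excess or deficit in fixation probability across all possible
#' timings of the mutation relative to the cultural sweep.
#'
#' @param solution a \code{pi_delta_solution}.
#' @return scalar integral of (Pi - 1) dT.
#' @export
net_sweep_effect <- function(solution) {
  T <- solution$T
  y <- solution$Pi - 1
  sum(diff(T) * (y[-length(y)] + y[-1]) / 2)
}

#' Cross-check of the analytic fixation probability against simulation
#'
#' Simulates the fate of a single new A copy introduced when the cultural
#' sweep has reached x = x(T0), divides its fixation probability by the
#' no-culture baseline, and compares with the analytic Pi(T0).
#'
#' @param model a \code{\link{transmission_model}}.
#' @param s_A,s_C selection coefficients.
#' @param T0 rescaled time at which the mutation arises.
#' @param N population size for the simulation.
#' @param replicates number of replicate invasions.
#' @param seed RNG seed.
#' @return list with \code{Pi_analytic}, \code{ratio_simulated},
#'   \code{ratio_se}, \code{x0} and the underlying
#'   \code{\link{fixation_experiment}} result.
#' @export
simulation_crosscheck <- function(model, s_A, s_C, T0, N = 5000L,
                                  replicates = 20000L, seed = 1L) {
  x0 <- sweep_frequency(T0)
  fc <- fixation_curve(model, s_A, s_C,
                       T_grid = seq(min(T0, -20), 20, by = 0.05))
  Pi0 <- stats::approx(fc$T, fc$Pi, xout = T0)$y
  cfg <- stochastic_run_config(N = N, fit = fitness_params(s_A, s_C),
                               model = model, x0 = x0,
                               replicates = replicates, seed = seed)
  fx <- fixation_experiment(cfg)
  # delta-method SE of the ratio of two independent binomial proportions
  rse <- fx$p_fix_ratio *
    sqrt((fx$p_fix_se / fx$p_fix)^2 + (fx$baseline$p_fix_se / fx$p_fix_baseline)^2)
  list(Pi_analytic = Pi0, ratio_simulated = fx$p_fix_ratio, ratio_se = rse,
       x0 = x0, experiment = fx)
}
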