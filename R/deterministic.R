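#' One-generation closed-form recursion under affinity bias
#'
#' Closed-form recursion for the neutral-locus case (\code{s_A = 0}), derived
#' from the transmission table with mean fitness 1 + x s_C. For
#' \code{s_A != 0} no closed form is used and the exact engine
#' \code{\link{next_generation_exact}} is called instead.
#'
#' With \code{beta1 = beta2 = r} the recursion is mathematically identical to
#' classic two-locus genetic hitchhiking with recombination rate r (see
#' \code{\link{msh_reference_step}}).
#'
#' @param state a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @param beta1,beta2 affinity-bias mixing parameters in [0, 1].
#' @return the next-generation \code{\link{pheno_state}}.
#' @export
step_affinity <- function(state, fit, beta1, beta2) {
  if (fit$s_A != 0)
    return(next_generation_exact(state, fit, affinity_bias(beta1, beta2)))
  f <- .step_affinity_vec(state$x, state$Q, state$R, fit$s_C, beta1, beta2)
  pheno_state_from_frequencies(drop(f))
}

# Vectorised closed forms (s_A = 0). Returns n x 4 phenogenotype frequencies.
.step_affinity_vec <- function(x, Q, R, sC, beta1, beta2) {
  wbar2 <- (1 + x * sC)^2
  fAC <- x * (1 + sC) * (Q * (1 + x * sC) + beta1 * (1 - x) * (R - Q))
  faC <- x * (1 + sC) * ((1 - Q) * (1 + x * sC) + beta2 * (1 - x) * (Q - R))
  fAc <- (1 - x) * (x * (1 + sC) * (R + beta1 * (Q - R)) + (1 - x) * R)
  fac <- (1 - x) * (x * (1 + sC) * (1 - R + beta2 * (R - Q)) + (1 - x) * (1 - R))
  cbind(AC = fAC, aC = faC, Ac = fAc, ac = fac) / wbar2
}

#' One-generation closed-form recursion under cultural trait bias
#'
#' As \code{\link{step_affinity}} but for genotype-dependent copying biases
#' \code{gamma1} (A-bearing offspring) and \code{gamma2} (a-bearing), again
#' restricted to \code{s_A = 0} with fallback to the exact engine otherwise.
#'
#' @param state a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @param gamma1,gamma2 trait-bias parameters in [0, 1].
#' @return the next-generation \code{\link{pheno_state}}.
#' @export
step_trait_bias <- function(state, fit, gamma1, gamma2) {
  if (fit$s_A != 0)
    return(next_generation_exact(state, fit, trait_bias(gamma1, gamma2)))
  f <- .step_trait_bias_vec(state$x, state$Q, state$R, fit$s_C, gamma1, gamma2)
  pheno_state_from_frequencies(drop(f))
}

.step_trait_bias_vec <- function(x, Q, R, sC, gamma1, gamma2) {
  wbar2 <- (1 + x * sC)^2
  fAC <- x * (1 + sC) * (x * Q * (1 + sC) + gamma1 * (1 - x) * (Q + R))
  faC <- x * (1 + sC) * (x * (1 - Q) * (1 + sC) + gamma2 * (1 - x) * (2 - Q - R))
  fAc <- (1 - x) * (x * (1 + sC) * (1 - gamma1) * (Q + R) + (1 - x) * R)
  fac <- (1 - x) * (x * (1 + sC) * (1 - gamma2) * (2 - Q - R) + (1 - x) * (1 - R))
  cbind(AC = fAC, aC = faC, Ac = fAc, ac = fac) / wbar2
}

.step_model_vec <- function(x, Q, R, fit, model) {
  if (fit$s_A != 0) return(.next_gen_freqs_vec(x, Q, R, fit, model))
  if (model$variant == "affinity")
    .step_affinity_vec(x, Q, R, fit$s_C, model$beta1, model$beta2)
  else
    .step_trait_bias_vec(x, Q, R, fit$s_C, model$gamma1, model$gamma2)
}

#' Deterministic cultural sweep
#'
#' Iterates the one-generation recursion from an initial state, recording the
#' trajectory of (x, Q, R), the allele-A frequency p = xQ + (1-x)R, and the
#' running relative heterozygosity H_rel = Q_t(1-Q_t) / (R0(1-R0)), whose
#' final value is the relative heterozygosity of the sweep.
#'
#' The convention for a cultural innovation introduced in a single individual
#' of a population of size N is x0 = 1/N, Q0 = 1 (the innovation arises on
#' the A background) and R0 equal to the pre-existing allele frequency.
#'
#' @param initial a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @param model a \code{\link{transmission_model}}.
#' @param t_max maximum number of generations to iterate (default 200).
#' @param loss_threshold x below this counts as loss of C (default 1e-9).
#' @param fix_threshold x above this counts as fixation of C (default
#'   1 - 1e-9).
#' @param stop_at_absorption if TRUE (default) iteration stops once C is
#'   deemed fixed or lost; the final recorded state then defines Q_hat. With
#'   FALSE the full \code{t_max} generations are always recorded and Q_hat is
#'   read at \code{t_max}.
#' @return an object of class \code{sweep_trajectory}: a data.frame with
#'   columns \code{t, x, Q, R, p, H_rel} and attributes \code{outcome}
#'   (\code{"C_fixed"}, \code{"C_lost"} or \code{"running"}), \code{Q_hat},
#'   \code{H_hat}, \code{p_final}, \code{R0}.
#' @examples
#' traj <- run_sweep(pheno_state(1e-6, 1, 0.5), fitness_params(0, 0.1),
#'                   affinity_bias(0.05, 0.001))
#' attr(traj, "outcome"); attr(traj, "H_hat")
#' @export
run_sweep <- function(initial, fit, model, t_max = 200L,
                      loss_threshold = 1e-9, fix_threshold = 1 - 1e-9,
                      stop_at_absorption = TRUE) {
  stopifnot(t_max >= 1L)
  n <- t_max + 1L
  x <- Q <- R <- numeric(n)
  x[1] <- initial$x; Q[1] <- initial$Q; R[1] <- initial$R
  R0 <- initial$R
  last <- n
  for (t in seq_len(t_max)) {
    f <- drop(.step_model_vec(x[t], Q[t], R[t], fit, model))
    s <- sum(f)
    xn <- (f[1] + f[2]) / s
    x[t + 1] <- xn
    Q[t + 1] <- if (xn > 0) f[1] / (f[1] + f[2]) else Q[t]
    R[t + 1] <- if (xn < 1) f[3] / (f[3] + f[4]) else R[t]
    if (stop_at_absorption &&
        (x[t + 1] > fix_threshold || x[t + 1] < loss_threshold)) {
      last <- t + 1L
      break
    }
  }
  idx <- seq_len(last)
  x <- x[idx]; Q <- Q[idx]; R <- R[idx]
  p <- x * Q + (1 - x) * R
  H_rel <- if (R0 > 0 && R0 < 1) Q * (1 - Q) / (R0 * (1 - R0)) else rep(NA_real_, last)
  outcome <- if (x[last] > fix_threshold) "C_fixed"
             else if (x[last] < loss_threshold) "C_lost"
             else "running"
  out <- data.frame(t = idx - 1L, x = x, Q = Q, R = R, p = p, H_rel = H_rel)
  attr(out, "outcome") <- outcome
  attr(out, "Q_hat") <- Q[last]
  attr(out, "H_hat") <- if (R0 > 0 && R0 < 1)
    relative_heterozygosity(Q[last], R0) else NA_real_
  attr(out, "p_final") <- p[last]
  attr(out, "R0") <- R0
  class(out) <- c("sweep_trajectory", "data.frame")
  out
}

#' Relative heterozygosity after a cultural sweep
#'
#' H_hat = Q_hat (1 - Q_hat) / (R0 (1 - R0)): the expected heterozygosity at
#' the neutral locus after the sweep relative to its initial value. At
#' R0 = 0.5 the normalising factor 1/(R0(1-R0)) equals 4. A value of 1 means
#' variation was untouched; values near 0 mean the sweep stripped variation.
#'
#' @param Q_hat frequency of allele A among C-practitioners after the sweep.
#' @param R0 initial frequency of allele A among c-practitioners, in (0, 1).
#' @return scalar relative heterozygosity.
#' @export
relative_heterozygosity <- function(Q_hat, R0) {
  if (any(R0 <= 0) || any(R0 >= 1))
    stop("R0 must lie strictly inside (0, 1)")
  Q_hat * (1 - Q_hat) / (R0 * (1 - R0))
}

#' Classic two-locus hitchhiking recursion (independent oracle)
#'
#' One generation of the standard deterministic two-locus haploid model: a
#' selected locus (advantage s), a linked neutral locus, recombination rate
#' r. Implemented directly on haplotype frequencies via selection followed by
#' recombination (f'_AB = f*_AB - r D*, with D the linkage disequilibrium),
#' independently of the transmission-table engine. Affinity-bias cultural
#' hitchhiking with \code{beta1 = beta2 = r} reproduces this recursion
#' exactly.
#'
#' @param state a \code{\link{pheno_state}} reinterpreted as a two-locus
#'   state: x = frequency of the selected allele, Q/R = neutral-allele
#'   frequency on the selected/ancestral background.
#' @param s selection coefficient of the selected locus.
#' @param r recombination rate in [0, 0.5] (any value in [0, 1] accepted).
#' @return the next-generation \code{\link{pheno_state}}.
#' @export
msh_reference_step <- function(state, s, r) {
  x <- state$x; Q <- state$Q; R <- state$R
  # haplotypes: AB = neutral-A on selected background, etc.
  f <- c(AB = x * Q, aB = x * (1 - Q), Ab = (1 - x) * R, ab = (1 - x) * (1 - R))
  w <- c(1 + s, 1 + s, 1, 1)
  fs <- f * w / sum(f * w)
  D <- fs["AB"] * fs["ab"] - fs["aB"] * fs["Ab"]
  fr <- fs + r * c(-D, D, D, -D)
  pheno_state_from_frequencies(unname(fr))
}

#' Final heterozygosity and allele frequency over a grid of bias parameters
#'
#' Runs the deterministic sweep at every point of a bias-parameter grid and
#' tabulates the outcome, the final relative heterozygosity H_hat and the
#' final allele-A frequency. Mirrors the parameter-plane summaries of the
#' hitchhiking analysis: for affinity bias the diagonal beta1 = beta2 is
#' classic genetic hitchhiking; for trait bias the plane splits into regions
#' where C fails to fix, where the final p falls below its initial value, and
#' where hitchhiking raises p.
#'
#' @param model_variant \code{"affinity"} or \code{"trait_bias"}.
#' @param bias1_values,bias2_values numeric grids for (beta1, beta2) or
#'   (gamma1, gamma2).
#' @param fit a \code{\link{fitness_params}} with \code{s_A = 0}.
#' @param initial a \code{\link{pheno_state}}; default is a single-individual
#'   introduction x0 = 1e-6, Q0 = 1, R0 = 0.5.
#' @param t_max generations per grid point (default 200).
#' @return data.frame with columns \code{param1, param2, outcome, Q_hat,
#'   H_hat, p_final}.
#' @export
heterozygosity_surface <- function(model_variant = c("affinity", "trait_bias"),
                                   bias1_values, bias2_values,
                                   fit = fitness_params(0, 0.1),
                                   initial = pheno_state(1e-6, 1, 0.5),
                                   t_max = 200L) {
  model_variant <- match.arg(model_variant)
  grid <- expand.grid(param1 = bias1_values, param2 = bias2_values,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  x <- rep(initial$x, n); Q <- rep(initial$Q, n); R <- rep(initial$R, n)
  R0 <- initial$R
  sC <- fit$s_C
  stopifnot(fit$s_A == 0)
  for (t in seq_len(t_max)) {
    f <- if (model_variant == "affinity")
      .step_affinity_vec(x, Q, R, sC, grid$param1, grid$param2)
    else
      .step_trait_bias_vec(x, Q, R, sC, grid$param1, grid$param2)
    tot <- rowSums(f)
    xn <- (f[, 1] + f[, 2]) / tot
    Qn <- ifelse(xn > 0, f[, 1] / (f[, 1] + f[, 2]), Q)
    Rn <- ifelse(xn < 1, f[, 3] / (f[, 3] + f[, 4]), R)
    x <- xn; Q <- Qn; R <- Rn
  }
  outcome <- ifelse(x > 1 - 1e-9, "C_fixed",
                    ifelse(x < 1e-9, "C_lost", "running"))
  data.frame(grid,
             outcome = outcome,
             Q_hat = Q,
             H_hat = relative_heterozygosity(Q, R0),
             p_final = x * Q + (1 - x) * R)
}
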