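#' Configuration of a stochastic interference experiment
#'
#' Bundles the parameters of a finite-population Wright-Fisher simulation of
#' one selected genetic locus and one selected cultural trait.
#'
#' @param N population size (>= 2).
#' @param fit a \code{\link{fitness_params}}.
#' @param model a \code{\link{transmission_model}}.
#' @param x0 initial frequency of cultural trait C among residents, in
#'   [0, 1] (default 0.5).
#' @param replicates number of replicate invasions (>= 1).
#' @param seed RNG seed recorded with the run (applied via
#'   \code{set.seed}).
#' @param max_generations cap on generations per replicate; defaults to
#'   100 * N.
#' @return an object of class \code{stochastic_run_config}.
#' @export
stochastic_run_config <- function(N = 1000L, fit = fitness_params(0.1, 0.1),
                                  model = affinity_bias(0.001, 0.001),
                                  x0 = 0.5, replicates = 1000L, seed = 1L,
                                  max_generations = 100L * N) {
  stopifnot(N >= 2, replicates >= 1, x0 >= 0, x0 <= 1)
  structure(list(N = as.integer(N), fit = fit, model = model,
                 x0 = as.numeric(x0), replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 max_generations = as.integer(max_generations)),
            class = "stochastic_run_config")
}

.model_codes <- function(model) {
  if (model$variant == "affinity")
    list(variant = 0L, p1 = model$beta1, p2 = model$beta2)
  else
    list(variant = 1L, p1 = model$gamma1, p2 = model$gamma2)
}

#' One Wright-Fisher generation on phenogenotype counts
#'
#' Multinomial resampling of the four phenogenotype classes with expected
#' frequencies given by the exact transmission-table engine
#' (\code{\link{next_generation_exact}}). This is the infinite-gamete
#' Wright-Fisher construction: random union of gametes, selection and
#' transmission in expectation, then drift by multinomial sampling of N
#' offspring.
#'
#' @param counts integer vector of four phenogenotype counts (AC, aC, Ac,
#'   ac) summing to N.
#' @param fit a \code{\link{fitness_params}}.
#' @param model a \code{\link{transmission_model}}.
#' @return integer vector of next-generation counts summing to N.
#' @export
wf_step <- function(counts, fit, model) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  N <- sum(counts)
  state <- pheno_state_from_frequencies(counts / N)
  nxt <- next_generation_exact(state, fit, model)
  drop(stats::rmultinom(1L, N, pheno_frequencies(nxt)))
}

#' Fate of a single new A copy in a finite population
#'
#' Introduces exactly one copy of allele A into a population of size N whose
#' residents all carry a and whose cultural backgrounds are set to frequency
#' \code{x0} (deterministic rounding); the mutant's own cultural background
#' is C with probability \code{x0}, or can be forced. The population is then
#' iterated by \code{\link{wf_step}} until A fixes or is lost.
#'
#' @param config a \code{\link{stochastic_run_config}}.
#' @param background \code{"random"} (C with probability x0), \code{"C"} or
#'   \code{"c"}: cultural background of the initial A copy.
#' @return list with elements \code{outcome} (\code{"A_fixed"},
#'   \code{"A_lost"} or \code{"timeout"}), \code{t_fix} (generation of
#'   absorption) and \code{origin_background} (\code{"C"} or \code{"c"}).
#' @export
run_replicate <- function(config, background = c("random", "C", "c")) {
  background <- match.arg(background)
  N <- config$N
  n_C_res <- round(config$x0 * (N - 1))
  on_C <- switch(background,
                 random = stats::runif(1) < config$x0,
                 C = TRUE, c = FALSE)
  counts <- c(as.integer(on_C), n_C_res, as.integer(!on_C), N - 1 - n_C_res)
  t <- 0L
  repeat {
    nA <- counts[1] + counts[3]
    if (nA == 0L)
      return(list(outcome = "A_lost", t_fix = t,
                  origin_background = if (on_C) "C" else "c"))
    if (nA == N)
      return(list(outcome = "A_fixed", t_fix = t,
                  origin_background = if (on_C) "C" else "c"))
    if (t >= config$max_generations)
      return(list(outcome = "timeout", t_fix = t,
                  origin_background = if (on_C) "C" else "c"))
    counts <- wf_step(counts, config$fit, config$model)
    t <- t + 1L
  }
}

# Batch replicate runner backed by the C++ core (same construction as
# run_replicate). background: -1 random, 0 c, 1 C.
.replicates_batch <- function(config, background = -1L) {
  mc <- .model_codes(config$model)
  cpp_interference_replicates(config$N, config$fit$s_A, config$fit$s_C,
                              mc$variant, mc$p1, mc$p2, config$x0,
                              config$replicates, config$max_generations,
                              as.integer(background))
}

#' Fixation probability and time under cultural interference
#'
#' Estimates the fixation probability and the conditional mean fixation time
#' of a new beneficial allele A in the presence of a segregating, selected
#' cultural trait, together with a no-culture baseline computed with
#' identical machinery but the cultural trait fixed at its ancestral state
#' (x0 = 0, so culture is monomorphic and inert). Ratios of the two quantify
#' selective interference: a probability ratio below 1 means the cultural
#' sweep hinders the genetic sweep (the gene-culture Hill-Robertson effect);
#' above 1, cultural selection facilitates fixation.
#'
#' @param config a \code{\link{stochastic_run_config}}; \code{config$seed}
#'   seeds the RNG for the whole experiment.
#' @param baseline_x0 cultural frequency of the baseline comparator
#'   (default 0: monomorphic c; with multiplicative fitness, x0 = 1 gives
#'   identical A-dynamics).
#' @return an object of class \code{fixation_result}: a list with the
#'   estimated \code{p_fix} and binomial standard error, conditional
#'   \code{t_fix_mean} and standard error, \code{n_fixed}, \code{n_timeout},
#'   baseline analogues, and \code{p_fix_ratio} / \code{t_fix_ratio}.
#' @examples
#' \donttest{
#' cfg <- stochastic_run_config(N = 200, replicates = 2000, seed = 7,
#'                              model = affinity_bias(0.001, 0.001))
#' fixation_experiment(cfg)
#' }
#' @export
fixation_experiment <- function(config, baseline_x0 = 0) {
  set.seed(config$seed)
  trt <- .replicates_batch(config)
  base_cfg <- config
  base_cfg$x0 <- baseline_x0
  base <- .replicates_batch(base_cfg)
  summarise <- function(r, n) {
    fixed <- r$outcome == 1L
    p <- mean(fixed)
    tf <- r$t_fix[fixed]
    list(p_fix = p,
         p_fix_se = sqrt(p * (1 - p) / n),
         t_fix_mean = if (any(fixed)) mean(tf) else NA_real_,
         t_fix_se = if (sum(fixed) > 1) stats::sd(tf) / sqrt(length(tf)) else NA_real_,
         n_fixed = sum(fixed),
         n_timeout = sum(r$outcome == -1L))
  }
  s_t <- summarise(trt, config$replicates)
  s_b <- summarise(base, config$replicates)
  structure(list(
    config = config,
    treatment = s_t,
    baseline = s_b,
    p_fix = s_t$p_fix, p_fix_se = s_t$p_fix_se,
    t_fix_mean = s_t$t_fix_mean, t_fix_se = s_t$t_fix_se,
    n_fixed = s_t$n_fixed,
    p_fix_baseline = s_b$p_fix,
    t_fix_baseline = s_b$t_fix_mean,
    p_fix_ratio = if (s_b$p_fix > 0) s_t$p_fix / s_b$p_fix else NA_real_,
    t_fix_ratio = if (!is.na(s_b$t_fix_mean) && s_b$t_fix_mean > 0)
      s_t$t_fix_mean / s_b$t_fix_mean else NA_real_,
    origin_background = ifelse(trt$origin == 1L, "C", "c"),
    outcome = c("A_lost", "A_fixed", "timeout")[match(trt$outcome, c(0L, 1L, -1L))],
    t_fix = trt$t_fix),
    class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("<fixation_result> N = %d, replicates = %d\n",
              x$config$N, x$config$replicates))
  cat(sprintf("  p_fix       = %.5f (SE %.5f)  [baseline %.5f]  ratio %.3f\n",
              x$p_fix, x$p_fix_se, x$p_fix_baseline, x$p_fix_ratio))
  cat(sprintf("  t_fix | fix = %.1f (SE %.2f)   [baseline %.1f]  ratio %.3f\n",
              x$t_fix_mean, x$t_fix_se, x$t_fix_baseline, x$t_fix_ratio))
  invisible(x)
}

#' Haploid diffusion fixation probability (independent reference)
#'
#' Closed-form diffusion approximation for the fixation probability of a
#' single new mutant with selective advantage s in a haploid Wright-Fisher
#' population of size N: (1 - exp(-2s)) / (1 - exp(-2Ns)). For s = 0 this is
#' the neutral value 1/N; for large Ns and small s it approaches 2s.
#'
#' @param N population size (>= 2).
#' @param s selection coefficient.
#' @return scalar fixation probability.
#' @export
kimura_reference <- function(N, s) {
  stopifnot(N >= 2)
  if (s == 0) return(1 / N)
  (1 - exp(-2 * s)) / (1 - exp(-2 * N * s))
}
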