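#' Population state of the gene-culture system
#'
#' The joint state of a haploid biallelic genetic locus (alleles A/a) and a
#' binary vertically transmitted cultural trait (C/c) is summarised by three
#' frequencies: \code{x}, the frequency of cultural trait C; \code{Q}, the
#' frequency of allele A among C-practitioners; and \code{R}, the frequency of
#' allele A among c-practitioners. The four phenogenotype frequencies are then
#' AC = xQ, aC = x(1-Q), Ac = (1-x)R, ac = (1-x)(1-R).
#'
#' At the boundaries the conditional frequencies are undefined: when
#' \code{x = 0} there are no C-practitioners so \code{Q} carries a canonical
#' placeholder (0.5) and is flagged unused; likewise \code{R} when
#' \code{x = 1}. This avoids NaN propagation without affecting any
#' phenogenotype frequency.
#'
#' @param x frequency of cultural trait C, in [0, 1].
#' @param Q frequency of allele A among C-practitioners, in [0, 1]. Ignored
#'   (placeholder 0.5) when \code{x = 0}.
#' @param R frequency of allele A among c-practitioners, in [0, 1]. Ignored
#'   (placeholder 0.5) when \code{x = 1}.
#' @return an object of class \code{pheno_state}: a list with elements
#'   \code{x}, \code{Q}, \code{R} and logical flags \code{Q_defined},
#'   \code{R_defined}.
#' @examples
#' st <- pheno_state(x = 0.3, Q = 0.4, R = 0.6)
#' pheno_frequencies(st)
#' allele_freq(st)
#' @export
pheno_state <- function(x, Q = 0.5, R = 0.5) {
  stopifnot(length(x) == 1L, length(Q) == 1L, length(R) == 1L)
  if (is.na(x) || x < 0 || x > 1) stop("x must be in [0, 1]")
  q_def <- x > 0
  r_def <- x < 1
  if (q_def && (is.na(Q) || Q < 0 || Q > 1)) stop("Q must be in [0, 1]")
  if (r_def && (is.na(R) || R < 0 || R > 1)) stop("R must be in [0, 1]")
  structure(
    list(x = as.numeric(x),
         Q = if (q_def) as.numeric(Q) else 0.5,
         R = if (r_def) as.numeric(R) else 0.5,
         Q_defined = q_def, R_defined = r_def),
    class = "pheno_state")
}

#' @export
print.pheno_state <- function(x, ...) {
  cat(sprintf("<pheno_state> x = %g, Q = %g%s, R = %g%s\n",
              x$x, x$Q, if (x$Q_defined) "" else " (unused)",
              x$R, if (x$R_defined) "" else " (unused)"))
  f <- pheno_frequencies(x)
  cat(sprintf("  freqs: AC = %g, aC = %g, Ac = %g, ac = %g;  p(A) = %g\n",
              f[1], f[2], f[3], f[4], allele_freq(x)))
  invisible(x)
}

#' Selection coefficients of the gene-culture system
#'
#' Fitness is multiplicative over the genetic and cultural components:
#' W_AC = (1+s_C)(1+s_A), W_aC = 1+s_C, W_Ac = 1+s_A, W_ac = 1. With
#' \code{s_A = 0} this reduces to the neutral-locus scheme in which only the
#' cultural trait is under selection.
#'
#' @param s_A selective advantage of allele A (>= -1).
#' @param s_C selective advantage of cultural trait C (>= -1).
#' @return an object of class \code{fitness_params}.
#' @export
fitness_params <- function(s_A = 0, s_C = 0) {
  stopifnot(is.numeric(s_A), is.numeric(s_C), s_A >= -1, s_C >= -1)
  structure(list(s_A = as.numeric(s_A), s_C = as.numeric(s_C)),
            class = "fitness_params")
}

#' Phenogenotype fitnesses
#'
#' @param fit a \code{\link{fitness_params}} object.
#' @return named numeric vector \code{c(AC, aC, Ac, ac)} of fitnesses.
#' @export
pheno_fitnesses <- function(fit) {
  c(AC = (1 + fit$s_C) * (1 + fit$s_A),
    aC = 1 + fit$s_C,
    Ac = 1 + fit$s_A,
    ac = 1)
}

#' Vertical cultural transmission models
#'
#' Two rules govern which parental cultural trait an offspring adopts when its
#' parents differ culturally.
#'
#' \emph{Affinity bias}: the offspring copies the trait of its genetically
#' more similar parent (matching at the focal locus) with probability
#' \code{1 - beta_i}, and of the less similar parent with probability
#' \code{beta_i} (\code{beta1} for A-bearing offspring, \code{beta2} for
#' a-bearing). The betas play the role of recombination rates between gene and
#' culture. When both parents are equally similar, a random parent is copied.
#'
#' \emph{Cultural trait bias}: the offspring's own genotype biases it toward
#' trait C: A-bearing offspring adopt C with probability \code{gamma1},
#' a-bearing with probability \code{gamma2}, whenever the parents differ.
#'
#' With \code{beta1 = beta2 = 1/2} and \code{gamma1 = gamma2 = 1/2} the two
#' rules coincide (copy a uniformly random parent).
#'
#' @param beta1,beta2 probability that an A-bearing / a-bearing offspring
#'   copies the cultural trait of its genetically less similar parent, in
#'   [0, 1].
#' @param gamma1,gamma2 bias of an A-bearing / a-bearing offspring toward
#'   trait C when parents differ culturally, in [0, 1].
#' @return an object of class \code{transmission_model} with a
#'   \code{variant} field (\code{"affinity"} or \code{"trait_bias"}).
#' @examples
#' affinity_bias(0.05, 0.001)
#' trait_bias(0.75, 0.5)
#' @export
affinity_bias <- function(beta1, beta2) {
  stopifnot(beta1 >= 0, beta1 <= 1, beta2 >= 0, beta2 <= 1)
  structure(list(variant = "affinity",
                 beta1 = as.numeric(beta1), beta2 = as.numeric(beta2)),
            class = "transmission_model")
}

#' @rdname affinity_bias
#' @export
trait_bias <- function(gamma1, gamma2) {
  stopifnot(gamma1 >= 0, gamma1 <= 1, gamma2 >= 0, gamma2 <= 1)
  structure(list(variant = "trait_bias",
                 gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2)),
            class = "transmission_model")
}

#' @export
print.transmission_model <- function(x, ...) {
  if (x$variant == "affinity")
    cat(sprintf("<transmission_model> affinity bias: beta1 = %g, beta2 = %g\n",
                x$beta1, x$beta2))
  else
    cat(sprintf("<transmission_model> cultural trait bias: gamma1 = %g, gamma2 = %g\n",
                x$gamma1, x$gamma2))
  invisible(x)
}

.pheno_names <- c("AC", "aC", "Ac", "ac")

#' Phenogenotype frequencies of a population state
#'
#' @param state a \code{\link{pheno_state}}.
#' @return named numeric vector \code{c(AC, aC, Ac, ac)} summing to 1.
#' @export
pheno_frequencies <- function(state) {
  stopifnot(inherits(state, "pheno_state"))
  x <- state$x; Q <- state$Q; R <- state$R
  out <- c(x * Q, x * (1 - Q), (1 - x) * R, (1 - x) * (1 - R))
  names(out) <- .pheno_names
  out
}

#' Reconstruct a pheno_state from phenogenotype frequencies
#'
#' @param f numeric vector of four nonnegative frequencies in the order
#'   (AC, aC, Ac, ac); normalised internally.
#' @return a \code{\link{pheno_state}}.
#' @export
pheno_state_from_frequencies <- function(f) {
  stopifnot(length(f) == 4L, all(f >= -1e-15))
  f <- pmax(f, 0)
  f <- f / sum(f)
  x <- f[1] + f[2]
  Q <- if (x > 0) f[1] / x else 0.5
  R <- if (x < 1) f[3] / (1 - x) else 0.5
  pheno_state(min(x, 1), min(Q, 1), min(R, 1))
}

#' Population frequency of allele A
#'
#' p = xQ + (1-x)R.
#'
#' @param state a \code{\link{pheno_state}}.
#' @return scalar frequency of allele A.
#' @export
allele_freq <- function(state) {
  state$x * state$Q + (1 - state$x) * state$R
}

#' Mean fitness of the population
#'
#' Frequency-weighted mean of the four phenogenotype fitnesses. With
#' \code{s_A = 0} this equals \code{1 + x * s_C} exactly.
#'
#' @param state a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @return scalar mean fitness.
#' @export
mean_fitness <- function(state, fit) {
  sum(pheno_frequencies(state) * pheno_fitnesses(fit))
}

# The ten mating classes, as unordered pairs of phenogenotypes. Order is the
# canonical one used throughout the package (and by the C++ simulator cores).
.mating_pairs <- matrix(c(
  1L, 1L,   # AC x AC
  1L, 2L,   # AC x aC
  1L, 3L,   # AC x Ac
  1L, 4L,   # AC x ac
  2L, 2L,   # aC x aC
  2L, 3L,   # aC x Ac
  2L, 4L,   # aC x ac
  3L, 3L,   # Ac x Ac
  3L, 4L,   # Ac x ac
  4L, 4L),  # ac x ac
  ncol = 2L, byrow = TRUE)

#' Names of the ten mating classes
#'
#' @return character vector of the ten unordered phenogenotype pairings, e.g.
#'   \code{"AC x ac"}.
#' @export
mating_classes <- function() {
  apply(.mating_pairs, 1L, function(ij)
    paste(.pheno_names[ij[1]], "x", .pheno_names[ij[2]]))
}

#' Fitness-weighted mating frequencies
#'
#' Random union of phenogenotypes (with replacement), weighted by fitness and
#' normalised by the squared mean fitness; cross-class matings are counted
#' once with the factor 2 of the unordered pairing. The ten frequencies sum
#' to 1.
#'
#' @param state a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @return named numeric vector of length 10 over \code{\link{mating_classes}}.
#' @export
mating_frequencies <- function(state, fit) {
  f <- pheno_frequencies(state)
  g <- f * pheno_fitnesses(fit)   # fitness-weighted parental contributions
  wbar <- sum(g)
  i <- .mating_pairs[, 1L]; j <- .mating_pairs[, 2L]
  m <- ifelse(i == j, g[i] * g[j], 2 * g[i] * g[j]) / wbar^2
  names(m) <- mating_classes()
  m
}

# 10 x 4 matrix of offspring phenogenotype probabilities, one row per mating
# class, columns (AC, aC, Ac, ac).
.offspring_matrix <- function(model) {
  if (model$variant == "affinity") {
    b1 <- model$beta1; b2 <- model$beta2
    rows <- rbind(
      c(1, 0, 0, 0),                                        # AC x AC
      c(0.5, 0.5, 0, 0),                                    # AC x aC
      c(0.5, 0, 0.5, 0),                                    # AC x Ac
      c((1 - b1) / 2, b2 / 2, b1 / 2, (1 - b2) / 2),        # AC x ac
      c(0, 1, 0, 0),                                        # aC x aC
      c(b1 / 2, (1 - b2) / 2, (1 - b1) / 2, b2 / 2),        # aC x Ac
      c(0, 0.5, 0, 0.5),                                    # aC x ac
      c(0, 0, 1, 0),                                        # Ac x Ac
      c(0, 0, 0.5, 0.5),                                    # Ac x ac
      c(0, 0, 0, 1))                                        # ac x ac
  } else {
    g1 <- model$gamma1; g2 <- model$gamma2
    rows <- rbind(
      c(1, 0, 0, 0),                                        # AC x AC
      c(0.5, 0.5, 0, 0),                                    # AC x aC
      c(g1, 0, 1 - g1, 0),                                  # AC x Ac
      c(g1 / 2, g2 / 2, (1 - g1) / 2, (1 - g2) / 2),        # AC x ac
      c(0, 1, 0, 0),                                        # aC x aC
      c(g1 / 2, g2 / 2, (1 - g1) / 2, (1 - g2) / 2),        # aC x Ac
      c(0, g2, 0, 1 - g2),                                  # aC x ac
      c(0, 0, 1, 0),                                        # Ac x Ac
      c(0, 0, 0.5, 0.5),                                    # Ac x ac
      c(0, 0, 0, 1))                                        # ac x ac
  }
  dimnames(rows) <- list(mating_classes(), .pheno_names)
  rows
}

#' Offspring phenogenotype distribution of a mating class
#'
#' Returns the distribution of offspring phenogenotypes for one of the ten
#' mating classes under the given transmission rule. Genetic transmission is
#' always unbiased: the expected offspring allele-A frequency equals the
#' parental mean for every class and any bias parameters.
#'
#' @param mating a mating class name as returned by
#'   \code{\link{mating_classes}} (e.g. \code{"AC x ac"}), or its index 1-10.
#' @param model a \code{\link{transmission_model}}.
#' @return named numeric vector \code{c(AC, aC, Ac, ac)}, nonnegative, summing
#'   to 1.
#' @examples
#' offspring_distribution("AC x ac", affinity_bias(0.05, 0.001))
#' offspring_distribution("AC x aC", trait_bias(0.8, 0.2))
#' @export
offspring_distribution <- function(mating, model) {
  stopifnot(inherits(model, "transmission_model"))
  classes <- mating_classes()
  if (is.character(mating)) {
    idx <- match(mating, classes)
    if (is.na(idx)) stop("unknown mating class: ", mating)
  } else {
    idx <- as.integer(mating)
    if (is.na(idx) || idx < 1L || idx > 10L)
      stop("mating class index must be in 1..10")
  }
  .offspring_matrix(model)[idx, ]
}

#' Exact one-generation update from the transmission table
#'
#' The authoritative expectation engine: sums the fitness-weighted mating
#' frequencies times the offspring distributions over all ten mating classes
#' to give next-generation phenogenotype frequencies. All closed-form
#' recursions in the package are verified against this engine.
#'
#' @param state a \code{\link{pheno_state}}.
#' @param fit a \code{\link{fitness_params}}.
#' @param model a \code{\link{transmission_model}}.
#' @return the next-generation \code{\link{pheno_state}}.
#' @examples
#' st <- pheno_state(0.5, 1, 0.5)
#' next_generation_exact(st, fitness_params(0, 0.1), affinity_bias(0.05, 0.001))
#' @export
next_generation_exact <- function(state, fit, model) {
  m <- mating_frequencies(state, fit)
  f_next <- drop(m %*% .offspring_matrix(model))
  pheno_state_from_frequencies(f_next)
}

# Vectorised engine over many states: x, Q, R numeric vectors of equal
# length. Returns an n x 4 matrix of next-generation phenogenotype
# frequencies. Used by the deterministic iteration and the property tests.
.next_gen_freqs_vec <- function(x, Q, R, fit, model) {
  W <- pheno_fitnesses(fit)
  f <- cbind(x * Q, x * (1 - Q), (1 - x) * R, (1 - x) * (1 - R))
  g <- sweep(f, 2L, W, `*`)
  wbar <- rowSums(g)
  i <- .mating_pairs[, 1L]; j <- .mating_pairs[, 2L]
  # n x 10 mating-frequency matrix
  m <- g[, i, drop = FALSE] * g[, j, drop = FALSE]
  m[, i != j] <- 2 * m[, i != j, drop = FALSE]
  m <- m / wbar^2
  out <- m %*% .offspring_matrix(model)
  colnames(out) <- .pheno_names
  out
}
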