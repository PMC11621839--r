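#' Configuration of the multilocus chromosome simulation
#'
#' Five biallelic loci lie on a chromosome with the focal locus at the
#' centre (index 3 of 5); the two inner flanks sit at recombination distance
#' \code{r_near} from the focal locus and the two outer flanks at
#' \code{r_far}. Adjacent-interval crossover probabilities are derived from
#' the distances to the focal locus under independent intervals
#' (r_outer combines with r_near as r_far = r_outer(1 - r_near) +
#' r_near(1 - r_outer)). A binary cultural trait is transmitted vertically
#' with gc-pseudolinkage to the focal locus.
#'
#' @param N population size.
#' @param mu per-locus per-generation symmetric mutation rate; the focal
#'   locus is exempt.
#' @param r_near,r_far recombination distances from the inner/outer flanking
#'   loci to the focal locus, each in [0, 0.5].
#' @param burn_in_generations neutral generations before any sweep (default
#'   5N).
#' @param sweep_type \code{"cultural"}, \code{"genetic"} or \code{"none"}.
#' @param s selection coefficient of the favoured element (s_C for cultural
#'   sweeps, s_A for genetic sweeps).
#' @param model a \code{\link{transmission_model}} governing cultural
#'   transmission.
#' @param min_sweeps number of successful sweeps to collect.
#' @param independent_burnins if TRUE each sweep attempt starts from its own
#'   full burn-in; the default shares one burn-in and lets the neutral
#'   reservoir drift for \code{perturb_generations} between attempts.
#' @param perturb_generations drift generations between attempts in shared
#'   mode (default N/10).
#' @param max_generations cap per sweep attempt.
#' @param max_attempts cap on total attempts.
#' @return an object of class \code{chromosome_config}.
#' @export
chromosome_config <- function(N = 1000L, mu = 1e-4, r_near = 0.001,
                              r_far = 0.2, burn_in_generations = 5L * N,
                              sweep_type = c("cultural", "genetic", "none"),
                              s = 0.1, model = affinity_bias(0.001, 0.001),
                              min_sweeps = 100L,
                              independent_burnins = FALSE,
                              perturb_generations = max(1L, N %/% 10L),
                              max_generations = 100L * N,
                              max_attempts = 10000L) {
  sweep_type <- match.arg(sweep_type)
  stopifnot(r_near >= 0, r_near <= 0.5, r_far >= 0, r_far <= 0.5,
            r_far >= r_near)
  structure(list(N = as.integer(N), mu = mu, r_near = r_near, r_far = r_far,
                 r_adj = adjacent_recomb(r_near, r_far),
                 burn_in_generations = as.integer(burn_in_generations),
                 sweep_type = sweep_type, s = s, model = model,
                 min_sweeps = as.integer(min_sweeps),
                 independent_burnins = independent_burnins,
                 perturb_generations = as.integer(perturb_generations),
                 max_generations = as.integer(max_generations),
                 max_attempts = as.integer(max_attempts)),
            class = "chromosome_config")
}

#' Adjacent-interval crossover probabilities from distances to the focal locus
#'
#' Locus layout is (outer, inner, focal, inner, outer). The inner interval
#' crossover probability equals \code{r_near}; the outer one solves
#' r_far = r_out (1 - r_near) + r_near (1 - r_out) so that independent
#' crossovers in the two intervals compose to the stated distance between
#' each outer flank and the focal locus.
#'
#' @param r_near,r_far recombination distances to the focal locus.
#' @return numeric vector of four adjacent-interval probabilities.
#' @export
adjacent_recomb <- function(r_near, r_far) {
  r_out <- (r_far - r_near) / (1 - 2 * r_near)
  c(r_out, r_near, r_near, r_out)
}

#' Recombination distances of the five loci to the focal locus
#'
#' @param config a \code{\link{chromosome_config}}.
#' @return numeric vector of length five, signed map coordinates
#'   (-r_far, -r_near, 0, r_near, r_far).
#' @export
map_positions <- function(config) {
  c(-config$r_far, -config$r_near, 0, config$r_near, config$r_far)
}

#' Produce one offspring from two parents (reference implementation)
#'
#' The single-offspring rule of the multilocus simulator, in R: free choice
#' of starting parent, independent crossovers in each adjacent interval,
#' symmetric mutation at the non-focal loci, then cultural transmission by
#' the configured rule evaluated on the offspring's focal-locus allele and
#' the parents' traits. \code{n} i.i.d. offspring are drawn at once.
#'
#' @param parent1,parent2 lists with fields \code{genome} (integer vector of
#'   five 0/1 alleles) and \code{trait} (0 = c, 1 = C).
#' @param model a \code{\link{transmission_model}}.
#' @param r_adj numeric vector of four adjacent-interval crossover
#'   probabilities.
#' @param mu mutation rate (focal locus exempt).
#' @param n number of offspring to draw.
#' @return list with \code{genome} (n x 5 integer matrix) and \code{trait}
#'   (length-n integer vector).
#' @export
make_offspring <- function(parent1, parent2, model, r_adj = rep(0, 4),
                           mu = 0, n = 1L) {
  stopifnot(length(parent1$genome) == 5L, length(parent2$genome) == 5L)
  g1 <- parent1$genome; g2 <- parent2$genome
  # which parent each locus is copied from: cumulative XOR of switches
  start <- stats::runif(n) < 0.5
  switches <- matrix(stats::runif(n * 4) < rep(r_adj, each = n), n, 4)
  from2 <- matrix(FALSE, n, 5)
  from2[, 1] <- start
  for (l in 2:5) from2[, l] <- xor(from2[, l - 1], switches[, l - 1])
  genome <- matrix(rep(g1, each = n), n, 5)
  g2m <- matrix(rep(g2, each = n), n, 5)
  genome[from2] <- g2m[from2]
  if (mu > 0) {
    flips <- matrix(stats::runif(n * 5) < mu, n, 5)
    flips[, 3] <- FALSE
    genome[flips] <- 1L - genome[flips]
  }
  t1 <- parent1$trait; t2 <- parent2$trait
  if (t1 == t2) {
    trait <- rep(t1, n)
  } else {
    off_focal <- genome[, 3]
    if (model$variant == "affinity") {
      f1 <- g1[3]; f2 <- g2[3]
      beta <- ifelse(off_focal == 1L, model$beta1, model$beta2)
      if (f1 == f2) {
        trait <- ifelse(stats::runif(n) < 0.5, t1, t2)
      } else {
        sim_trait <- ifelse(f1 == off_focal, t1, t2)
        oth_trait <- ifelse(f1 == off_focal, t2, t1)
        trait <- ifelse(stats::runif(n) < beta, oth_trait, sim_trait)
      }
    } else {
      gma <- ifelse(off_focal == 1L, model$gamma1, model$gamma2)
      trait <- as.integer(stats::runif(n) < gma)
    }
  }
  list(genome = genome, trait = as.integer(trait))
}

#' Neutral burn-in to mutation-drift balance
#'
#' Runs the population from a monomorphic start for
#' \code{burn_in_generations} neutral generations. The focal locus stays
#' monomorphic ancestral (no mutation there) and all traits remain c.
#'
#' @param config a \code{\link{chromosome_config}}.
#' @param record_every if positive, per-locus heterozygosity is recorded
#'   every that many generations.
#' @return list with \code{genome} (N x 5 matrix), \code{het} (final
#'   per-locus heterozygosity) and \code{het_series} (matrix of recorded
#'   heterozygosities, possibly 0 rows).
#' @export
neutral_burn_in <- function(config, record_every = 0L) {
  mc <- .model_codes(config$model)
  cpp_burn_in(config$N, config$mu, config$r_adj, mc$variant, mc$p1, mc$p2,
              config$burn_in_generations, as.integer(record_every))
}

#' Replicated sweep experiment on the five-locus chromosome
#'
#' After burn-in, repeatedly introduces the favoured element in a single
#' random individual and tracks it to fixation or loss. A genetic sweep
#' introduces one copy of a beneficial allele at the focal locus. A cultural
#' sweep introduces the favoured trait C together with a single new neutral
#' marker allele at the focal position in the same individual: the trait
#' arises once on a unique genetic background (the single-origin convention
#' of the single-locus model) and remains associated with it only through
#' the vertical-transmission rule, so low mixing drags the founder
#' haplotype upward (hard-sweep-like) while high mixing lets the trait fix
#' without moving the genome. Only fixations are kept; attempts repeat
#' until \code{min_sweeps} successes. With \code{sweep_type = "none"} the
#' standing neutral variation is recorded instead, once per replicate.
#'
#' @param config a \code{\link{chromosome_config}}.
#' @param seed optional RNG seed applied before the run.
#' @return an object of class \code{sweep_experiment}: a list with
#'   \code{heterozygosity} (data.frame: sweep_id, locus, map_distance, het),
#'   \code{haplotypes} (data.frame: sweep_id, haplotype, count; 5-character
#'   binary strings), \code{durations}, \code{successes}, \code{attempts}.
#' @export
sweep_experiment <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mc <- .model_codes(config$model)
  st <- match(config$sweep_type, c("genetic", "cultural", "none")) - 1L
  res <- cpp_chromosome_experiment(
    config$N, config$mu, config$r_adj, mc$variant, mc$p1, mc$p2, st,
    config$s, config$burn_in_generations, config$min_sweeps,
    config$perturb_generations, config$independent_burnins,
    config$max_generations, config$max_attempts)
  k <- res$successes
  if (k < config$min_sweeps)
    warning(sprintf("only %d of %d sweeps succeeded within max_attempts",
                    k, config$min_sweeps))
  het <- res$het[seq_len(k), , drop = FALSE]
  hap <- res$hap[seq_len(k), , drop = FALSE]
  pos <- map_positions(config)
  het_df <- data.frame(
    sweep_id = rep(seq_len(k), each = 5L),
    locus = rep(1:5, k),
    map_distance = rep(pos, k),
    heterozygosity = as.vector(t(het)))
  labels <- vapply(0:31, function(h)
    paste(rev(as.integer(intToBits(h))[1:5]), collapse = ""), character(1))
  nz <- which(hap > 0, arr.ind = TRUE)
  hap_df <- data.frame(
    sweep_id = nz[, 1],
    haplotype = labels[nz[, 2]],
    count = hap[nz])
  hap_df <- hap_df[order(hap_df$sweep_id, -hap_df$count), ]
  rownames(hap_df) <- NULL
  structure(list(heterozygosity = het_df, haplotypes = hap_df,
                 durations = res$duration[seq_len(k)],
                 successes = k, attempts = res$attempts,
                 config = config),
            class = "sweep_experiment")
}

#' @export
print.sweep_experiment <- function(x, ...) {
  cat(sprintf("<sweep_experiment> %s sweeps: %d successes / %d attempts (N = %d)\n",
              x$config$sweep_type, x$successes, x$attempts, x$config$N))
  m <- tapply(x$heterozygosity$heterozygosity, x$heterozygosity$locus, mean)
  cat("  mean per-locus heterozygosity:",
      paste(sprintf("%.4f", m), collapse = "  "), "\n")
  invisible(x)
}

#' Per-locus expected heterozygosity of a population
#'
#' 2p(1-p) at each locus, with p the derived-allele frequency.
#'
#' @param genome an N x L matrix of 0/1 alleles (individuals in rows).
#' @return numeric vector of L heterozygosities.
#' @export
locus_heterozygosities <- function(genome) {
  stopifnot(is.matrix(genome), nrow(genome) >= 1L)
  p <- colMeans(genome)
  2 * p * (1 - p)
}
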