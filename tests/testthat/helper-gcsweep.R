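# Random draw helpers shared across the suite.

random_state <- function() {
  pheno_state(runif(1), runif(1), runif(1))
}

random_fit <- function(neutral_A = TRUE) {
  fitness_params(if (neutral_A) 0 else runif(1, -0.5, 1), runif(1, -0.5, 1))
}

random_model <- function(variant = sample(c("affinity", "trait_bias"), 1)) {
  if (variant == "affinity") affinity_bias(runif(1), runif(1))
  else trait_bias(runif(1), runif(1))
}

# allele-A frequency implied by a vector/matrix of phenogenotype frequencies
freq_A <- function(f) {
  if (is.matrix(f)) f[, 1] + f[, 3] else f[1] + f[3]
}

# mean allele-A frequency of a mating class (index 1..10): average of the two
# parents' A indicator
parental_A_mean <- local({
  has_A <- c(1, 0, 1, 0)  # AC, aC, Ac, ac
  pairs <- rbind(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(2, 2), c(2, 3),
                 c(2, 4), c(3, 3), c(3, 4), c(4, 4))
  function(k) mean(has_A[pairs[k, ]])
})
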