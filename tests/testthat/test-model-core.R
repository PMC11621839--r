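test_that("phenogenotype frequencies follow the (x, Q, R) parameterisation", {
  expect_equal(unname(pheno_frequencies(pheno_state(1, 1))), c(1, 0, 0, 0))
  expect_equal(unname(pheno_frequencies(pheno_state(0.5, 1, 0))),
               c(0.5, 0, 0, 0.5))
  expect_equal(unname(pheno_frequencies(pheno_state(0.3, 0.4, 0.6))),
               c(0.12, 0.18, 0.42, 0.28))
  set.seed(101)
  for (i in 1:200) {
    f <- pheno_frequencies(random_state())
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-14)
  }
})

test_that("boundary states carry placeholder conditionals without NaN", {
  s0 <- pheno_state(0, R = 0.3)
  expect_false(s0$Q_defined)
  expect_equal(s0$Q, 0.5)
  expect_equal(allele_freq(s0), 0.3)
  s1 <- pheno_state(1, Q = 0.7)
  expect_false(s1$R_defined)
  expect_equal(allele_freq(s1), 0.7)
  expect_error(pheno_state(1.2), "x must be")
})

test_that("mean fitness reduces to 1 + x s_C for a neutral A locus", {
  expect_equal(mean_fitness(pheno_state(0.5, 0.3, 0.9),
                            fitness_params(0, 0.1)), 1.05)
  expect_equal(mean_fitness(pheno_state(0.8, 0.1, 0.2),
                            fitness_params(0, 0)), 1)
  # selected case: weighted sum over the multiplicative fitness scheme
  expect_equal(mean_fitness(pheno_state(0.5, 1, 0),
                            fitness_params(0.1, 0.1)),
               0.5 * 1.21 + 0.5 * 1)
  set.seed(102)
  for (i in 1:100) {
    st <- random_state(); fit <- random_fit(neutral_A = TRUE)
    expect_equal(mean_fitness(st, fit), 1 + st$x * fit$s_C, tolerance = 1e-14)
  }
})

test_that("mating frequencies are fitness-weighted random union summing to 1", {
  m <- mating_frequencies(pheno_state(1, 1), fitness_params(0, 0.3))
  expect_equal(unname(m["AC x AC"]), 1)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  # hand enumeration: only AC and ac present at 50/50, no selection
  m <- mating_frequencies(pheno_state(0.5, 1, 0), fitness_params(0, 0))
  expect_equal(unname(m[c("AC x AC", "AC x ac", "ac x ac")]),
               c(0.25, 0.5, 0.25))
  expect_equal(sum(m != 0), 3L)
  set.seed(103)
  for (i in 1:200) {
    m <- mating_frequencies(random_state(), random_fit(neutral_A = FALSE))
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("offspring distributions reproduce the transmission-table rows", {
  aff <- affinity_bias(0.3, 0.7)
  tb <- trait_bias(0.8, 0.2)
  for (model in list(aff, tb)) {
    expect_equal(unname(offspring_distribution("AC x AC", model)),
                 c(1, 0, 0, 0))
    expect_equal(unname(offspring_distribution("AC x aC", model)),
                 c(0.5, 0.5, 0, 0))
    expect_equal(unname(offspring_distribution("ac x ac", model)),
                 c(0, 0, 0, 1))
  }
  # the mixed mating AC x ac, written out
  expect_equal(unname(offspring_distribution("AC x ac", aff)),
               c((1 - 0.3) / 2, 0.7 / 2, 0.3 / 2, (1 - 0.7) / 2))
  expect_equal(unname(offspring_distribution("AC x ac", tb)),
               c(0.8 / 2, 0.2 / 2, (1 - 0.8) / 2, (1 - 0.2) / 2))
  # perfect copying preserves parental phenogenotypes
  expect_equal(unname(offspring_distribution("AC x ac", affinity_bias(0, 0))),
               c(0.5, 0, 0, 0.5))
  expect_error(offspring_distribution("AC x CC", aff), "unknown mating class")
})

test_that("genetic transmission is unbiased in every family", {
  set.seed(104)
  for (i in 1:50) {
    model <- random_model()
    for (k in 1:10) {
      d <- offspring_distribution(k, model)
      expect_equal(sum(d), 1, tolerance = 1e-15)
      expect_true(all(d >= 0))
      expect_equal(unname(d["AC"] + d["Ac"]), parental_A_mean(k),
                   tolerance = 1e-15)
    }
  }
})

test_that("the exact engine conserves frequency and fixed points", {
  fit0 <- fitness_params(0, 0)
  st <- pheno_state(0.37, 0.81, 0.12)
  # no selection, no mixing: state unchanged
  nxt <- next_generation_exact(st, fit0, affinity_bias(0, 0))
  expect_equal(pheno_frequencies(nxt), pheno_frequencies(st),
               tolerance = 1e-14)
  # monomorphic AC is absorbing
  nxt <- next_generation_exact(pheno_state(1, 1), fitness_params(0.2, 0.3),
                               trait_bias(0.9, 0.1))
  expect_equal(unname(pheno_frequencies(nxt)), c(1, 0, 0, 0))
  set.seed(105)
  x <- runif(2000); Q <- runif(2000); R <- runif(2000)
  for (variant in c("affinity", "trait_bias")) {
    model <- random_model(variant)
    f <- gcsweep:::.next_gen_freqs_vec(x, Q, R, random_fit(neutral_A = FALSE),
                                       model)
    expect_true(all(abs(rowSums(f) - 1) < 1e-12))
    expect_true(all(f > -1e-15))
  }
})

test_that("cultural transmission distortion in AC x ac families is (1-b1+b2)/2", {
  set.seed(106)
  for (i in 1:20) {
    b1 <- runif(1); b2 <- runif(1)
    d <- offspring_distribution("AC x ac", affinity_bias(b1, b2))
    expect_equal(unname(d["AC"] + d["aC"]), (1 - b1 + b2) / 2,
                 tolerance = 1e-15)
    d2 <- offspring_distribution("aC x Ac", affinity_bias(b1, b2))
    expect_equal(unname(d2["AC"] + d2["aC"]), (1 + b1 - b2) / 2,
                 tolerance = 1e-15)
    g1 <- runif(1); g2 <- runif(1)
    d3 <- offspring_distribution("AC x ac", trait_bias(g1, g2))
    expect_equal(unname(d3["AC"] + d3["aC"]), (g1 + g2) / 2,
                 tolerance = 1e-15)
  }
})

test_that("unbiased affinity and unbiased trait bias are the same rule", {
  set.seed(107)
  fit <- fitness_params(0.15, 0.25)
  for (i in 1:1000) {
    st <- random_state()
    a <- next_generation_exact(st, fit, affinity_bias(0.5, 0.5))
    b <- next_generation_exact(st, fit, trait_bias(0.5, 0.5))
    expect_equal(pheno_frequencies(a), pheno_frequencies(b),
                 tolerance = 1e-12)
  }
})

test_that("the C++ engine used by the simulators matches the R engine", {
  set.seed(108)
  for (i in 1:200) {
    st <- random_state(); fit <- random_fit(neutral_A = FALSE)
    model <- random_model()
    mc <- gcsweep:::.model_codes(model)
    f <- pheno_frequencies(st)
    cpp <- gcsweep:::cpp_next_gen_expected(unname(f), fit$s_A, fit$s_C,
                                           mc$variant, mc$p1, mc$p2)
    r <- pheno_frequencies(next_generation_exact(st, fit, model))
    expect_equal(cpp, unname(r), tolerance = 1e-13)
  }
})
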