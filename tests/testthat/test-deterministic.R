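test_that("closed-form recursions agree with the exact engine", {
  set.seed(201)
  n <- 10000
  x <- runif(n); Q <- runif(n); R <- runif(n)
  for (variant in c("affinity", "trait_bias")) {
    sC <- runif(1, -0.5, 1)
    b1 <- runif(1); b2 <- runif(1)
    fit <- fitness_params(0, sC)
    model <- if (variant == "affinity") affinity_bias(b1, b2)
             else trait_bias(b1, b2)
    engine <- gcsweep:::.next_gen_freqs_vec(x, Q, R, fit, model)
    closed <- gcsweep:::.step_model_vec(x, Q, R, fit, model)
    expect_lt(max(abs(engine - closed)), 1e-12)
  }
  # scalar interface spot checks, including the sweep-start state
  st <- pheno_state(0.5, 1, 0.5)
  fit <- fitness_params(0, 0.1)
  a <- step_affinity(st, fit, 0.05, 0.001)
  e <- next_generation_exact(st, fit, affinity_bias(0.05, 0.001))
  expect_equal(pheno_frequencies(a), pheno_frequencies(e), tolerance = 1e-13)
  tbs <- step_trait_bias(st, fit, 0.75, 0.5)
  et <- next_generation_exact(st, fit, trait_bias(0.75, 0.5))
  expect_equal(pheno_frequencies(tbs), pheno_frequencies(et),
               tolerance = 1e-13)
})

test_that("no gene-culture association means pure logistic selection on C", {
  set.seed(202)
  for (i in 1:50) {
    Q <- runif(1); x <- runif(1); sC <- runif(1, 0, 1)
    st <- pheno_state(x, Q, Q)  # Q = R: no association
    nxt <- step_affinity(st, fitness_params(0, sC), runif(1), runif(1))
    expect_equal(nxt$Q, Q, tolerance = 1e-12)
    expect_equal(nxt$x, x * (1 + sC) / (1 + x * sC), tolerance = 1e-12)
  }
  # unbiased trait bias without selection leaves x and p untouched while
  # random-parent copying mixes the backgrounds (Q and R converge)
  st <- pheno_state(0.4, 0.9, 0.2)
  nxt <- step_trait_bias(st, fitness_params(0, 0), 0.5, 0.5)
  expect_equal(nxt$x, st$x, tolerance = 1e-13)
  expect_equal(allele_freq(nxt), allele_freq(st), tolerance = 1e-13)
  expect_lt(abs(nxt$Q - nxt$R), abs(st$Q - st$R))
})

test_that("equal mixing rates reproduce classic two-locus hitchhiking exactly", {
  set.seed(203)
  for (i in 1:2000) {
    st <- random_state()
    s <- runif(1, 0, 0.5); r <- runif(1)
    a <- step_affinity(st, fitness_params(0, s), r, r)
    m <- msh_reference_step(st, s, r)
    expect_equal(pheno_frequencies(a), pheno_frequencies(m),
                 tolerance = 1e-12)
  }
  # r = 0: backgrounds never mix; s = 0: allele frequencies stay put while
  # recombination decays the disequilibrium by a factor (1 - r)
  st <- pheno_state(0.3, 0.9, 0.2)
  m0 <- msh_reference_step(st, 0.2, 0)
  expect_equal(m0$Q, st$Q); expect_equal(m0$R, st$R)
  mn <- msh_reference_step(st, 0, 0.3)
  expect_equal(mn$x, st$x, tolerance = 1e-14)
  expect_equal(allele_freq(mn), allele_freq(st), tolerance = 1e-14)
  D <- function(s) s$x * (1 - s$x) * (s$Q - s$R)
  expect_equal(D(mn), (1 - 0.3) * D(st), tolerance = 1e-12)
})

test_that("a cultural sweep drags the pseudolinked neutral allele upward", {
  traj <- run_sweep(pheno_state(1e-6, 1, 0.5), fitness_params(0, 0.1),
                    affinity_bias(0.05, 0.001), t_max = 200)
  expect_gt(attr(traj, "p_final"), 0.5)
  expect_equal(traj$p, traj$x * traj$Q + (1 - traj$x) * traj$R)
  expect_true(all(diff(traj$t) == 1))
  expect_true(all(traj$x >= 0 & traj$x <= 1))
  # without selection and with unbiased transmission x stays put
  flat <- run_sweep(pheno_state(0.2, 0.8, 0.5), fitness_params(0, 0),
                    affinity_bias(0.5, 0.5), t_max = 50)
  expect_equal(var(flat$x), 0)
  # strong bias against copying C loses the favoured innovation
  lost <- run_sweep(pheno_state(1e-3, 1, 0.5), fitness_params(0, 0.1),
                    trait_bias(0.05, 0.05), t_max = 200)
  expect_equal(attr(lost, "outcome"), "C_lost")
})

test_that("relative heterozygosity normalises by initial variation", {
  expect_equal(relative_heterozygosity(0.5, 0.5), 1)
  expect_equal(relative_heterozygosity(1, 0.5), 0)
  q <- seq(0, 1, by = 0.05)
  expect_equal(relative_heterozygosity(q, 0.5), 4 * q * (1 - q))
  expect_error(relative_heterozygosity(0.5, 0), "strictly inside")
  expect_error(relative_heterozygosity(0.5, 1), "strictly inside")
})

test_that("hitchhiking strengthens as the recombinant-producing rate drops", {
  surf <- heterozygosity_surface("affinity", 0.05, 10^seq(-5, -1),
                                 fit = fitness_params(0, 0.1),
                                 initial = pheno_state(1e-6, 1, 0.5))
  surf <- surf[order(surf$param2), ]
  expect_true(all(diff(surf$H_hat) >= -1e-12))  # H_hat grows with beta2
  # the beta1 = beta2 diagonal equals iterated two-locus hitchhiking
  for (b in c(0.01, 0.1)) {
    row <- heterozygosity_surface("affinity", b, b,
                                  fit = fitness_params(0, 0.1),
                                  initial = pheno_state(1e-6, 1, 0.5))
    st <- pheno_state(1e-6, 1, 0.5)
    for (t in 1:200) st <- msh_reference_step(st, 0.1, b)
    expect_equal(row$H_hat, relative_heterozygosity(st$Q, 0.5),
                 tolerance = 1e-9)
  }
})

test_that("trait-bias direction controls whether A gains or loses frequency", {
  init <- pheno_state(1e-4, 1, 0.5)
  fit <- fitness_params(0, 0.1)
  for (g1 in c(0.6, 0.75, 0.9)) {
    up <- run_sweep(init, fit, trait_bias(g1, 0.5), t_max = 400)
    expect_gte(attr(up, "p_final"), allele_freq(init))
  }
  for (g1 in c(0.2, 0.35)) {
    dn <- run_sweep(init, fit, trait_bias(g1, 0.5), t_max = 400)
    expect_lte(attr(dn, "p_final"), allele_freq(init))
  }
  # p is invariant under a generation iff Q = R or s_C = 0 (neutral A locus)
  st <- pheno_state(0.4, 0.9, 0.3)
  same_p <- step_affinity(st, fitness_params(0, 0), 0.2, 0.7)
  expect_equal(allele_freq(same_p), allele_freq(st), tolerance = 1e-13)
  moved <- step_affinity(st, fitness_params(0, 0.2), 0.2, 0.7)
  expect_gt(abs(allele_freq(moved) - allele_freq(st)), 1e-6)
})
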