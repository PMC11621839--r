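test_that("adjacent intervals compose to the stated map distances", {
  r <- adjacent_recomb(0.001, 0.2)
  expect_equal(r[2], 0.001)
  expect_equal(r[1] * (1 - r[2]) + r[2] * (1 - r[1]), 0.2, tolerance = 1e-14)
  expect_equal(r, rev(r))
  expect_equal(adjacent_recomb(0, 0), rep(0, 4))
  cfg <- chromosome_config(N = 100, r_near = 0.001, r_far = 0.2)
  expect_equal(map_positions(cfg), c(-0.2, -0.001, 0, 0.001, 0.2))
})

test_that("offspring formation respects parents, recombination and mutation", {
  set.seed(401)
  p1 <- list(genome = c(1L, 1L, 1L, 1L, 1L), trait = 1L)
  p2 <- list(genome = c(0L, 0L, 0L, 0L, 0L), trait = 0L)
  model <- affinity_bias(0.1, 0.2)
  # identical parents, no mutation: clone
  off <- make_offspring(p1, p1, model, r_adj = rep(0.3, 4), mu = 0, n = 50)
  expect_true(all(off$genome == 1L))
  expect_true(all(off$trait == 1L))
  # no recombination, no mutation: one intact parental genome
  off <- make_offspring(p1, p2, model, r_adj = rep(0, 4), mu = 0, n = 200)
  rs <- rowSums(off$genome)
  expect_true(all(rs %in% c(0L, 5L)))
})

test_that("offspring phenogenotype fractions match the transmission table", {
  # AC x ac at the focal locus, affinity bias, no recombination or mutation
  set.seed(402)
  b1 <- 0.15; b2 <- 0.4
  p1 <- list(genome = c(1L, 1L, 1L, 1L, 1L), trait = 1L)  # A-focal, trait C
  p2 <- list(genome = c(0L, 0L, 0L, 0L, 0L), trait = 0L)  # a-focal, trait c
  n <- 100000
  off <- make_offspring(p1, p2, affinity_bias(b1, b2), r_adj = rep(0, 4),
                        mu = 0, n = n)
  A <- off$genome[, 3] == 1L
  C <- off$trait == 1L
  obs <- c(mean(A & C), mean(!A & C), mean(A & !C), mean(!A & !C))
  expc <- unname(offspring_distribution("AC x ac", affinity_bias(b1, b2)))
  se <- sqrt(expc * (1 - expc) / n)
  expect_true(all(abs(obs - expc) <= 4 * se))
  # trait bias, same mating
  off <- make_offspring(p1, p2, trait_bias(0.7, 0.3), r_adj = rep(0, 4),
                        mu = 0, n = n)
  A <- off$genome[, 3] == 1L; C <- off$trait == 1L
  obs <- c(mean(A & C), mean(!A & C), mean(A & !C), mean(!A & !C))
  expc <- unname(offspring_distribution("AC x ac", trait_bias(0.7, 0.3)))
  se <- sqrt(expc * (1 - expc) / n)
  expect_true(all(abs(obs - expc) <= 4 * se))
})

test_that("genetic transmission is unbiased at every locus", {
  set.seed(403)
  p1 <- list(genome = c(1L, 0L, 1L, 0L, 1L), trait = 1L)
  p2 <- list(genome = c(0L, 1L, 1L, 1L, 0L), trait = 0L)
  n <- 100000
  off <- make_offspring(p1, p2, trait_bias(0.9, 0.1),
                        r_adj = adjacent_recomb(0.001, 0.2), mu = 0, n = n)
  parental_mean <- (p1$genome + p2$genome) / 2
  obs <- colMeans(off$genome)
  se <- sqrt(0.25 / n)
  fixed <- parental_mean %in% c(0, 1)
  expect_equal(obs[fixed], parental_mean[fixed])
  expect_true(all(abs(obs[!fixed] - parental_mean[!fixed]) <= 4 * se))
})

test_that("per-locus heterozygosity is 2p(1-p)", {
  g <- rbind(c(1, 1, 0, 1, 0), c(1, 0, 0, 1, 0), c(1, 1, 0, 1, 0),
             c(1, 0, 0, 1, 0), c(1, 1, 0, 1, 1))
  expect_equal(locus_heterozygosities(g),
               2 * c(1, 0.6, 0, 1, 0.2) * (1 - c(1, 0.6, 0, 1, 0.2)))
  expect_equal(locus_heterozygosities(matrix(0L, 10, 5)), rep(0, 5))
  p <- 0.1
  expect_equal(2 * p * (1 - p), 0.18)
})

test_that("burn-in reaches a stationary level of flanking variation", {
  set.seed(404)
  # replicate burn-ins of 10N generations; mean flanking heterozygosity at
  # 5N and at 10N should agree (paired across replicates) once stationary
  cfg <- chromosome_config(N = 200, mu = 5e-4, r_near = 0.001, r_far = 0.2,
                           burn_in_generations = 2000)
  hh <- hf <- numeric(30)
  for (i in 1:30) {
    bi <- neutral_burn_in(cfg, record_every = 1000)
    hh[i] <- mean(bi$het_series[1, c(1, 2, 4, 5)])
    hf[i] <- mean(bi$het_series[2, c(1, 2, 4, 5)])
  }
  tt <- stats::t.test(hf, hh, paired = TRUE)
  expect_gt(tt$p.value, 0.01)
  expect_gt(mean(hf), 0.05)  # variation is actually maintained
  # focal locus stays monomorphic ancestral
  expect_true(all(bi$genome[, 3] == 0L))
  expect_equal(bi$het[3], 0)
  # mu = 0 from a monomorphic start stays monomorphic
  cfg0 <- chromosome_config(N = 100, mu = 0, burn_in_generations = 200)
  expect_equal(neutral_burn_in(cfg0)$het, rep(0, 5))
})

test_that("sweep experiments are deterministic under a fixed seed", {
  cfg <- chromosome_config(N = 200, mu = 1e-3, sweep_type = "cultural",
                           s = 0.1, model = affinity_bias(0.01, 0.01),
                           min_sweeps = 5)
  a <- sweep_experiment(cfg, seed = 405)
  b <- sweep_experiment(cfg, seed = 405)
  expect_identical(a$heterozygosity, b$heterozygosity)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("a genetic sweep removes focal variation and scars near flanks most", {
  set.seed(406)
  cfg <- chromosome_config(N = 500, mu = 2e-4, r_near = 0.001, r_far = 0.2,
                           sweep_type = "genetic", s = 0.1, min_sweeps = 60,
                           burn_in_generations = 2500)
  r <- sweep_experiment(cfg, seed = 406)
  het <- r$heterozygosity
  expect_equal(het$heterozygosity[het$locus == 3], rep(0, r$successes))
  near <- het$heterozygosity[het$locus %in% c(2, 4)]
  far <- het$heterozygosity[het$locus %in% c(1, 5)]
  wt <- stats::wilcox.test(near, far, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("free cultural mixing leaves no genomic footprint", {
  set.seed(407)
  base <- chromosome_config(N = 500, mu = 2e-4, r_near = 0.001, r_far = 0.2,
                            burn_in_generations = 2500, min_sweeps = 60,
                            sweep_type = "none")
  base$perturb_generations <- 500L
  ctrl <- sweep_experiment(base, seed = 407)
  mixed <- chromosome_config(N = 500, mu = 2e-4, r_near = 0.001, r_far = 0.2,
                             burn_in_generations = 2500, min_sweeps = 60,
                             sweep_type = "cultural", s = 0.1,
                             model = affinity_bias(0.5, 0.5))
  swp <- sweep_experiment(mixed, seed = 408)
  h_ctrl <- ctrl$heterozygosity
  h_swp <- swp$heterozygosity
  flank_ctrl <- h_ctrl$heterozygosity[h_ctrl$locus != 3]
  flank_swp <- h_swp$heterozygosity[h_swp$locus != 3]
  wt <- stats::wilcox.test(flank_swp, flank_ctrl)
  expect_gt(wt$p.value, 0.01)
})
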