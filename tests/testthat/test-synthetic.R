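two_trait_spec <- function(seed = 1, G = 10, r = 4) {
  cohort_spec(G = G, r = r,
              traits = data.frame(trait = c("a", "b"),
                                  mean = c(50, 10),
                                  sigma_g2 = c(9, 1),
                                  sigma_e2 = c(4, 0.5)),
              seed = seed)
}

test_that("identical specs reproduce byte-identical cohorts", {
  t1 <- simulate_cohort(two_trait_spec(seed = 99))
  t2 <- simulate_cohort(two_trait_spec(seed = 99))
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(t1, f1); write_trait_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  t3 <- simulate_cohort(two_trait_spec(seed = 100))
  expect_false(identical(t1$value, t3$value))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_cohort(two_trait_spec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("noise-free limit collapses replicates onto the genotype mean", {
  sp <- cohort_spec(G = 10, r = 4,
                    traits = data.frame(trait = "y", mean = 5,
                                        sigma_g2 = 2, sigma_e2 = 1e-12),
                    seed = 3)
  an <- trait_anova(simulate_cohort(sp))
  expect_lt(an$QMr, 1e-10)
  expect_gt(an$QMg, 1)
})

test_that("null model (sigma_g2 = 0) gives F near 1 on average", {
  sp <- cohort_spec(G = 30, r = 4,
                    traits = data.frame(trait = sprintf("t%03d", 1:200),
                                        mean = 10, sigma_g2 = 0,
                                        sigma_e2 = 4),
                    seed = 7)
  an <- trait_anova(simulate_cohort(sp))
  # E[QMg] = E[QMr] = sigma_e2 under the null
  expect_equal(mean(an$QMg), mean(an$QMr), tolerance = 0.05)
  expect_equal(mean(an$F), 1, tolerance = 0.1)
})

test_that("expected_parameters gives the closed-form reference values", {
  sp <- cohort_spec(G = 5, r = 2,
                    traits = data.frame(trait = "y", mean = 6,
                                        sigma_g2 = 15, sigma_e2 = 2),
                    seed = 1)
  ep <- expected_parameters(sp)
  expect_equal(ep$h2, 0.9375)
  expect_equal(ep$ratio, sqrt(15 / 2), tolerance = 1e-6)
  expect_equal(ep$ratio, 2.7386, tolerance = 1e-4)
  expect_equal(ep$cvg, 100 * sqrt(15) / 6)
  expect_equal(ep$cve, 100 * sqrt(2) / 6)

  sp0 <- cohort_spec(G = 5, r = 2,
                     traits = data.frame(trait = "y", mean = 6,
                                         sigma_g2 = 0, sigma_e2 = 2),
                     seed = 1)
  ep0 <- expected_parameters(sp0)
  expect_equal(ep0$h2, 0)
  expect_equal(ep0$ratio, 0)

  # h2 -> 1 as replication grows, at any sigma_e2 = sigma_g2
  spr <- cohort_spec(G = 5, r = 10000,
                     traits = data.frame(trait = "y", mean = 6,
                                         sigma_g2 = 2, sigma_e2 = 2),
                     seed = 1)
  expect_equal(expected_parameters(spr)$h2, 1, tolerance = 1e-3)
})

test_that("invalid specs are rejected", {
  tr <- data.frame(trait = "y", mean = 6, sigma_g2 = 15, sigma_e2 = 2)
  expect_error(cohort_spec(G = 5, r = 2, traits = tr), "seed")
  expect_error(cohort_spec(G = 5, r = 2,
                           traits = transform(tr, sigma_e2 = 0), seed = 1),
               "sigma_e2")
  expect_error(cohort_spec(G = 5, r = 2,
                           traits = transform(tr, sigma_g2 = -1), seed = 1),
               "sigma_g2")
  bad_R <- matrix(c(1, 2, 2, 1), 2)  # |off-diagonal| > 1: not PSD
  tr2 <- data.frame(trait = c("a", "b"), mean = 1, sigma_g2 = 1,
                    sigma_e2 = 1)
  expect_error(cohort_spec(G = 5, r = 2, traits = tr2,
                           genetic_correlation = bad_R, seed = 1),
               "positive semidefinite")
  expect_error(expected_parameters(
    cohort_spec(G = 5, r = 2,
                traits = data.frame(trait = "y", mean = 0, sigma_g2 = 1,
                                    sigma_e2 = 1), seed = 1)),
    "zero trait mean")
})

test_that("cross-trait genetic correlation is realized in genotype effects", {
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  sp <- cohort_spec(G = 200, r = 2,
                    traits = data.frame(trait = c("a", "b"), mean = 0,
                                        sigma_g2 = 10, sigma_e2 = 0.01),
                    genetic_correlation = R, seed = 17)
  m <- trait_means(simulate_cohort(sp))
  expect_equal(cor(m[, 1], m[, 2]), 0.9, tolerance = 0.05)
})

test_that("estimators recover the planted variance components", {
  # scaled-down Monte Carlo; the acceptance suite runs the full design
  sigma_e2 <- 20; r <- 4; h2_true <- 0.7
  sigma_g2 <- (sigma_e2 / r) * h2_true / (1 - h2_true)
  h2_hat <- sg_hat <- numeric(40)
  for (i in seq_len(40)) {
    sp <- cohort_spec(G = 160, r = r,
                      traits = data.frame(trait = "y", mean = 50,
                                          sigma_g2 = sigma_g2,
                                          sigma_e2 = sigma_e2),
                      seed = 5000 + i)
    gp <- genetic_parameters(trait_anova(simulate_cohort(sp)))
    h2_hat[i] <- gp$h2
    sg_hat[i] <- gp$sigma_g2
  }
  expect_lt(abs(mean(h2_hat) - h2_true), 0.02)
  expect_lt(abs(mean(sg_hat) - sigma_g2), 0.05 * sigma_g2)
})
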