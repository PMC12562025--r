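pooled_cov_of <- function(psi_matrix, df = 100) {
  structure(list(psi = psi_matrix, df = df, scale = "observations"),
            class = "pooled_cov")
}

test_that("single-trait pooled covariance reduces to the residual MS", {
  tt <- fixture_3x2()
  pc <- pooled_residual_covariance(tt)
  expect_equal(dim(pc$psi), c(1L, 1L))
  expect_equal(pc$psi[1, 1], trait_anova(tt)$QMr)
  expect_equal(pc$df, 3L)
})

test_that("pooled covariance matches the element-by-element hand sum", {
  tt <- random_table(G = 3, Tn = 2, r = 4, seed = 91)
  pc <- suppressWarnings(pooled_residual_covariance(tt))
  m <- trait_means(tt)
  tn <- attr(tt, "traits")
  hand <- matrix(0, 2, 2)
  for (t in 1:2) for (u in 1:2) {
    s <- 0
    for (g in attr(tt, "genotypes")) {
      yt <- tt$value[tt$genotype == g & tt$trait == tn[t]]
      yu <- tt$value[tt$genotype == g & tt$trait == tn[u]]
      s <- s + sum((yt - mean(yt)) * (yu - mean(yu)))
    }
    hand[t, u] <- s / (3 * (4 - 1))
  }
  expect_equal(unname(pc$psi), hand, tolerance = 1e-12)
  # diagonal equals each trait's residual mean square
  expect_equal(unname(diag(pc$psi)), trait_anova(tt)$QMr, tolerance = 1e-12)
})

test_that("a duplicated trait makes the metric singular", {
  tt <- random_table(G = 5, Tn = 1, r = 3, seed = 92)
  df <- as.data.frame(tt)
  dup <- df; dup$trait <- "copy"
  both <- trait_table(rbind(df, dup))
  expect_error(pooled_residual_covariance(both), "singular")
})

test_that("D2 reduces to known closed forms for injected metrics", {
  # two genotypes with mean difference (3, 4), identity metric -> 25
  tt <- make_table(matrix(c(3, 0, 4, 0), 2, 2,
                          dimnames = list(c("A", "B"), c("x", "y"))),
                   matrix(0.0, 4, 2), r = 2)
  d2 <- mahalanobis_matrix(tt, pooled_cov_of(diag(2)))
  expect_equal(d2["A", "B"], 25)
  expect_equal(diag(d2), c(A = 0, B = 0))

  # diag(2, 1) metric, difference (2, 3) -> 4/2 + 9/1 = 11
  tt2 <- make_table(matrix(c(2, 0, 3, 0), 2, 2,
                           dimnames = list(c("A", "B"), c("x", "y"))),
                    matrix(0.0, 4, 2), r = 2)
  d22 <- mahalanobis_matrix(tt2, pooled_cov_of(diag(c(2, 1))))
  expect_equal(d22["A", "B"], 11)

  # identical genotype means -> all distances zero
  set.seed(90)
  tt3 <- make_table(matrix(1, 3, 2, dimnames = list(c("A", "B", "C"),
                                                    c("x", "y"))),
                    block_center(matrix(rnorm(12, sd = 0.5), 12, 2), r = 4),
                    r = 4)
  d23 <- mahalanobis_matrix(tt3, pooled_cov_of(diag(2)))
  expect_equal(unname(d23), matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("with an identity metric D2 is the squared Euclidean distance", {
  tt <- random_table(G = 6, Tn = 3, r = 3, seed = 93)
  m <- trait_means(tt)
  d2 <- mahalanobis_matrix(tt, pooled_cov_of(diag(3)))
  expect_equal(d2, as.matrix(dist(m))^2, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Singh terms decompose every pairwise D2 and sum to 100%", {
  tt <- random_table(G = 5, Tn = 3, r = 4, seed = 94)
  pc <- pooled_residual_covariance(tt)
  d2 <- mahalanobis_matrix(tt, pc)
  cb <- singh_contributions(tt, pc)
  orc <- singh_oracle(trait_means(tt), pc$psi)
  expect_equal(sum(cb$percent), 100, tolerance = 1e-9)
  expect_equal(cb$S[match(attr(tt, "traits"), cb$trait)], orc$S,
               tolerance = 1e-9, ignore_attr = TRUE)
  # per-trait sums add up to the total of all pairwise distances
  expect_equal(sum(cb$S), sum(d2[upper.tri(d2)]), tolerance = 1e-9)
  expect_equal(sum(cb$S), orc$total_d2, tolerance = 1e-9)
})

test_that("Singh contributions: identity-metric and constant-trait cases", {
  tt <- make_table(matrix(c(3, 0, 4, 0), 2, 2,
                          dimnames = list(c("A", "B"), c("x", "y"))),
                   matrix(0.0, 4, 2), r = 2)
  cb <- singh_contributions(tt, pooled_cov_of(diag(2)))
  expect_equal(cb$percent[cb$trait == "x"], 36)
  expect_equal(cb$percent[cb$trait == "y"], 64)

  # a trait with identical genotype means contributes nothing
  means <- cbind(x = c(0, 3, 7), flat = c(5, 5, 5))
  rownames(means) <- c("A", "B", "C")
  set.seed(95)
  tt2 <- make_table(means,
                    block_center(matrix(rnorm(12, sd = 0.3), 12, 2), r = 4),
                    r = 4)
  cb2 <- singh_contributions(tt2, pooled_cov_of(diag(2)))
  expect_equal(cb2$percent[cb2$trait == "flat"], 0)

  # all genotypes identical: total divergence zero is an error
  tt3 <- make_table(matrix(1, 3, 2, dimnames = list(c("A", "B", "C"),
                                                    c("x", "y"))),
                    block_center(matrix(rnorm(12, sd = 0.2), 12, 2), r = 4),
                    r = 4)
  expect_error(singh_contributions(tt3, pooled_cov_of(diag(2))),
               "identical")
})

test_that("D2 is invariant under affine rescaling of a trait", {
  tt <- random_table(G = 6, Tn = 3, r = 4, seed = 96)
  d2 <- mahalanobis_matrix(tt)
  df <- as.data.frame(tt)
  tr1 <- attr(tt, "traits")[1]
  df$value[df$trait == tr1] <- 10 * df$value[df$trait == tr1] + 7
  d2s <- mahalanobis_matrix(trait_table(df))
  expect_equal(d2, d2s, tolerance = 1e-6)
})

test_that("scaling the covariance to means divides D2 by r exactly", {
  tt <- random_table(G = 5, Tn = 2, r = 4, seed = 97)
  d2_obs <- mahalanobis_matrix(tt, pooled_residual_covariance(tt))
  d2_means <- mahalanobis_matrix(tt,
    pooled_residual_covariance(tt, scale = "means"))
  expect_equal(d2_means, 4 * d2_obs, tolerance = 1e-9)
})
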