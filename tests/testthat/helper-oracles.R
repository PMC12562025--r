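# Independent oracles and fixture builders used across the suite.
# Every oracle recomputes its quantity by the most direct route available
# (explicit loops, exhaustive enumeration), not by the code path it checks.

# Long data.frame for a balanced design from a G x T matrix of genotype
# means plus a per-observation residual matrix ((G*r) x T, rows grouped by
# genotype).
make_table <- function(means, resid, r) {
  G <- nrow(means); Tn <- ncol(means)
  gnames <- rownames(means); tnames <- colnames(means)
  rows <- expand.grid(replicate = seq_len(r), genotype = gnames,
                      trait = tnames, stringsAsFactors = FALSE)
  rows$value <- vapply(seq_len(nrow(rows)), function(i) {
    g <- match(rows$genotype[i], gnames)
    t <- match(rows$trait[i], tnames)
    means[g, t] + resid[(g - 1L) * r + rows$replicate[i], t]
  }, numeric(1))
  trait_table(rows[c("genotype", "replicate", "trait", "value")])
}

# Remove per-(genotype, trait) means from a (G*r) x T residual matrix so
# that make_table produces genotype means exactly equal to `means`.
block_center <- function(resid, r) {
  g <- rep(seq_len(nrow(resid) / r), each = r)
  resid - apply(resid, 2L, function(col) ave(col, g))
}

random_table <- function(G, Tn, r, seed, sd_g = 3, sd_e = 1) {
  set.seed(seed)
  means <- matrix(rnorm(G * Tn, mean = 20, sd = sd_g), G, Tn,
                  dimnames = list(sprintf("g%02d", 1:G),
                                  sprintf("t%02d", 1:Tn)))
  resid <- matrix(rnorm(G * r * Tn, sd = sd_e), G * r, Tn)
  make_table(means, resid, r)
}

# three genotypes, two replicates, QMg = 32, QMr = 2, grand mean 6
fixture_3x2 <- function() {
  trait_table(data.frame(
    genotype = rep(c("A", "B", "C"), each = 2),
    replicate = rep(1:2, 3),
    trait = "y",
    value = c(1, 3, 5, 7, 9, 11)))
}

# --- one-way ANOVA sums of squares, written out longhand -----------------
anova_oracle <- function(values_by_genotype, r = lengths(values_by_genotype)[1]) {
  G <- length(values_by_genotype)
  gm <- mean(unlist(values_by_genotype))
  gmeans <- vapply(values_by_genotype, mean, numeric(1))
  ssg <- r * sum((gmeans - gm)^2)
  ssr <- sum(vapply(seq_len(G), function(i) {
    sum((values_by_genotype[[i]] - gmeans[i])^2)
  }, numeric(1)))
  list(QMg = ssg / (G - 1), QMr = ssr / (G * (r - 1)),
       SSg = ssg, SSr = ssr, grand_mean = gm)
}

# --- Scott-Knott by exhaustive contiguous-split enumeration --------------
# means: any order; returns integer group ids aligned with the DESCENDING
# mean order. Enumerates every contiguous split at every node, computes B0
# from group means, applies the chi-squared rule, recurses.
sk_oracle <- function(means, nu, s2_ybar, alpha) {
  m <- sort(means, decreasing = TRUE)
  groups <- integer(length(m))
  gid <- 0L
  assign_group <- function(idx) {
    k <- length(idx)
    if (k >= 2L) {
      mm <- m[idx]
      b0 <- -Inf; best <- NA_integer_
      for (p in seq_len(k - 1L)) {
        m1 <- mean(mm[1:p]); m2 <- mean(mm[(p + 1L):k]); mo <- mean(mm)
        b <- p * (m1 - mo)^2 + (k - p) * (m2 - mo)^2
        if (b > b0 + 1e-12) { b0 <- b; best <- p }
      }
      s0 <- (sum((mm - mean(mm))^2) + nu * s2_ybar) / (k + nu)
      lambda <- pi / (2 * (pi - 2)) * b0 / s0
      if (lambda > qchisq(1 - alpha, df = k / (pi - 2))) {
        assign_group(idx[1:best])
        assign_group(idx[(best + 1L):k])
        return(invisible(NULL))
      }
    }
    gid <<- gid + 1L
    groups[idx] <<- gid
    invisible(NULL)
  }
  assign_group(seq_along(m))
  groups
}

# --- naive O(G^3) UPGMA ---------------------------------------------------
# Average inter-cluster dissimilarity recomputed from the ORIGINAL matrix
# at every step (no Lance-Williams update). Returns fusion levels in merge
# order and the cophenetic matrix (level at which each leaf pair joins).
upgma_naive <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      if (avg < bestd - 1e-12) { bestd <- avg; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- bestd; coph[ib, ia] <- bestd
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, coph = coph)
}

# --- Singh decomposition by explicit pair loop ---------------------------
singh_oracle <- function(means, psi) {
  A <- solve(psi)
  G <- nrow(means); Tn <- ncol(means)
  S <- numeric(Tn)
  total_d2 <- 0
  for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
    d <- means[i, ] - means[j, ]
    cj <- d * drop(A %*% d)
    S <- S + cj
    total_d2 <- total_d2 + drop(t(d) %*% A %*% d)
  }
  list(S = S, total_d2 = total_d2)
}

# symmetric positive dissimilarity matrix with zero diagonal
random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * n, 1, 10), n, n)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  d
}
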