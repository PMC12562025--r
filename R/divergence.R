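#' Pooled within-genotype (residual) covariance matrix
#'
#' The error covariance of the balanced CRD, pooled over genotypes:
#' `psi[t, u] = sum_i sum_j (y_ijt - ybar_it) (y_iju - ybar_iu) / (G (r - 1))`.
#' Its diagonal equals each trait's residual mean square `QMr`, and it is
#' the metric the generalized Mahalanobis distance inverts.
#'
#' @param x a [trait_table].
#' @param scale `"observations"` (default) pools the covariance of raw
#'   observations; `"means"` divides by `r`, giving the covariance of
#'   genotype means. The choice rescales all distances by the constant `r`
#'   and therefore changes no grouping.
#' @return object of class `pooled_cov`: list with `psi` (T x T symmetric
#'   matrix), `df` (pooling degrees of freedom `G (r - 1)`) and `scale`.
#'   Warns when `df < T` (the matrix cannot be full rank); errors when
#'   `psi` is singular, naming a trait to consider removing.
#' @export
pooled_residual_covariance <- function(x, scale = c("observations", "means")) {
  scale <- match.arg(scale)
  x <- as_trait_table(x)
  G <- n_genotypes(x); r <- n_replicates(x); Tn <- n_traits(x)
  df <- G * (r - 1L)
  if (df < Tn) {
    warning("pooling df (", df, ") < number of traits (", Tn,
            "): covariance cannot be full rank", call. = FALSE)
  }
  # residuals about genotype means, observations as a (G*r) x T matrix
  wide <- matrix(x$value[order(match(x$trait, attr(x, "traits")),
                               match(x$genotype, attr(x, "genotypes")),
                               x$replicate)],
                 nrow = G * r, ncol = Tn,
                 dimnames = list(NULL, attr(x, "traits")))
  gidx <- rep(seq_len(G), each = r)
  centred <- wide - apply(wide, 2L, function(col) stats::ave(col, gidx))

  psi <- crossprod(centred) / df
  if (scale == "means") psi <- psi / r

  rc <- rcond(psi)
  if (!is.finite(rc) || rc < .Machine$double.eps * 100) {
    dup <- which.min(diag(psi) / pmax(apply(abs(psi), 1L, max), 1e-300))
    stop("pooled residual covariance is singular; consider removing a ",
         "linearly dependent trait (e.g. '", colnames(psi)[dup], "')",
         call. = FALSE)
  }
  if (rc < 1e-12) {
    warning("pooled residual covariance is ill-conditioned ",
            "(reciprocal condition number ", format(rc, digits = 3), ")",
            call. = FALSE)
  }
  structure(list(psi = psi, df = df, scale = scale), class = "pooled_cov")
}

#' Generalized Mahalanobis distance matrix between genotypes
#'
#' For every genotype pair, `D2 = d' psi^-1 d` where `d` is the vector of
#' genotype-mean differences over the traits and `psi` the pooled residual
#' covariance — the standard dissimilarity of multivariate germplasm
#' divergence studies. Computed through a Cholesky factorization (whitening
#' the mean vectors, then squared Euclidean distances), never by forming
#' `psi^-1` against each pair.
#'
#' @param x a [trait_table].
#' @param psi a [pooled_residual_covariance] result; computed from `x` by
#'   default.
#' @return symmetric `G x G` matrix of D2 values with zero diagonal,
#'   dimnames the genotype ids.
#' @export
mahalanobis_matrix <- function(x, psi = pooled_residual_covariance(x)) {
  x <- as_trait_table(x)
  stopifnot(inherits(psi, "pooled_cov"))
  M <- trait_means(x)
  L <- chol(psi$psi)
  Z <- t(backsolve(L, t(M), transpose = TRUE))  # rows m_i L^-1 (whitened)
  d2 <- as.matrix(stats::dist(Z))^2
  dimnames(d2) <- list(rownames(M), rownames(M))
  d2
}

#' Singh's per-trait contribution to total divergence
#'
#' Decomposes each pairwise Mahalanobis D2 into additive per-trait terms
#' `c_j = d_j * (psi^-1 d)_j` (so `sum_j c_j = D2` exactly), sums them over
#' all unordered genotype pairs into `S_j`, and reports each trait's
#' relative contribution `100 * S_j / sum(S_j)` — the standard criterion
#' for ranking which traits drive the observed divergence. With correlated
#' traits individual `c_j` can be negative; the signed values are kept, as
#' that is the only decomposition consistent with the identity.
#'
#' @param x a [trait_table].
#' @param psi a [pooled_residual_covariance] result; computed from `x` by
#'   default.
#' @return data.frame of class `singh_contributions` with columns
#'   `trait, S, percent`, sorted by descending contribution; percentages
#'   sum to 100.
#' @export
singh_contributions <- function(x, psi = pooled_residual_covariance(x)) {
  x <- as_trait_table(x)
  stopifnot(inherits(psi, "pooled_cov"))
  M <- trait_means(x)
  G <- nrow(M)
  if (G < 2L) stop("at least 2 genotypes are required", call. = FALSE)
  # sum over unordered pairs of d d' equals G * crossprod of centred means
  C <- crossprod(scale(M, center = TRUE, scale = FALSE))
  A <- chol2inv(chol(psi$psi))
  S <- diag(G * C %*% A)
  total <- sum(S)
  if (total <= 0) {
    stop("total divergence is zero: all genotype mean vectors identical",
         call. = FALSE)
  }
  out <- data.frame(trait = colnames(M), S = unname(S),
                    percent = 100 * unname(S) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$S), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("singh_contributions", "data.frame"))
}
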