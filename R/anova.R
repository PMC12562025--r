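#' Per-trait one-way ANOVA for a balanced CRD
#'
#' Fits the one-way fixed-effects model `value ~ genotype` separately for
#' each trait and extracts the quantities the genetic-parameter estimators
#' need: the genotype mean square `QMg` (df `G - 1`), the residual mean
#' square `QMr` (df `G (r - 1)`), the F ratio `QMg / QMr` with its
#' upper-tail p-value, the grand mean `m`, and the experimental coefficient
#' of variation `CV% = 100 * sqrt(QMr) / m`.
#'
#' @param x a [trait_table].
#' @param traits traits to analyse; default all.
#' @return data.frame of class `trait_anova`, one row per trait, columns
#'   `trait, df_g, df_r, QMg, QMr, F, p, grand_mean, cv_percent`, with
#'   attribute `r` (replicates). `cv_percent` is `NaN` when the grand mean
#'   is zero.
#' @examples
#' tt <- simulate_cohort(cohort_spec(G = 10, r = 4,
#'   traits = data.frame(trait = "y", mean = 50, sigma_g2 = 9, sigma_e2 = 4),
#'   seed = 1))
#' trait_anova(tt)
#' @export
trait_anova <- function(x, traits = NULL) {
  x <- as_trait_table(x)
  all_traits <- attr(x, "traits")
  if (is.null(traits)) traits <- all_traits
  if (!all(traits %in% all_traits)) {
    stop("unknown trait(s): ",
         paste(setdiff(traits, all_traits), collapse = ", "), call. = FALSE)
  }
  G <- n_genotypes(x)
  r <- n_replicates(x)
  if (G < 2L) stop("ANOVA needs at least 2 genotypes", call. = FALSE)

  rows <- lapply(traits, function(tr) {
    sub <- x[x$trait == tr, , drop = FALSE]
    fit <- stats::lm(value ~ factor(genotype, levels = attr(x, "genotypes")),
                     data = sub)
    # anova.lm warns on zero-residual fits; QMr = 0 is a legitimate
    # degenerate case here (noise-free simulations)
    an <- withCallingHandlers(
      stats::anova(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    QMg <- an$`Mean Sq`[1L]
    QMr <- an$`Mean Sq`[2L]
    m <- mean(sub$value)
    data.frame(trait = tr,
               df_g = an$Df[1L], df_r = an$Df[2L],
               QMg = QMg, QMr = QMr,
               F = if (QMr > 0) QMg / QMr else ifelse(QMg > 0, Inf, NaN),
               p = an$`Pr(>F)`[1L],
               grand_mean = m,
               cv_percent = if (m != 0) 100 * sqrt(QMr) / abs(m) else NaN,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, r = r, class = c("trait_anova", "data.frame"))
}

# Significance stars following the conventional ANOVA-table footnote.
signif_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

# Alphabetic group labels: a..z, then aa, ab, ... for > 26 groups.
group_labels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  first <- rep(letters, each = 26L)
  c(letters, paste0(first, rep(letters, times = 26L)))[seq_len(n)]
}

#' Scott-Knott clustering of genotype means
#'
#' Partitions the genotype means of one trait into statistically
#' homogeneous, non-overlapping groups by the Scott-Knott (1974) procedure:
#' the means are ordered, and each candidate group of `k` means is split at
#' the contiguous cut maximizing the between-group sum of squares `B0`. The
#' split is accepted when the likelihood-ratio statistic
#' `lambda = pi / (2 * (pi - 2)) * B0 / s0^2` exceeds the chi-squared
#' quantile at level `alpha` with `k / (pi - 2)` (non-integer) degrees of
#' freedom, where `s0^2 = (sum((m_i - m)^2) + nu * s2_ybar) / (k + nu)`,
#' `s2_ybar = QMr / r` is the variance of a treatment mean, and `nu` is the
#' residual degrees of freedom of the trait's own ANOVA (reused, with
#' `s2_ybar`, at every recursion depth, as in the classical procedure).
#' Recursion stops when no split is significant. Unlike pairwise multiple
#' comparisons, the resulting classes never overlap.
#'
#' Ties between splits with equal `B0` are broken to the leftmost split,
#' for determinism.
#'
#' @param x a [trait_table].
#' @param trait trait name to group.
#' @param alpha significance level in (0, 1); the conventional choice in
#'   germplasm screening is 0.05.
#' @return data.frame of class `sk_grouping` with columns
#'   `genotype, mean, group` (letters `a, b, ...` by descending group
#'   mean), sorted by descending mean; attributes `trait` and `alpha`.
#' @references Scott, A.J. and Knott, M. (1974) A cluster analysis method
#'   for grouping means in the analysis of variance. Biometrics 30,
#'   507-512.
#' @export
scott_knott <- function(x, trait, alpha = 0.05) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  x <- as_trait_table(x)
  an <- trait_anova(x, traits = trait)
  r <- n_replicates(x)
  nu <- an$df_r
  s2_ybar <- an$QMr / r

  m <- trait_means(x)[, trait]
  ord <- order(m, decreasing = TRUE)
  means <- m[ord]

  groups <- integer(length(means))
  next_id <- 0L
  recurse <- function(idx) {
    k <- length(idx)
    if (k >= 2L) {
      mm <- means[idx]
      split_at <- sk_best_split(mm)
      if (!is.na(split_at) &&
          sk_split_significant(mm, split_at, nu, s2_ybar, alpha)) {
        recurse(idx[seq_len(split_at)])
        recurse(idx[(split_at + 1L):k])
        return(invisible(NULL))
      }
    }
    next_id <<- next_id + 1L
    groups[idx] <<- next_id
    invisible(NULL)
  }
  recurse(seq_along(means))

  out <- data.frame(genotype = names(means), mean = unname(means),
                    group = group_labels(next_id)[groups],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, trait = trait, alpha = alpha,
            class = c("sk_grouping", "data.frame"))
}

# Index p (1 <= p < k) of the contiguous split of the ordered means
# maximizing the between-group sum of squares; leftmost on ties.
sk_best_split <- function(means) {
  k <- length(means)
  if (k < 2L) return(NA_integer_)
  tot <- sum(means)
  csum <- cumsum(means)[-k]
  p <- seq_len(k - 1L)
  b0 <- csum^2 / p + (tot - csum)^2 / (k - p) - tot^2 / k
  which.max(b0)  # which.max takes the first maximum: leftmost tie-break
}

# Scott-Knott likelihood-ratio test for an accepted split.
sk_split_significant <- function(means, split_at, nu, s2_ybar, alpha) {
  k <- length(means)
  tot <- sum(means)
  csum <- sum(means[seq_len(split_at)])
  b0 <- csum^2 / split_at + (tot - csum)^2 / (k - split_at) - tot^2 / k
  s0_sq <- (sum((means - tot / k)^2) + nu * s2_ybar) / (k + nu)
  if (s0_sq <= 0) return(b0 > 0)  # degenerate: zero variance, any gap splits
  lambda <- pi / (2 * (pi - 2)) * b0 / s0_sq
  lambda > stats::qchisq(1 - alpha, df = k / (pi - 2))
}
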