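#' Specify a synthetic balanced CRD cohort
#'
#' Defines the generating model for a synthetic genotype cohort:
#' `y_ijt = mu_t + g_it + e_ijt`, with genotypic effects `g_i` multivariate
#' normal with per-trait variances `sigma_g2` and optional cross-trait
#' correlation, and residuals independent normal with variances `sigma_e2`.
#' Under this model the one-way ANOVA expectations are
#' `E[QMg] = sigma_e2 + r * sigma_g2` and `E[QMr] = sigma_e2`, which is
#' exactly the model the variance-component estimators invert — so a
#' simulated cohort has known true values for every quantity the pipeline
#' estimates.
#'
#' @param G number of genotypes (>= 2).
#' @param r replicates per genotype (>= 2).
#' @param traits data.frame with columns `trait`, `mean`, `sigma_g2`
#'   (genetic variance, >= 0) and `sigma_e2` (residual variance, > 0); one
#'   row per trait, values in trait units squared.
#' @param genetic_correlation optional `T x T` positive-semidefinite
#'   correlation matrix of genotypic effects (unit diagonal). `NULL` means
#'   independent traits.
#' @param seed integer RNG seed; mandatory, so a spec always regenerates
#'   the identical cohort and no global RNG state is consumed.
#' @return an object of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec(G = 20, r = 4,
#'                   traits = data.frame(trait = "FL", mean = 91,
#'                                       sigma_g2 = 200, sigma_e2 = 25),
#'                   seed = 42)
#' tt <- simulate_cohort(sp)
#' @export
cohort_spec <- function(G, r, traits, genetic_correlation = NULL, seed) {
  stopifnot(length(G) == 1L, G >= 2, length(r) == 1L, r >= 2)
  required <- c("trait", "mean", "sigma_g2", "sigma_e2")
  if (!is.data.frame(traits) || !all(required %in% names(traits))) {
    stop("'traits' must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(traits$trait)) stop("duplicate trait names",
                                        call. = FALSE)
  if (any(!is.finite(traits$mean))) stop("trait means must be finite",
                                         call. = FALSE)
  if (any(traits$sigma_g2 < 0)) stop("sigma_g2 must be >= 0", call. = FALSE)
  if (any(traits$sigma_e2 <= 0)) stop("sigma_e2 must be > 0", call. = FALSE)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("an integer 'seed' is required", call. = FALSE)
  }
  Tn <- nrow(traits)
  if (!is.null(genetic_correlation)) {
    R <- as.matrix(genetic_correlation)
    if (!isTRUE(all.equal(dim(R), c(Tn, Tn))) ||
        !isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
        !isTRUE(all.equal(unname(diag(R)), rep(1, Tn), tolerance = 1e-8))) {
      stop("genetic_correlation must be a symmetric T x T matrix with ",
           "unit diagonal", call. = FALSE)
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("genetic_correlation is not positive semidefinite", call. = FALSE)
    }
  }
  structure(list(G = as.integer(G), r = as.integer(r),
                 traits = as.data.frame(traits)[required],
                 genetic_correlation = genetic_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Run expr with its own RNG stream; the caller's .Random.seed is untouched.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a balanced CRD cohort with known variance components
#'
#' Draws a cohort from the model documented in [cohort_spec] and returns it
#' as a validated [trait_table]. Identical specs (including the seed)
#' produce identical tables.
#'
#' @param spec a [cohort_spec].
#' @return a [trait_table] with `G x T x r` observations; genotypes are
#'   labelled `g001, g002, ...`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  G <- spec$G; r <- spec$r; tr <- spec$traits
  Tn <- nrow(tr)
  with_private_seed(spec$seed, {
    Z <- matrix(stats::rnorm(G * Tn), G, Tn)
    if (!is.null(spec$genetic_correlation)) {
      # PSD square root via eigendecomposition (chol fails on singular R)
      eg <- eigen(spec$genetic_correlation, symmetric = TRUE)
      Z <- Z %*% (eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0))))
    }
    gfx <- sweep(Z, 2L, sqrt(tr$sigma_g2), `*`)
    err <- array(stats::rnorm(G * r * Tn), dim = c(G, r, Tn))
    err <- sweep(err, 3L, sqrt(tr$sigma_e2), `*`)
    value <- sweep(err, c(1L, 3L), gfx, `+`)
    value <- sweep(value, 3L, tr$mean, `+`)
    genotypes <- sprintf("g%03d", seq_len(G))
    long <- data.frame(
      genotype = rep(genotypes, each = r * Tn),
      replicate = rep(rep(seq_len(r), each = Tn), times = G),
      trait = rep(tr$trait, times = G * r),
      value = as.vector(aperm(value, c(3L, 2L, 1L))),
      stringsAsFactors = FALSE)
    trait_table(long)
  })
}

#' Population-level genetic parameters implied by a cohort spec
#'
#' Closed-form reference values the estimators should recover, per trait:
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2 / r)` (heritability of a genotype
#' mean over `r` replicates), `CVg = 100 * sigma_g / mean`,
#' `CVe = 100 * sigma_e / mean`, and `CVg/CVe = sigma_g / sigma_e`.
#'
#' @param spec a [cohort_spec].
#' @return data.frame with columns `trait, h2, cvg, cve, ratio`; `h2` a
#'   fraction in `[0, 1]`, CVs in percent.
#' @export
expected_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tr <- spec$traits
  if (any(tr$mean == 0 & (tr$sigma_g2 > 0 | tr$sigma_e2 > 0))) {
    stop("coefficient of variation undefined for zero trait mean",
         call. = FALSE)
  }
  data.frame(
    trait = tr$trait,
    h2 = tr$sigma_g2 / (tr$sigma_g2 + tr$sigma_e2 / spec$r),
    cvg = 100 * sqrt(tr$sigma_g2) / tr$mean,
    cve = 100 * sqrt(tr$sigma_e2) / tr$mean,
    ratio = sqrt(tr$sigma_g2 / tr$sigma_e2),
    stringsAsFactors = FALSE)
}
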