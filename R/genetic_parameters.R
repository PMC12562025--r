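#' Variance components and broad-sense heritability from mean squares
#'
#' Converts one-way ANOVA mean squares of a balanced CRD with `k`
#' replicates into the classical genetic-parameter estimators used in
#' germplasm characterization:
#' \describe{
#'   \item{phenotypic variance}{`sigma_f2 = QMg / k`}
#'   \item{environmental variance}{`sigma_e2 = QMr / k`}
#'   \item{genetic variance}{`sigma_g2 = (QMg - QMr) / k`}
#'   \item{broad-sense heritability}{`h2 = sigma_g2 / sigma_f2`, i.e. the
#'     proportion of the variance among genotype means that is genetic;
#'     algebraically `1 - QMr / QMg`}
#'   \item{genetic coefficient of variation}{`CVg = 100 * sqrt(sigma_g2) / m`}
#'   \item{environmental coefficient of variation}{`CVe = 100 * sqrt(QMr) / m`,
#'     the residual standard deviation on the observation scale — the
#'     experimental CV% — so that
#'     `CVg/CVe = sqrt((QMg - QMr) / (k * QMr))`}
#' }
#' A `CVg/CVe` ratio above 1 indicates that genetic variation predominates
#' over residual variation, the usual screen for traits worth selecting on.
#'
#' When `QMr > QMg` the genetic-variance estimator is negative; it is
#' reported as-is and flagged (`negative_sigma_g2`), never truncated to
#' zero, so simulation studies see the estimator's true sampling behavior.
#'
#' @param object a `trait_anova` table (from [trait_anova]) or a
#'   data.frame with columns `trait`, `QMg`, `QMr` and `mean` (printed
#'   ANOVA summaries can be replayed directly this way).
#' @param k replicates per genotype. Defaults to the `r` attribute when
#'   `object` is a `trait_anova`.
#' @param ... unused.
#' @return data.frame of class `genetic_parameters`: columns `trait,
#'   sigma_f2, sigma_e2, sigma_g2, h2, cvg, cve, ratio, flags`. `h2` is a
#'   fraction; multiply by 100 for the conventional percent rendering
#'   (reports and [write_report] do). Flags: `negative_sigma_g2`,
#'   `zero_QMr` (ratio infinite), `zero_mean` (CVs undefined).
#' @examples
#' # replaying printed mean squares (k = 4 replicates)
#' ms <- data.frame(trait = "fruit_length", QMg = 837.33, QMr = 25.52,
#'                  mean = 91.12)
#' genetic_parameters(ms, k = 4)
#' @export
genetic_parameters <- function(object, k = NULL, ...) {
  if (inherits(object, "trait_anova") && is.null(k)) k <- attr(object, "r")
  if (is.null(k) || length(k) != 1L || k < 2) {
    stop("'k' (replicates) must be a single value >= 2", call. = FALSE)
  }
  df <- as.data.frame(object)
  if ("grand_mean" %in% names(df) && !"mean" %in% names(df)) {
    df$mean <- df$grand_mean
  }
  required <- c("trait", "QMg", "QMr", "mean")
  if (!all(required %in% names(df))) {
    stop("'object' must provide columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }

  sigma_f2 <- df$QMg / k
  sigma_e2 <- df$QMr / k
  sigma_g2 <- (df$QMg - df$QMr) / k
  h2 <- ifelse(df$QMg > 0, sigma_g2 / sigma_f2, 0)
  sg <- sqrt(pmax(sigma_g2, 0))  # sqrt of the positive part; negatives flagged
  cvg <- ifelse(df$mean != 0, 100 * sg / abs(df$mean), NaN)
  cve <- ifelse(df$mean != 0, 100 * sqrt(df$QMr) / abs(df$mean), NaN)
  ratio <- ifelse(df$QMr > 0, sg / sqrt(df$QMr), Inf)

  flags <- character(nrow(df))
  flags[sigma_g2 < 0] <- "negative_sigma_g2"
  flags[df$QMr == 0] <- paste0(flags[df$QMr == 0], ";zero_QMr")
  flags[df$mean == 0] <- paste0(flags[df$mean == 0], ";zero_mean")
  flags <- sub("^;", "", flags)

  out <- data.frame(trait = df$trait,
                    sigma_f2 = sigma_f2, sigma_e2 = sigma_e2,
                    sigma_g2 = sigma_g2,
                    h2 = h2, cvg = cvg, cve = cve, ratio = ratio,
                    flags = flags, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, k = as.integer(k),
            class = c("genetic_parameters", "data.frame"))
}
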