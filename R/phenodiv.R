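#' Fit the full phenotypic-divergence analysis
#'
#' One call runs the complete pipeline used to characterize phenotypic
#' divergence among genotypes (mother plants) in a balanced completely
#' randomized trial:
#' per-trait one-way ANOVA ([trait_anova]), Scott-Knott grouping of
#' genotype means ([scott_knott]), variance components with broad-sense
#' heritability and CVg/CVe ([genetic_parameters]), pooled residual
#' covariance ([pooled_residual_covariance]), generalized Mahalanobis D2
#' between all genotype pairs ([mahalanobis_matrix]), Singh's per-trait
#' contributions ([singh_contributions]), UPGMA clustering ([upgma]) with
#' cophenetic correlation, and group extraction at the Mojena cutoff
#' ([mojena_cutoff], [cut_tree]).
#'
#' @param data a [trait_table], or a long data.frame coercible to one
#'   (columns `genotype, replicate, trait, value`).
#' @param alpha Scott-Knott significance level; default 0.05.
#' @param mojena_k Mojena cutoff multiplier; default 1.25.
#' @param cov_scale covariance scaling passed to
#'   [pooled_residual_covariance]; groupings are invariant to it.
#' @return an object of class `phenodiv` with components `table`, `anova`,
#'   `genetic_parameters`, `scott_knott` (list of per-trait groupings),
#'   `psi`, `d2`, `contributions`, `tree`, `cophenetic`, `cutoff`,
#'   `groups`, and the matched `call`. See [summary.phenodiv],
#'   [plot.phenodiv], [write_report].
#' @examples
#' sp <- cohort_spec(G = 12, r = 4,
#'   traits = data.frame(trait = c("FL", "SW"), mean = c(90, 5),
#'                       sigma_g2 = c(150, 0.5), sigma_e2 = c(25, 0.1)),
#'   seed = 7)
#' fit <- phenodiv(simulate_cohort(sp))
#' summary(fit)
#' @export
phenodiv <- function(data, alpha = 0.05, mojena_k = 1.25,
                     cov_scale = c("observations", "means")) {
  cov_scale <- match.arg(cov_scale)
  x <- as_trait_table(data)
  if (n_genotypes(x) < 3L) {
    stop("phenodiv needs at least 3 genotypes (cophenetic correlation is ",
         "degenerate below that)", call. = FALSE)
  }

  an <- trait_anova(x)
  gp <- genetic_parameters(an)
  sk <- lapply(attr(x, "traits"), function(tr) scott_knott(x, tr, alpha))
  names(sk) <- attr(x, "traits")
  psi <- pooled_residual_covariance(x, scale = cov_scale)
  d2 <- mahalanobis_matrix(x, psi)
  contrib <- singh_contributions(x, psi)
  tree <- upgma(d2)
  coph <- cophenetic_correlation(tree, d2)
  cutoff <- mojena_cutoff(tree, k = mojena_k)
  groups <- cut_tree(tree, cutoff)

  structure(list(table = x, anova = an, genetic_parameters = gp,
                 scott_knott = sk, psi = psi, d2 = d2,
                 contributions = contrib, tree = tree,
                 cophenetic = coph, cutoff = cutoff, groups = groups,
                 alpha = alpha, mojena_k = mojena_k,
                 cov_scale = cov_scale, call = match.call()),
            class = "phenodiv")
}

#' @export
print.phenodiv <- function(x, ...) {
  cat("Phenotypic divergence analysis\n")
  cat("  ", n_genotypes(x$table), " genotypes, ", n_traits(x$table),
      " traits, ", n_replicates(x$table), " replicates\n", sep = "")
  cat("  Scott-Knott alpha = ", x$alpha, ", Mojena k = ", x$mojena_k,
      "\n", sep = "")
  cat("  Cophenetic correlation: ", format(x$cophenetic, digits = 3),
      "\n", sep = "")
  cat("  Mojena cutoff ", format(x$cutoff, digits = 4), " -> ",
      max(x$groups), " group(s)\n", sep = "")
  invisible(x)
}

#' Summarize a phenotypic-divergence fit
#'
#' @param object a [phenodiv] fit.
#' @param ... unused.
#' @return a `summary.phenodiv` object: per-trait table joining the ANOVA
#'   and genetic-parameter results (h2 and CVs in percent, significance
#'   stars on F), the top trait contributions, and the clustering summary.
#' @export
summary.phenodiv <- function(object, ...) {
  an <- object$anova
  gp <- object$genetic_parameters
  tab <- data.frame(trait = an$trait,
                    QMg = an$QMg, QMr = an$QMr,
                    F = an$F, signif = signif_stars(an$p),
                    mean = an$grand_mean,
                    h2_percent = 100 * gp$h2,
                    cvg_cve = gp$ratio,
                    cv_percent = an$cv_percent,
                    stringsAsFactors = FALSE)
  structure(list(traits = tab, contributions = object$contributions,
                 cophenetic = object$cophenetic, cutoff = object$cutoff,
                 n_groups = max(object$groups), groups = object$groups),
            class = "summary.phenodiv")
}

#' @export
print.summary.phenodiv <- function(x, digits = 4, ...) {
  cat("Per-trait ANOVA and genetic parameters:\n")
  print(format(x$traits, digits = digits), row.names = FALSE)
  cat("\nTrait contributions to divergence (Singh):\n")
  print(format(x$contributions, digits = digits), row.names = FALSE)
  cat("\nCophenetic correlation: ", format(x$cophenetic, digits = 3),
      "\nMojena cutoff: ", format(x$cutoff, digits = digits),
      " -> ", x$n_groups, " group(s)\n", sep = "")
  sizes <- table(x$groups)
  cat("Group sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.phenodiv <- function(object, ...) {
  x <- object$table
  m <- trait_means(x)
  m[cbind(match(x$genotype, rownames(m)), match(x$trait, colnames(m)))]
}

#' @export
residuals.phenodiv <- function(object, ...) {
  object$table$value - fitted(object)
}

#' Plot a phenotypic-divergence fit
#'
#' `which = "dendrogram"` draws the UPGMA dendrogram with the Mojena
#' cutoff as a dashed line; `which = "contributions"` draws the Singh
#' per-trait contribution bar chart, sorted descending.
#'
#' @param x a [phenodiv] fit.
#' @param which `"dendrogram"` or `"contributions"`.
#' @param ... passed to the underlying plot function.
#' @return `x`, invisibly.
#' @export
plot.phenodiv <- function(x, which = c("dendrogram", "contributions"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(x$tree, hang = -1, xlab = "genotype",
         ylab = expression(D^2 ~ "fusion level"),
         main = "UPGMA dendrogram", sub = "", ...)
    graphics::abline(h = x$cutoff, lty = 2, col = "red3")
  } else {
    cb <- x$contributions
    graphics::barplot(cb$percent, names.arg = cb$trait, las = 2,
                      ylab = "relative contribution (%)",
                      main = "Trait contributions to divergence", ...)
  }
  invisible(x)
}

#' Write the full report bundle of a fit
#'
#' Writes the standard CSV/Newick outputs of a divergence study into
#' `dir`: `anova.csv` (with significance stars), `genetic_params.csv` (h2
#' and CVs in percent), `sk_groups.csv`, `d2_matrix.csv`,
#' `contributions.csv`, `dendrogram.newick`, `groups.csv` and `run_log.txt`
#' recording every numeric decision (alpha, Mojena k, covariance scale,
#' cutoff). Outputs are deterministic: the same fit writes byte-identical
#' files.
#'
#' @param fit a [phenodiv] fit.
#' @param dir output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "phenodiv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)

  an <- as.data.frame(fit$anova)
  an$signif <- signif_stars(an$p)
  utils::write.csv(an, fp("anova.csv"), row.names = FALSE, quote = FALSE)

  gp <- as.data.frame(fit$genetic_parameters)
  out <- data.frame(trait = gp$trait, sigma_f2 = gp$sigma_f2,
                    sigma_e2 = gp$sigma_e2, sigma_g2 = gp$sigma_g2,
                    h2_percent = 100 * gp$h2, cvg_percent = gp$cvg,
                    cve_percent = gp$cve, cvg_cve_ratio = gp$ratio,
                    flags = gp$flags)
  utils::write.csv(out, fp("genetic_params.csv"), row.names = FALSE,
                   quote = FALSE)

  sk <- do.call(rbind, lapply(names(fit$scott_knott), function(tr) {
    cbind(trait = tr, as.data.frame(fit$scott_knott[[tr]]))
  }))
  utils::write.csv(sk, fp("sk_groups.csv"), row.names = FALSE, quote = FALSE)

  utils::write.csv(as.data.frame(fit$d2), fp("d2_matrix.csv"),
                   quote = FALSE)
  utils::write.csv(as.data.frame(fit$contributions), fp("contributions.csv"),
                   row.names = FALSE, quote = FALSE)
  write_newick(fit$tree, fp("dendrogram.newick"))
  utils::write.csv(data.frame(genotype = names(fit$groups),
                              group = as.integer(fit$groups)),
                   fp("groups.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(merge_step = seq_along(fit$tree$height),
                              fusion_level = fit$tree$height),
                   fp("fusion_levels.csv"), row.names = FALSE, quote = FALSE)

  writeLines(c(
    "phenodiv run log",
    paste0("genotypes: ", n_genotypes(fit$table)),
    paste0("traits: ", n_traits(fit$table)),
    paste0("replicates: ", n_replicates(fit$table)),
    paste0("scott_knott_alpha: ", fit$alpha),
    paste0("mojena_k: ", fit$mojena_k),
    paste0("covariance_scale: ", fit$cov_scale),
    paste0("mojena_cutoff: ", format(fit$cutoff, digits = 10)),
    paste0("cophenetic_correlation: ", format(fit$cophenetic, digits = 10)),
    paste0("n_groups: ", max(fit$groups))
  ), fp("run_log.txt"))
  invisible(dir)
}
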