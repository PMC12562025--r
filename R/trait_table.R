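#' Construct a balanced replicated trait table
#'
#' A trait table holds observations from a balanced completely randomized
#' design (CRD): `G` genotypes (mother plants) by `T` traits by `r`
#' replicates. It is the sole real input of the divergence pipeline and is
#' stored in long format, one row per observation, with the original trait
#' units preserved (no internal standardization; the Mahalanobis metric
#' scales by covariance downstream).
#'
#' Validation is strict: every `(genotype, trait)` cell must hold exactly
#' `r` finite values, and `(genotype, replicate, trait)` keys must be
#' unique. Missing cells are rejected, never imputed, because all
#' downstream variance-component formulas assume equal replication.
#'
#' @param data a data.frame with columns `genotype`, `replicate`, `trait`,
#'   `value`. Genotype and trait ordering is first-appearance order.
#' @return an object of class `trait_table`: the validated long
#'   data.frame with attributes `genotypes`, `traits` (character vectors in
#'   first-appearance order) and `r` (replicates per cell).
#' @examples
#' df <- expand.grid(replicate = 1:2, genotype = c("g1", "g2", "g3"),
#'                   trait = c("length", "mass"))
#' df$value <- rnorm(nrow(df), 10)
#' tt <- trait_table(df)
#' n_genotypes(tt)
#' @export
trait_table <- function(data) {
  required <- c("genotype", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$genotype <- as.character(data$genotype)
  data$trait <- as.character(data$trait)

  if (!is.numeric(data$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(data$value))))[1L]
    stop("non-numeric trait value at row ", bad, call. = FALSE)
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    bad <- which(!is.finite(data$value))[1L]
    stop("missing or non-finite trait value at row ", bad,
         " (genotype ", data$genotype[bad], ", trait ", data$trait[bad], ")",
         call. = FALSE)
  }

  key <- paste(data$genotype, data$replicate, data$trait, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- data[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate observation for genotype ", bad$genotype,
         ", trait ", bad$trait, ", replicate ", bad$replicate, call. = FALSE)
  }

  genotypes <- unique(data$genotype)
  traits <- unique(data$trait)
  counts <- table(factor(data$genotype, levels = genotypes),
                  factor(data$trait, levels = traits))
  tab <- table(counts)
  r <- as.integer(names(tab)[which.max(tab)])  # modal replicate count
  if (any(counts != r)) {
    off <- which(counts != r, arr.ind = TRUE)[1L, ]
    stop("unbalanced design: genotype ", genotypes[off[1L]],
         ", trait ", traits[off[2L]], " has ", counts[off[1L], off[2L]],
         " replicate(s), expected ", r, call. = FALSE)
  }
  if (r < 2L) {
    stop("at least 2 replicates per (genotype, trait) cell are required",
         call. = FALSE)
  }

  data <- data[order(match(data$genotype, genotypes),
                     match(data$trait, traits),
                     data$replicate), , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            genotypes = genotypes,
            traits = traits,
            r = as.integer(r),
            class = c("trait_table", "data.frame"))
}

#' @rdname trait_table
#' @param x object to coerce or query.
#' @export
as_trait_table <- function(x) {
  if (inherits(x, "trait_table")) return(x)
  trait_table(x)
}

#' @rdname trait_table
#' @export
n_genotypes <- function(x) length(attr(x, "genotypes"))

#' @rdname trait_table
#' @export
n_traits <- function(x) length(attr(x, "traits"))

#' @rdname trait_table
#' @export
n_replicates <- function(x) attr(x, "r")

#' @export
print.trait_table <- function(x, ...) {
  cat("Balanced trait table: ", n_genotypes(x), " genotypes x ",
      n_traits(x), " traits x ", n_replicates(x), " replicates\n", sep = "")
  cat("Traits: ", paste(utils::head(attr(x, "traits"), 8L), collapse = ", "),
      if (n_traits(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Genotype-by-trait mean matrix
#'
#' Replicate means for every genotype and trait, the basis of the
#' Scott-Knott grouping and of all Mahalanobis distances.
#'
#' @param x a [trait_table].
#' @return numeric `G x T` matrix, rows named by genotype, columns by trait.
#' @export
trait_means <- function(x) {
  x <- as_trait_table(x)
  g <- factor(x$genotype, levels = attr(x, "genotypes"))
  t <- factor(x$trait, levels = attr(x, "traits"))
  m <- tapply(x$value, list(g, t), mean)
  m <- matrix(m, nrow = nlevels(g), ncol = nlevels(t),
              dimnames = list(levels(g), levels(t)))
  m
}

#' Read a replicated trait table from CSV
#'
#' Long format (the canonical dialect) has columns
#' `genotype,replicate,trait,value`; wide format has one row per
#' `(genotype, replicate)` and one column per trait. Both are validated to
#' a balanced [trait_table].
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param format `"long"` (default) or `"wide"`.
#' @return a validated [trait_table].
#' @export
read_trait_table <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "wide") {
    id <- c("genotype", "replicate")
    if (!all(id %in% names(df))) {
      stop("wide trait CSV must have 'genotype' and 'replicate' columns",
           call. = FALSE)
    }
    traits <- setdiff(names(df), id)
    if (length(traits) == 0L) stop("wide trait CSV has no trait columns",
                                   call. = FALSE)
    long <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(genotype = df$genotype, replicate = df$replicate,
                 trait = tr, value = df[[tr]], stringsAsFactors = FALSE)
    }))
    # keep first-appearance genotype order, traits in column order
    long <- long[order(match(long$genotype, unique(df$genotype)),
                       match(long$trait, traits)), , drop = FALSE]
    df <- long
  }
  trait_table(df)
}

#' Write a trait table to long-format CSV
#'
#' The inverse of [read_trait_table]; `read -> write -> read` is the
#' identity on validated tables.
#'
#' @param x a [trait_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  x <- as_trait_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
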