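#' Daily seedling-emergence counts
#'
#' Records new emergences per day for one seed lot (one genotype x
#' replicate), as scored in greenhouse emergence tests: `counts[i]`
#' seedlings newly emerged on day `days[i]` after sowing, out of `n_sown`
#' seeds.
#'
#' @param days strictly increasing positive integers (days after sowing).
#' @param counts non-negative integers, same length as `days`.
#' @param n_sown number of seeds sown (positive integer).
#' @return an object of class `emergence_counts`.
#' @seealso [emergence_speed_index], [mean_emergence_time]
#' @export
emergence_counts <- function(days, counts, n_sown) {
  if (length(days) != length(counts)) {
    stop("'days' and 'counts' must have the same length", call. = FALSE)
  }
  if (any(days <= 0) || any(days != round(days))) {
    stop("'days' must be strictly positive integers", call. = FALSE)
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  if (length(n_sown) != 1L || n_sown <= 0 || n_sown != round(n_sown)) {
    stop("'n_sown' must be a single positive integer", call. = FALSE)
  }
  if (sum(counts) > n_sown) {
    stop("total emergence (", sum(counts), ") exceeds seeds sown (",
         n_sown, ")", call. = FALSE)
  }
  structure(list(days = as.integer(days), counts = as.integer(counts),
                 n_sown = as.integer(n_sown)),
            class = "emergence_counts")
}

#' Maguire's emergence speed index (ESI)
#'
#' `ESI = sum_i counts_i / days_i`, in seedlings per day. Larger values
#' indicate faster, more vigorous emergence; a lot in which nothing
#' emerged scores 0.
#'
#' @param ec an [emergence_counts] object.
#' @return the index (seedlings/day).
#' @export
emergence_speed_index <- function(ec) {
  stopifnot(inherits(ec, "emergence_counts"))
  sum(ec$counts / ec$days)
}

#' Edmond-Drapala mean emergence time (MET)
#'
#' `MET = sum_i counts_i * days_i / sum_i counts_i`, the count-weighted
#' mean day of emergence, in days. Undefined (an error) when no seedling
#' emerged.
#'
#' @param ec an [emergence_counts] object.
#' @return mean emergence time in days, bounded by the first and last day
#'   with a nonzero count.
#' @export
mean_emergence_time <- function(ec) {
  stopifnot(inherits(ec, "emergence_counts"))
  total <- sum(ec$counts)
  if (total == 0L) {
    stop("mean emergence time is undefined: no seedling emerged",
         call. = FALSE)
  }
  sum(as.numeric(ec$counts) * ec$days) / total
}

#' Compute per-replicate vigor indices from a daily-count CSV
#'
#' Reads a CSV with columns `genotype,replicate,day,count` and computes
#' ESI, MET, the emergence percentage (`100 * emerged / n_sown`) and the
#' first-count percentage at `first_count_day` for every
#' `(genotype, replicate)` lot. The result is long-format rows ready to be
#' bound into a [trait_table], mirroring the practice of analysing vigor
#' indices as ordinary traits.
#'
#' @param path CSV file of daily counts.
#' @param n_sown seeds sown per replicate (scalar, applies to every lot).
#' @param first_count_day day of the first emergence count; `NA` disables
#'   the `FEC` trait.
#' @return data.frame with columns `genotype, replicate, trait, value`,
#'   traits `ESI`, `MET`, `EP` and optionally `FEC`.
#' @export
emergence_traits <- function(path, n_sown, first_count_day = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("genotype", "replicate", "day", "count")
  if (!all(required %in% names(df))) {
    stop("emergence CSV must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[c("genotype", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$genotype == keys$genotype[i] &
                df$replicate == keys$replicate[i], , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    ec <- emergence_counts(sub$day, sub$count, n_sown)
    out <- data.frame(
      genotype = keys$genotype[i], replicate = keys$replicate[i],
      trait = c("ESI", "MET", "EP"),
      value = c(emergence_speed_index(ec),
                if (sum(ec$counts) > 0L) mean_emergence_time(ec) else NA_real_,
                100 * sum(ec$counts) / ec$n_sown),
      stringsAsFactors = FALSE)
    if (!is.na(first_count_day)) {
      fec <- 100 * sum(ec$counts[ec$days <= first_count_day]) / ec$n_sown
      out <- rbind(out, data.frame(genotype = keys$genotype[i],
                                   replicate = keys$replicate[i],
                                   trait = "FEC", value = fec,
                                   stringsAsFactors = FALSE))
    }
    out
  })
  do.call(rbind, rows)
}
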