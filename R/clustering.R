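#' UPGMA agglomeration of a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering: at each step the two clusters
#' with the smallest mean cross-pair dissimilarity are merged, and the
#' fusion level recorded is that mean itself (not halved), so Newick
#' heights read directly in D2 units. On a proper dissimilarity the fusion
#' levels are non-decreasing and the implied cophenetic matrix is
#' ultrametric.
#'
#' @param d2 symmetric non-negative dissimilarity matrix with zero
#'   diagonal (e.g. from [mahalanobis_matrix]), `G >= 2` leaves.
#' @return an [stats::hclust] tree; `$height` holds the `G - 1` fusion
#'   levels.
#' @export
upgma <- function(d2) {
  d2 <- as.matrix(d2)
  if (nrow(d2) < 2L) stop("at least 2 leaves are required", call. = FALSE)
  if (!isTRUE(all.equal(d2, t(d2), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(d2 < 0)) stop("dissimilarities must be non-negative",
                        call. = FALSE)
  if (any(abs(diag(d2)) > 1e-12)) {
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  }
  stats::hclust(stats::as.dist(d2), method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise dissimilarities and
#' the cophenetic distances (the fusion level at which each pair of leaves
#' first joins). Values near 1 indicate the dendrogram faithfully
#' represents the dissimilarity matrix; germplasm studies conventionally
#' report it alongside the dendrogram.
#'
#' @param tree an [stats::hclust] tree (see [upgma]).
#' @param d2 the dissimilarity matrix the tree was built from.
#' @return correlation in `[-1, 1]`; exactly 1 when `d2` is ultrametric.
#' @export
cophenetic_correlation <- function(tree, d2) {
  stopifnot(inherits(tree, "hclust"))
  d2 <- as.matrix(d2)
  n <- nrow(d2)
  if (n < 3L) stop("cophenetic correlation needs at least 3 leaves",
                   call. = FALSE)
  if (length(tree$labels) != n ||
      !setequal(tree$labels, rownames(d2))) {
    stop("tree and dissimilarity matrix have different leaves",
         call. = FALSE)
  }
  coph <- as.matrix(stats::cophenetic(tree))
  coph <- coph[rownames(d2), colnames(d2)]
  stats::cor(stats::as.dist(d2), stats::as.dist(coph))
}

#' Mojena's dendrogram cutoff
#'
#' The stopping-rule cutoff `mean(alpha) + k * sd(alpha)` over the `G - 1`
#' fusion levels of the dendrogram (sample standard deviation): merges at
#' or above this level are considered to join genuinely distinct groups.
#'
#' @param tree an [stats::hclust] tree.
#' @param k non-negative multiplier; 1.25 is the widely used
#'   recommendation from Milligan and Cooper's evaluation of stopping
#'   rules.
#' @return the cutoff level, in the units of the input dissimilarity.
#' @export
mojena_cutoff <- function(tree, k = 1.25) {
  stopifnot(inherits(tree, "hclust"))
  if (length(k) != 1L || !is.finite(k) || k < 0) {
    stop("'k' must be a single non-negative number", call. = FALSE)
  }
  h <- tree$height
  if (length(h) < 2L) stop("Mojena cutoff needs at least 3 leaves",
                           call. = FALSE)
  mean(h) + k * stats::sd(h)
}

#' Cut a dendrogram into groups at a fusion-level cutoff
#'
#' Severs every merge whose fusion level is `>= cutoff`; the groups are the
#' connected subtrees whose internal merges all sit strictly below the
#' cutoff. Group ids are numbered by first appearance in leaf (genotype)
#' order. A cutoff below every fusion level yields all-singleton groups;
#' above every level, a single group.
#'
#' @param tree an [stats::hclust] tree.
#' @param cutoff non-negative fusion level, e.g. from [mojena_cutoff].
#' @return named integer vector mapping each leaf to its group id, with
#'   attribute `cutoff`.
#' @export
cut_tree <- function(tree, cutoff) {
  stopifnot(inherits(tree, "hclust"))
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0) {
    stop("'cutoff' must be a single non-negative number", call. = FALSE)
  }
  n <- length(tree$labels)
  leaf_group <- seq_len(n)              # provisional: each leaf its own set
  cluster_of <- vector("list", n - 1L)  # leaves under each internal merge
  for (m in seq_len(n - 1L)) {
    members <- unlist(lapply(tree$merge[m, ], function(ch) {
      if (ch < 0) -ch else cluster_of[[ch]]
    }))
    cluster_of[[m]] <- members
    if (tree$height[m] < cutoff) {
      leaf_group[members] <- min(leaf_group[members])
    }
  }
  # renumber by first appearance in original leaf order
  ids <- match(leaf_group, unique(leaf_group))
  names(ids) <- tree$labels
  structure(ids, cutoff = cutoff)
}

#' Export a dendrogram as Newick
#'
#' Writes the tree with leaves at height 0 and each branch length equal to
#' the difference between the parent and child fusion levels, so root
#' depth equals the final fusion level in the input dissimilarity's units.
#'
#' @param tree an [stats::hclust] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  # as.phylo.hclust halves heights (ultrametric tree convention); restore
  # fusion-level units
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy, file = path)
  invisible(path)
}
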