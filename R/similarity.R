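#' Bray-Curtis similarity between two abundance vectors
#'
#' `2 * sum(min(x, y)) / (sum(x) + sum(y))`: 1 for identical composition,
#' 0 for disjoint species sets. Rescaling both vectors by the same positive
#' constant leaves it unchanged; rescaling one vector does not — the index
#' is deliberately sensitive to density differences.
#'
#' @param x,y equal-length non-negative abundance vectors (counts or
#'   densities), each with at least one positive entry
#' @return similarity in `[0, 1]`
#' @export
#' @examples
#' bray_curtis(c(10, 0, 5), c(5, 5, 5))  # 2/3
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  check_abundance(x, allow_zero = FALSE)
  check_abundance(y, allow_zero = FALSE)
  2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Pairwise Bray-Curtis similarity among sites
#'
#' @param abund an [abundance_matrix()] (or any site x species matrix of
#'   pooled densities) with at least two sites
#' @return symmetric similarity matrix with unit diagonal, class
#'   `similarity_matrix`
#' @seealso [similarity_to_dist()] for the `1 - similarity` distance view
#' @export
similarity_matrix <- function(abund) {
  abund <- as.matrix(abund)
  if (nrow(abund) < 2) stop("need at least two sites")
  n <- nrow(abund)
  m <- diag(1, n)
  dimnames(m) <- list(rownames(abund), rownames(abund))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bray_curtis(abund[i, ], abund[j, ])
    }
  }
  structure(m, class = c("similarity_matrix", "matrix"))
}

#' Distance view of a similarity matrix
#'
#' @param sim a symmetric similarity matrix with unit diagonal
#' @return a [stats::dist] object holding `1 - similarity`
#' @export
similarity_to_dist <- function(sim) {
  sim <- unclass(as.matrix(sim))
  if (!isSymmetric(sim, tol = 1e-8)) stop("similarity matrix not symmetric")
  stats::as.dist(1 - sim)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance between
#' two clusters is the unweighted arithmetic mean of all cross-pair
#' distances, and each merge height is the merging distance, so the
#' implied cophenetic distances are ultrametric.
#'
#' @param d a [stats::dist] object or a symmetric distance matrix with
#'   zero diagonal, over at least two labels
#' @return an object of class `c("upgma", "hclust")`
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(d, tol = 1e-8)) stop("distance matrix not symmetric")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2) stop("need at least two labels")
  hc <- stats::hclust(d, method = "average")
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Cophenetic correlation of a dendrogram against its input distances
#'
#' Pearson correlation between the original pairwise distances and the
#' merge-height (cophenetic) distances over all unordered pairs; the
#' standard measure of how faithfully the tree represents the matrix.
#'
#' @param tree an `hclust`/[upgma()] tree
#' @param d the distance matrix (or `dist`) the tree was built from
#' @return correlation in `[-1, 1]`; `NA` with a warning for fewer than
#'   three labels (a single pair leaves the correlation undefined)
#' @export
cophenetic_correlation <- function(tree, d) {
  stopifnot(inherits(tree, "hclust"))
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 3) {
    warning("cophenetic correlation undefined for < 3 labels")
    return(NA_real_)
  }
  coph <- stats::cophenetic(tree)
  m <- as.matrix(d)[tree$labels, tree$labels]
  stats::cor(stats::as.dist(m), coph)
}

#' Bootstrap branch support for the UPGMA site dendrogram
#'
#' Resamples species (matrix columns) with replacement, rebuilds the
#' Bray-Curtis similarity and UPGMA tree for each replicate, and scores
#' every internal node of the reference tree by the percentage of
#' replicate trees containing the same label clade. Replicates in which
#' some site loses all abundance (possible when its species are not drawn)
#' are redrawn and counted.
#'
#' @param abund pooled site x species [abundance_matrix()], >= 3 sites for
#'   non-trivial support
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer seed; the same seed and `n_reps` give identical
#'   support values
#' @return list of class `branch_support`: `tree` (the reference
#'   [upgma()] tree), `support` (% per internal node, in
#'   [ape::as.phylo()] node order, root first), `n_reps`, `n_redrawn`
#' @export
branch_support <- function(abund, n_reps = 999, seed = 1) {
  abund <- as.matrix(abund)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (nrow(abund) < 2) stop("need at least two sites")
  ref <- upgma(similarity_to_dist(similarity_matrix(abund)))
  ref_phy <- ape::as.phylo(ref)

  n_sp <- ncol(abund)
  n_redrawn <- 0L
  boot <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      repeat {
        idx <- sample.int(n_sp, n_sp, replace = TRUE)
        b <- abund[, idx, drop = FALSE]
        if (all(rowSums(b) > 0)) break
        n_redrawn <<- n_redrawn + 1L
      }
      ape::as.phylo(upgma(similarity_to_dist(similarity_matrix(b))))
    })
  })

  counts <- ape::prop.clades(ref_phy, boot, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  structure(
    list(tree = ref, support = counts / n_reps * 100,
         n_reps = n_reps, n_redrawn = n_redrawn),
    class = "branch_support"
  )
}

#' @export
print.branch_support <- function(x, ...) {
  cat("UPGMA bootstrap support (", x$n_reps, " species resamples, ",
      x$n_redrawn, " degenerate redraws)\n", sep = "")
  phy <- ape::as.phylo(x$tree)
  for (i in seq_along(x$support)) {
    tips <- ape::extract.clade(phy, ape::Ntip(phy) + i)$tip.label
    cat(sprintf("  {%s}: %.1f%%\n", paste(tips, collapse = ","),
                x$support[i]))
  }
  invisible(x)
}

#' Export a dendrogram (with optional support) as Newick text
#'
#' Internal-node labels carry bootstrap support percentages when a
#' [branch_support()] result is given; branch lengths follow the merge
#' heights (each tip-to-tip cophenetic distance equals the corresponding
#' merge height).
#'
#' @param tree an `hclust`/[upgma()] tree, or a [branch_support()] result
#' @param path output file; `NULL` returns the Newick string
#' @param digits number of digits for branch lengths
#' @return the Newick string, invisibly when written to `path`
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  support <- NULL
  if (inherits(tree, "branch_support")) {
    support <- tree$support
    tree <- tree$tree
  }
  phy <- ape::as.phylo(tree)
  if (!is.null(support)) phy$node.label <- formatC(support, format = "g")
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
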