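#' Jaccard index of two sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}; defined as 0 when both sets are
#' empty (so empty tissues never appear spuriously similar).
#'
#' @param set_a,set_b vectors treated as sets
#' @return a proportion in \[0, 1\]
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cross-tissue similarity of age-associated gene sets
#'
#' Computes the pairwise Jaccard matrix over per-tissue gene sets (genes
#' with at least one age-associated splicing event) and clusters tissues by
#' hierarchical agglomeration on the distance 1 - J.
#'
#' @param gene_sets named list (one character vector per tissue), length >= 2
#' @param linkage agglomeration method passed to \code{\link[stats]{hclust}}
#'   (default "average"; the figure-level choice is not fixed by the method)
#' @return list of class \code{tissue_similarity}: \code{jaccard} (symmetric
#'   matrix, diagonal 1 for non-empty sets), \code{hclust}, and \code{tree}
#'   (an \pkg{ape} phylo object, writable as Newick)
#' @export
tissue_similarity <- function(gene_sets, linkage = "average") {
  if (length(gene_sets) < 2L) stopf("need at least 2 tissues")
  nms <- names(gene_sets) %||% paste0("tissue", seq_along(gene_sets))
  k <- length(gene_sets)
  J <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    J[i, i] <- if (length(unique(gene_sets[[i]])) > 0) 1 else 0
    if (i < k) for (j in (i + 1L):k) {
      J[i, j] <- J[j, i] <- jaccard_index(gene_sets[[i]], gene_sets[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - J), method = linkage)
  structure(list(jaccard = J, hclust = hc, tree = ape::as.phylo(hc)),
            class = "tissue_similarity")
}

#' Write the tissue clustering as a Newick tree
#'
#' @param sim a \code{tissue_similarity} object
#' @param path output file
#' @export
write_tissue_tree <- function(sim, path) {
  ape::write.tree(sim$tree, file = path)
  invisible(path)
}
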