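#' Principal-component sample scores of a feature matrix
#'
#' Columns are samples. Sentinel (-1) and NA cells are imputed with the row
#' mean, rows are centered, and sample scores of the top \code{k} right
#' singular vectors are returned. Scores have exactly zero mean across
#' samples; each component's sign is fixed so that its largest-magnitude
#' score is positive, making the decomposition deterministic.
#'
#' @param mat features x samples numeric matrix
#' @param k number of components
#' @return samples x k matrix of scores, ordered by decreasing variance
#' @keywords internal
pc_scores <- function(mat, k) {
  x <- t(impute_sentinels(mat))          # samples x features
  x <- sweep(x, 2L, colMeans(x), "-")
  k <- min(k, dim(x) - c(1L, 0L))
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  flip <- apply(scores, 2L, function(s) sign(s[which.max(abs(s))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, "*")
  rownames(scores) <- colnames(mat)
  colnames(scores) <- paste0("C", seq_len(k))
  scores
}

#' Estimate hidden confounding factors from a feature matrix
#'
#' A principal-component surrogate for PEER-style latent confounders: the
#' top \code{n_factors} sample scores of the row-centered, sentinel-imputed
#' matrix capture the dominant shared variation (batch effects and other
#' hidden structure) across events or genes.
#'
#' @param feature_matrix features x samples matrix; -1 sentinels permitted
#' @param n_factors number of factors (the scan default is 20)
#' @return object of class \code{hidden_factors}: list with \code{factors}
#'   (samples x n_factors score matrix) and \code{age_cor_p} (filled by
#'   \code{\link{filter_age_correlated_factors}})
#' @export
estimate_hidden_factors <- function(feature_matrix, n_factors = 20) {
  n_samples <- ncol(feature_matrix)
  if (n_samples < n_factors + 2) {
    stopf("need at least n_factors + 2 = %d samples, got %d",
          n_factors + 2, n_samples)
  }
  structure(list(factors = pc_scores(feature_matrix, n_factors),
                 age_cor_p = NULL),
            class = "hidden_factors")
}

#' Drop hidden factors significantly correlated with age
#'
#' Each factor is tested for Pearson correlation with age; factors with
#' p < \code{p_threshold} are removed so that the downstream adjustment
#' cannot absorb a genuine age signal. Retained factors carry their
#' correlation p-values.
#'
#' @param factors a \code{hidden_factors} object
#' @param ages numeric age vector aligned with the factor rows
#' @param p_threshold Pearson-correlation p-value below which a factor is
#'   excluded (default 0.05)
#' @return a \code{hidden_factors} object with the surviving factors
#' @export
filter_age_correlated_factors <- function(factors, ages, p_threshold = 0.05) {
  stopifnot(inherits(factors, "hidden_factors"))
  f <- factors$factors
  if (ncol(f) == 0L) return(factors)
  if (nrow(f) != length(ages)) stopf("factors and ages are not aligned")
  if (stats::sd(ages) == 0) stopf("age vector has zero variance")
  pv <- apply(f, 2L, function(col) {
    if (stats::sd(col) == 0) return(1)
    stats::cor.test(col, ages)$p.value
  })
  keep <- pv >= p_threshold
  structure(list(factors = f[, keep, drop = FALSE],
                 age_cor_p = pv[keep]),
            class = "hidden_factors")
}
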