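#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

PSI_SENTINEL <- -1

#' Replace sentinel / missing cells by the row mean
#'
#' Rows that are entirely missing are imputed with 0.5 for PSI-like input
#' (values bounded in \[0,1\]) and 0 otherwise.
#' @param mat numeric matrix, features x samples; -1 marks missing cells
#' @return matrix of the same shape with no sentinels
#' @keywords internal
impute_sentinels <- function(mat) {
  miss <- mat == PSI_SENTINEL | is.na(mat)
  if (!any(miss)) return(mat)
  psi_like <- all(mat[!miss] >= 0 & mat[!miss] <= 1)
  out <- mat
  out[miss] <- NA_real_
  rm_ <- rowMeans(out, na.rm = TRUE)
  rm_[is.nan(rm_)] <- if (psi_like) 0.5 else 0
  idx <- which(miss, arr.ind = TRUE)
  out[idx] <- rm_[idx[, 1L]]
  out
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Keeps derived seeds within the 32-bit integer range so they are valid
#' arguments to \code{set.seed}.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
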