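#' Fit the per-event age model
#'
#' Ordinary least squares of a single response (one event's PSI values, or
#' one feature's expression) on age, gender and the retained hidden factors:
#' \deqn{y_j = \alpha + \beta^1 age_j + \beta^2 gender_j +
#'   \sum_k \beta^{k+2} CF_j^k + \epsilon_j}
#' Cells equal to -1 (the SUPPA "gene not expressed" sentinel) or NA are
#' excluded; the fit is only reported when at least \code{min_samples}
#' usable samples remain and the response has non-zero variance, otherwise a
#' \code{not_tested} result is returned. The age p-value is the two-sided
#' t-test on \eqn{\beta^1}.
#'
#' @param response numeric vector; -1 marks unusable cells
#' @param ages,genders aligned covariate vectors
#' @param factors optional \code{hidden_factors} object or samples x k matrix
#' @param min_samples minimum usable samples to report a fit (default 50)
#' @return object of class \code{age_model_fit}: when tested, a list with
#'   coefficients, beta_age, se_age, p_age, df, n_used, residuals; otherwise
#'   \code{tested = FALSE} with a reason
#' @export
fit_age_model <- function(response, ages, genders, factors = NULL,
                          min_samples = 50) {
  fm <- if (inherits(factors, "hidden_factors")) factors$factors else factors
  n <- length(response)
  if (length(ages) != n || length(genders) != n ||
      (!is.null(fm) && nrow(fm) != n)) {
    stopf("response, ages, genders and factors are not aligned")
  }
  usable <- !(response == PSI_SENTINEL | is.na(response))
  n_used <- sum(usable)
  if (n_used < min_samples) {
    return(structure(list(tested = FALSE, n_used = n_used,
                          reason = sprintf("only %d usable samples (< %d)",
                                           n_used, min_samples)),
                     class = "age_model_fit"))
  }
  y <- response[usable]
  if (stats::sd(y) == 0) {
    return(structure(list(tested = FALSE, n_used = n_used,
                          reason = "zero-variance response"),
                     class = "age_model_fit"))
  }
  X <- cbind(`(Intercept)` = 1, age = ages[usable], gender = genders[usable])
  if (!is.null(fm) && ncol(fm) > 0) {
    cf <- fm[usable, , drop = FALSE]
    colnames(cf) <- colnames(fm) %||% paste0("CF", seq_len(ncol(fm)))
    X <- cbind(X, cf)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("rank-deficient design: column(s) %s are collinear",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n_used - ncol(X)
  if (df <= 0) {
    return(structure(list(tested = FALSE, n_used = n_used,
                          reason = "no residual degrees of freedom"),
                     class = "age_model_fit"))
  }
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta / se
  structure(list(tested = TRUE,
                 coefficients = beta,
                 beta_age = unname(beta["age"]),
                 se_age = unname(se[2L]),
                 t_age = unname(tstat[2L]),
                 p_age = unname(2 * stats::pt(-abs(tstat[2L]), df)),
                 df = df, n_used = n_used,
                 residuals = res),
            class = "age_model_fit")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return q-values of the same length and order
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}

# Projection-based age test used by both the observed fit and the
# permutation null (Frisch-Waugh: partial out intercept/gender/factors, then
# test the age residual). `age_cols` may be a matrix whose columns are
# (permuted) age vectors; returns a p-value per column plus the per-column
# beta estimate.
age_partial_test <- function(y, age_cols, Z) {
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  ra <- qr.resid(qz, age_cols)
  if (is.null(dim(ra))) ra <- matrix(ra, ncol = 1L)
  ssa <- colSums(ra^2)
  df <- length(y) - qz$rank - 1L
  beta <- colSums(ra * ry) / ssa
  rss <- pmax(sum(ry^2) - beta^2 * ssa, 0)
  se <- sqrt(rss / df / ssa)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[ssa < 1e-12 * sum(y^2 + 1)] <- 1   # permuted age collinear with Z
  list(beta = beta, se = se, t = tstat, p = p, df = df)
}

# Build the matrix of permuted age vectors used by a scan: one master seed,
# shared by all events, so results do not depend on event iteration order.
permutation_matrix <- function(ages, n_perm, seed) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) ages[sample.int(length(ages))],
         numeric(length(ages)))
}

#' Permutation null for one event's age association
#'
#' Refits the age model \code{n_perm} times with donor ages shuffled across
#' all individuals (gender and hidden factors stay fixed). By default the
#' returned fraction is the empirical permutation p-value — the share of
#' permutations whose age p-value is at or below the observed one — so a
#' genuinely age-driven event scores near 0 while an artefact of the
#' parametric approximation scores near its nominal p. An event survives
#' the permutation criterion when fewer than 5\% of the permuted fits are
#' as significant as the observed fit. Supplying a numeric \code{alpha}
#' instead returns the share of permutations reaching that fixed nominal
#' level (useful for checking the null property of the permuted statistic,
#' which concentrates near \code{alpha} for any event).
#'
#' @inheritParams fit_age_model
#' @param n_perm number of permutations (the headline scan uses 1000)
#' @param seed RNG seed for the permutation stream
#' @param alpha NULL (default) to compare permuted fits against the observed
#'   p-value; a numeric level to count permuted fits below that fixed level
#' @return the permutation fraction described above
#' @export
permutation_null <- function(response, ages, genders, factors = NULL,
                             n_perm = 1000, seed = 1L, alpha = NULL,
                             min_samples = 50) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  fit <- fit_age_model(response, ages, genders, factors, min_samples)
  if (!fit$tested) {
    stopf("event is not_tested (%s); permutation null undefined", fit$reason)
  }
  fm <- if (inherits(factors, "hidden_factors")) factors$factors else factors
  usable <- !(response == PSI_SENTINEL | is.na(response))
  P <- permutation_matrix(ages, n_perm, seed)
  Z <- cbind(1, genders[usable])
  if (!is.null(fm) && ncol(fm) > 0) Z <- cbind(Z, fm[usable, , drop = FALSE])
  pt_ <- age_partial_test(response[usable], P[usable, , drop = FALSE], Z)
  mean(pt_$p <= (alpha %||% fit$p_age))
}

#' Scan a feature matrix for age-associated rows
#'
#' The complete detection core: hidden factors are estimated from
#' \code{factor_source} (default: the scanned matrix itself), factors
#' significantly correlated with age are excluded, every row with at least
#' \code{min_samples} usable cells is fitted to the age model, p-values are
#' BH-adjusted across all tested rows, and each tested row receives an
#' age-shuffling permutation fraction (the share of permuted fits at least
#' as significant as the observed one). A row is called significant when
#' q <= \code{fdr} and fewer than \code{perm_threshold} of its permutations
#' match the observed significance.
#'
#' @param mat features x samples matrix (-1 sentinel allowed)
#' @param phenotypes data.frame with columns sample_id, age, gender, aligned
#'   to (or matched by name against) the matrix columns
#' @param n_factors hidden factors to estimate (default 20)
#' @param n_perm permutations per tested row (default 1000)
#' @param min_samples usable-sample floor (default 50)
#' @param fdr BH threshold for the significance call (default 0.05)
#' @param perm_threshold permutation-fraction ceiling (default 0.05,
#'   exclusive)
#' @param seed master seed for the shared permutation stream
#' @param use_factors set FALSE to fit without confounder adjustment
#' @param factor_source optional matrix from which confounders are estimated
#'   (e.g. a genome-wide expression matrix for the gene scan)
#' @return data.frame (one row per feature) with event_id, n_used, beta_age,
#'   se, p, q, perm_fraction, significant, direction; the retained
#'   \code{hidden_factors} object is attached as attribute \code{"factors"}
#' @export
scan_age_association <- function(mat, phenotypes, n_factors = 20,
                                 n_perm = 1000, min_samples = 50,
                                 fdr = 0.05, perm_threshold = 0.05,
                                 seed = 1L, use_factors = TRUE,
                                 factor_source = NULL) {
  ph <- phenotypes
  if (!is.null(colnames(mat)) && all(colnames(mat) %in% ph$sample_id)) {
    ph <- ph[match(colnames(mat), ph$sample_id), , drop = FALSE]
  } else if (ncol(mat) != nrow(ph)) {
    stopf("matrix columns and phenotype rows are not aligned")
  }
  ages <- ph$age
  genders <- ph$gender

  hf <- NULL
  fm <- NULL
  if (use_factors && n_factors > 0) {
    hf <- estimate_hidden_factors(factor_source %||% mat, n_factors)
    hf <- filter_age_correlated_factors(hf, ages)
    fm <- hf$factors
  }

  P <- permutation_matrix(ages, n_perm, derive_seed(seed, 11L))
  m <- nrow(mat)
  ids <- rownames(mat) %||% sprintf("row%05d", seq_len(m))
  n_used <- integer(m)
  beta <- se <- p <- perm_frac <- rep(NA_real_, m)
  tested <- logical(m)

  for (i in seq_len(m)) {
    y_all <- mat[i, ]
    usable <- !(y_all == PSI_SENTINEL | is.na(y_all))
    n_used[i] <- sum(usable)
    if (n_used[i] < min_samples) next
    y <- y_all[usable]
    if (stats::sd(y) == 0) next
    Z <- cbind(1, genders[usable])
    if (!is.null(fm) && ncol(fm) > 0) {
      Z <- cbind(Z, fm[usable, , drop = FALSE])
    }
    qz_rank <- qr(Z)$rank
    if (qz_rank < ncol(Z) || n_used[i] - qz_rank - 1L <= 0) next
    obs <- age_partial_test(y, matrix(ages[usable], ncol = 1L), Z)
    if (!is.finite(obs$p[1])) next
    tested[i] <- TRUE
    beta[i] <- obs$beta[1]
    se[i] <- obs$se[1]
    p[i] <- obs$p[1]
    pp <- age_partial_test(y, P[usable, , drop = FALSE], Z)
    perm_frac[i] <- mean(pp$p <= obs$p[1])
  }

  res <- data.frame(event_id = ids, n_used = n_used, tested = tested,
                    beta_age = beta, se = se, p = p,
                    q = NA_real_, perm_fraction = perm_frac,
                    stringsAsFactors = FALSE)
  res$q[tested] <- benjamini_hochberg(res$p[tested])
  res <- call_significant(res, fdr = fdr, perm_threshold = perm_threshold)
  attr(res, "factors") <- hf
  res
}

#' Apply the dual significance criterion
#'
#' An event is significant when its BH q-value is at most \code{fdr} AND
#' fewer than \code{perm_threshold} of its age-shuffling permutations
#' reached nominal significance. Direction is the sign of the fitted age
#' coefficient.
#'
#' @param results data.frame with columns q, perm_fraction, beta_age
#' @param fdr BH threshold (default 0.05)
#' @param perm_threshold permutation-fraction ceiling, exclusive
#'   (default 0.05)
#' @return the input with columns \code{significant} and \code{direction}
#'   set/refreshed
#' @export
call_significant <- function(results, fdr = 0.05, perm_threshold = 0.05) {
  sig <- !is.na(results$q) & results$q <= fdr &
    !is.na(results$perm_fraction) & results$perm_fraction < perm_threshold
  results$significant <- sig
  results$direction <- ifelse(is.na(results$beta_age), 0L,
                              as.integer(sign(results$beta_age)))
  results
}
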