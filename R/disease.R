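#' Nested-model likelihood-ratio test of splicing's disease contribution
#'
#' Compares two nested models of binary disease status:
#' \describe{
#'   \item{null}{D ~ age + gender + gene-expression components}
#'   \item{splicing}{D ~ age + gender + gene-expression components +
#'     PSI components of the significant age-associated events}
#' }
#' Both are fitted by maximum likelihood; the statistic
#' \eqn{LLR = 2(\ell_{alt} - \ell_{null})} is referred to a chi-square
#' distribution with degrees of freedom equal to the number of added PSI
#' components. The default likelihood is binomial (logistic regression),
#' which makes the LLR chi-square test proper for a 0/1 outcome; a
#' Gaussian-linear fit of the same design is available via
#' \code{family = "gaussian"}.
#'
#' @param disease_labels 0/1 vector, both classes present
#' @param ages,genders covariate vectors
#' @param ge_features samples x k matrix of gene-expression components
#'   (see \code{\link{mds_reduce}})
#' @param psi_features samples x k' matrix of PSI components built from the
#'   significant age-associated events only
#' @param family "binomial" (default) or "gaussian"
#' @return list of class \code{nested_llr}: ll_null, ll_alt, llr, df,
#'   p_value, separation flag and note
#' @export
nested_llr_test <- function(disease_labels, ages, genders, ge_features,
                            psi_features,
                            family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  d <- as.integer(disease_labels)
  if (!all(d %in% c(0L, 1L))) stopf("disease labels must be 0/1")
  if (length(unique(d)) < 2L) stopf("both disease classes must be present")
  ge <- as.matrix(ge_features)
  psi <- as.matrix(psi_features)
  n <- length(d)
  p_alt <- 3L + ncol(ge) + ncol(psi)
  if (n <= p_alt) {
    stopf("n (%d) must exceed the alternative model's covariates (%d)",
          n, p_alt)
  }
  colnames(ge) <- paste0("GE", seq_len(ncol(ge)))
  colnames(psi) <- paste0("PSI", seq_len(ncol(psi)))
  dat <- data.frame(d = d, age = ages, gender = genders, ge, psi)
  f_null <- stats::as.formula(paste(
    "d ~ age + gender +", paste(colnames(ge), collapse = " + ")))
  f_alt <- stats::as.formula(paste(
    "d ~ age + gender +", paste(c(colnames(ge), colnames(psi)),
                                collapse = " + ")))
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  fit_null <- suppressWarnings(stats::glm(f_null, data = dat, family = fam))
  fit_alt <- suppressWarnings(stats::glm(f_alt, data = dat, family = fam))
  ll_null <- as.numeric(stats::logLik(fit_null))
  ll_alt <- as.numeric(stats::logLik(fit_alt))
  llr <- 2 * (ll_alt - ll_null)
  df <- ncol(psi)
  sep <- FALSE
  note <- NULL
  if (family == "binomial") {
    mu <- stats::fitted(fit_alt)
    sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || !fit_alt$converged
    if (sep) {
      note <- paste("possible complete separation: fitted probabilities at",
                    "the boundary; consider a penalised likelihood")
    }
  }
  structure(list(ll_null = ll_null, ll_alt = ll_alt, llr = llr, df = df,
                 p_value = stats::pchisq(max(llr, 0), df,
                                         lower.tail = FALSE),
                 family = family, separation = sep, note = note),
            class = "nested_llr")
}

#' Build both feature blocks and run the nested LLR test
#'
#' Convenience wrapper: reduces log gene expression and the significant
#' events' PSI rows to their top components and applies
#' \code{\link{nested_llr_test}}.
#'
#' @param disease_labels,phenotypes labels and phenotype table
#' @param gene_expr genes x samples expression matrix
#' @param psi events x samples PSI matrix
#' @param significant_events event IDs flagged by the association scan
#' @param n_ge_components,n_psi_components component counts (the full-scale
#'   analysis uses 100 of each; reduced counts keep n/df healthy at
#'   simulation scale)
#' @param family passed to \code{\link{nested_llr_test}}
#' @return a \code{nested_llr} result
#' @export
disease_llr <- function(disease_labels, phenotypes, gene_expr, psi,
                        significant_events, n_ge_components = 100,
                        n_psi_components = 100, family = "binomial") {
  if (length(significant_events) == 0L) {
    stopf("no significant age-associated events to build PSI features from")
  }
  ge_feat <- mds_reduce(log2(gene_expr + 1), n_ge_components)
  psi_feat <- mds_reduce(psi[significant_events, , drop = FALSE],
                         min(n_psi_components,
                             length(significant_events)))
  nested_llr_test(disease_labels, phenotypes$age, phenotypes$gender,
                  ge_feat, psi_feat, family = family)
}
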