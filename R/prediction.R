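#' Reduce a profile matrix to sample-level components
#'
#' Classical metric multidimensional scaling of the samples on Euclidean
#' distances, computed via the singular value decomposition of the centered
#' profile — identical (up to per-axis sign) to principal-component scores.
#' Sentinel cells are imputed with the row (event) mean first. Components
#' are ordered by decreasing explained variance and have zero mean.
#'
#' @param profile_matrix features x samples matrix (-1 sentinel allowed)
#' @param n_components number of components (30 for age models, 100 for the
#'   disease models at full scale)
#' @return samples x n_components score matrix of class
#'   \code{reduced_features}, with attribute \code{"var_explained"}
#' @export
mds_reduce <- function(profile_matrix, n_components) {
  n_samples <- ncol(profile_matrix)
  if (n_components >= n_samples) {
    stopf("n_components (%d) must be < number of samples (%d)",
          n_components, n_samples)
  }
  scores <- pc_scores(profile_matrix, n_components)
  v <- apply(scores, 2L, stats::var)
  structure(scores, var_explained = v / max(sum(v), .Machine$double.eps),
            class = c("reduced_features", class(scores)))
}

glmnet_xy <- function(features) {
  x <- unclass(features)
  if (ncol(x) < 2L) stopf("need at least 2 feature columns for the L1 model")
  x
}

make_folds <- function(n, n_folds, strata = NULL) {
  if (is.null(strata)) return(sample(rep_len(seq_len(n_folds), n)))
  id <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    id[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  id
}

#' Repeated cross-validated age prediction accuracy
#'
#' Fits an L1-penalised (LASSO) linear model of age on the reduced profile
#' features under \code{n_repeats} randomisations of \code{n_folds}-fold
#' cross-validation. Within each training fold the penalty is tuned by an
#' inner cross-validation (\code{\link[glmnet]{cv.glmnet}}). Each sample's
#' predicted age is the mean of its out-of-fold predictions across repeats;
#' accuracy is the Spearman correlation between these mean predictions and
#' the true ages.
#'
#' @param features samples x components matrix (see \code{\link{mds_reduce}})
#' @param ages true ages
#' @param n_repeats CV randomisations (default 100)
#' @param n_folds outer folds (default 10)
#' @param seed RNG seed
#' @param inner_nfolds folds of the penalty-tuning inner CV (default 5)
#' @return list with \code{accuracy} (Spearman rho), \code{predictions}
#'   (per-sample mean out-of-fold prediction) and \code{n_repeats}
#' @export
cv_age_prediction <- function(features, ages, n_repeats = 100, n_folds = 10,
                              seed = 1L, inner_nfolds = 5) {
  x <- glmnet_xy(features)
  n <- nrow(x)
  if (length(ages) != n) stopf("features and ages are not aligned")
  if (stats::sd(ages) == 0) stopf("ages are constant; correlation undefined")
  if (n < n_folds) stopf("need at least n_folds samples")
  set.seed(seed)
  pred_sum <- numeric(n)
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(n, n_folds)
    pred <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], ages[tr],
                                 nfolds = inner_nfolds)
      pred[!tr] <- as.numeric(stats::predict(cvfit, x[!tr, , drop = FALSE],
                                             s = "lambda.min"))
    }
    pred_sum <- pred_sum + pred
  }
  predictions <- pred_sum / n_repeats
  list(accuracy = stats::cor(predictions, ages, method = "spearman"),
       predictions = predictions, n_repeats = n_repeats)
}

#' Old-vs-young classification accuracy from profile features
#'
#' Restricts the cohort to its age-extreme quantiles (oldest and youngest
#' \code{quantile} fractions), fits an L1-penalised logistic model under the
#' same repeated stratified cross-validation scheme as the age regression,
#' and reports the proportion of extreme samples whose averaged out-of-fold
#' class probability falls on the correct side of 0.5.
#'
#' @inheritParams cv_age_prediction
#' @param quantile fraction defining each class (default 0.25; 0.5 gives a
#'   median split using every sample)
#' @return list with \code{accuracy}, \code{labels}, \code{probabilities}
#' @export
old_young_classification <- function(features, ages, quantile = 0.25,
                                     n_repeats = 100, n_folds = 10,
                                     seed = 1L, inner_nfolds = 5) {
  x <- glmnet_xy(features)
  qs <- stats::quantile(ages, c(quantile, 1 - quantile), type = 7)
  young <- ages <= qs[1]
  old <- ages >= qs[2]
  keep <- young | old
  if (sum(young) < 8 || sum(old) < 8) {
    stopf("need >= 8 samples per class (young: %d, old: %d)",
          sum(young), sum(old))
  }
  x <- x[keep, , drop = FALSE]
  lab <- as.integer(old[keep])
  n <- nrow(x)
  set.seed(seed)
  prob_sum <- numeric(n)
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(n, n_folds, strata = lab)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(lab[tr])) < 2L) next
      cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], lab[tr],
                                 family = "binomial", nfolds = inner_nfolds)
      prob_sum[!tr] <- prob_sum[!tr] +
        as.numeric(stats::predict(cvfit, x[!tr, , drop = FALSE],
                                  s = "lambda.min", type = "response"))
    }
  }
  prob <- prob_sum / n_repeats
  list(accuracy = mean((prob > 0.5) == (lab == 1L)),
       labels = lab, probabilities = prob)
}

#' Select events robust to the stochastic permutation criterion
#'
#' Because the permutation null is stochastic, the detection pipeline is run
#' \code{n_runs} times with distinct permutation seeds; events called
#' significant in at least \code{min_detections} runs are retained (the
#' full-scale analysis used 10 runs and a floor of 8).
#'
#' @param psi PSI matrix
#' @param phenotypes phenotype data.frame
#' @param n_runs number of pipeline runs (default 10)
#' @param min_detections detection floor (default 8)
#' @param seed master seed; run r uses an independent permutation stream
#' @param ... passed to \code{\link{scan_age_association}}
#' @return character vector of robust event IDs, with per-event detection
#'   counts attached as attribute \code{"detections"}
#' @export
select_robust_events <- function(psi, phenotypes, n_runs = 10,
                                 min_detections = 8, seed = 1L, ...) {
  if (min_detections > n_runs) {
    stopf("min_detections (%d) exceeds n_runs (%d)", min_detections, n_runs)
  }
  counts <- NULL
  for (r in seq_len(n_runs)) {
    res <- scan_age_association(psi, phenotypes,
                                seed = derive_seed(seed, 1000L + r), ...)
    if (is.null(counts)) {
      counts <- stats::setNames(integer(nrow(res)), res$event_id)
    }
    counts[res$event_id[res$significant]] <-
      counts[res$event_id[res$significant]] + 1L
  }
  robust <- names(counts)[counts >= min_detections]
  attr(robust, "detections") <- counts
  robust
}

#' Relative-age z-scores for independent samples
#'
#' Fits, for each of \code{n_rounds} rounds, an L1-penalised age model on
#' the training samples' PSI values over the robust event set (penalty by
#' randomised cross-validation), predicts the test samples, and expresses
#' each test prediction as a z-score against that round's training
#' prediction distribution. Sentinel cells are imputed with the training row
#' mean in both matrices.
#'
#' @param train_psi,test_psi events x samples PSI matrices sharing the
#'   robust events
#' @param train_ages ages of the training samples
#' @param robust_events event IDs used as features
#' @param n_rounds fitting rounds (default 100)
#' @param seed RNG seed
#' @param inner_nfolds folds of the penalty-tuning CV (default 5)
#' @return list of class \code{relative_age_report}: \code{z} (test samples
#'   x rounds), \code{train_mean}, \code{train_sd} (per round)
#' @export
relative_age_zscores <- function(train_psi, train_ages, test_psi,
                                 robust_events, n_rounds = 100, seed = 1L,
                                 inner_nfolds = 5) {
  missing_ev <- setdiff(robust_events, rownames(test_psi))
  if (length(missing_ev)) {
    stopf("robust event(s) absent from test matrix: %s",
          paste(utils::head(missing_ev, 5), collapse = ", "))
  }
  if (length(robust_events) < 2L) {
    stopf("need at least 2 robust events to fit the model")
  }
  tr <- train_psi[robust_events, , drop = FALSE]
  te <- test_psi[robust_events, , drop = FALSE]
  tr_imp <- impute_sentinels(tr)
  row_mean <- rowMeans(tr_imp)
  te_imp <- te
  miss <- te_imp == PSI_SENTINEL | is.na(te_imp)
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)
    te_imp[idx] <- row_mean[idx[, 1L]]
  }
  x_tr <- t(tr_imp)
  x_te <- t(te_imp)
  set.seed(seed)
  z <- matrix(NA_real_, ncol(test_psi), n_rounds,
              dimnames = list(colnames(test_psi), NULL))
  tm <- ts_ <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    cvfit <- glmnet::cv.glmnet(x_tr, train_ages, nfolds = inner_nfolds)
    p_tr <- as.numeric(stats::predict(cvfit, x_tr, s = "lambda.min"))
    p_te <- as.numeric(stats::predict(cvfit, x_te, s = "lambda.min"))
    tm[r] <- mean(p_tr)
    ts_[r] <- stats::sd(p_tr)
    if (ts_[r] == 0) stopf("degenerate round %d: constant training predictions (penalty removed all features)", r)
    z[, r] <- (p_te - tm[r]) / ts_[r]
  }
  structure(list(z = z, train_mean = tm, train_sd = ts_),
            class = "relative_age_report")
}

#' Compare relative ages within sample pairs
#'
#' For each (younger, older) candidate pair, compares the two members'
#' z-score distributions across fitting rounds: the ordering call is the
#' sign of the median z difference, and a paired Wilcoxon signed-rank test
#' over rounds quantifies its stability.
#'
#' @param report a \code{relative_age_report}
#' @param pairs data.frame with columns \code{young} and \code{old} holding
#'   test sample IDs
#' @return data.frame with median z per member, the ordering call
#'   (\code{old_called_older}) and the Wilcoxon p-value
#' @export
compare_relative_ages <- function(report, pairs) {
  z <- report$z
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    zy <- z[pairs$young[i], ]
    zo <- z[pairs$old[i], ]
    wt <- suppressWarnings(stats::wilcox.test(zo, zy, paired = TRUE))
    data.frame(young = pairs$young[i], old = pairs$old[i],
               median_z_young = stats::median(zy),
               median_z_old = stats::median(zo),
               old_called_older = stats::median(zo) > stats::median(zy),
               p_wilcoxon = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
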