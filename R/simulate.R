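#' Simulate a donor cohort
#'
#' Draws ages uniformly over the configured range and gender as a fair coin
#' (coded 0/1). One sample per donor.
#'
#' @param config a \code{\link{sim_config}}
#' @return data.frame with columns donor_id, sample_id, age, gender
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_individuals
  donor <- sprintf("D%04d", seq_len(n))
  data.frame(
    donor_id = donor,
    sample_id = paste0(donor, "-S1"),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    gender = stats::rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE
  )
}

event_type_panel <- c("SE", "A5", "A3", "MX", "RI", "AF", "AL")

make_event_table <- function(config) {
  n <- config$n_events
  # roughly 70% exon skipping, the rest spread over the other six types;
  # only SE events receive flanking-region sequences downstream
  n_se <- ceiling(0.7 * n)
  type <- c(rep("SE", n_se),
            rep_len(event_type_panel[-1], n - n_se))
  gene <- sprintf("G%04d", rep_len(seq_len(config$n_genes), n))
  start <- 10000L + 5000L * seq_len(n)
  event_id <- sprintf("%s;%s:chr%d:%d-%d:%d-%d:%s",
                      gene, type, rep_len(1:22, n),
                      start, start + 150L, start + 1500L, start + 1650L,
                      rep_len(c("+", "-"), n))
  data.frame(event_id = event_id, gene_id = gene, type = type,
             stringsAsFactors = FALSE)
}

#' Simulate a PSI matrix with known ground truth
#'
#' Inclusion levels follow a logit-linear model: for event i and sample j,
#' \deqn{PSI_{ij} = logistic(\alpha_i + \beta_i age_j + \gamma_i gender_j +
#'   \sum_k \lambda_{ik} f_{kj} + \epsilon_{ij})}
#' with shared hidden factors f standing in for batch effects. A
#' \code{frac_age_assoc} fraction of events receives \eqn{\beta_i = \pm}
#' \code{effect_size}; the rest have \eqn{\beta_i = 0}. A
#' \code{missing_rate} fraction of cells, plus all events of dropped-out
#' (gene, sample) pairs, are set to the -1 sentinel.
#'
#' When \code{truth} is supplied (from a previous call), all event-level
#' parameters and factor loadings are reused and only factors, noise and
#' missingness are redrawn — this generates new samples from the same tissue
#' model, e.g. longitudinal follow-ups.
#'
#' @param cohort data.frame as from \code{\link{simulate_cohort}}
#' @param config a \code{\link{sim_config}}
#' @param truth optional ground truth to reuse
#' @param seed optional seed override (defaults to a stream derived from
#'   \code{config$seed})
#' @return list with \code{psi} (events x samples matrix, -1 sentinel) and
#'   \code{truth} (event table with is_age_assoc, beta_age, trend_class;
#'   alpha, gamma, loadings, factors)
#' @export
simulate_psi <- function(cohort, config, truth = NULL, seed = NULL) {
  validate_sim_config(config)
  if (nrow(cohort) == 0L) stopf("cohort is empty")
  set.seed(seed %||% derive_seed(config$seed, 2L))
  n <- nrow(cohort)
  mid <- mean(config$age_range)
  K <- config$n_hidden_factors

  if (is.null(truth)) {
    events <- make_event_table(config)
    m <- nrow(events)
    n_assoc <- round(config$frac_age_assoc * m)
    flagged <- sort(sample.int(m, n_assoc))
    beta <- numeric(m)
    beta[flagged] <- config$effect_size *
      sample(c(-1, 1), n_assoc, replace = TRUE)
    events$is_age_assoc <- seq_len(m) %in% flagged
    events$beta_age <- beta
    events$trend_class <- c("down", "stable", "up")[sign(beta) + 2]
    alpha0 <- stats::rnorm(m, 0, 0.8)
    gamma <- stats::rnorm(m, 0, config$gender_effect_sd)
    loadings <- if (K > 0) {
      matrix(stats::rnorm(m * K, 0, config$factor_sd), m, K)
    } else matrix(0, m, 0)
    truth <- list(events = events,
                  # intercept on the raw-age scale: alpha = alpha0 - beta*mid
                  alpha = alpha0 - beta * mid,
                  gamma = gamma,
                  loadings = loadings)
  } else {
    events <- truth$events
    m <- nrow(events)
    beta <- events$beta_age
  }

  factors <- if (K > 0) matrix(stats::rnorm(K * n), K, n) else matrix(0, 0, n)
  if (K > 0 && isTRUE(config$factor_age_orthogonal)) {
    factors <- t(stats::resid(stats::lm(t(factors) ~ cohort$age)))
  }
  eps <- matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
  eta <- truth$alpha +
    outer(beta, cohort$age) +
    outer(truth$gamma, cohort$gender) +
    truth$loadings %*% factors + eps
  psi <- inv_logit(eta)

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(m * n) < config$missing_rate, m, n)
    psi[miss] <- PSI_SENTINEL
  }
  if (config$gene_dropout_rate > 0) {
    genes <- unique(events$gene_id)
    drop <- matrix(stats::runif(length(genes) * n) < config$gene_dropout_rate,
                   length(genes), n, dimnames = list(genes, NULL))
    for (g in genes) {
      cols <- which(drop[g, ])
      if (length(cols)) psi[events$gene_id == g, cols] <- PSI_SENTINEL
    }
  }
  dimnames(psi) <- list(events$event_id, cohort$sample_id)
  truth$factors <- factors
  list(psi = psi, truth = truth)
}

#' Simulate gene and transcript expression with known ground truth
#'
#' Transcript expression is log-normal around a transcript baseline with
#' hidden factors and, for a \code{frac_gene_assoc} fraction of genes, a
#' log-linear age trend shared by all transcripts of the gene. A disjoint
#' \code{frac_ratio_assoc} fraction of genes are isoform-switch genes: their
#' first two transcripts trade off with age (a logistic mixing weight) while
#' total gene output stays flat, so the signal is visible to transcript and
#' transcript-ratio scans but cancels exactly at the gene level. Gene
#' expression is the column-wise sum of the gene's transcripts, exactly.
#'
#' @inheritParams simulate_psi
#' @return list with \code{gene} (genes x samples), \code{transcript}
#'   (transcripts x samples), \code{tx2gene} (named character vector) and
#'   \code{truth} (per-gene and per-transcript tables)
#' @export
simulate_expression <- function(cohort, config, seed = NULL) {
  validate_sim_config(config)
  if (nrow(cohort) == 0L) stopf("cohort is empty")
  set.seed(seed %||% derive_seed(config$seed, 3L))
  n <- nrow(cohort)
  G <- config$n_genes
  Tg <- config$n_transcripts_per_gene
  mid <- mean(config$age_range)
  age_c <- cohort$age - mid

  gene_id <- sprintf("G%04d", seq_len(G))
  n_gene_assoc <- round(config$frac_gene_assoc * G)
  n_ratio <- if (Tg >= 2) round(config$frac_ratio_assoc * G) else 0L
  pick <- sample.int(G, n_gene_assoc + n_ratio)
  gene_assoc <- pick[seq_len(n_gene_assoc)]
  ratio_genes <- pick[seq_len(n_ratio) + n_gene_assoc]
  beta_gene <- numeric(G)
  beta_gene[gene_assoc] <- config$expr_effect *
    sample(c(-1, 1), n_gene_assoc, replace = TRUE)

  tx_id <- sprintf("%s.T%d", rep(gene_id, each = Tg), rep(seq_len(Tg), G))
  tx2gene <- stats::setNames(rep(gene_id, each = Tg), tx_id)
  K <- config$n_hidden_factors
  factors <- if (K > 0) matrix(stats::rnorm(K * n), K, n) else matrix(0, 0, n)

  ntx <- G * Tg
  mu <- stats::rnorm(ntx, 3, 1)
  loadings <- if (K > 0) {
    matrix(stats::rnorm(ntx * K, 0, config$factor_sd), ntx, K)
  } else matrix(0, ntx, 0)
  eps <- matrix(stats::rnorm(ntx * n, 0, config$expr_noise_sd), ntx, n)
  log_tx <- mu + outer(rep(beta_gene, each = Tg), age_c) +
    loadings %*% factors + eps
  tx <- exp(log_tx)
  rownames(tx) <- tx_id

  tx_class <- rep("none", ntx)
  tx_class[rep(beta_gene != 0, each = Tg)] <- "gene"
  beta_tx <- rep(beta_gene, each = Tg)
  for (g in ratio_genes) {
    rows <- (g - 1L) * Tg + 1:2
    # total output of the two switching isoforms is flat in age
    total <- exp(3 + stats::rnorm(1) +
                   stats::rnorm(n, 0, config$expr_noise_sd))
    w <- inv_logit(stats::rnorm(1, 0, 0.5) + 0.03 * age_c)
    tx[rows[1], ] <- total * w
    tx[rows[2], ] <- total * (1 - w)
    tx_class[rows] <- "ratio"
    beta_tx[rows] <- c(0.03, -0.03)
  }

  gene <- rowsum(tx, group = rep(gene_id, each = Tg), reorder = TRUE)
  gene <- gene[gene_id, , drop = FALSE]
  colnames(tx) <- colnames(gene) <- cohort$sample_id

  truth <- list(
    genes = data.frame(gene_id = gene_id,
                       is_age_assoc = beta_gene != 0,
                       beta_age = beta_gene,
                       is_ratio_switch = seq_len(G) %in% ratio_genes,
                       stringsAsFactors = FALSE),
    transcripts = data.frame(tx_id = tx_id, gene_id = tx2gene[tx_id],
                             class = tx_class, beta_age = beta_tx,
                             stringsAsFactors = FALSE)
  )
  list(gene = gene, transcript = tx, tx2gene = tx2gene, truth = truth)
}

random_dna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Expand an IUPAC consensus into one concrete realisation
#' @keywords internal
realize_iupac <- function(consensus) {
  codes <- iupac_code_table()
  letters_ <- strsplit(consensus, "")[[1]]
  paste(vapply(letters_, function(b) {
    opts <- codes[[b]]
    if (is.null(opts)) stopf("invalid IUPAC symbol '%s'", b)
    sample(opts, 1)
  }, character(1)), collapse = "")
}

insert_motif <- function(seq, consensus, n_copies) {
  if (n_copies == 0L) return(seq)
  len <- nchar(seq)
  mlen <- nchar(consensus)
  if (mlen > len) return(seq)
  for (i in seq_len(n_copies)) {
    pos <- sample.int(len - mlen + 1L, 1L)
    substr(seq, pos, pos + mlen - 1L) <- realize_iupac(consensus)
  }
  seq
}

#' Simulate flanking-region sequences and splicing-factor expression
#'
#' For every exon-skipping event in \code{truth}, draws i.i.d. uniform
#' nucleotide sequences for the seven functional regions around the cassette
#' exon. Every motif in the configured set is inserted at a background
#' Poisson rate per region; the planted driver motif is inserted at the
#' elevated \code{driver_rate} in its configured region for events of its
#' configured trend class. The driver's splicing factor receives a
#' log-linear expression trend of sign \code{sf_trend_sign}; decoy factors
#' have no trend.
#'
#' @param truth ground truth from \code{\link{simulate_psi}} (trend classes
#'   are taken from the true event effects)
#' @param cohort cohort the SF expression is simulated for
#' @param config a \code{\link{sim_config}}
#' @param seed optional seed override
#' @return list with \code{regions} (data.frame event_id / region / seq) and
#'   \code{sf_expr} (SF genes x samples, natural-scale expression)
#' @export
simulate_regions_and_sf <- function(truth, cohort, config, seed = NULL) {
  validate_sim_config(config)
  set.seed(seed %||% derive_seed(config$seed, 4L))
  ev <- truth$events
  if (is.null(ev$trend_class)) stopf("truth lacks trend classes")
  se <- ev[ev$type == "SE", , drop = FALSE]
  if (nrow(se) == 0L) stopf("no exon-skipping events in truth")

  regs <- region_names()
  lens <- c(config$exon_flank_nt, config$intron_window_nt,
            config$intron_window_nt, config$cassette_exon_nt,
            config$intron_window_nt, config$intron_window_nt,
            config$exon_flank_nt)
  names(lens) <- regs

  out <- vector("list", length(regs))
  pd <- config$planted_driver
  ms <- config$motif_set
  # insert the planted driver's copies last: insertions overwrite sequence,
  # so planting first would let decoy insertions erode the configured
  # driver rate
  motif_order <- seq_len(nrow(ms))
  if (!is.null(pd)) {
    di <- which(ms$motif_id == pd$motif_id)
    motif_order <- c(setdiff(motif_order, di), di)
  }
  for (r in seq_along(regs)) {
    seqs <- random_dna(nrow(se), lens[r])
    for (k in motif_order) {
      rate <- rep(config$background_rate, nrow(se))
      if (!is.null(pd) && ms$motif_id[k] == pd$motif_id &&
          regs[r] == pd$region) {
        rate[se$trend_class == pd$trend_class] <- config$driver_rate
      }
      copies <- stats::rpois(nrow(se), rate)
      for (i in which(copies > 0L)) {
        seqs[i] <- insert_motif(seqs[i], ms$consensus[k], copies[i])
      }
    }
    out[[r]] <- data.frame(event_id = se$event_id, region = regs[r],
                           seq = seqs, stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(match(regions$event_id, se$event_id)), ]
  rownames(regions) <- NULL

  sf_genes <- unique(ms$sf_gene)
  n <- nrow(cohort)
  age_c <- cohort$age - mean(config$age_range)
  slope <- stats::setNames(numeric(length(sf_genes)), sf_genes)
  if (!is.null(pd)) {
    driver_sf <- ms$sf_gene[ms$motif_id == pd$motif_id][1]
    slope[driver_sf] <- config$sf_trend_sign * config$sf_effect
  }
  log_sf <- stats::rnorm(length(sf_genes), 3, 0.5) +
    outer(slope, age_c) +
    matrix(stats::rnorm(length(sf_genes) * n, 0, config$expr_noise_sd),
           length(sf_genes), n)
  sf_expr <- exp(log_sf)
  dimnames(sf_expr) <- list(sf_genes, cohort$sample_id)
  list(regions = regions, sf_expr = sf_expr)
}

#' Simulate binary disease labels
#'
#' Disease probability follows a logistic model on standardised age, gender,
#' the leading principal component of log gene expression, and the leading
#' principal component of the (sentinel-imputed) PSI matrix:
#' \deqn{P(D_j = 1) = logistic(a + b\,age_j + c\,gender_j + d\,GE_j +
#'   e\,PSI_j)}
#' where \eqn{e} is \code{config$disease_effect}; setting it to 0 yields the
#' null world in which splicing carries no information about disease beyond
#' the other covariates.
#'
#' @param cohort cohort data.frame
#' @param psi PSI matrix (events x samples, -1 sentinel allowed)
#' @param expr gene expression matrix (genes x samples)
#' @param config a \code{\link{sim_config}}
#' @param seed optional seed override
#' @return integer 0/1 vector named by sample_id, with the generating linear
#'   predictor attached as attribute \code{"linpred"}
#' @export
simulate_disease <- function(cohort, psi, expr, config, seed = NULL) {
  validate_sim_config(config)
  set.seed(seed %||% derive_seed(config$seed, 5L))
  cf <- config$disease_coefs
  psi_comp <- scale(pc_scores(impute_sentinels(psi), 1)[, 1])[, 1]
  ge_comp <- scale(pc_scores(log2(expr + 1), 1)[, 1])[, 1]
  age_s <- scale(cohort$age)[, 1]
  eta <- cf$intercept + cf$age * age_s + cf$gender * cohort$gender +
    cf$expr * ge_comp + config$disease_effect * psi_comp
  d <- stats::rbinom(nrow(cohort), 1L, inv_logit(eta))
  names(d) <- cohort$sample_id
  attr(d, "linpred") <- eta
  d
}
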