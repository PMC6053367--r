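#' Default splicing-factor motif table used by the simulator
#'
#' A small panel of degenerate (IUPAC) RNA-binding-protein motifs written in
#' DNA alphabet. The first entry is a PTBP1-style polypyrimidine motif; the
#' remainder act as decoys unless configured otherwise.
#'
#' @return data.frame with columns \code{motif_id}, \code{sf_gene},
#'   \code{consensus}
#' @export
default_motif_set <- function() {
  data.frame(
    motif_id = c("M_PTBP1", "M_SRSF1", "M_HNRNPA1", "M_RBFOX1", "M_QKI",
                 "M_NOVA1", "M_MBNL1", "M_TIA1"),
    sf_gene  = c("PTBP1", "SRSF1", "HNRNPA1", "RBFOX1", "QKI",
                 "NOVA1", "MBNL1", "TIA1"),
    consensus = c("YTCYCY", "RGAAGA", "TAGGGT", "TGCATG", "ACTAAY",
                  "YCAY", "YGCTKY", "TTTTTR"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes the synthetic world from which PSI matrices, expression
#' matrices, flanking-region sequences, splicing-factor profiles and disease
#' labels are generated. Defaults model one mid-sized bulk tissue cohort:
#' 150 donors aged 20-70, events whose inclusion follows a logit-linear age
#' trend (the age effect, when planted, moves PSI by roughly 0.2 over the
#' age window), a few batch-like hidden factors shared across events, and a
#' SUPPA-style -1 sentinel marking unquantifiable cells.
#'
#' @param n_individuals number of donors (one sample per donor per tissue)
#' @param age_range numeric length-2, min and max age in years
#' @param n_events number of splicing events
#' @param frac_age_assoc fraction of events given a true age effect
#' @param effect_size absolute age effect on the logit-PSI scale, per year
#' @param n_hidden_factors number of batch-like hidden confounders
#' @param factor_sd standard deviation of per-event factor loadings
#' @param noise_sd residual standard deviation on the logit scale
#' @param factor_age_orthogonal when TRUE, hidden-factor sample scores are
#'   residualised on age so the planted batch structure is exactly
#'   uncorrelated with age in the realised cohort (isolates variance
#'   inflation from chance confounding in calibration experiments)
#' @param missing_rate fraction of (event, sample) cells set to the -1
#'   sentinel, uniformly at random
#' @param gene_dropout_rate fraction of (gene, sample) pairs whose events are
#'   all set to -1, emulating "gene not expressed" missingness
#' @param gender_effect_sd standard deviation of per-event gender effects
#'   (logit scale)
#' @param n_genes,n_transcripts_per_gene size of the expression universe
#' @param frac_gene_assoc fraction of genes with an age trend shared by all
#'   their transcripts
#' @param frac_ratio_assoc fraction of genes whose transcripts trade off with
#'   age while total gene output stays flat (isoform-switch genes)
#' @param expr_effect absolute age effect on log expression, per year
#' @param expr_noise_sd residual sd of log expression
#' @param motif_set data.frame of motif_id / sf_gene / consensus
#' @param planted_driver list(motif_id, region, trend_class) naming the motif
#'   enriched near one trend class of cassette exons, or NULL for the null
#'   world
#' @param driver_rate expected planted-motif copies per region for events of
#'   the driver's trend class
#' @param background_rate expected motif copies per region otherwise
#' @param exon_flank_nt,intron_window_nt,cassette_exon_nt region lengths
#' @param sf_trend_sign sign of the driver splicing factor's own expression
#'   trend with age (-1: decreases, matching a repressor losing activity)
#' @param sf_effect absolute SF log-expression age slope, per year
#' @param disease_effect log-odds of disease per standard deviation of the
#'   leading PSI component (0 gives the null world for LLR calibration)
#' @param disease_coefs named list of the remaining disease log-odds terms:
#'   intercept, age (per sd), gender, expr (per sd of leading expression
#'   component)
#' @param seed master RNG seed
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_individuals = 150,
                       age_range = c(20, 70),
                       n_events = 500,
                       frac_age_assoc = 0.1,
                       effect_size = 0.016,
                       n_hidden_factors = 3,
                       factor_sd = 0.5,
                       factor_age_orthogonal = FALSE,
                       noise_sd = 0.5,
                       missing_rate = 0.05,
                       gene_dropout_rate = 0,
                       gender_effect_sd = 0.1,
                       n_genes = 100,
                       n_transcripts_per_gene = 3,
                       frac_gene_assoc = 0.1,
                       frac_ratio_assoc = 0.1,
                       expr_effect = 0.01,
                       expr_noise_sd = 0.3,
                       motif_set = default_motif_set(),
                       planted_driver = list(motif_id = "M_PTBP1",
                                             region = "upstream_intron_3p",
                                             trend_class = "up"),
                       driver_rate = 3,
                       background_rate = 1,
                       exon_flank_nt = 100,
                       intron_window_nt = 200,
                       cassette_exon_nt = 150,
                       sf_trend_sign = -1,
                       sf_effect = 0.01,
                       disease_effect = 0.8,
                       disease_coefs = list(intercept = 0, age = 0.5,
                                            gender = 0.3, expr = 0.5),
                       seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, age_range = age_range,
    n_events = n_events, frac_age_assoc = frac_age_assoc,
    effect_size = effect_size, n_hidden_factors = n_hidden_factors,
    factor_sd = factor_sd, factor_age_orthogonal = factor_age_orthogonal,
    noise_sd = noise_sd,
    missing_rate = missing_rate, gene_dropout_rate = gene_dropout_rate,
    gender_effect_sd = gender_effect_sd,
    n_genes = n_genes, n_transcripts_per_gene = n_transcripts_per_gene,
    frac_gene_assoc = frac_gene_assoc, frac_ratio_assoc = frac_ratio_assoc,
    expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
    motif_set = motif_set, planted_driver = planted_driver,
    driver_rate = driver_rate, background_rate = background_rate,
    exon_flank_nt = exon_flank_nt, intron_window_nt = intron_window_nt,
    cassette_exon_nt = cassette_exon_nt,
    sf_trend_sign = sf_trend_sign, sf_effect = sf_effect,
    disease_effect = disease_effect, disease_coefs = disease_coefs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stopf("invalid sim_config: %s", msg)
  chk(is.numeric(cfg$age_range) && length(cfg$age_range) == 2 &&
        cfg$age_range[1] < cfg$age_range[2],
      "age_range must be (min, max) with min < max")
  chk(cfg$frac_age_assoc >= 0 && cfg$frac_age_assoc <= 1,
      "frac_age_assoc must be in [0, 1]")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate must be in [0, 1)")
  for (f in c("n_individuals", "n_events", "n_genes",
              "n_transcripts_per_gene")) {
    chk(cfg[[f]] >= 1, sprintf("%s must be >= 1", f))
  }
  chk(cfg$n_hidden_factors >= 0, "n_hidden_factors must be >= 0")
  chk(cfg$noise_sd >= 0 && cfg$factor_sd >= 0, "sd parameters must be >= 0")
  ms <- cfg$motif_set
  chk(is.data.frame(ms) &&
        all(c("motif_id", "sf_gene", "consensus") %in% names(ms)),
      "motif_set needs motif_id / sf_gene / consensus columns")
  if (!is.null(cfg$planted_driver)) {
    pd <- cfg$planted_driver
    chk(all(c("motif_id", "region", "trend_class") %in% names(pd)),
        "planted_driver needs motif_id, region, trend_class")
    chk(pd$region %in% region_names(),
        sprintf("unknown planted_driver region '%s'", pd$region))
    chk(pd$trend_class %in% c("up", "stable", "down"),
        "planted_driver trend_class must be up/stable/down")
    chk(pd$motif_id %in% ms$motif_id,
        "planted_driver motif_id absent from motif_set")
  }
  invisible(cfg)
}

#' Names of the seven functional regions around a cassette exon
#'
#' Ordered 5' to 3' on the sense strand: the 3' end of the upstream exon,
#' both ends of the upstream intron, the cassette exon itself, both ends of
#' the downstream intron, and the 5' end of the downstream exon.
#' @return character vector of length 7
#' @export
region_names <- function() {
  c("upstream_exon_3p", "upstream_intron_5p", "upstream_intron_3p",
    "cassette_exon", "downstream_intron_5p", "downstream_intron_3p",
    "downstream_exon_5p")
}
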