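#' @keywords internal
iupac_code_table <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

# Bit encoding A=1 C=2 G=4 T=8; an 'N' in the *subject* encodes to 0 so it
# can never satisfy a pattern position, while pattern letters expand to the
# union of their IUPAC bits.
iupac_bits <- function() {
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(iupac_code_table(), function(opts) sum(base_bits[opts]),
         integer(1))
}

#' Count IUPAC motif occurrences in sequences
#'
#' Counts every (possibly overlapping) position at which the degenerate
#' consensus matches. Subject letters are fixed nucleotides: an \code{N} in
#' the sequence never matches any pattern position, while pattern letters
#' follow IUPAC degeneracy (e.g. \code{Y} matches C or T).
#'
#' @param seqs character vector of sequences over A/C/G/T/N
#' @param consensus IUPAC consensus string (uppercase)
#' @return integer vector of counts, one per sequence
#' @export
count_iupac <- function(seqs, consensus) {
  bits <- iupac_bits()
  pat <- strsplit(toupper(consensus), "")[[1]]
  if (length(pat) == 0L) stopf("empty consensus")
  if (!all(pat %in% names(bits))) {
    stopf("invalid IUPAC symbol(s): %s",
          paste(unique(pat[!pat %in% names(bits)]), collapse = ", "))
  }
  pbits <- bits[pat]
  m <- length(pat)
  vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    sb <- integer(length(ch))
    known <- ch %in% c("A", "C", "G", "T")
    sb[known] <- bits[ch[known]]        # N and anything else stays 0
    L <- length(sb)
    if (L < m) return(0L)
    ok <- rep(TRUE, L - m + 1L)
    for (k in seq_len(m)) {
      ok <- ok & bitwAnd(sb[k:(L - m + k)], pbits[k]) > 0L
    }
    sum(ok)
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-region motif counts for one event
#'
#' @param regions named character vector of the event's seven region
#'   sequences (names as in \code{\link{region_names}}), or a one-event
#'   subset of the long regions data.frame
#' @param motif list or one-row data.frame with \code{motif_id} and
#'   \code{consensus}
#' @return named integer vector of per-region counts
#' @export
count_motif_occurrences <- function(regions, motif) {
  if (is.data.frame(regions)) {
    regions <- stats::setNames(regions$seq, regions$region)
  }
  stats::setNames(count_iupac(unname(regions), motif$consensus),
                  names(regions))
}

#' Build the events x regions motif-count table
#'
#' @param regions long data.frame (event_id, region, seq)
#' @param motifs motif data.frame (motif_id, sf_gene, consensus)
#' @return long data.frame event_id / region / motif_id / count
#' @export
count_motif_table <- function(regions, motifs) {
  out <- lapply(seq_len(nrow(motifs)), function(k) {
    data.frame(event_id = regions$event_id, region = regions$region,
               motif_id = motifs$motif_id[k],
               count = count_iupac(regions$seq, motifs$consensus[k]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify events into age-trend classes
#'
#' Significant events become "up" or "down" by the sign of their age
#' coefficient. The "stable" background class contains tested,
#' non-significant events whose nominal age p-value is at least
#' \code{stable_p_floor}, keeping the background clearly null; tested events
#' in the buffer zone (non-significant but p below the floor) belong to no
#' class.
#'
#' @param results association result data.frame from the PSI scan
#' @param stable_p_floor nominal-p floor for the stable class (default 0.5)
#' @return named character vector (event_id -> up/stable/down), NA for
#'   unclassified events
#' @export
classify_trend <- function(results, stable_p_floor = 0.5) {
  cls <- rep(NA_character_, nrow(results))
  cls[results$significant & results$direction > 0] <- "up"
  cls[results$significant & results$direction < 0] <- "down"
  cls[results$tested & !results$significant &
        results$p >= stable_p_floor] <- "stable"
  stats::setNames(cls, results$event_id)
}

#' Motif enrichment between trend classes
#'
#' For every (motif, region) cell and each contrast — inclusion-up versus
#' stable, and inclusion-down versus stable — compares the per-event motif
#' counts with a two-sided rank-sum (Wilcoxon) test, then applies BH
#' correction across the full scan. Direction is the sign of the difference
#' in median counts (trend class minus stable), with the mean difference
#' breaking median ties.
#'
#' @param counts long count table from \code{\link{count_motif_table}}
#' @param classes named event -> class vector from
#'   \code{\link{classify_trend}}
#' @param fdr BH threshold for the enrichment call (default 0.1)
#' @param min_events minimum events per class (default 10)
#' @return data.frame motif_id / region / comparison / p / q / direction /
#'   significant
#' @export
motif_enrichment_scan <- function(counts, classes, fdr = 0.1,
                                  min_events = 10) {
  ev_class <- classes[counts$event_id]
  for (cl in c("up", "stable", "down")) {
    n_cl <- length(unique(counts$event_id[!is.na(ev_class) &
                                            ev_class == cl]))
    if (n_cl < min_events) {
      stopf("class '%s' has %d events; need >= %d", cl, n_cl, min_events)
    }
  }
  grid <- expand.grid(motif_id = unique(counts$motif_id),
                      region = unique(counts$region),
                      comparison = c("up-vs-stable", "down-vs-stable"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cls1 <- sub("-vs-stable", "", grid$comparison[i])
    sel <- counts$motif_id == grid$motif_id[i] &
      counts$region == grid$region[i]
    x <- counts$count[sel & !is.na(ev_class) & ev_class == cls1]
    y <- counts$count[sel & !is.na(ev_class) & ev_class == "stable"]
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    dd <- stats::median(x) - stats::median(y)
    if (dd == 0) dd <- mean(x) - mean(y)
    data.frame(grid[i, , drop = FALSE], p = p,
               direction = as.integer(sign(dd)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- benjamini_hochberg(res$p)
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res[, c("motif_id", "region", "comparison", "p", "q", "direction",
          "significant")]
}

mechanism_note <- function(comparison, enr_direction, sf_sign) {
  cls <- sub("-vs-stable", "", comparison)
  sf_txt <- if (sf_sign < 0) "SF-down" else "SF-up"
  incl <- if (cls == "up") "inclusion-up" else "inclusion-down"
  # a factor whose level falls while its motif marks inclusion-up exons acts
  # like a repressor losing activity (the PTBP1 pattern); the other sign
  # combinations follow the same logic
  role <- if ((cls == "up") == (sf_sign < 0)) "repressor" else "activator"
  sprintf("%s + motif near %s exons: consistent with %s %s",
          sf_txt, incl, role,
          if (sf_sign < 0) "losing activity with age"
          else "gaining activity with age")
}

#' Nominate upstream splicing-factor drivers
#'
#' A splicing factor is called a candidate driver of age-associated splicing
#' when (i) its own expression is significantly associated with age
#' (nominal p <= \code{sf_p} under the same confounder-adjusted model,
#' fitted on log2 transcript-level expression) and (ii) at least one of its
#' motifs is enriched (q <= \code{fdr}) in some region/contrast of the
#' enrichment scan. Factors absent from the expression matrix are reported
#' as untestable rather than failing the run.
#'
#' @param enrichments result of \code{\link{motif_enrichment_scan}}
#' @param sf_expr splicing factor (transcript-level) expression matrix,
#'   factors x samples, natural scale
#' @param phenotypes phenotype data.frame aligned to the expression columns
#' @param motif_set motif table mapping motifs to factors
#' @param sf_p age-association p threshold for the factor (default 0.05)
#' @param fdr enrichment q threshold (default 0.1)
#' @param factors optional \code{hidden_factors} for the SF fit
#' @param min_samples usable-sample floor for the SF fit (default 50)
#' @return data.frame of driver calls: sf_gene, sf_beta_age, sf_p, motif_id,
#'   region, comparison, enrichment_q, mechanism; untestable factors carry
#'   NA statistics and a note
#' @export
identify_drivers <- function(enrichments, sf_expr, phenotypes, motif_set,
                             sf_p = 0.05, fdr = 0.1, factors = NULL,
                             min_samples = 50) {
  hits <- enrichments[enrichments$q <= fdr, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(sf_gene = character(0), sf_beta_age = numeric(0),
                      sf_p = numeric(0), motif_id = character(0),
                      region = character(0), comparison = character(0),
                      enrichment_q = numeric(0), mechanism = character(0),
                      stringsAsFactors = FALSE))
  }
  hits$sf_gene <- motif_set$sf_gene[match(hits$motif_id, motif_set$motif_id)]
  ph <- phenotypes
  if (!is.null(colnames(sf_expr)) && all(colnames(sf_expr) %in% ph$sample_id)) {
    ph <- ph[match(colnames(sf_expr), ph$sample_id), , drop = FALSE]
  }
  out <- lapply(unique(hits$sf_gene), function(sf) {
    hh <- hits[hits$sf_gene == sf, , drop = FALSE]
    hh <- hh[order(hh$q), , drop = FALSE]
    if (!sf %in% rownames(sf_expr)) {
      return(data.frame(sf_gene = sf, sf_beta_age = NA_real_,
                        sf_p = NA_real_, motif_id = hh$motif_id[1],
                        region = hh$region[1], comparison = hh$comparison[1],
                        enrichment_q = hh$q[1],
                        mechanism = "untestable: factor absent from expression matrix",
                        stringsAsFactors = FALSE))
    }
    fit <- fit_age_model(log2(sf_expr[sf, ] + 1), ph$age, ph$gender,
                         factors = factors, min_samples = min_samples)
    if (!fit$tested || fit$p_age > sf_p) return(NULL)
    data.frame(sf_gene = sf, sf_beta_age = fit$beta_age, sf_p = fit$p_age,
               motif_id = hh$motif_id[1], region = hh$region[1],
               comparison = hh$comparison[1], enrichment_q = hh$q[1],
               mechanism = mechanism_note(hh$comparison[1], hh$direction[1],
                                          sign(fit$beta_age)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sf_gene = character(0), sf_beta_age = numeric(0),
                      sf_p = numeric(0), motif_id = character(0),
                      region = character(0), comparison = character(0),
                      enrichment_q = numeric(0), mechanism = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fisher overlap test of pipeline targets against an external target list
#'
#' Tests whether genes nominated by the pipeline are over-represented in an
#' externally derived target set (e.g. CLIP-defined splicing-factor
#' targets), within a common background universe, via a two-sided Fisher
#' exact test on the 2x2 membership table.
#'
#' @param pipeline_targets,external_targets gene sets (subsets of
#'   \code{background})
#' @param background background gene universe
#' @return list with \code{odds_ratio} (conditional MLE; \code{Inf} for
#'   degenerate tables), \code{p_value}, \code{table}, and an optional
#'   \code{note}
#' @export
target_overlap_test <- function(pipeline_targets, external_targets,
                                background) {
  background <- unique(background)
  if (length(background) == 0L) stopf("background gene set is empty")
  a <- unique(pipeline_targets)
  b <- unique(external_targets)
  if (!all(a %in% background) || !all(b %in% background)) {
    stopf("target sets must be subsets of the background")
  }
  tab <- matrix(c(length(intersect(a, b)),
                  length(setdiff(a, b)),
                  length(setdiff(b, a)),
                  length(setdiff(background, union(a, b)))),
                2L, 2L,
                dimnames = list(pipeline = c("in", "out"),
                                external = c("in", "out")))
  if (all(tab[1, 2] == 0, tab[2, 1] == 0) &&
      (tab[2, 2] == 0 || tab[1, 1] == 0)) {
    return(list(odds_ratio = Inf, p_value = 1, table = tab,
                note = "degenerate table: sets coincide; odds ratio undefined, reported as Inf"))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab,
       note = NULL)
}
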