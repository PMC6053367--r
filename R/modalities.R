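#' Compute within-gene transcript ratios
#'
#' For transcript x of gene g in sample j, the ratio is
#' \eqn{TR = T_x / \sum_{x' \in g} T_{x'}}. Gene-sample cells whose
#' transcripts sum to zero are masked with the -1 sentinel (the ratio is
#' undefined there, mirroring the unexpressed-gene convention).
#'
#' @param transcript_matrix transcripts x samples expression matrix
#' @param tx2gene named character vector mapping transcript IDs to gene IDs
#' @return transcripts x samples ratio matrix with -1 sentinels
#' @export
compute_transcript_ratios <- function(transcript_matrix, tx2gene) {
  ids <- rownames(transcript_matrix)
  if (is.null(ids)) stopf("transcript matrix must have rownames")
  if (!all(ids %in% names(tx2gene))) {
    miss <- setdiff(ids, names(tx2gene))
    stopf("transcript(s) not mapped to a gene: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  genes <- tx2gene[ids]
  totals <- rowsum(transcript_matrix, group = genes, reorder = FALSE)
  denom <- totals[match(genes, rownames(totals)), , drop = FALSE]
  tr <- transcript_matrix / denom
  tr[denom == 0] <- PSI_SENTINEL
  tr
}

#' Run the age-association scan for one modality
#'
#' Dispatches the shared detection core over the four profiled modalities:
#' \describe{
#'   \item{psi}{event PSI values, confounders from the PSI matrix}
#'   \item{gene}{log2(TPM+1) gene expression, confounders from the gene
#'     matrix}
#'   \item{transcript}{log2(TPM+1) transcript expression, confounders from
#'     the transcript matrix}
#'   \item{ratio}{within-gene transcript ratios, confounders from the
#'     transcript matrix}
#' }
#' Expression responses are log-transformed before fitting to stabilise
#' variance; ratios and PSI are fitted on their natural \[0,1\] scale.
#'
#' @param modality one of "psi", "gene", "transcript", "ratio"
#' @param matrices list with elements \code{psi}, \code{gene},
#'   \code{transcript} (and \code{tx2gene} for the ratio scan) as needed
#' @param phenotypes phenotype data.frame (sample_id, age, gender)
#' @param ... passed to \code{\link{scan_age_association}}
#' @return an association result data.frame
#' @export
run_modality_scan <- function(modality = c("psi", "gene", "transcript",
                                           "ratio"),
                              matrices, phenotypes, ...) {
  modality <- match.arg(modality)
  log1p2 <- function(x) log2(x + 1)
  switch(modality,
    psi = scan_age_association(matrices$psi, phenotypes, ...),
    gene = {
      g <- log1p2(matrices$gene)
      scan_age_association(g, phenotypes, factor_source = g, ...)
    },
    transcript = {
      tx <- log1p2(matrices$transcript)
      scan_age_association(tx, phenotypes, factor_source = tx, ...)
    },
    ratio = {
      tr <- compute_transcript_ratios(matrices$transcript, matrices$tx2gene)
      scan_age_association(tr, phenotypes,
                           factor_source = log1p2(matrices$transcript), ...)
    }
  )
}

#' Overlap structure of the four modalities' age-associated gene sets
#'
#' Maps each modality's significant features to genes and reports the full
#' membership table, all intersection counts over the non-empty modality
#' combinations, and the genes unique to each modality.
#'
#' @param result_sets named list of association result data.frames (or
#'   character vectors of already-mapped genes)
#' @param feature_to_gene named character vector mapping feature IDs to gene
#'   IDs; features absent from the map are passed through unchanged
#' @return list with \code{membership} (data.frame, gene_id plus one flag
#'   column per modality),
#'   \code{intersections} (data.frame combo / count) and \code{unique_genes}
#'   (named list)
#' @export
modality_overlap <- function(result_sets, feature_to_gene = NULL) {
  to_genes <- function(x) {
    feats <- if (is.data.frame(x)) x$event_id[x$significant] else x
    if (!is.null(feature_to_gene)) {
      mapped <- feature_to_gene[feats]
      feats <- ifelse(is.na(mapped), feats, mapped)
    }
    unique(feats)
  }
  sets <- lapply(result_sets, to_genes)
  all_genes <- sort(unique(unlist(sets)))
  flags <- lapply(sets, function(s) all_genes %in% s)
  membership <- data.frame(gene_id = all_genes, flags, check.names = FALSE,
                           stringsAsFactors = FALSE)

  nms <- names(sets)
  combos <- unlist(lapply(seq_along(nms), function(k) {
    utils::combn(nms, k, simplify = FALSE)
  }), recursive = FALSE)
  inter <- data.frame(
    combo = vapply(combos, paste, character(1), collapse = "&"),
    count = vapply(combos, function(cc) {
      length(Reduce(intersect, sets[cc]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  uniq <- lapply(nms, function(nm) {
    setdiff(sets[[nm]], unlist(sets[setdiff(nms, nm)]))
  })
  names(uniq) <- nms
  list(membership = membership, intersections = inter, unique_genes = uniq)
}

#' Map event IDs of the form "gene;TYPE:chr:a-b:c-d:strand" to genes
#'
#' IDs that do not follow the pattern are returned unchanged.
#' @param event_ids character vector
#' @return named character vector of gene IDs
#' @export
event_to_gene <- function(event_ids) {
  genes <- sub(";.*$", "", event_ids)
  stats::setNames(genes, event_ids)
}
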