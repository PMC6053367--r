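#' Parse SUPPA-style event identifiers
#'
#' IDs of the form \code{"gene;TYPE:chr:a-b:c-d:strand"} are split into
#' their parts; IDs not matching the pattern yield NA fields and are treated
#' as opaque downstream. Coordinates are kept as printed (1-based
#' inclusive); no arithmetic is performed on them.
#'
#' @param event_ids character vector
#' @return data.frame with event_id, gene, type, chrom, coords, strand
#' @export
parse_event_id <- function(event_ids) {
  pat <- "^([^;]+);([A-Z0-9]+):([^:]+):([0-9]+-[0-9]+):([0-9]+-[0-9]+):([+-])$"
  ok <- grepl(pat, event_ids)
  out <- data.frame(event_id = event_ids,
                    gene = NA_character_, type = NA_character_,
                    chrom = NA_character_, coords = NA_character_,
                    strand = NA_character_, stringsAsFactors = FALSE)
  if (any(ok)) {
    m <- regmatches(event_ids[ok], regexec(pat, event_ids[ok]))
    m <- do.call(rbind, m)
    out$gene[ok] <- m[, 2]
    out$type[ok] <- m[, 3]
    out$chrom[ok] <- m[, 4]
    out$coords[ok] <- paste(m[, 5], m[, 6], sep = ":")
    out$strand[ok] <- m[, 7]
  }
  out
}

#' Write a PSI (or expression) matrix as tab-delimited text
#'
#' First column holds feature IDs, remaining columns one sample each; -1
#' sentinels are preserved verbatim.
#'
#' @param mat features x samples matrix with dimnames
#' @param path output file
#' @export
write_psi_table <- function(mat, path) {
  df <- data.frame(event_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSI matrix from tab-delimited text
#'
#' Validates that every value lies in \[0, 1\] or equals the -1 sentinel and
#' that event IDs are unique; the parsed event annotation (for IDs following
#' the \code{"gene;TYPE:..."} pattern) is attached as attribute
#' \code{"annotation"}.
#'
#' @param path tab-delimited file: header of sample IDs, first column event
#'   IDs
#' @return events x samples numeric matrix
#' @export
read_psi_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate event ID(s): %s",
          paste(utils::head(unique(ids[duplicated(ids)]), 3),
                collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric values in %s", path)
  bad <- which(!(mat == PSI_SENTINEL | (mat >= 0 & mat <= 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("value %g outside [0,1] and != -1 at event '%s', sample '%s'",
          mat[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
          colnames(mat)[bad[1, 2]])
  }
  rownames(mat) <- ids
  attr(mat, "annotation") <- parse_event_id(ids)
  mat
}

#' Read an expression matrix (TSV, same layout as the PSI table)
#' @param path tab-delimited file
#' @return features x samples numeric matrix
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read the phenotype table
#'
#' Columns: sample_id, donor_id, age, gender and, when present, disease.
#' @param phenotypes data.frame
#' @param path file path
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "gender")
  if (!all(need %in% names(ph))) {
    stopf("phenotype table must have columns %s", paste(need, collapse = ", "))
  }
  if ("disease" %in% names(ph) &&
      !all(ph$disease %in% c(0L, 1L, NA))) {
    stopf("disease column must be 0/1")
  }
  ph
}

#' Write / read cassette-exon region sequences as FASTA
#'
#' Headers are \code{"eventID|regionName"}; sequences are written on the
#' gene's sense strand.
#' @param regions long data.frame (event_id, region, seq)
#' @param path FASTA path
#' @export
write_regions_fasta <- function(regions, path) {
  seqs <- Biostrings::DNAStringSet(regions$seq)
  names(seqs) <- paste(regions$event_id, regions$region, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_regions_fasta
#' @export
read_regions_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  pos <- regexpr("\\|[^|]*$", nm)
  data.frame(event_id = substr(nm, 1L, pos - 1L),
             region = substr(nm, pos + 1L, nchar(nm)),
             seq = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read a motif table (motif_id, sf_gene, consensus)
#' @param path tab-delimited file
#' @return data.frame
#' @export
read_motif_table <- function(path) {
  ms <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_id", "sf_gene", "consensus")
  if (!all(need %in% names(ms))) {
    stopf("motif table must have columns %s", paste(need, collapse = ", "))
  }
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", ms$consensus)
  if (any(bad)) {
    stopf("invalid IUPAC consensus: %s",
          paste(utils::head(ms$consensus[bad], 3), collapse = ", "))
  }
  ms
}

#' Write ground truth (or any result list) as JSON
#' @param x list to serialise
#' @param path JSON path
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
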