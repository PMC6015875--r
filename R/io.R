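#' Read a panel of mature miRNAs from FASTA
#'
#' Sequences may use the RNA or DNA alphabet; T is normalised to U.
#'
#' @param path FASTA file of mature miRNA sequences, 5'->3'.
#' @return list of [mature_mirna].
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    mature_mirna(nms[i], as.character(set[[i]]))
  })
}

#' Read 3'UTR regions from FASTA
#'
#' The description line may carry `offset=<int>` giving the 1-based
#' transcript coordinate of the region's first base (default 1), so that
#' cloned fragments report sites in full-transcript numbering.
#'
#' @param path FASTA file of UTR sequences (DNA alphabet; U normalised).
#' @return list of [utr_region].
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  offs <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("offset=\\d+", h))
    if (length(m)) as.integer(sub("offset=", "", m)) else 1L
  }, integer(1), USE.NAMES = FALSE)
  lapply(seq_along(set), function(i) {
    utr_region(ids[i], as.character(set[[i]]), offs[i])
  })
}

#' Write UTR regions to FASTA
#'
#' Non-default offsets are recorded as `offset=<int>` on the description
#' line, so a write/read round trip preserves transcript numbering.
#'
#' @param utrs a [utr_region] or list of them.
#' @param path output FASTA path.
#' @export
write_utr_fasta <- function(utrs, path) {
  if (inherits(utrs, "utr_region")) utrs <- list(utrs)
  seqs <- Biostrings::DNAStringSet(vapply(utrs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(utrs, function(u) {
    if (u$offset != 1L) paste0(u$transcript_id, " offset=", u$offset)
    else u$transcript_id
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a mature-miRNA count matrix
#'
#' Tab-separated, first column miRNA ids, header row sample ids.
#'
#' @param path TSV path.
#' @return integer matrix, miRNAs in rows, samples in columns.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_count_matrix(m)
  m
}

#' Read the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `clone_id`, `age_group`
#' (young/old), `pd_value`, `pd_group` (low/high).
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  meta
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
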